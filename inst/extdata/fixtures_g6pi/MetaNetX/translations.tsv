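from_namespace	from_id	to_namespace	to_id
rhea	11816	kegg_reaction	R00771
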