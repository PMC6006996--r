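namespace	id	quantity_type	value	unit	compound	ph	temperature_k	organism	reference
kegg_reaction	R00771	keq	0.361	dimensionless					eQuilibrator
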