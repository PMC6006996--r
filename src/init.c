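#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_cmrl_set_model(SEXP model);
SEXP C_cmrl_flux(SEXP state);
SEXP C_cmrl_rhs(SEXP state);
void C_cmrl_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

static const R_CallMethodDef callMethods[] = {
    {"C_cmrl_set_model", (DL_FUNC) &C_cmrl_set_model, 1},
    {"C_cmrl_flux",      (DL_FUNC) &C_cmrl_flux,      1},
    {"C_cmrl_rhs",       (DL_FUNC) &C_cmrl_rhs,       1},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"C_cmrl_derivs", (DL_FUNC) &C_cmrl_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_dynamet(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
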