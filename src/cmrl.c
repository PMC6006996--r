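/* Common modular rate law: flux evaluation and ODE right-hand side.
 *
 * The model structure is packed on the R side into a list of numeric /
 * integer vectors and installed here as module-level state; the deSolve
 * integrator then calls cmrl_derivs natively. Single-threaded use with one
 * active model at a time (the R wrapper installs the model immediately
 * before integrating).
 *
 * Species indexing: the full concentration vector holds the nState state
 * species first, followed by nBound boundary species whose concentrations
 * are fixed. Negative state values are floored at zero for flux
 * evaluation, matching the documented rate-law contract.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>

static SEXP g_model = NULL;

static int nState, nBound, nRxn, nPair, nReg, nS;
static double *rx_u, *rx_kcatf, *rx_kcatr, *rx_h;
static int *pair_rxn, *pair_met;
static double *pair_coef, *pair_km;
static int *reg_rxn, *reg_met, *reg_mode; /* 0 activator, 1 inhibitor */
static double *reg_km;
static int *s_met, *s_rxn;
static double *s_coef;
static double *boundConc;
static double *concBuf, *fluxBuf;

static SEXP getEl(SEXP list, const char *name)
{
    SEXP names = getAttrib(list, R_NamesSymbol);
    for (int i = 0; i < length(list); i++)
        if (strcmp(CHAR(STRING_ELT(names, i)), name) == 0)
            return VECTOR_ELT(list, i);
    error("cmrl model: missing element '%s'", name);
    return R_NilValue;
}

SEXP C_cmrl_set_model(SEXP model)
{
    if (g_model != NULL) {
        R_ReleaseObject(g_model);
        g_model = NULL;
    }
    if (concBuf) { free(concBuf); concBuf = NULL; }
    if (fluxBuf) { free(fluxBuf); fluxBuf = NULL; }
    R_PreserveObject(model);
    g_model = model;

    nState = asInteger(getEl(model, "nState"));
    nBound = asInteger(getEl(model, "nBound"));
    nRxn   = asInteger(getEl(model, "nRxn"));

    rx_u     = REAL(getEl(model, "u"));
    rx_kcatf = REAL(getEl(model, "kcatf"));
    rx_kcatr = REAL(getEl(model, "kcatr"));
    rx_h     = REAL(getEl(model, "h"));

    SEXP e;
    e = getEl(model, "pairRxn");  nPair = length(e); pair_rxn = INTEGER(e);
    pair_met  = INTEGER(getEl(model, "pairMet"));
    pair_coef = REAL(getEl(model, "pairCoef"));
    pair_km   = REAL(getEl(model, "pairKm"));

    e = getEl(model, "regRxn");   nReg = length(e); reg_rxn = INTEGER(e);
    reg_met  = INTEGER(getEl(model, "regMet"));
    reg_mode = INTEGER(getEl(model, "regMode"));
    reg_km   = REAL(getEl(model, "regKm"));

    e = getEl(model, "sMet");     nS = length(e); s_met = INTEGER(e);
    s_rxn  = INTEGER(getEl(model, "sRxn"));
    s_coef = REAL(getEl(model, "sCoef"));

    boundConc = REAL(getEl(model, "boundConc"));

    concBuf = (double *) malloc(sizeof(double) * (size_t)(nState + nBound));
    fluxBuf = (double *) malloc(sizeof(double) * (size_t) nRxn);
    if (!concBuf || !fluxBuf) error("cmrl: allocation failed");
    return R_NilValue;
}

/* fluxes for the full (state + boundary) concentration buffer */
static void eval_flux(const double *conc, double *v)
{
    /* accumulators per reaction */
    for (int j = 0; j < nRxn; j++) {
        v[j] = 0.0;
        fluxBuf[j] = 0.0;
    }
    /* use stack-less accumulation: fwd, rev, denS, denP per reaction */
    static double *fwd = NULL, *rev = NULL, *denS = NULL, *denP = NULL,
        *freg = NULL, *dreg = NULL;
    static int cap = 0;
    if (cap < nRxn) {
        free(fwd); free(rev); free(denS); free(denP); free(freg); free(dreg);
        fwd = malloc(sizeof(double) * (size_t) nRxn);
        rev = malloc(sizeof(double) * (size_t) nRxn);
        denS = malloc(sizeof(double) * (size_t) nRxn);
        denP = malloc(sizeof(double) * (size_t) nRxn);
        freg = malloc(sizeof(double) * (size_t) nRxn);
        dreg = malloc(sizeof(double) * (size_t) nRxn);
        if (!fwd || !rev || !denS || !denP || !freg || !dreg)
            error("cmrl: allocation failed");
        cap = nRxn;
    }
    for (int j = 0; j < nRxn; j++) {
        fwd[j] = rx_kcatf[j];
        rev[j] = rx_kcatr[j];
        denS[j] = 1.0;
        denP[j] = 1.0;
        freg[j] = 1.0;
        dreg[j] = 0.0;
    }
    for (int p = 0; p < nPair; p++) {
        int j = pair_rxn[p];
        double x = conc[pair_met[p]];
        if (x < 0.0) x = 0.0;
        double s = x / pair_km[p];
        double e = rx_h[j] * fabs(pair_coef[p]);
        double se = (e == 1.0) ? s : R_pow(s, e);
        double de = (e == 1.0) ? (1.0 + s) : R_pow(1.0 + s, e);
        if (pair_coef[p] < 0.0) {
            fwd[j] *= se;
            denS[j] *= de;
        } else {
            rev[j] *= se;
            denP[j] *= de;
        }
    }
    for (int q = 0; q < nReg; q++) {
        int j = reg_rxn[q];
        double x = conc[reg_met[q]];
        if (x < 0.0) x = 0.0;
        double r = x / reg_km[q];
        if (reg_mode[q] == 0) {          /* activator */
            if (x <= 0.0) {
                freg[j] = 0.0;           /* no activator present: no flux */
            } else {
                freg[j] *= r / (1.0 + r);
                dreg[j] += reg_km[q] / x;
            }
        } else {                          /* inhibitor */
            freg[j] *= 1.0 / (1.0 + r);
            dreg[j] += r;
        }
    }
    for (int j = 0; j < nRxn; j++) {
        double den = denS[j] + denP[j] - 1.0 + dreg[j];
        v[j] = rx_u[j] * freg[j] * (fwd[j] - rev[j]) / den;
    }
}

static void fill_conc(const double *y)
{
    for (int i = 0; i < nState; i++) concBuf[i] = y[i];
    for (int i = 0; i < nBound; i++) concBuf[nState + i] = boundConc[i];
}

/* deSolve-compatible derivative routine (compiled-code interface) */
void C_cmrl_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    fill_conc(y);
    eval_flux(concBuf, fluxBuf);
    for (int i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (int k = 0; k < nS; k++)
        ydot[s_met[k]] += s_coef[k] * fluxBuf[s_rxn[k]];
}

SEXP C_cmrl_flux(SEXP state)
{
    if (g_model == NULL) error("cmrl: no model installed");
    if (length(state) != nState)
        error("cmrl: state length %d, expected %d", length(state), nState);
    fill_conc(REAL(state));
    SEXP out = PROTECT(allocVector(REALSXP, nRxn));
    eval_flux(concBuf, REAL(out));
    UNPROTECT(1);
    return out;
}

SEXP C_cmrl_rhs(SEXP state)
{
    if (g_model == NULL) error("cmrl: no model installed");
    int neq = nState;
    SEXP out = PROTECT(allocVector(REALSXP, neq));
    double *ydot = REAL(out);
    double t = 0.0;
    C_cmrl_derivs(&neq, &t, REAL(state), ydot, NULL, NULL);
    UNPROTECT(1);
    return out;
}
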