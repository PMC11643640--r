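#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void kndy_initparms(void (*odeparms)(int *, double *));
void kndy_initforc(void (*odeforcs)(int *, double *));
void kndy_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"kndy_initparms", (DL_FUNC) &kndy_initparms, 1},
    {"kndy_initforc",  (DL_FUNC) &kndy_initforc,  1},
    {"kndy_derivs",    (DL_FUNC) &kndy_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_kndysim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    R_forceSymbols(dll, FALSE);
}
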