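#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void protalloc_init(void (*odeparms)(int *, double *));
void protalloc_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip);
void protalloc_root(int *neq, double *t, double *y, int *ng,
                    double *gout);

static const R_CMethodDef CEntries[] = {
    {"protalloc_init",   (DL_FUNC) &protalloc_init,   1},
    {"protalloc_derivs", (DL_FUNC) &protalloc_derivs, 6},
    {"protalloc_root",   (DL_FUNC) &protalloc_root,   5},
    {NULL, NULL, 0}
};

void R_init_protalloc(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
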