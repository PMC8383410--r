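#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void dormprey_init(void (*odeparms)(int *, double *));
void dormprey_rhs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

/* Registered so deSolve can look the symbols up by name. */
static const R_CMethodDef CEntries[] = {
    {"dormprey_init", (DL_FUNC) &dormprey_init, 1},
    {"dormprey_rhs",  (DL_FUNC) &dormprey_rhs,  6},
    {NULL, NULL, 0}
};

void R_init_dormprey(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
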