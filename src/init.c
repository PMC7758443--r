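#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_tissue_rhs(SEXP st, SEXP sy, SEXP sp);

static const R_CallMethodDef CallEntries[] = {
    {"C_tissue_rhs", (DL_FUNC) &C_tissue_rhs, 3},
    {NULL, NULL, 0}
};

void R_init_mecwave(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
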