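#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP epigp_set_blas_threads(SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"epigp_set_blas_threads", (DL_FUNC) &epigp_set_blas_threads, 1},
    {NULL, NULL, 0}
};

void R_init_epigp(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
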