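/* Runtime control of BLAS threading. On single-CPU machines OpenBLAS's
 * default thread pool spins and slows dense algebra severalfold; this looks
 * up openblas_set_num_threads dynamically so it works with any BLAS (no-op
 * when the symbol is absent). */
#include <R.h>
#include <Rinternals.h>

#ifdef _WIN32
SEXP epigp_set_blas_threads(SEXP n)
{
    return Rf_ScalarLogical(0);
}
#else
#include <dlfcn.h>

typedef void (*set_threads_fun)(int);

SEXP epigp_set_blas_threads(SEXP n)
{
    set_threads_fun f =
        (set_threads_fun) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    if (f == NULL)
        return Rf_ScalarLogical(0);
    f(Rf_asInteger(n));
    return Rf_ScalarLogical(1);
}
#endif
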