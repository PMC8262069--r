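#' Set the number of BLAS threads at runtime
#'
#' Dense kernel algebra dominates the package's runtime, and on single-CPU
#' machines OpenBLAS's default thread pool can be several times slower than
#' single-threaded execution. This looks up `openblas_set_num_threads` in the
#' running process and calls it; it is a silent no-op for other BLAS
#' implementations.
#'
#' @param n number of threads.
#' @return TRUE (invisibly) if the thread count was set, FALSE when the
#'   running BLAS does not expose the control.
#' @export
set_blas_threads <- function(n = 1L) {
  invisible(.Call(epigp_set_blas_threads, as.integer(n)))
}
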