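#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// Cap the BLAS thread pool. The denoisers run ~1e5 factorizations of
// matrices no larger than ~150x150 per volume; at that size thread fan-out
// costs more than it saves. Resolved dynamically so this is a no-op when
// the linked BLAS is not OpenBLAS.
// [[Rcpp::export]]
void set_blas_threads(int n) {
#ifndef _WIN32
  typedef void (*setter)(int);
  setter f = (setter) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f != NULL) f(n);
#endif
}
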