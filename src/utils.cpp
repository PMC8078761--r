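#include <Rcpp.h>

// [[Rcpp::export]]
bool cpp_xptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}
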