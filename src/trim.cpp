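#include <Rcpp.h>
using namespace Rcpp;

// Adapter trimming of a batch of reads.
//
// For each read, scan left to right for the first position where a prefix of
// the adapter matches the read through its 3' end (overlap >= min_overlap,
// at most max_mismatch mismatches), or where the full adapter occurs
// internally (bases after the adapter are ignored).  The insert is everything
// before that position.
//
// status codes: 0 = kept, 1 = no_adapter, 2 = too_short
// [[Rcpp::export]]
List trim_batch_cpp(CharacterVector reads, std::string adapter,
                    int min_overlap, int max_mismatch, int min_length) {
  int n = reads.size();
  int m = adapter.size();
  IntegerVector status(n);
  CharacterVector insert(n);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) stop("read %d is NA", r + 1);
    std::string s = as<std::string>(reads[r]);
    int L = s.size();
    int hit = -1;
    for (int p = 0; p + min_overlap <= L; ++p) {
      int wlen = std::min(m, L - p);
      int mm = 0;
      bool ok = true;
      for (int i = 0; i < wlen; ++i) {
        if (s[p + i] != adapter[i]) {
          if (++mm > max_mismatch) { ok = false; break; }
        }
      }
      if (ok) { hit = p; break; }
    }
    if (hit < 0) {
      status[r] = 1;
      insert[r] = NA_STRING;
    } else if (hit < min_length) {
      status[r] = 2;
      insert[r] = NA_STRING;
    } else {
      status[r] = 0;
      insert[r] = s.substr(0, hit);
    }
  }
  return List::create(_["status"] = status, _["insert"] = insert);
}
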