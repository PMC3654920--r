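#include <Rcpp.h>
using namespace Rcpp;

// Hamming mismatch counts between `query` and `subject` at the given
// 1-based start positions. Positions where the query would run off the
// subject end are returned as NA.
// [[Rcpp::export(name = ".mismatch_at")]]
IntegerVector mismatch_at_cpp(std::string subject, std::string query,
                              IntegerVector starts) {
  const int n = query.size();
  const int L = subject.size();
  IntegerVector out(starts.size());
  for (int i = 0; i < starts.size(); ++i) {
    const int s = starts[i] - 1;
    if (s < 0 || s + n > L) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (int j = 0; j < n; ++j) if (subject[s + j] != query[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Exhaustive scan: every 1-based start position in `subject` where `query`
// matches end-to-end with at most `max_mm` mismatches, with the mismatch
// count at each. Early exit once the budget is exceeded keeps this linear
// in practice.
// [[Rcpp::export(name = ".scan_mismatch")]]
List scan_mismatch_cpp(std::string subject, std::string query, int max_mm) {
  const int n = query.size();
  const int L = subject.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + n <= L; ++s) {
    int mm = 0;
    for (int j = 0; j < n; ++j) {
      if (subject[s + j] != query[j]) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { starts.push_back(s + 1); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mm"] = wrap(mms));
}

// 3' adapter search: for each read, the 1-based position of the leftmost
// adapter occurrence (full adapter anywhere, or a >= min_overlap prefix of
// the adapter reaching the read's 3' end) with mismatch rate <= max_rate.
// Returns the number of 5' bases kept (read length when no adapter found).
// [[Rcpp::export(name = ".adapter_keep_len")]]
IntegerVector adapter_keep_len_cpp(CharacterVector reads, std::string adapter,
                                   int min_overlap, double max_rate) {
  const int alen = adapter.size();
  IntegerVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    const int rlen = r.size();
    int keep = rlen;
    for (int s = 0; s < rlen; ++s) {
      const int ov = std::min(alen, rlen - s);
      if (ov < min_overlap) break;
      const int allowed = (int) std::floor(max_rate * ov);
      int mm = 0;
      for (int j = 0; j < ov; ++j) {
        if (r[s + j] != adapter[j]) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) { keep = s; break; }
    }
    out[i] = keep;
  }
  return out;
}
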