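#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding Hamming scan of `query` along `subject`.
// Returns 1-based start positions and exact distances for every window
// with distance <= max_mm. 'N' never matches.
// [[Rcpp::export(name = ".cpp_hamming_scan")]]
List cpp_hamming_scan(std::string query, std::string subject, int max_mm) {
  const int q = query.size(), s = subject.size();
  std::vector<int> pos, mm;
  for (int i = 0; i + q <= s; ++i) {
    int d = 0;
    for (int j = 0; j < q; ++j) {
      const char a = query[j], b = subject[i + j];
      if (a != b || a == 'N') {
        if (++d > max_mm) break;
      }
    }
    if (d <= max_mm) {
      pos.push_back(i + 1);
      mm.push_back(d);
    }
  }
  return List::create(_["position"] = wrap(pos), _["mismatches"] = wrap(mm));
}

// Minimum ungapped Hamming distance of each query over all windows of each
// subject. Entry [i, j] = min distance of queries[i] in subjects[j];
// NA when subjects[j] is shorter than queries[i].
// [[Rcpp::export(name = ".cpp_min_hamming")]]
IntegerMatrix cpp_min_hamming(CharacterVector queries,
                              CharacterVector subjects) {
  const int nq = queries.size(), ns = subjects.size();
  IntegerMatrix out(nq, ns);
  std::vector<std::string> subj(ns);
  for (int j = 0; j < ns; ++j) subj[j] = as<std::string>(subjects[j]);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    const int ql = q.size();
    for (int j = 0; j < ns; ++j) {
      const std::string &s = subj[j];
      const int sl = s.size();
      if (sl < ql) {
        out(i, j) = NA_INTEGER;
        continue;
      }
      int best = ql + 1;
      for (int p = 0; p + ql <= sl; ++p) {
        int d = 0;
        for (int k = 0; k < ql; ++k) {
          const char a = q[k], b = s[p + k];
          if (a != b || a == 'N') {
            if (++d >= best) break;
          }
        }
        if (d < best) best = d;
        if (best == 0) break;
      }
      out(i, j) = best;
    }
  }
  return out;
}
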