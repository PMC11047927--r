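#include <Rcpp.h>
using namespace Rcpp;

// Overlap merging of a read pair. mate2 must already be reverse-complemented
// so the admissible layouts are: suffix of s1 aligned to prefix of s2 with
// overlap length L in [min_overlap, min(n1, n2)]. Among overlaps whose
// mismatch fraction is <= max_mm_frac the one with the most matching bases
// wins; ties go to the longest overlap. Mismatching bases are resolved
// toward the higher-quality base (toward mate 1 when no qualities are
// supplied).
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector s1, CharacterVector s2rc,
                     int min_overlap, double max_mm_frac,
                     CharacterVector q1, CharacterVector q2rc) {
  int n = s1.size();
  bool have_q = q1.size() == n && q2rc.size() == n;
  CharacterVector merged(n);
  IntegerVector overlap(n), mismatches(n);
  LogicalVector ok(n);

  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]);
    std::string b = as<std::string>(s2rc[i]);
    int n1 = a.size(), n2 = b.size();
    int maxL = std::min(n1, n2);
    int bestL = -1, bestMatch = -1, bestMM = 0;
    for (int L = min_overlap; L <= maxL; ++L) {
      int allowed = (int)std::floor(max_mm_frac * L);
      int mm = 0;
      const char *pa = a.data() + (n1 - L);
      bool fail = false;
      for (int k = 0; k < L; ++k) {
        if (pa[k] != b[k] && ++mm > allowed) { fail = true; break; }
      }
      if (fail) continue;
      int match = L - mm;
      if (match > bestMatch || (match == bestMatch && L > bestL)) {
        bestMatch = match; bestL = L; bestMM = mm;
      }
    }
    if (bestL < 0) {
      ok[i] = false; merged[i] = NA_STRING;
      overlap[i] = NA_INTEGER; mismatches[i] = NA_INTEGER;
      continue;
    }
    std::string out = a + b.substr(bestL);
    if (bestMM > 0 && have_q) {
      std::string qa = as<std::string>(q1[i]);
      std::string qb = as<std::string>(q2rc[i]);
      if ((int)qa.size() == n1 && (int)qb.size() == n2) {
        for (int k = 0; k < bestL; ++k) {
          int pos = n1 - bestL + k;
          if (a[pos] != b[k] && qb[k] > qa[pos]) out[pos] = b[k];
        }
      }
    }
    ok[i] = true; merged[i] = out;
    overlap[i] = bestL; mismatches[i] = bestMM;
  }
  return List::create(_["ok"] = ok, _["merged"] = merged,
                      _["overlap"] = overlap, _["mismatches"] = mismatches);
}

// First occurrence (1-based; 0 = not found) of `pattern` in `seq` at or
// after 1-based position `from`, allowing up to max_errors substitutions.
static int approx_find(const std::string &seq, const std::string &pat,
                       int from, int max_errors) {
  int n = seq.size(), m = pat.size();
  for (int s = from - 1; s + m <= n; ++s) {
    int mm = 0; bool fail = false;
    for (int k = 0; k < m; ++k) {
      if (seq[s + k] != pat[k] && ++mm > max_errors) { fail = true; break; }
    }
    if (!fail) return s + 1;
  }
  return 0;
}

// Locate the 5' and 3' primers (substitutions only) and return the region
// strictly between them. found == FALSE when either primer is absent.
// [[Rcpp::export(name = ".trim_primers_cpp")]]
List trim_primers_cpp(CharacterVector seqs, std::string p5, std::string p3,
                      int max_errors) {
  int n = seqs.size();
  CharacterVector inner(n);
  LogicalVector found(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int a = approx_find(s, p5, 1, max_errors);
    if (a == 0) { found[i] = false; inner[i] = NA_STRING; continue; }
    int start = a + p5.size();           // 1-based start of inner region
    int b = approx_find(s, p3, start, max_errors);
    if (b == 0) { found[i] = false; inner[i] = NA_STRING; continue; }
    found[i] = true;
    inner[i] = s.substr(start - 1, b - start);
  }
  return List::create(_["found"] = found, _["inner"] = inner);
}

// Hamming distances from one seed string to a vector of equal-length
// strings; NA for length mismatches.
// [[Rcpp::export(name = ".hamming_to_seed_cpp")]]
IntegerVector hamming_to_seed_cpp(std::string seed, CharacterVector xs) {
  int n = xs.size();
  IntegerVector d(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(xs[i]);
    if (x.size() != seed.size()) { d[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (size_t k = 0; k < x.size(); ++k) if (x[k] != seed[k]) ++mm;
    d[i] = mm;
  }
  return d;
}
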