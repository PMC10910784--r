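#include <Rcpp.h>
using namespace Rcpp;

// Wraparound (cyclic) edit-distance decomposition of a text against tandem
// copies of a consensus. Costs are in twentieths of an edit: mismatch 20,
// indel 20, and a "junk" state that skips one text base for 9 between copies
// (or before the first / after the last), so random flanking sequence and
// interspersed insertions (CRM elements) are skipped rather than absorbed
// into monomers: aligning random DNA costs ~10-13 per base while a monomer
// within the usual identity range costs less than 9. Every pass of the
// consensus end back to its start ("wrap") marks a monomer boundary, so
// boundaries always sit at consensus position 0 (canonical phase). The phase
// of a partial first/last copy is free. Returns one row per decomposed copy
// with its half-open text interval and alignment column counts.

static const unsigned char P_START = 0, P_DIAG = 1, P_UP = 2, P_LEFT = 3,
                           P_WRAP = 4, P_SKIP = 5;
static const int C_SUB = 20, C_INDEL = 20, C_SKIP = 9;

// [[Rcpp::export(name = ".wrap_decompose_cpp")]]
DataFrame wrap_decompose_cpp(std::string text, std::string cons) {
  const int N = (int)text.size(), L = (int)cons.size();
  if (L < 1) stop("empty consensus");
  if (N < 1)
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["end"] = IntegerVector(0),
                             _["match"] = IntegerVector(0),
                             _["mismatch"] = IntegerVector(0),
                             _["ins"] = IntegerVector(0),
                             _["del"] = IntegerVector(0));
  const double cells = (double)(N + 1) * (double)(L + 1);
  if (cells > 6e8) stop("region too large for decomposition DP");

  std::vector<int> prev(L + 1), cur(L + 1);
  std::vector<unsigned char> ptr((size_t)(N + 1) * (L + 1), P_START);

  for (int j = 0; j <= L; ++j) prev[j] = 0;  // free start phase at i = 0

  for (int i = 1; i <= N; ++i) {
    unsigned char *pi = &ptr[(size_t)i * (L + 1)];
    const char ti = text[i - 1];
    cur[0] = prev[0] + C_SKIP;  // junk base between / around copies
    pi[0] = P_SKIP;
    for (int j = 1; j <= L; ++j) {
      int best = prev[j - 1] + (ti == cons[j - 1] ? 0 : C_SUB);
      unsigned char mv = P_DIAG;
      int c = prev[j] + C_INDEL;
      if (c < best) { best = c; mv = P_UP; }
      c = cur[j - 1] + C_INDEL;
      if (c < best) { best = c; mv = P_LEFT; }
      cur[j] = best;
      pi[j] = mv;
    }
    if (cur[L] < cur[0]) {  // wrap: a copy ends (and may restart) here
      cur[0] = cur[L];
      pi[0] = P_WRAP;
      for (int j = 1; j <= L; ++j) {  // relax deletions after the wrap
        if (cur[j - 1] + C_INDEL < cur[j]) {
          cur[j] = cur[j - 1] + C_INDEL;
          pi[j] = P_LEFT;
        }
      }
    }
    std::swap(prev, cur);
  }

  int jend = 0;  // free end: trailing junk (j = 0) or a partial last copy
  for (int j = 1; j <= L; ++j)
    if (prev[j] < prev[jend]) jend = j;

  // traceback; segments collected right to left
  std::vector<int> st, en, ma, mi, in, de;
  int i = N, j = jend;
  int segEnd = N, m = 0, x = 0, ii = 0, dd = 0;
  bool open = j > 0;  // inside a (partial) copy?
  while (i > 0 || j > 0) {
    unsigned char mv = ptr[(size_t)i * (L + 1) + j];
    if (i == 0) break;  // free start phase: leading partial copy to text 0
    if (mv == P_DIAG) {
      if (text[i - 1] == cons[j - 1]) ++m; else ++x;
      --i; --j;
    } else if (mv == P_UP) {
      ++ii; --i;
    } else if (mv == P_LEFT) {
      ++dd; --j;
    } else if (mv == P_WRAP) {
      if (open) {  // close the copy that started here
        st.push_back(i); en.push_back(segEnd);
        ma.push_back(m); mi.push_back(x); in.push_back(ii); de.push_back(dd);
      }
      segEnd = i; m = x = ii = dd = 0;
      j = L; open = true;
    } else if (mv == P_SKIP) {
      if (open) {  // a copy started here, preceded by junk
        st.push_back(i); en.push_back(segEnd);
        ma.push_back(m); mi.push_back(x); in.push_back(ii); de.push_back(dd);
        m = x = ii = dd = 0;
      }
      --i;
      segEnd = i;  // junk: the next copy (leftwards) ends here
      open = false;
    } else {
      break;
    }
  }
  if (open && segEnd > 0) {  // leading partial copy reaching text start
    st.push_back(0); en.push_back(segEnd);
    ma.push_back(m); mi.push_back(x); in.push_back(ii); de.push_back(dd);
  }

  const int n = (int)st.size();
  IntegerVector S(n), E(n), M(n), X(n), I(n), D(n);
  for (int k = 0; k < n; ++k) {  // reverse into left-to-right order
    S[k] = st[n - 1 - k]; E[k] = en[n - 1 - k];
    M[k] = ma[n - 1 - k]; X[k] = mi[n - 1 - k];
    I[k] = in[n - 1 - k]; D[k] = de[n - 1 - k];
  }
  return DataFrame::create(_["start"] = S, _["end"] = E, _["match"] = M,
                           _["mismatch"] = X, _["ins"] = I, _["del"] = D);
}

// 3'-overlap merger for a read pair. r2rc is mate 2 already reverse
// complemented, so a true fragment is r1's prefix + r2rc's suffix and the
// overlap is a suffix of r1 against a prefix of r2rc. Among candidate overlap
// lengths the lowest mismatch rate wins, ties to the longer overlap.
// Disagreeing overlap bases are resolved by the higher quality character.
// [[Rcpp::export(name = ".merge_overlap_cpp")]]
List merge_overlap_cpp(CharacterVector r1, CharacterVector r2rc,
                       CharacterVector q1, CharacterVector q2rc,
                       int min_overlap, double max_mismatch_rate) {
  const int n = r1.size();
  CharacterVector merged(n);
  IntegerVector flen(n), olen(n);
  NumericVector mmrate(n);
  for (int p = 0; p < n; ++p) {
    std::string a = as<std::string>(r1[p]), b = as<std::string>(r2rc[p]);
    std::string qa = as<std::string>(q1[p]), qb = as<std::string>(q2rc[p]);
    const int l1 = (int)a.size(), l2 = (int)b.size();
    const int omax = std::min(l1, l2);
    int bestO = -1;
    double bestRate = 2.0;
    for (int o = min_overlap; o <= omax; ++o) {
      int mm = 0;
      const char *sa = a.data() + (l1 - o), *sb = b.data();
      for (int k = 0; k < o; ++k)
        if (sa[k] != sb[k]) ++mm;
      double rate = (double)mm / o;
      if (rate < bestRate || (rate == bestRate && o > bestO)) {
        bestRate = rate; bestO = o;
      }
    }
    if (bestO >= min_overlap && bestRate <= max_mismatch_rate) {
      std::string out = a + b.substr(bestO);
      for (int k = 0; k < bestO; ++k) {  // quality-resolved overlap bases
        const int ia = l1 - bestO + k;
        if (a[ia] != b[k] && qb[k] > qa[ia]) out[ia] = b[k];
      }
      merged[p] = out;
      flen[p] = (int)out.size();
      olen[p] = bestO;
      mmrate[p] = bestRate;
    } else {
      merged[p] = NA_STRING;
      flen[p] = NA_INTEGER;
      olen[p] = NA_INTEGER;
      mmrate[p] = NA_REAL;
    }
  }
  return List::create(_["merged"] = merged, _["length"] = flen,
                      _["overlap"] = olen, _["mismatch_rate"] = mmrate);
}
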