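#include <Rcpp.h>
using namespace Rcpp;

// A/C/G/T match only if equal; N (or any ambiguity code) never matches.
static inline bool base_match(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// Two-color-chemistry 3' quality trim (running-sum rule). G bases count as
// quality 0 because a dark cycle is indistinguishable from a real G. Walk in
// from the 3' end accumulating (qcut - q_eff); the cut lands where that sum is
// maximal, i.e. where the retained suffix score is minimal. Returns the number
// of bases kept.
// [[Rcpp::export]]
IntegerVector nextseq_trim_len(CharacterVector seqs, CharacterVector quals,
                               int qcut) {
  int n = seqs.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    long sum = 0, best = 0;
    int cut = len;
    for (int i = len - 1; i >= 0; --i) {
      int qv = (s[i] == 'G') ? 0 : (q[i] - 33);
      sum += (long)qcut - qv;
      if (sum < 0) break;
      if (sum > best) { best = sum; cut = i; }
    }
    out[r] = cut;
  }
  return out;
}

static inline int mm_count(const char *a, const char *b, int len, int max_mm) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (!base_match(a[i], b[i])) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// 3' adapter search and removal. Candidates are (a) the full adapter starting
// at any internal offset, (b) an adapter prefix of length >= min_overlap that
// ends flush with the 3' end. Mismatch budget floor(max_error_rate * matched
// length); ties break longest match then leftmost. Trimming iterates to a
// fixed point so no qualifying occurrence survives in the output, but a read
// counts as "trimmed" only if the first pass cut. Returns kept insert length,
// or -1 when no adapter was found.
// [[Rcpp::export]]
IntegerVector adapter_trim_len(CharacterVector seqs, std::string adapter,
                               int min_overlap, double max_error_rate) {
  int n = seqs.size();
  int alen = (int)adapter.size();
  const char *ad = adapter.c_str();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    bool trimmed_first_pass = false;
    bool pass_one = true;
    for (;;) {
      int best_len = -1, best_start = -1;
      // full adapter at internal offsets (also covers flush full occurrence)
      int full_budget = (int)std::floor(max_error_rate * alen);
      for (int i = 0; i + alen <= len; ++i) {
        if (mm_count(s + i, ad, alen, full_budget) <= full_budget) {
          best_len = alen; best_start = i;
          break; // leftmost; nothing can beat full length
        }
      }
      if (best_len < 0) {
        // terminal prefixes, longest first
        int lmax = std::min(alen, len);
        for (int l = lmax; l >= min_overlap; --l) {
          if (l == alen) continue; // already tried as full
          int budget = (int)std::floor(max_error_rate * l);
          int i = len - l;
          if (mm_count(s + i, ad, l, budget) <= budget) {
            best_len = l; best_start = i;
            break;
          }
        }
      }
      if (best_start < 0) break;
      if (pass_one) trimmed_first_pass = true;
      len = best_start;
      pass_one = false;
      if (len == 0) break;
    }
    out[r] = trimmed_first_pass ? len : -1;
  }
  return out;
}

// Mismatches between the read prefix and a tag; NA when the read is shorter
// than the tag.
// [[Rcpp::export]]
IntegerVector prefix_mismatches(CharacterVector seqs, std::string tag) {
  int n = seqs.size();
  int tlen = (int)tag.size();
  const char *tg = tag.c_str();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    if (len < tlen) { out[r] = NA_INTEGER; continue; }
    out[r] = mm_count(s, tg, tlen, tlen);
  }
  return out;
}

// Fraction of bases with Phred quality >= min_q (Phred+33 strings).
// [[Rcpp::export]]
NumericVector qual_fraction_ge(CharacterVector quals, int min_q) {
  int n = quals.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(quals, r));
    if (len == 0) { out[r] = NA_REAL; continue; }
    int ok = 0;
    for (int i = 0; i < len; ++i) if (q[i] - 33 >= min_q) ++ok;
    out[r] = (double)ok / len;
  }
  return out;
}

// All ungapped placements of query within reference with Hamming distance
// <= max_mm. Returns a two-column matrix (start, mismatches), 1-based starts.
// [[Rcpp::export]]
IntegerMatrix hamming_placements(std::string query, std::string reference,
                                 int max_mm) {
  int qlen = (int)query.size(), rlen = (int)reference.size();
  const char *q = query.c_str(), *rf = reference.c_str();
  std::vector<int> starts, mms;
  for (int i = 0; i + qlen <= rlen; ++i) {
    int mm = mm_count(rf + i, q, qlen, max_mm);
    if (mm <= max_mm) { starts.push_back(i + 1); mms.push_back(mm); }
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (size_t j = 0; j < starts.size(); ++j) {
    out(j, 0) = starts[j];
    out(j, 1) = mms[j];
  }
  colnames(out) = CharacterVector::create("start", "mismatches");
  return out;
}

// Best (fewest-mismatch, then leftmost) placement of each query against each
// reference, capped at max_mm. Returns for every query the per-reference best
// as a long vector set; -1 encodes no placement. Used by the tiered annotator
// to avoid R-level loops over the query x reference grid.
// [[Rcpp::export]]
List best_placements(CharacterVector queries, CharacterVector refs,
                     int max_mm) {
  int nq = queries.size(), nr = refs.size();
  IntegerMatrix start(nq, nr), mism(nq, nr);
  for (int j = 0; j < nr; ++j) {
    const char *rf = CHAR(STRING_ELT(refs, j));
    int rlen = LENGTH(STRING_ELT(refs, j));
    for (int i = 0; i < nq; ++i) {
      const char *q = CHAR(STRING_ELT(queries, i));
      int qlen = LENGTH(STRING_ELT(queries, i));
      int bs = -1, bm = max_mm + 1;
      for (int p = 0; p + qlen <= rlen; ++p) {
        int mm = mm_count(rf + p, q, qlen, bm - 1 < max_mm ? bm - 1 : max_mm);
        if (mm < bm) { bm = mm; bs = p + 1; if (bm == 0) break; }
      }
      start(i, j) = bs;
      mism(i, j) = (bs > 0) ? bm : NA_INTEGER;
    }
  }
  return List::create(_["start"] = start, _["mismatches"] = mism);
}
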