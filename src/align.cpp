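#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) of a position-specific score
// matrix against an integer-encoded subject. The query is represented only
// through `scores`: scores(i-1, s-1) is the score of aligning query row i to
// subject state s. Subject state 0 marks unalignable positions (stop codons,
// ambiguous translations) which no alignment may cross. A gap of length k
// costs open + (k-1) * ext.
//
// One linear-memory forward pass records, for every subject position j, the
// best local-alignment score ending at j (and its query row). Candidate end
// positions with score >= min_score are then visited in descending score
// order; each hit's full alignment is recovered by a windowed traceback (the
// subject span of a local alignment is bounded by its score and the gap
// penalties), and candidates overlapping an already-reported hit are
// dropped, yielding greedy non-overlapping hits.

static const double NEG = -1e12;

// [[Rcpp::export]]
List sw_scan_cpp(NumericMatrix scores, IntegerVector subject,
                 double gap_open, double gap_ext,
                 double min_score, int max_hits) {
  const int m = scores.nrow();
  const int n = subject.size();
  const double *sc = REAL(scores);
  const int *sub = INTEGER(subject);

  std::vector<double> Hprev(n + 1, 0.0), H(n + 1, 0.0), Fcol(n + 1, NEG);
  std::vector<double> colbest(n + 1, 0.0);
  std::vector<int> colrow(n + 1, 0);

  for (int i = 1; i <= m; ++i) {
    const double *row = sc + (i - 1); // row i scores: row[m * (state-1)]
    double E = NEG;
    double *hp = Hprev.data(), *hc = H.data(), *fc = Fcol.data();
    hc[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      const int st = sub[j - 1];
      double h;
      if (st <= 0) {
        E = NEG; fc[j] = NEG; h = 0.0;
      } else {
        const double s = row[m * (st - 1)];
        double diag = hp[j - 1] + s;
        double eo = hc[j - 1] - gap_open;
        E = (E - gap_ext > eo) ? E - gap_ext : eo;
        double fo = hp[j] - gap_open;
        double fe = fc[j] - gap_ext;
        fc[j] = (fe > fo) ? fe : fo;
        h = diag;
        if (E > h) h = E;
        if (fc[j] > h) h = fc[j];
        if (h < 0.0) h = 0.0;
      }
      hc[j] = h;
      if (h > colbest[j]) { colbest[j] = h; colrow[j] = i; }
    }
    std::swap(Hprev, H);
  }

  // candidate end positions: score peaks only (leftmost point of each
  // plateau), capped after sorting
  std::vector<int> cand;
  for (int j = 1; j <= n; ++j) {
    if (colbest[j] < min_score) continue;
    if (j > 1 && colbest[j - 1] >= colbest[j]) continue;
    if (j < n && colbest[j + 1] > colbest[j]) continue;
    cand.push_back(j);
  }
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (colbest[a] != colbest[b]) return colbest[a] > colbest[b];
    return a < b;
  });

  double max_entry = 0.0;
  for (int k = 0; k < scores.nrow() * scores.ncol(); ++k)
    if (sc[k] > max_entry) max_entry = sc[k];
  const int span_bound =
      m + (int)std::ceil((m * max_entry) / std::max(gap_ext, 1e-9)) + 2;

  const size_t cand_cap = (size_t)std::max(10 * max_hits + 50, 200);
  if (cand.size() > cand_cap) cand.resize(cand_cap);

  std::vector<bool> taken(n + 1, false);
  List hits;

  for (size_t c = 0; c < cand.size() && (int)hits.size() < max_hits; ++c) {
    const int bj = cand[c];
    if (taken[bj]) continue;
    const int bi = colrow[bj];
    const double best = colbest[bj];

    const int j0 = std::max(0, bj - span_bound); // window (j0, bj]
    const int wn = bj - j0;
    std::vector<std::vector<double> > Hm(bi + 1, std::vector<double>(wn + 1, 0.0));
    std::vector<std::vector<double> > Em(bi + 1, std::vector<double>(wn + 1, NEG));
    std::vector<std::vector<double> > Fm(bi + 1, std::vector<double>(wn + 1, NEG));
    for (int i = 1; i <= bi; ++i) {
      const double *row = sc + (i - 1);
      for (int j = 1; j <= wn; ++j) {
        const int st = sub[j0 + j - 1];
        const bool bad = (st <= 0) || taken[j0 + j];
        const double s = bad ? NEG : row[m * (st - 1)];
        Em[i][j] = std::max(Hm[i][j - 1] - gap_open, Em[i][j - 1] - gap_ext);
        Fm[i][j] = std::max(Hm[i - 1][j] - gap_open, Fm[i - 1][j] - gap_ext);
        double val = std::max(0.0, std::max(Hm[i - 1][j - 1] + s,
                                            std::max(Em[i][j], Fm[i][j])));
        if (bad) val = 0.0;
        Hm[i][j] = val;
      }
    }
    if (std::abs(Hm[bi][wn] - best) > 1e-6) continue; // clipped by earlier hit
    // traceback from (bi, bj)
    int i = bi, j = wn;
    std::vector<int> qidx, sidx;
    int state = 0;
    while (i > 0 && j > 0) {
      if (state == 0) {
        const double cur = Hm[i][j];
        if (cur <= 0.0) break;
        const int st = sub[j0 + j - 1];
        const double s = (st <= 0 || taken[j0 + j]) ? NEG
                         : sc[(i - 1) + m * (st - 1)];
        if (std::abs(cur - (Hm[i - 1][j - 1] + s)) < 1e-9) {
          qidx.push_back(i); sidx.push_back(j0 + j); --i; --j;
        } else if (std::abs(cur - Fm[i][j]) < 1e-9) {
          state = 2;
        } else if (std::abs(cur - Em[i][j]) < 1e-9) {
          state = 1;
        } else break;
      } else if (state == 1) { // gap in query, consume subject
        const double cur = Em[i][j];
        qidx.push_back(0); sidx.push_back(j0 + j);
        if (std::abs(cur - (Hm[i][j - 1] - gap_open)) < 1e-9) { --j; state = 0; }
        else --j;
      } else {                 // gap in subject, consume query
        const double cur = Fm[i][j];
        qidx.push_back(i); sidx.push_back(0);
        if (std::abs(cur - (Hm[i - 1][j] - gap_open)) < 1e-9) { --i; state = 0; }
        else --i;
      }
    }
    std::reverse(qidx.begin(), qidx.end());
    std::reverse(sidx.begin(), sidx.end());
    int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
    for (size_t k = 0; k < qidx.size(); ++k) {
      if (qidx[k] > 0) { if (!q_start) q_start = qidx[k]; q_end = qidx[k]; }
      if (sidx[k] > 0) { if (!s_start) s_start = sidx[k]; s_end = sidx[k]; }
    }
    if (s_start == 0) continue;
    bool overlaps = false;
    for (int k = s_start; k <= s_end; ++k)
      if (taken[k]) { overlaps = true; break; }
    if (overlaps) continue;
    for (int k = s_start; k <= s_end; ++k) taken[k] = true;
    hits.push_back(List::create(
      _["score"] = best,
      _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end,
      _["q_path"] = IntegerVector(qidx.begin(), qidx.end()),
      _["s_path"] = IntegerVector(sidx.begin(), sidx.end())));
  }
  return hits;
}
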