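#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of an integer-coded protein sequence
// against a position-specific score matrix (rows = profile positions,
// columns = 20 residues). Affine gaps: a gap of length L costs
// gap_open + L * gap_extend (Biostrings convention). Residue code -1
// (unknown / X) scores 0 at every position.
//
// Returns the optimal score and the 0-based half-open spans of the optimal
// local alignment on the profile and on the sequence.

static inline double cell_score(const NumericMatrix &pssm, int i, int code) {
  return code < 0 ? 0.0 : pssm(i, code);
}

// [[Rcpp::export]]
List pssm_local_align_cpp(NumericMatrix pssm, IntegerVector seq,
                          double gap_open, double gap_extend) {
  const int m = pssm.nrow();   // profile positions
  const int n = seq.size();    // sequence length
  const double gi = gap_open + gap_extend;  // gap initiation
  const double ge = gap_extend;

  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, R_NegInf), Ecur(n + 1, R_NegInf);
  std::vector<double> Fcol(n + 1, R_NegInf);
  // start coordinates (profile, sequence) per state, encoded i * (n+1) + j
  std::vector<int> sHprev(n + 1), sHcur(n + 1), sEprev(n + 1), sEcur(n + 1),
      sFcol(n + 1);
  for (int j = 0; j <= n; ++j) sHprev[j] = 0 * (n + 1) + j;

  double best = 0.0;
  int best_end_i = 0, best_end_j = 0, best_start = 0;

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = R_NegInf;
    sHcur[0] = i * (n + 1) + 0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in profile (consumes sequence), same row
      double e_open = Hcur[j - 1] - gi, e_ext = Ecur[j - 1] - ge;
      if (e_open >= e_ext) { Ecur[j] = e_open; sEcur[j] = sHcur[j - 1]; }
      else { Ecur[j] = e_ext; sEcur[j] = sEcur[j - 1]; }
      // F: gap in sequence (consumes profile), same column
      double f_open = Hprev[j] - gi, f_ext = Fcol[j] - ge;
      if (f_open >= f_ext) { Fcol[j] = f_open; sFcol[j] = sHprev[j]; }
      else { Fcol[j] = f_ext; /* sFcol[j] unchanged */ }
      // H
      double diag = Hprev[j - 1] + cell_score(pssm, i - 1, seq[j - 1]);
      double h = 0.0;
      int sh = i * (n + 1) + j;
      if (diag > h) { h = diag; sh = sHprev[j - 1]; }
      if (Ecur[j] > h) { h = Ecur[j]; sh = sEcur[j]; }
      if (Fcol[j] > h) { h = Fcol[j]; sh = sFcol[j]; }
      Hcur[j] = h;
      sHcur[j] = sh;
      if (h > best) {
        best = h;
        best_end_i = i;
        best_end_j = j;
        best_start = sh;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(sHprev, sHcur);
    std::swap(sEprev, sEcur);
  }

  int si = best_start / (n + 1), sj = best_start % (n + 1);
  return List::create(_["score"] = best,
                      _["profile_span"] = IntegerVector::create(si, best_end_i),
                      _["query_span"] = IntegerVector::create(sj, best_end_j));
}

// Batch variant: maximal local score of each sequence against one profile
// (no span bookkeeping; used for decoy calibration and coverage counting).

// [[Rcpp::export]]
NumericVector pssm_local_scores_cpp(NumericMatrix pssm, List seqs,
                                    double gap_open, double gap_extend) {
  const int m = pssm.nrow();
  const double gi = gap_open + gap_extend, ge = gap_extend;
  const double *P = REAL(pssm);  // column-major: P[i + 20th column * m]
  const int nseq = seqs.size();
  NumericVector out(nseq);
  std::vector<double> H, F;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector seqv = seqs[s];
    const int n = seqv.size();
    const int *q = INTEGER(seqv);
    H.assign(n + 1, 0.0);
    F.assign(n + 1, R_NegInf);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      const double *Pi = P + (i - 1);  // row i-1; column stride m
      double diag = 0.0;               // H[i-1][j-1], updated in place
      double Erow = R_NegInf;
      for (int j = 1; j <= n; ++j) {
        const int code = q[j - 1];
        double e1 = H[j - 1] - gi, e2 = Erow - ge;
        Erow = e1 > e2 ? e1 : e2;
        double f1 = H[j] - gi, f2 = F[j] - ge;
        F[j] = f1 > f2 ? f1 : f2;
        double h = diag + (code < 0 ? 0.0 : Pi[(size_t)code * m]);
        if (h < 0.0) h = 0.0;
        if (Erow > h) h = Erow;
        if (F[j] > h) h = F[j];
        diag = H[j];
        H[j] = h;
        if (h > best) best = h;
      }
    }
    out[s] = best;
  }
  return out;
}

// Needleman-Wunsch global alignment with affine gaps (gap of length L costs
// gap_open + L * gap_extend) over integer-coded sequences and an arbitrary
// substitution matrix. Traceback ties prefer diagonal, then gap in b
// (consuming a), then gap in a. Returns aligned code vectors with -9 at gaps.

// [[Rcpp::export]]
List nw_align_batch_cpp(List aseqs, List bseqs, NumericMatrix submat,
                        double gap_open, double gap_extend) {
  const double gi = gap_open + gap_extend, ge = gap_extend;
  const double NEG = -1e30;
  const int nal = submat.nrow();
  const double *S = REAL(submat);
  const int npair = aseqs.size();
  List out(npair);
  std::vector<double> M, E, F;
  std::vector<unsigned char> TBM, TBE, TBF;
  for (int p = 0; p < npair; ++p) {
    IntegerVector av = aseqs[p], bv = bseqs[p];
    const int na = av.size(), nb = bv.size();
    const int *a = INTEGER(av), *b = INTEGER(bv);
    const size_t W = nb + 1;
    M.assign((na + 1) * W, NEG);
    E.assign((na + 1) * W, NEG);
    F.assign((na + 1) * W, NEG);
    // traceback: which predecessor state fed each cell (0=M,1=E,2=F)
    TBM.assign((na + 1) * W, 0);
    TBE.assign((na + 1) * W, 0);
    TBF.assign((na + 1) * W, 0);
    M[0] = 0.0;
    for (int j = 1; j <= nb; ++j) E[j] = -(gap_open + j * ge);
    for (int i = 1; i <= na; ++i) F[i * W] = -(gap_open + i * ge);
    for (int i = 1; i <= na; ++i) {
      const double *Sa = S + a[i - 1];
      for (int j = 1; j <= nb; ++j) {
        const size_t c = i * W + j, d = c - W - 1, up = c - W, lf = c - 1;
        // M: diagonal from best of three
        double best = M[d]; unsigned char tb = 0;
        if (E[d] > best) { best = E[d]; tb = 1; }
        if (F[d] > best) { best = F[d]; tb = 2; }
        M[c] = best + Sa[(size_t)b[j - 1] * nal];
        TBM[c] = tb;
        // E: gap in a, consumes b (move left)
        double eo = M[lf] - gi, ef = E[lf] - ge, ff = F[lf] - gi;
        if (eo >= ef && eo >= ff) { E[c] = eo; TBE[c] = 0; }
        else if (ef >= ff) { E[c] = ef; TBE[c] = 1; }
        else { E[c] = ff; TBE[c] = 2; }
        // F: gap in b, consumes a (move up)
        double fo = M[up] - gi, fe = F[up] - ge, ef2 = E[up] - gi;
        if (fo >= fe && fo >= ef2) { F[c] = fo; TBF[c] = 0; }
        else if (fe >= ef2) { F[c] = fe; TBF[c] = 2; }
        else { F[c] = ef2; TBF[c] = 1; }
      }
    }
    const size_t end = na * W + nb;
    double sc = M[end]; int state = 0;
    if (F[end] > sc) { sc = F[end]; state = 2; }
    if (E[end] > sc) { sc = E[end]; state = 1; }
    // traceback
    std::vector<int> ga, gb;
    ga.reserve(na + nb); gb.reserve(na + nb);
    int i = na, j = nb;
    while (i > 0 || j > 0) {
      const size_t c = i * W + j;
      if (i == 0) state = 1;
      else if (j == 0) state = 2;
      if (state == 0) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        state = TBM[c]; --i; --j;
      } else if (state == 1) {
        ga.push_back(-9); gb.push_back(b[j - 1]);
        state = TBE[c]; --j;
      } else {
        ga.push_back(a[i - 1]); gb.push_back(-9);
        state = TBF[c]; --i;
      }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    out[p] = List::create(_["score"] = sc,
                          _["a"] = IntegerVector(ga.begin(), ga.end()),
                          _["b"] = IntegerVector(gb.begin(), gb.end()));
  }
  return out;
}
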