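#include <Rcpp.h>
using namespace Rcpp;

// Spliced protein-to-genome alignment: global in the query, local in the
// genome, over codon-aligned blocks separated by GT-AG introns.
//
// State E[i][j]: best score with the first i query residues consumed and
// the current exon ending exactly at genomic position j (1-based).
// Transitions: codon match (i-1, j-3) + S(q_i, aa(j)); query-residue
// deletion (i-1, j) - gap; genomic codon insertion (i, j-3) - gap; and an
// intron ending at j-3 (acceptor AG) opened at any earlier donor GT, paid
// intron_open, followed immediately by a codon consuming q_i.  Introns sit
// on codon boundaries only (phase 0), so every aligned block is
// codon-complete.  Tie preference: codon > deletion > insertion > intron
// (fewer introns on equal score), and the smallest end position.
//
// qidx:   query residues as 0-based rows of submat (length m)
// aa:     0-based submat row of the codon ending at j (j = 1..n; -1 if
//         j < 3 or codon untranslatable)
// donor:  donor[j] true if genome[j..j+1] == "GT" (1-based j)
// accend: accend[j] true if genome[j-1..j] == "AG"
// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(IntegerVector qidx, IntegerVector aa,
                       LogicalVector donor, LogicalVector accend,
                       NumericMatrix submat, double gap, double intron_open,
                       int min_intron) {
  const int m = qidx.size();
  const int n = aa.size();
  const double NEG = -1e18;

  std::vector<double> Eprev(n + 1), Ecur(n + 1);
  std::vector<double> Dmax(n + 1, NEG);
  std::vector<int> Darg(n + 1, 0);
  // traceback: move code and intron donor position
  IntegerMatrix tb(m + 1, n + 1);
  IntegerMatrix dnr(m + 1, n + 1);

  for (int j = 0; j <= n; ++j) Eprev[j] = 0.0;  // free genomic start

  for (int i = 1; i <= m; ++i) {
    // donor prefix maxima of row i-1
    double run = NEG; int arg = 0;
    Dmax[0] = NEG; Darg[0] = 0;
    for (int k = 1; k <= n; ++k) {
      if (donor[k - 1] && Eprev[k - 1] > run) { run = Eprev[k - 1]; arg = k; }
      Dmax[k] = run; Darg[k] = arg;
    }
    const int qi = qidx[i - 1];
    for (int j = 0; j <= n; ++j) {
      double best = Eprev[j] - gap;  // query residue deleted
      int move = 2;
      if (j >= 3 && aa[j - 1] >= 0) {
        double s = submat(qi, aa[j - 1]);
        double v = Eprev[j - 3] + s;
        if (v > best) { best = v; move = 1; }
        // intron ending at j-3, then codon [j-2, j]
        int klim = j - min_intron - 2;
        if (j - 3 >= 2 && accend[j - 4] && klim >= 1 && Dmax[klim] > NEG) {
          double w = Dmax[klim] - intron_open + s;
          if (w > best) { best = w; move = 4; dnr(i, j) = Darg[klim]; }
        }
      }
      if (j >= 3) {
        double v = Ecur[j - 3] - gap;  // genomic codon insertion
        if (v > best) { best = v; move = 3; }
      }
      Ecur[j] = best; tb(i, j) = move;
    }
    std::swap(Eprev, Ecur);
  }

  // best end (global in query): smallest j on ties
  double bestScore = NEG; int jbest = 0;
  for (int j = 0; j <= n; ++j)
    if (Eprev[j] > bestScore) { bestScore = Eprev[j]; jbest = j; }

  IntegerVector gpos(m, 0);
  std::vector<int> intr;
  if (bestScore > 0.0) {
    int i = m, j = jbest;
    while (i > 0) {
      int move = tb(i, j);
      if (move == 1) { gpos[i - 1] = j; --i; j -= 3; }
      else if (move == 2) { gpos[i - 1] = 0; --i; }
      else if (move == 3) { j -= 3; }
      else {  // intron
        int d = dnr(i, j);
        gpos[i - 1] = j;
        intr.push_back(d); intr.push_back(j - 3);
        --i; j = d - 1;
      }
    }
  }
  int ni = intr.size() / 2;
  IntegerMatrix introns(ni, 2);
  for (int k = 0; k < ni; ++k) {  // recorded back-to-front
    introns(k, 0) = intr[2 * (ni - 1 - k)];
    introns(k, 1) = intr[2 * (ni - 1 - k) + 1];
  }
  return List::create(_["score"] = bestScore > 0.0 ? bestScore : 0.0,
                      _["gpos"] = gpos, _["introns"] = introns);
}

static double pssm_local_one(const int *pep, int plen, const NumericMatrix &pssm,
                             const NumericVector &del_cost, double ins_cost) {
  const int L = pssm.ncol();
  std::vector<double> prev(L + 1, 0.0), cur(L + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= plen; ++i) {
    cur[0] = 0.0;
    const int a = pep[i - 1];
    for (int j = 1; j <= L; ++j) {
      double s = (a >= 1 && a <= pssm.nrow()) ? pssm(a - 1, j - 1) : -1.0;
      double v = prev[j - 1] + s;
      if (prev[j] - ins_cost > v) v = prev[j] - ins_cost;        // extra residue
      if (cur[j - 1] - del_cost[j - 1] > v) v = cur[j - 1] - del_cost[j - 1];
      if (v < 0.0) v = 0.0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Best local alignment score of a peptide against a position profile
// (rows: 20 amino acids; cols: profile positions).  Skipping a profile
// column costs del_cost[j] (cheap at sparsely occupied spacer slots, like
// an HMM insert state); an unaligned peptide residue costs ins_cost.
// pep: 1-based amino-acid codes (0 = unknown, scored -1).
// [[Rcpp::export(name = ".pssm_local_score_cpp")]]
double pssm_local_score_cpp(IntegerVector pep, NumericMatrix pssm,
                            NumericVector del_cost, double ins_cost) {
  return pssm_local_one(INTEGER(pep), pep.size(), pssm, del_cost, ins_cost);
}

// Null-score batch: one score per row of peps (0-padded on the right).
// [[Rcpp::export(name = ".pssm_null_scores_cpp")]]
NumericVector pssm_null_scores_cpp(IntegerMatrix peps, NumericMatrix pssm,
                                   NumericVector del_cost, double ins_cost) {
  const int nr = peps.nrow(), nc = peps.ncol();
  NumericVector out(nr);
  std::vector<int> buf(nc);
  for (int r = 0; r < nr; ++r) {
    int len = 0;
    for (int c = 0; c < nc; ++c) {
      int v = peps(r, c);
      if (v == 0) break;
      buf[len++] = v;
    }
    out[r] = pssm_local_one(buf.data(), len, pssm, del_cost, ins_cost);
  }
  return out;
}
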