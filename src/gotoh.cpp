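#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Three-state Gotoh global alignment with affine gaps.
// States: M = match/substitution, X = gap in b (deletion from a),
//         Y = gap in a (insertion in b).
// A gap of length L costs gap_open + gap_extend * L.
// Tie-breaking is fixed: prefer M, then X, then Y, both when choosing the
// source state of a cell and when choosing the final state, so alignments
// are bit-reproducible.

static const double NEG_INF = -1e18;

enum State { SM = 0, SX = 1, SY = 2 };

// pick argmax with preference M > X > Y on ties
static inline int argmax3(double m, double x, double y, double &best) {
  best = m; int s = SM;
  if (x > best) { best = x; s = SX; }
  if (y > best) { best = y; s = SY; }
  return s;
}

struct AlnResult {
  std::string a, b;
  double score;
};

static AlnResult gotoh_core(const std::string &a, const std::string &b,
                            double match, double mismatch,
                            double gap_open, double gap_extend,
                            bool end_gaps) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  const double open1 = gap_open + gap_extend; // cost of a new 1-residue gap

  std::vector<double> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);
  std::vector<signed char> tm((n + 1) * W), tx((n + 1) * W), ty((n + 1) * W);

  M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M[i * W] = NEG_INF;
    Y[i * W] = NEG_INF;
    X[i * W] = end_gaps ? -(gap_open + gap_extend * i) : 0.0;
    tx[i * W] = (i == 1) ? SM : SX;
  }
  for (int j = 1; j <= m; ++j) {
    M[j] = NEG_INF;
    X[j] = NEG_INF;
    Y[j] = end_gaps ? -(gap_open + gap_extend * j) : 0.0;
    ty[j] = (j == 1) ? SM : SY;
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    const int r = i * W, rp = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = (ai == b[j - 1]) ? match : mismatch;
      double best;
      // M: diagonal from any state
      tm[r + j] = (signed char)argmax3(M[rp + j - 1], X[rp + j - 1], Y[rp + j - 1], best);
      M[r + j] = best + s;
      // X: from (i-1, j), consuming a[i-1] against a gap
      tx[r + j] = (signed char)argmax3(M[rp + j] - open1, X[rp + j] - gap_extend,
                                       Y[rp + j] - open1, best);
      X[r + j] = best;
      // Y: from (i, j-1), consuming b[j-1] against a gap
      ty[r + j] = (signed char)argmax3(M[r + j - 1] - open1, X[r + j - 1] - open1,
                                       Y[r + j - 1] - gap_extend, best);
      Y[r + j] = best;
    }
  }

  // choose the traceback start
  int si = n, sj = m, sstate;
  double sscore;
  {
    double best;
    int st = argmax3(M[n * W + m], X[n * W + m], Y[n * W + m], best);
    sstate = st; sscore = best;
  }
  if (!end_gaps) {
    // free end gaps: best over last row and last column, (n, m) preferred,
    // then last row right-to-left, then last column bottom-to-top
    for (int j = m - 1; j >= 0; --j) {
      double best;
      int st = argmax3(M[n * W + j], X[n * W + j], Y[n * W + j], best);
      if (best > sscore) { sscore = best; si = n; sj = j; sstate = st; }
    }
    for (int i = n - 1; i >= 0; --i) {
      double best;
      int st = argmax3(M[i * W + m], X[i * W + m], Y[i * W + m], best);
      if (best > sscore) { sscore = best; si = i; sj = m; sstate = st; }
    }
  }

  std::string ra, rb; // reversed
  ra.reserve(n + m); rb.reserve(n + m);
  // trailing unaligned tails (free end gaps only)
  for (int j = m; j > sj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  for (int i = n; i > si; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

  int i = si, j = sj, st = sstate;
  while (i > 0 || j > 0) {
    if (st == SM) {
      int nxt = tm[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; st = nxt;
    } else if (st == SX) {
      int nxt = tx[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = nxt;
    } else {
      int nxt = ty[i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = nxt;
    }
  }
  AlnResult out;
  out.a.assign(ra.rbegin(), ra.rend());
  out.b.assign(rb.rbegin(), rb.rend());
  out.score = sscore;
  return out;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align_cpp(std::string a, std::string b, double match, double mismatch,
                     double gap_open, double gap_extend, bool end_gaps) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  AlnResult r = gotoh_core(a, b, match, mismatch, gap_open, gap_extend, end_gaps);
  return List::create(_["aligned_a"] = r.a, _["aligned_b"] = r.b,
                      _["score"] = r.score);
}

// Align many b sequences against one a (the reference); returns parallel
// character/numeric vectors to keep R-side overhead low.
// [[Rcpp::export(name = ".gotoh_align_batch")]]
List gotoh_align_batch_cpp(std::string a, CharacterVector bs, double match,
                           double mismatch, double gap_open, double gap_extend,
                           bool end_gaps) {
  const int nb = bs.size();
  CharacterVector aa(nb), ab(nb);
  NumericVector sc(nb);
  for (int k = 0; k < nb; ++k) {
    std::string b = as<std::string>(bs[k]);
    if (a.empty() || b.empty()) stop("sequences must be non-empty");
    AlnResult r = gotoh_core(a, b, match, mismatch, gap_open, gap_extend, end_gaps);
    aa[k] = r.a; ab[k] = r.b; sc[k] = r.score;
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["aligned_a"] = aa, _["aligned_b"] = ab, _["score"] = sc);
}

// Paired-end merge. r2c is mate 2 already reverse-complemented and q2c its
// quality reversed, so both sequences are in mate-1 orientation and the
// overlap is a suffix of r1 against a prefix of r2c. Chooses the overlap
// length maximizing matched bases subject to mismatch fraction <=
// max_mismatch_frac and length >= min_overlap; ties go to the longer
// overlap. Discordant overlap columns take the base with the higher Phred
// quality (ties -> mate 1); concordant columns keep the higher quality.
// [[Rcpp::export(name = ".merge_pairs_batch")]]
List merge_pairs_batch_cpp(CharacterVector r1, CharacterVector q1,
                           CharacterVector r2c, CharacterVector q2c,
                           int min_overlap, double max_mismatch_frac) {
  const int n = r1.size();
  CharacterVector seq(n), qual(n);
  IntegerVector overlap(n);
  LogicalVector merged(n);
  for (int k = 0; k < n; ++k) {
    std::string s1 = as<std::string>(r1[k]), u1 = as<std::string>(q1[k]);
    std::string s2 = as<std::string>(r2c[k]), u2 = as<std::string>(q2c[k]);
    if (s1.size() != u1.size() || s2.size() != u2.size())
      stop("sequence/quality length mismatch in pair %d", k + 1);
    const int l1 = (int)s1.size(), l2 = (int)s2.size();
    const int omax = std::min(l1, l2);
    int best_o = -1, best_matched = -1;
    for (int o = omax; o >= min_overlap; --o) {
      int mm = 0;
      const int off = l1 - o;
      for (int t = 0; t < o; ++t) if (s1[off + t] != s2[t]) ++mm;
      if ((double)mm / o <= max_mismatch_frac) {
        const int matched = o - mm;
        if (matched > best_matched) { best_matched = matched; best_o = o; }
      }
    }
    if (best_o < 0) {
      seq[k] = NA_STRING; qual[k] = NA_STRING; overlap[k] = NA_INTEGER;
      merged[k] = false;
      continue;
    }
    const int o = best_o, off = l1 - o;
    std::string ms = s1.substr(0, off), mq = u1.substr(0, off);
    ms.reserve(l1 + l2 - o); mq.reserve(l1 + l2 - o);
    for (int t = 0; t < o; ++t) {
      const char b1 = s1[off + t], b2 = s2[t];
      const char c1 = u1[off + t], c2 = u2[t];
      if (b1 == b2) { ms.push_back(b1); mq.push_back(c1 >= c2 ? c1 : c2); }
      else if (c2 > c1) { ms.push_back(b2); mq.push_back(c2); }
      else { ms.push_back(b1); mq.push_back(c1); }
    }
    ms += s2.substr(o); mq += u2.substr(o);
    seq[k] = ms; qual[k] = mq; overlap[k] = o; merged[k] = true;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual,
                      _["overlap_len"] = overlap, _["merged"] = merged);
}

// Remove the longest 3' suffix of each read matching a prefix of the adapter
// with mismatch fraction <= max_err_frac and length >= min_overlap.
// [[Rcpp::export(name = ".trim_adapter_batch")]]
List trim_adapter_batch_cpp(CharacterVector seqs, CharacterVector quals,
                            std::string adapter, int min_overlap,
                            double max_err_frac) {
  const int n = seqs.size();
  const int la = (int)adapter.size();
  CharacterVector ts(n), tq(n);
  IntegerVector trimmed(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(seqs[k]), q = as<std::string>(quals[k]);
    if (s.size() != q.size()) stop("sequence/quality length mismatch in read %d", k + 1);
    const int l = (int)s.size();
    int best = 0;
    const int kmax = std::min(l, la);
    for (int m = kmax; m >= min_overlap; --m) {
      int mm = 0;
      const int off = l - m;
      for (int t = 0; t < m; ++t) if (s[off + t] != adapter[t]) ++mm;
      if ((double)mm / m <= max_err_frac) { best = m; break; } // longest wins
    }
    ts[k] = s.substr(0, l - best);
    tq[k] = q.substr(0, l - best);
    trimmed[k] = best;
  }
  return List::create(_["seq"] = ts, _["qual"] = tq, _["trimmed_len"] = trimmed);
}
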