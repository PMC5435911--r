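#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps and full traceback.
// Gap of length g costs gap_open + g * gap_ext (first gapped base pays
// gap_open + gap_ext), matching the convention of Biostrings.
// Ties are broken toward the smallest subject end coordinate, then the
// smallest query end coordinate, so results are deterministic.
// Returns 0-based half-open coordinates on query and subject.
// [[Rcpp::export]]
List cpp_sw(std::string query, std::string subject,
            int match = 2, int mismatch = -4,
            int gap_open = 6, int gap_ext = 1) {
  const int n = query.size(), m = subject.size();
  const int NEG = -1000000000;
  // H: best score ending at (i,j) in match state; E: gap in query (D op,
  // consumes subject); F: gap in subject (I op, consumes query).
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[at(i, j - 1)] - gap_open - gap_ext,
                       E[at(i, j - 1)] - gap_ext);
      int f = std::max(H[at(i - 1, j)] - gap_open - gap_ext,
                       F[at(i - 1, j)] - gap_ext);
      int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      int d = H[at(i - 1, j - 1)];
      int dd = (E[at(i - 1, j - 1)] > d) ? E[at(i - 1, j - 1)] : d;
      dd = (F[at(i - 1, j - 1)] > dd) ? F[at(i - 1, j - 1)] : dd;
      int h = dd + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["cigar"] = "",
                        _["edits"] = 0);
  }
  // traceback from (bi, bj) in H state
  std::string ops;
  int i = bi, j = bj, edits = 0;
  int state = 0;  // 0 = H, 1 = E (D), 2 = F (I)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int e = E[at(i, j)], f = F[at(i, j)];
      int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      int dd = std::max(H[at(i - 1, j - 1)],
                        std::max(E[at(i - 1, j - 1)], F[at(i - 1, j - 1)]));
      if (h == dd + s) {
        char op = (query[i - 1] == subject[j - 1]) ? 'M' : 'X';
        if (op == 'X') ++edits;
        ops.push_back(op);
        // resolve which state the diagonal came from
        if (H[at(i - 1, j - 1)] == dd) state = 0;
        else if (E[at(i - 1, j - 1)] == dd) state = 1;
        else state = 2;
        --i; --j;
        if (state == 0 && H[at(i, j)] == 0) break;
        if (state != 0) continue;
      } else if (h == e) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back('D');
      ++edits;
      int e = E[at(i, j)];
      if (e == E[at(i, j - 1)] - gap_ext) { --j; state = 1; }
      else { --j; state = 0; if (H[at(i, j)] == 0) break; }
    } else {
      ops.push_back('I');
      ++edits;
      int f = F[at(i, j)];
      if (f == F[at(i - 1, j)] - gap_ext) { --i; state = 2; }
      else { --i; state = 0; if (H[at(i, j)] == 0) break; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cigar;
  size_t k = 0;
  while (k < ops.size()) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k);
    cigar.push_back(ops[k]);
    k = k2;
  }
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj, _["cigar"] = cigar,
                      _["edits"] = edits);
}

// Maximal exact extension of a seed match between query position q0 and
// subject position s0, in both directions. Returns the 0-based half-open
// matched intervals plus the number of mismatches in the `look` bases
// beyond each end (to decide whether gapped alignment could extend
// further). Bounds are the string ends.
// [[Rcpp::export]]
List cpp_exact_extend(std::string query, std::string subject,
                      int q0, int s0, int look = 11) {
  const int n = query.size(), m = subject.size();
  int qs = q0, ss = s0;
  while (qs > 0 && ss > 0 && query[qs - 1] == subject[ss - 1]) { --qs; --ss; }
  int qe = q0, se = s0;
  while (qe < n && se < m && query[qe] == subject[se]) { ++qe; ++se; }
  int mmf = 0, nf = 0;
  for (int t = 1; t <= look && qe + t <= n && se + t <= m; ++t) {
    ++nf;
    if (query[qe + t - 1] != subject[se + t - 1]) ++mmf;
  }
  int mmb = 0, nb = 0;
  for (int t = 1; t <= look && qs - t >= 0 && ss - t >= 0; ++t) {
    ++nb;
    if (query[qs - t] != subject[ss - t]) ++mmb;
  }
  return List::create(_["qstart"] = qs, _["qend"] = qe,
                      _["sstart"] = ss, _["send"] = se,
                      _["mm_fwd"] = mmf, _["n_fwd"] = nf,
                      _["mm_back"] = mmb, _["n_back"] = nb);
}

// Cyclic anchor extension of a collapsed monomer against a circular
// genome: starting from the anchor (query offset q0 matching genome
// position g0), extend forward then backward, treating the query as
// circular with period p = len(query). Isolated mismatches are tolerated
// (up to `budget`) when the following `look` bases all match. Returns the
// forward and backward extents and the mismatch count.
// [[Rcpp::export]]
List cpp_cyclic_extend(std::string query, std::string genome,
                       int q0, int g0, int budget = 2, int look = 6) {
  const int p = query.size(), L = genome.size();
  auto qat = [&](long i) { return query[((i % p) + p) % p]; };
  auto gat = [&](long i) { return genome[((i % L) + L) % L]; };
  int used = 0;
  auto look_ok = [&](long qi, long gi, int dir) {
    for (int t = 1; t <= look; ++t)
      if (qat(qi + (long)dir * t) != gat(gi + (long)dir * t)) return false;
    return true;
  };
  auto extend = [&](int dir, int limit) {
    int t = 0;
    while (t < limit) {
      long qp = q0 + (long)dir * (t + 1);
      long gp = g0 + (long)dir * (t + 1);
      if (qat(qp) == gat(gp)) {
        ++t;
      } else if (used < budget && t + 1 < limit && look_ok(qp, gp, dir)) {
        ++used;
        ++t;
      } else break;
    }
    return t;
  };
  int tf = extend(1, p - 1);
  int tb = extend(-1, p - 1 - tf);
  return List::create(_["tf"] = tf, _["tb"] = tb, _["mismatches"] = used);
}

// Mismatch count of query placed at every offset of subject
// (ungapped). Returns integer vector of length len(subject)-len(query)+1.
// [[Rcpp::export]]
IntegerVector cpp_hamming_scan(std::string query, std::string subject) {
  const int n = query.size(), m = subject.size();
  if (m < n) return IntegerVector(0);
  IntegerVector out(m - n + 1);
  for (int off = 0; off <= m - n; ++off) {
    int mm = 0;
    for (int i = 0; i < n; ++i)
      if (query[i] != subject[off + i]) ++mm;
    out[off] = mm;
  }
  return out;
}

// Leftmost position (1-based) at which a 3' adapter starts in the read:
// internal occurrences must match the full adapter and terminal occurrences
// its prefix, allowing floor(max_error_rate * overlap) mismatches, with a
// minimum terminal overlap. Returns 0 when no occurrence qualifies.
// [[Rcpp::export]]
int cpp_adapter_pos(std::string seq, std::string adapter,
                    double max_error_rate = 0.1, int min_overlap = 3) {
  const int n = seq.size(), na = adapter.size();
  for (int st = 0; st + min_overlap <= n; ++st) {
    const int o = std::min(na, n - st);
    const int allowed = (int)(max_error_rate * o);
    int mm = 0;
    for (int i = 0; i < o && mm <= allowed; ++i)
      if (seq[st + i] != adapter[i]) ++mm;
    if (mm <= allowed) return st + 1;
  }
  return 0;
}

// Mismatches between the last o bases of a and the first o bases of b,
// for every candidate overlap length o = 1..min(len(a), len(b)).
// [[Rcpp::export]]
IntegerVector cpp_overlap_mismatches(std::string a, std::string b) {
  const int na = a.size(), nb = b.size();
  const int omax = std::min(na, nb);
  IntegerVector out(omax);
  for (int o = 1; o <= omax; ++o) {
    int mm = 0;
    const int start = na - o;
    for (int i = 0; i < o; ++i)
      if (a[start + i] != b[i]) ++mm;
    out[o - 1] = mm;
  }
  return out;
}

// Self-correlation period scan: for each candidate period p, the number of
// mismatching positions between seq[i] and seq[i+p] over all valid i, and
// the number of comparisons made.
// [[Rcpp::export]]
List cpp_period_scan(std::string seq, int minp, int maxp) {
  const int n = seq.size();
  if (maxp < minp) return List::create(_["period"] = IntegerVector(0),
                                       _["mismatches"] = IntegerVector(0),
                                       _["compared"] = IntegerVector(0));
  const int np = maxp - minp + 1;
  IntegerVector period(np), mism(np), comp(np);
  for (int p = minp; p <= maxp; ++p) {
    int mm = 0;
    const int lim = n - p;
    for (int i = 0; i < lim; ++i)
      if (seq[i] != seq[i + p]) ++mm;
    period[p - minp] = p;
    mism[p - minp] = mm;
    comp[p - minp] = lim;
  }
  return List::create(_["period"] = period, _["mismatches"] = mism,
                      _["compared"] = comp);
}

// Per-column majority-vote consensus over the tandem copies of a read with
// a given period; the partial last copy contributes where present.
// Ties go to the base of the earliest copy. Also returns the mean
// per-column agreement of the winning base.
// [[Rcpp::export]]
List cpp_consensus(std::string seq, int period) {
  const int n = seq.size();
  std::string cons(period, 'N');
  double support = 0.0;
  for (int col = 0; col < period; ++col) {
    int counts[5] = {0, 0, 0, 0, 0};  // A C G T other
    int total = 0;
    for (int pos = col; pos < n; pos += period) {
      int k;
      switch (seq[pos]) {
        case 'A': k = 0; break;
        case 'C': k = 1; break;
        case 'G': k = 2; break;
        case 'T': k = 3; break;
        default: k = 4;
      }
      ++counts[k];
      ++total;
    }
    int bestk = -1, bestc = -1;
    for (int pos = col; pos < n; pos += period) {  // earliest copy wins ties
      int k;
      switch (seq[pos]) {
        case 'A': k = 0; break;
        case 'C': k = 1; break;
        case 'G': k = 2; break;
        case 'T': k = 3; break;
        default: k = 4;
      }
      if (counts[k] > bestc) { bestc = counts[k]; bestk = k; }
    }
    const char bases[6] = "ACGTN";
    cons[col] = bases[bestk];
    support += (double)bestc / total;
  }
  return List::create(_["consensus"] = cons,
                      _["support"] = support / period);
}
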