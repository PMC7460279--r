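#include <Rcpp.h>
using namespace Rcpp;

// Constraint-based ROH calling on one chromosome of one individual.
//
// Genotype codes: 0/2 homozygous, 1 heterozygous, NA missing.
// A window [i, j] (0-based SNP indices) is feasible when
//   het(i..j)            <= max_het
//   missing(i..j)        <= max_missing
//   j - i + 1            >= min_snps
//   pos[j] - pos[i]      >= min_length_bp
//   (pos[j] - pos[i]) / (j - i + 1) <= max_density_bp_per_snp
//   no inter-SNP gap within (i..j] exceeds max_gap_bp
// Emitted segments are the greedy longest-first (ties: leftmost start)
// selection of non-overlapping feasible windows — identical to sorting the
// full feasible set by (length desc, start asc) and discarding any window
// overlapping an already selected one.

namespace {

struct Seg {
  int i, j;          // 0-based inclusive SNP index range
  double len;        // bp span pos[j] - pos[i]
};

// prefix sums over the whole chromosome; het[k], mis[k] = counts in [0, k)
struct Prefix {
  std::vector<int> het, mis;
  explicit Prefix(const IntegerVector& codes) {
    int m = codes.size();
    het.assign(m + 1, 0);
    mis.assign(m + 1, 0);
    for (int k = 0; k < m; ++k) {
      bool na = IntegerVector::is_na(codes[k]);
      het[k + 1] = het[k] + (!na && codes[k] == 1 ? 1 : 0);
      mis[k + 1] = mis[k] + (na ? 1 : 0);
    }
  }
  int nhet(int i, int j) const { return het[j + 1] - het[i]; }
  int nmis(int i, int j) const { return mis[j + 1] - mis[i]; }
};

// Longest feasible window inside index range [a, b]; ties -> leftmost start.
// Gap constraint is already guaranteed by block splitting.
bool bestWindow(const Prefix& pre, const IntegerVector& pos, int a, int b,
                int min_snps, double min_length_bp, int max_het,
                int max_missing, double max_density, Seg& out) {
  bool found = false;
  int J = a;  // two-pointer upper end for het/missing feasibility
  for (int i = a; i <= b; ++i) {
    if (J < i) J = i;
    while (J + 1 <= b && pre.nhet(i, J + 1) <= max_het &&
           pre.nmis(i, J + 1) <= max_missing)
      ++J;
    int jmax = J;
    // lower bound on j from min_snps and min_length
    int jlo = i + min_snps - 1;
    if (jlo > jmax) continue;
    while (jlo <= jmax &&
           (double)(pos[jlo] - pos[i]) < min_length_bp)
      ++jlo;
    if (jlo > jmax) continue;
    // largest j in [jlo, jmax] meeting the density bound
    for (int j = jmax; j >= jlo; --j) {
      double len = (double)pos[j] - (double)pos[i];
      if (len <= max_density * (double)(j - i + 1)) {
        if (!found || len > out.len) {  // strictly longer, or first
          out.i = i; out.j = j; out.len = len;
          found = true;
        }
        break;  // smaller j only shortens this start
      }
    }
  }
  return found;
}

}  // namespace

// [[Rcpp::export(name = ".roh_segment_chrom")]]
DataFrame roh_segment_chrom(IntegerVector codes, IntegerVector pos,
                            int min_snps, double min_length_bp, int max_het,
                            int max_missing, double max_density_bp_per_snp,
                            double max_gap_bp) {
  int m = codes.size();
  if (pos.size() != m) stop("codes and positions differ in length");
  for (int k = 1; k < m; ++k)
    if (pos[k] <= pos[k - 1]) stop("positions must be strictly increasing");

  Prefix pre(codes);
  std::vector<int> si, sj;

  // split into blocks at gaps > max_gap_bp; recurse greedily within blocks
  int bstart = 0;
  for (int k = 1; k <= m; ++k) {
    bool cut = (k == m) || ((double)pos[k] - (double)pos[k - 1] > max_gap_bp);
    if (!cut) continue;
    // process block [bstart, k-1] with an explicit stack of free ranges
    std::vector<std::pair<int, int> > stack;
    if (k - 1 >= bstart) stack.push_back(std::make_pair(bstart, k - 1));
    while (!stack.empty()) {
      std::pair<int, int> r = stack.back();
      stack.pop_back();
      if (r.second - r.first + 1 < min_snps) continue;
      Seg best;
      if (!bestWindow(pre, pos, r.first, r.second, min_snps, min_length_bp,
                      max_het, max_missing, max_density_bp_per_snp, best))
        continue;
      si.push_back(best.i);
      sj.push_back(best.j);
      if (best.i - 1 >= r.first)
        stack.push_back(std::make_pair(r.first, best.i - 1));
      if (r.second >= best.j + 1)
        stack.push_back(std::make_pair(best.j + 1, r.second));
    }
    bstart = k;
  }

  // sort selected segments by start index
  std::vector<size_t> ord(si.size());
  for (size_t t = 0; t < ord.size(); ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(),
            [&](size_t x, size_t y) { return si[x] < si[y]; });

  int n = (int)ord.size();
  IntegerVector start_idx(n), end_idx(n), n_snps(n), n_het(n), n_missing(n);
  for (int t = 0; t < n; ++t) {
    int i = si[ord[t]], j = sj[ord[t]];
    start_idx[t] = i + 1;  // 1-based for R
    end_idx[t] = j + 1;
    n_snps[t] = j - i + 1;
    n_het[t] = pre.nhet(i, j);
    n_missing[t] = pre.nmis(i, j);
  }
  return DataFrame::create(_["start_idx"] = start_idx, _["end_idx"] = end_idx,
                           _["n_snps"] = n_snps, _["n_het"] = n_het,
                           _["n_missing"] = n_missing);
}

// Sliding-window heuristic: windows of `window_snps` consecutive SNPs are
// scored homozygous when they contain <= max_het heterozygotes and
// <= max_missing missing calls; a SNP is in-run when the fraction of
// windows covering it that are homozygous is >= hit_threshold. Maximal
// in-run stretches are split at gaps > max_gap_bp, then filtered by the
// five segment-level constraints.
// [[Rcpp::export(name = ".roh_window_chrom")]]
DataFrame roh_window_chrom(IntegerVector codes, IntegerVector pos,
                           int window_snps, double hit_threshold,
                           int min_snps, double min_length_bp, int max_het,
                           int max_missing, double max_density_bp_per_snp,
                           double max_gap_bp) {
  int m = codes.size();
  if (pos.size() != m) stop("codes and positions differ in length");
  for (int k = 1; k < m; ++k)
    if (pos[k] <= pos[k - 1]) stop("positions must be strictly increasing");

  Prefix pre(codes);
  std::vector<bool> inrun(m, false);
  if (m >= window_snps) {
    // hit[s] = window starting at s is homozygous
    int nw = m - window_snps + 1;
    std::vector<int> hitcum(nw + 1, 0);
    for (int s = 0; s < nw; ++s) {
      int e = s + window_snps - 1;
      bool hom = pre.nhet(s, e) <= max_het && pre.nmis(s, e) <= max_missing;
      hitcum[s + 1] = hitcum[s] + (hom ? 1 : 0);
    }
    for (int k = 0; k < m; ++k) {
      int slo = std::max(0, k - window_snps + 1);
      int shi = std::min(k, nw - 1);
      if (shi < slo) continue;
      int cover = shi - slo + 1;
      int hits = hitcum[shi + 1] - hitcum[slo];
      if ((double)hits / (double)cover >= hit_threshold) inrun[k] = true;
    }
  }

  std::vector<int> si, sj;
  int k = 0;
  while (k < m) {
    if (!inrun[k]) { ++k; continue; }
    int s = k;
    while (k + 1 < m && inrun[k + 1]) ++k;
    int e = k;
    ++k;
    // split stretch at large gaps
    int cs = s;
    for (int t = s + 1; t <= e + 1; ++t) {
      bool cut = (t == e + 1) ||
                 ((double)pos[t] - (double)pos[t - 1] > max_gap_bp);
      if (!cut) continue;
      int ce = t - 1;
      double len = (double)pos[ce] - (double)pos[cs];
      int n = ce - cs + 1;
      if (n >= min_snps && len >= min_length_bp &&
          len <= max_density_bp_per_snp * (double)n &&
          pre.nhet(cs, ce) <= max_het && pre.nmis(cs, ce) <= max_missing) {
        si.push_back(cs);
        sj.push_back(ce);
      }
      cs = t;
    }
  }

  int n = (int)si.size();
  IntegerVector start_idx(n), end_idx(n), n_snps(n), n_het(n), n_missing(n);
  for (int t = 0; t < n; ++t) {
    start_idx[t] = si[t] + 1;
    end_idx[t] = sj[t] + 1;
    n_snps[t] = sj[t] - si[t] + 1;
    n_het[t] = pre.nhet(si[t], sj[t]);
    n_missing[t] = pre.nmis(si[t], sj[t]);
  }
  return DataFrame::create(_["start_idx"] = start_idx, _["end_idx"] = end_idx,
                           _["n_snps"] = n_snps, _["n_het"] = n_het,
                           _["n_missing"] = n_missing);
}
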