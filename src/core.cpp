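#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Extend haplotype group partitions one SNP at a time and record EHH.
// EHH at a point = sum_g C(n_g,2) / C(m,2) over the partition of the m
// carrier haplotypes by their allele string from the core out to that point.
// Truncation: stop after the first point with EHH < min_ehh, and stop
// (without crossing) at any inter-SNP gap > max_gap_bp.
// Group refinement uses a dense relabel table indexed by 2*group+allele;
// only touched entries are reset, so each step is O(m).
static void extend_side(const IntegerMatrix& haps, const NumericVector& pos,
                        const std::vector<int>& carriers,
                        std::vector<int>& group, int ngroups,
                        int from, int step, int last,
                        double min_ehh, double max_gap_bp,
                        std::vector<double>& out_pos,
                        std::vector<double>& out_ehh) {
  const int m = (int)carriers.size();
  const double denom = (double)m * (m - 1) / 2.0;
  double prev_pos = pos[from];
  std::vector<int> relabel(2 * m, -1), touched, counts;
  touched.reserve(2 * m);
  for (int j = from + step; step > 0 ? j <= last : j >= last; j += step) {
    if (std::abs(pos[j] - prev_pos) > max_gap_bp) break;
    prev_pos = pos[j];
    touched.clear();
    int next_id = 0;
    for (int k = 0; k < m; ++k) {
      int key = 2 * group[k] + haps(carriers[k], j);
      if (relabel[key] < 0) {
        relabel[key] = next_id++;
        touched.push_back(key);
      }
      group[k] = relabel[key];
    }
    for (int key : touched) relabel[key] = -1;
    ngroups = next_id;
    counts.assign(ngroups, 0);
    for (int k = 0; k < m; ++k) counts[group[k]]++;
    double num = 0.0;
    for (int gidx = 0; gidx < ngroups; ++gidx)
      num += (double)counts[gidx] * (counts[gidx] - 1) / 2.0;
    double e = num / denom;
    out_pos.push_back(pos[j]);
    out_ehh.push_back(e);
    if (e < min_ehh) break;
    if (ngroups == m) break;             // all singletons; EHH stays 0
  }
}

// [[Rcpp::export]]
List ehh_profile_cpp(const IntegerMatrix& haps, const NumericVector& pos,
                     int core, const IntegerVector& carriers,
                     double min_ehh, double max_gap_bp, bool split_core) {
  const int L = haps.ncol();
  std::vector<int> car(carriers.begin(), carriers.end());
  const int m = (int)car.size();
  if (m < 2) stop("need at least 2 carrier haplotypes");
  std::vector<int> group(m, 0);
  int ngroups = 1;
  double core_ehh = 1.0;
  if (split_core) {
    // partition by the core allele itself (pooled/site EHH)
    int n1 = 0;
    for (int k = 0; k < m; ++k) {
      group[k] = haps(car[k], core);
      n1 += group[k];
    }
    ngroups = (n1 == 0 || n1 == m) ? 1 : 2;
    if (ngroups == 1) for (int k = 0; k < m; ++k) group[k] = 0;
    double denom = (double)m * (m - 1) / 2.0;
    core_ehh = ((double)n1 * (n1 - 1) / 2.0 +
                (double)(m - n1) * (m - n1 - 1) / 2.0) / denom;
  }
  std::vector<double> lp, le, rp, re;
  lp.push_back(pos[core]); le.push_back(core_ehh);
  rp.push_back(pos[core]); re.push_back(core_ehh);
  if (core_ehh >= min_ehh) {
    std::vector<int> gl(group), gr(group);
    extend_side(haps, pos, car, gl, ngroups, core, -1, 0,
                min_ehh, max_gap_bp, lp, le);
    extend_side(haps, pos, car, gr, ngroups, core, +1, L - 1,
                min_ehh, max_gap_bp, rp, re);
  }
  return List::create(_["pos_left"] = lp, _["ehh_left"] = le,
                      _["pos_right"] = rp, _["ehh_right"] = re);
}

// One Wright-Fisher generation with recombination and fitness-weighted
// parent sampling, on TRANSPOSED haplotype storage (sites x haplotypes,
// so each gamete copy walks a contiguous column). parentsT: L x 2*Np
// (columns 2i, 2i+1 = individual i); fitness: length Np; cummap:
// cumulative genetic map position (Morgans) per site. Crossovers are a
// Poisson process on the map (Haldane, no interference). Uses R's RNG,
// so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix wf_next_gen_cpp(const IntegerMatrix& parentsT, int n_children,
                              const NumericVector& fitness,
                              const NumericVector& cummap) {
  const int L = parentsT.nrow();
  const int np = parentsT.ncol() / 2;
  if ((int)fitness.size() != np) stop("fitness length mismatch");
  std::vector<double> cum(np);
  double tot = 0.0;
  for (int i = 0; i < np; ++i) { tot += fitness[i]; cum[i] = tot; }
  if (tot <= 0) stop("total fitness must be positive");
  const double map_len = cummap[L - 1] - cummap[0];
  IntegerMatrix childT(L, 2 * n_children);
  const int* par_ptr = INTEGER(parentsT);
  int* chi_ptr = INTEGER(childT);
  std::vector<double> cx;
  for (int c = 0; c < 2 * n_children; ++c) {
    double u = unif_rand() * tot;
    int pidx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (pidx >= np) pidx = np - 1;
    int h = unif_rand() < 0.5 ? 0 : 1;
    const int* col0 = par_ptr + (size_t)L * (2 * pidx);
    const int* col1 = par_ptr + (size_t)L * (2 * pidx + 1);
    int* out = chi_ptr + (size_t)L * c;
    int nc = map_len > 0 ? (int)R::rpois(map_len) : 0;
    if (nc == 0) {
      const int* src = h == 0 ? col0 : col1;
      std::copy(src, src + L, out);
    } else {
      cx.resize(nc);
      for (int k = 0; k < nc; ++k) cx[k] = cummap[0] + unif_rand() * map_len;
      std::sort(cx.begin(), cx.end());
      int k = 0;
      for (int l = 0; l < L; ++l) {
        while (k < nc && cx[k] < cummap[l]) { h = 1 - h; ++k; }
        out[l] = h == 0 ? col0[l] : col1[l];
      }
    }
  }
  return childT;
}
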