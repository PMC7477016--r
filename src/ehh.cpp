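// Extended haplotype homozygosity and its integrals.
//
// EHH at site x for a core is the probability that two random members of the
// core set carry identical haplotypes over the span core..x, normalised so
// the profile equals 1 at the core (for allele-agnostic cores the
// denominator is the pair-homozygosity at the core itself).  iHH is the
// trapezoidal integral of the profile against physical position, each
// direction truncated where EHH first drops below a cutoff (with linear
// interpolation at the crossing) or at an inter-SNP gap exceeding max_gap.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

inline double npairs(double c) { return c * (c - 1) / 2.0; }

// core membership + initial partition; returns D0 (pair count denominator)
double init_groups(const IntegerMatrix &haps, int core, int mode,
                   std::vector<int> &members, std::vector<int> &labels) {
  int n = haps.nrow();
  members.clear();
  labels.clear();
  if (mode == 2) {
    for (int i = 0; i < n; ++i) {
      members.push_back(i);
      labels.push_back(haps(i, core));
    }
    double c1 = 0, c0 = 0;
    for (int i = 0; i < n; ++i) (haps(i, core) ? c1 : c0) += 1;
    return npairs(c0) + npairs(c1);
  }
  for (int i = 0; i < n; ++i)
    if (haps(i, core) == mode) {
      members.push_back(i);
      labels.push_back(0);
    }
  return npairs((double)members.size());
}

// refine partition by alleles at site j; returns pair count of the
// partition (labels are compact, so keys 2*label+allele fit a flat array)
double refine(const IntegerMatrix &haps, int j,
              const std::vector<int> &members, std::vector<int> &labels) {
  int m = (int)members.size();
  static thread_local std::vector<int> cnt, newid;
  if ((int)cnt.size() < 2 * m + 2) {
    cnt.resize(2 * m + 2);
    newid.resize(2 * m + 2);
  }
  std::fill(cnt.begin(), cnt.begin() + 2 * m + 2, 0);
  for (int i = 0; i < m; ++i) {
    labels[i] = 2 * labels[i] + haps(members[i], j);
    cnt[labels[i]] += 1;
  }
  double num = 0;
  int next = 0;
  for (int k = 0; k < 2 * m + 2; ++k)
    if (cnt[k] > 0) {
      newid[k] = next++;
      num += npairs((double)cnt[k]);
    }
  for (int i = 0; i < m; ++i) labels[i] = newid[labels[i]];
  return num;
}

// walk one direction from the core, integrating EHH; returns iHH and writes
// the distance at which the profile was truncated (crossing or last site)
double walk_ihh(const IntegerMatrix &haps, const NumericVector &pos, int core,
                int dir, double cutoff, double max_gap, double bound,
                double D0, std::vector<int> &members, std::vector<int> &labels,
                double *ended_at) {
  int S = haps.ncol();
  double ihh = 0, prev_d = 0, prev_e = 1.0, prev_pos = pos[core];
  *ended_at = 0;
  for (int j = core + dir; j >= 0 && j < S; j += dir) {
    if (std::abs(pos[j] - prev_pos) > max_gap) break;
    double d = std::abs(pos[j] - pos[core]);
    double e = refine(haps, j, members, labels) / D0;
    if (d > bound) {
      double eb = prev_e + (e - prev_e) * (bound - prev_d) / (d - prev_d);
      ihh += (prev_e + eb) / 2.0 * (bound - prev_d);
      *ended_at = bound;
      return ihh;
    }
    if (e < cutoff) {
      double xstar = prev_d + (prev_e - cutoff) / (prev_e - e) * (d - prev_d);
      ihh += (prev_e + cutoff) / 2.0 * (xstar - prev_d);
      *ended_at = xstar;
      return ihh;
    }
    ihh += (prev_e + e) / 2.0 * (d - prev_d);
    prev_d = d;
    prev_e = e;
    prev_pos = pos[j];
    *ended_at = d;
    if (e == 0) break;
  }
  return ihh;
}

}  // namespace

// Full EHH decay profile around one core (mode: 0/1 = carriers of that
// allele, 2 = all haplotypes with the core-site partition as denominator).
// [[Rcpp::export]]
List ehh_profile_cpp(IntegerMatrix haps, NumericVector pos, int core,
                     int mode, double max_gap) {
  int S = haps.ncol();
  std::vector<int> members, labels;
  double D0 = init_groups(haps, core, mode, members, labels);
  if (D0 <= 0)
    return List::create(_["defined"] = false, _["n_core"] = (int)members.size());
  List out;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> lab = labels;
    std::vector<double> pvec{pos[core]}, evec{1.0};
    double prev_pos = pos[core], num = D0;
    for (int j = core + dir; j >= 0 && j < S; j += dir) {
      if (std::abs(pos[j] - prev_pos) > max_gap) break;
      if (num > 0) num = refine(haps, j, members, lab);
      pvec.push_back(pos[j]);
      evec.push_back(num / D0);
      prev_pos = pos[j];
    }
    out[dir < 0 ? "left" : "right"] =
        DataFrame::create(_["pos"] = pvec, _["ehh"] = evec);
  }
  out["defined"] = true;
  out["n_core"] = (int)members.size();
  out["d0"] = D0;
  return out;
}

// iHH per core for one mode; NA where the core set has < 2 members
// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix haps, NumericVector pos,
                           IntegerVector cores, double cutoff, double max_gap,
                           int mode, Nullable<NumericMatrix> bounds = R_NilValue) {
  int nc = cores.size();
  NumericVector out(nc, NA_REAL);
  NumericMatrix B;
  bool has_b = bounds.isNotNull();
  if (has_b) B = NumericMatrix(bounds);
  std::vector<int> members, labels;
  for (int k = 0; k < nc; ++k) {
    int core = cores[k];
    double D0 = init_groups(haps, core, mode, members, labels);
    if (D0 <= 0) continue;
    double ihh = 0, ended;
    for (int d = 0; d < 2; ++d) {
      std::vector<int> lab = labels;
      double bound = has_b ? B(k, d) : R_PosInf;
      ihh += walk_ihh(haps, pos, core, d == 0 ? -1 : 1, cutoff, max_gap,
                      bound, D0, members, lab, &ended);
    }
    out[k] = ihh;
  }
  return out;
}

// distance from the core at which the allele-agnostic EHH profile is
// truncated on each side (cutoff crossing, gap, or chromosome end)
// [[Rcpp::export]]
NumericMatrix ehh_crossing_cpp(IntegerMatrix haps, NumericVector pos,
                               IntegerVector cores, double cutoff,
                               double max_gap) {
  int nc = cores.size();
  NumericMatrix out(nc, 2);
  std::vector<int> members, labels;
  for (int k = 0; k < nc; ++k) {
    double D0 = init_groups(haps, cores[k], 2, members, labels);
    for (int d = 0; d < 2; ++d) {
      double ended = NA_REAL;
      if (D0 > 0) {
        std::vector<int> lab = labels;
        walk_ihh(haps, pos, cores[k], d == 0 ? -1 : 1, cutoff, max_gap,
                 R_PosInf, D0, members, lab, &ended);
      }
      out(k, d) = ended;
    }
  }
  return out;
}
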