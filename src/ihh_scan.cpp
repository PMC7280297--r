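#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One-sided EHH walk with trapezoid accumulation.
// H: n x m haplotype matrix (0/1), carriers: row indices of the core-allele
// carriers, j0: core column, dir: +1 (right) or -1 (left).
// Returns integrated EHH in bp; sets truncated when the chromosome ends
// before EHH drops below the cutoff.
static double walk_side(const IntegerMatrix &H, const NumericVector &pos,
                        const std::vector<int> &carriers, int j0, int dir,
                        double cutoff, bool &truncated) {
  const int m = H.ncol();
  const int na = (int)carriers.size();
  const double denom = (double)na * (na - 1) / 2.0;
  std::vector<int> grp(na, 0);
  std::vector<int> remap(2 * na, -1);
  std::vector<int> sizes(na, 0);

  double ehh_prev = 1.0, pos_prev = pos[j0], ihh = 0.0;
  truncated = true;
  int j = j0 + dir;
  while (j >= 0 && j < m) {
    int next_id = 0;
    std::vector<int> used;
    used.reserve(na);
    for (int i = 0; i < na; ++i) {
      int key = grp[i] * 2 + H(carriers[i], j);
      if (remap[key] < 0) {
        remap[key] = next_id++;
        used.push_back(key);
      }
      grp[i] = remap[key];
    }
    for (size_t k = 0; k < used.size(); ++k) remap[used[k]] = -1;

    std::fill(sizes.begin(), sizes.begin() + next_id, 0);
    for (int i = 0; i < na; ++i) sizes[grp[i]]++;
    double hom = 0.0;
    for (int g = 0; g < next_id; ++g)
      hom += (double)sizes[g] * (sizes[g] - 1) / 2.0;
    double ehh = hom / denom;

    ihh += (pos[j] - pos_prev) * dir * (ehh_prev + ehh) / 2.0;
    pos_prev = pos[j];
    ehh_prev = ehh;
    if (ehh < cutoff) {
      truncated = false;
      break;
    }
    j += dir;
  }
  return ihh;
}

// [[Rcpp::export]]
List ihh_scan_cpp(IntegerMatrix H, NumericVector pos, double cutoff,
                  double min_freq, bool integrate_truncated) {
  const int n = H.nrow(), m = H.ncol();
  NumericVector ihh_a(m, NA_REAL), ihh_d(m, NA_REAL), freq(m);
  LogicalVector scored(m, false);

  for (int j = 0; j < m; ++j) {
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += H(i, j);
    double p = (double)n1 / n;
    freq[j] = p;
    int n0 = n - n1;
    if (n1 < 2 || n0 < 2 || p < min_freq || p > 1.0 - min_freq) continue;

    std::vector<int> der, anc;
    der.reserve(n1);
    anc.reserve(n0);
    for (int i = 0; i < n; ++i) {
      if (H(i, j) == 1) der.push_back(i); else anc.push_back(i);
    }
    bool tr_dl, tr_dr, tr_al, tr_ar;
    double d_l = walk_side(H, pos, der, j, -1, cutoff, tr_dl);
    double d_r = walk_side(H, pos, der, j, +1, cutoff, tr_dr);
    double a_l = walk_side(H, pos, anc, j, -1, cutoff, tr_al);
    double a_r = walk_side(H, pos, anc, j, +1, cutoff, tr_ar);
    bool truncated = tr_dl || tr_dr || tr_al || tr_ar;
    if (truncated && !integrate_truncated) continue;
    ihh_d[j] = d_l + d_r;
    ihh_a[j] = a_l + a_r;
    scored[j] = true;
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["freq"] = freq, _["scored"] = scored);
}
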