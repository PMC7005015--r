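#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX4[4] = {0, 0, -1, 1};
static const int DY4[4] = {-1, 1, 0, 0};

// Connected-component labelling of a logical mask (stored as integer 0/1)
// under 4- or 8-neighbour connectivity. Labels are 1..k in scan order;
// background stays 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nd = (connectivity == 4) ? 4 : 8;
  const int *dx = (connectivity == 4) ? DX4 : DX8;
  const int *dy = (connectivity == 4) ? DY4 : DY8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          int rr = q.front().first, cc = q.front().second;
          q.pop();
          for (int d = 0; d < nd; ++d) {
            int r2 = rr + dy[d], c2 = cc + dx[d];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
                mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              q.push(std::make_pair(r2, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Maximum cluster statistic of a t-map: clusters are connected components of
// {t > tcrit} and, separately, of {t < -tcrit}; the statistic is the pixel
// count (mass = false) or the sum of |t| over the cluster (mass = true).
// Signs are pooled by taking the maximum over both sets. Used in the
// permutation inner loop.
// [[Rcpp::export(name = ".max_cluster_stat")]]
double max_cluster_stat(NumericMatrix tmap, double tcrit, int connectivity,
                        bool mass) {
  const int nr = tmap.nrow(), nc = tmap.ncol();
  const int nd = (connectivity == 4) ? 4 : 8;
  const int *dx = (connectivity == 4) ? DX4 : DX8;
  const int *dy = (connectivity == 4) ? DY4 : DY8;
  std::vector<signed char> state(nr * nc, 0);  // 0 untouched, 1 visited
  double best = 0.0;
  std::queue<int> q;
  for (int sign = 0; sign < 2; ++sign) {
    std::fill(state.begin(), state.end(), 0);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double v = tmap(r, c);
        bool supra = sign == 0 ? (v > tcrit) : (v < -tcrit);
        if (!supra || state[c * nr + r]) continue;
        double stat = 0.0;
        state[c * nr + r] = 1;
        q.push(c * nr + r);
        while (!q.empty()) {
          int idx = q.front();
          q.pop();
          int rr = idx % nr, cc = idx / nr;
          stat += mass ? std::fabs(tmap(rr, cc)) : 1.0;
          for (int d = 0; d < nd; ++d) {
            int r2 = rr + dy[d], c2 = cc + dx[d];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            double v2 = tmap(r2, c2);
            bool s2 = sign == 0 ? (v2 > tcrit) : (v2 < -tcrit);
            if (s2 && !state[c2 * nr + r2]) {
              state[c2 * nr + r2] = 1;
              q.push(c2 * nr + r2);
            }
          }
        }
        if (stat > best) best = stat;
      }
    }
  }
  return best;
}
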