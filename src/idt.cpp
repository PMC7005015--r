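#include <Rcpp.h>
using namespace Rcpp;

// Classic dispersion-threshold (I-DT) scan over one contiguous run of valid
// samples. Inputs are time (ms) and gaze position already converted to
// degrees. Grows a window from the left until it spans min_dur; if its
// dispersion is within max_disp, extends it sample by sample while the
// threshold holds, emits the window, and restarts after it; otherwise slides
// the left edge by one sample. Dispersion is the larger of the x and y ranges
// (metric_sum = false) or their sum (metric_sum = true).
//
// Returns a 2-column integer matrix of (start, end) 1-based indices.
// [[Rcpp::export(name = ".idt_scan")]]
IntegerMatrix idt_scan(NumericVector t, NumericVector xd, NumericVector yd,
                       double min_dur, double max_disp, bool metric_sum) {
  const int n = t.size();
  const double eps = 1e-9;
  std::vector<int> starts, ends;

  int i = 0;
  while (i < n) {
    // minimal window spanning min_dur
    int j = i;
    while (j + 1 < n && t[j] - t[i] < min_dur - eps) ++j;
    if (t[j] - t[i] < min_dur - eps) break;  // tail too short for any fixation

    double xmin = xd[i], xmax = xd[i], ymin = yd[i], ymax = yd[i];
    for (int k = i + 1; k <= j; ++k) {
      if (xd[k] < xmin) xmin = xd[k];
      if (xd[k] > xmax) xmax = xd[k];
      if (yd[k] < ymin) ymin = yd[k];
      if (yd[k] > ymax) ymax = yd[k];
    }
    double disp = metric_sum ? (xmax - xmin) + (ymax - ymin)
                             : std::max(xmax - xmin, ymax - ymin);
    if (disp <= max_disp + eps) {
      while (j + 1 < n) {
        int k = j + 1;
        double nxmin = std::min(xmin, xd[k]), nxmax = std::max(xmax, xd[k]);
        double nymin = std::min(ymin, yd[k]), nymax = std::max(ymax, yd[k]);
        double ndisp = metric_sum ? (nxmax - nxmin) + (nymax - nymin)
                                  : std::max(nxmax - nxmin, nymax - nymin);
        if (ndisp > max_disp + eps) break;
        xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax;
        j = k;
      }
      starts.push_back(i + 1);
      ends.push_back(j + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }

  IntegerMatrix out(starts.size(), 2);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = ends[r];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
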