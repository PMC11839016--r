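#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask (4- or 8-connectivity).
// Labels are assigned 1..N in scan order (column-major, matching R).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * h + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          int r2 = pr + dr8[k], c2 = pc + dc8[k];
          if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(c2 * h + r2);
          }
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double height;   // distance-map value: flood high values first
  long order;      // FIFO tie-break for equal heights
  int pixel;
  int label;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.height != b.height) return a.height < b.height; // max-heap on height
    return a.order > b.order;
  }
};

// Marker-controlled watershed: flood the negated distance map from seed
// markers, restricted to the foreground mask. Every reachable foreground
// pixel is assigned to a basin (no unlabeled ridge); foreground components
// containing no seed stay 0. 8-connected flooding.
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix dmap, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  int h = dmap.nrow(), w = dmap.ncol();
  if (seeds.nrow() != h || seeds.ncol() != w || mask.nrow() != h ||
      mask.ncol() != w)
    stop("watershed inputs must share one shape");
  IntegerMatrix lab(h, w);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long order = 0;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) lab(r, c) = seeds(r, c);
  // push unlabeled mask neighbors of every labeled pixel
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (lab(r, c) == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
        if (mask(r2, c2) && lab(r2, c2) == 0) {
          pq.push({dmap(r2, c2), order++, c2 * h + r2, lab(r, c)});
        }
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int r = e.pixel % h, c = e.pixel / h;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.label;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0) {
        pq.push({dmap(r2, c2), order++, c2 * h + r2, e.label});
      }
    }
  }
  return lab;
}
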