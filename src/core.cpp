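#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel index helpers for column-major R matrices: idx = row + col*nrow.
// "Raster order" throughout means top-to-bottom rows, left-to-right columns
// within a row, i.e. ordered by (row, col).

static inline void neighbours(int idx, int nr, int nc, int conn,
                              int* out, int& n) {
  int r = idx % nr, c = idx / nr;
  n = 0;
  if (r > 0)      out[n++] = idx - 1;
  if (r < nr - 1) out[n++] = idx + 1;
  if (c > 0)      out[n++] = idx - nr;
  if (c < nc - 1) out[n++] = idx + nr;
  if (conn == 8) {
    if (r > 0 && c > 0)           out[n++] = idx - 1 - nr;
    if (r > 0 && c < nc - 1)      out[n++] = idx - 1 + nr;
    if (r < nr - 1 && c > 0)      out[n++] = idx + 1 - nr;
    if (r < nr - 1 && c < nc - 1) out[n++] = idx + 1 + nr;
  }
}

// Connected components of a binary mask. Labels are assigned 1..k in raster
// order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_cc_label(const LogicalMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nb[8], nn;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    int idx = r + c * nr;
    if (!mask[idx] || lab[idx]) continue;
    ++next;
    lab[idx] = next;
    stack.clear(); stack.push_back(idx);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      neighbours(p, nr, nc, connectivity, nb, nn);
      for (int i = 0; i < nn; ++i) {
        int q = nb[i];
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Morphological reconstruction by erosion of `marker` above `mask`
// (marker >= mask pointwise): the limit of iterating
// marker <- max(erode(marker), mask). Hybrid raster/anti-raster sweeps
// followed by a FIFO queue (dual of Vincent's reconstruction-by-dilation).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erosion(const NumericMatrix& marker,
                                      const NumericMatrix& mask,
                                      int connectivity) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(clone(marker));
  int nb[8], nn;
  // forward raster sweep
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int idx = r + c * nr;
    double v = J[idx];
    neighbours(idx, nr, nc, connectivity, nb, nn);
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      int qr = q % nr, qc = q / nr;
      if (qc < c || (qc == c && qr < r)) if (J[q] < v) v = J[q];
    }
    if (v < mask[idx]) v = mask[idx];
    J[idx] = v;
  }
  // backward sweep, queue pixels that may still propagate
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) for (int r = nr - 1; r >= 0; --r) {
    int idx = r + c * nr;
    double v = J[idx];
    neighbours(idx, nr, nc, connectivity, nb, nn);
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      int qr = q % nr, qc = q / nr;
      if (qc > c || (qc == c && qr > r)) if (J[q] < v) v = J[q];
    }
    if (v < mask[idx]) v = mask[idx];
    J[idx] = v;
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      int qr = q % nr, qc = q / nr;
      if ((qc > c || (qc == c && qr > r)) && J[q] > J[idx] && J[q] > mask[q]) {
        fifo.push(idx); break;
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    neighbours(p, nr, nc, connectivity, nb, nn);
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      if (J[q] > J[p] && J[q] > mask[q]) {
        J[q] = J[p] > mask[q] ? J[p] : mask[q];
        fifo.push(q);
      }
    }
  }
  return J;
}

// Regional minima of an image: flat zones none of whose neighbours is lower.
// Returns a label matrix, components numbered in raster order, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(const NumericMatrix& img, int connectivity) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<signed char> state(static_cast<size_t>(nr) * nc, 0); // 0 unvisited, 1 min, -1 not
  int nb[8], nn;
  int next = 0;
  std::vector<int> zone, stack;
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    int idx = r + c * nr;
    if (state[idx] != 0) continue;
    double v = img[idx];
    bool is_min = true;
    zone.clear(); stack.clear();
    stack.push_back(idx); state[idx] = 1; zone.push_back(idx);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      neighbours(p, nr, nc, connectivity, nb, nn);
      for (int i = 0; i < nn; ++i) {
        int q = nb[i];
        if (img[q] == v) {
          if (state[q] == 0) { state[q] = 1; zone.push_back(q); stack.push_back(q); }
        } else if (img[q] < v) {
          is_min = false;
        }
      }
    }
    if (is_min) {
      ++next;
      for (size_t i = 0; i < zone.size(); ++i) lab[zone[i]] = next;
    } else {
      for (size_t i = 0; i < zone.size(); ++i) state[zone[i]] = -1;
    }
  }
  return lab;
}

struct QEntry {
  double value;
  long long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;                         // FIFO on ties
  }
};

// Meyer's marker-controlled watershed flood. Seeds carry labels > 0; the
// flood grows basins with 4-connectivity in order of increasing relief value
// (FIFO among equal values). A pixel reached by two distinct basins becomes
// a watershed-line pixel (label 0, permanent).
// [[Rcpp::export]]
IntegerMatrix cpp_ws_flood(const NumericMatrix& relief,
                           const IntegerMatrix& seeds) {
  int nr = relief.nrow(), nc = relief.ncol();
  int npx = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<signed char> resolved(npx, 0); // 1 once final (basin or line)
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long order = 0;
  int nb[8], nn;
  // initialise with seed pixels (in raster order for determinism)
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    int idx = r + c * nr;
    if (seeds[idx] > 0) { lab[idx] = seeds[idx]; resolved[idx] = 1; }
  }
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    int idx = r + c * nr;
    if (!resolved[idx]) continue;
    neighbours(idx, nr, nc, 4, nb, nn);
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      if (!resolved[q])
        pq.push(QEntry{relief[q], order++, q, lab[idx]});
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int p = e.idx;
    if (resolved[p]) continue;
    // inspect already-resolved basin neighbours
    int found = 0; bool conflict = false;
    neighbours(p, nr, nc, 4, nb, nn);
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      if (resolved[q] && lab[q] > 0) {
        if (found == 0) found = lab[q];
        else if (lab[q] != found) conflict = true;
      }
    }
    resolved[p] = 1;
    if (conflict) {
      lab[p] = 0; // watershed line
      continue;
    }
    lab[p] = found > 0 ? found : e.label;
    for (int i = 0; i < nn; ++i) {
      int q = nb[i];
      if (!resolved[q])
        pq.push(QEntry{relief[q], order++, q, lab[p]});
    }
  }
  return lab;
}

// Renumber positive labels consecutively 1..k in raster order of each
// label's first pixel; 0 stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_relabel_raster(const IntegerMatrix& labels) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out(nr, nc);
  int maxl = 0;
  for (int i = 0; i < nr * nc; ++i) if (labels[i] > maxl) maxl = labels[i];
  std::vector<int> map(maxl + 1, 0);
  int next = 0;
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    int idx = r + c * nr;
    int l = labels[idx];
    if (l > 0 && map[l] == 0) map[l] = ++next;
  }
  for (int i = 0; i < nr * nc; ++i)
    out[i] = labels[i] > 0 ? map[labels[i]] : 0;
  return out;
}

// 3x3 morphological gradient (dilation minus erosion, box structuring
// element) of a grayscale image.
// [[Rcpp::export]]
NumericMatrix cpp_morph_gradient3(const NumericMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    double mx = img(r, c), mn = img(r, c);
    for (int dc = -1; dc <= 1; ++dc) for (int dr = -1; dr <= 1; ++dr) {
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double v = img(rr, cc);
      if (v > mx) mx = v;
      if (v < mn) mn = v;
    }
    out(r, c) = mx - mn;
  }
  return out;
}
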