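#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disc structuring-element offsets: all (dr, dc) with dr^2 + dc^2 <= r^2.
static std::vector<std::pair<int,int>> disc_offsets(int radius) {
  std::vector<std::pair<int,int>> off;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

// [[Rcpp::export(name = ".cpp_disc_size")]]
int cpp_disc_size(int radius) {
  return (int) disc_offsets(radius).size();
}

// Erosion with a disc SE; pixels outside the image count as background.
// [[Rcpp::export(name = ".cpp_erode")]]
IntegerMatrix cpp_erode(const IntegerMatrix& mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  if (radius <= 0) return clone(mask);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) { out(i, j) = 0; continue; }
      int keep = 1;
      for (size_t k = 0; k < off.size(); ++k) {
        int r = i + off[k].first, c = j + off[k].second;
        if (r < 0 || r >= H || c < 0 || c >= W || !mask(r, c)) { keep = 0; break; }
      }
      out(i, j) = keep;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_dilate")]]
IntegerMatrix cpp_dilate(const IntegerMatrix& mask, int radius) {
  int H = mask.nrow(), W = mask.ncol();
  if (radius <= 0) return clone(mask);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int r = i + off[k].first, c = j + off[k].second;
        if (r >= 0 && r < H && c >= 0 && c < W) out(r, c) = 1;
      }
    }
  return out;
}

// Connected-component labeling, 4- or 8-connectivity, BFS flood fill.
// Labels are 1..K in scan order of the first-found pixel; 0 = background.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity = 8) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int ndir = (connectivity == 8) ? 8 : 4;
  static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int d = 0; d < ndir; ++d) {
          int r = pi + DR[d], c = pj + DC[d];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            stack.push_back(r + c * H);
          }
        }
      }
    }
  return lab;
}
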