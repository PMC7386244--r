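#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// SLIC superpixels: local k-means over (color, position) with the
// distance D^2 = dc^2 + (ds / S)^2 * m^2, followed by the usual
// connectivity enforcement pass that merges orphaned fragments into an
// adjacent segment. img is an H x W x C array in column-major R layout,
// channel values on a common scale (typically [0, 1]).
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericVector img, int H, int W, int C,
                       int n_segments, double compactness, int max_iter) {
  const int N = H * W;
  const double S = std::sqrt((double)N / n_segments);
  const double invS2m2 = (compactness * compactness) / (S * S);

  auto px = [&](int r, int c, int ch) { return img[r + H * (c + W * ch)]; };

  // grid initialization: centers on an even lattice with spacing ~S
  int grid_r = std::max(1, (int)std::round(H / S));
  int grid_c = std::max(1, (int)std::round(W / S));
  while (grid_r * grid_c > n_segments) {
    if (grid_r >= grid_c && grid_r > 1) grid_r--; else if (grid_c > 1) grid_c--;
    else break;
  }
  // grow toward n_segments if rounding fell short
  while ((grid_r + 1) * grid_c <= n_segments && grid_r < H) grid_r++;
  while (grid_r * (grid_c + 1) <= n_segments && grid_c < W) grid_c++;

  int K = grid_r * grid_c;
  std::vector<double> cy(K), cx(K);
  std::vector<std::vector<double>> ccol(K, std::vector<double>(C));
  {
    int k = 0;
    for (int i = 0; i < grid_r; ++i) {
      for (int j = 0; j < grid_c; ++j, ++k) {
        double y = (i + 0.5) * H / grid_r - 0.5;
        double x = (j + 0.5) * W / grid_c - 0.5;
        int r = std::min(H - 1, std::max(0, (int)std::round(y)));
        int c = std::min(W - 1, std::max(0, (int)std::round(x)));
        // move to the lowest-gradient pixel in the 3x3 neighborhood
        // (skipped when segments are so small that centers could collide)
        double best_g = R_PosInf; int br = r, bc = c;
        for (int dr = -1; dr <= 1 && S >= 3; ++dr) for (int dc = -1; dc <= 1; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (rr < 1 || rr >= H - 1 || cc < 1 || cc >= W - 1) continue;
          double g = 0;
          for (int ch = 0; ch < C; ++ch) {
            double gx = px(rr, cc + 1, ch) - px(rr, cc - 1, ch);
            double gy = px(rr + 1, cc, ch) - px(rr - 1, cc, ch);
            g += gx * gx + gy * gy;
          }
          if (g < best_g) { best_g = g; br = rr; bc = cc; }
        }
        cy[k] = br; cx[k] = bc;
        for (int ch = 0; ch < C; ++ch) ccol[k][ch] = px(br, bc, ch);
      }
    }
  }

  std::vector<int> label(N, -1);
  std::vector<double> dist(N);
  const int win = std::max(1, (int)std::ceil(2 * S));

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int r0 = std::max(0, (int)cy[k] - win), r1 = std::min(H - 1, (int)cy[k] + win);
      int c0 = std::max(0, (int)cx[k] - win), c1 = std::min(W - 1, (int)cx[k] + win);
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          double dc2 = 0;
          for (int ch = 0; ch < C; ++ch) {
            double d = px(r, c, ch) - ccol[k][ch];
            dc2 += d * d;
          }
          double dy = r - cy[k], dx = c - cx[k];
          double D = dc2 + (dy * dy + dx * dx) * invS2m2;
          int idx = r + H * c;
          if (D < dist[idx]) { dist[idx] = D; label[idx] = k; }
        }
      }
    }
    // centers <- cluster means
    std::vector<double> sy(K, 0), sx(K, 0);
    std::vector<int> cnt(K, 0);
    std::vector<std::vector<double>> scol(K, std::vector<double>(C, 0));
    for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
      int k = label[r + H * c];
      if (k < 0) continue;
      sy[k] += r; sx[k] += c; cnt[k]++;
      for (int ch = 0; ch < C; ++ch) scol[k][ch] += px(r, c, ch);
    }
    for (int k = 0; k < K; ++k) {
      if (!cnt[k]) continue;
      cy[k] = sy[k] / cnt[k]; cx[k] = sx[k] / cnt[k];
      for (int ch = 0; ch < C; ++ch) ccol[k][ch] = scol[k][ch] / cnt[k];
    }
  }

  // any pixel never reached by a window (possible on extreme aspect ratios):
  // assign to nearest center spatially
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    int idx = r + H * c;
    if (label[idx] >= 0) continue;
    double best = R_PosInf; int bk = 0;
    for (int k = 0; k < K; ++k) {
      double dy = r - cy[k], dx = c - cx[k];
      double d = dy * dy + dx * dx;
      if (d < best) { best = d; bk = k; }
    }
    label[idx] = bk;
  }

  // connectivity: flood-fill components; fragments smaller than S^2/4 are
  // merged into the previously finalized adjacent segment
  const int min_size = std::max(1, (int)(S * S / 4.0));
  std::vector<int> newlab(N, -1);
  int next = 0;
  std::vector<int> comp;
  comp.reserve(N);
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    int idx = r + H * c;
    if (newlab[idx] >= 0) continue;
    comp.clear();
    int adj = -1;  // neighboring already-finalized label
    std::queue<int> q;
    q.push(idx);
    newlab[idx] = next;
    comp.push_back(idx);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int rr = cur % H, cc = cur / H;
      for (int d = 0; d < 4; ++d) {
        int nr = rr + dr4[d], nc = cc + dc4[d];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        int nidx = nr + H * nc;
        if (newlab[nidx] >= 0 && newlab[nidx] != next) adj = newlab[nidx];
        if (newlab[nidx] < 0 && label[nidx] == label[idx]) {
          newlab[nidx] = next;
          comp.push_back(nidx);
          q.push(nidx);
        }
      }
    }
    if ((int)comp.size() < min_size && adj >= 0) {
      for (int p : comp) newlab[p] = adj;
    } else {
      next++;
    }
  }

  // compact ids to 1..L (merging can leave gaps)
  std::vector<int> remap(next, -1);
  int L = 0;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    int k = newlab[r + H * c];
    if (remap[k] < 0) remap[k] = ++L;
    out(r, c) = remap[k];
  }
  return out;
}
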