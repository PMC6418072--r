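// Marker-based watershed by priority flooding (Meyer's algorithm) on a
// priority surface, restricted to a foreground mask, 4-connectivity.
// Flooding proceeds from high priority (granule interiors on a distance
// map) to low, so every foreground pixel reachable from a marker receives
// the label of the basin that reaches it first; ridge pixels join the
// basin with the larger priority at their frontier, so no pixel is lost.

#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

struct QItem {
  double priority;
  unsigned long order;   // FIFO tie-break for determinism
  int idx;
};

struct QLess {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;      // earlier insertion floods first
  }
};

// [[Rcpp::export(name = ".priority_flood")]]
IntegerMatrix priority_flood(NumericMatrix priority, IntegerMatrix markers,
                             LogicalMatrix mask) {
  const int H = priority.nrow(), W = priority.ncol();
  IntegerMatrix labels(H, W);
  std::vector<bool> queued((size_t)H * W, false);
  std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
  unsigned long order = 0;

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int idx = i + H * j;
      if (markers[idx] > 0 && mask[idx]) {
        labels[idx] = markers[idx];
        queued[idx] = true;
        pq.push({priority[idx], order++, idx});
      }
    }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    const int i = it.idx % H, j = it.idx / H;
    for (int k = 0; k < 4; ++k) {
      const int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const int nidx = ni + H * nj;
      if (!mask[nidx] || queued[nidx]) continue;
      labels[nidx] = labels[it.idx];
      queued[nidx] = true;
      pq.push({priority[nidx], order++, nidx});
    }
  }
  return labels;
}
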