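#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Meyer flooding from labelled seeds over a priority surface (lower values are
// flooded first). 4-connected. Ties are broken by insertion order so the result
// is deterministic. Unreached pixels (none here, the grid is connected) keep 0.
struct QItem {
  double priority;
  unsigned long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".seeded_watershed_cpp")]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix priority, IntegerMatrix seeds) {
  const int nr = priority.nrow(), nc = priority.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("priority and seeds must have identical dimensions");
  IntegerMatrix labels(nr, nc);
  std::vector<char> queued((size_t) nr * nc, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long counter = 0;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      labels(r, c) = seeds(r, c);

  // queue unlabelled neighbours of the seeds
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int idx = rr + cc * nr;
        if (labels(rr, cc) == 0 && !queued[idx]) {
          queued[idx] = 1;
          pq.push({priority(rr, cc), counter++, idx});
        }
      }
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    if (labels(r, c) != 0) continue;
    // label of the already-flooded neighbour with the lowest priority value
    int best = 0;
    double bestp = R_PosInf;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) > 0 && priority(rr, cc) < bestp) {
        bestp = priority(rr, cc);
        best = labels(rr, cc);
      }
    }
    if (best == 0) continue;  // cannot happen on a connected grid
    labels(r, c) = best;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int idx = rr + cc * nr;
      if (labels(rr, cc) == 0 && !queued[idx]) {
        queued[idx] = 1;
        pq.push({priority(rr, cc), counter++, idx});
      }
    }
  }
  return labels;
}
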