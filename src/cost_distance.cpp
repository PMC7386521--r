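#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Exact multi-source Dijkstra over the 8-connected raster graph.
//
// speed:   traversal speed in km/h per cell (NA on barrier cells)
// barrier: TRUE where the cell is untraversable
// sources: k x 2 matrix of 1-based (row, col) source cells
// cellSize: cell edge length in metres
//
// Edge time between adjacent cells a,b is d(a,b) * (1/v_a + 1/v_b) / 2 with
// d = cellSize for axis moves and cellSize * sqrt(2) for diagonal moves:
// time accrues half in each cell at that cell's speed. Result in minutes;
// unreachable (and barrier) cells stay +Inf. The priority queue orders by
// (time, row, col) so the pop order is deterministic.
//
// [[Rcpp::export]]
NumericMatrix dijkstra_grid(NumericMatrix speed, LogicalMatrix barrier,
                            IntegerMatrix sources, double cellSize) {
  const int nr = speed.nrow(), nc = speed.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  typedef std::tuple<double, int, int> Node;  // (minutes, row, col) 0-based
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  int nLive = 0;
  for (int k = 0; k < sources.nrow(); ++k) {
    int r = sources(k, 0) - 1, c = sources(k, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside the grid");
    if (barrier(r, c)) continue;
    if (dist(r, c) > 0.0) {
      dist(r, c) = 0.0;
      pq.push(Node(0.0, r, c));
      ++nLive;
    }
  }
  if (nLive == 0) stop("no source lies on a traversable cell");

  const double dkm = cellSize / 1000.0;
  const double SQRT2 = std::sqrt(2.0);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int r = std::get<1>(top), c = std::get<2>(top);
    if (d > dist(r, c)) continue;  // stale entry
    double paceA = 1.0 / speed(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (barrier(rr, cc)) continue;
      double step = dkm * ((dr[k] != 0 && dc[k] != 0) ? SQRT2 : 1.0);
      double nd = d + step * 0.5 * (paceA + 1.0 / speed(rr, cc)) * 60.0;
      if (nd < dist(rr, cc)) {
        dist(rr, cc) = nd;
        pq.push(Node(nd, rr, cc));
      }
    }
  }
  return dist;
}
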