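#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// Marker-based watershed flood of the negated distance map.
//
// Starting from labelled marker pixels, pixels are popped in order of
// decreasing distance value (FIFO on ties, so the result is deterministic)
// and unlabelled 8-connected foreground neighbours inherit the popping
// pixel's label, until every foreground pixel reachable from a marker is
// labelled.
// [[Rcpp::export]]
IntegerMatrix watershed_flood_cpp(NumericMatrix dist, LogicalMatrix mask,
                                  IntegerMatrix markers) {
  const int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix labels(nr, nc);
  // priority: highest distance first; ties broken by insertion order
  typedef std::tuple<double, long, int, int> Node; // (-priority handled below)
  std::priority_queue<Node> q;
  long counter = 0;
  for (int i = 0; i < markers.nrow(); ++i) {
    const int r = markers(i, 0) - 1, c = markers(i, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc || !mask(r, c)) continue;
    labels(r, c) = markers(i, 2);
    q.push(Node(dist(r, c), -(counter++), r, c));
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    Node nd = q.top(); q.pop();
    const int r = std::get<2>(nd), c = std::get<3>(nd);
    const int lab = labels(r, c);
    for (int k = 0; k < 8; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || labels(rr, cc) != 0) continue;
      labels(rr, cc) = lab;
      q.push(Node(dist(rr, cc), -(counter++), rr, cc));
    }
  }
  return labels;
}
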