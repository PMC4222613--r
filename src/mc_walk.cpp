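#include <Rcpp.h>
using namespace Rcpp;

// Batch random-walk first-passage simulation.
//
// Edges are grouped by source node: node l owns edge slots
// [edge_start[l], edge_start[l+1]) (0-based), each with a cumulative
// probability bound cump (within the node, increasing, last == 1), a target
// node and a local time tau. Each step draws one uniform number u and takes
// the first edge with u < cump (a draw exactly on a boundary therefore
// selects the latter interval); the edge's tau is added to the walker's
// first-passage time. A walker starting on a final node still takes at
// least one step (return-time semantics). Uses R's RNG (Mersenne Twister).
//
// Returns the mean first-passage time over walkers, plus the sum and the
// walker count, or raises if any walker exceeds max_steps.
// [[Rcpp::export]]
List mc_walk_batch(int n_nodes,
                   IntegerVector edge_start,
                   IntegerVector edge_to,
                   NumericVector edge_cump,
                   NumericVector edge_tau,
                   int initial,
                   LogicalVector is_final,
                   double n_walkers,
                   double max_steps) {
  double total = 0.0;
  double total2 = 0.0;
  long long nw = (long long)n_walkers;
  for (long long w = 0; w < nw; ++w) {
    int pos = initial;
    double t = 0.0;
    double steps = 0.0;
    do {
      int lo = edge_start[pos], hi = edge_start[pos + 1];
      if (lo == hi)
        stop("walker reached absorbing non-final node %d", pos);
      double u = unif_rand();
      int e = lo;
      while (e < hi - 1 && u >= edge_cump[e]) ++e;
      t += edge_tau[e];
      pos = edge_to[e];
      steps += 1.0;
      if (steps > max_steps)
        stop("walker exceeded max_steps (%g); network may be astronomically slow", max_steps);
    } while (!is_final[pos]);
    total += t;
    total2 += t * t;
  }
  return List::create(_["mean"] = total / (double)nw,
                      _["sum"] = total,
                      _["sumsq"] = total2,
                      _["n"] = (double)nw);
}
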