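#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scent-tracking attraction field.
//
// Force law per source point j acting on target i:
//   magnitude = strength / max(d_ij, dist_min), direction toward j,
//   contributions only for d_ij <= max_dist; coincident pairs (d ~ 0) skipped.
//
// taxis_exact_cpp sums the pairwise law directly (the reference path);
// taxis_bh_cpp approximates it with a Barnes-Hut quadtree.  A cell is taken
// as an aggregate only when the opening criterion w/l < theta holds AND the
// whole cell lies inside the cutoff radius, so cutoff membership is exact and
// only the centre-of-mass grouping is approximate.

static const double EPS_COINCIDENT = 1e-12;

// [[Rcpp::export]]
NumericMatrix taxis_exact_cpp(NumericVector sx, NumericVector sy,
                              NumericVector tx, NumericVector ty,
                              double strength, double max_dist,
                              double dist_min) {
  int ns = sx.size(), nt = tx.size();
  NumericMatrix out(nt, 2);
  for (int i = 0; i < nt; ++i) {
    double fx = 0.0, fy = 0.0;
    for (int j = 0; j < ns; ++j) {
      double dx = sx[j] - tx[i];
      double dy = sy[j] - ty[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < EPS_COINCIDENT || d > max_dist) continue;
      double w = strength / std::max(d, dist_min) / d;
      fx += dx * w;
      fy += dy * w;
    }
    out(i, 0) = fx;
    out(i, 1) = fy;
  }
  return out;
}

struct QuadNode {
  double cx, cy, half;   // cell centre and half-width
  double comx, comy;     // centre of mass of contained points
  int mass;              // number of contained points
  int child[4];          // -1 if absent
  std::vector<int> pts;  // point indices (leaves only)
  bool leaf;
};

class QuadTree {
public:
  std::vector<QuadNode> nodes;
  const NumericVector &x, &y;
  int max_depth;

  QuadTree(const NumericVector &x_, const NumericVector &y_) : x(x_), y(y_) {
    max_depth = 48;
    int n = x.size();
    if (n == 0) return;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    double half = 0.5 * std::max(xmax - xmin, ymax - ymin) + 1e-9;
    new_node(0.5 * (xmin + xmax), 0.5 * (ymin + ymax), half);
    for (int i = 0; i < n; ++i) insert(0, i, 0);
    finalize(0);
  }

  int new_node(double cx, double cy, double half) {
    QuadNode nd;
    nd.cx = cx; nd.cy = cy; nd.half = half;
    nd.comx = 0.0; nd.comy = 0.0; nd.mass = 0;
    nd.child[0] = nd.child[1] = nd.child[2] = nd.child[3] = -1;
    nd.leaf = true;
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int quadrant(int ni, int pi) const {
    int q = 0;
    if (x[pi] >= nodes[ni].cx) q |= 1;
    if (y[pi] >= nodes[ni].cy) q |= 2;
    return q;
  }

  void insert(int ni, int pi, int depth) {
    QuadNode &nd0 = nodes[ni];
    nd0.mass += 1;
    nd0.comx += x[pi];
    nd0.comy += y[pi];
    if (nodes[ni].leaf) {
      if ((int)nodes[ni].pts.size() == 0 || depth >= max_depth) {
        nodes[ni].pts.push_back(pi);
        return;
      }
      // split: push existing points down
      std::vector<int> old;
      old.swap(nodes[ni].pts);
      nodes[ni].leaf = false;
      for (size_t k = 0; k < old.size(); ++k) push_down(ni, old[k], depth);
    }
    push_down(ni, pi, depth);
  }

  void push_down(int ni, int pi, int depth) {
    int q = quadrant(ni, pi);
    int ci = nodes[ni].child[q];
    if (ci < 0) {
      double h = 0.5 * nodes[ni].half;
      double cx = nodes[ni].cx + ((q & 1) ? h : -h);
      double cy = nodes[ni].cy + ((q & 2) ? h : -h);
      ci = new_node(cx, cy, h);
      nodes[ni].child[q] = ci;
    }
    // child insert (not via insert() to avoid double mass counting? no:
    // child keeps its own totals)
    QuadNode &cd = nodes[ci];
    cd.mass += 1;
    cd.comx += x[pi];
    cd.comy += y[pi];
    if (cd.leaf) {
      if ((int)nodes[ci].pts.size() == 0 || depth + 1 >= max_depth) {
        nodes[ci].pts.push_back(pi);
        return;
      }
      std::vector<int> old;
      old.swap(nodes[ci].pts);
      nodes[ci].leaf = false;
      for (size_t k = 0; k < old.size(); ++k) push_down(ci, old[k], depth + 1);
    }
    push_down(ci, pi, depth + 1);
  }

  void finalize(int ni) {
    QuadNode &nd = nodes[ni];
    if (nd.mass > 0) {
      nd.comx /= nd.mass;
      nd.comy /= nd.mass;
    }
    for (int q = 0; q < 4; ++q)
      if (nd.child[q] >= 0) finalize(nd.child[q]);
  }
};

// mass was accumulated both at the node and again in push_down for children;
// insert() adds at the root then push_down handles descendants exactly once,
// so totals are consistent: every node's mass equals the points it contains.

// [[Rcpp::export]]
NumericMatrix taxis_bh_cpp(NumericVector sx, NumericVector sy,
                           NumericVector tx, NumericVector ty,
                           double strength, double max_dist,
                           double dist_min, double theta) {
  int nt = tx.size();
  NumericMatrix out(nt, 2);
  if (sx.size() == 0) return out;
  QuadTree tree(sx, sy);

  std::vector<int> stack;
  for (int i = 0; i < nt; ++i) {
    double px = tx[i], py = ty[i];
    double fx = 0.0, fy = 0.0;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const QuadNode &nd = tree.nodes[ni];
      if (nd.mass == 0) continue;
      double adx = std::fabs(px - nd.cx), ady = std::fabs(py - nd.cy);
      double nx = std::max(adx - nd.half, 0.0);
      double ny = std::max(ady - nd.half, 0.0);
      double near2 = nx * nx + ny * ny;
      if (near2 > max_dist * max_dist) continue;  // cell fully outside cutoff
      double fxc = adx + nd.half, fyc = ady + nd.half;
      double far2 = fxc * fxc + fyc * fyc;
      double dx = nd.comx - px, dy = nd.comy - py;
      double l = std::sqrt(dx * dx + dy * dy);
      double w = 2.0 * nd.half;
      bool inside_cutoff = far2 <= max_dist * max_dist;
      if (inside_cutoff && l > EPS_COINCIDENT && w / l < theta) {
        double mag = nd.mass * strength / std::max(l, dist_min);
        fx += dx / l * mag;
        fy += dy / l * mag;
        continue;
      }
      if (nd.leaf) {
        for (size_t k = 0; k < nd.pts.size(); ++k) {
          int j = nd.pts[k];
          double ddx = tree.x[j] - px, ddy = tree.y[j] - py;
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d < EPS_COINCIDENT || d > max_dist) continue;
          double ww = strength / std::max(d, dist_min) / d;
          fx += ddx * ww;
          fy += ddy * ww;
        }
      } else {
        for (int q = 0; q < 4; ++q)
          if (nd.child[q] >= 0) stack.push_back(nd.child[q]);
      }
    }
    out(i, 0) = fx;
    out(i, 1) = fy;
  }
  return out;
}
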