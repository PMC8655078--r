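#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Spatial index for thresholded nearest-neighbor queries.
//
// The cost sum_i min(d_i, l) never needs a neighbor distance beyond the
// saturation threshold l, so a uniform grid is an exact index as long as the
// cell edge is >= l: any neighbor closer than l lies in one of the 3^d cells
// adjacent to the query's cell. Queries that find nothing within l saturate
// at l. The grid is stored CSR-style (counting sort of point indices by
// cell), and the cell edge is grown above l when l is small relative to the
// data extent so the cell count stays bounded.

struct NNGrid {
  int dim;                   // 2 or 3
  double l, l2;              // threshold, threshold^2
  double edge;               // cell edge (>= l)
  double x0[3];              // grid origin
  int nc[3];                 // cells per dimension
  std::vector<int> start;    // CSR offsets, length ncell+1
  std::vector<int> order;    // point indices sorted by cell
  std::vector<double> px, py, pz;
  std::vector<int> ids;      // stable identifiers (self-exclusion by id)

  void build(const NumericMatrix &ref, const IntegerVector &rid) {
    int n = ref.nrow();
    px.resize(n); py.resize(n); ids.resize(n);
    if (dim == 3) pz.resize(n);
    double mn[3], mx[3];
    for (int j = 0; j < dim; ++j) { mn[j] = R_PosInf; mx[j] = R_NegInf; }
    for (int i = 0; i < n; ++i) {
      px[i] = ref(i, 0); py[i] = ref(i, 1);
      if (dim == 3) pz[i] = ref(i, 2);
      ids[i] = rid[i];
      for (int j = 0; j < dim; ++j) {
        mn[j] = std::min(mn[j], ref(i, j));
        mx[j] = std::max(mx[j], ref(i, j));
      }
    }
    // choose a cell edge >= l keeping the total cell count ~O(n)
    edge = l;
    double cap = std::max(4.0 * n + 64.0, 4096.0);
    for (;;) {
      double tot = 1;
      for (int j = 0; j < dim; ++j)
        tot *= std::floor((mx[j] - mn[j]) / edge) + 1;
      if (tot <= cap) break;
      edge *= 2;
    }
    long long ncell = 1;
    for (int j = 0; j < dim; ++j) {
      x0[j] = mn[j];
      nc[j] = (n > 0) ? (int) std::floor((mx[j] - mn[j]) / edge) + 1 : 1;
      ncell *= nc[j];
    }
    std::vector<int> cell(n);
    start.assign((size_t) ncell + 1, 0);
    for (int i = 0; i < n; ++i) {
      cell[i] = cell_of(px[i], py[i], dim == 3 ? pz[i] : 0.0);
      ++start[cell[i] + 1];
    }
    for (long long c = 0; c < ncell; ++c) start[c + 1] += start[c];
    order.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cell[i]]++] = i;
  }

  inline int clampc(double v, double o, int m) const {
    int c = (int) std::floor((v - o) / edge);
    return c;  // may be out of range; caller bounds the scan window
  }

  inline int cell_of(double x, double y, double z) const {
    int cx = std::min(std::max(clampc(x, x0[0], nc[0]), 0), nc[0] - 1);
    int cy = std::min(std::max(clampc(y, x0[1], nc[1]), 0), nc[1] - 1);
    int c = cy * nc[0] + cx;
    if (dim == 3) {
      int cz = std::min(std::max(clampc(z, x0[2], nc[2]), 0), nc[2] - 1);
      c += cz * nc[0] * nc[1];
    }
    return c;
  }

  // Squared distance to nearest reference point within l; l^2 if none.
  double nn_sq(double qx, double qy, double qz, int qid,
               bool exclude_self) const {
    double best = l2;
    int cx = clampc(qx, x0[0], nc[0]), cy = clampc(qy, x0[1], nc[1]);
    int cz = (dim == 3) ? clampc(qz, x0[2], nc[2]) : 0;
    int x_lo = std::max(cx - 1, 0), x_hi = std::min(cx + 1, nc[0] - 1);
    int y_lo = std::max(cy - 1, 0), y_hi = std::min(cy + 1, nc[1] - 1);
    int z_lo = 0, z_hi = 0;
    if (dim == 3) {
      z_lo = std::max(cz - 1, 0);
      z_hi = std::min(cz + 1, nc[2] - 1);
    }
    if (x_lo > x_hi || y_lo > y_hi || z_lo > z_hi) return best;
    for (int zz = z_lo; zz <= z_hi; ++zz)
      for (int yy = y_lo; yy <= y_hi; ++yy) {
        int base = zz * nc[0] * nc[1] + yy * nc[0];
        int a = start[base + x_lo], b = start[base + x_hi + 1];
        for (int t = a; t < b; ++t) {
          int i = order[t];
          if (exclude_self && ids[i] == qid) continue;
          double dx = qx - px[i], dy = qy - py[i];
          double s = dx * dx + dy * dy;
          if (dim == 3) { double dz = qz - pz[i]; s += dz * dz; }
          if (s < best) best = s;
        }
      }
    return best;
  }
};

static double cost_from_grid(const NNGrid &g, const NumericMatrix &query,
                             const IntegerVector &qid, bool exclude_self) {
  int n = query.nrow();
  if (g.order.empty()) return n * g.l;  // empty reference: all saturate
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double qz = (g.dim == 3) ? query(i, 2) : 0.0;
    total += std::sqrt(g.nn_sq(query(i, 0), query(i, 1), qz, qid[i],
                               exclude_self));
  }
  return total;
}

// [[Rcpp::export]]
SEXP nn_grid_build_cpp(NumericMatrix ref, double l, IntegerVector ids) {
  NNGrid *g = new NNGrid();
  g->dim = ref.ncol();
  g->l = l;
  g->l2 = l * l;
  g->build(ref, ids);
  XPtr<NNGrid> p(g, true);
  return p;
}

// [[Rcpp::export]]
double nn_grid_cost_cpp(SEXP ptr, NumericMatrix query, IntegerVector qids,
                        bool exclude_self) {
  XPtr<NNGrid> g(ptr);
  if (query.ncol() != g->dim) stop("query dimension mismatch with index");
  return cost_from_grid(*g, query, qids, exclude_self);
}

// [[Rcpp::export]]
double nnd_cost_cpp(NumericMatrix query, NumericMatrix ref, double l,
                    IntegerVector qids, IntegerVector rids,
                    bool exclude_self) {
  if (query.ncol() != ref.ncol()) stop("query/reference dimension mismatch");
  NNGrid g;
  g.dim = ref.ncol();
  g.l = l;
  g.l2 = l * l;
  g.build(ref, rids);
  return cost_from_grid(g, query, qids, exclude_self);
}

// [[Rcpp::export]]
NumericVector nnd_dist_cpp(NumericMatrix query, NumericMatrix ref, double l,
                           IntegerVector qids, IntegerVector rids,
                           bool exclude_self) {
  if (query.ncol() != ref.ncol()) stop("query/reference dimension mismatch");
  NNGrid g;
  g.dim = ref.ncol();
  g.l = l;
  g.l2 = l * l;
  g.build(ref, rids);
  int n = query.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double qz = (g.dim == 3) ? query(i, 2) : 0.0;
    out[i] = std::sqrt(g.nn_sq(query(i, 0), query(i, 1), qz, qids[i],
                               exclude_self));
  }
  return out;
}

// Alternating-renewal blinking traces: off-durations ~ Exp(rate K_on),
// on-durations ~ Exp(rate K_off), each emitter starting in the off state
// (exponential waits are memoryless, so this is a random phase). Uses the
// R RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
DataFrame gen_blink_events_cpp(int n_emitters, double n_frames,
                               double k_on, double k_off) {
  std::vector<int> emitter;
  std::vector<double> t_on, t_off;
  for (int e = 0; e < n_emitters; ++e) {
    double t = 0.0;
    for (;;) {
      t += R::rexp(1.0 / k_on);
      if (t >= n_frames) break;
      double dur = R::rexp(1.0 / k_off);
      emitter.push_back(e + 1);
      t_on.push_back(t);
      t_off.push_back(std::min(t + dur, n_frames));
      t += dur;
      if (t >= n_frames) break;
    }
  }
  return DataFrame::create(_["emitter"] = emitter, _["t_on"] = t_on,
                           _["t_off"] = t_off);
}
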