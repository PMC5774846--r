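// Persistence engine: filtered-complex construction and Z2 boundary-matrix
// reduction.  Sizes here are molecular (tens of atoms), so clarity and
// exactness are preferred over asymptotic tricks; no approximation anywhere.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::vector<int> ivec;

struct Simplex {
  ivec verts;          // sorted ascending
  double value;        // filtration value
  int dim() const { return (int)verts.size() - 1; }
};

static bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.value != b.value) return a.value < b.value;
  int da = a.dim(), db = b.dim();
  if (da != db) return da < db;            // faces precede cofaces at ties
  return a.verts < b.verts;                // stable lexicographic tie-break
}

// symmetric difference of two sorted index vectors (Z2 column addition)
static ivec symdiff(const ivec &a, const ivec &b) {
  ivec out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// Standard persistence pairing by column reduction in filtration order.
// Returns matrix with rows (dim, birth, death); death = +Inf for essential
// classes.  max_dim caps the reported homology dimension.
static NumericMatrix reduce_all(std::vector<Simplex> &simp, int max_dim) {
  const int m = (int)simp.size();
  std::stable_sort(simp.begin(), simp.end(), simplex_less);

  std::map<ivec, int> index_of;
  for (int j = 0; j < m; ++j) index_of[simp[j].verts] = j;

  std::vector<ivec> R(m);
  std::vector<int> low_inv(m, -1);
  std::vector<char> paired_as_birth(m, 0), paired_as_death(m, 0);

  std::vector<double> bb, bd;
  std::vector<int> bdim;

  for (int j = 0; j < m; ++j) {
    const Simplex &s = simp[j];
    ivec col;
    if (s.dim() > 0) {
      for (size_t v = 0; v < s.verts.size(); ++v) {
        ivec face(s.verts);
        face.erase(face.begin() + v);
        std::map<ivec,int>::const_iterator it = index_of.find(face);
        if (it == index_of.end())
          stop("filtration not closed under faces");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
    }
    while (!col.empty() && low_inv[col.back()] >= 0)
      col = symdiff(col, R[low_inv[col.back()]]);
    if (!col.empty()) {
      int piv = col.back();
      low_inv[piv] = j;
      R[j] = col;
      paired_as_birth[piv] = 1;
      paired_as_death[j] = 1;
      const Simplex &bs = simp[piv];
      if (bs.dim() <= max_dim && s.value > bs.value) {
        bdim.push_back(bs.dim()); bb.push_back(bs.value);
        bd.push_back(s.value);
      }
    }
  }
  for (int j = 0; j < m; ++j) {
    if (!paired_as_birth[j] && !paired_as_death[j] &&
        simp[j].dim() <= max_dim) {
      bdim.push_back(simp[j].dim()); bb.push_back(simp[j].value);
      bd.push_back(R_PosInf);
    }
  }
  NumericMatrix out((int)bb.size(), 3);
  for (int i = 0; i < (int)bb.size(); ++i) {
    out(i,0) = bdim[i]; out(i,1) = bb[i]; out(i,2) = bd[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix reduce_filtration_cpp(List simplices, NumericVector values,
                                    int max_dim) {
  std::vector<Simplex> simp(simplices.size());
  for (int i = 0; i < simplices.size(); ++i) {
    IntegerVector v = simplices[i];
    simp[i].verts = as<ivec>(v);
    std::sort(simp[i].verts.begin(), simp[i].verts.end());
    simp[i].value = values[i];
  }
  return reduce_all(simp, max_dim);
}

// Vietoris-Rips filtration from a (possibly partial) dissimilarity matrix.
// NA entries are excluded pairs and never form an edge; entries > cap are
// likewise dropped.  Simplices are enumerated up to dimension max_dim + 1.
// [[Rcpp::export]]
NumericMatrix rips_persistence_cpp(NumericMatrix d, double cap, int max_dim) {
  const int n = d.nrow();
  std::vector<std::vector<char> > adj(n, std::vector<char>(n, 0));
  std::vector<Simplex> simp;
  for (int i = 0; i < n; ++i) {
    Simplex s; s.verts.push_back(i); s.value = 0.0;
    simp.push_back(s);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = d(i, j);
      if (!NumericVector::is_na(v) && v <= cap) {
        adj[i][j] = adj[j][i] = 1;
        Simplex s; s.verts.push_back(i); s.verts.push_back(j);
        s.value = v;
        simp.push_back(s);
      }
    }
  int top_dim = max_dim + 1;
  if (top_dim >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (!adj[i][j]) continue;
        for (int k = j + 1; k < n; ++k) {
          if (!(adj[i][k] && adj[j][k])) continue;
          double v = std::max(d(i,j), std::max(d(i,k), d(j,k)));
          Simplex s; s.verts.push_back(i); s.verts.push_back(j);
          s.verts.push_back(k); s.value = v;
          simp.push_back(s);
          if (top_dim >= 3) {
            for (int l = k + 1; l < n; ++l) {
              if (!(adj[i][l] && adj[j][l] && adj[k][l])) continue;
              double v4 = std::max(v, std::max(d(i,l),
                           std::max(d(j,l), d(k,l))));
              Simplex t; t.verts.push_back(i); t.verts.push_back(j);
              t.verts.push_back(k); t.verts.push_back(l); t.value = v4;
              simp.push_back(t);
            }
          }
        }
      }
  }
  return reduce_all(simp, max_dim);
}

// ---- brute-force Delaunay ------------------------------------------------

// 2D Delaunay by circumcircle emptiness.  coords: n x 2.  Returns triangles
// (1-based vertex triples); degenerate (collinear) triples are skipped.
// [[Rcpp::export]]
IntegerMatrix delaunay2d_cpp(NumericMatrix coords, double tol) {
  const int n = coords.nrow();
  std::vector<ivec> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k = j + 1; k < n; ++k) {
        double ax = coords(i,0), ay = coords(i,1);
        double bx = coords(j,0), by = coords(j,1);
        double cx = coords(k,0), cy = coords(k,1);
        double dd = 2.0 * (ax*(by-cy) + bx*(cy-ay) + cx*(ay-by));
        if (std::fabs(dd) < tol) continue;  // collinear
        double a2 = ax*ax + ay*ay, b2 = bx*bx + by*by, c2 = cx*cx + cy*cy;
        double ux = (a2*(by-cy) + b2*(cy-ay) + c2*(ay-by)) / dd;
        double uy = (a2*(cx-bx) + b2*(ax-cx) + c2*(bx-ax)) / dd;
        double r2 = (ax-ux)*(ax-ux) + (ay-uy)*(ay-uy);
        bool empty = true;
        for (int p = 0; p < n && empty; ++p) {
          if (p == i || p == j || p == k) continue;
          double d2 = (coords(p,0)-ux)*(coords(p,0)-ux) +
                      (coords(p,1)-uy)*(coords(p,1)-uy);
          if (d2 < r2 - tol * (1.0 + r2)) empty = false;
        }
        if (empty) {
          ivec t; t.push_back(i+1); t.push_back(j+1); t.push_back(k+1);
          tris.push_back(t);
        }
      }
  IntegerMatrix out((int)tris.size(), 3);
  for (int r = 0; r < (int)tris.size(); ++r)
    for (int c = 0; c < 3; ++c) out(r,c) = tris[r][c];
  return out;
}

// 3D Delaunay by circumsphere emptiness.  coords: n x 3.  Returns
// tetrahedra (1-based); degenerate (coplanar) quadruples are skipped.
// [[Rcpp::export]]
IntegerMatrix delaunay3d_cpp(NumericMatrix coords, double tol) {
  const int n = coords.nrow();
  std::vector<ivec> tets;
  for (int i = 0; i < n; ++i)
   for (int j = i + 1; j < n; ++j)
    for (int k = j + 1; k < n; ++k)
     for (int l = k + 1; l < n; ++l) {
       // circumcenter: solve 2 (p_m - p_i) . x = |p_m|^2 - |p_i|^2
       double A[3][3], b[3];
       int rows[3] = { j, k, l };
       for (int r = 0; r < 3; ++r) {
         double s2 = 0, si2 = 0;
         for (int c = 0; c < 3; ++c) {
           A[r][c] = 2.0 * (coords(rows[r],c) - coords(i,c));
           s2  += coords(rows[r],c) * coords(rows[r],c);
           si2 += coords(i,c) * coords(i,c);
         }
         b[r] = s2 - si2;
       }
       // Gaussian elimination with partial pivoting
       double M[3][4];
       for (int r = 0; r < 3; ++r) {
         for (int c = 0; c < 3; ++c) M[r][c] = A[r][c];
         M[r][3] = b[r];
       }
       bool singular = false;
       for (int c = 0; c < 3 && !singular; ++c) {
         int piv = c;
         for (int r = c + 1; r < 3; ++r)
           if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
         if (std::fabs(M[piv][c]) < tol) { singular = true; break; }
         if (piv != c)
           for (int cc = 0; cc < 4; ++cc) std::swap(M[piv][cc], M[c][cc]);
         for (int r = 0; r < 3; ++r) {
           if (r == c) continue;
           double f = M[r][c] / M[c][c];
           for (int cc = c; cc < 4; ++cc) M[r][cc] -= f * M[c][cc];
         }
       }
       if (singular) continue;
       double u[3];
       for (int c = 0; c < 3; ++c) u[c] = M[c][3] / M[c][c];
       double r2 = 0;
       for (int c = 0; c < 3; ++c)
         r2 += (coords(i,c)-u[c]) * (coords(i,c)-u[c]);
       bool empty = true;
       for (int p = 0; p < n && empty; ++p) {
         if (p == i || p == j || p == k || p == l) continue;
         double d2 = 0;
         for (int c = 0; c < 3; ++c)
           d2 += (coords(p,c)-u[c]) * (coords(p,c)-u[c]);
         if (d2 < r2 - tol * (1.0 + r2)) empty = false;
       }
       if (empty) {
         ivec t; t.push_back(i+1); t.push_back(j+1);
         t.push_back(k+1); t.push_back(l+1);
         tets.push_back(t);
       }
     }
  IntegerMatrix out((int)tets.size(), 4);
  for (int r = 0; r < (int)tets.size(); ++r)
    for (int c = 0; c < 4; ++c) out(r,c) = tets[r][c];
  return out;
}

// ---- exact assignment (Hungarian / Jonker-Volgenant potentials) ----------

// Minimum-cost perfect assignment on a square cost matrix.  Used for the
// Wasserstein distance on diagonal-augmented barcode cost matrices.
// Returns total cost; entries may be large-but-finite sentinels.
// [[Rcpp::export]]
double hungarian_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j) total += cost(p[j] - 1, j - 1);
  return total;
}
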