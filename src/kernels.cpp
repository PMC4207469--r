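#include <Rcpp.h>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image delta for one component.
static inline double mi(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Unique molecule pairs (i<j) with any bead-bead minimum-image distance
// strictly below cutoff. lateral=true restricts the distance to xy.
// Cell list over the lateral plane; falls back to an all-pairs sweep when
// the box holds fewer than 3 cells per lateral edge.
// [[Rcpp::export]]
IntegerMatrix cpp_close_mol_pairs(NumericVector x, NumericVector y,
                                  NumericVector z, IntegerVector mol,
                                  NumericVector box, double cutoff,
                                  bool lateral) {
  const int n = x.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double c2 = cutoff * cutoff;
  std::set<std::pair<int,int> > pairs;

  auto check = [&](int i, int j) {
    if (mol[i] == mol[j]) return;
    double dx = mi(x[i] - x[j], Lx);
    double dy = mi(y[i] - y[j], Ly);
    double d2 = dx * dx + dy * dy;
    if (!lateral) {
      double dz = mi(z[i] - z[j], Lz);
      d2 += dz * dz;
    }
    if (d2 < c2) {
      int a = mol[i], b = mol[j];
      if (a > b) std::swap(a, b);
      pairs.insert(std::make_pair(a, b));
    }
  };

  int ncx = (int)std::floor(Lx / cutoff);
  int ncy = (int)std::floor(Ly / cutoff);
  if (ncx < 3 || ncy < 3 || n < 64) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) check(i, j);
  } else {
    const double cwx = Lx / ncx, cwy = Ly / ncy;
    std::vector<std::vector<int> > cells((size_t)ncx * ncy);
    std::vector<int> ci(n), cj(n);
    for (int i = 0; i < n; ++i) {
      double xi = x[i] - Lx * std::floor(x[i] / Lx);
      double yi = y[i] - Ly * std::floor(y[i] / Ly);
      int cx = std::min((int)(xi / cwx), ncx - 1);
      int cy = std::min((int)(yi / cwy), ncy - 1);
      ci[i] = cx; cj[i] = cy;
      cells[(size_t)cx * ncy + cy].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = (ci[i] + dx + ncx) % ncx;
        for (int dy = -1; dy <= 1; ++dy) {
          int cy = (cj[i] + dy + ncy) % ncy;
          const std::vector<int> &cell = cells[(size_t)cx * ncy + cy];
          for (size_t k = 0; k < cell.size(); ++k)
            if (cell[k] > i) check(i, cell[k]);
        }
      }
    }
  }

  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (std::set<std::pair<int,int> >::iterator it = pairs.begin();
       it != pairs.end(); ++it, ++r) {
    out(r, 0) = it->first;
    out(r, 1) = it->second;
  }
  return out;
}

// All cross-set pairs with minimum-image distance < rmax; returns 1-based
// indices into each set plus the distance.
// [[Rcpp::export]]
List cpp_cross_pairs(NumericVector ax, NumericVector ay, NumericVector az,
                     NumericVector bx, NumericVector by, NumericVector bz,
                     NumericVector box, double rmax, bool lateral) {
  const int na = ax.size(), nb = bx.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double r2 = rmax * rmax;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = mi(ax[i] - bx[j], Lx);
      double dy = mi(ay[i] - by[j], Ly);
      double d2 = dx * dx + dy * dy;
      if (!lateral) {
        double dz = mi(az[i] - bz[j], Lz);
        d2 += dz * dz;
      }
      if (d2 < r2) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["d"] = wrap(vd));
}

// Random sequential adsorption of n points in an Lx x Ly periodic box with
// hard-core minimum spacing rmin. Uses R's RNG so runs are reproducible
// under set.seed(). Errors if the target density cannot be reached within
// the retry budget.
// [[Rcpp::export]]
NumericMatrix cpp_rsa_positions(int n, double Lx, double Ly, double rmin,
                                int tries_per_point) {
  NumericMatrix pts(n, 2);
  int ncx = std::max(3, (int)std::floor(Lx / rmin));
  int ncy = std::max(3, (int)std::floor(Ly / rmin));
  const double cwx = Lx / ncx, cwy = Ly / ncy;
  std::vector<std::vector<int> > cells((size_t)ncx * ncy);
  const double r2 = rmin * rmin;
  long budget = (long)n * tries_per_point;
  int placed = 0;
  while (placed < n) {
    if (budget-- <= 0)
      stop("hard-core packing failed: density too high for spacing %f", rmin);
    double px = unif_rand() * Lx;
    double py = unif_rand() * Ly;
    int cx = std::min((int)(px / cwx), ncx - 1);
    int cy = std::min((int)(py / cwy), ncy - 1);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx) {
      int ix = (cx + dx + ncx) % ncx;
      for (int dy = -1; dy <= 1 && ok; ++dy) {
        int iy = (cy + dy + ncy) % ncy;
        const std::vector<int> &cell = cells[(size_t)ix * ncy + iy];
        for (size_t k = 0; k < cell.size(); ++k) {
          double ddx = mi(px - pts(cell[k], 0), Lx);
          double ddy = mi(py - pts(cell[k], 1), Ly);
          if (ddx * ddx + ddy * ddy < r2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      pts(placed, 0) = px;
      pts(placed, 1) = py;
      cells[(size_t)cx * ncy + cy].push_back(placed);
      ++placed;
    }
  }
  return pts;
}
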