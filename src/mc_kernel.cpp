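#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Photon random walk through a voxelized slab occupying
// [0, nx*h] x [0, ny*h] x [0, nz*h] cm, probe face at z = 0.
// Scattering step lengths ~ Exp(mus); absorption handled as continuous
// weight attenuation exp(-mua * path) (microscopic Beer-Lambert), no
// roulette, so path-length statistics are unbiased. Boundaries are
// index-matched: any photon crossing an outer face leaves the medium.
//
// Voxel traversal uses the Amanatides-Woo incremental scheme so each
// scattering segment deposits exact per-voxel path lengths.

namespace {

struct PairStore {
  std::vector<double> w;       // raw weight per detected photon
  std::vector<double> tot;     // total in-tissue path per detected photon
  std::vector<int>    ptr;     // CSR pointer into vox/len (ptr[0] = 0)
  std::vector<int>    vox;     // 1-based voxel linear indices
  std::vector<double> len;     // path length within that voxel, cm
  PairStore() { ptr.push_back(0); }
};

inline void sample_isotropic(double &ux, double &uy, double &uz) {
  double ct = 2.0 * unif_rand() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  ux = st * std::cos(phi);
  uy = st * std::sin(phi);
  uz = ct;
}

// Henyey-Greenstein deflection about the current direction (MCML-style).
inline void sample_hg(double g, double &ux, double &uy, double &uz) {
  double ct;
  if (std::fabs(g) < 1e-8) {
    ct = 2.0 * unif_rand() - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
}

} // namespace

// [[Rcpp::export]]
List mc_transport_cpp(int nx, int ny, int nz, double h,
                      double mus, double mua, double g_aniso, bool use_hg,
                      NumericMatrix src, NumericMatrix det, double acc_r,
                      int nphot, double max_path,
                      NumericVector rbin_edges) {
  const int M = src.nrow(), J = det.nrow();
  const double Lx = nx * h, Ly = ny * h, Lz = nz * h;
  const int nvox = nx * ny * nz;
  const int nbin = rbin_edges.size() - 1;
  const double acc_r2 = acc_r * acc_r;

  std::vector<PairStore> pairs((size_t)M * J);
  NumericMatrix refl(M, nbin);          // summed exit weights per annulus
  NumericVector top_weight(M);          // total weight exiting the top face

  std::vector<double> acc(nvox, 0.0);   // per-photon voxel path scratch
  std::vector<int> touched;
  touched.reserve(512);

  for (int m = 0; m < M; ++m) {
    const double sx = src(m, 0), sy = src(m, 1);
    for (int q = 0; q < nphot; ++q) {
      double px = sx, py = sy, pz = 0.0;
      double ux = 0.0, uy = 0.0, uz = 1.0;  // launched downward
      double total = 0.0;
      bool alive = true, exit_top = false;
      double ex = 0.0, ey = 0.0;
      touched.clear();

      int ix = std::min(nx - 1, std::max(0, (int)std::floor(px / h)));
      int iy = std::min(ny - 1, std::max(0, (int)std::floor(py / h)));
      int iz = 0;

      while (alive) {
        double s = -std::log(std::max(unif_rand(), 1e-300)) / mus;
        if (total + s > max_path) s = max_path - total;

        // Amanatides-Woo setup for this segment
        int stepx = (ux > 0) - (ux < 0);
        int stepy = (uy > 0) - (uy < 0);
        int stepz = (uz > 0) - (uz < 0);
        const double INF = 1e30;
        double tdx = (stepx != 0) ? h / std::fabs(ux) : INF;
        double tdy = (stepy != 0) ? h / std::fabs(uy) : INF;
        double tdz = (stepz != 0) ? h / std::fabs(uz) : INF;
        double tmx = (stepx > 0) ? ((ix + 1) * h - px) / ux
                   : (stepx < 0) ? (ix * h - px) / ux : INF;
        double tmy = (stepy > 0) ? ((iy + 1) * h - py) / uy
                   : (stepy < 0) ? (iy * h - py) / uy : INF;
        double tmz = (stepz > 0) ? ((iz + 1) * h - pz) / uz
                   : (stepz < 0) ? (iz * h - pz) / uz : INF;
        if (tmx < 0) tmx = 0;
        if (tmy < 0) tmy = 0;
        if (tmz < 0) tmz = 0;

        double traveled = 0.0;
        bool scattered = false;
        while (true) {
          double tnext = std::min(tmx, std::min(tmy, tmz));
          int lin = iz * nx * ny + iy * nx + ix;
          double seg;
          if (tnext >= s) {              // scatter within current voxel
            seg = s - traveled;
            scattered = true;
          } else {
            seg = tnext - traveled;
          }
          if (seg > 0) {
            if (acc[lin] == 0.0) touched.push_back(lin);
            acc[lin] += seg;
            total += seg;
          }
          if (scattered) { traveled = s; break; }
          traveled = tnext;
          if (tmx <= tmy && tmx <= tmz) { ix += stepx; tmx += tdx; }
          else if (tmy <= tmz)          { iy += stepy; tmy += tdy; }
          else                          { iz += stepz; tmz += tdz; }
          if (iz < 0) {                  // crossed the top face, z = 0
            alive = false; exit_top = true;
            ex = px + ux * traveled;
            ey = py + uy * traveled;
            break;
          }
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz >= nz) {
            alive = false;               // lost through side/bottom
            break;
          }
        }

        if (!alive) break;
        px += ux * s; py += uy * s; pz += uz * s;
        // keep indices consistent with position (guards rounding drift)
        px = std::min(std::max(px, 0.0), Lx);
        py = std::min(std::max(py, 0.0), Ly);
        pz = std::min(std::max(pz, 0.0), Lz);
        if (total >= max_path) break;    // terminated, not detected
        if (use_hg) sample_hg(g_aniso, ux, uy, uz);
        else sample_isotropic(ux, uy, uz);
      }

      if (exit_top) {
        double wgt = std::exp(-mua * total);
        top_weight[m] += wgt;
        double rr = std::sqrt((ex - sx) * (ex - sx) + (ey - sy) * (ey - sy));
        for (int b = 0; b < nbin; ++b) {
          if (rr >= rbin_edges[b] && rr < rbin_edges[b + 1]) {
            refl(m, b) += wgt;
            break;
          }
        }
        for (int j = 0; j < J; ++j) {
          double dx = ex - det(j, 0), dy = ey - det(j, 1);
          if (dx * dx + dy * dy <= acc_r2) {
            PairStore &ps = pairs[(size_t)m * J + j];
            ps.w.push_back(wgt);
            ps.tot.push_back(total);
            for (size_t t = 0; t < touched.size(); ++t) {
              ps.vox.push_back(touched[t] + 1);
              ps.len.push_back(acc[touched[t]]);
            }
            ps.ptr.push_back((int)ps.vox.size());
            break;                       // one fiber per photon
          }
        }
      }
      for (size_t t = 0; t < touched.size(); ++t) acc[touched[t]] = 0.0;
    }
  }

  List out(M * J);
  for (int m = 0; m < M; ++m) {
    for (int j = 0; j < J; ++j) {
      PairStore &ps = pairs[(size_t)m * J + j];
      out[m * J + j] = List::create(
        _["w"] = NumericVector(ps.w.begin(), ps.w.end()),
        _["tot"] = NumericVector(ps.tot.begin(), ps.tot.end()),
        _["ptr"] = IntegerVector(ps.ptr.begin(), ps.ptr.end()),
        _["vox"] = IntegerVector(ps.vox.begin(), ps.vox.end()),
        _["len"] = NumericVector(ps.len.begin(), ps.len.end()));
    }
  }
  return List::create(_["pairs"] = out, _["refl"] = refl,
                      _["top_weight"] = top_weight);
}
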