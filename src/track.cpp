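#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic streamline propagation on a discrete orientation field.
// Direction lookup is nearest-voxel with sign disambiguation: among the
// voxel's peaks, pick the one maximizing |dot| with the incoming direction,
// oriented so the dot product is positive. Propagation halts on: voxel with
// no peaks, angle change above threshold, stepping outside mask/grid, or the
// length budget being exhausted.

namespace {

struct Field {
  const double *peaks;   // (3, maxp, nx, ny, nz)
  const int *npk;        // per-voxel peak count
  const int *mask;
  int nx, ny, nz, maxp;
  const double *ainv;    // 4x4 world->voxel, column-major

  inline bool voxel_of(const double *p, int &i, int &j, int &k) const {
    double x = ainv[0] * p[0] + ainv[4] * p[1] + ainv[8]  * p[2] + ainv[12];
    double y = ainv[1] * p[0] + ainv[5] * p[1] + ainv[9]  * p[2] + ainv[13];
    double z = ainv[2] * p[0] + ainv[6] * p[1] + ainv[10] * p[2] + ainv[14];
    i = (int)std::lround(x); j = (int)std::lround(y); k = (int)std::lround(z);
    return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
  }
  inline long lin(int i, int j, int k) const { return i + (long)nx * (j + (long)ny * k); }
};

// One-directional propagation from p0 with incoming direction d0.
// Appends points beyond p0 to pts; returns traversed length.
double propagate(const Field &F, const double *p0, const double *d0,
                 double step, double cos_thr, double budget,
                 std::vector<double> &pts) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  double len = 0.0;
  int i, j, k;
  for (;;) {
    if (!F.voxel_of(p, i, j, k)) break;
    long v = F.lin(i, j, k);
    int np = F.npk[v];
    if (np == 0 || !F.mask[v]) break;
    const double *pk = F.peaks + (size_t)v * 3 * F.maxp;
    double bestdot = 0.0; int best = -1;
    for (int q = 0; q < np; ++q) {
      double dot = d[0] * pk[3 * q] + d[1] * pk[3 * q + 1] + d[2] * pk[3 * q + 2];
      if (std::fabs(dot) > std::fabs(bestdot)) { bestdot = dot; best = q; }
    }
    if (best < 0) break;
    if (std::fabs(bestdot) < cos_thr - 1e-12) break;  // angular threshold
    double sgn = bestdot >= 0 ? 1.0 : -1.0;
    double nd[3] = {sgn * pk[3 * best], sgn * pk[3 * best + 1], sgn * pk[3 * best + 2]};
    if (len + step > budget + 1e-9) break;            // length budget
    double pn[3] = {p[0] + step * nd[0], p[1] + step * nd[1], p[2] + step * nd[2]};
    int ii, jj, kk;
    if (!F.voxel_of(pn, ii, jj, kk)) break;
    if (!F.mask[F.lin(ii, jj, kk)]) break;
    pts.push_back(pn[0]); pts.push_back(pn[1]); pts.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
    len += step;
  }
  return len;
}

} // namespace

// Track one streamline per seed (bidirectional). Returns a list of n x 3
// point matrices (row order: one end to the other); seeds whose streamline is
// shorter than min_len yield NULL.
// [[Rcpp::export]]
List cpp_track(NumericVector peaks, IntegerVector npeaks, LogicalVector mask,
               IntegerVector dims, int maxp, NumericMatrix ainv,
               NumericMatrix seeds, double step, double ang_thr_deg,
               double max_len, double min_len) {
  Field F;
  F.peaks = REAL(peaks);
  std::vector<int> npk(npeaks.begin(), npeaks.end());
  std::vector<int> msk(mask.size());
  for (long v = 0; v < (long)mask.size(); ++v) msk[v] = mask[v] ? 1 : 0;
  F.npk = npk.data(); F.mask = msk.data();
  F.nx = dims[0]; F.ny = dims[1]; F.nz = dims[2]; F.maxp = maxp;
  std::vector<double> AI(ainv.begin(), ainv.end());
  F.ainv = AI.data();
  double cos_thr = std::cos(ang_thr_deg * M_PI / 180.0);

  int nseed = seeds.nrow();
  List out(nseed);
  std::vector<double> fwd, bwd;
  for (int s = 0; s < nseed; ++s) {
    double p0[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    int i, j, k;
    if (!F.voxel_of(p0, i, j, k)) { out[s] = R_NilValue; continue; }
    long v = F.lin(i, j, k);
    if (!F.mask[v] || F.npk[v] == 0) { out[s] = R_NilValue; continue; }
    const double *pk = F.peaks + (size_t)v * 3 * F.maxp;
    double d0[3] = {pk[0], pk[1], pk[2]};
    double dneg[3] = {-d0[0], -d0[1], -d0[2]};
    fwd.clear(); bwd.clear();
    double len_f = propagate(F, p0, d0, step, cos_thr, max_len, fwd);
    double len_b = propagate(F, p0, dneg, step, cos_thr, max_len - len_f, bwd);
    double total = len_f + len_b;
    if (total < min_len) { out[s] = R_NilValue; continue; }
    int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    NumericMatrix m(nb + 1 + nf, 3);
    for (int r = 0; r < nb; ++r) {         // backward half, reversed
      int src = nb - 1 - r;
      m(r, 0) = bwd[3 * src]; m(r, 1) = bwd[3 * src + 1]; m(r, 2) = bwd[3 * src + 2];
    }
    m(nb, 0) = p0[0]; m(nb, 1) = p0[1]; m(nb, 2) = p0[2];
    for (int r = 0; r < nf; ++r) {
      m(nb + 1 + r, 0) = fwd[3 * r]; m(nb + 1 + r, 1) = fwd[3 * r + 1]; m(nb + 1 + r, 2) = fwd[3 * r + 2];
    }
    out[s] = m;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
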