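#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear voxel index convention: idx = i + nx*(j + ny*k), all 0-based.

namespace {

struct Stamp {
  std::vector<int> dx, dy, dz;
  std::vector<double> val;
};

// Incremental ALE builder over a sparse set of kernel stamps.
// MA holds the per-study modeled-activation map (max over foci), P the
// running product of (1 - MA_s) across studies; both are version-stamped so
// no full-grid clearing is needed between maps/permutations.
struct AleScratch {
  int nx, ny, nz;
  long V;
  std::vector<double> MA, P;
  std::vector<int> ver_ma, ver_p;
  int ms_ver = 0, p_ver = 0;
  std::vector<int> touched;        // voxels touched by current map
  std::vector<int> touched_s;      // voxels touched by current study

  AleScratch(int nx_, int ny_, int nz_)
    : nx(nx_), ny(ny_), nz(nz_), V((long)nx_ * ny_ * nz_),
      MA(V), P(V), ver_ma(V, -1), ver_p(V, -1) {}

  // Add one study: foci given as linear voxel indices.
  void add_study(const int *foci, int nf, const Stamp &st, const int *mask) {
    ++ms_ver;
    touched_s.clear();
    const int S = (int)st.val.size();
    for (int f = 0; f < nf; ++f) {
      int idx = foci[f];
      int k = idx / (nx * ny), rem = idx - k * nx * ny;
      int j = rem / nx, i = rem - j * nx;
      for (int s = 0; s < S; ++s) {
        int ii = i + st.dx[s]; if (ii < 0 || ii >= nx) continue;
        int jj = j + st.dy[s]; if (jj < 0 || jj >= ny) continue;
        int kk = k + st.dz[s]; if (kk < 0 || kk >= nz) continue;
        long l = ii + (long)nx * (jj + (long)ny * kk);
        if (!mask[l]) continue;
        double v = st.val[s];
        if (ver_ma[l] != ms_ver) { ver_ma[l] = ms_ver; MA[l] = v; touched_s.push_back((int)l); }
        else if (v > MA[l]) MA[l] = v;
      }
    }
    for (int l : touched_s) {
      if (ver_p[l] != p_ver) { ver_p[l] = p_ver; P[l] = 1.0; touched.push_back(l); }
      P[l] *= (1.0 - MA[l]);
    }
  }

  void new_map() { ++p_ver; touched.clear(); }
  double ale_at(int l) const { return 1.0 - P[l]; }
};

std::vector<Stamp> unpack_stamps(List stamps) {
  std::vector<Stamp> out(stamps.size());
  for (int s = 0; s < stamps.size(); ++s) {
    List st = stamps[s];
    IntegerMatrix off = st["offsets"];
    NumericVector val = st["values"];
    Stamp &S = out[s];
    int n = off.nrow();
    S.dx.resize(n); S.dy.resize(n); S.dz.resize(n); S.val.resize(n);
    for (int r = 0; r < n; ++r) {
      S.dx[r] = off(r, 0); S.dy[r] = off(r, 1); S.dz[r] = off(r, 2);
      S.val[r] = val[r];
    }
  }
  return out;
}

// 26- or 6-neighbourhood offsets.
void neigh_offsets(int conn, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && man != 1) continue;
        off.push_back({dx, dy, dz});
      }
}

} // namespace

// Connected components of a binary volume. Returns integer labels (0 =
// background), components numbered in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vol, IntegerVector dims, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long V = (long)nx * ny * nz;
  if ((long)vol.size() != V) stop("volume size does not match dims");
  IntegerVector lab(V, 0);
  std::vector<std::array<int,3>> off;
  neigh_offsets(conn, off);
  std::vector<long> stack;
  int next = 0;
  for (long v0 = 0; v0 < V; ++v0) {
    if (!vol[v0] || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    stack.clear(); stack.push_back(v0);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int k = (int)(v / (nx * ny)), rem = (int)(v - (long)k * nx * ny);
      int j = rem / nx, i = rem - j * nx;
      for (auto &o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        long w = ii + (long)nx * (jj + (long)ny * kk);
        if (vol[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Modeled-activation map for one study: per-focus kernel stamps combined by
// voxelwise maximum, clipped to the mask. Foci are 0-based linear indices.
// [[Rcpp::export]]
NumericVector cpp_ma_map(IntegerVector foci, IntegerVector dims, LogicalVector mask,
                         List stamp) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  AleScratch sc(nx, ny, nz);
  List stl = List::create(stamp);
  std::vector<Stamp> st = unpack_stamps(stl);
  std::vector<int> msk(sc.V);
  for (long v = 0; v < sc.V; ++v) msk[v] = mask[v] ? 1 : 0;
  sc.new_map();
  std::vector<int> f(foci.begin(), foci.end());
  sc.add_study(f.data(), (int)f.size(), st[0], msk.data());
  NumericVector out(sc.V);
  for (int l : sc.touched) out[l] = sc.MA[l];
  return out;
}

// Monte-Carlo permutation engine for ALE inference.
//
// Builds the observed ALE map (map 0) plus `nperm` maps with every focus
// relocated uniformly at random over the mask, using R's RNG. Returns:
//  - obs_ale: dense observed ALE
//  - count_ge: per voxel, number of permutation maps with ALE >= observed
//  - cutoff: ALE cluster-forming cutoff, the (1 - voxel_p) quantile of the
//    pooled relocation-null histogram (all mask voxels x all permutations,
//    zeros included); a map is suprathreshold where value >= cutoff (> 0)
//  - max_size: maximum suprathreshold cluster size for each of the nperm+1 maps
//  - labels: cluster labels of the observed suprathreshold set
// [[Rcpp::export]]
List cpp_ale_perm_engine(IntegerVector dims, LogicalVector mask, IntegerVector mask_idx,
                         List study_foci, IntegerVector stamp_id, List stamps,
                         int nperm, double voxel_p, int conn, bool do_clusters) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  AleScratch sc(nx, ny, nz);
  long V = sc.V;
  if ((long)mask.size() != V) stop("mask size does not match dims");
  std::vector<int> msk(V);
  for (long v = 0; v < V; ++v) msk[v] = mask[v] ? 1 : 0;
  std::vector<Stamp> st = unpack_stamps(stamps);
  int ns = study_foci.size();
  if (stamp_id.size() != ns) stop("stamp_id length != number of studies");

  // flatten observed foci
  std::vector<std::vector<int>> obs(ns);
  int nf_total = 0;
  for (int s = 0; s < ns; ++s) {
    IntegerVector f = study_foci[s];
    obs[s] = std::vector<int>(f.begin(), f.end());
    nf_total += f.size();
  }

  // pre-draw permutation foci (uniform over mask voxels) so both passes see
  // the identical relocations
  int nmask = mask_idx.size();
  if (nmask < 1) stop("empty mask");
  std::vector<int> perm((size_t)nperm * nf_total);
  {
    RNGScope rng;
    for (long t = 0; t < (long)nperm * nf_total; ++t) {
      int r = (int)(unif_rand() * nmask);
      if (r >= nmask) r = nmask - 1;
      perm[t] = mask_idx[r];
    }
  }

  NumericVector obs_ale(V);
  IntegerVector count_ge(V);
  const int nbins = 200000;           // histogram resolution for ALE in [0, 1)
  std::vector<long> hist;
  if (do_clusters) hist.assign(nbins, 0L);
  long n_hist_pos = 0;                // positive null values accumulated

  auto build = [&](int j) {
    sc.new_map();
    if (j == 0) {
      for (int s = 0; s < ns; ++s)
        sc.add_study(obs[s].data(), (int)obs[s].size(), st[stamp_id[s]], msk.data());
    } else {
      const int *base = perm.data() + (size_t)(j - 1) * nf_total;
      int pos = 0;
      for (int s = 0; s < ns; ++s) {
        sc.add_study(base + pos, (int)obs[s].size(), st[stamp_id[s]], msk.data());
        pos += (int)obs[s].size();
      }
    }
  };

  // pass 1: observed map, voxelwise null counts, pooled null histogram
  for (int j = 0; j <= nperm; ++j) {
    build(j);
    if (j == 0) {
      for (int l : sc.touched) obs_ale[l] = sc.ale_at(l);
    } else {
      for (int l : sc.touched) {
        double x = sc.ale_at(l);
        if (obs_ale[l] > 0 && x >= obs_ale[l]) ++count_ge[l];
        if (do_clusters) {
          int b = (int)(x * nbins);
          if (b >= nbins) b = nbins - 1;
          if (b > 0) { ++hist[b]; ++n_hist_pos; }
        }
      }
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(Named("obs_ale") = obs_ale, Named("count_ge") = count_ge);
  if (!do_clusters) return out;

  // cluster-forming cutoff: smallest bin edge with tail mass <= voxel_p of
  // all pooled null values (zeros at unstamped mask voxels included)
  const double total = (double)nmask * (double)nperm;
  long tail = 0;
  int b0 = nbins;                 // exclusive upper bound if never reached
  for (int b = nbins - 1; b >= 1; --b) {
    if ((double)(tail + hist[b]) > voxel_p * total) break;
    tail += hist[b];
    b0 = b;
  }
  const double cutoff = (double)b0 / nbins;

  // pass 2: suprathreshold components and max cluster size per map
  std::vector<std::array<int,3>> noff;
  neigh_offsets(conn, noff);
  IntegerVector max_size(nperm + 1);
  IntegerVector labels(V, 0);
  std::vector<int> supra_ver(V, -1), lab_ver(V, -1);
  std::vector<int> supra; supra.reserve(1 << 16);
  std::vector<long> stack;

  for (int j = 0; j <= nperm; ++j) {
    build(j);
    supra.clear();
    for (int l : sc.touched) {
      double x = sc.ale_at(l);
      if (x >= cutoff && x > 0) { supra_ver[l] = j; supra.push_back(l); }
    }
    int best = 0, next = 0;
    for (int v0 : supra) {
      if (lab_ver[v0] == j) continue;
      ++next;
      int size = 0;
      lab_ver[v0] = j;
      stack.clear(); stack.push_back(v0);
      if (j == 0) labels[v0] = next;
      while (!stack.empty()) {
        long v = stack.back(); stack.pop_back();
        ++size;
        int k = (int)(v / (nx * ny)), rem = (int)(v - (long)k * nx * ny);
        int jj0 = rem / nx, i = rem - jj0 * nx;
        for (auto &o : noff) {
          int ii = i + o[0], jy = jj0 + o[1], kk = k + o[2];
          if (ii < 0 || ii >= nx || jy < 0 || jy >= ny || kk < 0 || kk >= nz) continue;
          long w = ii + (long)nx * (jy + (long)ny * kk);
          if (supra_ver[w] == j && lab_ver[w] != j) {
            lab_ver[w] = j;
            if (j == 0) labels[w] = next;
            stack.push_back(w);
          }
        }
      }
      if (size > best) best = size;
    }
    max_size[j] = best;
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }

  out["cutoff"] = cutoff;
  out["max_size"] = max_size;
  out["labels"] = labels;
  return out;
}
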