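// Deterministic streamline tracking on precomputed ODF peak fields.
// Stepping rule: from the current position, advance by a fixed step along
// the voxel peak best aligned with the previous direction; stop on low gFA,
// sharp turns, volume exit, peak-free voxels, or the step cap.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// termination codes (match R-side factor levels)
enum Reason { NONE = 0, LOW_GFA = 1, SHARP_TURN = 2, OUT_OF_VOLUME = 3,
              NO_SIGNAL = 4, MAX_STEPS = 5 };

struct Field {
  const double *peaks;   // nvox x 9, column-major (R matrix)
  const int *npk;
  const double *gfa;
  int nx, ny, nz;
  double vx, vy, vz;
  long nvox;
};

static inline bool inside(const Field &f, const double *p) {
  return p[0] >= 0 && p[1] >= 0 && p[2] >= 0 &&
         p[0] < f.nx * f.vx && p[1] < f.ny * f.vy && p[2] < f.nz * f.vz;
}

static inline long voxel_of(const Field &f, const double *p) {
  int i = (int)std::floor(p[0] / f.vx);
  int j = (int)std::floor(p[1] / f.vy);
  int k = (int)std::floor(p[2] / f.vz);
  if (i < 0 || j < 0 || k < 0 || i >= f.nx || j >= f.ny || k >= f.nz) return -1;
  return (long)i + (long)f.nx * j + (long)f.nx * f.ny * k;
}

// trilinear interpolation of the gFA map at a position in mm; grid values
// live at voxel centers, NA counts as zero anisotropy
static double gfa_at(const Field &f, const double *p) {
  double u[3] = { p[0] / f.vx - 0.5, p[1] / f.vy - 0.5, p[2] / f.vz - 0.5 };
  int n[3] = { f.nx, f.ny, f.nz };
  int i0[3]; double fr[3];
  for (int d = 0; d < 3; ++d) {
    double c = u[d];
    if (c < 0) c = 0;
    if (c > n[d] - 1) c = n[d] - 1;
    int i = (int)std::floor(c);
    if (i > n[d] - 2) i = n[d] - 2;
    if (i < 0) i = 0;
    i0[d] = i;
    fr[d] = c - i;
  }
  double out = 0.0;
  for (int c = 0; c < 8; ++c) {
    int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
    long idx = (long)(i0[0] + dx) + (long)f.nx * (i0[1] + dy) +
               (long)f.nx * f.ny * (i0[2] + dz);
    double v = f.gfa[idx];
    if (!R_finite(v)) v = 0.0;
    double w = (dx ? fr[0] : 1 - fr[0]) * (dy ? fr[1] : 1 - fr[1]) *
               (dz ? fr[2] : 1 - fr[2]);
    out += w * v;
  }
  return out;
}

// best-aligned peak in voxel v; returns false if the voxel has no peaks
static bool pick_peak(const Field &f, long v, const double *dir,
                      double *out, double *cosang) {
  int np = f.npk[v];
  if (np <= 0) return false;
  double best = -1.0; int bi = -1; double sgn = 1.0;
  for (int k = 0; k < np; ++k) {
    double px = f.peaks[v + f.nvox * (3 * k + 0)];
    double py = f.peaks[v + f.nvox * (3 * k + 1)];
    double pz = f.peaks[v + f.nvox * (3 * k + 2)];
    double d = dir[0] * px + dir[1] * py + dir[2] * pz;
    double ad = std::fabs(d);
    if (ad > best) { best = ad; bi = k; sgn = (d >= 0) ? 1.0 : -1.0; }
  }
  out[0] = sgn * f.peaks[v + f.nvox * (3 * bi + 0)];
  out[1] = sgn * f.peaks[v + f.nvox * (3 * bi + 1)];
  out[2] = sgn * f.peaks[v + f.nvox * (3 * bi + 2)];
  *cosang = best;
  return true;
}

// one tracking half; appends points (excluding the seed) to pts
static Reason track_half(const Field &f, const double *seed,
                         const double *dir0, double step, double cos_min,
                         double gfa_thresh, int max_steps,
                         std::vector<double> &pts) {
  double pos[3] = { seed[0], seed[1], seed[2] };
  double dir[3] = { dir0[0], dir0[1], dir0[2] };
  for (int s = 0; s < max_steps; ++s) {
    double npos[3] = { pos[0] + step * dir[0], pos[1] + step * dir[1],
                       pos[2] + step * dir[2] };
    if (!inside(f, npos)) return OUT_OF_VOLUME;
    long v = voxel_of(f, npos);
    if (v < 0) return OUT_OF_VOLUME;
    double ndir[3], cosang;
    if (!pick_peak(f, v, dir, ndir, &cosang)) return NO_SIGNAL;
    if (cosang < cos_min) return SHARP_TURN;
    if (gfa_at(f, npos) < gfa_thresh) return LOW_GFA;
    pos[0] = npos[0]; pos[1] = npos[1]; pos[2] = npos[2];
    dir[0] = ndir[0]; dir[1] = ndir[1]; dir[2] = ndir[2];
    pts.push_back(pos[0]); pts.push_back(pos[1]); pts.push_back(pos[2]);
  }
  return MAX_STEPS;
}

// interior causes outrank volume exit when merging the two halves
static int reason_priority(Reason r) {
  switch (r) {
    case SHARP_TURN: return 5;
    case LOW_GFA: return 4;
    case NO_SIGNAL: return 3;
    case MAX_STEPS: return 2;
    case OUT_OF_VOLUME: return 1;
    default: return 0;
  }
}

// [[Rcpp::export(name = ".track_streamlines_cpp")]]
List track_streamlines_cpp(NumericMatrix peaks, IntegerVector npk,
                           NumericVector gfa, IntegerVector dims,
                           NumericVector voxel_size, NumericMatrix seeds,
                           double step, double cos_min, double gfa_thresh,
                           int max_steps) {
  Field f;
  f.peaks = peaks.begin(); f.npk = npk.begin(); f.gfa = gfa.begin();
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2];
  f.vx = voxel_size[0]; f.vy = voxel_size[1]; f.vz = voxel_size[2];
  f.nvox = (long)f.nx * f.ny * f.nz;
  int n = seeds.nrow();
  std::vector<double> all_pts;
  std::vector<int> lengths(n), reason(n), reason_fwd(n), reason_bwd(n);
  std::vector<double> fwd, bwd;
  for (int i = 0; i < n; ++i) {
    double seed[3] = { seeds(i, 0), seeds(i, 1), seeds(i, 2) };
    Reason rf, rb;
    fwd.clear(); bwd.clear();
    long v = inside(f, seed) ? voxel_of(f, seed) : -1;
    double d0[3] = { 0, 0, 0 };
    bool ok = false;
    if (v < 0) {
      rf = rb = OUT_OF_VOLUME;
    } else if (f.npk[v] <= 0) {
      rf = rb = NO_SIGNAL;
    } else if (gfa_at(f, seed) < gfa_thresh) {
      rf = rb = LOW_GFA;
    } else {
      d0[0] = f.peaks[v]; d0[1] = f.peaks[v + f.nvox];
      d0[2] = f.peaks[v + 2 * f.nvox];
      ok = true;
    }
    if (ok) {
      rf = track_half(f, seed, d0, step, cos_min, gfa_thresh, max_steps, fwd);
      double d0n[3] = { -d0[0], -d0[1], -d0[2] };
      rb = track_half(f, seed, d0n, step, cos_min, gfa_thresh, max_steps, bwd);
    }
    // merged polyline: reversed backward half, seed, forward half
    int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    for (int k = nb - 1; k >= 0; --k) {
      all_pts.push_back(bwd[3 * k]); all_pts.push_back(bwd[3 * k + 1]);
      all_pts.push_back(bwd[3 * k + 2]);
    }
    all_pts.push_back(seed[0]); all_pts.push_back(seed[1]);
    all_pts.push_back(seed[2]);
    for (int k = 0; k < nf; ++k) {
      all_pts.push_back(fwd[3 * k]); all_pts.push_back(fwd[3 * k + 1]);
      all_pts.push_back(fwd[3 * k + 2]);
    }
    lengths[i] = nb + nf + 1;
    reason_fwd[i] = rf; reason_bwd[i] = rb;
    reason[i] = (reason_priority(rf) >= reason_priority(rb)) ? rf : rb;
  }
  long total = (long)all_pts.size() / 3;
  NumericMatrix pts(total, 3);
  for (long k = 0; k < total; ++k) {
    pts(k, 0) = all_pts[3 * k]; pts(k, 1) = all_pts[3 * k + 1];
    pts(k, 2) = all_pts[3 * k + 2];
  }
  return List::create(_["points"] = pts,
                      _["lengths"] = IntegerVector(lengths.begin(), lengths.end()),
                      _["reason"] = IntegerVector(reason.begin(), reason.end()),
                      _["reason_fwd"] = IntegerVector(reason_fwd.begin(), reason_fwd.end()),
                      _["reason_bwd"] = IntegerVector(reason_bwd.begin(), reason_bwd.end()));
}
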