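// Probabilistic streamline propagation (PICo-style).
//
// Streamlines step at a fixed step size through a per-voxel orientation
// field, stop on entering the exclusion mask (the complement of white
// matter; the first excluded point is retained so grey-matter terminations
// are recorded), on exceeding the length cap, or when the direction change
// over one voxel of trailing arc reaches the curvature limit.
//
// Randomness is a deterministic counter-based scheme: each streamline's
// generator is seeded by hashing (base seed, subject, seed-voxel linear
// index, streamline index), so any single streamline is reproducible in
// isolation and results are independent of execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t s;
  bool have;
  double cached;
  explicit Rng(uint64_t seed) : have(false), cached(0.0) {
    s = splitmix64(seed);
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {  // xorshift64*
    uint64_t x = s;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {  // Box-Muller
    if (have) { have = false; return cached; }
    double u1 = unif();
    while (u1 <= 0.0) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static inline uint64_t mix_seed(uint64_t base, uint64_t subject,
                                uint64_t voxel, uint64_t stream) {
  uint64_t h = splitmix64(base);
  h = splitmix64(h ^ subject);
  h = splitmix64(h ^ voxel);
  h = splitmix64(h ^ stream);
  return h;
}

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;
  double ox, oy, oz;
  inline bool voxel_of(const double* p, int* v) const {
    v[0] = (int)std::floor((p[0] - ox) / vx + 0.5);
    v[1] = (int)std::floor((p[1] - oy) / vy + 0.5);
    v[2] = (int)std::floor((p[2] - oz) / vz + 0.5);
    return v[0] >= 0 && v[0] < nx && v[1] >= 0 && v[1] < ny &&
           v[2] >= 0 && v[2] < nz;
  }
  inline int lin(const int* v) const { return v[0] + nx * (v[1] + ny * v[2]); }
};

// draw from the voxel orientation distribution: tangent perturbed by a
// rotation of half-normal angle (SD = dispersion) about a uniform axis in
// the plane perpendicular to the tangent, then sign-aligned to prev
// (prev == NULL: uniform random sign).
static void sample_dir(Rng& rng, const double* mean, const double* prev,
                       double disp_rad, double* out) {
  double d[3] = {mean[0], mean[1], mean[2]};
  if (disp_rad > 0.0) {
    double theta = std::fabs(rng.norm()) * disp_rad;
    double phi = 2.0 * M_PI * rng.unif();
    // orthonormal basis perpendicular to mean
    double a[3] = {1.0, 0.0, 0.0};
    if (std::fabs(mean[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
    double u[3] = {mean[1] * a[2] - mean[2] * a[1],
                   mean[2] * a[0] - mean[0] * a[2],
                   mean[0] * a[1] - mean[1] * a[0]};
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int i = 0; i < 3; ++i) u[i] /= nu;
    double w[3] = {mean[1] * u[2] - mean[2] * u[1],
                   mean[2] * u[0] - mean[0] * u[2],
                   mean[0] * u[1] - mean[1] * u[0]};
    double ct = std::cos(theta), st = std::sin(theta);
    double cp = std::cos(phi), sp = std::sin(phi);
    for (int i = 0; i < 3; ++i)
      d[i] = ct * mean[i] + st * (cp * u[i] + sp * w[i]);
  }
  double sign = 1.0;
  if (prev) {
    double dot = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
    if (dot < 0.0) sign = -1.0;
  } else {
    if (rng.unif() < 0.5) sign = -1.0;
  }
  out[0] = sign * d[0]; out[1] = sign * d[1]; out[2] = sign * d[2];
}

enum StopReason { STOP_EXCLUSION = 1, STOP_MAX_LENGTH = 2, STOP_CURVATURE = 3 };

struct TrackResult {
  int reason;
  std::vector<double> points;       // flat xyz
  std::vector<int> visited;         // linear voxel indices, first-visit order
};

// propagate one streamline from a world-space start point
static void propagate(const Grid& g, const int* wm, const double* orient,
                      double disp_rad, const double* start, double step,
                      double max_len, double curv_deg, Rng& rng,
                      std::vector<int>& stamp, int stamp_id,
                      bool keep_points, TrackResult& res) {
  res.reason = 0;
  res.points.clear();
  res.visited.clear();
  double pos[3] = {start[0], start[1], start[2]};
  int vox[3];
  if (!g.voxel_of(pos, vox)) { res.reason = STOP_EXCLUSION; return; }
  int vlin = g.lin(vox);
  if (keep_points) { res.points.insert(res.points.end(), pos, pos + 3); }
  if (stamp[vlin] != stamp_id) { stamp[vlin] = stamp_id; res.visited.push_back(vlin); }
  if (!wm[vlin]) { res.reason = STOP_EXCLUSION; return; }

  double mean_vox = (g.vx + g.vy + g.vz) / 3.0;
  int lag = (int)std::lround(mean_vox / step);
  if (lag < 1) lag = 1;
  double cos_lim = std::cos(curv_deg * M_PI / 180.0);
  std::vector<double> hist;  // direction ring buffer, flat xyz
  hist.reserve(3 * (lag + 1));
  double prev[3];
  bool has_prev = false;
  double len = 0.0;
  int nstep = 0;
  for (;;) {
    const double* mean = orient + 3 * (size_t)vlin;
    double nm = mean[0] * mean[0] + mean[1] * mean[1] + mean[2] * mean[2];
    if (nm < 0.25) { res.reason = STOP_EXCLUSION; return; }  // no orientation
    double dir[3];
    sample_dir(rng, mean, has_prev ? prev : (const double*)0, disp_rad, dir);
    if ((int)hist.size() >= 3 * lag) {
      const double* old = &hist[hist.size() - 3 * (size_t)lag];
      double dot = dir[0] * old[0] + dir[1] * old[1] + dir[2] * old[2];
      if (dot <= cos_lim + 1e-12) { res.reason = STOP_CURVATURE; return; }
    }
    if (len + step > max_len + 1e-9) { res.reason = STOP_MAX_LENGTH; return; }
    pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
    len += step;
    ++nstep;
    if (keep_points) res.points.insert(res.points.end(), pos, pos + 3);
    hist.insert(hist.end(), dir, dir + 3);
    if (hist.size() > 3 * (size_t)(lag + 1))
      hist.erase(hist.begin(), hist.begin() + 3);
    prev[0] = dir[0]; prev[1] = dir[1]; prev[2] = dir[2];
    has_prev = true;
    if (!g.voxel_of(pos, vox)) { res.reason = STOP_EXCLUSION; return; }
    vlin = g.lin(vox);
    if (stamp[vlin] != stamp_id) { stamp[vlin] = stamp_id; res.visited.push_back(vlin); }
    if (!wm[vlin]) { res.reason = STOP_EXCLUSION; return; }
  }
}

static Grid make_grid(IntegerVector shape, NumericVector voxel, NumericVector origin) {
  Grid g;
  g.nx = shape[0]; g.ny = shape[1]; g.nz = shape[2];
  g.vx = voxel[0]; g.vy = voxel[1]; g.vz = voxel[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_directions(int n, NumericVector mean_dir,
                                    Nullable<NumericVector> prev_dir,
                                    double dispersion_deg, double base_seed) {
  NumericMatrix out(n, 3);
  double mean[3] = {mean_dir[0], mean_dir[1], mean_dir[2]};
  double prevbuf[3];
  const double* prev = 0;
  if (prev_dir.isNotNull()) {
    NumericVector p(prev_dir);
    prevbuf[0] = p[0]; prevbuf[1] = p[1]; prevbuf[2] = p[2];
    prev = prevbuf;
  }
  double disp = dispersion_deg * M_PI / 180.0;
  for (int i = 0; i < n; ++i) {
    Rng rng(mix_seed((uint64_t)base_seed, 0, 0, (uint64_t)i));
    double d[3];
    sample_dir(rng, mean, prev, disp, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_track_seed(IntegerVector shape, NumericVector voxel, NumericVector origin,
                    IntegerVector wm, NumericVector orient, double dispersion_deg,
                    IntegerVector seed_voxel, int n_streamlines, double step,
                    double max_len, double curv_deg, double base_seed,
                    int subject, bool keep_streamlines, int stream_offset) {
  Grid g = make_grid(shape, voxel, origin);
  size_t v = (size_t)g.nx * g.ny * g.nz;
  std::vector<int> stamp(v, -1);
  IntegerVector counts((R_xlen_t)v);
  int sv[3] = {seed_voxel[0], seed_voxel[1], seed_voxel[2]};
  double start[3] = {g.ox + sv[0] * g.vx, g.oy + sv[1] * g.vy, g.oz + sv[2] * g.vz};
  int slin = g.lin(sv);
  double disp = dispersion_deg * M_PI / 180.0;
  List lines(keep_streamlines ? n_streamlines : 0);
  IntegerVector reasons(n_streamlines);
  TrackResult res;
  for (int j = 0; j < n_streamlines; ++j) {
    Rng rng(mix_seed((uint64_t)base_seed, (uint64_t)subject,
                     (uint64_t)slin, (uint64_t)(j + stream_offset)));
    propagate(g, INTEGER(wm), REAL(orient), disp, start, step, max_len,
              curv_deg, rng, stamp, j, keep_streamlines, res);
    for (size_t t = 0; t < res.visited.size(); ++t) counts[res.visited[t]]++;
    reasons[j] = res.reason;
    if (keep_streamlines) {
      NumericMatrix pts(res.points.size() / 3, 3);
      for (size_t r = 0; r < res.points.size() / 3; ++r)
        for (int c = 0; c < 3; ++c) pts(r, c) = res.points[3 * r + c];
      lines[j] = pts;
    }
  }
  return List::create(_["counts"] = counts, _["reasons"] = reasons,
                      _["streamlines"] = lines);
}

// batch tracking over many seeds: returns per-seed ROI hit counts and the
// global visitation profile (each streamline counts once per voxel)
// [[Rcpp::export]]
List cpp_track_batch(IntegerVector shape, NumericVector voxel, NumericVector origin,
                     IntegerVector wm, NumericVector orient, double dispersion_deg,
                     IntegerMatrix seeds, IntegerMatrix roi_labels,
                     int n_streamlines, double step, double max_len,
                     double curv_deg, double base_seed, int subject) {
  Grid g = make_grid(shape, voxel, origin);
  size_t v = (size_t)g.nx * g.ny * g.nz;
  int n_seeds = seeds.nrow();
  int n_roi = roi_labels.ncol();
  std::vector<int> stamp(v, -1);
  IntegerVector global((R_xlen_t)v);
  IntegerMatrix hits(n_seeds, n_roi);
  double disp = dispersion_deg * M_PI / 180.0;
  const int* roim = INTEGER(roi_labels);
  TrackResult res;
  std::vector<char> hit(n_roi);
  int stamp_id = 0;
  for (int s = 0; s < n_seeds; ++s) {
    int sv[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    double start[3] = {g.ox + sv[0] * g.vx, g.oy + sv[1] * g.vy,
                       g.oz + sv[2] * g.vz};
    int slin = g.lin(sv);
    for (int j = 0; j < n_streamlines; ++j) {
      Rng rng(mix_seed((uint64_t)base_seed, (uint64_t)subject,
                       (uint64_t)slin, (uint64_t)j));
      propagate(g, INTEGER(wm), REAL(orient), disp, start, step, max_len,
                curv_deg, rng, stamp, stamp_id++, false, res);
      std::fill(hit.begin(), hit.end(), 0);
      for (size_t t = 0; t < res.visited.size(); ++t) {
        int vl = res.visited[t];
        global[vl]++;
        for (int r = 0; r < n_roi; ++r)
          if (!hit[r] && roim[(size_t)r * v + vl]) hit[r] = 1;
      }
      for (int r = 0; r < n_roi; ++r) if (hit[r]) hits(s, r)++;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["hits"] = hits, _["global"] = global);
}
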