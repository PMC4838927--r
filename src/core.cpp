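#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chamber geometry: rows x cols square wells of side sw on a pitch of
// sw + pw, connected by passages of width pw centered on shared walls.
// Origin at the outer upper-left corner, x rightward, y downward, um.
struct Geom {
  double sw, pw, pitch, side;
  int nrow, ncol;
};

static Geom as_geom(const List& g) {
  Geom gm;
  gm.sw = as<double>(g["square_width"]);
  gm.pw = as<double>(g["passage_width"]);
  gm.nrow = as<int>(g["rows"]);
  gm.ncol = as<int>(g["cols"]);
  gm.pitch = gm.sw + gm.pw;
  gm.side = gm.ncol * gm.sw + (gm.ncol - 1) * gm.pw;
  return gm;
}

// region code: -2 outside, -1 wall, 0 passage, 1..25 square index.
// Half-open ownership: a region owns its low edge.
static inline int locate_region(const Geom& g, double x, double y) {
  if (!(x >= 0.0) || !(y >= 0.0) || x >= g.side || y >= g.side) return -2;
  int cx = (int)(x / g.pitch); if (cx > g.ncol - 1) cx = g.ncol - 1;
  int cy = (int)(y / g.pitch); if (cy > g.nrow - 1) cy = g.nrow - 1;
  double ox = x - cx * g.pitch, oy = y - cy * g.pitch;
  bool sx = ox < g.sw, sy = oy < g.sw;
  if (sx && sy) return cy * g.ncol + cx + 1;
  double lo = (g.sw - g.pw) * 0.5, hi = (g.sw + g.pw) * 0.5;
  if (!sx && oy >= lo && oy < hi) return 0; // x-gap passage
  if (!sy && ox >= lo && ox < hi) return 0; // y-gap passage
  return -1;
}

static inline bool is_interior(const Geom& g, double x, double y) {
  return locate_region(g, x, y) >= 0;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(NumericVector x, NumericVector y, List geom) {
  Geom g = as_geom(geom);
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = locate_region(g, x[i], y[i]);
  return out;
}

static inline double wall_jit(double amp) {
  return (unif_rand() * 2.0 - 1.0) * amp;
}

// Attempt to move agent i to (nx, ny); on hitting a wall, reflect the
// heading off the blocked axis (specular) with uniform jitter and slide
// along the open axis. Guarantees the final position stays interior.
static inline void move_checked(const Geom& g, double& x, double& y,
                                double& heading, double nx, double ny,
                                double jitter_amp) {
  if (is_interior(g, nx, ny)) { x = nx; y = ny; return; }
  bool okx = is_interior(g, nx, y);
  bool oky = is_interior(g, x, ny);
  if (okx && !oky) {        // y-motion blocked
    heading = -heading + wall_jit(jitter_amp);
    x = nx;
  } else if (oky && !okx) { // x-motion blocked
    heading = M_PI - heading + wall_jit(jitter_amp);
    y = ny;
  } else {                  // corner: reverse
    heading = heading + M_PI + wall_jit(jitter_amp);
  }
}

// [[Rcpp::export]]
List cpp_reflect(double x, double y, double nx, double ny, double heading,
                 List geom, double jitter_amp) {
  Geom g = as_geom(geom);
  move_checked(g, x, y, heading, nx, ny, jitter_amp);
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = heading);
}

// Advance one dish population through one feedback cycle of nsub sub-ticks
// of length dt under the current illumination pattern. Mutates x, y,
// heading, mode in place; fills the trajectory matrices tx, ty
// (n x (nsub + 1)) and per-segment stroke widths segw (n x nsub, um;
// 0 = segment not drawn).
//
// species 0 (Euglena-like): mode 0 swimming / 1 tumbling, set by the
// illumination of the occupied square. Swimming: straight run at the cell's
// speed with heading diffusion, specular wall reflection, and a photophobic
// turn at illuminated borders with probability border_turn_prob. Tumbling:
// slow drift at tumble_speed_frac * speed with heading re-randomized each
// sub-tick with probability tumble_reorient; stroke width while tumbling is
// tumble_stroke_frac * body_length (the spinning body sweeps laterally).
//
// species 1 (Chlamydomonas-like): mode 0 resting / 1 active. Resting cells
// under light activate with rate k_act; active cells in the dark rest with
// rate k_rest. Active cells random-walk; while in an illuminated square,
// attempts to leave the square succeed only with probability exit_damping.
// [[Rcpp::export]]
void cpp_cycle(NumericVector x, NumericVector y, NumericVector heading,
               NumericVector speed, IntegerVector mode,
               NumericVector dim1, NumericVector dim2,
               int species, LogicalVector lit, List geom, List par,
               double dt, int nsub,
               NumericMatrix tx, NumericMatrix ty, NumericMatrix segw) {
  Geom g = as_geom(geom);
  const int n = x.size();
  const double sdt = std::sqrt(dt);

  double border_turn = 0, e_noise = 0, tum_frac = 0, tum_reor = 0,
         tum_stroke = 0, jitter_amp = 0, p_act = 0, p_rest = 0,
         c_noise = 0, exit_damp = 0;
  bool draw_resting = true;
  jitter_amp = as<double>(par["wall_jitter"]);
  if (species == 0) {
    border_turn = as<double>(par["euglena_border_turn_prob"]);
    e_noise = as<double>(par["euglena_heading_noise"]);
    tum_frac = as<double>(par["euglena_tumble_speed_frac"]);
    tum_reor = as<double>(par["euglena_tumble_reorient"]);
    tum_stroke = as<double>(par["euglena_tumble_stroke_frac"]);
  } else {
    p_act = 1.0 - std::exp(-as<double>(par["chlamy_k_act"]) * dt);
    p_rest = 1.0 - std::exp(-as<double>(par["chlamy_k_rest"]) * dt);
    c_noise = as<double>(par["chlamy_heading_noise"]);
    exit_damp = as<double>(par["chlamy_exit_damping"]);
    draw_resting = as<bool>(par["draw_resting"]);
  }

  for (int i = 0; i < n; ++i) { tx(i, 0) = x[i]; ty(i, 0) = y[i]; }

  for (int k = 0; k < nsub; ++k) {
    for (int i = 0; i < n; ++i) {
      int here = locate_region(g, x[i], y[i]);
      bool lit_here = here > 0 && lit[here - 1];
      double w = 0.0;

      if (species == 0) {
        if (lit_here) { // tumbling under blue light
          mode[i] = 1;
          if (unif_rand() < tum_reor) heading[i] = unif_rand() * 2.0 * M_PI;
          double step = speed[i] * tum_frac * dt;
          double nx2 = x[i] + std::cos(heading[i]) * step;
          double ny2 = y[i] + std::sin(heading[i]) * step;
          move_checked(g, x[i], y[i], heading[i], nx2, ny2, jitter_amp);
          w = tum_stroke * dim2[i];
        } else {        // straight swimming
          mode[i] = 0;
          heading[i] += norm_rand() * e_noise * sdt;
          double nx2 = x[i] + std::cos(heading[i]) * speed[i] * dt;
          double ny2 = y[i] + std::sin(heading[i]) * speed[i] * dt;
          int tgt = locate_region(g, nx2, ny2);
          if (tgt > 0 && lit[tgt - 1] && tgt != here &&
              unif_rand() < border_turn) {
            // photophobic turn at the illumination border
            heading[i] += M_PI + wall_jit(jitter_amp);
          } else {
            move_checked(g, x[i], y[i], heading[i], nx2, ny2, jitter_amp);
          }
          w = dim1[i];
        }
      } else {
        if (mode[i] == 0) {
          if (lit_here && unif_rand() < p_act) mode[i] = 1;
        } else {
          if (!lit_here && unif_rand() < p_rest) mode[i] = 0;
        }
        if (mode[i] == 1) {
          heading[i] += norm_rand() * c_noise * sdt;
          double nx2 = x[i] + std::cos(heading[i]) * speed[i] * dt;
          double ny2 = y[i] + std::sin(heading[i]) * speed[i] * dt;
          int tgt = locate_region(g, nx2, ny2);
          if (lit_here && tgt >= 0 && tgt != here) {
            // bottom illumination: cells rarely find the exits
            if (unif_rand() < exit_damp) {
              x[i] = nx2; y[i] = ny2;
            } else {
              heading[i] += M_PI + wall_jit(jitter_amp);
            }
          } else {
            move_checked(g, x[i], y[i], heading[i], nx2, ny2, jitter_amp);
          }
          w = dim1[i];
        } else {
          w = draw_resting ? dim1[i] : 0.0; // static body footprint
        }
      }

      tx(i, k + 1) = x[i];
      ty(i, k + 1) = y[i];
      segw(i, k) = w;
    }
  }
}

// Stamp a stroked segment (capsule) into the binary raster: every pixel
// whose center lies within w/2 + res/2 of the segment is set. Newly set
// pixels falling inside a square well increment that square's TM count.
static inline void stamp_segment(double x0, double y0, double x1, double y1,
                                 double w, double res, Rbyte* img,
                                 int W, int H, const int* sqmap, int* tm) {
  double r = 0.5 * w + 0.5 * res;
  double xmin = std::min(x0, x1) - r, xmax = std::max(x0, x1) + r;
  double ymin = std::min(y0, y1) - r, ymax = std::max(y0, y1) + r;
  int i0 = std::max(0, (int)std::floor(xmin / res - 0.5));
  int i1 = std::min(W - 1, (int)std::ceil(xmax / res - 0.5));
  int j0 = std::max(0, (int)std::floor(ymin / res - 0.5));
  int j1 = std::min(H - 1, (int)std::ceil(ymax / res - 0.5));
  double dx = x1 - x0, dy = y1 - y0;
  double len2 = dx * dx + dy * dy;
  double r2 = r * r;
  for (int j = j0; j <= j1; ++j) {
    double cy = (j + 0.5) * res;
    for (int i = i0; i <= i1; ++i) {
      double cx = (i + 0.5) * res;
      double px = cx - x0, py = cy - y0;
      double d2;
      if (len2 <= 0.0) {
        d2 = px * px + py * py;
      } else {
        double t = (px * dx + py * dy) / len2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        double qx = px - t * dx, qy = py - t * dy;
        d2 = qx * qx + qy * qy;
      }
      if (d2 <= r2) {
        R_xlen_t idx = (R_xlen_t)j * W + i;
        if (!img[idx]) {
          img[idx] = 1;
          if (tm && sqmap[idx] > 0) tm[sqmap[idx] - 1]++;
        }
      }
    }
  }
}

// Rasterize one cycle's trajectories (from cpp_cycle) into img (raw, W x H,
// column index = y) and return the 25 per-square trace-momentum pixel
// counts. sqmap maps each pixel to its owning square (0 = none).
// [[Rcpp::export]]
IntegerVector cpp_raster_tm(NumericMatrix tx, NumericMatrix ty,
                            NumericMatrix segw, RawVector img,
                            int W, int H, double res,
                            IntegerVector sqmap, bool clear) {
  if ((R_xlen_t)W * H != img.size())
    stop("image buffer does not match W x H");
  if (img.size() != sqmap.size())
    stop("square map does not match image dimensions");
  Rbyte* p = img.begin();
  if (clear) std::memset(p, 0, img.size());
  IntegerVector tm(25);
  int* tmp = tm.begin();
  const int* sq = sqmap.begin();
  int n = tx.nrow(), ns = segw.ncol();
  for (int i = 0; i < n; ++i) {
    double lx = NA_REAL, ly = NA_REAL, lw = -1.0; // last drawn segment end
    for (int k = 0; k < ns; ++k) {
      double w = segw(i, k);
      if (w <= 0.0) { lw = -1.0; continue; }
      double x0 = tx(i, k), y0 = ty(i, k);
      double x1 = tx(i, k + 1), y1 = ty(i, k + 1);
      // skip re-stamping identical stationary footprints
      if (x0 == x1 && y0 == y1 && x0 == lx && y0 == ly && w == lw) continue;
      stamp_segment(x0, y0, x1, y1, w, res, p, W, H, sq, tmp);
      lx = x1; ly = y1; lw = w;
    }
  }
  return tm;
}

// Rasterize explicit polylines (list of m x 2 matrices, um) with one stroke
// width per polyline. A single-point polyline stamps the body footprint
// disk. Same pixel rule as cpp_raster_tm.
// [[Rcpp::export]]
IntegerVector cpp_raster_polylines(List polylines, NumericVector widths,
                                   RawVector img, int W, int H, double res,
                                   IntegerVector sqmap, bool clear) {
  if ((R_xlen_t)W * H != img.size())
    stop("image buffer does not match W x H");
  Rbyte* p = img.begin();
  if (clear) std::memset(p, 0, img.size());
  IntegerVector tm(25);
  int* tmp = tm.begin();
  const int* sq = sqmap.begin();
  for (int i = 0; i < polylines.size(); ++i) {
    NumericMatrix pl = polylines[i];
    double w = widths[i];
    if (w <= 0.0) stop("stroke widths must be positive");
    int m = pl.nrow();
    if (m == 0) continue;
    if (m == 1) {
      stamp_segment(pl(0, 0), pl(0, 1), pl(0, 0), pl(0, 1), w, res,
                    p, W, H, sq, tmp);
    } else {
      for (int k = 0; k + 1 < m; ++k)
        stamp_segment(pl(k, 0), pl(k, 1), pl(k + 1, 0), pl(k + 1, 1),
                      w, res, p, W, H, sq, tmp);
    }
  }
  return tm;
}
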