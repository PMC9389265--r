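#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rigid+scale resampling and mutual information.
//
// Coordinate conventions (documented in ?apply_transform):
//   - pixel centers at 0-based (row, col); geometric center ((H-1)/2, (W-1)/2)
//   - x translation acts along the vertical axis, positive = up (toward row 0)
//   - y translation acts along the horizontal axis, positive = left (toward col 0)
//   - theta in degrees, positive = counterclockwise on screen
//   - forward composition: scale by Z about center, rotate theta about center,
//     then translate; resampling uses the inverse map per output pixel.
//
// Internally points are (h, v): h = col - cc (positive right), v = cr - row
// (positive up). Translating up by x and left by y adds (-y, +x) in (h, v).

// Exact cosine/sine for quarter-turn angles so that integer translations with
// theta in {0, 90, 180, 270} and Z = 1 resample without interpolation dust.
static inline void trig_deg(double theta, double &ct, double &st) {
  // remainder via floor (exact for quarter-turn angles, which are all that
  // matters here; the general branch below uses theta directly)
  double m = theta - 360.0 * std::floor(theta / 360.0);
  if (m == 0.0)        { ct = 1.0;  st = 0.0; }
  else if (m == 90.0)  { ct = 0.0;  st = 1.0; }
  else if (m == 180.0) { ct = -1.0; st = 0.0; }
  else if (m == 270.0) { ct = 0.0;  st = -1.0; }
  else {
    double r = theta * M_PI / 180.0;
    ct = std::cos(r);
    st = std::sin(r);
  }
}

// Bilinear sample of (px, mask) at source coords (rs, cs); valid only if the
// point is inside the domain and every contributing pixel carries real data.
static inline bool sample_bilinear(const double *px, const int *mask,
                                   int H, int W, double rs, double cs,
                                   double &value) {
  if (!(rs >= 0.0 && rs <= H - 1.0 && cs >= 0.0 && cs <= W - 1.0))
    return false;
  int r0 = (int)std::floor(rs);
  int c0 = (int)std::floor(cs);
  if (r0 > H - 1) r0 = H - 1;
  if (c0 > W - 1) c0 = W - 1;
  double fr = rs - r0, fc = cs - c0;
  int r1 = (fr > 0.0) ? r0 + 1 : r0;
  int c1 = (fc > 0.0) ? c0 + 1 : c0;
  // column-major indexing
  int i00 = r0 + c0 * H, i10 = r1 + c0 * H, i01 = r0 + c1 * H, i11 = r1 + c1 * H;
  if (!(mask[i00] && mask[i10] && mask[i01] && mask[i11]))
    return false;
  if (fr == 0.0 && fc == 0.0) {   // exact gather: bit-identical to the source
    value = px[i00];
    return true;
  }
  value = px[i00] * (1 - fr) * (1 - fc) + px[i10] * fr * (1 - fc) +
          px[i01] * (1 - fr) * fc + px[i11] * fr * fc;
  return true;
}

// [[Rcpp::export(name = ".resample_cpp")]]
List resample_cpp(NumericMatrix px, LogicalMatrix mask,
                  double x, double y, double theta, double Z) {
  int H = px.nrow(), W = px.ncol();
  double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  double ct, st;
  trig_deg(theta, ct, st);
  NumericMatrix out(H, W);
  LogicalMatrix outmask(H, W);
  const double *p = px.begin();
  const int *m = mask.begin();
  for (int j = 0; j < W; ++j) {
    double h0 = (j - cc) + y;           // (h_o - t_h), t_h = -y
    for (int i = 0; i < H; ++i) {
      double v0 = (cr - i) - x;         // (v_o - t_v), t_v = +x
      double hs = (h0 * ct + v0 * st) / Z;
      double vs = (-h0 * st + v0 * ct) / Z;
      double val;
      if (sample_bilinear(p, m, H, W, cr - vs, cc + hs, val)) {
        out(i, j) = val;
        outmask(i, j) = true;
      } else {
        out(i, j) = 0.0;
        outmask(i, j) = false;
      }
    }
  }
  return List::create(_["pixels"] = out, _["mask"] = outmask);
}

static inline int quantize(double v, int B) {
  int q = (int)std::floor(v * B);
  if (q >= B) q = B - 1;   // right-closed last bin: v = 1 falls in bin B-1
  if (q < 0) q = 0;
  return q;
}

// [[Rcpp::export(name = ".joint_hist_cpp")]]
IntegerMatrix joint_hist_cpp(NumericMatrix a, NumericMatrix b,
                             LogicalMatrix ma, LogicalMatrix mb, int bins) {
  int n = a.size();
  IntegerMatrix counts(bins, bins);
  for (int i = 0; i < n; ++i) {
    if (ma[i] && mb[i]) {
      int qa = quantize(a[i], bins);
      int qb = quantize(b[i], bins);
      counts(qa, qb) += 1;
    }
  }
  return counts;
}

static double mi_from_counts(const std::vector<int> &counts, int B) {
  long total = 0;
  std::vector<long> rowm(B, 0), colm(B, 0);
  for (int qa = 0; qa < B; ++qa)
    for (int qb = 0; qb < B; ++qb) {
      int c = counts[qa + qb * B];
      total += c;
      rowm[qa] += c;
      colm[qb] += c;
    }
  if (total == 0) return NA_REAL;
  double N = (double)total;
  // One p log2(p / (pa pb)) term per nonzero cell. Cells (i,j) and (j,i) are
  // summed as a commutative pair in a fixed (i <= j) traversal so that the
  // result is bit-identical under transposition of the histogram.
  auto term = [&](int qa, int qb) -> double {
    int c = counts[qa + (size_t)qb * B];
    if (c == 0) return 0.0;
    double pab = c / N;
    return pab * std::log2(pab * N * N / ((double)rowm[qa] * (double)colm[qb]));
  };
  double mi = 0.0;
  for (int i = 0; i < B; ++i) {
    mi += term(i, i);
    for (int j = i + 1; j < B; ++j)
      mi += term(i, j) + term(j, i);
  }
  return mi > 0.0 ? mi : 0.0;
}

// Fused objective: resample the float, accumulate the joint histogram over the
// jointly valid region, return MI in bits. Degenerate overlap scores 0 so that
// optimizers can move back toward the frame. Identical quantization and
// resampling as the unfused .resample_cpp / .joint_hist_cpp route.
// [[Rcpp::export(name = ".mi_transform_cpp")]]
double mi_transform_cpp(NumericMatrix ref, LogicalMatrix refmask,
                        NumericMatrix flt, LogicalMatrix fltmask,
                        double x, double y, double theta, double Z, int bins) {
  int H = ref.nrow(), W = ref.ncol();
  double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  double ct, st;
  trig_deg(theta, ct, st);
  std::vector<int> counts((size_t)bins * bins, 0);
  const double *p = flt.begin();
  const int *m = fltmask.begin();
  for (int j = 0; j < W; ++j) {
    double h0 = (j - cc) + y;
    for (int i = 0; i < H; ++i) {
      if (!refmask(i, j)) continue;
      double v0 = (cr - i) - x;
      double hs = (h0 * ct + v0 * st) / Z;
      double vs = (-h0 * st + v0 * ct) / Z;
      double val;
      if (sample_bilinear(p, m, H, W, cr - vs, cc + hs, val)) {
        counts[quantize(ref(i, j), bins) + (size_t)quantize(val, bins) * bins] += 1;
      }
    }
  }
  double mi = mi_from_counts(counts, bins);
  return R_IsNA(mi) ? 0.0 : mi;
}

// [[Rcpp::export(name = ".mi_counts_cpp")]]
double mi_counts_cpp(IntegerMatrix counts) {
  int B = counts.nrow();
  if (counts.ncol() != B) stop("counts must be square");
  std::vector<int> c(counts.begin(), counts.end());
  double mi = mi_from_counts(c, B);
  if (R_IsNA(mi)) stop("empty histogram");
  return mi;
}
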