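// Fixed-point / CORDIC datapath and Euler integration loops.
//
// All arithmetic is integer-only (two's complement payloads held in int64_t);
// the R level passes raw payloads encoded as doubles, which is exact for the
// bit widths used here (<< 53 bits). Right shifts are arithmetic (truncate
// toward -inf), matching shift registers in hardware.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <utility>

using namespace Rcpp;

// guard bits carried inside a CORDIC iteration loop below the I/O fraction,
// so every scheduled shift 2^-i is representable and per-iteration truncation
// does not bias the accumulator
static const int CORDIC_GUARD_BITS = 16;

static inline int64_t asr(int64_t v, int k) {
  // gcc/clang implement >> on signed as arithmetic shift
  return v >> k;
}

static inline int64_t fmt_max(int total) { return (int64_t(1) << (total - 1)) - 1; }
static inline int64_t fmt_min(int total) { return -(int64_t(1) << (total - 1)); }

static inline int64_t clamp_raw(int64_t v, int total, bool saturate, bool *overflowed) {
  int64_t hi = fmt_max(total), lo = fmt_min(total);
  if (v > hi) { if (overflowed) *overflowed = true; return saturate ? hi : v; }
  if (v < lo) { if (overflowed) *overflowed = true; return saturate ? lo : v; }
  return v;
}

static int64_t quantize1(double x, int frac, bool nearest) {
  double scaled = std::ldexp(x, frac);
  if (nearest) return (int64_t) std::llround(scaled);
  return (int64_t) std::floor(scaled);
}

// canonical signed-digit decomposition of a nonnegative integer;
// digits in {-1,+1} at distinct powers, minimal nonzero-digit count
static void csd_decompose(int64_t v, std::vector< std::pair<int,int> > &out) {
  int sgn = 1;
  if (v < 0) { sgn = -1; v = -v; }
  int k = 0;
  while (v != 0) {
    if (v & 1) {
      int d = ((v & 3) == 3) ? -1 : 1;
      out.push_back(std::make_pair(k, sgn * d));
      v -= d;
    }
    v >>= 1;
    ++k;
  }
}

// x * c for a constant held as CSD digits at the same fraction as x:
// sum of +/- shifted copies of x, each term truncated individually
static inline int64_t csd_mul(int64_t x, const std::vector< std::pair<int,int> > &digits,
                              int frac) {
  int64_t acc = 0;
  for (size_t t = 0; t < digits.size(); ++t) {
    int shift = frac - digits[t].first; // right shift amount; can be <= 0
    int64_t term = (shift >= 0) ? asr(x, shift) : (x << (-shift));
    acc += digits[t].second >= 0 ? term : -term;
  }
  return acc;
}

// ---- linear-mode rotation CORDIC -------------------------------------------
// y accumulates x * z while z is driven to zero through the shift schedule
// 2^-i0, 2^-(i0+1), ...; d = sign(z) with sign(0) = +1.
// core loop at an already guard-extended fraction fg; z is consumed in
// exact steps 2^-i, y accumulates arithmetically shifted copies of x
static int64_t cordic_iterate(int64_t x, int64_t z, int fg, int n_iter, int i0) {
  int64_t y = 0;
  for (int i = i0; i < i0 + n_iter; ++i) {
    if (z >= 0) { y += asr(x, i); z -= (int64_t(1) << (fg - i)); }
    else        { y -= asr(x, i); z += (int64_t(1) << (fg - i)); }
  }
  return y;
}

static int64_t cordic_mul_core(int64_t x_raw, int64_t z_raw, int frac,
                               int n_iter, int i0) {
  const int G = CORDIC_GUARD_BITS;
  return asr(cordic_iterate(x_raw << G, z_raw << G, frac + G, n_iter, i0), G);
}

static inline int64_t pow2_core(int64_t x_raw, int frac, int n_iter, int i0) {
  // initial Y = 0, initial Z = X -> Y converges to X*X
  return cordic_mul_core(x_raw, x_raw, frac, n_iter, i0);
}

static inline int64_t pow2_ext_core(int64_t x_raw, int frac, int n_iter, int i0) {
  // halve, square on the (-2,2) block, scale back by 4; the halving and
  // scaling shifts are internal to the block and run at its guard-extended
  // width, so only the output register truncates to the I/O format
  const int G = CORDIC_GUARD_BITS;
  int64_t h = asr(x_raw << G, 1);
  int64_t y = cordic_iterate(h, h, frac + G, n_iter, i0);
  return asr(y, G - 2);
}

static inline int64_t pow3_core(int64_t x_raw, int frac, int n_iter, int i0) {
  // (x/2)^2 by the squaring block, times x/2 by a linear multiply, times 8;
  // shifts internal to the block as in pow2_ext_core
  const int G = CORDIC_GUARD_BITS;
  int64_t h = asr(x_raw << G, 1);
  int64_t s = cordic_iterate(h, h, frac + G, n_iter, i0);
  int64_t c = cordic_iterate(s, h, frac + G, n_iter, i0);
  return asr(c, G - 3);
}

// ---- exported fixed-point primitives ---------------------------------------

// [[Rcpp::export]]
NumericVector fp_quantize_cpp(NumericVector x, int total, int frac,
                              bool nearest, bool saturate) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i])) stop("non-finite value cannot be quantized");
    int64_t raw = quantize1(x[i], frac, nearest);
    bool ovf = false;
    raw = clamp_raw(raw, total, saturate, &ovf);
    if (ovf && !saturate)
      stop("value %g overflows Q(%d,1,%d) range", x[i], total, frac);
    out[i] = (double) raw;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector fp_shift_cpp(NumericVector raw, int k, int total, bool saturate) {
  int n = raw.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int64_t v = (int64_t) raw[i];
    int64_t r = (k >= 0) ? (v << k) : asr(v, -k);
    bool ovf = false;
    r = clamp_raw(r, total, saturate, &ovf);
    if (ovf && !saturate) stop("left shift overflows the fixed-point range");
    out[i] = (double) r;
  }
  return out;
}

// [[Rcpp::export]]
List csd_cpp(double raw) {
  std::vector< std::pair<int,int> > digits;
  csd_decompose((int64_t) raw, digits);
  int m = digits.size();
  IntegerVector powers(m), signs(m);
  for (int t = 0; t < m; ++t) { powers[t] = digits[t].first; signs[t] = digits[t].second; }
  return List::create(_["power"] = powers, _["sign"] = signs);
}

// [[Rcpp::export]]
NumericVector fp_constmul_cpp(NumericVector x_raw, double c, int total, int frac,
                              bool saturate) {
  std::vector< std::pair<int,int> > digits;
  csd_decompose(quantize1(c, frac, true), digits);
  int n = x_raw.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int64_t r = csd_mul((int64_t) x_raw[i], digits, frac);
    bool ovf = false;
    r = clamp_raw(r, total, saturate, &ovf);
    if (ovf && !saturate) stop("constant multiply overflows the fixed-point range");
    out[i] = (double) r;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cordic_mul_cpp(NumericVector x_raw, NumericVector z_raw,
                             int total, int frac, int n_iter, int i0,
                             bool saturate) {
  if (i0 + n_iter - 1 > frac + CORDIC_GUARD_BITS)
    stop("shift schedule exceeds datapath resolution");
  int n = x_raw.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int64_t r = cordic_mul_core((int64_t) x_raw[i], (int64_t) z_raw[i % z_raw.size()],
                                frac, n_iter, i0);
    out[i] = (double) clamp_raw(r, total, saturate, NULL);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cordic_pow_cpp(NumericVector x_raw, int power_kind,
                             int total, int frac, int n_iter, int i0,
                             bool saturate) {
  // power_kind: 2 = squaring block on (-2,2); 3 = pow2_ext on (-2,2.5);
  //             4 = cubing block on (-2,2.5)
  if (i0 + n_iter - 1 > frac + CORDIC_GUARD_BITS)
    stop("shift schedule exceeds datapath resolution");
  int n = x_raw.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int64_t x = (int64_t) x_raw[i], r;
    if (power_kind == 2)      r = pow2_core(x, frac, n_iter, i0);
    else if (power_kind == 3) r = pow2_ext_core(x, frac, n_iter, i0);
    else                      r = pow3_core(x, frac, n_iter, i0);
    out[i] = (double) clamp_raw(r, total, saturate, NULL);
  }
  return out;
}

// ---- Euler integration loops ------------------------------------------------

// [[Rcpp::export]]
List hr_sim_ref_cpp(double x0, double y0, double z0,
                    NumericVector I, double r, double dt, int n_steps) {
  NumericVector X(n_steps + 1), Y(n_steps + 1), Z(n_steps + 1);
  double x = x0, y = y0, z = z0;
  X[0] = x; Y[0] = y; Z[0] = z;
  bool iconst = (I.size() == 1);
  for (int k = 0; k < n_steps; ++k) {
    double Ik = iconst ? I[0] : I[k];
    double x2 = x * x;
    double dx = y + x2 * (3.0 - x) - z + Ik;
    double dy = 1.0 - 5.0 * x2 - y;
    double dz = r * (4.0 * (x + 1.6) - z);
    x += dt * dx; y += dt * dy; z += dt * dz;
    X[k + 1] = x; Y[k + 1] = y; Z[k + 1] = z;
  }
  return List::create(_["X"] = X, _["Y"] = Y, _["Z"] = Z);
}

struct CordicHRStepper {
  int io_total, io_frac, n_iter, i0, wide_frac, dt_shift;
  int up;                 // wide_frac - io_frac
  int64_t wide_hi, wide_lo, io_hi, io_lo, one_w, c64_w;
  std::vector< std::pair<int,int> > csd_4r, csd_r;

  CordicHRStepper(double r, int dt_shift_, int io_total_, int io_frac_,
                  int n_iter_, int i0_, int wide_frac_)
    : io_total(io_total_), io_frac(io_frac_), n_iter(n_iter_), i0(i0_),
      wide_frac(wide_frac_), dt_shift(dt_shift_) {
    up = wide_frac - io_frac;
    int int_bits = io_total - 1 - io_frac;        // same integer range, wide fraction
    int wide_total = 1 + int_bits + wide_frac;
    wide_hi = fmt_max(wide_total); wide_lo = fmt_min(wide_total);
    io_hi = fmt_max(io_total); io_lo = fmt_min(io_total);
    one_w = int64_t(1) << wide_frac;
    c64_w = quantize1(6.4 * r, wide_frac, true);
    csd_decompose(quantize1(4.0 * r, wide_frac, true), csd_4r);
    csd_decompose(quantize1(r, wide_frac, true), csd_r);
  }

  inline int64_t sat_wide(int64_t v) const {
    return v > wide_hi ? wide_hi : (v < wide_lo ? wide_lo : v);
  }

  inline void step(int64_t &Xw, int64_t &Yw, int64_t &Zw, int64_t Iw) const {
    // POW-block input register: truncate the wide state to the Q I/O format
    int64_t xq = asr(Xw, up);
    if (xq > io_hi) xq = io_hi; else if (xq < io_lo) xq = io_lo;
    int64_t p2 = pow2_ext_core(xq, io_frac, n_iter, i0) << up;
    int64_t p3 = pow3_core(xq, io_frac, n_iter, i0) << up;
    int64_t dX = Yw + ((p2 << 1) + p2) - p3 - Zw + Iw;
    int64_t dY = one_w - ((p2 << 2) + p2) - Yw;
    int64_t dZ = csd_mul(Xw, csd_4r, wide_frac) + c64_w - csd_mul(Zw, csd_r, wide_frac);
    Xw = sat_wide(Xw + asr(dX, dt_shift));
    Yw = sat_wide(Yw + asr(dY, dt_shift));
    Zw = sat_wide(Zw + asr(dZ, dt_shift));
  }
};

// [[Rcpp::export]]
List hr_sim_cordic_cpp(double x0, double y0, double z0,
                       NumericVector I, double r, int dt_shift, int n_steps,
                       int io_total, int io_frac, int n_iter, int i0,
                       int wide_frac) {
  if (i0 + n_iter - 1 > io_frac + CORDIC_GUARD_BITS)
    stop("shift schedule exceeds datapath resolution");
  CordicHRStepper st(r, dt_shift, io_total, io_frac, n_iter, i0, wide_frac);
  NumericVector X(n_steps + 1), Y(n_steps + 1), Z(n_steps + 1);
  int64_t Xw = quantize1(x0, wide_frac, true);
  int64_t Yw = quantize1(y0, wide_frac, true);
  int64_t Zw = quantize1(z0, wide_frac, true);
  const double scale = std::ldexp(1.0, -wide_frac);
  X[0] = Xw * scale; Y[0] = Yw * scale; Z[0] = Zw * scale;
  bool iconst = (I.size() == 1);
  int64_t Iw = quantize1(I[0], wide_frac, true);
  for (int k = 0; k < n_steps; ++k) {
    if (!iconst) Iw = quantize1(I[k], wide_frac, true);
    st.step(Xw, Yw, Zw, Iw);
    X[k + 1] = Xw * scale; Y[k + 1] = Yw * scale; Z[k + 1] = Zw * scale;
  }
  return List::create(_["X"] = X, _["Y"] = Y, _["Z"] = Z);
}

// [[Rcpp::export]]
List hr_network_sim_cpp(int n, IntegerVector edge_src, IntegerVector edge_dst,
                        NumericVector pre_sign, bool cordic,
                        double I, double r, double dt, int dt_shift, int n_steps,
                        double g, double tau_syn, double weight,
                        double threshold, double min_separation,
                        double x0, double y0, double z0,
                        int io_total, int io_frac, int n_iter, int i0,
                        int wide_frac) {
  // CSR adjacency over presynaptic index
  int m = edge_src.size();
  std::vector<int> deg(n, 0), row(n + 1, 0), col(m);
  for (int e = 0; e < m; ++e) deg[edge_src[e]]++;
  for (int i = 0; i < n; ++i) row[i + 1] = row[i] + deg[i];
  { std::vector<int> fill(row.begin(), row.end() - 1);
    for (int e = 0; e < m; ++e) col[fill[edge_src[e]]++] = edge_dst[e]; }

  const double decay = std::exp(-dt / tau_syn);
  std::vector<double> syn(n, 0.0), syn_inc(n, 0.0);
  std::vector<double> last_spike(n, -1e18);
  std::vector< std::vector<double> > spikes(n);

  CordicHRStepper st(r, dt_shift, io_total, io_frac, n_iter, i0, wide_frac);
  std::vector<int64_t> Xw(n), Yw(n), Zw(n);
  std::vector<double> x(n), y(n), z(n), prevX(n);
  const double scale = std::ldexp(1.0, -wide_frac);
  for (int i = 0; i < n; ++i) {
    if (cordic) {
      Xw[i] = quantize1(x0, wide_frac, true);
      Yw[i] = quantize1(y0, wide_frac, true);
      Zw[i] = quantize1(z0, wide_frac, true);
      prevX[i] = Xw[i] * scale;
    } else {
      x[i] = x0; y[i] = y0; z[i] = z0; prevX[i] = x0;
    }
  }

  for (int k = 0; k < n_steps; ++k) {
    double t = (k + 1) * dt;
    for (int i = 0; i < n; ++i) {
      syn[i] = syn[i] * decay + syn_inc[i];
      syn_inc[i] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      double Ii = I + syn[i];
      double Xi;
      if (cordic) {
        int64_t Iw = quantize1(Ii, wide_frac, true);
        st.step(Xw[i], Yw[i], Zw[i], Iw);
        Xi = Xw[i] * scale;
      } else {
        double x2 = x[i] * x[i];
        double dx = y[i] + x2 * (3.0 - x[i]) - z[i] + Ii;
        double dy = 1.0 - 5.0 * x2 - y[i];
        double dz = r * (4.0 * (x[i] + 1.6) - z[i]);
        x[i] += dt * dx; y[i] += dt * dy; z[i] += dt * dz;
        Xi = x[i];
      }
      if (prevX[i] < threshold && Xi >= threshold &&
          t - last_spike[i] >= min_separation) {
        last_spike[i] = t;
        spikes[i].push_back(t);
        double w = pre_sign[i] * weight * g;
        for (int e = row[i]; e < row[i + 1]; ++e) syn_inc[col[e]] += w;
      }
      prevX[i] = Xi;
    }
  }

  List out(n);
  for (int i = 0; i < n; ++i) out[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return out;
}
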