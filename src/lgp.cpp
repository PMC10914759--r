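#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear genetic program virtual machine.
//
// A program is an integer instruction matrix (rows = instructions) with
// columns: fn, dst, t1, i1, t2, i2, t3, i3 (all 1-based), plus a constant
// pool. Operand types: 1 = register, 2 = feature, 3 = constant. Registers
// are initialised to 0; the program's score is register 1 after the last
// instruction. All 48 functions are total ("protected"): any non-finite
// intermediate collapses to 0 and results are clamped, so execution can
// never emit NaN/Inf.

static const double VCLAMP = 1e9;

static inline double guard(double x) {
  if (!std::isfinite(x)) return 0.0;
  if (x > VCLAMP) return VCLAMP;
  if (x < -VCLAMP) return -VCLAMP;
  return x;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Function palette. IDs are stable for serialization.
//  1-19 binary, 20-44 unary, 45-48 ternary (see R/palette.R for the table).
static inline double apply_fn(int fn, double a, double b, double c) {
  switch (fn) {
  case 1: return a + b;                                   // add
  case 2: return a - b;                                   // sub
  case 3: return a * b;                                   // mul
  case 4: return std::fabs(b) < 1e-9 ? a : a / b;         // div (protected)
  case 5: return a < b ? a : b;                           // min
  case 6: return a > b ? a : b;                           // max
  case 7: {                                               // pow (protected)
    double e = clampd(b, -5.0, 5.0);
    return std::pow(std::fabs(a) + 1e-12, e);
  }
  case 8: return std::fabs(b) < 1e-9 ? 0.0 : a - std::trunc(a / b) * b; // mod
  case 9: return std::hypot(a, b);                        // hypot
  case 10: return 0.5 * (a + b);                          // mean2
  case 11: return std::fabs(a - b);                       // absdiff
  case 12: return a > b ? 1.0 : 0.0;                      // gt
  case 13: return a < b ? 1.0 : 0.0;                      // lt
  case 14: return std::fabs(a - b) < 1e-9 ? 1.0 : 0.0;    // eq
  case 15: return (a > 0 && b > 0) ? 1.0 : 0.0;           // and
  case 16: return (a > 0 || b > 0) ? 1.0 : 0.0;           // or
  case 17: return ((a > 0) != (b > 0)) ? 1.0 : 0.0;       // xor
  case 18: {                                              // gauss2 kernel
    double d = a - b;
    return std::exp(-clampd(d * d, 0.0, 50.0));
  }
  case 19: return std::atan2(a, b);                       // atan2
  case 20: return std::fabs(a);                           // abs
  case 21: return -a;                                     // neg
  case 22: return a > 0 ? 1.0 : (a < 0 ? -1.0 : 0.0);     // sign
  case 23: return std::sqrt(std::fabs(a));                // sqrt|x|
  case 24: return a * a;                                  // square
  case 25: return a * a * a;                              // cube
  case 26: return std::exp(clampd(a, -50.0, 50.0));       // exp (clamped)
  case 27: return std::log(std::fabs(a) + 1e-12);         // log|x|
  case 28: return std::log1p(std::fabs(a));               // log1p|x|
  case 29: return std::sin(a);                            // sin
  case 30: return std::cos(a);                            // cos
  case 31: return clampd(std::tan(a), -VCLAMP, VCLAMP);   // tan (clamped)
  case 32: return std::tanh(a);                           // tanh
  case 33: return std::sinh(clampd(a, -50.0, 50.0));      // sinh
  case 34: return std::cosh(clampd(a, -50.0, 50.0));      // cosh
  case 35: return std::asin(clampd(a, -1.0, 1.0));        // asin
  case 36: return std::acos(clampd(a, -1.0, 1.0));        // acos
  case 37: return std::atan(a);                           // atan
  case 38: return 1.0 / (1.0 + std::exp(clampd(-a, -50.0, 50.0))); // sigmoid
  case 39: return a > 0 ? a : 0.0;                        // relu
  case 40: return std::floor(a);                          // floor
  case 41: return std::ceil(a);                           // ceil
  case 42: return std::nearbyint(a);                      // round
  case 43: return std::fabs(a) < 1e-9 ? 0.0 : 1.0 / a;    // recip (protected)
  case 44: return a > 0 ? 0.0 : 1.0;                      // not
  case 45: return a > 0 ? b : c;                          // ifpos
  case 46: {                                              // clip3
    double lo = b < c ? b : c, hi = b < c ? c : b;
    return clampd(a, lo, hi);
  }
  case 47: return a * b + c;                              // fma
  case 48: return (a + b + c) / 3.0;                      // mean3
  default: return 0.0;
  }
}

static inline double fetch(int type, int idx, const double* reg,
                           const NumericMatrix& X, int row,
                           const NumericVector& consts) {
  switch (type) {
  case 1: return reg[idx - 1];
  case 2: return X(row, idx - 1);
  case 3: return consts[idx - 1];
  default: return 0.0;
  }
}

static void run_program(const IntegerMatrix& instr, const NumericVector& consts,
                        const NumericMatrix& X, int row, double* reg, int nreg) {
  for (int j = 0; j < nreg; ++j) reg[j] = 0.0;
  int ni = instr.nrow();
  for (int k = 0; k < ni; ++k) {
    double a = fetch(instr(k, 2), instr(k, 3), reg, X, row, consts);
    double b = fetch(instr(k, 4), instr(k, 5), reg, X, row, consts);
    double c = fetch(instr(k, 6), instr(k, 7), reg, X, row, consts);
    reg[instr(k, 1) - 1] = guard(apply_fn(instr(k, 0), a, b, c));
  }
}

// [[Rcpp::export]]
NumericVector cpp_execute_program(IntegerMatrix instr, NumericVector consts,
                                  NumericMatrix X, int nreg) {
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> reg(nreg);
  for (int i = 0; i < n; ++i) {
    run_program(instr, consts, X, i, reg.data(), nreg);
    out[i] = reg[0];
  }
  return out;
}

// Batch fitness: classification accuracy of score > 0 against labels y
// (0/1), balanced ((sens + spec) / 2) or raw.
// [[Rcpp::export]]
NumericVector cpp_fitness_batch(List instr_list, List consts_list,
                                NumericMatrix X, IntegerVector y,
                                int nreg, bool balanced) {
  int m = instr_list.size();
  int n = X.nrow();
  int npos = 0, nneg = 0;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? npos : nneg)++;
  NumericVector out(m);
  std::vector<double> reg(nreg);
  for (int pj = 0; pj < m; ++pj) {
    IntegerMatrix instr = instr_list[pj];
    NumericVector consts = consts_list[pj];
    int tp = 0, tn = 0;
    for (int i = 0; i < n; ++i) {
      run_program(instr, consts, X, i, reg.data(), nreg);
      bool call = reg[0] > 0;
      if (y[i] == 1 && call) tp++;
      if (y[i] == 0 && !call) tn++;
    }
    if (balanced) {
      double sens = npos > 0 ? (double)tp / npos : 0.0;
      double spec = nneg > 0 ? (double)tn / nneg : 0.0;
      out[pj] = 0.5 * (sens + spec);
    } else {
      out[pj] = (double)(tp + tn) / n;
    }
  }
  return out;
}
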