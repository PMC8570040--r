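// Compact EEG CNN engine: temporal conv -> BN -> depthwise spatial conv -> BN
// -> ELU -> avgpool -> separable (depthwise temporal + pointwise) conv -> BN
// -> ELU -> avgpool -> flatten -> dense -> softmax.
//
// Layout conventions (chosen so every inner loop walks contiguous memory):
//   * batches cross the R/C++ boundary as cubes (E, T, n) — slice = trial;
//   * stage-1 activations live as (T, E, n*F1) with slice i*F1 + f;
//   * later stages as (time, channels, n) — columns are single channels;
//   * flatten order is column-major over the (T2, F2) map: time fastest.
// Batch norm uses biased batch variance; running stats follow
// r <- momentum * r + (1 - momentum) * batch.

#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using namespace arma;

struct Dims {
  int E, T, M, F1, F2, K1, K2, D, P1, P2;
  int C1, T1, T2, dfeat;
};

static Dims read_dims(const List& cfg) {
  Dims d;
  d.E  = as<int>(cfg["E"]);
  d.T  = as<int>(cfg["T"]);
  d.M  = as<int>(cfg["M"]);
  d.F1 = as<int>(cfg["F1"]);
  d.F2 = as<int>(cfg["F2"]);
  d.K1 = as<int>(cfg["K1"]);
  d.K2 = as<int>(cfg["K2"]);
  d.D  = as<int>(cfg["D"]);
  d.P1 = as<int>(cfg["P1"]);
  d.P2 = as<int>(cfg["P2"]);
  if (d.T % d.P1 != 0) stop("T must be divisible by P1");
  if ((d.T / d.P1) % d.P2 != 0) stop("T/P1 must be divisible by P2");
  d.C1 = d.F1 * d.D;
  d.T1 = d.T / d.P1;
  d.T2 = d.T1 / d.P2;
  d.dfeat = d.F2 * d.T2;
  return d;
}

static inline double elu_fwd(double x) { return x > 0.0 ? x : std::expm1(x); }
// derivative of ELU (alpha = 1) expressed through its output
static inline double elu_grad(double a) { return a > 0.0 ? 1.0 : a + 1.0; }

struct Cache {
  mat IC;          // im2col of the input, (n*E*T) x K1
  mat xhat1;       // BN1 normalised conv1 output, (n*E*T) x F1
  vec var1;
  cube A1;         // post-BN1 activations, (T, E, n*F1)
  cube xhat2;      // (T, C1, n)
  vec var2;
  cube A2;         // post-ELU, (T, C1, n)
  cube Pl1;        // pooled (and possibly dropped) stage-2 output, (T1, C1, n)
  cube mask1;      // dropout mask (empty when unused)
  cube Z3s;        // depthwise temporal conv output, (T1, C1, n)
  cube xhat3;      // (T1, F2, n)
  vec var3;
  cube A3;         // post-ELU, (T1, F2, n)
  cube mask2;      // (T2, F2, n)
  mat feats;       // n x dfeat
  mat probs;       // n x M
};

// channel-wise batch norm (+ optional ELU) over the columns `c` of every
// slice of `Z`; statistics pooled over (rows x slices)
static void bn_channel_forward(const cube& Z, cube& xhat, cube& act,
                               vec& var_out, vec& rm, vec& rv,
                               const vec& gamma, const vec& beta,
                               bool training, double momentum, double eps,
                               bool apply_elu) {
  const int C = Z.n_cols, n = Z.n_slices;
  const uword len = Z.n_rows;
  const double m = (double)n * len;
  for (int c = 0; c < C; ++c) {
    double mu, va;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* z = Z.slice_colptr(i, c);
        for (uword t = 0; t < len; ++t) { s += z[t]; ss += z[t] * z[t]; }
      }
      mu = s / m;
      va = ss / m - mu * mu;
      if (va < 0) va = 0;
      rm[c] = momentum * rm[c] + (1.0 - momentum) * mu;
      rv[c] = momentum * rv[c] + (1.0 - momentum) * va;
    } else {
      mu = rm[c];
      va = rv[c];
    }
    var_out[c] = va;
    const double inv = 1.0 / std::sqrt(va + eps);
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double* z = Z.slice_colptr(i, c);
      double* xh = xhat.slice_colptr(i, c);
      double* a = act.slice_colptr(i, c);
      for (uword t = 0; t < len; ++t) {
        xh[t] = (z[t] - mu) * inv;
        const double y = g * xh[t] + b;
        a[t] = apply_elu ? elu_fwd(y) : y;
      }
    }
  }
}

// backward through (optional ELU +) channel-wise batch norm.
// dact holds the gradient at the activation output and is overwritten with
// the post-ELU gradient; dZ receives the gradient at the BN input.
static void bn_channel_backward(cube& dact, const cube& act,
                                const cube& xhat, const vec& var,
                                const vec& gamma, double eps, bool had_elu,
                                cube& dZ, vec& dgamma, vec& dbeta) {
  const int C = dact.n_cols, n = dact.n_slices;
  const uword len = dact.n_rows;
  const double m = (double)n * len;
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double* dy = dact.slice_colptr(i, c);
      const double* a = act.slice_colptr(i, c);
      const double* xh = xhat.slice_colptr(i, c);
      for (uword t = 0; t < len; ++t) {
        if (had_elu) dy[t] *= elu_grad(a[t]);
        s1 += dy[t];
        s2 += dy[t] * xh[t];
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double inv = gamma[c] / std::sqrt(var[c] + eps);
    const double c1 = s1 / m, c2 = s2 / m;
    for (int i = 0; i < n; ++i) {
      const double* dy = dact.slice_colptr(i, c);
      const double* xh = xhat.slice_colptr(i, c);
      double* dz = dZ.slice_colptr(i, c);
      for (uword t = 0; t < len; ++t)
        dz[t] = inv * (dy[t] - c1 - xh[t] * c2);
    }
  }
}

// Forward pass. When `training` is true batch statistics are used (and the
// new running stats are written into the rm*/rv* outputs); otherwise running
// statistics are used.
static void forward_impl(const cube& X, const List& par, const List& bn,
                         const Dims& d, bool training,
                         double momentum, double eps,
                         double dropout, uint32_t drop_seed,
                         Cache& C, mat& logits,
                         vec& rm1o, vec& rv1o, vec& rm2o, vec& rv2o,
                         vec& rm3o, vec& rv3o) {
  const int n = X.n_slices;
  if ((int)X.n_rows != d.E || (int)X.n_cols != d.T)
    stop("batch shape (%d, %d) does not match config (E=%d, T=%d)",
         (int)X.n_rows, (int)X.n_cols, d.E, d.T);

  const mat W1  = as<mat>(par["W1"]);    // K1 x F1
  const mat Wd  = as<mat>(par["Wd"]);    // E x C1
  const mat Ws  = as<mat>(par["Ws"]);    // K2 x C1
  const mat Wp  = as<mat>(par["Wp"]);    // C1 x F2
  const mat Wfc = as<mat>(par["Wfc"]);   // dfeat x M
  const rowvec bfc = as<rowvec>(par["bfc"]);
  const vec g1 = as<vec>(par["g1"]), b1 = as<vec>(par["b1"]);
  const vec g2 = as<vec>(par["g2"]), b2 = as<vec>(par["b2"]);
  const vec g3 = as<vec>(par["g3"]), b3 = as<vec>(par["b3"]);

  vec rm1 = as<vec>(bn["rm1"]), rv1 = as<vec>(bn["rv1"]);
  vec rm2 = as<vec>(bn["rm2"]), rv2 = as<vec>(bn["rv2"]);
  vec rm3 = as<vec>(bn["rm3"]), rv3 = as<vec>(bn["rv3"]);

  const int pad1 = (d.K1 - 1) / 2;
  const int pad2 = (d.K2 - 1) / 2;
  const int nET = n * d.E * d.T;

  // ---- stage 1: temporal convolution via im2col --------------------------
  C.IC.set_size(nET, d.K1);
  {
    std::vector<double> row(d.T);
    for (int i = 0; i < n; ++i)
      for (int e = 0; e < d.E; ++e) {
        for (int t = 0; t < d.T; ++t) row[t] = X(e, t, i);
        const int base = (i * d.E + e) * d.T;
        for (int k = 0; k < d.K1; ++k) {
          double* dst = C.IC.colptr(k) + base;
          const int off = k - pad1;
          const int lo = std::max(0, -off), hi = std::min(d.T, d.T - off);
          for (int t = 0; t < lo; ++t) dst[t] = 0.0;
          for (int t = lo; t < hi; ++t) dst[t] = row[t + off];
          for (int t = hi; t < d.T; ++t) dst[t] = 0.0;
        }
      }
  }
  mat Z1 = C.IC * W1;  // nET x F1

  // BN1 (statistics per temporal filter over batch x electrodes x time)
  C.xhat1.set_size(nET, d.F1);
  C.var1.set_size(d.F1);
  mat A1cols(nET, d.F1);
  for (int f = 0; f < d.F1; ++f) {
    double mu, va;
    if (training) {
      mu = mean(Z1.col(f));
      va = mean(square(Z1.col(f) - mu));
      rm1[f] = momentum * rm1[f] + (1.0 - momentum) * mu;
      rv1[f] = momentum * rv1[f] + (1.0 - momentum) * va;
    } else {
      mu = rm1[f];
      va = rv1[f];
    }
    C.var1[f] = va;
    C.xhat1.col(f) = (Z1.col(f) - mu) / std::sqrt(va + eps);
    A1cols.col(f) = g1[f] * C.xhat1.col(f) + b1[f];
  }

  // reshape to (T, E, n*F1) for the spatial stage
  C.A1.set_size(d.T, d.E, n * d.F1);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < d.F1; ++f) {
      const double* src = A1cols.colptr(f) + (uword)i * d.E * d.T;
      mat& sl = C.A1.slice(i * d.F1 + f);
      for (int e = 0; e < d.E; ++e)
        std::copy(src + (uword)e * d.T, src + (uword)(e + 1) * d.T,
                  sl.colptr(e));
    }

  // ---- stage 2: depthwise spatial convolution (collapses E -> 1) ---------
  cube Z2(d.T, d.C1, n);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < d.F1; ++f) {
      const mat& sl = C.A1.slice(i * d.F1 + f);  // T x E
      Z2.slice(i).cols(f * d.D, f * d.D + d.D - 1) =
        sl * Wd.cols(f * d.D, f * d.D + d.D - 1);
    }

  // BN2 + ELU
  C.xhat2.set_size(d.T, d.C1, n);
  C.A2.set_size(d.T, d.C1, n);
  C.var2.set_size(d.C1);
  bn_channel_forward(Z2, C.xhat2, C.A2, C.var2, rm2, rv2, g2, b2,
                     training, momentum, eps, true);

  // average pooling (P1, 1)
  C.Pl1.set_size(d.T1, d.C1, n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d.C1; ++c) {
      const double* a = C.A2.slice_colptr(i, c);
      double* o = C.Pl1.slice_colptr(i, c);
      for (int t = 0; t < d.T1; ++t) {
        double s = 0.0;
        for (int p = 0; p < d.P1; ++p) s += a[t * d.P1 + p];
        o[t] = s / d.P1;
      }
    }

  std::mt19937 rng(drop_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const bool drop = training && dropout > 0.0;
  if (drop) {
    C.mask1.set_size(d.T1, d.C1, n);
    const double keep = 1.0 - dropout;
    for (uword q = 0; q < C.mask1.n_elem; ++q)
      C.mask1(q) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    C.Pl1 %= C.mask1;
  } else {
    C.mask1.reset();
  }

  // ---- stage 3: separable convolution ------------------------------------
  // depthwise temporal
  C.Z3s.zeros(d.T1, d.C1, n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d.C1; ++c) {
      const double* in = C.Pl1.slice_colptr(i, c);
      double* o = C.Z3s.slice_colptr(i, c);
      for (int k = 0; k < d.K2; ++k) {
        const double w = Ws(k, c);
        const int off = k - pad2;
        const int lo = std::max(0, -off), hi = std::min(d.T1, d.T1 - off);
        for (int t = lo; t < hi; ++t) o[t] += w * in[t + off];
      }
    }
  // pointwise mixing
  cube Z3(d.T1, d.F2, n);
  for (int i = 0; i < n; ++i) Z3.slice(i) = C.Z3s.slice(i) * Wp;

  // BN3 + ELU
  C.xhat3.set_size(d.T1, d.F2, n);
  C.A3.set_size(d.T1, d.F2, n);
  C.var3.set_size(d.F2);
  bn_channel_forward(Z3, C.xhat3, C.A3, C.var3, rm3, rv3, g3, b3,
                     training, momentum, eps, true);

  // average pooling (P2, 1)
  cube Pl2(d.T2, d.F2, n);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < d.F2; ++g) {
      const double* a = C.A3.slice_colptr(i, g);
      double* o = Pl2.slice_colptr(i, g);
      for (int t = 0; t < d.T2; ++t) {
        double s = 0.0;
        for (int p = 0; p < d.P2; ++p) s += a[t * d.P2 + p];
        o[t] = s / d.P2;
      }
    }
  if (drop) {
    C.mask2.set_size(d.T2, d.F2, n);
    const double keep = 1.0 - dropout;
    for (uword q = 0; q < C.mask2.n_elem; ++q)
      C.mask2(q) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    Pl2 %= C.mask2;
  } else {
    C.mask2.reset();
  }

  // flatten + dense + softmax
  C.feats.set_size(n, d.dfeat);
  for (int i = 0; i < n; ++i)
    C.feats.row(i) = vectorise(Pl2.slice(i)).t();
  logits = C.feats * Wfc;
  logits.each_row() += bfc;

  C.probs.set_size(n, d.M);
  for (int i = 0; i < n; ++i) {
    rowvec z = logits.row(i);
    z -= z.max();
    rowvec ez = exp(z);
    C.probs.row(i) = ez / accu(ez);
  }

  rm1o = rm1; rv1o = rv1; rm2o = rm2; rv2o = rv2; rm3o = rm3; rv3o = rv3;
}

// [[Rcpp::export]]
List nn_forward_cpp(arma::cube X, List par, List bn, List cfg, bool training,
                    double momentum, double eps, double dropout, int drop_seed) {
  Dims d = read_dims(cfg);
  Cache C;
  mat logits;
  vec rm1, rv1, rm2, rv2, rm3, rv3;
  forward_impl(X, par, bn, d, training, momentum, eps, dropout,
               (uint32_t)drop_seed, C, logits, rm1, rv1, rm2, rv2, rm3, rv3);
  List shapes = List::create(
      _["input"] = IntegerVector::create(d.T, d.E, 1),
      _["conv_temporal"] = IntegerVector::create(d.T, d.E, d.F1),
      _["depthwise"] = IntegerVector::create(d.T, 1, d.C1),
      _["pool1"] = IntegerVector::create(d.T1, 1, d.C1),
      _["separable"] = IntegerVector::create(d.T1, 1, d.F2),
      _["pool2"] = IntegerVector::create(d.T2, 1, d.F2),
      _["flatten"] = IntegerVector::create(d.dfeat),
      _["dense"] = IntegerVector::create(d.M));
  List bn_new = List::create(_["rm1"] = rm1, _["rv1"] = rv1,
                             _["rm2"] = rm2, _["rv2"] = rv2,
                             _["rm3"] = rm3, _["rv3"] = rv3);
  return List::create(_["logits"] = logits, _["probabilities"] = C.probs,
                      _["features"] = C.feats, _["shapes"] = shapes,
                      _["bn"] = bn_new);
}

// One training step: forward in training mode, combined loss
// (cross-entropy + alpha_lsr * uniform-CE + alpha_ct * center loss, all mean
// reduced), full backward pass. Centers are constants here (they move only
// through their own update rule).
// [[Rcpp::export]]
List nn_train_step_cpp(arma::cube X, arma::ivec labels, List par, List bn,
                       List cfg, double alpha_lsr, double alpha_ct,
                       arma::mat centers, double momentum, double eps,
                       double floorp, double dropout, int drop_seed) {
  Dims d = read_dims(cfg);
  const int n = X.n_slices;
  if ((int)labels.n_elem != n) stop("labels length does not match batch size");
  for (int i = 0; i < n; ++i)
    if (labels[i] < 0 || labels[i] >= d.M) stop("label out of range [0, M)");

  Cache C;
  mat logits;
  vec rm1, rv1, rm2, rv2, rm3, rv3;
  forward_impl(X, par, bn, d, true, momentum, eps, dropout,
               (uint32_t)drop_seed, C, logits, rm1, rv1, rm2, rv2, rm3, rv3);

  const mat Wd  = as<mat>(par["Wd"]);
  const mat Ws  = as<mat>(par["Ws"]);
  const mat Wp  = as<mat>(par["Wp"]);
  const mat Wfc = as<mat>(par["Wfc"]);
  const vec g1 = as<vec>(par["g1"]);
  const vec g2 = as<vec>(par["g2"]);
  const vec g3 = as<vec>(par["g3"]);

  const int pad2 = (d.K2 - 1) / 2;
  const int nET = n * d.E * d.T;

  // ---- loss terms (mean reduction) ---------------------------------------
  double Lcl = 0.0, Llsr = 0.0, Lct = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d.M; ++j) {
      const double q = std::max(C.probs(i, j), floorp);
      Llsr -= std::log(q) / d.M;
      if (j == labels[i]) Lcl -= std::log(q);
    }
    const rowvec diff = C.feats.row(i) - centers.row(labels[i]);
    Lct += 0.5 * dot(diff, diff);
  }
  Lcl /= n; Llsr /= n; Lct /= n;
  const double Ltot = Lcl + alpha_lsr * Llsr + alpha_ct * Lct;

  // ---- backward ----------------------------------------------------------
  // d total / d logits for CE(onehot) + alpha_lsr * CE(uniform), mean-reduced
  mat dlogits = (1.0 + alpha_lsr) * C.probs;
  dlogits -= alpha_lsr / d.M;
  for (int i = 0; i < n; ++i) dlogits(i, labels[i]) -= 1.0;
  dlogits /= n;

  mat dWfc = C.feats.t() * dlogits;
  rowvec dbfc = sum(dlogits, 0);
  mat dfeats = dlogits * Wfc.t();
  if (alpha_ct != 0.0)
    for (int i = 0; i < n; ++i)
      dfeats.row(i) += (alpha_ct / n) * (C.feats.row(i) - centers.row(labels[i]));

  // unflatten, dropout2, pool2 backward
  cube dA3(d.T1, d.F2, n);
  for (int i = 0; i < n; ++i) {
    mat dPl2 = reshape(dfeats.row(i).t(), d.T2, d.F2);
    if (C.mask2.n_elem > 0) dPl2 %= C.mask2.slice(i);
    for (int g = 0; g < d.F2; ++g) {
      const double* src = dPl2.colptr(g);
      double* o = dA3.slice_colptr(i, g);
      for (int t = 0; t < d.T1; ++t) o[t] = src[t / d.P2] / d.P2;
    }
  }

  // ELU + BN3 backward
  cube dZ3(d.T1, d.F2, n);
  vec dg3(d.F2), db3(d.F2);
  bn_channel_backward(dA3, C.A3, C.xhat3, C.var3, g3, eps, true,
                      dZ3, dg3, db3);

  // pointwise backward
  mat dWp(d.C1, d.F2, fill::zeros);
  cube dZ3s(d.T1, d.C1, n);
  for (int i = 0; i < n; ++i) {
    dWp += C.Z3s.slice(i).t() * dZ3.slice(i);
    dZ3s.slice(i) = dZ3.slice(i) * Wp.t();
  }

  // depthwise temporal backward
  mat dWs(d.K2, d.C1, fill::zeros);
  cube dPl1(d.T1, d.C1, n, fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d.C1; ++c) {
      const double* g = dZ3s.slice_colptr(i, c);
      const double* in = C.Pl1.slice_colptr(i, c);
      double* dp = dPl1.slice_colptr(i, c);
      for (int k = 0; k < d.K2; ++k) {
        const int off = k - pad2;
        const int lo = std::max(0, -off), hi = std::min(d.T1, d.T1 - off);
        double acc = 0.0;
        const double w = Ws(k, c);
        for (int t = lo; t < hi; ++t) {
          acc += in[t + off] * g[t];
          dp[t + off] += w * g[t];
        }
        dWs(k, c) += acc;
      }
    }

  // dropout1 + pool1 backward
  cube dA2(d.T, d.C1, n);
  for (int i = 0; i < n; ++i) {
    if (C.mask1.n_elem > 0) dPl1.slice(i) %= C.mask1.slice(i);
    for (int c = 0; c < d.C1; ++c) {
      const double* src = dPl1.slice_colptr(i, c);
      double* o = dA2.slice_colptr(i, c);
      for (int t = 0; t < d.T; ++t) o[t] = src[t / d.P1] / d.P1;
    }
  }

  // ELU + BN2 backward
  cube dZ2(d.T, d.C1, n);
  vec dg2(d.C1), db2(d.C1);
  bn_channel_backward(dA2, C.A2, C.xhat2, C.var2, g2, eps, true,
                      dZ2, dg2, db2);

  // depthwise spatial backward
  mat dWd(d.E, d.C1, fill::zeros);
  mat dA1cols(nET, d.F1);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < d.F1; ++f) {
      const int c0 = f * d.D;
      const mat& sl = C.A1.slice(i * d.F1 + f);          // T x E
      const mat dblock = dZ2.slice(i).cols(c0, c0 + d.D - 1);  // T x D
      dWd.cols(c0, c0 + d.D - 1) += sl.t() * dblock;
      const mat dsl = dblock * Wd.cols(c0, c0 + d.D - 1).t();  // T x E
      double* dst = dA1cols.colptr(f) + (uword)i * d.E * d.T;
      for (int e = 0; e < d.E; ++e)
        std::copy(dsl.colptr(e), dsl.colptr(e) + d.T, dst + (uword)e * d.T);
    }

  // BN1 backward
  mat dZ1(nET, d.F1);
  vec dg1(d.F1), db1(d.F1);
  {
    const double m1 = (double)nET;
    for (int f = 0; f < d.F1; ++f) {
      const double s1 = accu(dA1cols.col(f));
      const double s2 = dot(dA1cols.col(f), C.xhat1.col(f));
      dg1[f] = s2;
      db1[f] = s1;
      const double inv = g1[f] / std::sqrt(C.var1[f] + eps);
      dZ1.col(f) = inv * (dA1cols.col(f) - s1 / m1 - C.xhat1.col(f) * s2 / m1);
    }
  }

  // temporal conv backward (weights only; no input gradient needed)
  mat dW1 = C.IC.t() * dZ1;

  List grads = List::create(
      _["W1"] = dW1, _["Wd"] = dWd, _["Ws"] = dWs, _["Wp"] = dWp,
      _["Wfc"] = dWfc, _["bfc"] = dbfc,
      _["g1"] = dg1, _["b1"] = db1,
      _["g2"] = dg2, _["b2"] = db2,
      _["g3"] = dg3, _["b3"] = db3);
  List bn_new = List::create(_["rm1"] = rm1, _["rv1"] = rv1,
                             _["rm2"] = rm2, _["rv2"] = rv2,
                             _["rm3"] = rm3, _["rv3"] = rv3);
  List loss = List::create(_["cl"] = Lcl, _["lsr"] = Llsr, _["ct"] = Lct,
                           _["total"] = Ltot);
  return List::create(_["grads"] = grads, _["loss"] = loss,
                      _["probabilities"] = C.probs, _["features"] = C.feats,
                      _["bn"] = bn_new);
}
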