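#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Jansen-Rit column constants, unpacked once per run.
struct JRParams {
  double A, B, a, b, C1, C2, C3, C4, e0, v0, r;
};

static inline double sigm(double y, const JRParams &P) {
  return 2.0 * P.e0 / (1.0 + std::exp(P.r * (P.v0 - y)));
}

// Drift of the 6N-dimensional column system. State layout per column:
// (y0, y1, y2, z0, z1, z2). p_exc[i] is the full pyramidal input
// (constant + coupling + periodic + OU) for column i.
static void column_drift(const std::vector<double> &x, int N,
                         const JRParams &P, const std::vector<double> &p_exc,
                         std::vector<double> &dx) {
  for (int i = 0; i < N; ++i) {
    const double *s = &x[6 * i];
    double *d = &dx[6 * i];
    double y0 = s[0], y1 = s[1], y2 = s[2];
    double z0 = s[3], z1 = s[4], z2 = s[5];
    d[0] = z0;
    d[1] = z1;
    d[2] = z2;
    d[3] = P.A * P.a * sigm(y1 - y2, P) - 2.0 * P.a * z0 - P.a * P.a * y0;
    d[4] = P.A * P.a * (p_exc[i] + P.C2 * sigm(P.C1 * y0, P)) -
           2.0 * P.a * z1 - P.a * P.a * y1;
    d[5] = P.B * P.b * P.C4 * sigm(P.C3 * y0, P) - 2.0 * P.b * z2 -
           P.b * P.b * y2;
  }
}

// Normalized coupling input: coup[i] = (1/(N-1)) * sum_{j != i} K(j,i) *
// Sigm(y1_j - y2_j). Zero for N == 1.
static void coupling(const std::vector<double> &x, int N, const JRParams &P,
                     const NumericMatrix &K, std::vector<double> &coup) {
  if (N == 1) {
    coup[0] = 0.0;
    return;
  }
  std::vector<double> rate(N);
  for (int j = 0; j < N; ++j)
    rate[j] = sigm(x[6 * j + 1] - x[6 * j + 2], P);
  double norm = 1.0 / (N - 1);
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int j = 0; j < N; ++j)
      if (j != i) acc += K(j, i) * rate[j];
    coup[i] = norm * acc;
  }
}

// [[Rcpp::export]]
List heun_simulate_cpp(NumericMatrix init, NumericVector xi0, List params,
                       NumericMatrix K, double p_const, NumericVector posc,
                       NumericMatrix W, double D, double tau, double h,
                       int record_stride, bool record_coupling) {
  const int N = init.ncol();
  if (init.nrow() != 6) stop("init must be a 6 x N matrix");
  if (K.nrow() != N || K.ncol() != N) stop("K must be N x N");
  const int nsteps = posc.size() - 1;
  const bool noisy = (D > 0.0);
  if (noisy && (W.nrow() != nsteps || W.ncol() != N))
    stop("white-noise matrix must be nsteps x N");

  JRParams P;
  P.A = params["A"]; P.B = params["B"]; P.a = params["a"]; P.b = params["b"];
  P.C1 = params["C1"]; P.C2 = params["C2"]; P.C3 = params["C3"];
  P.C4 = params["C4"]; P.e0 = params["e0"]; P.v0 = params["v0"];
  P.r = params["r"];

  const double cnoise = std::sqrt(2.0 * D) / tau * std::sqrt(h);

  std::vector<double> x(6 * N), xp(6 * N), f0(6 * N), f1(6 * N);
  std::vector<double> xi(N), xip(N), coup0(N), coup1(N), pexc(6 * N);
  std::vector<double> pe0(N), pe1(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 6; ++k) x[6 * i + k] = init(k, i);
    xi[i] = xi0[i];
  }

  const int nrec = nsteps / record_stride + 1;
  NumericMatrix eeg(nrec, N);
  NumericMatrix coup_rec(record_coupling ? nrec : 0,
                         record_coupling ? N : 0);

  int irec = 0;
  coupling(x, N, P, K, coup0);
  for (int i = 0; i < N; ++i) eeg(irec, i) = x[6 * i + 1] - x[6 * i + 2];
  if (record_coupling)
    for (int i = 0; i < N; ++i) coup_rec(irec, i) = coup0[i];
  ++irec;

  for (int k = 0; k < nsteps; ++k) {
    // predictor (Euler) at time t_k
    coupling(x, N, P, K, coup0);
    for (int i = 0; i < N; ++i)
      pe0[i] = p_const + coup0[i] + posc[k] + xi[i];
    column_drift(x, N, P, pe0, f0);
    for (int i = 0; i < 6 * N; ++i) xp[i] = x[i] + h * f0[i];
    for (int i = 0; i < N; ++i) {
      double w = noisy ? W(k, i) : 0.0;
      xip[i] = xi[i] - h * xi[i] / tau + cnoise * w;
    }
    // corrector (trapezoidal) at time t_{k+1}, same noise increment
    coupling(xp, N, P, K, coup1);
    for (int i = 0; i < N; ++i)
      pe1[i] = p_const + coup1[i] + posc[k + 1] + xip[i];
    column_drift(xp, N, P, pe1, f1);
    for (int i = 0; i < 6 * N; ++i)
      x[i] += 0.5 * h * (f0[i] + f1[i]);
    for (int i = 0; i < N; ++i) {
      double w = noisy ? W(k, i) : 0.0;
      xi[i] += -0.5 * h * (xi[i] + xip[i]) / tau + cnoise * w;
    }

    for (int i = 0; i < N; ++i) {
      double v = x[6 * i + 1] - x[6 * i + 2];
      if (!std::isfinite(v) || std::fabs(v) > 1e6)
        stop("numerical blow-up in column %d at t = %g s", i + 1,
             (k + 1) * h);
    }

    if ((k + 1) % record_stride == 0) {
      for (int i = 0; i < N; ++i)
        eeg(irec, i) = x[6 * i + 1] - x[6 * i + 2];
      if (record_coupling) {
        coupling(x, N, P, K, coup1);
        for (int i = 0; i < N; ++i) coup_rec(irec, i) = coup1[i];
      }
      ++irec;
    }
  }

  NumericMatrix final_state(6, N);
  NumericVector final_xi(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 6; ++k) final_state(k, i) = x[6 * i + k];
    final_xi[i] = xi[i];
  }

  List out = List::create(_["eeg"] = eeg, _["final_state"] = final_state,
                          _["final_xi"] = final_xi);
  if (record_coupling) out["coupling"] = coup_rec;
  return out;
}
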