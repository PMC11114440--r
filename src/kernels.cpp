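// Compiled kernels for the per-subject connectivity pipeline.
// These are plain numerical routines; all validation and RNG live in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double PI_ = 3.141592653589793238462643383280;

// Wrap a phase difference (input in (-2*pi, 2*pi]) to (-pi, pi].
static inline double wrap_pm_pi(double d) {
  if (d > PI_) d -= 2.0 * PI_;
  else if (d <= -PI_) d += 2.0 * PI_;
  return d;
}

// FFT-overlap filtering of all channels with a bank of FIR filters sharing
// one forward transform. X is samples x channels; each element of H is the
// length-M complex frequency response of one filter (M = n + 2*pad).
// Reflection padding of `pad` samples at each end; `delay` samples of group
// delay are removed so outputs are time-aligned with the input.
// Requires pad + delay >= taps - 1 so the circular wrap-around never touches
// the retained samples, and n > pad for the reflection to be well defined.
// Real channels are packed in pairs into complex transforms (two real FFTs
// per complex FFT), and because every filtered output is real, two channels
// share each inverse transform as well.
// [[Rcpp::export]]
Rcpp::List cpp_filter_bank(const arma::mat& X, const Rcpp::List& H,
                           const int pad, const int delay) {
  const uword n = X.n_rows, C = X.n_cols;
  const uword M = n + 2 * (uword)pad;
  mat P(M, C);
  for (uword c = 0; c < C; ++c) {
    for (int i = 0; i < pad; ++i) P(pad - 1 - i, c) = X(i + 1, c);
    P.col(c).subvec(pad, pad + n - 1) = X.col(c);
    for (int i = 0; i < pad; ++i) P(pad + n + i, c) = X(n - 2 - i, c);
  }
  // forward: two real columns per complex FFT, split by conjugate symmetry;
  // all transforms are batched into single matrix FFT calls so the plan is
  // reused across columns
  const uword np = (C + 1) / 2;
  cx_mat Z(M, np);
  for (uword p = 0; p < np; ++p) {
    const uword c = 2 * p;
    const bool two = (c + 1 < C);
    for (uword k = 0; k < M; ++k) {
      Z(k, p) = cx_double(P(k, c), two ? P(k, c + 1) : 0.0);
    }
  }
  cx_mat Fp = fft(Z);
  cx_mat F(M, C);
  for (uword p = 0; p < np; ++p) {
    const uword c = 2 * p;
    const bool two = (c + 1 < C);
    F(0, c) = cx_double(Fp(0, p).real(), 0.0);
    if (two) F(0, c + 1) = cx_double(Fp(0, p).imag(), 0.0);
    for (uword k = 1; k < M; ++k) {
      cx_double a = Fp(k, p), bb = std::conj(Fp(M - k, p));
      F(k, c) = 0.5 * (a + bb);
      if (two) F(k, c + 1) = cx_double(0.0, -0.5) * (a - bb);
    }
  }
  const int B = H.size();
  // each inverse transform carries two real outputs (one channel pair)
  cx_mat G(M, (uword)B * np);
  for (int b = 0; b < B; ++b) {
    cx_vec h = Rcpp::as<cx_vec>(H[b]);
    for (uword p = 0; p < np; ++p) {
      const uword c = 2 * p;
      const bool two = (c + 1 < C);
      cx_double* g = G.colptr((uword)b * np + p);
      if (two) {
        for (uword k = 0; k < M; ++k) {
          g[k] = h(k) * (F(k, c) + cx_double(0.0, 1.0) * F(k, c + 1));
        }
      } else {
        for (uword k = 0; k < M; ++k) g[k] = h(k) * F(k, c);
      }
    }
  }
  cx_mat Yc = ifft(G);
  Rcpp::List out(B);
  const uword o = (uword)pad + (uword)delay;  // first retained sample
  for (int b = 0; b < B; ++b) {
    mat Y(n, C);
    for (uword p = 0; p < np; ++p) {
      const uword c = 2 * p;
      const bool two = (c + 1 < C);
      const cx_double* f = Yc.colptr((uword)b * np + p);
      for (uword i = 0; i < n; ++i) {
        Y(i, c) = f[o + i].real();
        if (two) Y(i, c + 1) = f[o + i].imag();
      }
    }
    out[b] = Y;
  }
  return out;
}

// Instantaneous phase per epoch and channel via the analytic signal of each
// epoch. Y is samples x channels (one band-filtered record); epochs are the
// contiguous windows of length S starting at `offsets` (0-based sample
// indices). Returns an S x C x E cube of phases in (-pi, pi].
// [[Rcpp::export]]
arma::cube cpp_epoch_phase(const arma::mat& Y, const int S,
                           const arma::uvec& offsets) {
  const uword C = Y.n_cols, E = offsets.n_elem;
  const uword nseg = C * E;
  const uword half = S / 2;
  const uword np = (nseg + 1) / 2;
  cube ph(S, C, E);
  // forward FFTs of two real segments share one complex transform; all
  // transforms are batched so the FFT plan is reused across columns
  cx_mat Z(S, np);
  for (uword p = 0; p < np; ++p) {
    const uword s = 2 * p;
    const bool two = (s + 1 < nseg);
    const double* y1 = Y.colptr(s % C) + offsets(s / C);
    const double* y2 = two ? (Y.colptr((s + 1) % C) + offsets((s + 1) / C))
                           : nullptr;
    cx_double* z = Z.colptr(p);
    for (int k = 0; k < S; ++k) {
      z[k] = cx_double(y1[k], two ? y2[k] : 0.0);
    }
  }
  cx_mat Fp = fft(Z);
  // unpack, apply the analytic-signal mask (keep DC and Nyquist, double
  // positive frequencies, zero negative ones)
  cx_mat A(S, nseg);
  const uword kmax = (S % 2 == 0) ? half - 1 : half;  // last doubled bin
  for (uword p = 0; p < np; ++p) {
    const uword s = 2 * p;
    const bool two = (s + 1 < nseg);
    const cx_double* f = Fp.colptr(p);
    cx_double* a1 = A.colptr(s);
    cx_double* a2 = two ? A.colptr(s + 1) : nullptr;
    a1[0] = cx_double(f[0].real(), 0.0);
    if (two) a2[0] = cx_double(f[0].imag(), 0.0);
    for (uword k = 1; k < (uword)S; ++k) {
      double w = (k <= kmax) ? 2.0 : ((k == half && S % 2 == 0) ? 1.0 : 0.0);
      if (w == 0.0) {
        a1[k] = cx_double(0, 0);
        if (two) a2[k] = cx_double(0, 0);
        continue;
      }
      cx_double u = f[k], v = std::conj(f[S - k]);
      a1[k] = w * 0.5 * (u + v);
      if (two) a2[k] = w * cx_double(0.0, -0.5) * (u - v);
    }
  }
  cx_mat An = ifft(A);
  for (uword s = 0; s < nseg; ++s) {
    const cx_double* a = An.colptr(s);
    double* p = ph.slice(s / C).colptr(s % C);
    for (int k = 0; k < S; ++k) p[k] = std::atan2(a[k].imag(), a[k].real());
  }
  return ph;
}

// Fused band pipeline kernel: per-epoch analytic signal plus PLI in one
// pass. The sign of the wrapped phase difference equals the sign of
// Im(z_a * conj(z_b)) (both are the sign of sin(dphi)), so the PLI can be
// accumulated from the analytic samples without computing phases. Output:
// C x C x E cube of per-epoch PLI.
// [[Rcpp::export]]
arma::cube cpp_epoch_pli(const arma::mat& Y, const int S,
                         const arma::uvec& offsets) {
  const uword C = Y.n_cols, E = offsets.n_elem;
  const uword nseg = C * E;
  const uword half = S / 2;
  const uword np = (nseg + 1) / 2;
  cx_mat Z(S, np);
  for (uword p = 0; p < np; ++p) {
    const uword s = 2 * p;
    const bool two = (s + 1 < nseg);
    const double* y1 = Y.colptr(s % C) + offsets(s / C);
    const double* y2 = two ? (Y.colptr((s + 1) % C) + offsets((s + 1) / C))
                           : nullptr;
    cx_double* z = Z.colptr(p);
    for (int k = 0; k < S; ++k) z[k] = cx_double(y1[k], two ? y2[k] : 0.0);
  }
  cx_mat Fp = fft(Z);
  cx_mat A(S, nseg);
  const uword kmax = (S % 2 == 0) ? half - 1 : half;
  for (uword p = 0; p < np; ++p) {
    const uword s = 2 * p;
    const bool two = (s + 1 < nseg);
    const cx_double* f = Fp.colptr(p);
    cx_double* a1 = A.colptr(s);
    cx_double* a2 = two ? A.colptr(s + 1) : nullptr;
    a1[0] = cx_double(f[0].real(), 0.0);
    if (two) a2[0] = cx_double(f[0].imag(), 0.0);
    for (uword k = 1; k < (uword)S; ++k) {
      double w = (k <= kmax) ? 2.0 : ((k == half && S % 2 == 0) ? 1.0 : 0.0);
      if (w == 0.0) {
        a1[k] = cx_double(0, 0);
        if (two) a2[k] = cx_double(0, 0);
        continue;
      }
      cx_double u = f[k], v = std::conj(f[S - k]);
      a1[k] = w * 0.5 * (u + v);
      if (two) a2[k] = w * cx_double(0.0, -0.5) * (u - v);
    }
  }
  cx_mat An = ifft(A);  // column s = epoch s/C, channel s%C
  cube out(C, C, E, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    for (uword a = 0; a + 1 < C; ++a) {
      const cx_double* za = An.colptr(e * C + a);
      for (uword b = a + 1; b < C; ++b) {
        const cx_double* zb = An.colptr(e * C + b);
        double acc = 0.0;
        for (int k = 0; k < S; ++k) {
          double im = za[k].imag() * zb[k].real() -
                      za[k].real() * zb[k].imag();
          acc += (im > 0.0) - (im < 0.0);
        }
        double v = std::abs(acc) / (double)S;
        out(a, b, e) = v;
        out(b, a, e) = v;
      }
    }
  }
  return out;
}

// PLI for every unordered channel pair in every epoch.
// phases: S x C x E cube (output of cpp_epoch_phase).
// Returns a C x C x E cube of per-epoch PLI values (diagonal 0, symmetric).
// PLI = | mean_k sign( wrap(phi_a - phi_b) ) | with wrap to (-pi, pi] and
// sign(0) = 0.
// [[Rcpp::export]]
arma::cube cpp_pli_epochs(const arma::cube& phases) {
  const uword S = phases.n_rows, C = phases.n_cols, E = phases.n_slices;
  cube out(C, C, E, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    const mat& P = phases.slice(e);
    for (uword a = 0; a + 1 < C; ++a) {
      const double* pa = P.colptr(a);
      for (uword b = a + 1; b < C; ++b) {
        const double* pb = P.colptr(b);
        double acc = 0.0;
        for (uword k = 0; k < S; ++k) {  // branchless wrap to (-pi, pi]
          double d = pa[k] - pb[k];
          d += 2.0 * PI_ * ((d <= -PI_) - (d > PI_));
          acc += (d > 0.0) - (d < 0.0);
        }
        double v = std::abs(acc) / (double)S;
        out(a, b, e) = v;
        out(b, a, e) = v;
      }
    }
  }
  return out;
}

// Brandes betweenness centrality on a dense undirected graph of edge
// lengths (len(i,j) = Inf or <=0 means "no edge"). Shortest paths by total
// length; co-minimal paths share credit via path counting, with a relative
// tolerance when comparing floating-point path lengths. Returns raw ordered
// -pair betweenness (caller normalizes by (n-1)(n-2)).
// [[Rcpp::export]]
arma::vec cpp_brandes_bc(const arma::mat& len, const double rel_tol) {
  const uword n = len.n_rows;
  vec bc(n, fill::zeros);
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<std::vector<uword>> pred(n);
  std::vector<uword> order;  // settled vertices in ascending distance
  order.reserve(n);
  for (uword s = 0; s < n; ++s) {
    for (uword v = 0; v < n; ++v) {
      dist[v] = datum::inf; sigma[v] = 0.0; delta[v] = 0.0;
      done[v] = false; pred[v].clear();
    }
    dist[s] = 0.0; sigma[s] = 1.0;
    order.clear();
    for (;;) {  // O(n^2) Dijkstra: fine at electrode counts
      double best = datum::inf; uword u = n;
      for (uword v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u == n) break;
      done[u] = true;
      order.push_back(u);
      for (uword v = 0; v < n; ++v) {
        if (v == u || done[v]) continue;
        double w = len(u, v);
        if (!std::isfinite(w) || w <= 0.0) continue;
        double nd = dist[u] + w;
        if (!std::isfinite(dist[v])) {
          dist[v] = nd; sigma[v] = sigma[u]; pred[v].assign(1, u);
          continue;
        }
        double tol = rel_tol * std::max(1.0, std::max(nd, dist[v]));
        if (std::abs(nd - dist[v]) <= tol) {          // co-minimal path
          sigma[v] += sigma[u]; pred[v].push_back(u);
        } else if (nd < dist[v]) {                    // strictly shorter
          dist[v] = nd; sigma[v] = sigma[u]; pred[v].assign(1, u);
        }
      }
    }
    for (uword i = order.size(); i-- > 1;) {  // skip source itself (order[0])
      uword w = order[i];
      for (uword v : pred[w]) delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      bc(w) += delta[w];
    }
  }
  return bc;
}

// Narrowband oscillation synthesis for one band: each channel carries a
// phase random walk around carrier f0, and each hub spec injects the hub
// channel's oscillation into its targets at a fixed phase lag.
// incr: samples x channels matrix of standard-normal phase increments;
// theta0: initial phase per channel; hub/targets are 0-based indices.
// target mixing keeps unit variance: sqrt(1-c^2)*own + c*lagged hub copy.
// `incr` may be supplied at a coarser rate: row k/block is used for sample
// k (piecewise-constant diffusion steps); sigma is the per-sample step SD.
// [[Rcpp::export]]
arma::mat cpp_synth_band(const arma::mat& incr, const double sigma,
                         const double f0, const double fs,
                         const arma::vec& theta0,
                         const arma::ivec& hub, const arma::vec& coupling,
                         const arma::vec& lag, const Rcpp::List& targets,
                         const int n_out, const int block) {
  const uword n = (uword)n_out, C = incr.n_cols;
  const double dphi = 2.0 * PI_ * f0 / fs;
  mat X(n, C);
  // oscillators advance by incremental complex rotation; the step changes
  // once per block and the modulus is renormalized there
  std::map<uword, cx_vec> hub_z;  // full oscillator state per hub channel
  for (uword h = 0; h < hub.n_elem; ++h) hub_z[(uword)hub(h)];
  for (uword c = 0; c < C; ++c) {
    const double* in = incr.colptr(c);
    double* x = X.colptr(c);
    cx_double z(std::cos(theta0(c)), std::sin(theta0(c)));
    cx_double step(1.0, 0.0);
    auto it = hub_z.find(c);
    cx_vec* zh = (it == hub_z.end()) ? nullptr : &it->second;
    if (zh) zh->set_size(n);
    for (uword k = 0; k < n; ++k) {
      if (k % block == 0) {
        double a = dphi + sigma * in[k / block];
        step = cx_double(std::cos(a), std::sin(a));
        z /= std::abs(z);
      }
      z *= step;
      x[k] = z.real();
      if (zh) (*zh)(k) = z;
    }
  }
  for (uword h = 0; h < hub.n_elem; ++h) {
    const double c = coupling(h);
    if (c <= 0.0) continue;
    const double own = std::sqrt(std::max(0.0, 1.0 - c * c));
    const cx_double rot(std::cos(lag(h)), -std::sin(lag(h)));
    const cx_vec& zh = hub_z[(uword)hub(h)];
    vec inj(n);
    for (uword k = 0; k < n; ++k) inj(k) = (zh(k) * rot).real();
    ivec tg = Rcpp::as<ivec>(targets[h]);
    for (uword t = 0; t < tg.n_elem; ++t)
      X.col(tg(t)) = own * X.col(tg(t)) + c * inj;
  }
  return X;
}

// 1/f ("pink") spectral shaping of white noise, channel-wise, with the
// magnitude response flattened below f_lo to keep variance finite. Each
// output column is rescaled to unit standard deviation.
// [[Rcpp::export]]
arma::mat cpp_pink_noise(const arma::mat& white, const double fs,
                         const double f_lo) {
  const uword n = white.n_rows, C = white.n_cols;
  uword M = 1; while (M < n) M <<= 1;
  vec g(M);
  for (uword k = 0; k < M; ++k) {
    double f = (k <= M / 2) ? k * fs / (double)M : (M - k) * fs / (double)M;
    g(k) = 1.0 / std::sqrt(std::max(f, f_lo));
  }
  mat out(n, C);
  const uword np = (C + 1) / 2;
  cx_mat Z(M, np);
  for (uword p = 0; p < np; ++p) {
    const uword c = 2 * p;
    const bool two = (c + 1 < C);
    cx_double* z = Z.colptr(p);
    // cycle the white noise up to the transform length; pack two channels
    for (uword k = 0; k < M; ++k) {
      z[k] = cx_double(white(k % n, c), two ? white(k % n, c + 1) : 0.0);
    }
  }
  cx_mat F = fft(Z);
  // shaping a packed pair keeps the pair packed: scaling the spectrum of
  // (x1 + i*x2) by the real gain g shapes both real channels at once
  for (uword p = 0; p < np; ++p) {
    cx_double* f = F.colptr(p);
    for (uword k = 0; k < M; ++k) f[k] *= g(k);
  }
  cx_mat Yc = ifft(F);
  for (uword p = 0; p < np; ++p) {
    const uword c = 2 * p;
    const bool two = (c + 1 < C);
    const cx_double* f = Yc.colptr(p);
    vec y1(n), y2(n);
    for (uword k = 0; k < n; ++k) { y1(k) = f[k].real(); y2(k) = f[k].imag(); }
    double s1 = stddev(y1);
    out.col(c) = (s1 > 0) ? vec(y1 / s1) : y1;
    if (two) {
      double s2 = stddev(y2);
      out.col(c + 1) = (s2 > 0) ? vec(y2 / s2) : y2;
    }
  }
  return out;
}
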