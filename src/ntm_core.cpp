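#include <Rcpp.h>
using namespace Rcpp;

// Sliding dot product between a multichannel trace V (T x N, column-major)
// and a template mu (L x N). out[t] = sum_c sum_j V(t+j, c) * mu(j, c),
// t = 0 .. T-L. Window slides through time, not channel.
// [[Rcpp::export]]
NumericVector cpp_sliding_dot(const NumericMatrix& V, const NumericMatrix& mu) {
  const int T = V.nrow(), N = V.ncol(), L = mu.nrow();
  if (mu.ncol() != N) stop("template and voltage channel counts differ");
  if (T < L) stop("trace shorter than template");
  const int M = T - L + 1;
  NumericVector out(M);
  double* o = out.begin();
  // blocked axpy formulation: for each template lag j, out[t] += v[t+j]*m[j]
  // over a cache-resident block of t, which vectorizes cleanly
  const int B = 8192;
  for (int c = 0; c < N; ++c) {
    const double* v = &V(0, c);
    const double* m = &mu(0, c);
    for (int t0 = 0; t0 < M; t0 += B) {
      const int tn = std::min(M, t0 + B);
      for (int j = 0; j < L; ++j) {
        const double mj = m[j];
        const double* vj = v + j;
        for (int t = t0; t < tn; ++t) o[t] += vj[t] * mj;
      }
    }
  }
  return out;
}

// Gather fixed-length windows from selected channels of a voltage matrix
// into an n x L x N array (clip extraction). starts are 1-based.
// [[Rcpp::export]]
NumericVector cpp_gather_clips(const NumericMatrix& V,
                               const IntegerVector& starts, int L,
                               const IntegerVector& channels) {
  const int n = starts.size(), N = channels.size(), T = V.nrow();
  NumericVector out(Dimension(n, L, N));
  double* o = out.begin();
  for (int c = 0; c < N; ++c) {
    const double* v = &V(0, channels[c] - 1);
    for (int i = 0; i < n; ++i) {
      const int s0 = starts[i] - 1;
      if (s0 < 0 || s0 + L > T) stop("clip window outside trace");
      double* oc = o + i + (std::size_t)n * L * c;
      for (int j = 0; j < L; ++j) oc[(std::size_t)n * j] = v[s0 + j];
    }
  }
  return out;
}

// Rolling sum of squares over an L-sample window pooled across channels:
// out[t] = sum_c sum_j V(t+j, c)^2. Maintained by a rolling update with
// periodic exact recomputation to bound floating-point drift.
// [[Rcpp::export]]
NumericVector cpp_rolling_sumsq(const NumericMatrix& V, int L,
                                int recompute_every = 4096) {
  const int T = V.nrow(), N = V.ncol();
  if (T < L) stop("trace shorter than window");
  const int M = T - L + 1;
  std::vector<double> rowsq(T, 0.0);
  for (int c = 0; c < N; ++c) {
    const double* v = &V(0, c);
    for (int t = 0; t < T; ++t) rowsq[t] += v[t] * v[t];
  }
  NumericVector out(M);
  double acc = 0.0;
  for (int j = 0; j < L; ++j) acc += rowsq[j];
  out[0] = acc;
  for (int t = 1; t < M; ++t) {
    if (t % recompute_every == 0) {
      acc = 0.0;
      for (int j = 0; j < L; ++j) acc += rowsq[t + j];
    } else {
      acc += rowsq[t + L - 1] - rowsq[t - 1];
      if (acc < 0) acc = 0;   // guard against cancellation on silent spans
    }
    out[t] = acc;
  }
  return out;
}

// Fixed-threshold down-crossing detector with one tetrode-wide shadow clock.
// A crossing is the first sample strictly below thr[c] following a sample
// at-or-above it, on any channel. shadow is in (possibly fractional) samples;
// an event is accepted only if it is more than `shadow` samples after the
// last accepted event. Returns 1-based sample indices.
// [[Rcpp::export]]
IntegerVector cpp_detect_crossings(const NumericMatrix& V,
                                   const NumericVector& thr,
                                   double shadow) {
  const int T = V.nrow(), N = V.ncol();
  if (thr.size() != N) stop("one threshold per channel required");
  std::vector<int> hits;
  double last = -1e18;
  for (int t = 1; t < T; ++t) {
    if (t - last <= shadow) continue;
    bool cross = false;
    for (int c = 0; c < N; ++c) {
      if (V(t, c) < thr[c] && V(t - 1, c) >= thr[c]) { cross = true; break; }
    }
    if (cross) {
      hits.push_back(t + 1);
      last = t;
    }
  }
  return wrap(hits);
}

// One event per contiguous supra-threshold epoch of a similarity trace,
// placed at the epoch's maximum (earliest sample on ties), then censored by
// a shadow clock measured between accepted peaks. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_epoch_peaks(const NumericVector& S, double alpha,
                              double shadow) {
  const int n = S.size();
  std::vector<int> out;
  double last = -1e18;
  int t = 0;
  while (t < n) {
    if (S[t] >= alpha) {
      int best = t;
      double bv = S[t];
      while (t < n && S[t] >= alpha) {
        if (S[t] > bv) { bv = S[t]; best = t; }
        ++t;
      }
      if (best - last > shadow) {
        out.push_back(best + 1);
        last = best;
      }
    } else {
      ++t;
    }
  }
  return wrap(out);
}

// Negative-peak alignment without materializing clips: for each event
// centre (1-based sample), find the global across-channel minimum within
// the clip window [centre - pre, centre - pre + L). Returns the 1-based
// trough sample, or NA when the trough is not interior to the window or
// the shift exceeds the pre-window.
// [[Rcpp::export]]
IntegerVector cpp_align_events(const NumericMatrix& V,
                               const IntegerVector& centres, int pre, int L) {
  const int T = V.nrow(), N = V.ncol(), n = centres.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const int s0 = centres[i] - 1 - pre;   // 0-based window start
    if (s0 < 0 || s0 + L > T) { out[i] = NA_INTEGER; continue; }
    int jmin = 0;
    double vmin = R_PosInf;
    for (int c = 0; c < N; ++c) {
      const double* v = &V(s0, c);
      for (int j = 0; j < L; ++j) {
        if (v[j] < vmin) { vmin = v[j]; jmin = j; }
      }
    }
    if (jmin == 0 || jmin == L - 1 || std::abs(jmin - pre) > pre)
      out[i] = NA_INTEGER;
    else
      out[i] = s0 + jmin + 1;
  }
  return out;
}

// Add scaled multichannel waveforms into a voltage matrix, in place.
// starts are 1-based row indices of the first waveform sample; spikes whose
// waveform would run off either edge are skipped (returns number inserted).
// [[Rcpp::export]]
int cpp_add_waveforms(NumericMatrix V, const IntegerVector& starts,
                      const NumericVector& amps, const NumericMatrix& W) {
  const int T = V.nrow(), N = V.ncol(), Lw = W.nrow();
  if (W.ncol() != N) stop("waveform and voltage channel counts differ");
  if (starts.size() != amps.size()) stop("starts and amps lengths differ");
  int n_in = 0;
  for (int k = 0; k < starts.size(); ++k) {
    const int s0 = starts[k] - 1;
    if (s0 < 0 || s0 + Lw > T) continue;
    const double a = amps[k];
    for (int c = 0; c < N; ++c) {
      double* v = &V(s0, c);
      const double* w = &W(0, c);
      for (int j = 0; j < Lw; ++j) v[j] += a * w[j];
    }
    ++n_in;
  }
  return n_in;
}
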