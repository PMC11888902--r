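# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package.

naive_quantile <- function(x, p) {
  # linear interpolation between order statistics (type-7 definition)
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

naive_channel_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu,
    sd = sqrt(m2),
    median = naive_quantile(x, 0.5),
    max = max(x), min = min(x), range = max(x) - min(x),
    q1 = naive_quantile(x, 0.25), q3 = naive_quantile(x, 0.75),
    iqr = naive_quantile(x, 0.75) - naive_quantile(x, 0.25),
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

naive_metrics <- function(y, p) {
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp); sens <- div(tp, tp + fn)
  c(accuracy = (tp + tn) / length(y), precision = prec, sensitivity = sens,
    specificity = div(tn, tn + fp),
    f1 = div(2 * prec * sens, prec + sens),
    jaccard = div(tp, tp + fp + fn))
}

naive_kappa <- function(y, p) {
  n <- length(y)
  po <- sum(y == p) / n
  pe <- sum(sapply(0:1, function(k) sum(y == k) * sum(p == k))) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# AUC as the Mann-Whitney rank statistic: pairwise concordance with ties = 1/2
naive_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}

# Amplitude gain of a forward-backward Butterworth filter at frequency f:
# a single pass has |H(f)|^2 = 1/(1 + r^(2n)) with the bilinear-prewarped
# frequency ratio r, and filtfilt applies the magnitude twice, so the
# zero-phase amplitude gain equals |H(f)|^2 itself.
butter_zero_phase_gain <- function(f, cutoff, fs, order, type) {
  warp <- function(freq) tan(pi * freq / fs)
  ratio <- if (type == "high") warp(cutoff) / warp(f) else warp(f) / warp(cutoff)
  1 / (1 + ratio^(2 * order))
}

# rms-based amplitude estimate of a sinusoid, robust to sampling-grid phase
sine_amplitude <- function(x) sqrt(2 * mean(x^2))
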