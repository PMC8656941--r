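# Shared fixtures and independently coded reference implementations used as
# oracles.  Everything here is built in code at test time; the reference
# functions deliberately avoid the package's own computation paths.

# small simulation used by several files: ~20 candidate epochs per subject,
# mirroring the 22-epoch / 8-selected geometry of a 5-min recording at a
# reduced sampling rate and region count
tiny_spec <- function(n_per_group = c(CN = 2L), seed = 1L,
                      artifact_rate = 0.1, drowsy_rate = 0.1, ...) {
  sim_spec(
    n_subjects_per_group = n_per_group, n_regions = 6L,
    fs = 250, duration = 170, epoch_len = 2048L,
    artifact_rate = artifact_rate, drowsy_rate = drowsy_rate, seed = seed, ...
  )
}

select_first_subject <- function(spec) {
  simd <- simulate_sources(spec)
  es <- select_epochs(
    score_epochs(segment_epochs(simd$recordings[[1L]], spec$epoch_len),
                 spec$occipital_idx)
  )
  list(eset = es, truth = simd$truth, rec = simd$recordings[[1L]])
}

# reference relative band power via R's own smoothed periodogram
# (stats::spec.pgram), integrating over band bins -- an independent spectral
# estimate, not the package's periodogram code
ref_band_fractions <- function(x, fs, scheme = band_scheme()) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0, plot = FALSE,
                          detrend = FALSE, demean = FALSE)
  f <- sp$freq
  p <- sp$spec
  pow <- vapply(seq_len(nrow(scheme)), function(b) {
    lo <- scheme$f_lo[b]
    hi <- scheme$f_hi[b]
    inb <- if (b == 1L) f >= lo & f <= hi else f > lo & f <= hi
    sum(p[inb])
  }, numeric(1L))
  setNames(pow / sum(pow), scheme$band)
}

# reference Benjamini-Hochberg step-up scan, coded directly from the
# definition: find the largest k with p_(k) <= k q / m and reject ranks 1..k
ref_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) k <- i
  }
  rej <- logical(m)
  if (k > 0L) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# reference analytic-signal envelope, written independently (loop-free direct
# DFT weighting is the package's path; here we use the convolution form via
# the quadrature filter on the DFT computed with explicit index arithmetic)
ref_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- rep(0, n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[seq(2L, n / 2)] <- 2
  } else {
    h[seq(2L, (n + 1L) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# reference singular values of a cross-correlation matrix via
# eigendecomposition of R'R (independent of svd())
ref_singular_values <- function(R) {
  ev <- eigen(crossprod(R), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

# planted one-component PLSC model: latent variable expressed in both
# blocks through known weight patterns, with controllable latent correlation
planted_blocks <- function(n = 100L, r = 0.7, seed = 1L, p = 4L, q = 3L) {
  set.seed(seed)
  wx <- c(1, -1, rep(0, p - 2L))
  wx <- wx / sqrt(sum(wx^2))
  wy <- c(1, rep(0, q - 1L))
  lat <- rnorm(n)
  X <- matrix(rnorm(n * p), n) * 0.5
  Y <- matrix(rnorm(n * q), n) * 0.5
  X <- X + lat %*% t(wx)
  Y <- Y + (r * lat + sqrt(1 - r^2) * rnorm(n)) %*% t(wy)
  colnames(X) <- paste0("x", seq_len(p))
  colnames(Y) <- paste0("y", seq_len(q))
  list(X = X, Y = Y, wx = wx, wy = wy)
}
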