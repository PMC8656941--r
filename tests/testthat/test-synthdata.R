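test_that("spec validation enforces its invariants", {
  expect_s3_class(sim_spec(), "sim_spec")
  bf <- rbind(CN = c(delta = 0.5, theta = 0.5, alpha1 = 0, alpha2 = 0,
                     beta = 0.2, gamma = 0))
  expect_error(sim_spec(n_subjects_per_group = c(CN = 2L), band_fractions = bf),
               "sum to 1")
  expect_error(sim_spec(fs = 90), "twice the highest")
  expect_error(sim_spec(artifact_rate = 1), "rates")
  expect_error(sim_spec(mixing_strength = 1), "mixing_strength")
  expect_error(
    sim_spec(coupling_pairs = tibble::tibble(i = 1L, j = 1L, strength = 0.5,
                                             band = "beta")),
    "distinct"
  )
})

test_that("generated recordings have the specified shape and are reproducible", {
  spec <- tiny_spec(seed = 3L)
  simd <- simulate_sources(spec)
  expect_length(simd$recordings, 2L)
  r <- simd$recordings[[1L]]
  expect_equal(dim(r$data), c(6L, round(250 * 170)))
  expect_equal(length(r$roi_names), 6L)
  expect_true(all(is.finite(r$data)))

  simd2 <- simulate_sources(tiny_spec(seed = 3L))
  expect_identical(simd$recordings[[1L]]$data, simd2$recordings[[1L]]$data)
  expect_identical(simd$truth$ipf, simd2$truth$ipf)

  simd3 <- simulate_sources(tiny_spec(seed = 4L))
  expect_false(identical(simd$recordings[[1L]]$data, simd3$recordings[[1L]]$data))
})

test_that("too short a recording for eight epochs is rejected", {
  expect_error(
    simulate_sources(sim_spec(n_subjects_per_group = c(CN = 1L), n_regions = 4L,
                              fs = 250, duration = 40, epoch_len = 2048L)),
    "too short"
  )
})

test_that("a single-band spec yields that band's relative power near one", {
  bf <- rbind(CN = c(delta = 0, theta = 0, alpha1 = 1, alpha2 = 0,
                     beta = 0, gamma = 0))
  spec <- sim_spec(
    n_subjects_per_group = c(CN = 1L), n_regions = 4L, fs = 250,
    duration = 70, epoch_len = 2048L, band_fractions = bf,
    band_fraction_sd = 0, artifact_rate = 0, drowsy_rate = 0,
    ipf_mean = c(CN = 9), ipf_sd = c(CN = 0), seed = 2L
  )
  simd <- simulate_sources(spec)
  rb <- relative_band_power(
    periodogram_psd(simd$recordings[[1L]]$data[, 1:4096], 250)
  )
  expect_true(all(rb$rbp[, "alpha1"] > 0.95))
})

test_that("planted band fractions are recovered by an independent spectral estimate", {
  # 20 subjects with theta fraction 0.40; whole-brain theta fraction measured
  # with stats::spec.pgram must sit within +/- 0.03 of the target
  bf <- rbind(CN = c(delta = 0.15, theta = 0.40, alpha1 = 0.10, alpha2 = 0.10,
                     beta = 0.15, gamma = 0.10))
  spec <- sim_spec(
    n_subjects_per_group = c(CN = 20L), n_regions = 4L, fs = 250,
    duration = 70, epoch_len = 2048L, band_fractions = bf,
    band_fraction_sd = 0, artifact_rate = 0, drowsy_rate = 0, seed = 1L
  )
  simd <- simulate_sources(spec)
  theta <- vapply(simd$recordings, function(r) {
    mean(apply(r$data[1:2, ], 1L, ref_band_fractions, fs = 250)["theta", ])
  }, numeric(1L))
  expect_lt(abs(mean(theta) - 0.40), 0.03)
})

test_that("planted envelope correlation matches the closed-form target", {
  strengths <- c(0.3, 0.6, 0.9)
  realized <- vapply(strengths, function(s) {
    spec <- sim_spec(
      n_subjects_per_group = c(CN = 3L), n_regions = 4L, fs = 250,
      duration = 170, epoch_len = 2048L,
      coupling_pairs = tibble::tibble(i = 1L, j = 3L, strength = s,
                                      band = "beta"),
      artifact_rate = 0, drowsy_rate = 0, seed = 10L
    )
    mean(simulate_sources(spec)$truth$coupling$realized_env_cor)
  }, numeric(1L))
  expect_lt(max(abs(realized - strengths)), 0.1)
  expect_true(all(diff(realized) > 0))
})

test_that("cohort generation links cognition to brain features as specified", {
  spec <- tiny_spec(n_per_group = c(CN = 60L), seed = 5L, missing_rate = 0)
  # planted features without simulating signals
  bf <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:60), group = "CN",
    theta_rbp = rnorm(60, 0.15, 0.05), beta_rbp = rnorm(60, 0.25, 0.05),
    alpha1_rbp = rnorm(60, 0.14, 0.04), ipf = rnorm(60, 9, 0.8)
  )
  cohort <- simulate_cohort(spec, bf)
  expect_true(all(!is.na(cohort$MMSE)))
  expect_equal(sum(attr(cohort, "missing_mask")$MMSE), 0L)

  # slope recovery by ordinary least squares: MMSE = a - 60 * theta + noise
  fit <- lm(cohort$MMSE ~ bf$theta_rbp)
  se <- summary(fit)$coefficients[2L, 2L]
  expect_lt(abs(unname(coef(fit)[2L]) - (-60)), 3 * se)

  # null effects give near-zero correlation
  spec0 <- tiny_spec(n_per_group = c(CN = 60L), seed = 6L, missing_rate = 0,
                     cognitive_effects = list(
                       MMSE = list(feature = "theta_rbp", intercept = 28,
                                   slope = 0, sd = 2)
                     ))
  cohort0 <- simulate_cohort(spec0, bf)
  expect_lt(abs(cor(cohort0$MMSE, bf$theta_rbp)), 2 / sqrt(60) + 0.1)

  expect_error(
    simulate_cohort(
      tiny_spec(cognitive_effects = list(
        MMSE = list(feature = "nope", intercept = 0, slope = 1, sd = 1)
      )),
      bf
    ),
    "unknown brain feature"
  )
})

test_that("missingness is inserted at the requested rate with a recorded mask", {
  spec <- tiny_spec(n_per_group = c(CN = 150L), seed = 8L, missing_rate = 0.2)
  bf <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:150), group = "CN",
    theta_rbp = rnorm(150, 0.15, 0.05), beta_rbp = rnorm(150, 0.25, 0.05),
    alpha1_rbp = rnorm(150, 0.14, 0.04), ipf = rnorm(150, 9, 0.8)
  )
  cohort <- simulate_cohort(spec, bf)
  mask <- attr(cohort, "missing_mask")
  expect_lt(abs(mean(mask$MMSE) - 0.2), 0.08)
  expect_identical(is.na(cohort$MMSE), mask$MMSE)
  # CAQ items are integers on the 1-5 scale
  items <- as.matrix(cohort[grep("^caq_", names(cohort))])
  expect_true(all(items[!is.na(items)] %in% 1:5))
})

test_that("forward model projects sources with unit-norm full-rank leads", {
  spec <- sim_spec(n_subjects_per_group = c(CN = 1L), n_regions = 4L, fs = 250,
                   duration = 70, epoch_len = 2048L, seed = 2L)
  simd <- simulate_sources(spec)
  fwd <- simulate_forward(simd$recordings, n_sensors = 10L,
                          sensor_noise_sd = 0, seed = 2L)
  L <- fwd$leads$lead_matrix
  expect_equal(dim(L), c(10L, 4L))
  expect_equal(colSums(L^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(qr(L)$rank, 4L)
  expect_equal(fwd$sensors[[1L]]$data, L %*% simd$recordings[[1L]]$data,
               tolerance = 1e-12)

  fwd2 <- simulate_forward(simd$recordings, n_sensors = 10L,
                           sensor_noise_sd = 0, seed = 2L)
  expect_identical(fwd$leads$lead_matrix, fwd2$leads$lead_matrix)
  expect_error(simulate_forward(simd$recordings, n_sensors = 2L), "must be >=")
})
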