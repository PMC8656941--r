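#' Simulation specification for synthetic resting-state source data
#'
#' Builds the parameter object driving the synthetic-data generators.  The
#' defaults emulate the acquisition and cohort conditions the package is
#' designed for: two groups of 35 cognitively normal (CN) and 11 cognitively
#' impaired (CI) subjects, 80 cortical regions sampled at 1250 Hz for
#' 5 minutes, epoch length 16384 samples, occipital alpha peaks at
#' 9.1 +/- 0.8 Hz (CN) and 8.7 +/- 0.3 Hz (CI), and per-group band power
#' fractions planted so that the CI-CN contrast has a standardized effect of
#' about +1.15 in theta and -1.23 in beta at the default between-subject
#' fraction jitter of 0.05.
#'
#' @param n_subjects_per_group Named integer vector, subjects per group.
#' @param n_regions Number of source regions.
#' @param fs Sampling frequency in Hz.
#' @param duration Recording duration in seconds.
#' @param epoch_len Epoch length in samples (used to place artifact and
#'   drowsiness segments on the epoch grid).
#' @param band_fractions Groups x bands matrix of target relative power
#'   fractions; each row must sum to 1 (+/- 1e-9).
#' @param band_fraction_sd Between-subject standard deviation of the band
#'   fractions (before renormalization).
#' @param ipf_mean,ipf_sd Per-group mean and SD of the individual peak
#'   frequency (Hz).
#' @param occipital_idx Indices of occipital regions (default: the last
#'   `max(2, round(n_regions/10))` regions).
#' @param coupling_pairs Tibble with columns `i`, `j`, `strength` (planted
#'   envelope correlation in `[0, 1]`) and `band`; applied to every subject.
#' @param envelope_depth Lognormal modulation depth (the sigma of
#'   `exp(sigma * g)` with `g` a slow unit Gaussian) of the planted
#'   envelopes; the default 1 gives bursty amplitude dynamics whose
#'   planted correlation dominates leakage-induced envelope noise.
#' @param mixing_strength Instantaneous leakage coefficient `eps` in
#'   `[0, 1)`: data are premultiplied by `I + eps * M` with `M` the
#'   symmetric nearest-neighbour adjacency (zero diagonal).
#' @param artifact_rate,drowsy_rate Per-epoch probabilities of planting a
#'   high-amplitude transient / of halving occipital alpha amplitude.
#' @param cognitive_effects Named list mapping each cognitive variable to
#'   `list(feature =, intercept =, slope =, sd =)` where `feature` names a
#'   column of the planted brain-feature table.
#' @param missing_rate Fraction of cognitive-score cells set missing.
#' @param scheme Band scheme, default [band_scheme()].
#' @param seed Integer seed; all generators are reproducible given the seed.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects_per_group = c(CN = 35L, CI = 11L),
                     n_regions = 80L,
                     fs = 1250,
                     duration = 300,
                     epoch_len = 16384L,
                     band_fractions = NULL,
                     band_fraction_sd = 0.05,
                     ipf_mean = c(CN = 9.1, CI = 8.7),
                     ipf_sd = c(CN = 0.8, CI = 0.3),
                     occipital_idx = NULL,
                     coupling_pairs = NULL,
                     envelope_depth = 1,
                     mixing_strength = 0,
                     artifact_rate = 0.1,
                     drowsy_rate = 0.1,
                     cognitive_effects = NULL,
                     missing_rate = 0.05,
                     scheme = band_scheme(),
                     seed = 1L) {
  groups <- names(n_subjects_per_group) %||% paste0("G", seq_along(n_subjects_per_group))
  if (is.null(band_fractions)) {
    band_fractions <- rbind(
      CN = c(delta = 0.220, theta = 0.1300, alpha1 = 0.140, alpha2 = 0.1300,
             beta = 0.2600, gamma = 0.1200),
      CI = c(delta = 0.230, theta = 0.1875, alpha1 = 0.150, alpha2 = 0.1455,
             beta = 0.1985, gamma = 0.0885)
    )[seq_along(groups), , drop = FALSE]
    rownames(band_fractions) <- groups
  }
  if (is.null(occipital_idx)) {
    n_occ <- max(2L, round(n_regions / 10))
    occipital_idx <- (n_regions - n_occ + 1L):n_regions
  }
  if (is.null(coupling_pairs)) {
    coupling_pairs <- tibble::tibble(
      i = integer(), j = integer(), strength = numeric(), band = character()
    )
  }
  if (is.null(cognitive_effects)) {
    cognitive_effects <- list(
      MMSE = list(feature = "theta_rbp", intercept = 36.1, slope = -60, sd = 1.5),
      CERAD = list(feature = "theta_rbp", intercept = 24.4, slope = -60, sd = 2.5),
      fluency = list(feature = "beta_rbp", intercept = 17.8, slope = 40, sd = 6),
      TMTB = list(feature = "ipf", intercept = 450, slope = -20, sd = 90),
      cCAQ = list(feature = "beta_rbp", intercept = -0.2, slope = 13, sd = 0.4),
      pCAQ = list(feature = "alpha1_rbp", intercept = 0, slope = 18, sd = 0.45)
    )
  }
  spec <- structure(
    list(
      n_subjects_per_group = n_subjects_per_group, groups = groups,
      n_regions = as.integer(n_regions), fs = fs, duration = duration,
      epoch_len = as.integer(epoch_len), band_fractions = band_fractions,
      band_fraction_sd = band_fraction_sd, ipf_mean = ipf_mean, ipf_sd = ipf_sd,
      occipital_idx = as.integer(occipital_idx), coupling_pairs = coupling_pairs,
      envelope_depth = envelope_depth, mixing_strength = mixing_strength,
      artifact_rate = artifact_rate, drowsy_rate = drowsy_rate,
      cognitive_effects = cognitive_effects, missing_rate = missing_rate,
      scheme = scheme, seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
  validate_sim_spec(spec)
}

#' @rdname sim_spec
#' @param spec A `sim_spec` object.
#' @export
validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  validate_band_scheme(spec$scheme)
  bf <- spec$band_fractions
  if (!identical(colnames(bf), spec$scheme$band)) {
    abort("band_fractions columns must match the band scheme, in order")
  }
  if (any(abs(rowSums(bf) - 1) > 1e-9)) {
    abort("each group's band fractions must sum to 1 (+/- 1e-9)")
  }
  if (any(bf < 0)) abort("band fractions must be non-negative")
  if (spec$fs <= 2 * max(spec$scheme$f_hi)) {
    abort("fs must exceed twice the highest band edge")
  }
  rates <- c(spec$artifact_rate, spec$drowsy_rate, spec$missing_rate)
  if (any(rates < 0 | rates >= 1)) abort("rates must lie in [0, 1)")
  if (spec$mixing_strength < 0 || spec$mixing_strength >= 1) {
    abort("mixing_strength must lie in [0, 1)")
  }
  if (any(spec$occipital_idx < 1L | spec$occipital_idx > spec$n_regions)) {
    abort("occipital_idx out of range")
  }
  cp <- spec$coupling_pairs
  if (nrow(cp)) {
    stopifnot(all(c("i", "j", "strength", "band") %in% names(cp)))
    if (any(cp$i == cp$j)) abort("coupling pairs must join distinct regions")
    if (any(!cp$band %in% spec$scheme$band)) abort("coupling pair in unknown band")
    if (any(cp$strength < 0 | cp$strength > 1)) abort("coupling strength must be in [0, 1]")
  }
  invisible(spec)
}

# slow positive envelope pair with planted correlation `strength`:
# correlated Gaussian knot processes at `rate` Hz, linearly interpolated and
# exponentiated (lognormal squash to positivity).  For lognormal envelopes
# corr(E1, E2) = (exp(rho s^2) - 1) / (exp(s^2) - 1) in closed form, so the
# Gaussian correlation rho is chosen to plant exactly the requested
# envelope correlation.
slow_envelope_pair <- function(nT, fs, strength, depth, rate = 4) {
  n_knots <- max(4L, ceiling(nT / fs * rate) + 2L)
  t_knots <- seq(0, nT - 1L, length.out = n_knots)
  rho <- if (depth > 0) log1p(strength * expm1(depth^2)) / depth^2 else strength
  g1 <- rnorm(n_knots)
  g2 <- rho * g1 + sqrt(pmax(1 - rho^2, 0)) * rnorm(n_knots)
  interp <- function(g) {
    exp(depth * approx(t_knots, g, xout = 0:(nT - 1L))$y)
  }
  list(e1 = interp(g1), e2 = interp(g2))
}

slow_envelope <- function(nT, fs, depth, rate = 4) {
  slow_envelope_pair(nT, fs, 0, depth, rate)$e1
}

# band-limited noise whose energy stays strictly inside [f_lo, f_hi] with a
# small guard margin at the edges, so planted power fractions and envelopes
# are recoverable by analysis filters without cross-band blur
inband_noise <- function(n_rows, nT, f_lo, f_hi, fs) {
  g <- min(0.5, (f_hi - f_lo) / 6)
  lo <- f_lo + g
  hi <- f_hi - g
  twb <- min(1, (hi - lo) / 3)
  unit_sd_rows(bandpass_fir(
    matrix(rnorm(n_rows * nT), n_rows, nT),
    lo + twb / 2, hi - twb / 2, fs,
    tw = twb
  ))
}

# constant-envelope in-band carrier: unit-variance sinusoid at a random
# frequency inside the band (away from the edges), random phase
inband_carrier <- function(nT, fs, f_lo, f_hi, avoid = numeric()) {
  pad <- 0.15 * (f_hi - f_lo)
  repeat {
    f <- runif(1L, f_lo + pad, f_hi - pad)
    if (!length(avoid) || min(abs(f - avoid)) >= 0.1) break
  }
  list(x = sqrt(2) * sin(2 * pi * f * (0:(nT - 1L)) / fs + runif(1L, 0, 2 * pi)), f = f)
}

unit_sd_rows <- function(m) {
  s <- sqrt(rowMeans(m^2) - rowMeans(m)^2)
  s[s == 0] <- 1
  m / s
}

#' Generate synthetic source-space recordings with planted ground truth
#'
#' Each region's signal is a sum of band-limited components (white noise
#' passed through the same least-squares FIR band-pass used by the
#' connectivity module) whose expected power fractions follow the
#' subject's planted band fractions.  Occipital regions carry a narrow-band
#' oscillation at the subject's planted peak frequency in place of the
#' broadband component of the band containing it.  Coupled region pairs
#' share correlated slow amplitude envelopes riding on constant-envelope
#' in-band carriers, so the planted envelope correlation is recoverable.
#' Artifact epochs receive a +/- 8 robust-SD half-sine transient of 100 ms;
#' drowsy epochs have the occipital oscillation halved in amplitude.
#' Optionally, an instantaneous symmetric nearest-neighbour mixing operator
#' `I + eps * M` emulates source leakage.
#'
#' @param spec A [sim_spec()] object.
#' @return List with `recordings` (list of `meg_recording`: `subject_id`,
#'   `fs`, `roi_names`, `data` regions x samples) and `truth`, a list
#'   recording everything planted: per-subject band fractions, group,
#'   peak frequencies, realized envelope correlations of the coupled pairs,
#'   artifact / drowsy / clean epoch indices, and the epoch grid used.
#' @export
simulate_sources <- function(spec) {
  validate_sim_spec(spec)
  set.seed(fan_seed(spec$seed, "simulate"))
  nT <- round(spec$fs * spec$duration)
  if (nT < 8L * spec$epoch_len) {
    abort("duration too short to hold 8 epochs of the configured length")
  }
  R <- spec$n_regions
  n_ep <- floor(nT / spec$epoch_len)
  groups <- rep(spec$groups, spec$n_subjects_per_group)
  n_sub <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_sub))
  bands <- spec$scheme$band

  mix <- NULL
  if (spec$mixing_strength > 0 && R > 1L) {
    M <- matrix(0, R, R)
    # symmetric nearest-neighbour mixing, rows normalized so eps is the
    # total leaked amplitude fraction per region
    nb <- cbind(seq_len(R - 1L), 2:R)
    M[nb] <- 0.5
    M[nb[, 2:1, drop = FALSE]] <- 0.5
    mix <- diag(R) + spec$mixing_strength * M
  }

  recordings <- vector("list", n_sub)
  frac_planted <- matrix(NA_real_, n_sub, length(bands), dimnames = list(ids, bands))
  ipf_planted <- numeric(n_sub)
  artifact_epochs <- drowsy_epochs <- vector("list", n_sub)
  coupling_truth <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    g <- groups[s]
    frac <- spec$band_fractions[g, ]
    if (spec$band_fraction_sd > 0) {
      frac <- pmax(frac + rnorm(length(frac), 0, spec$band_fraction_sd), 0)
      frac <- frac / sum(frac)
    }
    frac_planted[s, ] <- frac
    ipf <- min(max(rnorm(1L, spec$ipf_mean[g], spec$ipf_sd[g]), 5), 12.5)
    ipf_planted[s] <- ipf
    ipf_band <- which(spec$scheme$f_lo < ipf & ipf <= spec$scheme$f_hi)

    data <- matrix(0, R, nT)
    n_occ <- length(spec$occipital_idx)
    # occipital alpha-range content (the peak-frequency oscillation plus the
    # broadband alpha1 occipital component) is kept aside so drowsiness can
    # suppress it epoch-wise
    occ_alpha <- matrix(0, n_occ, nT)
    cp <- spec$coupling_pairs
    cp_env <- if (nrow(cp)) numeric(nrow(cp)) else numeric()
    cp_envelopes <- vector("list", nrow(cp))

    for (b in seq_along(bands)) {
      if (frac[b] <= 0) next
      f_lo <- spec$scheme$f_lo[b]
      f_hi <- spec$scheme$f_hi[b]
      comp <- inband_noise(R, nT, f_lo, f_hi, spec$fs)
      # occipital regions: amplitude-modulated oscillation at exactly the
      # planted peak frequency replaces the broadband component of its band
      if (b == ipf_band) {
        tt <- (0:(nT - 1L)) / spec$fs
        # shallow modulation keeps the oscillator's sidebands inside its band
        osc <- t(vapply(spec$occipital_idx, function(r) {
          e <- slow_envelope(nT, spec$fs, min(spec$envelope_depth, 0.3))
          e * sqrt(2) * sin(2 * pi * ipf * tt + runif(1L, 0, 2 * pi))
        }, numeric(nT)))
        occ_alpha <- occ_alpha + sqrt(frac[b]) * unit_sd_rows(osc)
        comp[spec$occipital_idx, ] <- 0
      } else if (bands[b] == "alpha1") {
        occ_alpha <- occ_alpha +
          sqrt(frac[b]) * comp[spec$occipital_idx, , drop = FALSE]
        comp[spec$occipital_idx, ] <- 0
      }
      # planted envelope coupling overrides this band's component for the pair
      if (nrow(cp)) {
        for (k in which(cp$band == bands[b])) {
          env <- slow_envelope_pair(nT, spec$fs, cp$strength[k], spec$envelope_depth)
          c1 <- inband_carrier(nT, spec$fs, f_lo, f_hi)
          c2 <- inband_carrier(nT, spec$fs, f_lo, f_hi, avoid = c1$f)
          m1 <- env$e1 * c1$x
          m2 <- env$e2 * c2$x
          comp[cp$i[k], ] <- m1 / sd(m1)
          comp[cp$j[k], ] <- m2 / sd(m2)
          cp_env[k] <- cor(env$e1, env$e2)
          cp_envelopes[[k]] <- env
        }
      }
      data <- data + sqrt(frac[b]) * comp
    }

    # drowsiness: halve the occipital alpha amplitude epoch-wise
    drowsy <- which(runif(n_ep) < spec$drowsy_rate)
    if (any(occ_alpha != 0)) {
      gain <- rep(1, nT)
      for (e in drowsy) {
        gain[((e - 1L) * spec$epoch_len + 1L):(e * spec$epoch_len)] <- 0.5
      }
      data[spec$occipital_idx, ] <- data[spec$occipital_idx, ] +
        occ_alpha * rep(gain, each = n_occ)
    } else {
      drowsy <- integer()
    }

    # artifacts: one +/- 8 robust-SD half-sine transient of 100 ms
    artifact <- which(runif(n_ep) < spec$artifact_rate)
    pulse_len <- max(4L, round(0.1 * spec$fs))
    pulse <- sin(pi * seq_len(pulse_len) / (pulse_len + 1L))
    for (e in artifact) {
      r <- sample.int(R, 1L)
      pos <- (e - 1L) * spec$epoch_len +
        sample.int(spec$epoch_len - pulse_len, 1L)
      amp <- 8 * sd(data[r, ]) * sample(c(-1, 1), 1L)
      data[r, pos:(pos + pulse_len - 1L)] <- data[r, pos:(pos + pulse_len - 1L)] + amp * pulse
    }

    if (!is.null(mix)) data <- mix %*% data

    artifact_epochs[[s]] <- artifact
    drowsy_epochs[[s]] <- drowsy
    coupling_truth[[s]] <- if (nrow(cp)) {
      dplyr::mutate(cp,
        realized_env_cor = cp_env, subject_id = ids[s],
        envelopes = cp_envelopes
      )
    }
    recordings[[s]] <- structure(
      list(
        subject_id = ids[s], fs = spec$fs,
        roi_names = sprintf("R%03d", seq_len(R)), data = data
      ),
      class = "meg_recording"
    )
  }

  clean <- purrr::map2(artifact_epochs, drowsy_epochs, function(a, d) {
    setdiff(seq_len(n_ep), union(a, d))
  })
  truth <- list(
    subject_id = ids, group = groups,
    band_fractions = frac_planted,
    group_fractions = spec$band_fractions,
    ipf = setNames(ipf_planted, ids),
    coupling = dplyr::bind_rows(coupling_truth),
    artifact_epochs = setNames(artifact_epochs, ids),
    drowsy_epochs = setNames(drowsy_epochs, ids),
    clean_epochs = setNames(clean, ids),
    n_candidate_epochs = n_ep, epoch_len = spec$epoch_len,
    occipital_idx = spec$occipital_idx, seed = spec$seed
  )
  list(recordings = recordings, truth = truth)
}

#' Planted brain-feature table from simulation truth
#'
#' One row per subject: planted whole-brain band fractions (as `<band>_rbp`)
#' and planted peak frequency, the generative features the synthetic
#' cognitive scores depend on.
#'
#' @param truth The `truth` element returned by [simulate_sources()].
#' @return Tibble with `subject_id`, `group`, `<band>_rbp` columns, `ipf`.
#' @export
truth_feature_table <- function(truth) {
  out <- tibble::as_tibble(truth$band_fractions, .name_repair = "minimal")
  names(out) <- paste0(colnames(truth$band_fractions), "_rbp")
  dplyr::bind_cols(
    tibble::tibble(subject_id = truth$subject_id, group = truth$group),
    out,
    tibble::tibble(ipf = unname(truth$ipf))
  )
}

#' Generate a synthetic cohort table tied to brain features
#'
#' Cognitive scores are linear in named brain features plus Gaussian noise
#' according to `spec$cognitive_effects`; demographics (age, gender,
#' education) are drawn per group; cognitive-activity questionnaire (CAQ)
#' responses are integers 1--5 for each of six activities at ages 6, 12, 18,
#' 40 and current, generated around latent current/past activity levels; the
#' composite cCAQ/pCAQ columns are computed from the item grid with
#' [caq_scores()].  Missing entries are inserted at `spec$missing_rate` into
#' the cognitive scores and CAQ items, with the mask recorded.
#'
#' @param spec A [sim_spec()] object.
#' @param brain_features Tibble with `subject_id`, `group` and the feature
#'   columns named by `spec$cognitive_effects` (e.g. from
#'   [truth_feature_table()] or [spectral_feature_table()]).
#' @return A tibble of class `meg_cohort` with attribute `missing_mask` (a
#'   logical tibble aligned to the data columns) and attribute `caq_ages`.
#' @export
simulate_cohort <- function(spec, brain_features) {
  validate_sim_spec(spec)
  set.seed(fan_seed(spec$seed, "cohort"))
  n <- nrow(brain_features)
  stopifnot(n >= 1L, "subject_id" %in% names(brain_features))
  eff <- spec$cognitive_effects
  feats <- vapply(eff, `[[`, character(1L), "feature")
  missing_feats <- setdiff(feats, names(brain_features))
  if (length(missing_feats)) {
    abort(paste0(
      "cognitive_effects name unknown brain features: ",
      paste(missing_feats, collapse = ", ")
    ))
  }
  grp <- brain_features$group
  age_mean <- setNames(c(92.2, 90.9), spec$groups[1:2])[grp]
  age_sd <- setNames(c(1.8, 1.9), spec$groups[1:2])[grp]
  p_female <- setNames(c(19 / 35, 1 / 11), spec$groups[1:2])[grp]
  age_mean[is.na(age_mean)] <- 91.9
  age_sd[is.na(age_sd)] <- 1.9
  p_female[is.na(p_female)] <- 0.5

  out <- tibble::tibble(
    subject_id = brain_features$subject_id,
    group = grp,
    age = round(rnorm(n, age_mean, age_sd), 1L),
    gender = ifelse(rbinom(n, 1L, p_female) == 1L, "F", "M")
  )
  latent <- list()
  for (v in names(eff)) {
    e <- eff[[v]]
    val <- e$intercept + e$slope * brain_features[[e$feature]] + rnorm(n, 0, e$sd)
    if (v %in% c("cCAQ", "pCAQ")) latent[[v]] <- val else out[[v]] <- round(val, 1L)
  }
  lat_c <- latent[["cCAQ"]] %||% rnorm(n, 3, 0.6)
  lat_p <- latent[["pCAQ"]] %||% rnorm(n, 2.6, 0.6)
  out$education <- pmin(pmax(round(6 + 1.6 * lat_p + rnorm(n, 0, 2)), 4L), 20L)

  caq_ages <- c(6L, 12L, 18L, 40L)
  n_act <- 6L
  for (a in seq_len(n_act)) {
    for (ag in caq_ages) {
      out[[sprintf("caq_p%02d_a%d", ag, a)]] <-
        pmin(pmax(round(lat_p + rnorm(n, 0, 0.6)), 1L), 5L)
    }
    out[[sprintf("caq_cur_a%d", a)]] <-
      pmin(pmax(round(lat_c + rnorm(n, 0, 0.6)), 1L), 5L)
  }

  maskable <- setdiff(
    names(out), c("subject_id", "group", "age", "gender", "education")
  )
  mask <- matrix(FALSE, n, ncol(out), dimnames = list(NULL, names(out)))
  if (spec$missing_rate > 0) {
    for (v in maskable) {
      miss <- runif(n) < spec$missing_rate
      out[[v]][miss] <- NA
      mask[, v] <- miss
    }
  }

  # composite CAQ scores from the (possibly incomplete) item grid
  caq <- caq_scores(out)
  out$cCAQ <- caq$cCAQ
  out$pCAQ <- caq$pCAQ
  mask <- cbind(mask, cCAQ = is.na(out$cCAQ), pCAQ = is.na(out$pCAQ))

  structure(
    out,
    missing_mask = tibble::as_tibble(mask),
    caq_ages = caq_ages,
    class = c("meg_cohort", class(out))
  )
}

#' Generate a synthetic forward model and sensor recordings
#'
#' Draws a pseudo-random lead-field matrix (sensors x regions) with
#' unit-normalized, full-rank columns and projects each source recording to
#' sensor space, adding white sensor noise.
#'
#' @param recordings List of `meg_recording` objects (source space).
#' @param n_sensors Number of sensors; must be at least the region count.
#' @param sensor_noise_sd White sensor-noise standard deviation.
#' @param seed Integer seed.
#' @return List with `leads` (class `meg_leadfield`: `lead_matrix`,
#'   `sensor_noise_sd`) and `sensors`, a list of sensor-space recordings
#'   (class `meg_recording` with channel names `C...`).
#' @export
simulate_forward <- function(recordings, n_sensors, sensor_noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(length(recordings) >= 1L)
  R <- nrow(recordings[[1L]]$data)
  if (n_sensors < R) abort("n_sensors must be >= number of regions")
  set.seed(fan_seed(seed, "forward"))
  for (try in 1:20) {
    L <- matrix(rnorm(n_sensors * R), n_sensors, R)
    L <- sweep(L, 2L, sqrt(colSums(L^2)), "/")
    if (qr(L)$rank == R) break
    if (try == 20L) abort("could not generate a full-rank lead field")
  }
  leads <- structure(
    list(lead_matrix = L, sensor_noise_sd = sensor_noise_sd),
    class = "meg_leadfield"
  )
  sensors <- lapply(recordings, function(rec) {
    y <- L %*% rec$data
    if (sensor_noise_sd > 0) {
      y <- y + matrix(rnorm(length(y), 0, sensor_noise_sd), nrow(y), ncol(y))
    }
    structure(
      list(
        subject_id = rec$subject_id, fs = rec$fs,
        roi_names = sprintf("C%03d", seq_len(n_sensors)), data = y
      ),
      class = "meg_recording"
    )
  })
  list(leads = leads, sensors = sensors)
}
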