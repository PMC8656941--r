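#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  Either a simulation
#' spec (synthetic study) or paths to existing recordings may drive the
#' data stage; all downstream stages are shared.
#'
#' @param sim A [sim_spec()] for synthetic input, or `NULL` to read
#'   recordings from `input_dir`.
#' @param input_dir Directory of recording containers (see
#'   [write_recording()]); ignored when `sim` is given.
#' @param cohort_path Cohort CSV path, or `NULL` to simulate the cohort.
#' @param parcellation Optional tibble of regions x network label counts
#'   for [rsn_majority_vote()] (or `NULL` to skip RSN aggregation).
#' @param use_beamformer Simulate a forward model, project to sensors and
#'   reconstruct sources before epoching (synthetic input only).
#' @param n_sensors,sensor_noise_sd Forward-model settings when
#'   `use_beamformer` is `TRUE`.
#' @param epoch_len,n_epochs Epoch length (samples) and number of selected
#'   epochs per subject.
#' @param connectivity_bands Bands for which AECc matrices are computed.
#' @param covariates Covariate columns for the group comparisons.
#' @param q FDR level.
#' @param n_perm,n_boot,z_thresh,k_impute PLSC settings.
#' @param seed Master seed; fanned out to per-stage streams.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_spec(),
                            input_dir = NULL,
                            cohort_path = NULL,
                            parcellation = NULL,
                            use_beamformer = FALSE,
                            n_sensors = 120L,
                            sensor_noise_sd = 0.1,
                            epoch_len = NULL,
                            n_epochs = 8L,
                            connectivity_bands = c("alpha2", "beta"),
                            covariates = c("age", "gender"),
                            q = 0.05,
                            n_perm = 1000L,
                            n_boot = 500L,
                            z_thresh = 3,
                            k_impute = 4L,
                            seed = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    abort("either a simulation spec or an input directory is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(paste0("input directory not found: ", input_dir))
  }
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    abort(paste0("cohort file not found: ", cohort_path))
  }
  epoch_len <- epoch_len %||% (if (!is.null(sim)) sim$epoch_len else 16384L)
  structure(
    list(
      sim = sim, input_dir = input_dir, cohort_path = cohort_path,
      parcellation = parcellation, use_beamformer = use_beamformer,
      n_sensors = n_sensors, sensor_noise_sd = sensor_noise_sd,
      epoch_len = as.integer(epoch_len), n_epochs = as.integer(n_epochs),
      connectivity_bands = connectivity_bands, covariates = covariates,
      q = q, n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
      z_thresh = z_thresh, k_impute = as.integer(k_impute),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the end-to-end resting-state analysis
#'
#' Executes the stages in order: data (simulate or load), optional
#' beamforming, epoch segmentation/scoring/selection, spectral profiling,
#' band-wise AECc connectivity, covariate-adjusted group statistics with
#' FDR and optional RSN aggregation, cognitive Spearman grid, and PLSC of
#' brain features against cognitive variables with permutation and
#' bootstrap inference.  Subjects whose recordings do not yield the
#' required number of clean epochs are excluded and logged.  Identical
#' config and seed give an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `results_bundle`: `spectral_features`,
#'   `profiles`, `connectivity` (per band: matrices and summary tibble),
#'   `group_tests`, `rsn_contribution` (or `NULL`), `spearman`, `plsc`,
#'   `cohort`, `excluded_subjects`, `truth` (synthetic runs) and a
#'   `manifest` (config hash, seed, package version) sufficient to
#'   reproduce the bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL

  # --- data stage ---------------------------------------------------------
  if (!is.null(config$sim)) {
    simd <- simulate_sources(config$sim)
    recordings <- simd$recordings
    truth <- simd$truth
  } else {
    stems <- unique(sub("\\.(csv|json)$", "",
                        list.files(config$input_dir, pattern = "\\.json$",
                                   full.names = TRUE)))
    if (!length(stems)) abort("no recording containers in input directory")
    recordings <- lapply(stems, read_recording)
  }
  occ <- if (!is.null(truth)) truth$occipital_idx else {
    n <- nrow(recordings[[1L]]$data)
    (n - max(2L, round(n / 10)) + 1L):n
  }

  # --- optional beamforming round trip ------------------------------------
  if (isTRUE(config$use_beamformer)) {
    fwd <- simulate_forward(recordings, config$n_sensors,
                            config$sensor_noise_sd,
                            seed = fan_seed(config$seed, "beamform"))
    recordings <- lapply(fwd$sensors, function(sr) {
      w <- beamformer_weights(sr, fwd$leads)
      reconstruct_sources(sr, w)
    })
  }

  # --- epoching + spectral -------------------------------------------------
  excluded <- character()
  esets <- list()
  for (rec in recordings) {
    es <- tryCatch(
      select_epochs(
        score_epochs(segment_epochs(rec, config$epoch_len), occ),
        config$n_epochs
      ),
      restmeg_subject_exclusion = function(e) {
        excluded <<- c(excluded, rec$subject_id)
        NULL
      }
    )
    if (!is.null(es)) esets[[es$subject_id]] <- es
  }
  if (!length(esets)) abort("pipeline aborted at stage 'epochs': no subject survived")
  profiles <- lapply(esets, spectral_profile, occipital_idx = occ)
  feats <- spectral_feature_table(profiles)

  # --- connectivity --------------------------------------------------------
  connectivity <- list()
  for (b in config$connectivity_bands) {
    mats <- lapply(esets, connectivity_matrix, band = b)
    summ <- purrr::imap_dfr(mats, function(m, id) {
      s <- connectivity_summary(m)
      tibble::tibble(subject_id = id, band = b, whole_brain = s$whole_brain)
    })
    connectivity[[b]] <- list(matrices = mats, summary = summ)
    feats[[paste0("aecc_", b)]] <- summ$whole_brain[match(feats$subject_id,
                                                          summ$subject_id)]
  }

  # --- cohort --------------------------------------------------------------
  if (!is.null(config$cohort_path)) {
    cohort <- read_cohort(config$cohort_path)
  } else if (!is.null(config$sim)) {
    bf <- truth_feature_table(truth)
    cohort <- simulate_cohort(config$sim, bf)
  } else {
    abort("no cohort source: give cohort_path or a simulation spec")
  }
  cohort <- cohort[cohort$subject_id %in% feats$subject_id, ]
  tab <- dplyr::left_join(feats, cohort, by = "subject_id")

  # --- group statistics ----------------------------------------------------
  rbp_cols <- grep("_rbp$", names(feats), value = TRUE)
  test_cols <- c(rbp_cols, "ipf", grep("^aecc_", names(feats), value = TRUE))
  group_tests <- group_compare(tab, test_cols, "group", config$covariates,
                               q = config$q)

  rsn_contribution <- NULL
  if (!is.null(config$parcellation)) {
    map <- rsn_majority_vote(config$parcellation)
    roi_tests <- roi_group_compare(profiles, tab, "theta", "group",
                                   config$covariates, q = config$q)
    rsn_contribution <- rsn_effect_contribution(
      roi_tests$cohens_d, roi_tests$significant, map
    )
  }

  # --- cognitive associations ---------------------------------------------
  cog_vars <- intersect(
    c("MMSE", "fluency", "TMTB", "CERAD", "cCAQ", "pCAQ", "education", "age"),
    names(tab)
  )
  spearman <- spearman_grid(tab, cog_vars, q = config$q)

  # --- PLSC ----------------------------------------------------------------
  x_cols <- c(rbp_cols, "ipf")
  yblk <- impute_knn(tab[cog_vars], k = config$k_impute)
  fit <- plsc(tab[x_cols], yblk)
  fit <- plsc_permutation(fit, config$n_perm, config$q,
                          seed = fan_seed(config$seed, "plsc_perm"))
  fit <- plsc_bootstrap(fit, config$n_boot, config$z_thresh,
                        seed = fan_seed(config$seed, "plsc_boot"))

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("restmeg")),
    n_subjects = nrow(feats),
    excluded_subjects = excluded
  )
  structure(
    list(
      spectral_features = feats, profiles = profiles,
      connectivity = connectivity, group_tests = group_tests,
      rsn_contribution = rsn_contribution, spearman = spearman,
      plsc = fit, cohort = cohort, excluded_subjects = excluded,
      truth = truth, manifest = manifest
    ),
    class = "results_bundle"
  )
}

#' Region-wise group comparison of relative band power
#'
#' ANCOVA per region for one band's RBP, FDR-controlled over regions.
#'
#' @param profiles List of `meg_spectral` objects.
#' @param cohort Data frame with `subject_id`, the group column and
#'   covariates.
#' @param band Band name.
#' @param group,covariates,q As in [group_compare()].
#' @return Tibble with one row per region (`feature` = ROI name).
#' @export
roi_group_compare <- function(profiles, cohort, band, group,
                              covariates = c("age", "gender"), q = 0.05) {
  roi_names <- profiles[[1L]]$roi_names
  vals <- vapply(profiles, function(p) p$rbp[, band], numeric(length(roi_names)))
  df <- tibble::as_tibble(t(vals), .name_repair = "minimal")
  names(df) <- roi_names
  df$subject_id <- vapply(profiles, `[[`, character(1L), "subject_id")
  df <- dplyr::left_join(df, cohort, by = "subject_id")
  group_compare(df, roi_names, group, covariates, q = q)
}

#' Write a results bundle to disk
#'
#' Persists every tabular result as CSV, the PLSC scalars as JSON and the
#' manifest (config hash, seed, package version) as JSON, into `dir`.
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$spectral_features,
                   file.path(dir, "spectral_features.csv"), row.names = FALSE)
  utils::write.csv(bundle$group_tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  for (b in names(bundle$connectivity)) {
    utils::write.csv(bundle$connectivity[[b]]$summary,
                     file.path(dir, paste0("connectivity_", b, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$rsn_contribution)) {
    utils::write.csv(bundle$rsn_contribution,
                     file.path(dir, "rsn_contribution.csv"), row.names = FALSE)
  }
  utils::write.csv(tidy(bundle$plsc), file.path(dir, "plsc_loadings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(bundle$manifest, list(
      plsc_perm_p = bundle$plsc$perm_p,
      plsc_r_squared = bundle$plsc$r_squared
    )),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
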