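sim_cohort_df <- function(n1 = 35L, n2 = 11L, shift = 0, seed = 1L) {
  set.seed(seed)
  n <- n1 + n2
  tibble::tibble(
    group = rep(c("CN", "CI"), c(n1, n2)),
    age = rnorm(n, 92, 2),
    gender = sample(c("F", "M"), n, replace = TRUE),
    y = rnorm(n) + 0.05 * (age - 92) + shift * (group == "CI")
  )
}

test_that("the nested-model F equals the squared t of the group coefficient", {
  for (seed in 1:5) {
    df <- sim_cohort_df(shift = 0.8, seed = seed)
    res <- ancova_group_test(df, "y", "group", c("age", "gender"))
    fit <- lm(y ~ group + age + gender, data = df)
    tval <- summary(fit)$coefficients["groupCN", "t value"]
    expect_equal(res$F, tval^2, tolerance = 1e-10)
    expect_equal(res$df1, 1L)
    expect_equal(res$df2, 46L - 3L - 1L)
  }
})

test_that("collinear designs raise a rank-deficiency error", {
  df <- sim_cohort_df()
  df$dup <- as.integer(df$group == "CI")
  expect_error(ancova_group_test(df, "y", "group", c("age", "dup")),
               "rank-deficient")
})

test_that("Monte-Carlo power matches the noncentral-F approximation", {
  n1 <- 35L
  n2 <- 11L
  shift <- 1
  set.seed(99)
  rej <- replicate(300, {
    df <- sim_cohort_df(shift = shift, seed = sample.int(1e6, 1))
    ancova_group_test(df, "y", "group", c("age", "gender"))$p < 0.05
  })
  lambda <- shift^2 * n1 * n2 / (n1 + n2)
  power <- 1 - pf(qf(0.95, 1, 42), 1, 42, ncp = lambda)
  expect_lt(abs(mean(rej) - power), 3 * sqrt(power * (1 - power) / 300) + 0.01)
})

test_that("Cohen's d on residuals matches the pooled-SD formula by hand", {
  # groups {1,1,1,2} vs {0,0,0,1}: hand pooled SD and mean difference
  df <- tibble::tibble(
    group = rep(c("A", "B"), each = 4L),
    y = c(1, 1, 1, 2, 0, 0, 0, 1)
  )
  d <- cohens_d_residual(df, "y", "group")
  res <- df$y - mean(df$y)
  a <- res[1:4]
  b <- res[5:8]
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(d, 1 / sqrt(0.25), tolerance = 1e-12) # means 1.25 vs 0.25, sp = 0.5

  dfz <- tibble::tibble(group = rep(c("A", "B"), each = 3L), y = rep(1, 6))
  expect_error(cohens_d_residual(dfz, "y", "group"), "zero pooled")

  # identical residual distributions give d = 0
  dfe <- tibble::tibble(group = rep(c("A", "B"), each = 3L),
                        y = rep(c(1, 2, 3), 2L))
  expect_equal(cohens_d_residual(dfe, "y", "group"), 0, tolerance = 1e-12)
})

test_that("BH step-up matches the independent scan and the worked example", {
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_true(bh_fdr(0.01, q = 0.05)$reject)

  p20 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205, 0.212,
           0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.41, 0.57, 0.60, 0.74,
           0.80)
  got <- bh_fdr(p20, q = 0.05)
  expect_identical(got$reject, ref_bh_reject(p20, 0.05))
  # only p(1) = 0.001 <= 1 * 0.05 / 20; p(2) = 0.008 > 2 * 0.05 / 20 and no
  # later rank catches up, so the step-up rejects exactly one hypothesis
  expect_equal(sum(got$reject), 1L)
  expect_equal(got$p_adj, p.adjust(p20, "BH"), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1L))
    expect_identical(bh_fdr(p, 0.05)$reject, ref_bh_reject(p, 0.05))
  }
  expect_error(bh_fdr(numeric()), "empty")
})

test_that("feature-wise comparison controls FDR across features", {
  set.seed(5)
  df <- sim_cohort_df(shift = 2)
  df$y2 <- rnorm(46)
  df$y3 <- df$y + rnorm(46, 0, 0.3)
  res <- group_compare(df, c("y", "y2", "y3"), "group", c("age", "gender"))
  expect_equal(nrow(res), 3L)
  expect_identical(res$significant, ref_bh_reject(res$p, 0.05))
})

test_that("Spearman grid honours monotone invariance, reversals and midranks", {
  df <- tibble::tibble(
    x = c(1, 2, 3, 4, 5, 6),
    y = exp(c(1, 2, 3, 4, 5, 6)), # monotone transform
    z = c(6, 5, 4, 3, 2, 1),
    w = c(1, 1, 2, 3, 4, 5) # tie -> midranks
  )
  g <- spearman_grid(df)
  expect_equal(g$rho["x", "y"], 1, tolerance = 1e-12)
  expect_equal(g$rho["x", "z"], -1, tolerance = 1e-12)
  # midrank oracle: Pearson correlation of average ranks
  expect_equal(g$rho["x", "w"],
               cor(rank(df$x), rank(df$w)), tolerance = 1e-12)
  expect_equal(g$p["x", "y"], 0)
  expect_true(isSymmetric(g$rho))

  # pairwise deletion and the minimum-pairs rule
  df$v <- c(1, 2, NA, NA, NA, 4)
  g2 <- spearman_grid(df, min_pairs = 4L)
  expect_true(is.na(g2$rho["x", "v"]))
  expect_equal(g2$n["x", "v"], 3)

  dfc <- tibble::tibble(a = 1:5, b = rep(2, 5))
  expect_warning(spearman_grid(dfc), "constant")
})

test_that("majority voting assigns networks with the documented tie-break", {
  counts <- rbind(
    r1 = c(VIS = 10, SM = 0, DA = 0, VA = 0, FP = 10, DMN = 90, LIM = 0),
    r2 = c(VIS = 50, SM = 50, DA = 0, VA = 0, FP = 0, DMN = 0, LIM = 0)
  )
  map <- rsn_majority_vote(counts)
  expect_equal(as.character(map$network), c("DMN", "VIS"))
  expect_equal(map$tie, c(FALSE, TRUE))
  expect_error(rsn_majority_vote(rbind(c(VIS = 0, SM = 0))), "all-zero")

  # random tables match a brute-force argmax oracle
  set.seed(2)
  for (i in 1:20) {
    cnt <- matrix(rpois(5 * 7, 3), 5, 7,
                  dimnames = list(NULL, c("VIS", "SM", "DA", "VA", "FP",
                                          "DMN", "LIM")))
    cnt[cnt == 0] <- 1
    m <- rsn_majority_vote(cnt)
    oracle <- apply(cnt, 1L, function(r) colnames(cnt)[which.max(r)])
    expect_equal(as.character(m$network), unname(oracle))
  }
})

test_that("network effect contributions normalize to 100 percent", {
  map <- rsn_majority_vote(rbind(
    r1 = c(VIS = 1, SM = 0, DA = 0, VA = 0, FP = 0, DMN = 9, LIM = 0),
    r2 = c(VIS = 1, SM = 0, DA = 0, VA = 0, FP = 0, DMN = 9, LIM = 0),
    r3 = c(VIS = 9, SM = 0, DA = 0, VA = 0, FP = 0, DMN = 1, LIM = 0)
  ))
  # DMN |d| sum 3, VIS |d| sum 1 -> 75 / 25
  ctr <- rsn_effect_contribution(c(1.5, -1.5, 1), rep(TRUE, 3), map)
  expect_equal(ctr$contribution_pct[ctr$network == "DMN"], 75)
  expect_equal(ctr$contribution_pct[ctr$network == "VIS"], 25)
  expect_equal(sum(ctr$contribution_pct), 100, tolerance = 1e-9)

  # invariant to uniform rescaling of d
  ctr2 <- rsn_effect_contribution(c(1.5, -1.5, 1) * 7, rep(TRUE, 3), map)
  expect_equal(ctr$contribution_pct, ctr2$contribution_pct, tolerance = 1e-12)

  # only significant regions count; all in one network -> 100
  ctr3 <- rsn_effect_contribution(c(1.5, -1.5, 1), c(TRUE, TRUE, FALSE), map)
  expect_equal(ctr3$contribution_pct[ctr3$network == "DMN"], 100)

  expect_warning(
    z <- rsn_effect_contribution(c(1, 1, 1), rep(FALSE, 3), map),
    "no significant"
  )
  expect_true(all(z$contribution_pct == 0))
})

test_that("CAQ composites average the right items over the right ages", {
  resp <- tibble::tibble(
    subject_id = "s1",
    caq_p06_a1 = 1L, caq_p12_a1 = 2L, caq_p18_a1 = 3L, caq_p40_a1 = 4L,
    caq_cur_a1 = 5L
  )
  sc <- caq_scores(resp)
  expect_equal(sc$pCAQ, 2.5) # mean of ages 6, 12, 18, 40 only
  expect_equal(sc$cCAQ, 5)

  allthree <- tibble::tibble(
    caq_p06_a1 = 3L, caq_p12_a1 = 3L, caq_p18_a1 = 3L, caq_p40_a1 = 3L,
    caq_cur_a1 = 3L, caq_cur_a2 = 3L
  )
  sc3 <- caq_scores(allthree)
  expect_equal(sc3$cCAQ, 3)
  expect_equal(sc3$pCAQ, 3)

  miss <- tibble::tibble(
    caq_p06_a1 = NA_integer_, caq_p12_a1 = 2L, caq_p18_a1 = NA_integer_,
    caq_p40_a1 = 4L, caq_cur_a1 = NA_integer_
  )
  scm <- caq_scores(miss)
  expect_equal(scm$pCAQ, 3)
  expect_equal(scm$n_past, 2)
  expect_true(is.na(scm$cCAQ))

  bad <- tibble::tibble(caq_p06_a1 = 7L, caq_cur_a1 = 1L)
  expect_error(caq_scores(bad), "1-5")
})
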