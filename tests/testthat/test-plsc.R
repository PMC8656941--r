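test_that("complete tables pass through imputation unchanged", {
  df <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  expect_identical(impute_knn(df), df)
  expect_error(impute_knn(df, k = 10L), "smaller")
})

test_that("a missing cell is filled with the hand-computed 4-NN mean", {
  # six subjects, two variables; distances on z-scored mutually observed data
  df <- tibble::tibble(
    a = c(0, 1, 2, 3, 4, 10),
    b = c(0.1, 1.1, NA, 3.2, 4.1, 9.5)
  )
  out <- impute_knn(df, k = 4L)
  za <- (df$a - mean(df$a)) / sd(df$a)
  d <- abs(za - za[3L]) # only `a` is mutually observed with subject 3
  nb <- order(d[-3L])[1:4]
  nb <- setdiff(seq_len(6L), 3L)[nb]
  expect_equal(out$b[3L], mean(df$b[nb]))
  expect_identical(out$a, df$a)

  expect_equal(formals(impute_knn)$k, 4L) # the default neighbourhood size

  all_na <- tibble::tibble(a = c(1, 2, 3, 4, 5), b = NA_real_)
  expect_error(impute_knn(all_na), "all subjects")
})

test_that("a single shared column gives a perfect one-variable pattern", {
  set.seed(2)
  X <- matrix(rnorm(300), 100L)
  colnames(X) <- c("x1", "x2", "x3")
  Y <- cbind(y1 = X[, 2L])
  fit <- plsc(X, Y)
  expect_equal(abs(fit$saliences_x[, 1L]), c(0, 1, 0), tolerance = 0.15)
  expect_equal(abs(fit$saliences_y[1L, 1L]), 1, tolerance = 1e-12)
  expect_gt(fit$r_squared[1L], 0.99) # exact up to sampling correlation noise
})

test_that("component count, energy and orthonormality contracts hold", {
  set.seed(3)
  X <- matrix(rnorm(46 * 7), 46)
  Y <- matrix(rnorm(46 * 8), 46)
  fit <- plsc(X, Y)
  expect_length(fit$singular_values, 7L)
  expect_true(all(diff(fit$singular_values) <= 1e-12))

  zx <- scale(X)
  zy <- scale(Y)
  Rxy <- crossprod(zx, zy) / 45
  expect_equal(sum(fit$singular_values^2), sum(Rxy^2), tolerance = 1e-9)
  expect_equal(crossprod(fit$saliences_x), diag(7), tolerance = 1e-9)
  expect_equal(crossprod(fit$saliences_y), diag(7), tolerance = 1e-9)
  expect_true(all(abs(fit$loadings_x) <= 1 + 1e-12))
  expect_true(all(fit$r_squared >= 0 & fit$r_squared <= 1))
})

test_that("singular values match an independent eigendecomposition on a toy block", {
  X <- cbind(x1 = c(1, 2, 4, 3, 5), x2 = c(2, 1, 2, 4, 3), x3 = c(5, 3, 1, 2, 2))
  Y <- cbind(y1 = c(1, 3, 2, 5, 4), y2 = c(2, 2, 4, 1, 3))
  fit <- plsc(X, Y)
  Rxy <- crossprod(scale(X), scale(Y)) / 4
  expect_equal(fit$singular_values, ref_singular_values(Rxy)[1:2],
               tolerance = 1e-10)
})

test_that("degenerate blocks are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(plsc(X, matrix(rnorm(8), 4)), "same number")
  expect_error(plsc(X[1:2, ], matrix(rnorm(4), 2)), "more than two")
  Xz <- cbind(X, 0)
  expect_error(plsc(Xz, matrix(rnorm(10), 10)), "zero-variance")
  Xna <- X
  Xna[1] <- NA
  expect_error(plsc(Xna, matrix(rnorm(10), 10)), "missing")
})

test_that("sign flips of a block column leave inference-relevant output unchanged", {
  pb <- planted_blocks(seed = 8L)
  f1 <- plsc(pb$X, pb$Y)
  X2 <- pb$X
  X2[, 1L] <- -X2[, 1L]
  f2 <- plsc(X2, pb$Y)
  expect_equal(f1$singular_values, f2$singular_values, tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(abs(f1$loadings_x[1L, ]), abs(f2$loadings_x[1L, ]),
               tolerance = 1e-10)

  p1 <- plsc_permutation(f1, n_perm = 100L, seed = 5L)
  p2 <- plsc_permutation(f2, n_perm = 100L, seed = 5L)
  expect_identical(p1$perm_p, p2$perm_p)
})

test_that("permutation p-values hit the floor under perfect dependence", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40)
  colnames(X) <- paste0("x", 1:3)
  fit <- plsc_permutation(plsc(X, X), n_perm = 200L, seed = 1L)
  expect_equal(fit$perm_p[1L], 1 / 201)
  expect_true(fit$significant[1L])
  expect_error(plsc_permutation(plsc(X, X), n_perm = 50L), "at least 100")
})

test_that("independent blocks rarely reach nominal significance", {
  set.seed(6)
  p1 <- replicate(30, {
    X <- matrix(rnorm(46 * 4), 46)
    Y <- matrix(rnorm(46 * 3), 46)
    plsc_permutation(plsc(X, Y), n_perm = 199L,
                     seed = sample.int(1e6, 1L))$perm_p[1L]
  })
  expect_gte(mean(p1 > 0.05), 0.8)
})

test_that("salience recovery: planted one-component structure is found", {
  cosines <- vapply(1:5, function(s) {
    pb <- planted_blocks(n = 100L, r = 0.7, seed = s)
    fit <- plsc(pb$X, pb$Y)
    abs(sum(fit$saliences_x[, 1L] * pb$wx))
  }, numeric(1L))
  expect_true(all(cosines >= 0.9))
})

test_that("bootstrap standard scores separate loaded from inert variables", {
  pb <- planted_blocks(n = 100L, r = 0.7, seed = 11L)
  fit <- plsc_bootstrap(plsc(pb$X, pb$Y), n_boot = 200L, seed = 2L)
  expect_true(fit$reliable_y[1L, 1L]) # the active cognitive variable
  expect_gt(abs(fit$boot_z_x[1L, 1L]), 3)
  expect_lt(abs(fit$boot_z_y[3L, 1L]), 3) # an inert variable

  # noiseless planted pattern: all truly loaded variables exceed threshold,
  # with zero-bootstrap-variance loadings capped at the documented maximum
  set.seed(12)
  X <- matrix(rnorm(50 * 3), 50)
  Y <- cbind(y1 = X[, 1L] + X[, 2L])
  colnames(X) <- paste0("x", 1:3)
  fitn <- plsc_bootstrap(plsc(X, Y), n_boot = 150L, seed = 3L)
  expect_true(all(abs(fitn$boot_z_y[, 1L]) > 3))
  expect_true(all(abs(fitn$boot_z_x[1:2, 1L]) > 3))
  expect_true(all(abs(fitn$boot_z_y) <= 100)) # documented cap
})

test_that("tidiers expose loadings and component summaries", {
  pb <- planted_blocks(seed = 13L)
  fit <- plsc_bootstrap(
    plsc_permutation(plsc(pb$X, pb$Y), n_perm = 100L, seed = 1L),
    n_boot = 100L, seed = 1L
  )
  td <- tidy(fit)
  expect_equal(nrow(td), (4L + 3L) * 3L)
  expect_true(all(c("block", "variable", "loading", "boot_z", "reliable")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 3L)
  expect_true(all(c("singular_value", "r_squared", "p", "p_fdr") %in% names(gl)))
})
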