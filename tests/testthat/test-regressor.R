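test_that("adjusted correlation reduces correctly and clamps at zero", {
  for (r in c(-0.9, -0.3, 0, 0.42, 0.8))
    expect_equal(adjusted_correlation(r, 50, 0), r)
  # strictly decreasing in k at fixed rho
  adj <- vapply(1:20, function(k) adjusted_correlation(0.8, 100, k), 0)
  expect_true(all(diff(adj) < 0))
  # direct evaluation: 1 - 0.75 * 19 / 9 < 0, clamped
  expect_equal(adjusted_correlation(0.5, 20, 10), 0)
  expect_error(adjusted_correlation(0.5, 10, 9), "undefined")
  expect_error(adjusted_correlation(1.2, 50, 1), "rho")
})

test_that("a perfect feature is selected first and assembly stops", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, "f3"]
  m <- greedy_assemble(X, y)
  expect_identical(m$selected[1], "f3")
  expect_equal(m$cum_rho[1], 1)
  expect_length(m$selected, 1)       # nothing can improve on rho = 1
  expect_equal(m$adj_rho[1], adjusted_correlation(1, 40, 1))
})

test_that("the first greedy pick matches a brute-force single-feature scan", {
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    y <- X %*% rnorm(10) + rnorm(n)
    m <- greedy_assemble(X, as.numeric(y), gate_alpha = NULL, max_k = 1)
    scan <- apply(X, 2, function(col)
      abs(suppressWarnings(cor(col, y, method = "spearman"))))
    expect_identical(m$selected[1], names(which.max(scan)))
  }
})

test_that("cumulative correlations are non-decreasing and bounded by 1", {
  set.seed(77)
  X <- matrix(rnorm(60 * 15), 60, 15,
              dimnames = list(NULL, sprintf("f%02d", 1:15)))
  y <- as.numeric(X[, 1:3] %*% c(1, 0.7, 0.5) + rnorm(60, 0, 0.8))
  m <- greedy_assemble(X, y, gate_alpha = NULL)
  expect_true(all(diff(m$cum_rho) >= 0))
  expect_true(all(m$cum_rho <= 1))
  expect_true(all(m$adj_rho <= abs(m$cum_rho) + 1e-12))
})

test_that("the significance gate blocks pure-noise features", {
  zero_selected <- 0L
  for (s in 1:10) {
    set.seed(s + 300)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    y <- sample(rnorm(50))
    m <- greedy_assemble(X, y)
    if (length(m$selected) == 0L) zero_selected <- zero_selected + 1L
  }
  expect_gte(zero_selected, 9L)
})

test_that("NaN cells are mean-imputed and too-small inputs rejected", {
  set.seed(12)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[c(3, 11), 2] <- NA
  y <- as.numeric(X[, 1] + rnorm(30, 0, 0.1))
  m <- greedy_assemble(X, y, gate_alpha = NULL)
  expect_equal(unname(m$impute_means["f2"]), mean(X[-c(3, 11), 2]))
  expect_error(greedy_assemble(X[1:8, ], y[1:8]), "at least 10")
})

test_that("the permutation p-value is exact for a perfect model", {
  set.seed(21)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 3]
  expect_equal(empirical_pvalue(X, y, n_perm = 100, seed = 1), 1 / 101)
  expect_error(empirical_pvalue(X, y, n_perm = 50), "at least 100")
})

test_that("predictions reproduce the training fit and handle gaps", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.numeric(X[, 1:2] %*% c(1, -0.5) + rnorm(40, 0, 0.2))
  m <- greedy_assemble(X, y, gate_alpha = NULL)
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-8)
  # missing a selected column is an error; NaN cells use stored means
  expect_error(predict(m, X[, -match(m$selected[1], colnames(X)),
                            drop = FALSE]), "missing selected")
  Xna <- X; Xna[1, m$selected[1]] <- NA
  pna <- predict(m, Xna)
  expect_false(anyNA(pna))
  expect_equal(pna[-1], predict(m, X)[-1])
  # a zero-feature model predicts its intercept
  m0 <- greedy_assemble(X, sample(y), gate_alpha = 1e-12)
  if (!length(m0$selected))
    expect_true(all(predict(m0, X) == m0$intercept))
})

test_that("cross-validation recovers a noise-free linear ground truth", {
  lib <- simulate_recovery_library(80, seed = 3, noise_sd = 0)
  cfg <- feature_config(gc_offsets = c(-12L, 3L), fe_offsets = c(-12L, 3L),
                        include_structure = FALSE)
  rho <- cross_validate(lib$constructs, lib$efficiency, config = cfg,
                        discover = FALSE, motif_set = lib$motif_set,
                        n_repeats = 5, seed = 9)
  expect_gt(median(rho), 0.95)
  # permuted labels carry no predictable signal (gate off so a model is
  # always fitted and its held-out correlation hovers around zero)
  set.seed(10)
  y_perm <- setNames(sample(lib$efficiency), names(lib$efficiency))
  rho0 <- cross_validate(lib$constructs, y_perm, config = cfg,
                         discover = FALSE, motif_set = lib$motif_set,
                         n_repeats = 10, seed = 10, gate_alpha = NULL,
                         max_k = 3)
  expect_lt(abs(median(rho0, na.rm = TRUE)), 0.35)
  expect_error(cross_validate(lib$constructs, lib$efficiency, config = cfg,
                              frac_train = 1), "frac_train")
  expect_error(cross_validate(lib$constructs[1:6], lib$efficiency[1:6],
                              config = cfg, frac_train = 0.5), "folds")
})

test_that("RPG and non-RPG subsets run through the identical code path", {
  lib <- simulate_recovery_library(120, seed = 17)
  cfg <- feature_config(gc_offsets = c(-12L, 3L), fe_offsets = c(-12L, 3L),
                        include_structure = FALSE)
  X <- build_feature_matrix(lib$constructs, lib$motif_set, cfg)
  rpg <- X[, "is_rpg"] == 1
  for (subset in list(rpg, !rpg)) {
    m <- greedy_assemble(X[subset, ], lib$efficiency[subset],
                         gate_alpha = NULL, max_k = 3)
    expect_s3_class(m, "regressor_model")
    expect_gt(tail(m$cum_rho, 1), 0)
  }
})
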