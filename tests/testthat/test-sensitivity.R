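lr01 <- rbind(c(0, 0), c(1, 1))  # parameters log-uniform on [1, 10]

test_that("first-order indices recover degenerate and additive cases", {
  # output depends on the first parameter only
  f1 <- function(v) log10(v[["a"]])
  S <- sobol_first_order(f1, c("a", "b"), lr01, 4000, seed = 2)
  expect_equal(unname(S["a", 1]), 1, tolerance = 0.05)
  expect_equal(unname(S["b", 1]), 0, tolerance = 0.05)
  # additive model: S_i = a_i^2 / sum(a_j^2) for iid inputs
  f2 <- function(v) 2 * log10(v[["a"]]) + 1 * log10(v[["b"]])
  S2 <- sobol_first_order(f2, c("a", "b"), lr01, 4000, seed = 2)
  expect_equal(unname(S2[, 1]), c(0.8, 0.2), tolerance = 0.05)
  # constant output: zero-variance guard
  S3 <- sobol_first_order(function(v) 7, c("a", "b"), lr01, 200, seed = 1)
  expect_equal(unname(S3[, 1]), c(0, 0))
  # determinism under the seed
  S4 <- sobol_first_order(f2, c("a", "b"), lr01, 500, seed = 9)
  S5 <- sobol_first_order(f2, c("a", "b"), lr01, 500, seed = 9)
  expect_identical(S4, S5)
})

test_that("additive indices stay within 3 MC standard errors of closed form", {
  # a1 z1 + a2 z2 with z = log10(p) ~ U(0,1): S_i = a_i^2/(a1^2+a2^2)
  a1 <- 3; a2 <- 1.5
  f <- function(v) a1 * log10(v[["a"]]) + a2 * log10(v[["b"]])
  n <- 4000
  reps <- vapply(1:8, function(s)
    sobol_first_order(f, c("a", "b"), lr01, n, seed = 100 + s)[, 1],
    numeric(2))
  se <- apply(reps, 1, stats::sd)
  truth <- c(a1^2, a2^2) / (a1^2 + a2^2)
  expect_lt(abs(mean(reps[1, ]) - truth[1]), 3 * se[1] / sqrt(8) + 1e-3)
  expect_lt(abs(mean(reps[2, ]) - truth[2]), 3 * se[2] / sqrt(8) + 1e-3)
  # additive model: first-order indices sum to (at most) one
  expect_lt(sum(rowMeans(reps)), 1 + 3 * max(se))
})

test_that("estimator agrees with the double-loop oracle", {
  fs <- list(
    function(v) 3 * log10(v[["a"]]) + log10(v[["b"]]),
    function(v) log10(v[["a"]])^2 + 0.5 * log10(v[["b"]]),
    function(v) sin(2 * pi * log10(v[["a"]])) + log10(v[["b"]]) +
      log10(v[["a"]]) * log10(v[["b"]]))
  for (i in seq_along(fs)) {
    S <- sobol_first_order(fs[[i]], c("a", "b"), lr01, 10000, seed = 11)
    So <- sobol_double_loop(fs[[i]], c("a", "b"), lr01,
                            n_outer = 200, n_inner = 2000, seed = 12)
    expect_lt(max(abs(S[, 1] - So)), 0.02)
  }
})

test_that("a linear ODE with closed-form solution yields known indices", {
  # dx/dt = -k1 x + k2, x(0) = 0  =>  x(t) = (k2/k1)(1 - exp(-k1 t));
  # the closed form is the output function, evaluated at several times
  tt <- c(1, 5, 15)
  f <- function(v) {
    k1 <- v[["k1"]]; k2 <- v[["k2"]]
    (k2 / k1) * (1 - exp(-k1 * tt))
  }
  lr <- rbind(c(-1, -1), c(0, 0))  # rates in [0.1, 1]
  S <- sobol_first_order(f, c("k1", "k2"), lr, 8000, seed = 5)
  for (j in seq_along(tt)) {
    So <- sobol_double_loop(function(v) f(v)[j], c("k1", "k2"), lr,
                            n_outer = 150, n_inner = 800, seed = 6)
    expect_lt(max(abs(S[, j] - So)), 0.03)
  }
  # at long times x ~ k2/k1: both parameters matter comparably
  expect_gt(S["k1", 3], 0.2)
  expect_gt(S["k2", 3], 0.2)
})

test_that("median screening applies the strictly-less exclusion rule", {
  S <- rbind(keep = rep(0.2, 31), drop = rep(0.1, 31),
             edge = rep(0.15, 31))
  scr <- median_screen(S, threshold = 0.15)
  expect_equal(scr$sensitive, c(TRUE, FALSE, TRUE))
  # raising the threshold never grows the sensitive set
  set.seed(3)
  Sr <- matrix(stats::runif(310), nrow = 10,
               dimnames = list(paste0("p", 1:10), NULL))
  n_sens <- vapply(seq(0, 1, by = 0.1), function(th)
    sum(median_screen(Sr, th)$sensitive), integer(1))
  expect_true(all(diff(n_sens) <= 0))
})

test_that("group runs flag inactive rates and reproduce under the seed", {
  p <- default_params()
  res <- group_sensitivity_run(p, 2, n_samples = 8, seed = 4)
  expect_s3_class(res, "bcr_sensitivity")
  expect_equal(dim(res$S), c(length(param_groups(p, 2)), 31))
  expect_true(all(is.finite(res$S)))
  # the OI-association rate multiplies no active reaction under WT
  oi_row <- res$screen[res$screen$parameter == "r_Inhibitor_association", ]
  expect_false(oi_row$sensitive)
  expect_lt(abs(oi_row$median_S), 0.05)
  # zero stimulation variance at t = 0 is defined as S = 0
  expect_equal(unname(res$S[, 1]), rep(0, nrow(res$S)))
  res2 <- group_sensitivity_run(p, 2, n_samples = 8, seed = 4)
  expect_identical(res$S, res2$S)
  expect_error(group_sensitivity_run(p, 9), "1..7")
  tmp <- tempfile()
  write_sensitivity(res, tmp)
  expect_true(file.exists(paste0(tmp, ".tsv")))
  expect_true(file.exists(paste0(tmp, ".json")))
})
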