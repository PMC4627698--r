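test_that("power-law affinity reduces to standard affinity at alpha = 1", {
  expect_equal(power_law_affinity(2, 4, alpha = 1), 0.5)
  expect_equal(power_law_affinity(8, 16, alpha = 0.75), 1.0)
  expect_equal(power_law_affinity(3, 1, alpha = 0.33), 3)
  expect_error(power_law_affinity(-1, 2), "positive")
})

test_that("region partition is disjoint, exhaustive, and range-checked", {
  s <- make_surface(g = function(f, r) f)
  regs <- partition_regions(s, -0.5)
  expect_true(all(xor(regs$low_kr, regs$high_kr)))
  expect_gt(sum(regs$low_kr), 0)
  expect_gt(sum(regs$high_kr), 0)
  # split at the axis minimum leaves the low region empty
  regs0 <- partition_regions(s, min(s$log10_kr))
  expect_equal(sum(regs0$low_kr), 0)
  expect_error(partition_regions(s, -7), "outside")
})

test_that("collapse exponent is recovered on constructed surfaces", {
  for (a0 in c(0.5, 0.75, 1.0)) {
    s <- make_surface(g = function(f, r) tanh(f - a0 * r))
    ce <- collapse_exponent(s, partition_regions(s, -0.5)$high_kr)
    expect_false(ce$degenerate)
    expect_lt(abs(ce$alpha_hat - a0), 0.05 + 1e-12)
  }
  # forward-rate-dominated surface: quality maximal at alpha = 0
  s0 <- make_surface(g = function(f, r) tanh(f))
  ce0 <- collapse_exponent(s0, partition_regions(s0, -0.5)$low_kr)
  expect_equal(ce0$alpha_hat, 0)
  # constant surface is degenerate
  sc <- make_surface(g = function(f, r) 0 * f)
  cec <- collapse_exponent(sc, partition_regions(sc, -0.5)$high_kr)
  expect_true(cec$degenerate)
  expect_true(is.na(cec$alpha_hat))
  # isotonic fit is available and agrees on a monotone surface
  s1 <- make_surface(g = function(f, r) tanh(f - 0.75 * r))
  ce1 <- collapse_exponent(s1, partition_regions(s1, -0.5)$high_kr,
                           fit = "isotonic")
  expect_lt(abs(ce1$alpha_hat - 0.75), 0.05 + 1e-12)
})

test_that("halted grid points are filled finitely from neighbours", {
  m <- outer(1:6, 1:6, function(i, j) i + j / 2)
  holes <- matrix(FALSE, 6, 6)
  holes[cbind(c(2, 3, 5), c(2, 5, 3))] <- TRUE
  m_holed <- m; m_holed[holes] <- NA
  filled <- fill_halted(m_holed, holes)
  expect_true(all(is.finite(filled)))
  # linear-in-index data are reproduced exactly by harmonic interpolation
  expect_lt(max(abs(filled - m)), 1e-6)
  expect_error(fill_halted(matrix(NA_real_, 2, 2)), "no completed")
})

test_that("grid evaluation is consistent with single simulations", {
  p <- default_params()
  surf <- evaluate_grid(p, "WT", 0, kf_range = c(0.5, 2),
                        kr_range = c(0.5, 2), n_per_axis = 2,
                        budget_per_point = 60)
  expect_equal(sum(surf$halted), 0)
  # recompute the (1,1) corner independently
  p11 <- param_set(param_set(p, "rw0_kf", 0.5), "rw0_kr", 0.5)
  b <- run_to_steady_state(p11, "WT")
  tc <- simulate_stimulation(b, p11, stimulus_protocol(20, 0, "WT"))
  erkp <- output_series(tc, "Erkp")[6]
  nfkb <- output_series(tc, "NFkB")[16]
  expect_equal(surf$raw_erkp[1, 1], erkp, tolerance = 1e-9)
  expect_equal(surf$raw_nfkb[1, 1], nfkb, tolerance = 1e-9)
  metric11 <- erkp / surf$normalizers[["Erkp"]] -
    nfkb / surf$normalizers[["NFkB"]]
  expect_equal(surf$metric[1, 1], metric11, tolerance = 1e-9)
  # normalized Erkp attains 1 somewhere on the WT surface
  expect_equal(max(surf$raw_erkp) / surf$normalizers[["Erkp"]], 1.0)
  tmp <- tempfile()
  write_surface(surf, tmp)
  expect_true(file.exists(paste0(tmp, ".tsv")))
})

test_that("low-unbinding regime depends on the forward rate only", {
  p <- default_params()
  surf <- evaluate_grid(p, "WT", 0, n_per_axis = 6, budget_per_point = 60)
  regs <- partition_regions(surf, -0.5)
  m <- surf$metric
  low <- regs$low_kr
  # variance along kr within the low region is a small fraction of the
  # variance along kf
  var_kf <- mean(apply(m, 2, stats::var)[colSums(low) > 0])
  var_kr <- mean(apply(m[, colSums(low) > 0, drop = FALSE], 1, stats::var))
  expect_lt(var_kr, 0.1 * var_kf)
})

test_that("Syk allocation fractions are conserved and inhibitor-monotone", {
  p <- default_params()
  sweep_K <- c(0.1, 1, 10)
  wt <- syk_allocation(p, "WT", 0, sweep_K)
  expect_equal(wt$frac_inhibited, rep(0, 3))
  sums <- rowSums(wt[, c("frac_Sykb", "frac_Syk342", "frac_Syk317",
                         "frac_inhibited", "frac_other")])
  expect_equal(sums, rep(1, 3), tolerance = 1e-6)
  # the inhibited fraction grows monotonically with inhibitor dose
  fr <- vapply(c(0, 0.5, 2, 8), function(oi)
    syk_allocation(p, "AQL", oi, 1)$frac_inhibited, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_gt(fr[4], 0.5)
})

test_that("amplification follows its defining arithmetic", {
  mk_tc <- function(erkp, dag) {
    structure(list(t = c(0, 15), states = NULL,
                   outputs = data.frame(Erkp = c(0, erkp),
                                        NFkB = c(0, 1),
                                        IkB = c(5, 5),
                                        DAG = c(0, dag)),
                   basal = c(Erkp = 0, NFkB = 0, IkB = 5, DAG = 0),
                   completed = TRUE), class = "bcr_timecourse")
  }
  wt <- mk_tc(erkp = 1.0, dag = 1.0)
  # equal fractional drops give amplification exactly 1
  expect_equal(amplification(wt, mk_tc(0.5, 0.5), "Erkp", 15), 1.0)
  # no output change but upstream drop: amplification 0
  expect_equal(amplification(wt, mk_tc(1.0, 0.5), "Erkp", 15), 0)
  # 14% output drop over 50% DAG drop = 0.28
  expect_equal(amplification(wt, mk_tc(0.86, 0.5), "Erkp", 15), 0.28)
  expect_error(amplification(wt, mk_tc(1, 1), "Erkp", 15), "DAG change")
})
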