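p_nom <- default_params()
baseline_wt <- run_to_steady_state(p_nom, "WT")

test_that("pre-equilibration satisfies the quiescent-baseline contract", {
  expect_lt(attr(baseline_wt, "residual"), 1e-8)
  # downstream outputs are structurally zero before stimulation
  for (nm in c("x_DAG", "x_PKCStar", "x_Erkp1", "x_Erkp2", "x_IKKStar",
               "x_NFkB", "x_MEKp", "x_RasStar"))
    expect_lt(baseline_wt[[nm]], 1e-8)
  # no Syk activity without receptor engagement
  expect_lt(baseline_wt[["x_Sykb"]] + baseline_wt[["x_Syk342"]], 1e-8)
  ct <- conserved_totals(baseline_wt, p_nom)
  expect_equal(ct[["Syk"]], p_nom$totals[["Syk_total"]])
  # the regulatory subsystem is NOT silent: CD45 drives basal Lyn turnover
  expect_gt(baseline_wt[["x_LynStar"]], 0.1)
})

test_that("equilibration reports nonconvergence with the residual", {
  err <- tryCatch(run_to_steady_state(p_nom, "WT", tol = 1e-300, t_max = 10),
                  error = function(e) conditionMessage(e))
  expect_match(err, "residual")
})

test_that("without ligand the baseline persists; with ligand Erkp responds", {
  tc0 <- simulate_stimulation(baseline_wt, p_nom,
                              stimulus_protocol(0, 0, "WT"))
  expect_lt(max(abs(sweep(tc0$states, 2, as.numeric(baseline_wt)))), 1e-6)
  tc <- simulate_stimulation(baseline_wt, p_nom,
                             stimulus_protocol(20, 0, "WT"))
  expect_gt(max(output_series(tc, "Erkp")), 0)
  expect_equal(unname(tc$states[1, ]), unname(as.numeric(baseline_wt)))
})

test_that("inhibited Syk accumulates monotonically under AQL + OI", {
  b <- run_to_steady_state(p_nom, "AQL")
  tc <- simulate_stimulation(b, p_nom, stimulus_protocol(20, 1, "AQL"))
  inh <- output_series(tc, "x_Syk_inh")
  expect_true(all(diff(inh) >= -1e-9))
  expect_gt(inh[length(inh)], 0)
  # scenario mismatch between baseline and protocol is refused
  expect_error(simulate_stimulation(baseline_wt, p_nom,
                                    stimulus_protocol(20, 1, "AQL")),
               "scenario")
})

test_that("pools are conserved along stimulated trajectories", {
  tc <- simulate_stimulation(baseline_wt, p_nom,
                             stimulus_protocol(50, 0, "WT"))
  ct0 <- conserved_totals(tc$states[1, ], p_nom)
  closed <- setdiff(names(ct0), attr(ct0, "source_sink"))
  bcr <- numeric(length(tc$t))
  for (i in seq_along(tc$t)) {
    ct <- conserved_totals(tc$states[i, ], p_nom)
    expect_lt(max(abs(ct[closed] / ct0[closed] - 1)), 1e-6)
    bcr[i] <- ct[["BCR"]]
  }
  expect_true(all(diff(bcr) <= 1e-9))
  expect_true(all(tc$states > -1e-8))
})

test_that("normalization conventions follow their definitions", {
  tc <- simulate_stimulation(baseline_wt, p_nom,
                             stimulus_protocol(20, 0, "WT"))
  # relative-to-basal: basal floor guards a structurally zero baseline
  y <- normalize_relative_to_basal(tc, "Erkp", 5, eps_basal = 1e-6)
  expect_equal(y, output_series(tc, "Erkp")[6] / 1e-6)
  # a nonzero-basal output normalizes to ~1 at t = 0
  expect_equal(normalize_relative_to_basal(tc, "IkB", 0), 1.0)
  # homogeneity: doubling the signal doubles the normalized value
  expect_equal(normalize_relative_to_basal(tc, "Erkp", 15),
               2 * normalize_relative_to_basal(tc, "Erkp", 15) / 2)
  # relative-to-final
  expect_equal(normalize_relative_to_final(tc, "Erkp", 30), 1.0)
  s <- output_series(tc, "Erkp")
  expect_equal(normalize_relative_to_final(tc, "Erkp", 10),
               s[11] / s[31])
  rising <- vapply(0:30, function(tt)
    normalize_relative_to_final(tc, "Erkp", tt), numeric(1))
  expect_true(all(rising <= 1 + 1e-9))
  expect_error(normalize_relative_to_basal(tc, "Erkp", 7.5), "grid")
  expect_error(normalize_relative_to_basal(tc, "nope", 5), "unknown output")
})

test_that("zero-basal floor reproduces the documented arithmetic", {
  # x_out(t_obs) = 1e-3 over a floored basal of 1e-6 gives exactly 1000
  tc <- list(t = c(0, 5), states = NULL,
             outputs = data.frame(Erkp = c(0, 1e-3)),
             basal = c(Erkp = 0), completed = TRUE)
  class(tc) <- "bcr_timecourse"
  expect_equal(normalize_relative_to_basal(tc, "Erkp", 5, 1e-6), 1000)
})

test_that("dose-response is graded, normalized, and inhibitor-sensitive", {
  doses <- c(5.5, 16.5, 50, 150)
  dr <- dose_response(p_nom, "WT", doses, normalization = "max_dose")
  expect_equal(dr$value[dr$dose == 150], 1.0)
  expect_true(all(diff(dr$value[order(dr$dose)]) >= -1e-9))
  # single dose normalizes to exactly one
  dr1 <- dose_response(p_nom, "WT", 20, normalization = "max_dose")
  expect_equal(dr1$value, 1.0)
  # increasing inhibitor lowers (or preserves) the whole curve
  dra <- dose_response(p_nom, "AQL", doses, oi_levels = c(0, 0.5, 2),
                       normalization = "max_dose")
  for (d in doses) {
    v <- dra$value[dra$dose == d][order(dra$oi[dra$dose == d])]
    expect_true(all(diff(v) <= 1e-9))
  }
  expect_error(dose_response(p_nom, "WT", numeric(0)), "empty")
})

test_that("simulation is deterministic and stable under tolerance changes", {
  pr <- stimulus_protocol(20, 0, "WT")
  tc1 <- simulate_stimulation(baseline_wt, p_nom, pr)
  tc2 <- simulate_stimulation(baseline_wt, p_nom, pr)
  expect_identical(tc1$states, tc2$states)
  tc3 <- simulate_stimulation(baseline_wt, p_nom, pr,
                              rtol = 1e-6, atol = 1e-8)
  expect_lt(max(abs(tc1$states - tc3$states)), 1e-6 * 10 *
              max(tc1$states))
  # refining the reporting grid does not change reported outputs
  pr_fine <- stimulus_protocol(20, 0, "WT", t_grid = seq(0, 30, by = 0.5))
  tc4 <- simulate_stimulation(baseline_wt, p_nom, pr_fine)
  on_grid <- match(0:30, tc4$t)
  expect_lt(max(abs(tc4$states[on_grid, ] - tc1$states)), 1e-4)
})

test_that("time courses serialize to delimited text", {
  tc <- simulate_stimulation(baseline_wt, p_nom,
                             stimulus_protocol(20, 0, "WT"))
  tmp <- tempfile(fileext = ".tsv")
  write_timecourse(tc, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(back$Erkp, unname(output_series(tc, "Erkp")))
})
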