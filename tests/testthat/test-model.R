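test_that("state inventory is fixed at 32 names and round-trips", {
  nm <- species_names()
  expect_length(nm, 32)
  expect_false(any(duplicated(nm)))
  x <- species_state(x_Sykb = 1.5, x_DAG = 0.2)
  expect_equal(unname(x[match(c("x_Sykb", "x_DAG"), nm)]), c(1.5, 0.2))
  expect_error(species_state(x_nonsense = 1), "unknown state")
  expect_error(species_state(x_Sykb = -1), ">= 0")
  # name -> index map survives serialization
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(x), tmp, auto_unbox = TRUE, digits = NA)
  back <- unlist(jsonlite::read_json(tmp, simplifyVector = TRUE))
  expect_identical(names(back), nm)
})

test_that("inhibitor-association reactions exist exactly under AQL", {
  p <- default_params()
  wt <- assemble_model(p, "WT")
  aql <- assemble_model(p, "AQL")
  expect_identical(wt$n_states, 32L)
  expect_identical(aql$n_states, 32L)
  n_oi <- function(led) sum(vapply(led$reactions, function(r)
    r$rate == "r_Inhibitor_association", logical(1)))
  expect_identical(n_oi(wt), 0L)
  expect_identical(n_oi(aql), 4L)
  # the four OI reactions capture each Syk form exactly once
  oi_rx <- Filter(function(r) r$rate == "r_Inhibitor_association",
                  aql$reactions)
  gains <- vapply(oi_rx, function(r) r$stoich[["x_Syk_inh"]], numeric(1))
  expect_equal(gains, rep(1, 4))
})

test_that("parameter validation rejects bad sets and unknown symbols", {
  p <- default_params()
  p_bad <- p; p_bad$rates[["r_association"]] <- -1
  expect_error(validate_params(p_bad), "r_association")
  p_missing <- p; p_missing$rates <- p$rates[-1]
  expect_error(assemble_model(p_missing, "WT"), "r_association")
  expect_error(param_set(p, "r_association", 0), "positive")
  expect_error(param_get(p, "no_such_rate"), "unknown parameter")
})

test_that("every pool closes reaction-by-reaction except flagged sinks", {
  p <- default_params()
  for (scen in c("WT", "AQL")) {
    led <- assemble_model(p, scen)
    pools <- bcrsyk:::.pool_members()
    for (pool_name in names(pools)) {
      for (r in led$reactions) {
        s <- bcrsyk:::.pool_stoich(r, pools[[pool_name]])
        if (r$source_sink &&
            pool_name %in% c("BCR", "IkB") &&
            r$name %in% c("BCR_degradation", "IkB_synthesis",
                          "IkBp_degradation", "IkB_degradation")) {
          next  # flagged source/sink reactions may move pool mass
        }
        expect_equal(s, 0, info = paste(scen, pool_name, r$name))
      }
    }
  }
})

test_that("rhs vanishes for the truly empty system", {
  # with no constitutive input (CD45 = 0) and empty state, nothing moves
  p <- default_params()
  p <- param_set(p, "CD45_level", 0)
  d <- model_rhs(species_state(), p, ligand = 0, oi = 0)
  expect_equal(unname(d), rep(0, 32))
})

test_that("a single active mass-action term is evaluated exactly", {
  p <- default_params()
  p <- param_set(p, "CD45_level", 0)
  # choose association rate so r_association * [L] = 0.2 with x_BCRfree = 5
  p <- param_set(p, "r_association", 0.2)
  x <- species_state(x_BCRfree = 5)
  d <- model_rhs(x, p, ligand = 1, oi = 0)
  expect_equal(d[["x_BCRb"]], 1.0)
  expect_equal(d[["x_BCRfree"]], -1.0)
  expect_equal(unname(d[setdiff(species_names(),
                                c("x_BCRb", "x_BCRfree"))]),
               rep(0, 30))
})

test_that("ledger-assembled RHS matches the hand-coded transcription", {
  p <- default_params()
  for (scen in c("WT", "AQL")) {
    led <- assemble_model(p, scen)
    for (s in 1:50) {
      pp <- random_params(seed = 1000 + s)
      x <- random_state(pp, seed = s)
      L <- stats::runif(1, 0, 2); OI <- stats::runif(1, 0, 2)
      d1 <- model_rhs(x, pp, L, OI, assemble_model(pp, scen))
      d2 <- reference_rhs(x, pp, L, OI, scen)
      scale <- max(abs(d2), 1)
      expect_lt(max(abs(d1 - d2)) / scale, 1e-12)
    }
  }
})

test_that("Syk mass balance closes under inhibitor exposure", {
  p <- default_params()
  led <- assemble_model(p, "AQL")
  for (s in 1:20) {
    x <- random_state(p, seed = 300 + s)
    d <- model_rhs(x, p, ligand = 1, oi = 2, ledger = led)
    # implied free-Syk derivative = -(sum of explicit Syk-state derivatives)
    syk_change <- sum(d[c("x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh")])
    free_syk_change <- -syk_change
    expect_equal(syk_change + free_syk_change, 0)
    # the explicit states alone change only through free-Syk exchange:
    # binding and free-Syk inhibition are the only fluxes in or out
    r <- p$rates
    free_syk <- max(0, p$totals[["Syk_total"]] -
                      sum(x[c("x_Sykb", "x_Syk342", "x_Syk317",
                              "x_Syk_inh")]))
    influx <- (r[["r_Syk_BCR_binding1"]] * x[["x_BCRp1"]] +
                 r[["r_Syk_BCR_binding2"]] * x[["x_BCRp2"]]) * free_syk +
      r[["r_Inhibitor_association"]] * 2 * free_syk
    outflux <- r[["r_Syk_BCR_unbinding"]] * x[["x_Sykb"]]
    expect_equal(syk_change, influx - outflux, tolerance = 1e-12)
  }
})

test_that("rhs is linear in each rate constant", {
  p <- default_params()
  led <- assemble_model(p, "AQL")
  x <- random_state(p, seed = 42)
  d0 <- model_rhs(x, p, 1, 0.5, led)
  for (nm in c("r_association", "r_Syk342_via_Lyn", "r_IkB_phos_IKK",
               "r_Inhibitor_association")) {
    # doubling a rate adds exactly one more copy of its term
    p2 <- param_set(p, nm, 2 * param_get(p, nm))
    d2 <- model_rhs(x, p2, 1, 0.5, assemble_model(p2, "AQL"))
    p3 <- param_set(p, nm, 3 * param_get(p, nm))
    d3 <- model_rhs(x, p3, 1, 0.5, assemble_model(p3, "AQL"))
    expect_equal(d3 - d2, d2 - d0, tolerance = 1e-10)
  }
})

test_that("rhs rejects invalid inputs", {
  p <- default_params()
  x <- species_state(); x[1] <- -1
  expect_error(model_rhs(x, p, 0, 0), "negative state")
  expect_error(model_rhs(species_state(), p, -1, 0), ">= 0")
})

test_that("conserved_totals reports pools and flags sinks", {
  p <- default_params()
  x <- species_state()
  ct <- conserved_totals(x, p)
  expect_equal(ct[["Syk"]], p$totals[["Syk_total"]])
  expect_equal(attr(ct, "source_sink"), c("BCR", "IkB"))
  # receptor degradation drains the BCR pool
  x2 <- species_state(x_BCRi = 3)
  d <- model_rhs(x2, param_set(p, "CD45_level", 0), 0, 0)
  bcr_members <- c("x_BCRfree", "x_BCRb", "x_BCRp1", "x_BCRp2", "x_BCRi",
                   "x_Sykb", "x_Syk342", "x_Syk317")
  expect_lt(sum(d[bcr_members]), 0)
})

test_that("ledger exports a complete reaction table", {
  p <- default_params()
  led <- assemble_model(p, "AQL")
  tab <- ledger_table(led)
  expect_equal(nrow(tab), length(led$reactions))
  expect_true(all(c("reaction", "rate", "factors", "consumes",
                    "produces", "source_sink") %in% names(tab)))
  tmp <- tempfile(fileext = ".tsv")
  ledger_table(led, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), nrow(tab))
})
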