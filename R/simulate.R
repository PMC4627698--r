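# Pre-equilibration, stimulation protocols and the normalization
# conventions used by the screening layer.

.output_names <- c("Erkp", "NFkB", "IkB", "DAG")

#' Define a stimulation protocol
#'
#' Ligand and orthogonal inhibitor are applied simultaneously at t = 0 and
#' held constant (no depletion); doses are given in physical units and are
#' converted to internal concentration units by the parameter set's
#' conversion scalars.
#'
#' @param ligand_dose Ligand dose in ug/mL, >= 0.
#' @param oi_dose Orthogonal-inhibitor dose in uM, >= 0.
#' @param scenario `"WT"` (wild-type Syk; ignores the inhibitor) or `"AQL"`
#'   (analog-sensitive Syk, inhibitable).
#' @param t_grid Strictly increasing reporting times in minutes, starting at
#'   0.  Default: integer minutes 0..30, the analysis window used throughout.
#' @return A `bcr_protocol` object.
#' @export
stimulus_protocol <- function(ligand_dose, oi_dose = 0,
                              scenario = c("WT", "AQL"), t_grid = 0:30) {
  scenario <- match.arg(scenario)
  if (ligand_dose < 0 || oi_dose < 0) stop("doses must be >= 0")
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 and be strictly increasing")
  structure(list(ligand_dose = ligand_dose, oi_dose = oi_dose,
                 scenario = scenario, t_grid = t_grid),
            class = "bcr_protocol")
}

#' Pre-equilibrate the model to its unstimulated steady state
#'
#' Integrates from the empty state with no ligand and no inhibitor until the
#' right-hand side is below `tol` in the max norm.  The regulatory
#' Lyn/SHP1/Csk/Cbp subsystem settles to a nonzero basal level driven by the
#' constant CD45 input; all downstream outputs (Erkp, NF-kB, DAG, IKK*, ...)
#' are structurally zero at this baseline, which is the model's "no activity
#' before stimulation" contract.
#'
#' @param params A `bcr_params` object.
#' @param scenario `"WT"` or `"AQL"`.
#' @param tol Steady-state residual tolerance on `max(abs(rhs))` (a.u./min).
#' @param t_max Maximum equilibration time (min) before a nonconvergence
#'   error is raised (the error carries the final residual).
#' @param rtol,atol Integrator tolerances.
#' @return Named baseline state vector (class `bcr_baseline`) with
#'   attributes `residual` and `scenario`.
#' @export
run_to_steady_state <- function(params, scenario = c("WT", "AQL"),
                                tol = 1e-8, t_max = 5000,
                                rtol = 1e-8, atol = 1e-10) {
  scenario <- match.arg(scenario)
  validate_params(params)
  rhs <- .make_rhs(params, scenario, ligand = 0, oi = 0)
  # all pool material starts unmodified; the receptor pool is explicit, so
  # the full complement sits in the free-receptor state
  y <- stats::setNames(numeric(32), .species)
  y[["x_BCRfree"]] <- params$totals[["BCR_total"]]
  resid <- max(abs(rhs(0, y, NULL)[[1]]))
  t_now <- 0
  chunk <- 100
  while (resid > tol && t_now < t_max) {
    t_end <- min(t_now + chunk, t_max)
    sol <- deSolve::ode(y = y, times = c(t_now, t_end), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
    y <- stats::setNames(as.numeric(sol[nrow(sol), -1]), .species)
    t_now <- t_end
    chunk <- chunk * 2
    resid <- max(abs(rhs(0, y, NULL)[[1]]))
  }
  if (resid > tol)
    stop(sprintf("steady state not reached by t = %g (residual %.3e)",
                 t_max, resid))
  structure(y, residual = resid, scenario = scenario,
            class = c("bcr_baseline", "numeric"))
}

.tc_outputs <- function(states, params) {
  nf_tot <- params$totals[["NFkB_total"]]
  data.frame(
    Erkp = states[, "x_Erkp1"] + states[, "x_Erkp2"],
    NFkB = states[, "x_NFkB"],
    IkB = states[, "x_IkB"] + pmax(0, nf_tot - states[, "x_NFkB"]),
    DAG = states[, "x_DAG"])
}

#' Simulate a stimulation protocol from a pre-equilibrated baseline
#'
#' Stiff adaptive implicit integration (lsoda) of the 32-state model from
#' the given baseline, with ligand and inhibitor applied at t = 0.  The
#' result is deterministic given (parameters, protocol, tolerances).
#'
#' @param baseline Baseline state from [run_to_steady_state()] computed with
#'   the same parameters and scenario.
#' @param params A `bcr_params` object.
#' @param protocol A `bcr_protocol`.
#' @param rtol,atol Integrator tolerances (defaults 1e-8 / 1e-10).
#' @param budget Optional wall-time budget in seconds; if exceeded the
#'   returned time course is flagged `completed = FALSE` with `NA` states
#'   (used by the response-surface grid, where such points are interpolated).
#' @return A `bcr_timecourse`: list with `t`, `states` (time x 32 matrix),
#'   `outputs` (Erkp = Erkp1 + Erkp2, NFkB, non-degraded IkB, DAG), `basal`
#'   (baseline value per output), `protocol`, `completed`, `wall_time`.
#' @export
simulate_stimulation <- function(baseline, params, protocol,
                                 rtol = 1e-8, atol = 1e-10, budget = NULL) {
  if (!inherits(protocol, "bcr_protocol")) stop("protocol must be a bcr_protocol")
  scen_b <- attr(baseline, "scenario")
  if (!is.null(scen_b) && scen_b != protocol$scenario)
    stop("baseline scenario (", scen_b, ") does not match protocol (",
         protocol$scenario, ")")
  ligand <- protocol$ligand_dose * params$ligand_scale
  oi <- protocol$oi_dose * params$oi_scale
  rhs <- .make_rhs(params, protocol$scenario, ligand = ligand, oi = oi)
  y0 <- stats::setNames(as.numeric(baseline), .species)
  t0 <- proc.time()[["elapsed"]]
  run <- function() deSolve::ode(y = y0, times = protocol$t_grid, func = rhs,
                                 parms = NULL, method = "lsoda",
                                 rtol = rtol, atol = atol, maxsteps = 50000)
  sol <- if (is.null(budget)) run() else {
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    tryCatch({ setTimeLimit(elapsed = budget, transient = TRUE); run() },
             error = function(e) {
               setTimeLimit(elapsed = Inf)
               if (grepl("time limit|elapsed", conditionMessage(e)))
                 return(NULL)
               stop(e)
             })
  }
  wall <- proc.time()[["elapsed"]] - t0
  nf_tot <- params$totals[["NFkB_total"]]
  basal_states <- matrix(y0, nrow = 1, dimnames = list(NULL, .species))
  basal <- as.numeric(.tc_outputs(basal_states, params)[1, ])
  names(basal) <- .output_names
  if (is.null(sol)) {
    states <- matrix(NA_real_, nrow = length(protocol$t_grid), ncol = 32,
                     dimnames = list(NULL, .species))
    return(structure(list(t = protocol$t_grid, states = states,
                          outputs = NULL, basal = basal,
                          protocol = protocol, completed = FALSE,
                          wall_time = wall), class = "bcr_timecourse"))
  }
  if (nrow(sol) < length(protocol$t_grid))
    stop("integrator failed near t = ", sol[nrow(sol), 1], " min")
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- .species
  structure(list(t = protocol$t_grid, states = states,
                 outputs = .tc_outputs(states, params), basal = basal,
                 protocol = protocol, completed = TRUE, wall_time = wall),
            class = "bcr_timecourse")
}

#' @export
print.bcr_timecourse <- function(x, ...) {
  cat("<bcr_timecourse>", x$protocol$scenario, "ligand",
      x$protocol$ligand_dose, "ug/mL, OI", x$protocol$oi_dose,
      "uM,", length(x$t), "time points,",
      if (x$completed) "completed" else "HALTED", "\n")
  invisible(x)
}

#' Extract an output series from a time course
#'
#' @param tc A `bcr_timecourse`.
#' @param output One of `"Erkp"`, `"NFkB"`, `"IkB"` (non-degraded), `"DAG"`,
#'   or any state name.
#' @return Numeric vector over `tc$t`.
#' @export
output_series <- function(tc, output) {
  if (!tc$completed) stop("time course was halted; no outputs available")
  if (output %in% names(tc$outputs)) return(tc$outputs[[output]])
  if (output %in% colnames(tc$states)) return(tc$states[, output])
  stop("unknown output: ", output)
}

.basal_value <- function(tc, output) {
  if (output %in% names(tc$basal)) return(tc$basal[[output]])
  if (output %in% colnames(tc$states)) {
    # basal stored only for derived outputs; states row 1 is the baseline
    return(tc$states[1, output])
  }
  stop("unknown output: ", output)
}

#' Normalize an output relative to its unstimulated basal value
#'
#' Implements the relative-to-basal convention of densitometry reported as
#' fold-over-basal: `x_out(t_obs) / max(x_out_basal, eps_basal)`.  The floor
#' `eps_basal` guards the downstream outputs whose basal level is
#' structurally zero.
#'
#' @param tc A `bcr_timecourse`.
#' @param output Output name (see [output_series()]).
#' @param t_obs Observation time; must lie on the reporting grid.
#' @param eps_basal Basal floor (a.u.), default 1e-6.
#' @return Normalized scalar.
#' @export
normalize_relative_to_basal <- function(tc, output, t_obs,
                                        eps_basal = 1e-6) {
  i <- match(t_obs, tc$t)
  if (is.na(i)) stop("t_obs = ", t_obs, " not on the reporting grid")
  output_series(tc, output)[i] / max(.basal_value(tc, output), eps_basal)
}

#' Normalize an output relative to its final-time value
#'
#' The convention used for in-house immunoblot time courses: signals are
#' divided by the final-time signal so the last point is exactly 1, avoiding
#' amplification of error from a small initial value.
#'
#' @inheritParams normalize_relative_to_basal
#' @param t_final Reference time (defaults to the last grid point);
#'   `x_out(t_final)` must be positive.
#' @return Normalized scalar; equals 1 when `t_obs == t_final`.
#' @export
normalize_relative_to_final <- function(tc, output, t_obs,
                                        t_final = max(tc$t)) {
  i <- match(t_obs, tc$t); j <- match(t_final, tc$t)
  if (is.na(i) || is.na(j)) stop("t_obs and t_final must lie on the grid")
  s <- output_series(tc, output)
  if (s[j] <= 0) stop("cannot normalize: output is zero at t_final")
  s[i] / s[j]
}

#' Simulate a dose-response curve
#'
#' One simulation per (ligand dose, inhibitor level), reading `output` at
#' `t_obs`.  Under `"max_dose"` normalization all values are divided by the
#' zero-inhibitor response at the maximum dose, so that curve ends at
#' exactly 1; under `"WT_max"` the normalizer is the wild-type zero-OI
#' response at the maximum dose (the convention for reporting mutant
#' activity relative to wild-type); `"none"` returns raw values.
#'
#' @param params A `bcr_params` object.
#' @param scenario `"WT"` or `"AQL"`.
#' @param doses Ascending ligand doses (ug/mL), nonempty.
#' @param oi_levels Inhibitor doses (uM); default 0.
#' @param output Output name, default `"Erkp"`.
#' @param t_obs Readout time (min), default 5 (the Erkp readout; IkB uses 15).
#' @param normalization `"max_dose"`, `"WT_max"`, or `"none"`.
#' @param t_grid Simulation grid; must contain `t_obs`.
#' @param params_wt Parameter set for the wild-type normalizer under
#'   `"WT_max"` (defaults to `params`).
#' @return Data frame (dose, oi, output, value, raw) in long format.
#' @export
dose_response <- function(params, scenario = c("WT", "AQL"), doses,
                          oi_levels = 0, output = "Erkp", t_obs = 5,
                          normalization = c("max_dose", "WT_max", "none"),
                          t_grid = 0:30, params_wt = params) {
  scenario <- match.arg(scenario)
  normalization <- match.arg(normalization)
  if (!length(doses)) stop("dose list is empty")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be ascending")
  baseline <- run_to_steady_state(params, scenario)
  val <- function(p, b, dose, oi, scen) {
    tc <- simulate_stimulation(b, p, stimulus_protocol(dose, oi, scen,
                                                       t_grid))
    output_series(tc, output)[match(t_obs, t_grid)]
  }
  grid <- expand.grid(dose = doses, oi = oi_levels)
  grid$raw <- mapply(function(d, o) val(params, baseline, d, o, scenario),
                     grid$dose, grid$oi)
  norm <- switch(normalization,
    none = 1,
    max_dose = {
      r <- grid$raw[grid$dose == max(doses) & grid$oi == 0]
      if (!length(r)) r <- val(params, baseline, max(doses), 0, scenario)
      r
    },
    WT_max = {
      b_wt <- if (identical(params_wt, params) && scenario == "WT") baseline
              else run_to_steady_state(params_wt, "WT")
      val(params_wt, b_wt, max(doses), 0, "WT")
    })
  if (norm <= 0) stop("normalizer is zero; cannot normalize")
  data.frame(dose = grid$dose, oi = grid$oi, output = output,
             value = grid$raw / norm, raw = grid$raw,
             stringsAsFactors = FALSE)
}

#' Write a time course as delimited text
#'
#' Long format (t, output, value) for the derived outputs plus optional
#' state columns.
#'
#' @param tc A `bcr_timecourse`.
#' @param path Output path (tab-separated).
#' @param states Include the full state matrix as extra columns.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, states = FALSE) {
  if (!tc$completed) stop("cannot write a halted time course")
  df <- data.frame(t = tc$t, tc$outputs)
  if (states) df <- cbind(df, as.data.frame(tc$states))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
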