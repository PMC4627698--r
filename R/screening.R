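# Objective function, noise model, acceptance rule, Latin-hypercube
# candidate generation, and multi-dataset parameter screening.

#' Linear measurement-uncertainty model
#'
#' Densitometry uncertainty grows roughly linearly with signal; the default
#' coefficients are the regression fit used throughout the screening layer:
#' `sigma = 0.0127 + 0.3084 * y_obs`.
#'
#' @param y_obs Observed normalized signal(s), >= 0.
#' @param intercept,slope Model coefficients (overridable via config).
#' @return Standard deviation(s) on the same scale as `y_obs`.
#' @export
sigma_model <- function(y_obs, intercept = 0.0127, slope = 0.3084) {
  if (any(y_obs < 0)) stop("y_obs must be >= 0")
  intercept + slope * y_obs
}

#' Standardized fitness objective
#'
#' `J = (y_obs - y_sim) / sigma`: the signed misfit in units of measurement
#' uncertainty.
#'
#' @param y_obs Observed value(s).
#' @param y_sim Simulated value(s).
#' @param sigma Positive uncertainty value(s).
#' @return Signed objective value(s).
#' @export
objective_J <- function(y_obs, y_sim, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  (y_obs - y_sim) / sigma
}

#' Acceptance rule
#'
#' A simulation is acceptable when it lies inside the band
#' `y_obs - eta*sigma <= y_sim <= y_obs + eta*sigma`, i.e. `|J| <= eta`
#' with inclusive boundaries.
#'
#' @param J Objective value(s).
#' @param eta Positive band half-width in sigma units.
#' @return Logical vector.
#' @export
accept_fit <- function(J, eta) {
  if (eta <= 0) stop("eta must be positive")
  abs(J) <= eta
}

#' Latin hypercube sample of candidate parameter vectors
#'
#' Stratified space-filling sample in log10 space: each dimension is split
#' into `n` equal log10 intervals with exactly one point per interval.
#' Candidates are returned as log10 offsets from nominal, so a row of zeros
#' is the nominal vector.
#'
#' @param param_names Names of the screened parameters (aliases allowed).
#' @param log_ranges Half-width in decades (scalar, default 2: two orders of
#'   magnitude either side of nominal) or a 2 x d matrix of log10-offset
#'   bounds.
#' @param n Number of candidates (>= 1).
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @return n x d matrix of log10 offsets with `param_names` as columns.
#' @export
lhs_sample <- function(param_names, log_ranges = 2, n, seed = 1L) {
  d <- length(param_names)
  if (n < 1) stop("n must be >= 1")
  if (length(log_ranges) == 1)
    log_ranges <- rbind(rep(-abs(log_ranges), d), rep(abs(log_ranges), d))
  lr <- .as_log_ranges(log_ranges, param_names)
  set.seed(seed)
  U <- lhs::randomLHS(n, d)
  X <- sweep(sweep(U, 2, lr[2, ] - lr[1, ], "*"), 2, lr[1, ], "+")
  colnames(X) <- param_names
  X
}

#' Build an observation table
#'
#' Canonical long-format container for (synthetic or imported) normalized
#' immunoblot observations.
#'
#' @param dataset Dataset id (character).
#' @param output Output name (`"Erkp"`, `"IkB"`, `"NFkB"`, ...).
#' @param dose Ligand dose (ug/mL).
#' @param t Observation time (min, >= 0).
#' @param y Observed normalized signal.
#' @param sigma Positive uncertainty.
#' @param mode Normalization mode: `"relative_to_basal"`,
#'   `"relative_to_final"` or `"WT_max"`.
#' @param scenario `"WT"` or `"AQL"` per row.
#' @param oi Orthogonal-inhibitor dose (uM).
#' @param rep Optional replicate id.
#' @return Data frame of class `bcr_observations`.
#' @export
observation_table <- function(dataset, output, dose, t, y, sigma, mode,
                              scenario = "WT", oi = 0, rep = NA_integer_) {
  df <- data.frame(dataset = dataset, output = output, dose = dose, t = t,
                   y = y, sigma = sigma, mode = mode, scenario = scenario,
                   oi = oi, rep = rep, stringsAsFactors = FALSE)
  validate_observations(df)
}

#' Validate an observation table
#' @param df Data frame with the [observation_table()] columns.
#' @return The validated table with class `bcr_observations`.
#' @export
validate_observations <- function(df) {
  need <- c("dataset", "output", "dose", "t", "y", "sigma", "mode",
            "scenario", "oi")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("observation table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$sigma <= 0)) stop("all sigma values must be positive")
  if (any(df$t < 0)) stop("observation times must be >= 0")
  ok_modes <- c("relative_to_basal", "relative_to_final", "WT_max")
  if (!all(df$mode %in% ok_modes))
    stop("unknown normalization mode(s): ",
         paste(setdiff(df$mode, ok_modes), collapse = ", "))
  if (!"rep" %in% names(df)) df$rep <- NA_integer_
  class(df) <- c("bcr_observations", "data.frame")
  df
}

#' Read / write observation tables as tab-separated text
#' @param df A `bcr_observations` table.
#' @param path File path.
#' @return `path` (write) or the validated table (read).
#' @export
write_observations <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  validate_observations(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Simulate the model once per distinct (scenario, dose, oi) condition in an
# observation table and return the simulated counterpart of every row under
# its dataset's normalization mode.  WT_max rows are normalized by the
# wild-type zero-OI output at the maximum dose present in their dataset.
.simulate_observations <- function(params, obs, t_grid = 0:30,
                                   eps_basal = 1e-6, budget = NULL) {
  conds <- unique(obs[, c("scenario", "dose", "oi")])
  tcs <- list()
  baselines <- list()
  for (i in seq_len(nrow(conds))) {
    sc <- conds$scenario[i]
    if (is.null(baselines[[sc]]))
      baselines[[sc]] <- run_to_steady_state(params, sc)
    key <- paste(sc, conds$dose[i], conds$oi[i], sep = "|")
    tc <- simulate_stimulation(baselines[[sc]], params,
            stimulus_protocol(conds$dose[i], conds$oi[i], sc, t_grid),
            budget = budget)
    if (!tc$completed) stop("halted")
    tcs[[key]] <- tc
  }
  wt_max_norm <- function(ds) {
    rows <- obs$dataset == ds
    dmax <- max(obs$dose[rows])
    key <- paste("WT", dmax, 0, sep = "|")
    if (is.null(tcs[[key]])) {
      if (is.null(baselines[["WT"]]))
        baselines[["WT"]] <- run_to_steady_state(params, "WT")
      tcs[[key]] <<- simulate_stimulation(baselines[["WT"]], params,
                       stimulus_protocol(dmax, 0, "WT", t_grid),
                       budget = budget)
      if (!tcs[[key]]$completed) stop("halted")
    }
    out <- unique(obs$output[rows])[1]
    tt <- unique(obs$t[rows & obs$dose == dmax])
    tt <- if (length(tt)) max(tt) else max(obs$t[rows])
    output_series(tcs[[key]], out)[match(tt, t_grid)]
  }
  norms <- new.env()
  vapply(seq_len(nrow(obs)), function(i) {
    key <- paste(obs$scenario[i], obs$dose[i], obs$oi[i], sep = "|")
    tc <- tcs[[key]]
    switch(obs$mode[i],
      relative_to_basal =
        normalize_relative_to_basal(tc, obs$output[i], obs$t[i], eps_basal),
      relative_to_final =
        normalize_relative_to_final(tc, obs$output[i], obs$t[i]),
      WT_max = {
        ds <- obs$dataset[i]
        if (is.null(norms[[ds]])) norms[[ds]] <- wt_max_norm(ds)
        if (norms[[ds]] <= 0) stop("WT_max normalizer is zero")
        output_series(tc, obs$output[i])[match(obs$t[i], t_grid)] /
          norms[[ds]]
      })
  }, numeric(1))
}

#' Screen candidate parameter vectors against observation datasets
#'
#' For each candidate (a row of log10 offsets over the screened parameters),
#' the model is re-equilibrated and simulated under every (scenario, dose,
#' inhibitor) condition the observations require; each observation row is
#' normalized per its dataset's convention and scored with [objective_J()].
#' A candidate is accepted when, for every dataset, `max |J| <= eta` for
#' that dataset's threshold.  Candidates whose simulation fails or exceeds
#' the per-candidate wall-time budget are rejected with a recorded cause.
#'
#' @param candidates Matrix of log10 offsets (columns named by screened
#'   parameters), e.g. from [lhs_sample()]; a row of zeros is nominal.
#' @param datasets A `bcr_observations` table (possibly several dataset
#'   ids).
#' @param params Nominal `bcr_params`.
#' @param thresholds Named numeric vector of eta per dataset id; datasets
#'   not named fall back to `eta_default`.
#' @param eta_default Default acceptance threshold (eta = 1).
#' @param t_grid Simulation grid covering all observation times.
#' @param eps_basal Basal floor for relative-to-basal rows.
#' @param budget_per_candidate Wall-time budget in seconds per candidate.
#' @return Object of class `bcr_screening`: list with `candidates`, `J`
#'   (candidate x observation matrix), `max_abs_J` per dataset, `accepted`
#'   logical, `cause` per candidate, thresholds and the observation table.
#' @export
screen_candidates <- function(candidates, datasets, params,
                              thresholds = NULL, eta_default = 1,
                              t_grid = 0:30, eps_basal = 1e-6,
                              budget_per_candidate = 60) {
  obs <- validate_observations(datasets)
  if (is.null(dim(candidates)))
    candidates <- matrix(candidates, nrow = 1,
                         dimnames = list(NULL, names(candidates)))
  ds_ids <- unique(obs$dataset)
  eta <- stats::setNames(rep(eta_default, length(ds_ids)), ds_ids)
  if (!is.null(thresholds)) {
    unknown <- setdiff(names(thresholds), ds_ids)
    if (length(unknown)) stop("thresholds name unknown dataset(s): ",
                              paste(unknown, collapse = ", "))
    eta[names(thresholds)] <- thresholds
  }
  n <- nrow(candidates)
  J <- matrix(NA_real_, nrow = n, ncol = nrow(obs))
  maxJ <- matrix(NA_real_, nrow = n, ncol = length(ds_ids),
                 dimnames = list(NULL, ds_ids))
  accepted <- logical(n)
  cause <- character(n)
  for (i in seq_len(n)) {
    p_i <- params_apply_offsets(params, candidates[i, ])
    y_sim <- tryCatch(
      .simulate_observations(p_i, obs, t_grid, eps_basal,
                             budget = budget_per_candidate),
      error = function(e) e)
    if (inherits(y_sim, "error")) {
      accepted[i] <- FALSE
      cause[i] <- if (grepl("halted|time limit|elapsed",
                            conditionMessage(y_sim))) "halted"
                  else conditionMessage(y_sim)
      next
    }
    J[i, ] <- objective_J(obs$y, y_sim, obs$sigma)
    for (ds in ds_ids)
      maxJ[i, ds] <- max(abs(J[i, obs$dataset == ds]))
    accepted[i] <- all(maxJ[i, ] <= eta[ds_ids])
    cause[i] <- if (accepted[i]) "accepted" else "rejected"
  }
  structure(list(candidates = candidates, J = J, max_abs_J = maxJ,
                 accepted = accepted, cause = cause, thresholds = eta,
                 observations = obs),
            class = "bcr_screening")
}

#' @export
print.bcr_screening <- function(x, ...) {
  cat("<bcr_screening>", nrow(x$candidates), "candidates,",
      sum(x$accepted), "accepted over", length(x$thresholds),
      "dataset(s)\n")
  invisible(x)
}

#' Write a screening result (candidate table + JSON summary)
#'
#' @param res A `bcr_screening` object.
#' @param prefix Path prefix; writes `<prefix>_candidates.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths.
#' @export
write_screening <- function(res, prefix) {
  tab <- data.frame(res$candidates, accepted = res$accepted,
                    cause = res$cause, res$max_abs_J, check.names = FALSE)
  tsv <- paste0(prefix, "_candidates.tsv")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(n_candidates = nrow(res$candidates),
         n_accepted = sum(res$accepted),
         thresholds = as.list(res$thresholds)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
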