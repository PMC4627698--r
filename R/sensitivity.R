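# First-order (primary) Sobol sensitivity of normalized model outputs over
# parameter groups, with the time-median screening rule.

#' First-order Sobol sensitivity indices (Monte-Carlo estimator)
#'
#' Estimates S_k = Var(E[Y | p_k]) / Var(Y) for each parameter by the
#' pick-freeze scheme with the correlation-form (Janon) estimator: two
#' independent uniform samples A and B of size `n_samples` are drawn in
#' log10 space over `log_ranges`; for each parameter the paired design
#' `BA_k` (B with column k taken from A) shares only p_k with A, so the
#' empirical correlation of f(A) and f(BA_k) estimates the first-order
#' index.  Cost: `n_samples * (d + 1)` evaluations of `output_fn`.
#'
#' @param output_fn Deterministic function taking a named numeric vector of
#'   parameter values (natural scale) and returning a numeric output vector
#'   (scalar or one value per time point); all evaluations must return the
#'   same length.
#' @param param_names Character vector of parameter names (dimension d).
#' @param log_ranges 2 x d matrix (or list) of finite log10 bounds per
#'   parameter: row 1 lower, row 2 upper.
#' @param n_samples Base sample size n (>= 2).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @return Matrix (d x m) of indices, one row per parameter, one column per
#'   output component, with attributes `n_samples` and `seed`.  Outputs with
#'   zero variance have all indices defined as 0.
#' @export
sobol_first_order <- function(output_fn, param_names, log_ranges,
                              n_samples, seed = 1L) {
  d <- length(param_names)
  lr <- .as_log_ranges(log_ranges, param_names)
  if (n_samples < 2) stop("n_samples must be >= 2")
  set.seed(seed)
  U <- matrix(stats::runif(2 * n_samples * d), ncol = d)
  A <- .scale_log(U[seq_len(n_samples), , drop = FALSE], lr)
  B <- .scale_log(U[n_samples + seq_len(n_samples), , drop = FALSE], lr)
  colnames(A) <- colnames(B) <- param_names
  evaln <- function(M) {
    out <- apply(M, 1, function(row) output_fn(stats::setNames(row,
                                                               param_names)))
    if (is.null(dim(out))) matrix(out, nrow = 1) else out
  }
  fA <- evaln(A)   # m x n
  m <- nrow(fA)
  S <- matrix(0, nrow = d, ncol = m,
              dimnames = list(param_names, rownames(fA)))
  for (k in seq_len(d)) {
    # BA_k = B with column k taken from A: f(A) and f(BA_k) share only the
    # k-th coordinate, so their correlation estimates Var(E[Y|p_k])/Var(Y)
    BAk <- B; BAk[, k] <- A[, k]
    fBAk <- evaln(BAk)
    mu <- rowMeans((fA + fBAk) / 2)
    num <- rowMeans(fA * fBAk) - mu^2
    den <- rowMeans((fA^2 + fBAk^2) / 2) - mu^2
    S[k, ] <- ifelse(den > 0, num / den, 0)
  }
  attr(S, "n_samples") <- n_samples
  attr(S, "seed") <- seed
  S
}

#' Brute-force double-loop Sobol oracle
#'
#' Independent reference estimator used to validate [sobol_first_order()]:
#' for each parameter, `n_outer` values of p_k are taken on the stratified
#' midpoint grid of its distribution; for each, the conditional mean
#' E[Y | p_k] is estimated from `n_inner` random draws of the remaining
#' parameters; S_k is the variance of those conditional means (corrected
#' for the inner Monte-Carlo noise) over the total variance.
#' O(d * n_outer * n_inner) evaluations -- usable only on cheap test
#' functions.
#'
#' @inheritParams sobol_first_order
#' @param n_outer,n_inner Outer and inner loop sizes.
#' @return Named numeric vector of first-order indices (scalar outputs only).
#' @export
sobol_double_loop <- function(output_fn, param_names, log_ranges,
                              n_outer = 200, n_inner = 200, seed = 1L) {
  d <- length(param_names)
  lr <- .as_log_ranges(log_ranges, param_names)
  set.seed(seed)
  # total variance from an independent sample
  M <- .scale_log(matrix(stats::runif(n_outer * n_inner * d), ncol = d), lr)
  colnames(M) <- param_names
  y_all <- apply(M, 1, function(row) output_fn(stats::setNames(row,
                                                               param_names)))
  V <- stats::var(y_all)
  S <- stats::setNames(numeric(d), param_names)
  if (V == 0) return(S)
  for (k in seq_len(d)) {
    pk <- .scale_log(matrix((seq_len(n_outer) - 0.5) / n_outer, ncol = 1),
                     lr[, k, drop = FALSE])
    inner <- vapply(pk, function(v) {
      rest <- .scale_log(matrix(stats::runif(n_inner * d), ncol = d), lr)
      rest[, k] <- v
      colnames(rest) <- param_names
      ys <- apply(rest, 1, function(row)
        output_fn(stats::setNames(row, param_names)))
      c(mean(ys), stats::var(ys))
    }, numeric(2))
    # the variance of the inner means overestimates Var(E[Y|p_k]) by the
    # inner Monte-Carlo noise E[Var(Y|p_k)] / n_inner; subtract it
    S[k] <- (stats::var(inner[1, ]) - mean(inner[2, ]) / n_inner) / V
  }
  pmax(S, 0)
}

.as_log_ranges <- function(log_ranges, param_names) {
  if (is.list(log_ranges)) log_ranges <- do.call(cbind, log_ranges)
  lr <- matrix(as.numeric(log_ranges), nrow = 2)
  if (ncol(lr) == 1) lr <- lr[, rep(1, length(param_names)), drop = FALSE]
  if (ncol(lr) != length(param_names))
    stop("log_ranges must give 2 bounds per parameter")
  if (!all(is.finite(lr))) stop("log_ranges must be finite")
  colnames(lr) <- param_names
  lr
}

.scale_log <- function(U, lr) {
  lo <- lr[1, ]; hi <- lr[2, ]
  10^(sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+"))
}

#' Median-over-time screening rule
#'
#' A parameter is retained as sensitive when the median of its sensitivity
#' index over the reported time points is at or above `threshold`; a median
#' strictly below the threshold marks it insensitive.
#'
#' @param S Matrix of indices (parameters x time points) as returned by
#'   [sobol_first_order()], or a list of numeric series.
#' @param threshold Screening threshold, default 0.15.
#' @return Data frame (parameter, median_S, sensitive).
#' @export
median_screen <- function(S, threshold = 0.15) {
  if (is.list(S)) S <- do.call(rbind, S)
  med <- apply(S, 1, stats::median)
  data.frame(parameter = rownames(S), median_S = unname(med),
             sensitive = unname(med >= threshold),
             stringsAsFactors = FALSE)
}

#' Sobol sensitivity of the normalized stimulation response for one
#' parameter group
#'
#' For every rate in the group, computes the primary Sobol index of the
#' relative-to-basal response `y_sim(t) = x_out(t) / max(x_out_basal, eps)`
#' at each reporting time, sampling the group's rates jointly and uniformly
#' in log10 space over `range_decades` decades either side of their nominal
#' values, then applies the time-median screening rule.  Group 3 (the
#' regulatory-enzyme subsystem) is allowed but flagged, as it is prone to
#' integration stiffness; evaluation failures are counted and an error with
#' a stiffness diagnostic is raised when their fraction exceeds
#' `max_fail_frac`.
#'
#' @param params Nominal `bcr_params`.
#' @param group_id Group label in 1..7.
#' @param stimulus_dose Ligand dose in ug/mL (default 20).
#' @param output Output name for y_sim (default `"Erkp"`).
#' @param range_decades Half-width of the log10 sampling range (default 1).
#' @param n_samples Base Sobol sample size.
#' @param seed Integer seed.
#' @param scenario `"WT"` or `"AQL"`.
#' @param t_grid Reporting grid (default 0..30 min).
#' @param threshold Median screening threshold.
#' @param eps_basal Basal floor for the normalization.
#' @param max_fail_frac Abort threshold on the failed-evaluation fraction.
#' @return Object of class `bcr_sensitivity`: list with `S` (parameters x
#'   times), `screen` (median table), `failures`, `group_id`, and estimator
#'   metadata.
#' @export
group_sensitivity_run <- function(params, group_id, stimulus_dose = 20,
                                  output = "Erkp", range_decades = 1,
                                  n_samples = 64, seed = 1L,
                                  scenario = "WT", t_grid = 0:30,
                                  threshold = 0.15, eps_basal = 1e-6,
                                  max_fail_frac = 0.2) {
  members <- param_groups(params, group_id)
  if (group_id == 3)
    message("group 3 (regulatory enzymes) is stiffness-prone; ",
            "failures will be diagnosed")
  nominal <- vapply(members, function(nm) param_get(params, nm), numeric(1))
  lr <- rbind(log10(nominal) - range_decades,
              log10(nominal) + range_decades)
  n_fail <- 0L
  n_eval <- 0L
  fn <- function(vals) {
    n_eval <<- n_eval + 1L
    p <- params
    for (nm in names(vals)) p <- param_set(p, nm, vals[[nm]])
    res <- tryCatch({
      b <- run_to_steady_state(p, scenario)
      tc <- simulate_stimulation(b, p,
              stimulus_protocol(stimulus_dose, 0, scenario, t_grid))
      sapply(t_grid, function(tt)
        normalize_relative_to_basal(tc, output, tt, eps_basal))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <<- n_fail + 1L
      if (n_fail / n_eval > max_fail_frac && n_eval >= 10)
        stop("stiffness diagnostic: ", n_fail, "/", n_eval,
             " evaluations failed in group ", group_id,
             " (last: ", conditionMessage(res), ")")
      return(rep(NA_real_, length(t_grid)))
    }
    res
  }
  S <- sobol_first_order(fn, members, lr, n_samples, seed)
  S[is.na(S)] <- 0
  colnames(S) <- paste0("t", t_grid)
  screen <- median_screen(S, threshold)
  screen$group <- group_id
  structure(list(S = S, screen = screen, failures = n_fail,
                 n_evaluations = n_eval, group_id = group_id,
                 n_samples = n_samples, seed = seed, output = output,
                 stimulus_dose = stimulus_dose, t_grid = t_grid),
            class = "bcr_sensitivity")
}

#' @export
print.bcr_sensitivity <- function(x, ...) {
  cat("<bcr_sensitivity> group", x$group_id, "-", nrow(x$S),
      "parameters, n =", x$n_samples, "\n")
  print(x$screen, row.names = FALSE)
  invisible(x)
}

#' Write sensitivity results as delimited text + JSON summary
#'
#' @param res A `bcr_sensitivity` object.
#' @param prefix Output path prefix; writes `<prefix>.tsv` (parameter,
#'   group, t, S) and `<prefix>.json` (medians, flags, metadata).
#' @return Invisibly, the two paths.
#' @export
write_sensitivity <- function(res, prefix) {
  long <- data.frame(
    parameter = rep(rownames(res$S), times = ncol(res$S)),
    group = res$group_id,
    t = rep(res$t_grid, each = nrow(res$S)),
    S = as.vector(res$S))
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(long, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(group = res$group_id, n_samples = res$n_samples, seed = res$seed,
         failures = res$failures, output = res$output,
         screen = res$screen),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
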