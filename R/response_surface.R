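# Contour analysis over ligand binding-rate grids: anergy metric surfaces,
# power-law affinity collapse, region partition, Syk allocation and
# DAG-relative pathway amplification.

#' Power-law affinity
#'
#' `K_{a,alpha} = kf / kr^alpha`.  With `alpha = 1` this reduces to the
#' standard affinity `kf / kr`; the binding-rate response surfaces of this
#' model collapse onto a power-law affinity with a non-unit exponent in the
#' high-unbinding-rate regime.
#'
#' @param kf,kr Positive forward / reverse binding rates.
#' @param alpha Exponent (default 3/4).
#' @return `kf / kr^alpha`.
#' @export
power_law_affinity <- function(kf, kr, alpha = 0.75) {
  if (any(kf <= 0) || any(kr <= 0)) stop("binding rates must be positive")
  kf / kr^alpha
}

#' Evaluate the anergy metric over a grid of binding rates
#'
#' For every point of an evenly log-spaced product grid over the forward
#' (`rw0_kf`) and reverse (`rw0_kr`) ligand binding rates, the model is
#' re-equilibrated and stimulated, and the metric
#' `Erkp(t_erkp)/N_Erkp - NFkB(t_nfkb)/N_NFkB` is recorded, where the
#' normalizers are the maxima of each output over the wild-type zero-OI
#' surface (computed from this surface when it is itself the WT zero-OI
#' one, otherwise passed in via `normalizers`).  Grid points exceeding the
#' per-point wall-time budget are flagged halted and filled by scattered
#' interpolation from the completed points ([fill_halted()]).
#'
#' @param params A `bcr_params` (binding rates overwritten per point).
#' @param scenario `"WT"` or `"AQL"`.
#' @param oi_dose Inhibitor dose in uM.
#' @param kf_range,kr_range Length-2 positive ranges (a.u.); default
#'   `c(1e-2, 1e2)` per axis.
#' @param n_per_axis Grid resolution per axis (>= 2).
#' @param dose Ligand dose in ug/mL (default 20).
#' @param t_erkp,t_nfkb Readout times (min) for the two outputs.
#' @param budget_per_point Wall-time budget per grid point in seconds.
#' @param normalizers Optional named vector `c(Erkp=, NFkB=)` from a WT
#'   surface ([surface_normalizers()]).
#' @param t_grid Simulation grid.
#' @return Object of class `bcr_surface`: list with `log10_kf`, `log10_kr`
#'   (axes), `metric` (kf x kr matrix, halted points filled), `raw_erkp`,
#'   `raw_nfkb`, `halted` (logical matrix), `normalizers`, `scenario`,
#'   `oi_dose`, `dose`.
#' @export
evaluate_grid <- function(params, scenario = c("WT", "AQL"), oi_dose = 0,
                          kf_range = c(1e-2, 1e2), kr_range = c(1e-2, 1e2),
                          n_per_axis = 8, dose = 20, t_erkp = 5, t_nfkb = 15,
                          budget_per_point = 30, normalizers = NULL,
                          t_grid = 0:30) {
  scenario <- match.arg(scenario)
  if (n_per_axis < 2) stop("n_per_axis must be >= 2")
  if (any(c(kf_range, kr_range) <= 0)) stop("rate ranges must be positive")
  lkf <- seq(log10(kf_range[1]), log10(kf_range[2]), length.out = n_per_axis)
  lkr <- seq(log10(kr_range[1]), log10(kr_range[2]), length.out = n_per_axis)
  erkp <- nfkb <- matrix(NA_real_, n_per_axis, n_per_axis)
  halted <- matrix(FALSE, n_per_axis, n_per_axis)
  for (i in seq_along(lkf)) for (j in seq_along(lkr)) {
    p_ij <- param_set(param_set(params, "rw0_kf", 10^lkf[i]),
                      "rw0_kr", 10^lkr[j])
    res <- tryCatch({
      b <- run_to_steady_state(p_ij, scenario)
      tc <- simulate_stimulation(b, p_ij,
              stimulus_protocol(dose, oi_dose, scenario, t_grid),
              budget = budget_per_point)
      if (!tc$completed) stop("halted")
      c(output_series(tc, "Erkp")[match(t_erkp, t_grid)],
        output_series(tc, "NFkB")[match(t_nfkb, t_grid)])
    }, error = function(e) NULL)
    if (is.null(res)) halted[i, j] <- TRUE
    else { erkp[i, j] <- res[1]; nfkb[i, j] <- res[2] }
  }
  if (all(halted)) stop("all grid points halted; no surface")
  if (is.null(normalizers)) {
    if (!(scenario == "WT" && oi_dose == 0))
      stop("normalizers from a WT zero-OI surface are required for ",
           "non-WT surfaces (see surface_normalizers)")
    normalizers <- c(Erkp = max(erkp, na.rm = TRUE),
                     NFkB = max(nfkb, na.rm = TRUE))
  }
  if (any(normalizers <= 0)) stop("normalizers must be positive")
  metric <- erkp / normalizers[["Erkp"]] - nfkb / normalizers[["NFkB"]]
  metric <- fill_halted(metric, halted)
  structure(list(log10_kf = lkf, log10_kr = lkr, metric = metric,
                 raw_erkp = erkp, raw_nfkb = nfkb, halted = halted,
                 normalizers = normalizers, scenario = scenario,
                 oi_dose = oi_dose, dose = dose,
                 t_erkp = t_erkp, t_nfkb = t_nfkb),
            class = "bcr_surface")
}

#' Maximum-response normalizers of a surface
#' @param surface A `bcr_surface` computed under WT with no inhibitor.
#' @return Named vector `c(Erkp=, NFkB=)` of surface maxima.
#' @export
surface_normalizers <- function(surface) {
  if (!(surface$scenario == "WT" && surface$oi_dose == 0))
    stop("normalizers are defined from the WT zero-OI surface")
  c(Erkp = max(surface$raw_erkp, na.rm = TRUE),
    NFkB = max(surface$raw_nfkb, na.rm = TRUE))
}

#' Fill halted grid points by interpolation from completed neighbours
#'
#' Missing entries of a regular-grid matrix are filled by solving the
#' discrete Laplace equation with the completed points as fixed boundary
#' data (Gauss-Seidel iteration); this is the grid analogue of linear
#' scattered-data interpolation, and reduces to nearest-neighbour fill for
#' points outside the completed hull (flagged via the `halted` mask kept on
#' the surface).
#'
#' @param m Numeric matrix with `NA` at halted points.
#' @param halted Logical matrix marking the missing entries.
#' @param max_iter,tol Iteration controls.
#' @return Matrix with all entries finite.
#' @export
fill_halted <- function(m, halted = is.na(m), max_iter = 2000, tol = 1e-10) {
  if (!any(halted)) return(m)
  if (all(halted)) stop("cannot interpolate: no completed points")
  # nearest-neighbour initialization
  idx <- which(halted, arr.ind = TRUE)
  comp <- which(!halted, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    d2 <- (comp[, 1] - idx[r, 1])^2 + (comp[, 2] - idx[r, 2])^2
    nn <- comp[which.min(d2), , drop = FALSE]
    m[idx[r, 1], idx[r, 2]] <- m[nn[1], nn[2]]
  }
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nr) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < nc) m[i, j + 1])
      v <- mean(nb)
      delta <- max(delta, abs(v - m[i, j]))
      m[i, j] <- v
    }
    if (delta < tol) break
  }
  m
}

#' Partition a surface into low- and high-reverse-rate regions
#'
#' In the low-`kr` region the response depends essentially on the forward
#' binding rate alone; above the split it collapses onto a power-law
#' affinity.  The default split is at `log10(rw0_kr) = -0.5`.
#'
#' @param surface A `bcr_surface`.
#' @param log10_kr_split Split point; must lie within the kr axis range.
#' @return List of two logical matrices `low_kr` and `high_kr` (disjoint,
#'   exhaustive; the split itself belongs to the high region).
#' @export
partition_regions <- function(surface, log10_kr_split = -0.5) {
  lkr <- surface$log10_kr
  if (log10_kr_split < min(lkr) || log10_kr_split > max(lkr))
    stop("split outside the kr axis range")
  high_cols <- lkr >= log10_kr_split
  n <- length(surface$log10_kf)
  low <- matrix(rep(!high_cols, each = n), nrow = n)
  high <- !low
  list(low_kr = low, high_kr = high)
}

#' Estimate the power-law collapse exponent of a surface region
#'
#' For each candidate exponent `alpha`, the metric values of the region are
#' regressed on the scalar `z = log10(kf) - alpha * log10(kr)` with a 1-D
#' curve fit (cross-validated smoothing spline, or isotonic regression),
#' and the fit quality `1 - Var(residual) / Var(metric)` is recorded.  The
#' estimate `alpha_hat` maximizes the profile: if the region's response is
#' a function of the power-law affinity `kf / kr^alpha0` alone, the profile
#' peaks at `alpha0` (and at `alpha = 0` in the forward-rate-dominated
#' low-`kr` regime).
#'
#' @param surface A `bcr_surface`.
#' @param region Logical matrix over the grid (e.g. from
#'   [partition_regions()]); needs >= 10 completed points.
#' @param alpha_grid Candidate exponents (default 0 to 1.5 by 0.05).
#' @param fit `"spline"` (default) or `"isotonic"`.
#' @return List with `alpha_hat`, `profile` (data frame alpha, quality),
#'   `degenerate` flag (constant metric), and `fit` method used.
#' @export
collapse_exponent <- function(surface, region,
                              alpha_grid = seq(0, 1.5, by = 0.05),
                              fit = c("spline", "isotonic")) {
  fit <- match.arg(fit)
  use <- region & !surface$halted
  if (sum(use) < 10) stop("region must contain at least 10 completed points")
  kf <- surface$log10_kf[row(surface$metric)[use]]
  kr <- surface$log10_kr[col(surface$metric)[use]]
  y <- surface$metric[use]
  if (stats::var(y) == 0)
    return(list(alpha_hat = NA_real_,
                profile = data.frame(alpha = alpha_grid, quality = NA_real_),
                degenerate = TRUE, fit = fit))
  quality <- vapply(alpha_grid, function(a) {
    z <- kf - a * kr
    yhat <- .curve_fit_1d(z, y, fit)
    1 - stats::var(y - yhat) / stats::var(y)
  }, numeric(1))
  list(alpha_hat = alpha_grid[which.max(quality)],
       profile = data.frame(alpha = alpha_grid, quality = quality),
       degenerate = FALSE, fit = fit)
}

.curve_fit_1d <- function(z, y, fit) {
  if (fit == "isotonic") {
    o <- order(z)
    # isotonic in the direction that fits better
    up <- stats::isoreg(z[o], y[o])$yf
    dn <- -stats::isoreg(z[o], -y[o])$yf
    yhat <- numeric(length(y))
    if (sum((y[o] - up)^2) <= sum((y[o] - dn)^2)) yhat[o] <- up
    else yhat[o] <- dn
    return(yhat)
  }
  nuniq <- length(unique(z))
  if (nuniq < 4) return(rep(mean(y), length(y)))
  df_max <- max(3, min(15, floor(nuniq / 2)))
  fitter <- tryCatch(stats::smooth.spline(z, y, df = df_max),
                     error = function(e) NULL)
  if (is.null(fitter)) return(rep(mean(y), length(y)))
  stats::predict(fitter, z)$y
}

#' Allocation of the Syk pool along an affinity sweep
#'
#' For each power-law affinity value, the forward binding rate is set to
#' `K * kr^alpha` at fixed reverse rate, the model is equilibrated and
#' stimulated, and the end-of-window fractions of total Syk in the
#' receptor-bound, Y342-phosphorylated, Y317-phosphorylated, inhibited and
#' remaining (free) forms are reported.  Fractions sum to 1 by conservation.
#'
#' @param params A `bcr_params`.
#' @param scenario `"WT"` or `"AQL"`.
#' @param oi_dose Inhibitor dose (uM).
#' @param affinity_sweep Positive power-law-affinity values.
#' @param alpha Collapse exponent used to realize the sweep (default 3/4).
#' @param kr Fixed reverse rate (default the parameter set's nominal).
#' @param dose Ligand dose (ug/mL).
#' @param t_read Readout time (default 30 min).
#' @return Data frame (affinity, kf, kr, frac_Sykb, frac_Syk342,
#'   frac_Syk317, frac_inhibited, frac_other).
#' @export
syk_allocation <- function(params, scenario = c("WT", "AQL"), oi_dose = 0,
                           affinity_sweep, alpha = 0.75, kr = NULL,
                           dose = 20, t_read = 30) {
  scenario <- match.arg(scenario)
  if (any(affinity_sweep <= 0)) stop("affinity sweep must be positive")
  if (is.null(kr)) kr <- param_get(params, "rw0_kr")
  syk_tot <- params$totals[["Syk_total"]]
  rows <- lapply(affinity_sweep, function(K) {
    kf <- K * kr^alpha
    p <- param_set(param_set(params, "rw0_kf", kf), "rw0_kr", kr)
    b <- run_to_steady_state(p, scenario)
    tc <- simulate_stimulation(b, p,
            stimulus_protocol(dose, oi_dose, scenario,
                              t_grid = sort(unique(c(0:30, t_read)))))
    x <- tc$states[match(t_read, tc$t), ]
    f <- c(x[["x_Sykb"]], x[["x_Syk342"]], x[["x_Syk317"]],
           x[["x_Syk_inh"]]) / syk_tot
    data.frame(affinity = K, kf = kf, kr = kr,
               frac_Sykb = f[1], frac_Syk342 = f[2], frac_Syk317 = f[3],
               frac_inhibited = f[4], frac_other = 1 - sum(f))
  })
  do.call(rbind, rows)
}

#' DAG-relative pathway amplification
#'
#' The fractional drop of an output between the wild-type and
#' mutant-plus-inhibitor simulations, divided by the fractional drop of the
#' common upstream messenger DAG at the same time: `[(out_WT - out_mut) /
#' out_WT] / [(DAG_WT - DAG_mut) / DAG_WT]`.  A value near 1 means the
#' pathway transmits signal reductions one-to-one; a value near 0 means the
#' output is buffered against upstream loss.
#'
#' @param tc_wt,tc_mut Time courses sharing the same reporting grid
#'   (typically WT and AQL-plus-inhibitor at the same dose).
#' @param output `"Erkp"` or `"NFkB"` (any output name).
#' @param t_obs Comparison time; WT output and WT DAG must be nonzero and
#'   the DAG drop nonzero.
#' @return The amplification ratio (dimensionless).
#' @export
amplification <- function(tc_wt, tc_mut, output, t_obs) {
  if (!identical(tc_wt$t, tc_mut$t))
    stop("time courses must share the reporting grid")
  i <- match(t_obs, tc_wt$t)
  if (is.na(i)) stop("t_obs not on the reporting grid")
  ow <- output_series(tc_wt, output)[i]
  om <- output_series(tc_mut, output)[i]
  dw <- output_series(tc_wt, "DAG")[i]
  dm <- output_series(tc_mut, "DAG")[i]
  if (ow == 0 || dw == 0) stop("wild-type output/DAG is zero at t_obs")
  dag_drop <- (dw - dm) / dw
  if (dag_drop == 0) stop("no DAG change between the scenarios")
  ((ow - om) / ow) / dag_drop
}

#' Write a response surface as delimited text + JSON metadata
#'
#' @param surface A `bcr_surface`.
#' @param prefix Path prefix; writes `<prefix>.tsv` (log10_kf, log10_kr,
#'   metric, halted) and `<prefix>.json` (normalizers, scenario, dose).
#' @return Invisibly, the two paths.
#' @export
write_surface <- function(surface, prefix) {
  g <- expand.grid(i = seq_along(surface$log10_kf),
                   j = seq_along(surface$log10_kr))
  tab <- data.frame(log10_kf = surface$log10_kf[g$i],
                    log10_kr = surface$log10_kr[g$j],
                    metric = surface$metric[cbind(g$i, g$j)],
                    halted = surface$halted[cbind(g$i, g$j)])
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(scenario = surface$scenario, oi_dose = surface$oi_dose,
         dose = surface$dose, normalizers = as.list(surface$normalizers),
         n_halted = sum(surface$halted)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' @export
print.bcr_surface <- function(x, ...) {
  cat("<bcr_surface>", length(x$log10_kf), "x", length(x$log10_kr),
      "grid,", x$scenario, "OI", x$oi_dose, "uM,",
      sum(x$halted), "halted\n")
  invisible(x)
}
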