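# Canonical kinetic-rate inventory.  One entry per distinct rate constant in
# the reaction ledger.  Units: first-order rates in 1/min, second-order rates
# in 1/(a.u. * min).  Group labels follow the seven natural divisions of the
# network: 1 BCR dynamics, 2 Syk activation, 3 regulatory enzymes + Lyn,
# 4 medial scaffold assembly (BLNK/BTK/PLC2g binding), 5 PLC2g activation and
# DAG turnover, 6 PKC + MAPK/Erk pathway, 7 IkB/NF-kB pathway.
.rate_defs <- function() {
  d <- rbind(
    # name                        default group
    c("r_association",            1.0, 1),
    c("r_disassociation",         1.0, 1),
    c("r_Recycling",              0.1, 1),
    c("r_Internalization",        0.02, 1),
    c("r_Degradation",            0.02, 1),
    c("r_BCRp1_phos_Lyn",         0.3, 1),
    c("r_BCRp1_phos_Syk342",      0.1, 1),
    c("r_BCRp1_dephos_SHP1",      0.2, 1),
    c("r_BCRp1_dephos_bg",        0.1, 1),
    c("r_BCRp2_phos_Syk342",      0.1, 1),
    c("r_BCRp2_dephos_SHP1",      0.2, 1),
    c("r_BCRp2_dephos_bg",        0.1, 1),
    c("r_Clathrin_localization",  0.05, 1),
    c("r_Clathrin_delocalization",0.2, 1),
    c("r_Syk_BCR_binding1",       0.05, 2),
    c("r_Syk_BCR_binding2",       0.05, 2),
    c("r_Syk_BCR_unbinding",      0.5, 2),
    c("r_Syk342_via_Lyn",         0.5, 2),
    c("r_Syk342_autophos",        0.02, 2),
    c("r_Syk342_dephos_SHP1",     0.3, 2),
    c("r_Syk342_dephos_bg",       0.2, 2),
    c("r_Syk317_phos1",           0.05, 2),
    c("r_Syk317_phos2",           0.05, 2),
    c("r_Syk317_dephos",          0.05, 2),
    c("r_Inhibitor_association",  0.1, 2),
    c("r_Lyn_dephos_CD45",        0.5, 3),
    c("r_Lyn_phos_Csk",           0.5, 3),
    c("r_LynStar_phos",           0.2, 3),
    c("r_LynStar_autophos",       0.5, 3),
    c("r_Lyn_deauto_CD45",        0.2, 3),
    c("r_Lyn_deauto_SHP1",        0.2, 3),
    c("r_Lyn_deauto_bg",          0.05, 3),
    c("r_SHP1_activation",        0.2, 3),
    c("r_SHP1_inactivation",      0.5, 3),
    c("r_Csk_activation",         0.5, 3),
    c("r_Csk_disassociation",     0.5, 3),
    c("r_Cbp_phos",               0.5, 3),
    c("r_Cbp_dephos_CD45",        0.5, 3),
    c("r_BLNK_phos_Syk342",       0.1, 4),
    c("r_BLNK_dephos_SHP1",       0.2, 4),
    c("r_BLNK_dephos_bg",         0.1, 4),
    c("r_BTK_BLNK_binding",       0.2, 4),
    c("r_BTK_BLNK_unbinding",     0.5, 4),
    c("r_BTK_phos_Syk342",        0.2, 4),
    c("r_BTK_phos_Lyn",           0.05, 4),
    c("r_BTK_dephos",             0.5, 4),
    c("r_PLC2g_BLNK_binding",     0.2, 4),
    c("r_PLC2g_BLNK_unbinding",   0.5, 4),
    c("r_PLC2g_phos_Syk342",      0.3, 5),
    c("r_PLC2g_phos_BTK",         0.3, 5),
    c("r_PLC2g_dephos",           0.5, 5),
    c("r_DAG_production",         0.1, 5),
    c("r_DAG_removal",            0.5, 5),
    c("r_PKC_activation",         0.1, 7),
    c("r_PKC_deactivation",       0.3, 7),
    c("r_SOS_BLNK_binding",       0.3, 6),
    c("r_SOS_BLNK_unbinding",     0.3, 6),
    c("r_Ras_activation",         0.2, 6),
    c("r_Ras_deactivation",       0.3, 6),
    c("r_Raf_activation",         0.3, 6),
    c("r_Raf_deactivation",       0.3, 6),
    c("r_MEK_phos",               0.3, 6),
    c("r_MEK_dephos",             0.3, 6),
    c("r_Erk_phos_MEK",           0.1, 6),
    c("r_Erkp1_dephos",           0.05, 6),
    c("r_Erkp2_dephos",           0.05, 6),
    c("r_IKK_activation",         0.3, 7),
    c("r_IKK_deactivation",       0.3, 7),
    c("r_IkB_phos_IKK",           0.05, 7),
    c("r_IkBp_degradation",       0.5, 7),
    c("r_IkB_synthesis",          0.2, 7),
    c("r_IkB_NFkB_association",   0.5, 7),
    c("r_IkB_degradation",        0.05, 7)
  )
  data.frame(name = d[, 1], default = as.numeric(d[, 2]),
             group = as.integer(d[, 3]), stringsAsFactors = FALSE)
}

# Conserved pool totals (a.u.).  IkB_total only normalizes the non-degraded
# IkB readout; the IkB pool itself carries a synthesis source and degradation
# sinks and is not conserved.
.total_defs <- function() {
  c(BCR_total = 10, Syk_total = 10, Lyn_total = 5, SHP1_total = 5,
    Csk_total = 5, Cbp_total = 5, Clathrin_total = 5, BLNK_total = 5,
    BTK_total = 5, PLC2g_total = 5, PIP2_total = 20, PKC_total = 5,
    SOS_total = 5, Ras_total = 10, Raf_total = 10, MEK_total = 10,
    Erk_total = 10, IKK_total = 5, IkB_total = 5, NFkB_total = 5)
}

# Short literature-style aliases for the screened rates, mapping onto the
# canonical inventory.  rw* names index early-signalling reactions, r1x/r3x
# names index medial and downstream reactions.
.param_aliases <- c(
  rw0_kf  = "r_association",
  rw0_kr  = "r_disassociation",
  rw7_kr  = "r_Syk342_dephos_bg",
  rw9_kf  = "r_Syk317_phos2",
  rw15_kf = "r_BLNK_phos_Syk342",
  rw16_kf = "r_PLC2g_BLNK_binding",
  rw16_kr = "r_PLC2g_BLNK_unbinding",
  r12s_kf = "r_PLC2g_phos_Syk342",
  r13_kf  = "r_DAG_production",
  r13_kr  = "r_DAG_removal",
  r18_kf  = "r_Erk_phos_MEK",
  r19_kf  = "r_SOS_BLNK_binding",
  r38_kf  = "r_IkB_phos_IKK"
)

#' Alias map for screened kinetic rates
#'
#' Short names used throughout the sensitivity and screening layers
#' (`rw0_kf`, `rw9_kf`, `r38_kf`, ...) mapped to the canonical rate names of
#' the reaction ledger.
#'
#' @return Named character vector: alias -> canonical rate name.
#' @export
param_aliases <- function() .param_aliases

.canonical_name <- function(name) {
  out <- name
  hit <- out %in% names(.param_aliases)
  out[hit] <- .param_aliases[out[hit]]
  out
}

#' Default ("surrogate nominal") parameter set
#'
#' Returns the packaged nominal parameter vector: every kinetic rate in the
#' reaction ledger, the conserved pool totals, the constant CD45 input level,
#' and the unit-conversion scalars that map a ligand dose in ug/mL and an
#' orthogonal-inhibitor dose in uM onto internal concentration units (a.u.).
#' The published source model does not print its nominal values, so these are
#' order-of-magnitude mass-action defaults chosen so the documented
#' qualitative behaviour of the network (graded dose response, inhibitor
#' suppression, saturating Erk branch) holds; see the methods vignette.
#'
#' @return An object of class `bcr_params`: a list with elements `rates`
#'   (named numeric), `totals` (named numeric), `cd45` (scalar),
#'   `ligand_scale` (a.u. per ug/mL), `oi_scale` (a.u. per uM), `groups`
#'   (named integer, one Table-style group label per rate) and `provenance`
#'   (character log of manual tunings).
#' @export
default_params <- function() {
  defs <- .rate_defs()
  rates <- stats::setNames(defs$default, defs$name)
  groups <- stats::setNames(defs$group, defs$name)
  p <- structure(
    list(rates = rates, totals = .total_defs(), cd45 = 1,
         ligand_scale = 0.01, oi_scale = 1, groups = groups,
         provenance = character(0)),
    class = "bcr_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks strict positivity of all rates and pool totals, nonnegativity of
#' the CD45 level, and completeness of the rate inventory against the
#' reaction ledger.
#'
#' @param params A `bcr_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "bcr_params"))
    stop("`params` must be a 'bcr_params' object")
  need <- .rate_defs()$name
  missing <- setdiff(need, names(params$rates))
  if (length(missing))
    stop("missing rate constant(s): ", paste(missing, collapse = ", "))
  bad <- names(params$rates)[!is.finite(params$rates) | params$rates <= 0]
  if (length(bad))
    stop("nonpositive or non-finite rate(s): ", paste(bad, collapse = ", "))
  badt <- names(params$totals)[!is.finite(params$totals) | params$totals <= 0]
  if (length(badt))
    stop("nonpositive or non-finite pool total(s): ",
         paste(badt, collapse = ", "))
  if (!is.finite(params$cd45) || params$cd45 < 0)
    stop("CD45 level must be finite and >= 0")
  if (params$ligand_scale <= 0 || params$oi_scale <= 0)
    stop("unit-conversion scalars must be positive")
  invisible(params)
}

#' Read a single parameter (alias-aware)
#'
#' @param params A `bcr_params` object.
#' @param name Canonical rate name, alias (e.g. `"rw0_kf"`), pool total name
#'   (e.g. `"Syk_total"`), or `"CD45_level"`.
#' @return The numeric value.
#' @export
param_get <- function(params, name) {
  nm <- .canonical_name(name)
  if (nm %in% names(params$rates)) return(unname(params$rates[[nm]]))
  if (nm %in% names(params$totals)) return(unname(params$totals[[nm]]))
  if (nm == "CD45_level") return(params$cd45)
  stop("unknown parameter: ", name)
}

#' Set a single parameter (alias-aware)
#'
#' @inheritParams param_get
#' @param value New positive value.
#' @return A modified copy of `params`.
#' @export
param_set <- function(params, name, value) {
  if (!is.finite(value)) stop("value for ", name, " must be finite")
  nm <- .canonical_name(name)
  if (nm %in% names(params$rates)) {
    if (value <= 0) stop("rate ", name, " must be positive")
    params$rates[[nm]] <- value
  } else if (nm %in% names(params$totals)) {
    if (value <= 0) stop("pool total ", name, " must be positive")
    params$totals[[nm]] <- value
  } else if (nm == "CD45_level") {
    if (value < 0) stop("CD45 level must be >= 0")
    params$cd45 <- value
  } else stop("unknown parameter: ", name)
  params
}

#' Multiply a rate or total by a factor, recording provenance
#'
#' Supports the manual-retuning workflow used to move from a wild-type fit to
#' a mutant fit (e.g. scaling the Y317 phosphorylation rate `rw9_kf`, or
#' halving `Syk_total` to emulate reduced kinase expression).
#'
#' @inheritParams param_get
#' @param factor Positive multiplier.
#' @return A modified copy of `params` with a provenance note appended.
#' @export
tune_parameter <- function(params, name, factor) {
  if (!is.finite(factor) || factor <= 0) stop("`factor` must be positive")
  old <- param_get(params, name)
  params <- param_set(params, name, old * factor)
  params$provenance <- c(params$provenance,
                         sprintf("%s: %g -> %g (x%g)", name, old,
                                 old * factor, factor))
  params
}

#' Table-style parameter groups
#'
#' @param params A `bcr_params` object.
#' @param group_id Optional integer in 1..7; if given, returns only the rate
#'   names in that group.
#' @return Named integer vector of group labels, or a character vector of
#'   member names when `group_id` is given.
#' @export
param_groups <- function(params, group_id = NULL) {
  if (is.null(group_id)) return(params$groups)
  if (!group_id %in% 1:7) stop("group_id must be in 1..7")
  names(params$groups)[params$groups == group_id]
}

#' Flatten a parameter set to a named numeric vector
#' @param params A `bcr_params` object.
#' @return Named numeric vector (rates, totals, CD45_level, scales).
#' @export
params_flatten <- function(params) {
  c(params$rates, params$totals,
    CD45_level = params$cd45,
    ligand_scale = params$ligand_scale, oi_scale = params$oi_scale)
}

#' Apply log10 offsets to named parameters
#'
#' Candidate vectors in the screening layer are stored as log10 offsets from
#' the nominal values of the screened parameters; this applies such an offset
#' vector and returns the perturbed parameter set.
#'
#' @param params A `bcr_params` object.
#' @param offsets Named numeric vector of log10 offsets (aliases allowed).
#' @return A modified copy of `params`.
#' @export
params_apply_offsets <- function(params, offsets) {
  for (nm in names(offsets)) {
    params <- param_set(params, nm,
                        param_get(params, nm) * 10^offsets[[nm]])
  }
  params
}

#' Write a parameter set to YAML or JSON
#'
#' Flat key -> value representation with group labels, round-trip exact.
#'
#' @param params A `bcr_params` object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  obj <- list(rates = as.list(params$rates),
              totals = as.list(params$totals),
              cd45 = params$cd45,
              ligand_scale = params$ligand_scale,
              oi_scale = params$oi_scale,
              groups = as.list(params$groups),
              provenance = as.list(params$provenance))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported parameter-file extension: ", path)
  invisible(path)
}

#' Read a parameter set from YAML or JSON
#'
#' @param path File written by [write_params()] (or hand-authored with the
#'   same keys).  Missing rates or totals fall back to the packaged defaults;
#'   unknown rate names are an error.
#' @return A `bcr_params` object.
#' @export
read_params <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                               simplifyVector = TRUE)
         else stop("unsupported parameter-file extension: ", path)
  p <- default_params()
  rates <- unlist(obj$rates)
  unknown <- setdiff(.canonical_name(names(rates)), names(p$rates))
  if (length(unknown))
    stop("unknown rate(s) in ", path, ": ", paste(unknown, collapse = ", "))
  for (nm in names(rates)) p <- param_set(p, nm, rates[[nm]])
  totals <- unlist(obj$totals)
  unknownt <- setdiff(names(totals), names(p$totals))
  if (length(unknownt))
    stop("unknown pool total(s) in ", path, ": ",
         paste(unknownt, collapse = ", "))
  for (nm in names(totals)) p <- param_set(p, nm, totals[[nm]])
  if (!is.null(obj$cd45)) p$cd45 <- obj$cd45
  if (!is.null(obj$ligand_scale)) p$ligand_scale <- obj$ligand_scale
  if (!is.null(obj$oi_scale)) p$oi_scale <- obj$oi_scale
  if (!is.null(obj$provenance)) p$provenance <- unlist(obj$provenance)
  validate_params(p)
  p
}

#' @export
print.bcr_params <- function(x, ...) {
  cat("<bcr_params>", length(x$rates), "kinetic rates,",
      length(x$totals), "pool totals, CD45 =", x$cd45, "\n")
  if (length(x$provenance))
    cat("tunings:\n ", paste(x$provenance, collapse = "\n  "), "\n")
  invisible(x)
}
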