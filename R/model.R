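# Model core: 32-state mass-action network for BCR -> Syk -> (Erk, NF-kB)
# signalling with optional Syk-AQL / orthogonal-inhibitor kinetics.
#
# All free (unmodified) pool members are implied by conservation and clamped
# at zero: e.g. free Syk = Syk_total - Sykb - Syk342 - Syk317 - Syk_inh.
# Receptor bound by Syk travels with the Syk-bound states (Sykb/Syk342/
# Syk317); when an orthogonal inhibitor captures a receptor-bound Syk form,
# the receptor is released back to the doubly-phosphorylated state so that
# receptor mass is never silently destroyed.

.species <- c(
  "x_BCRfree", "x_BCRb", "x_BCRp1", "x_BCRp2", "x_BCRi", "x_Clathrin_local",
  "x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh",
  "x_Lyndp", "x_LynStar", "x_SHP1Star", "x_CskStar", "x_Cbpp",
  "x_BLNKp", "x_BTKb", "x_BTKp", "x_PLC2gb", "x_PLC2gp",
  "x_DAG", "x_PKCStar", "x_SOSb", "x_RasStar", "x_RafStar", "x_MEKp",
  "x_Erkp1", "x_Erkp2", "x_IKKStar", "x_IkB", "x_IkBp", "x_NFkB")

# Implied (conservation-derived) quantities and external inputs usable as
# rate-law factors alongside the explicit states.
.derived <- c("free_Syk", "free_Lyn", "free_SHP1", "free_Csk", "free_Cbp",
              "free_Clathrin", "free_BLNK", "free_BTK", "free_PLC2g",
              "free_PIP2", "free_PKC", "free_SOS", "free_Ras", "free_Raf",
              "free_MEK", "free_Erk", "free_IKK", "complex_NFkB_IkB")
.inputs <- c("Ligand", "OI", "CD45", "ONE")

#' State-variable inventory
#'
#' The 32 tracked concentrations (arbitrary units): twenty early-signalling
#' states (receptor forms, clathrin, four Syk forms, Lyn, the SHP1/Csk/Cbp
#' regulatory enzymes, and the BLNK/BTK/PLC2g medial pathway) and twelve
#' downstream states (DAG, PKC*, the SOS/Ras/Raf/MEK/Erk cascade, and the
#' IKK/IkB/NF-kB module).
#'
#' @return Character vector of length 32; the position of each name is the
#'   fixed state index.
#' @export
species_names <- function() .species

#' Construct a state vector
#'
#' @param ... Named nonnegative concentrations; unnamed states default to 0.
#' @return Named numeric vector over [species_names()].
#' @export
species_state <- function(...) {
  vals <- c(...)
  x <- stats::setNames(numeric(length(.species)), .species)
  if (length(vals)) {
    unknown <- setdiff(names(vals), .species)
    if (length(unknown)) stop("unknown state(s): ",
                              paste(unknown, collapse = ", "))
    if (any(vals < 0)) stop("state concentrations must be >= 0")
    x[names(vals)] <- vals
  }
  x
}

.reaction <- function(name, rate, factors, stoich, source_sink = FALSE) {
  list(name = name, rate = rate, factors = factors, stoich = stoich,
       source_sink = source_sink)
}

#' Assemble the reaction ledger
#'
#' Builds the ordered mass-action reaction list for the requested scenario.
#' Under the wild-type (`"WT"`) scenario Syk does not bind the orthogonal
#' inhibitor and no inhibitor-association reactions exist; under the
#' analog-sensitive (`"AQL"`) scenario exactly four irreversible
#' inhibitor-association reactions are added, one per Syk form (receptor
#' bound by an inhibited Syk form is released to the doubly-phosphorylated
#' receptor state).
#'
#' @param params A `bcr_params` object (validated; every rate symbol in the
#'   ledger must resolve).
#' @param scenario `"WT"` or `"AQL"`.
#' @return An object of class `bcr_ledger`: list with elements `reactions`
#'   (list of reactions, each with name, rate symbol, multiplicative factor
#'   names, and a named stoichiometry over the explicit states), `scenario`,
#'   and `n_states` (always 32).
#' @export
assemble_model <- function(params, scenario = c("WT", "AQL")) {
  scenario <- match.arg(scenario)
  validate_params(params)
  R <- list(
    ## --- BCR engagement, trafficking, ITAM phosphorylation ---
    .reaction("ligand_association", "r_association",
              c("Ligand", "x_BCRfree"), c(x_BCRfree = -1, x_BCRb = 1)),
    .reaction("ligand_disassociation", "r_disassociation",
              "x_BCRb", c(x_BCRb = -1, x_BCRfree = 1)),
    .reaction("BCR_recycling", "r_Recycling",
              "x_BCRi", c(x_BCRi = -1, x_BCRfree = 1)),
    .reaction("BCR_internalization", "r_Internalization",
              c("x_Clathrin_local", "x_BCRfree"),
              c(x_BCRfree = -1, x_BCRi = 1)),
    .reaction("BCR_degradation", "r_Degradation",
              "x_BCRi", c(x_BCRi = -1), source_sink = TRUE),
    .reaction("ITAM1_phos_Lyn", "r_BCRp1_phos_Lyn",
              c("x_LynStar", "x_BCRb"), c(x_BCRb = -1, x_BCRp1 = 1)),
    .reaction("ITAM1_phos_Syk342", "r_BCRp1_phos_Syk342",
              c("x_Syk342", "x_BCRb"), c(x_BCRb = -1, x_BCRp1 = 1)),
    .reaction("ITAM1_dephos_SHP1", "r_BCRp1_dephos_SHP1",
              c("x_SHP1Star", "x_BCRp1"), c(x_BCRp1 = -1, x_BCRb = 1)),
    .reaction("ITAM1_dephos_bg", "r_BCRp1_dephos_bg",
              "x_BCRp1", c(x_BCRp1 = -1, x_BCRb = 1)),
    .reaction("ITAM2_phos_Syk342", "r_BCRp2_phos_Syk342",
              c("x_Syk342", "x_BCRp1"), c(x_BCRp1 = -1, x_BCRp2 = 1)),
    .reaction("ITAM2_dephos_SHP1", "r_BCRp2_dephos_SHP1",
              c("x_SHP1Star", "x_BCRp2"), c(x_BCRp2 = -1, x_BCRp1 = 1)),
    .reaction("ITAM2_dephos_bg", "r_BCRp2_dephos_bg",
              "x_BCRp2", c(x_BCRp2 = -1, x_BCRp1 = 1)),
    .reaction("clathrin_localization", "r_Clathrin_localization",
              c("x_Syk342", "free_Clathrin"), c(x_Clathrin_local = 1)),
    .reaction("clathrin_delocalization", "r_Clathrin_delocalization",
              "x_Clathrin_local", c(x_Clathrin_local = -1)),
    ## --- Syk binding and phosphorylation ---
    # Binding to singly-phosphorylated receptor: ITAM completion precedes
    # unbinding, so the receptor re-emerges (only) as doubly phosphorylated.
    .reaction("Syk_BCR_binding1", "r_Syk_BCR_binding1",
              c("x_BCRp1", "free_Syk"), c(x_BCRp1 = -1, x_Sykb = 1)),
    .reaction("Syk_BCR_binding2", "r_Syk_BCR_binding2",
              c("x_BCRp2", "free_Syk"), c(x_BCRp2 = -1, x_Sykb = 1)),
    .reaction("Syk_BCR_unbinding", "r_Syk_BCR_unbinding",
              "x_Sykb", c(x_Sykb = -1, x_BCRp2 = 1)),
    .reaction("Syk342_phos_Lyn", "r_Syk342_via_Lyn",
              c("x_LynStar", "x_Sykb"), c(x_Sykb = -1, x_Syk342 = 1)),
    .reaction("Syk342_autophos", "r_Syk342_autophos",
              c("x_Syk342", "x_Sykb"), c(x_Sykb = -1, x_Syk342 = 1)),
    .reaction("Syk342_dephos_SHP1", "r_Syk342_dephos_SHP1",
              c("x_SHP1Star", "x_Syk342"), c(x_Syk342 = -1, x_Sykb = 1)),
    .reaction("Syk342_dephos_bg", "r_Syk342_dephos_bg",
              "x_Syk342", c(x_Syk342 = -1, x_Sykb = 1)),
    .reaction("Syk317_phos_on_Sykb", "r_Syk317_phos1",
              c("x_LynStar", "x_Sykb"), c(x_Sykb = -1, x_Syk317 = 1)),
    .reaction("Syk317_phos_on_Syk342", "r_Syk317_phos2",
              c("x_LynStar", "x_Syk342"), c(x_Syk342 = -1, x_Syk317 = 1)),
    # Y317 dephosphorylation returns equally to the bound and Y342 forms;
    # total Syk317 loss is twice the elementary rate.
    .reaction("Syk317_dephos_to_Sykb", "r_Syk317_dephos",
              "x_Syk317", c(x_Syk317 = -1, x_Sykb = 1)),
    .reaction("Syk317_dephos_to_Syk342", "r_Syk317_dephos",
              "x_Syk317", c(x_Syk317 = -1, x_Syk342 = 1)),
    ## --- Lyn activation ---
    .reaction("Lyn_dephos_CD45", "r_Lyn_dephos_CD45",
              c("CD45", "free_Lyn"), c(x_Lyndp = 1)),
    .reaction("Lyn_phos_Csk", "r_Lyn_phos_Csk",
              c("x_CskStar", "x_Lyndp"), c(x_Lyndp = -1)),
    .reaction("LynStar_phos", "r_LynStar_phos",
              "x_Lyndp", c(x_Lyndp = -1, x_LynStar = 1)),
    .reaction("LynStar_autophos", "r_LynStar_autophos",
              c("x_LynStar", "x_Lyndp"), c(x_Lyndp = -1, x_LynStar = 1)),
    .reaction("Lyn_deauto_CD45", "r_Lyn_deauto_CD45",
              c("CD45", "x_LynStar"), c(x_LynStar = -1, x_Lyndp = 1)),
    .reaction("Lyn_deauto_SHP1", "r_Lyn_deauto_SHP1",
              c("x_SHP1Star", "x_LynStar"), c(x_LynStar = -1, x_Lyndp = 1)),
    .reaction("Lyn_deauto_bg", "r_Lyn_deauto_bg",
              "x_LynStar", c(x_LynStar = -1, x_Lyndp = 1)),
    ## --- Regulatory enzymes (SHP1, Csk, Cbp; CD45 constant input) ---
    .reaction("SHP1_activation", "r_SHP1_activation",
              c("x_Lyndp", "free_SHP1"), c(x_SHP1Star = 1)),
    .reaction("SHP1_inactivation", "r_SHP1_inactivation",
              "x_SHP1Star", c(x_SHP1Star = -1)),
    .reaction("Csk_activation", "r_Csk_activation",
              c("x_Cbpp", "free_Csk"), c(x_CskStar = 1)),
    .reaction("Csk_disassociation", "r_Csk_disassociation",
              "x_CskStar", c(x_CskStar = -1)),
    .reaction("Cbp_phos", "r_Cbp_phos",
              c("x_Lyndp", "free_Cbp"), c(x_Cbpp = 1)),
    .reaction("Cbp_dephos_CD45", "r_Cbp_dephos_CD45",
              c("CD45", "x_Cbpp"), c(x_Cbpp = -1)),
    ## --- Medial pathway: BLNK scaffold, BTK, PLC2g ---
    .reaction("BLNK_phos_Syk342", "r_BLNK_phos_Syk342",
              c("x_Syk342", "free_BLNK"), c(x_BLNKp = 1)),
    .reaction("BLNK_dephos_SHP1", "r_BLNK_dephos_SHP1",
              c("x_SHP1Star", "x_BLNKp"), c(x_BLNKp = -1)),
    .reaction("BLNK_dephos_bg", "r_BLNK_dephos_bg",
              "x_BLNKp", c(x_BLNKp = -1)),
    # BLNKp acts as a catalytic scaffold: BTK/PLC2g/SOS recruitment reads
    # x_BLNKp without depleting it.
    .reaction("BTK_BLNK_binding", "r_BTK_BLNK_binding",
              c("free_BTK", "x_BLNKp"), c(x_BTKb = 1)),
    .reaction("BTK_BLNK_unbinding", "r_BTK_BLNK_unbinding",
              "x_BTKb", c(x_BTKb = -1)),
    .reaction("BTK_phos_Syk342", "r_BTK_phos_Syk342",
              c("x_Syk342", "x_BTKb"), c(x_BTKb = -1, x_BTKp = 1)),
    .reaction("BTK_phos_Lyn", "r_BTK_phos_Lyn",
              c("x_LynStar", "x_BTKb"), c(x_BTKb = -1, x_BTKp = 1)),
    .reaction("BTK_dephos", "r_BTK_dephos",
              "x_BTKp", c(x_BTKp = -1, x_BTKb = 1)),
    .reaction("PLC2g_BLNK_binding", "r_PLC2g_BLNK_binding",
              c("free_PLC2g", "x_BLNKp"), c(x_PLC2gb = 1)),
    .reaction("PLC2g_BLNK_unbinding", "r_PLC2g_BLNK_unbinding",
              "x_PLC2gb", c(x_PLC2gb = -1)),
    .reaction("PLC2g_phos_Syk342", "r_PLC2g_phos_Syk342",
              c("x_Syk342", "x_PLC2gb"), c(x_PLC2gb = -1, x_PLC2gp = 1)),
    .reaction("PLC2g_phos_BTK", "r_PLC2g_phos_BTK",
              c("x_BTKp", "x_PLC2gb"), c(x_PLC2gb = -1, x_PLC2gp = 1)),
    .reaction("PLC2g_dephos", "r_PLC2g_dephos",
              "x_PLC2gp", c(x_PLC2gp = -1, x_PLC2gb = 1)),
    ## --- Downstream: DAG/PKC, MAPK cascade, IkB/NF-kB ---
    .reaction("DAG_production", "r_DAG_production",
              c("x_PLC2gp", "free_PIP2"), c(x_DAG = 1)),
    .reaction("DAG_removal", "r_DAG_removal",
              "x_DAG", c(x_DAG = -1)),
    .reaction("PKC_activation", "r_PKC_activation",
              c("x_DAG", "free_PKC"), c(x_PKCStar = 1)),
    .reaction("PKC_deactivation", "r_PKC_deactivation",
              "x_PKCStar", c(x_PKCStar = -1)),
    .reaction("SOS_BLNK_binding", "r_SOS_BLNK_binding",
              c("free_SOS", "x_BLNKp"), c(x_SOSb = 1)),
    .reaction("SOS_BLNK_unbinding", "r_SOS_BLNK_unbinding",
              "x_SOSb", c(x_SOSb = -1)),
    .reaction("Ras_activation", "r_Ras_activation",
              c("x_SOSb", "free_Ras"), c(x_RasStar = 1)),
    .reaction("Ras_deactivation", "r_Ras_deactivation",
              "x_RasStar", c(x_RasStar = -1)),
    .reaction("Raf_activation", "r_Raf_activation",
              c("x_RasStar", "free_Raf"), c(x_RafStar = 1)),
    .reaction("Raf_deactivation", "r_Raf_deactivation",
              "x_RafStar", c(x_RafStar = -1)),
    .reaction("MEK_phos", "r_MEK_phos",
              c("x_RafStar", "free_MEK"), c(x_MEKp = 1)),
    .reaction("MEK_dephos", "r_MEK_dephos",
              "x_MEKp", c(x_MEKp = -1)),
    .reaction("Erk_phos1", "r_Erk_phos_MEK",
              c("x_MEKp", "free_Erk"), c(x_Erkp1 = 1)),
    .reaction("Erk_phos2", "r_Erk_phos_MEK",
              c("x_MEKp", "x_Erkp1"), c(x_Erkp1 = -1, x_Erkp2 = 1)),
    .reaction("Erkp2_dephos", "r_Erkp2_dephos",
              "x_Erkp2", c(x_Erkp2 = -1, x_Erkp1 = 1)),
    .reaction("Erkp1_dephos", "r_Erkp1_dephos",
              "x_Erkp1", c(x_Erkp1 = -1)),
    .reaction("IKK_activation", "r_IKK_activation",
              c("x_PKCStar", "free_IKK"), c(x_IKKStar = 1)),
    .reaction("IKK_deactivation", "r_IKK_deactivation",
              "x_IKKStar", c(x_IKKStar = -1)),
    # IKK* phosphorylates IkB held in the NF-kB:IkB complex; phosphorylation
    # releases NF-kB and hands the tagged IkB to the degradation queue.
    .reaction("IkB_phos_IKK", "r_IkB_phos_IKK",
              c("x_IKKStar", "complex_NFkB_IkB"),
              c(x_IkBp = 1, x_NFkB = 1)),
    .reaction("IkBp_degradation", "r_IkBp_degradation",
              "x_IkBp", c(x_IkBp = -1), source_sink = TRUE),
    # NF-kB-driven IkB resynthesis: the negative feedback that re-sequesters
    # free NF-kB.
    .reaction("IkB_synthesis", "r_IkB_synthesis",
              "x_NFkB", c(x_IkB = 1), source_sink = TRUE),
    .reaction("IkB_NFkB_association", "r_IkB_NFkB_association",
              c("x_IkB", "x_NFkB"), c(x_IkB = -1, x_NFkB = -1)),
    .reaction("IkB_degradation", "r_IkB_degradation",
              "x_IkB", c(x_IkB = -1), source_sink = TRUE)
  )
  if (scenario == "AQL") {
    oi <- list(
      .reaction("OI_assoc_Sykb", "r_Inhibitor_association",
                c("OI", "x_Sykb"),
                c(x_Sykb = -1, x_Syk_inh = 1, x_BCRp2 = 1)),
      .reaction("OI_assoc_Syk342", "r_Inhibitor_association",
                c("OI", "x_Syk342"),
                c(x_Syk342 = -1, x_Syk_inh = 1, x_BCRp2 = 1)),
      .reaction("OI_assoc_Syk317", "r_Inhibitor_association",
                c("OI", "x_Syk317"),
                c(x_Syk317 = -1, x_Syk_inh = 1, x_BCRp2 = 1)),
      .reaction("OI_assoc_freeSyk", "r_Inhibitor_association",
                c("OI", "free_Syk"), c(x_Syk_inh = 1)))
    R <- c(R, oi)
  }
  # every rate symbol must resolve in the parameter set
  syms <- vapply(R, `[[`, "", "rate")
  missing <- setdiff(syms, names(params$rates))
  if (length(missing))
    stop("rate symbol(s) not in parameter set: ",
         paste(unique(missing), collapse = ", "))
  structure(list(reactions = R, scenario = scenario,
                 n_states = length(.species)),
            class = "bcr_ledger")
}

#' @export
print.bcr_ledger <- function(x, ...) {
  cat("<bcr_ledger>", length(x$reactions), "reactions,", x$n_states,
      "states, scenario", x$scenario, "\n")
  invisible(x)
}

#' Export a reaction ledger as a table
#'
#' @param ledger A `bcr_ledger`.
#' @param path Optional path; if given the table is written as
#'   tab-separated text.
#' @return Data frame with one row per reaction (name, rate symbol, factors,
#'   consumed/produced states, source/sink flag).
#' @export
ledger_table <- function(ledger, path = NULL) {
  rows <- lapply(ledger$reactions, function(r) {
    cons <- names(r$stoich)[r$stoich < 0]
    prod <- names(r$stoich)[r$stoich > 0]
    data.frame(reaction = r$name, rate = r$rate,
               factors = paste(r$factors, collapse = "*"),
               consumes = paste(cons, collapse = "+"),
               produces = paste(prod, collapse = "+"),
               source_sink = r$source_sink, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}

# Evaluate the derived (conservation-implied) quantities and external inputs
# given an explicit state vector.  Free pools are clamped at zero to guard
# against transient integrator undershoot.
.derived_values <- function(x, params, ligand, oi) {
  tt <- params$totals
  c(free_Syk = max(0, tt[["Syk_total"]] -
                     x[[7]] - x[[8]] - x[[9]] - x[[10]]),
    free_Lyn = max(0, tt[["Lyn_total"]] - x[[11]] - x[[12]]),
    free_SHP1 = max(0, tt[["SHP1_total"]] - x[[13]]),
    free_Csk = max(0, tt[["Csk_total"]] - x[[14]]),
    free_Cbp = max(0, tt[["Cbp_total"]] - x[[15]]),
    free_Clathrin = max(0, tt[["Clathrin_total"]] - x[[6]]),
    free_BLNK = max(0, tt[["BLNK_total"]] - x[[16]]),
    free_BTK = max(0, tt[["BTK_total"]] - x[[17]] - x[[18]]),
    free_PLC2g = max(0, tt[["PLC2g_total"]] - x[[19]] - x[[20]]),
    free_PIP2 = max(0, tt[["PIP2_total"]] - x[[21]]),
    free_PKC = max(0, tt[["PKC_total"]] - x[[22]]),
    free_SOS = max(0, tt[["SOS_total"]] - x[[23]]),
    free_Ras = max(0, tt[["Ras_total"]] - x[[24]]),
    free_Raf = max(0, tt[["Raf_total"]] - x[[25]]),
    free_MEK = max(0, tt[["MEK_total"]] - x[[26]]),
    free_Erk = max(0, tt[["Erk_total"]] - x[[27]] - x[[28]]),
    free_IKK = max(0, tt[["IKK_total"]] - x[[29]]),
    complex_NFkB_IkB = max(0, tt[["NFkB_total"]] - x[[32]]),
    Ligand = ligand, OI = oi, CD45 = params$cd45, ONE = 1)
}

# Compile a ledger into index arrays for fast flux evaluation:
# flux_j = k_j * v[i1_j] * v[i2_j] over the extended value vector
# v = c(states, derived, inputs).
.compile_ledger <- function(ledger, params) {
  ext <- c(.species, .derived, .inputs)
  n_rx <- length(ledger$reactions)
  k <- numeric(n_rx); i1 <- integer(n_rx); i2 <- integer(n_rx)
  one <- match("ONE", ext)
  S <- matrix(0, nrow = length(.species), ncol = n_rx,
              dimnames = list(.species, NULL))
  for (j in seq_len(n_rx)) {
    r <- ledger$reactions[[j]]
    k[j] <- params$rates[[r$rate]]
    f <- match(r$factors, ext)
    if (anyNA(f)) stop("unknown factor in reaction ", r$name)
    if (length(f) > 2) stop("rate laws are at most bimolecular")
    i1[j] <- f[1]
    i2[j] <- if (length(f) == 2) f[2] else one
    S[names(r$stoich), j] <- r$stoich
  }
  list(k = k, i1 = i1, i2 = i2, S = S)
}

#' Model right-hand side (assembled from the reaction ledger)
#'
#' Evaluates the time derivative of the 32 state concentrations under
#' mass-action kinetics with the ligand and orthogonal-inhibitor doses as
#' constant external inputs (internal units).  The derivative is linear in
#' every rate constant, and unmodified pool members enter via clamped
#' conservation laws.
#'
#' @param state Named or unnamed numeric vector of 32 nonnegative
#'   concentrations in [species_names()] order.
#' @param params A `bcr_params` object.
#' @param ligand Ligand concentration in internal units (a.u.), >= 0.
#' @param oi Orthogonal-inhibitor concentration in internal units, >= 0.
#' @param ledger A `bcr_ledger` from [assemble_model()]; if omitted, a WT
#'   ledger is assembled.
#' @param neg_tol States more negative than `-neg_tol` raise a domain error;
#'   smaller undershoots (integrator probing) are tolerated.
#' @return Named numeric derivative vector (a.u./min).
#' @export
model_rhs <- function(state, params, ligand = 0, oi = 0, ledger = NULL,
                      neg_tol = 1e-6) {
  if (length(state) != length(.species))
    stop("state must have exactly ", length(.species), " components")
  if (any(state < -neg_tol))
    stop("negative state component(s): ",
         paste(.species[state < -neg_tol], collapse = ", "))
  if (ligand < 0 || oi < 0) stop("ligand and oi must be >= 0")
  if (is.null(ledger)) ledger <- assemble_model(params, "WT")
  cc <- .compile_ledger(ledger, params)
  v <- c(as.numeric(state), .derived_values(as.numeric(state), params,
                                            ligand, oi))
  flux <- cc$k * v[cc$i1] * v[cc$i2]
  stats::setNames(as.numeric(cc$S %*% flux), .species)
}

# Fast closure used by the integrator: compiles the ledger once and reuses
# the index arrays on every call.
.make_rhs <- function(params, scenario, ligand, oi,
                      ledger = assemble_model(params, scenario)) {
  cc <- .compile_ledger(ledger, params)
  tt <- params$totals
  syk_tot <- tt[["Syk_total"]]; lyn_tot <- tt[["Lyn_total"]]
  shp1_tot <- tt[["SHP1_total"]]; csk_tot <- tt[["Csk_total"]]
  cbp_tot <- tt[["Cbp_total"]]; cla_tot <- tt[["Clathrin_total"]]
  blnk_tot <- tt[["BLNK_total"]]; btk_tot <- tt[["BTK_total"]]
  plc_tot <- tt[["PLC2g_total"]]; pip2_tot <- tt[["PIP2_total"]]
  pkc_tot <- tt[["PKC_total"]]; sos_tot <- tt[["SOS_total"]]
  ras_tot <- tt[["Ras_total"]]; raf_tot <- tt[["Raf_total"]]
  mek_tot <- tt[["MEK_total"]]; erk_tot <- tt[["Erk_total"]]
  ikk_tot <- tt[["IKK_total"]]; nfkb_tot <- tt[["NFkB_total"]]
  cd45 <- params$cd45
  k <- cc$k; i1 <- cc$i1; i2 <- cc$i2; S <- cc$S
  function(t, y, parms) {
    v <- c(y,
           max(0, syk_tot - y[7] - y[8] - y[9] - y[10]),
           max(0, lyn_tot - y[11] - y[12]),
           max(0, shp1_tot - y[13]),
           max(0, csk_tot - y[14]),
           max(0, cbp_tot - y[15]),
           max(0, cla_tot - y[6]),
           max(0, blnk_tot - y[16]),
           max(0, btk_tot - y[17] - y[18]),
           max(0, plc_tot - y[19] - y[20]),
           max(0, pip2_tot - y[21]),
           max(0, pkc_tot - y[22]),
           max(0, sos_tot - y[23]),
           max(0, ras_tot - y[24]),
           max(0, raf_tot - y[25]),
           max(0, mek_tot - y[26]),
           max(0, erk_tot - y[27] - y[28]),
           max(0, ikk_tot - y[29]),
           max(0, nfkb_tot - y[32]),
           ligand, oi, cd45, 1)
    list(as.numeric(S %*% (k * v[i1] * v[i2])))
  }
}

#' Current conserved-pool totals
#'
#' Reports the material balance of each conserved pool given an explicit
#' state vector: explicit members plus the clamped conservation-implied free
#' part.  Because the free part is clamped at zero, a reported total that
#' exceeds its nominal value signals integrator overshoot of the explicit
#' members.  The BCR pool (free + ligand-bound + phospho forms +
#' internalized + receptor sequestered in Syk-bound complexes) bears a
#' degradation sink and is only non-increasing; the IkB pool carries a
#' synthesis source and degradation sinks.  Both are flagged.
#'
#' @param state Numeric state vector of length 32.
#' @param params A `bcr_params` object.
#' @return Named numeric vector of pool totals with attribute
#'   `"source_sink"` naming the flagged pools.
#' @export
conserved_totals <- function(state, params) {
  x <- stats::setNames(as.numeric(state), .species)
  tt <- params$totals
  pool <- function(members, total) {
    s <- sum(x[members]); s + max(0, total - s)
  }
  out <- c(
    Syk = pool(c("x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh"),
               tt[["Syk_total"]]),
    Lyn = pool(c("x_Lyndp", "x_LynStar"), tt[["Lyn_total"]]),
    BLNK = pool("x_BLNKp", tt[["BLNK_total"]]),
    BTK = pool(c("x_BTKb", "x_BTKp"), tt[["BTK_total"]]),
    PLC2g = pool(c("x_PLC2gb", "x_PLC2gp"), tt[["PLC2g_total"]]),
    Clathrin = pool("x_Clathrin_local", tt[["Clathrin_total"]]),
    Erk = pool(c("x_Erkp1", "x_Erkp2"), tt[["Erk_total"]]),
    MEK = pool("x_MEKp", tt[["MEK_total"]]),
    NFkB = pool("x_NFkB", tt[["NFkB_total"]]),
    BCR = sum(x[c("x_BCRfree", "x_BCRb", "x_BCRp1", "x_BCRp2", "x_BCRi",
                  "x_Sykb", "x_Syk342", "x_Syk317")]),
    IkB = sum(x[c("x_IkB", "x_IkBp")]) +
      max(0, tt[["NFkB_total"]] - x[["x_NFkB"]])
  )
  attr(out, "source_sink") <- c("BCR", "IkB")
  out
}

# Pool membership over explicit states, used for the algebraic
# stoichiometry-closure check of the ledger.  `weight` rows give each
# state's contribution to the pool.
.pool_members <- function() {
  list(
    Syk = c("x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh", "free_Syk"),
    Lyn = c("x_Lyndp", "x_LynStar", "free_Lyn"),
    SHP1 = c("x_SHP1Star", "free_SHP1"),
    Csk = c("x_CskStar", "free_Csk"),
    Cbp = c("x_Cbpp", "free_Cbp"),
    Clathrin = c("x_Clathrin_local", "free_Clathrin"),
    BLNK = c("x_BLNKp", "free_BLNK"),
    BTK = c("x_BTKb", "x_BTKp", "free_BTK"),
    PLC2g = c("x_PLC2gb", "x_PLC2gp", "free_PLC2g"),
    PIP2 = c("x_DAG", "free_PIP2"),
    PKC = c("x_PKCStar", "free_PKC"),
    SOS = c("x_SOSb", "free_SOS"),
    Ras = c("x_RasStar", "free_Ras"),
    Raf = c("x_RafStar", "free_Raf"),
    MEK = c("x_MEKp", "free_MEK"),
    Erk = c("x_Erkp1", "x_Erkp2", "free_Erk"),
    IKK = c("x_IKKStar", "free_IKK"),
    NFkB = c("x_NFkB", "complex_NFkB_IkB"),
    BCR = c("x_BCRfree", "x_BCRb", "x_BCRp1", "x_BCRp2", "x_BCRi",
            "x_Sykb", "x_Syk342", "x_Syk317"),
    IkB = c("x_IkB", "x_IkBp", "complex_NFkB_IkB")
  )
}

# Net stoichiometry of one reaction over a pool, counting the implied free /
# complex species: a reaction that consumes a free-pool factor without an
# explicit stoichiometric entry implicitly moves material out of the free
# part, and x_NFkB changes imply opposite changes of the NF-kB:IkB complex.
.pool_stoich <- function(reaction, members) {
  s <- 0
  for (m in members) {
    if (m %in% names(reaction$stoich)) {
      s <- s + reaction$stoich[[m]]
    } else if (m == "free_Syk") {
      # free Syk falls when a binding/inhibition reaction produces a Syk
      # form without consuming one, i.e. net production of explicit Syk
      # states is matched by implicit loss of free Syk.
      syk_states <- c("x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh")
      s <- s - sum(reaction$stoich[names(reaction$stoich) %in% syk_states])
    } else if (grepl("^free_", m)) {
      expl <- switch(sub("free_", "", m),
        Lyn = c("x_Lyndp", "x_LynStar"), SHP1 = "x_SHP1Star",
        Csk = "x_CskStar", Cbp = "x_Cbpp", Clathrin = "x_Clathrin_local",
        BLNK = "x_BLNKp", BTK = c("x_BTKb", "x_BTKp"),
        PLC2g = c("x_PLC2gb", "x_PLC2gp"), PIP2 = "x_DAG",
        PKC = "x_PKCStar", SOS = "x_SOSb", Ras = "x_RasStar",
        Raf = "x_RafStar", MEK = "x_MEKp", Erk = c("x_Erkp1", "x_Erkp2"),
        IKK = "x_IKKStar")
      s <- s - sum(reaction$stoich[names(reaction$stoich) %in% expl])
    } else if (m == "complex_NFkB_IkB") {
      # the complex mirrors free NF-kB exactly (NFkB_total conservation)
      s <- s - sum(reaction$stoich[names(reaction$stoich) %in% "x_NFkB"])
    }
  }
  s
}
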