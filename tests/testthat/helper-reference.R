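# Independent hand-coded transcription of the model equations, written
# directly from the printed rate laws (not assembled from the ledger), used
# as the oracle for the ledger/RHS equivalence checks.

reference_rhs <- function(x, p, L, OI, scenario = "WT") {
  r <- p$rates; tt <- p$totals; CD45 <- p$cd45
  g <- function(nm) x[[nm]]
  Syk_free <- max(0, tt[["Syk_total"]] - g("x_Sykb") - g("x_Syk342") -
                    g("x_Syk317") - g("x_Syk_inh"))
  Lyn_free <- max(0, tt[["Lyn_total"]] - g("x_Lyndp") - g("x_LynStar"))
  SHP1_free <- max(0, tt[["SHP1_total"]] - g("x_SHP1Star"))
  Csk_free <- max(0, tt[["Csk_total"]] - g("x_CskStar"))
  Cbp_free <- max(0, tt[["Cbp_total"]] - g("x_Cbpp"))
  Cla_free <- max(0, tt[["Clathrin_total"]] - g("x_Clathrin_local"))
  BLNK_free <- max(0, tt[["BLNK_total"]] - g("x_BLNKp"))
  BTK_free <- max(0, tt[["BTK_total"]] - g("x_BTKb") - g("x_BTKp"))
  PLC_free <- max(0, tt[["PLC2g_total"]] - g("x_PLC2gb") - g("x_PLC2gp"))
  PIP2_free <- max(0, tt[["PIP2_total"]] - g("x_DAG"))
  PKC_free <- max(0, tt[["PKC_total"]] - g("x_PKCStar"))
  SOS_free <- max(0, tt[["SOS_total"]] - g("x_SOSb"))
  Ras_free <- max(0, tt[["Ras_total"]] - g("x_RasStar"))
  Raf_free <- max(0, tt[["Raf_total"]] - g("x_RafStar"))
  MEK_free <- max(0, tt[["MEK_total"]] - g("x_MEKp"))
  Erk_free <- max(0, tt[["Erk_total"]] - g("x_Erkp1") - g("x_Erkp2"))
  IKK_free <- max(0, tt[["IKK_total"]] - g("x_IKKStar"))
  C <- max(0, tt[["NFkB_total"]] - g("x_NFkB"))
  aql <- scenario == "AQL"
  inh <- if (aql) r[["r_Inhibitor_association"]] * OI else 0

  d <- numeric(32); names(d) <- species_names()
  d["x_BCRfree"] <- r[["r_Recycling"]] * g("x_BCRi") -
    r[["r_Internalization"]] * g("x_Clathrin_local") * g("x_BCRfree") +
    r[["r_disassociation"]] * g("x_BCRb") -
    r[["r_association"]] * L * g("x_BCRfree")
  d["x_BCRb"] <- r[["r_association"]] * L * g("x_BCRfree") -
    r[["r_disassociation"]] * g("x_BCRb") +
    (r[["r_BCRp1_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_BCRp1_dephos_bg"]]) * g("x_BCRp1") -
    (r[["r_BCRp1_phos_Lyn"]] * g("x_LynStar") +
       r[["r_BCRp1_phos_Syk342"]] * g("x_Syk342")) * g("x_BCRb")
  d["x_BCRp1"] <- (r[["r_BCRp1_phos_Lyn"]] * g("x_LynStar") +
       r[["r_BCRp1_phos_Syk342"]] * g("x_Syk342")) * g("x_BCRb") -
    (r[["r_BCRp1_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_BCRp1_dephos_bg"]]) * g("x_BCRp1") +
    (r[["r_BCRp2_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_BCRp2_dephos_bg"]]) * g("x_BCRp2") -
    (r[["r_BCRp2_phos_Syk342"]] * g("x_Syk342") +
       r[["r_Syk_BCR_binding1"]] * Syk_free) * g("x_BCRp1")
  d["x_BCRp2"] <- r[["r_BCRp2_phos_Syk342"]] * g("x_Syk342") * g("x_BCRp1") -
    (r[["r_BCRp2_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_BCRp2_dephos_bg"]]) * g("x_BCRp2") +
    r[["r_Syk_BCR_unbinding"]] * g("x_Sykb") -
    r[["r_Syk_BCR_binding2"]] * Syk_free * g("x_BCRp2") +
    inh * (g("x_Sykb") + g("x_Syk342") + g("x_Syk317"))
  d["x_BCRi"] <- r[["r_Internalization"]] * g("x_Clathrin_local") *
    g("x_BCRfree") - r[["r_Recycling"]] * g("x_BCRi") -
    r[["r_Degradation"]] * g("x_BCRi")
  d["x_Clathrin_local"] <- r[["r_Clathrin_localization"]] * g("x_Syk342") *
    Cla_free - r[["r_Clathrin_delocalization"]] * g("x_Clathrin_local")
  d["x_Sykb"] <- (r[["r_Syk_BCR_binding1"]] * g("x_BCRp1") +
       r[["r_Syk_BCR_binding2"]] * g("x_BCRp2")) * Syk_free -
    r[["r_Syk_BCR_unbinding"]] * g("x_Sykb") +
    (r[["r_Syk342_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_Syk342_dephos_bg"]]) * g("x_Syk342") -
    (r[["r_Syk342_via_Lyn"]] * g("x_LynStar") +
       r[["r_Syk342_autophos"]] * g("x_Syk342")) * g("x_Sykb") +
    r[["r_Syk317_dephos"]] * g("x_Syk317") -
    r[["r_Syk317_phos1"]] * g("x_LynStar") * g("x_Sykb") -
    inh * g("x_Sykb")
  d["x_Syk342"] <- (r[["r_Syk342_via_Lyn"]] * g("x_LynStar") +
       r[["r_Syk342_autophos"]] * g("x_Syk342")) * g("x_Sykb") -
    (r[["r_Syk342_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_Syk342_dephos_bg"]]) * g("x_Syk342") +
    r[["r_Syk317_dephos"]] * g("x_Syk317") -
    r[["r_Syk317_phos2"]] * g("x_LynStar") * g("x_Syk342") -
    inh * g("x_Syk342")
  d["x_Syk317"] <- (r[["r_Syk317_phos1"]] * g("x_Sykb") +
       r[["r_Syk317_phos2"]] * g("x_Syk342")) * g("x_LynStar") -
    2 * r[["r_Syk317_dephos"]] * g("x_Syk317") - inh * g("x_Syk317")
  d["x_Syk_inh"] <- inh * (g("x_Sykb") + g("x_Syk342") + g("x_Syk317") +
                             Syk_free)
  d["x_Lyndp"] <- r[["r_Lyn_dephos_CD45"]] * CD45 * Lyn_free -
    r[["r_Lyn_phos_Csk"]] * g("x_CskStar") * g("x_Lyndp") +
    (r[["r_Lyn_deauto_CD45"]] * CD45 +
       r[["r_Lyn_deauto_SHP1"]] * g("x_SHP1Star") +
       r[["r_Lyn_deauto_bg"]]) * g("x_LynStar") -
    (r[["r_LynStar_phos"]] +
       r[["r_LynStar_autophos"]] * g("x_LynStar")) * g("x_Lyndp")
  d["x_LynStar"] <- (r[["r_LynStar_phos"]] +
       r[["r_LynStar_autophos"]] * g("x_LynStar")) * g("x_Lyndp") -
    (r[["r_Lyn_deauto_CD45"]] * CD45 +
       r[["r_Lyn_deauto_SHP1"]] * g("x_SHP1Star") +
       r[["r_Lyn_deauto_bg"]]) * g("x_LynStar")
  d["x_SHP1Star"] <- r[["r_SHP1_activation"]] * g("x_Lyndp") * SHP1_free -
    r[["r_SHP1_inactivation"]] * g("x_SHP1Star")
  d["x_CskStar"] <- r[["r_Csk_activation"]] * g("x_Cbpp") * Csk_free -
    r[["r_Csk_disassociation"]] * g("x_CskStar")
  d["x_Cbpp"] <- r[["r_Cbp_phos"]] * g("x_Lyndp") * Cbp_free -
    r[["r_Cbp_dephos_CD45"]] * CD45 * g("x_Cbpp")
  d["x_BLNKp"] <- r[["r_BLNK_phos_Syk342"]] * g("x_Syk342") * BLNK_free -
    (r[["r_BLNK_dephos_SHP1"]] * g("x_SHP1Star") +
       r[["r_BLNK_dephos_bg"]]) * g("x_BLNKp")
  d["x_BTKb"] <- r[["r_BTK_BLNK_binding"]] * BTK_free * g("x_BLNKp") -
    r[["r_BTK_BLNK_unbinding"]] * g("x_BTKb") -
    (r[["r_BTK_phos_Syk342"]] * g("x_Syk342") +
       r[["r_BTK_phos_Lyn"]] * g("x_LynStar")) * g("x_BTKb") +
    r[["r_BTK_dephos"]] * g("x_BTKp")
  d["x_BTKp"] <- (r[["r_BTK_phos_Syk342"]] * g("x_Syk342") +
       r[["r_BTK_phos_Lyn"]] * g("x_LynStar")) * g("x_BTKb") -
    r[["r_BTK_dephos"]] * g("x_BTKp")
  d["x_PLC2gb"] <- r[["r_PLC2g_BLNK_binding"]] * PLC_free * g("x_BLNKp") -
    r[["r_PLC2g_BLNK_unbinding"]] * g("x_PLC2gb") -
    (r[["r_PLC2g_phos_Syk342"]] * g("x_Syk342") +
       r[["r_PLC2g_phos_BTK"]] * g("x_BTKp")) * g("x_PLC2gb") +
    r[["r_PLC2g_dephos"]] * g("x_PLC2gp")
  d["x_PLC2gp"] <- (r[["r_PLC2g_phos_Syk342"]] * g("x_Syk342") +
       r[["r_PLC2g_phos_BTK"]] * g("x_BTKp")) * g("x_PLC2gb") -
    r[["r_PLC2g_dephos"]] * g("x_PLC2gp")
  d["x_DAG"] <- r[["r_DAG_production"]] * g("x_PLC2gp") * PIP2_free -
    r[["r_DAG_removal"]] * g("x_DAG")
  d["x_PKCStar"] <- r[["r_PKC_activation"]] * g("x_DAG") * PKC_free -
    r[["r_PKC_deactivation"]] * g("x_PKCStar")
  d["x_SOSb"] <- r[["r_SOS_BLNK_binding"]] * SOS_free * g("x_BLNKp") -
    r[["r_SOS_BLNK_unbinding"]] * g("x_SOSb")
  d["x_RasStar"] <- r[["r_Ras_activation"]] * g("x_SOSb") * Ras_free -
    r[["r_Ras_deactivation"]] * g("x_RasStar")
  d["x_RafStar"] <- r[["r_Raf_activation"]] * g("x_RasStar") * Raf_free -
    r[["r_Raf_deactivation"]] * g("x_RafStar")
  d["x_MEKp"] <- r[["r_MEK_phos"]] * g("x_RafStar") * MEK_free -
    r[["r_MEK_dephos"]] * g("x_MEKp")
  d["x_Erkp1"] <- r[["r_Erk_phos_MEK"]] * g("x_MEKp") * Erk_free -
    r[["r_Erk_phos_MEK"]] * g("x_MEKp") * g("x_Erkp1") +
    r[["r_Erkp2_dephos"]] * g("x_Erkp2") -
    r[["r_Erkp1_dephos"]] * g("x_Erkp1")
  d["x_Erkp2"] <- r[["r_Erk_phos_MEK"]] * g("x_MEKp") * g("x_Erkp1") -
    r[["r_Erkp2_dephos"]] * g("x_Erkp2")
  d["x_IKKStar"] <- r[["r_IKK_activation"]] * g("x_PKCStar") * IKK_free -
    r[["r_IKK_deactivation"]] * g("x_IKKStar")
  d["x_IkB"] <- r[["r_IkB_synthesis"]] * g("x_NFkB") -
    r[["r_IkB_NFkB_association"]] * g("x_IkB") * g("x_NFkB") -
    r[["r_IkB_degradation"]] * g("x_IkB")
  d["x_IkBp"] <- r[["r_IkB_phos_IKK"]] * g("x_IKKStar") * C -
    r[["r_IkBp_degradation"]] * g("x_IkBp")
  d["x_NFkB"] <- r[["r_IkB_phos_IKK"]] * g("x_IKKStar") * C -
    r[["r_IkB_NFkB_association"]] * g("x_IkB") * g("x_NFkB")
  d
}

# Random nonnegative state with every pool respecting its total.
random_state <- function(p, seed) {
  set.seed(seed)
  tt <- p$totals
  part <- function(total, k) {
    w <- stats::runif(k + 1)
    (w / sum(w) * total * stats::runif(1))[seq_len(k)]
  }
  x <- species_state()
  x[c("x_BCRfree", "x_BCRb", "x_BCRp1", "x_BCRp2", "x_BCRi")] <-
    part(tt[["BCR_total"]] * 0.6, 5)
  x[c("x_Sykb", "x_Syk342", "x_Syk317", "x_Syk_inh")] <-
    part(tt[["Syk_total"]], 4)
  x[c("x_Lyndp", "x_LynStar")] <- part(tt[["Lyn_total"]], 2)
  x["x_SHP1Star"] <- part(tt[["SHP1_total"]], 1)
  x["x_CskStar"] <- part(tt[["Csk_total"]], 1)
  x["x_Cbpp"] <- part(tt[["Cbp_total"]], 1)
  x["x_Clathrin_local"] <- part(tt[["Clathrin_total"]], 1)
  x["x_BLNKp"] <- part(tt[["BLNK_total"]], 1)
  x[c("x_BTKb", "x_BTKp")] <- part(tt[["BTK_total"]], 2)
  x[c("x_PLC2gb", "x_PLC2gp")] <- part(tt[["PLC2g_total"]], 2)
  x["x_DAG"] <- part(tt[["PIP2_total"]], 1)
  x["x_PKCStar"] <- part(tt[["PKC_total"]], 1)
  x["x_SOSb"] <- part(tt[["SOS_total"]], 1)
  x["x_RasStar"] <- part(tt[["Ras_total"]], 1)
  x["x_RafStar"] <- part(tt[["Raf_total"]], 1)
  x["x_MEKp"] <- part(tt[["MEK_total"]], 1)
  x[c("x_Erkp1", "x_Erkp2")] <- part(tt[["Erk_total"]], 2)
  x["x_IKKStar"] <- part(tt[["IKK_total"]], 1)
  x["x_IkB"] <- stats::runif(1, 0, 2)
  x["x_IkBp"] <- stats::runif(1, 0, 2)
  x["x_NFkB"] <- part(tt[["NFkB_total"]], 1)
  x
}

# Random perturbation of the nominal vector over the screened rates.
random_params <- function(seed, decades = 1, which = names(param_aliases())) {
  set.seed(seed)
  p <- default_params()
  off <- stats::setNames(stats::runif(length(which), -decades, decades),
                         which)
  params_apply_offsets(p, off)
}

# Synthetic response surface with a known metric function of
# (log10 kf, log10 kr).
make_surface <- function(g, n = 25, lkf = seq(-2, 2, length.out = n),
                         lkr = seq(-2, 2, length.out = n)) {
  m <- outer(lkf, lkr, g)
  structure(list(log10_kf = lkf, log10_kr = lkr, metric = m,
                 raw_erkp = m, raw_nfkb = m * 0,
                 halted = matrix(FALSE, length(lkf), length(lkr)),
                 normalizers = c(Erkp = 1, NFkB = 1), scenario = "WT",
                 oi_dose = 0, dose = 20),
            class = "bcr_surface")
}
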