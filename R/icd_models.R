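# Shipped models of immunogenic cell death (ICD).
#
# Both models describe a mixed cell population (tumour cells, dendritic
# cells, T cells) after an ICD-inducing chemotherapy. Each simulated
# "cell" is one Boolean network state; cell identity is encoded by input
# nodes (TumorCell, DC, ...) and intercellular signals travel through
# population-updated rate parameters (a receptor's activation rate is
# proportional to the population probability of its ligand).
#
# Rate conventions: a process with reported mean time T gets rate 1/T
# (1/h); a species with reported half-life H gets rate ln(2)/H.

#' Bundle of a network, initial condition and cell-type map
#'
#' @param network A [bp_network()].
#' @param initial A [bp_initial_condition()].
#' @param celltypes Named list of Boolean state predicates (strings).
#' @param settings Named numeric simulation settings (`time_step`, `horizon`).
#' @param builder Function `(params) -> bp_model` that rebuilds the model
#'   from a full parameter vector (used by the sensitivity scan so that
#'   initial-composition parameters take effect).
#' @return An object of class `bp_model`.
#' @export
bp_model <- function(network, initial, celltypes = list(),
                     settings = numeric(0), builder = NULL) {
  structure(list(network = network, initial = initial, celltypes = celltypes,
                 settings = settings, builder = builder),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  print(x$network)
  cat(sprintf("  %d cell-type predicates; settings: %s\n", length(x$celltypes),
              paste(sprintf("%s=%g", names(x$settings), x$settings), collapse = ", ")))
  invisible(x)
}

#' Phenomenological ICD model
#'
#' Thirteen nodes covering three cell types: tumour cells (TumorCell,
#' DyingTumorCell), dendritic cells (DC, ActDC, MigrDC, LNodeDC) and T
#' cells (TCell, CTL), plus the danger signals CALR, ATP, HMGB1 and the
#' population nodes Death and Division. Nineteen rate parameters, of which
#' five are population-updated (initially 0): the sensed danger-signal
#' levels, the lymph-node DC level driving T-cell priming, and the CTL
#' level driving tumour killing.
#'
#' Timings: danger-signal exposure at mean 4 h (CALR, ATP) and 6 h (HMGB1)
#' after a cell starts dying; DC transit to the lymph node 5 days in total
#' (split evenly over the ActDC -> MigrDC and MigrDC -> LNodeDC steps);
#' T-cell differentiation into CTL 2 days;
#' tumour division every 10 days, CTL clonal expansion every 12 h; a tumour
#' cell fully surrounded by CTLs dies within 1 h; direct cytotoxicity of
#' the drug acts on a 50,000 h scale ("low").
#'
#' @param params Optional named overrides of the default parameters
#'   (including the initial composition `InitTumor`, `InitDC`, `InitT`,
#'   which are normalized to sum to 1).
#' @return A [bp_model()].
#' @export
build_phenomenological <- function(params = NULL) {
  defaults <- c(
    rate_dying = 1,        # ICD induction: mean 1 h after treatment
    u_CALR = 1 / 4,
    u_ATP = 1 / 4,
    u_HMGB1 = 1 / 6,
    u_ActDC = 0.15,        # scale of DC activation by sensed danger signals
    u_MigrDC = 1 / 60,     # 5-day tumour-to-lymph-node transit, split into
    u_LNodeDC = 1 / 60,    #   two 60 h stages (sharper arrival than one step)
    u_TCell = 0.115,       # scale of T-cell priming by lymph-node DCs
    u_CTL = 1 / 48,        # 2-day differentiation into CTL
    div_tumor = 1 / 240,   # 10-day tumour division
    clonal_exp_rate = 1 / 12, # CTL division every 12 h
    kill = 0.7,            # tumour kill per unit CTL population probability
    direct_cyt = 1 / 50000,
    d_CTL = 1 / 12,        # effector CTL turnover balancing its division
    # population-updated (initially 0)
    CALR_pop = 0, ATP_pop = 0, HMGB1_pop = 0, LNodeDC_pop = 0, CTL_pop = 0,
    # initial composition (not transition rates; kept outside the 19)
    InitTumor = 0.8, InitDC = 0.1, InitT = 0.1
  )
  pv <- bp_override(defaults, params)

  nodes <- list(
    bp_node("TumorCell"),
    bp_node("DyingTumorCell", rate_up = "TumorCell ? $rate_dying : 0"),
    bp_node("CALR", rate_up = "DyingTumorCell ? $u_CALR : 0"),
    bp_node("ATP", rate_up = "DyingTumorCell ? $u_ATP : 0"),
    bp_node("HMGB1", rate_up = "DyingTumorCell ? $u_HMGB1 : 0"),
    bp_node("DC"),
    bp_node("ActDC",
            rate_up = "DC ? $u_ActDC * ($CALR_pop + $ATP_pop + $HMGB1_pop) : 0"),
    bp_node("MigrDC", rate_up = "ActDC ? $u_MigrDC : 0"),
    bp_node("LNodeDC", rate_up = "MigrDC ? $u_LNodeDC : 0"),
    bp_node("TCell", rate_up = "(!TumorCell & !DC) ? $u_TCell * $LNodeDC_pop : 0"),
    bp_node("CTL", rate_up = "TCell ? $u_CTL : 0"),
    bp_node("Death",
            rate_up = paste("TumorCell ? $kill * $CTL_pop +",
                            "(DyingTumorCell ? $direct_cyt : 0) :",
                            "(CTL ? $d_CTL : 0)")),
    bp_node("Division",
            rate_up = paste("(TumorCell & !DyingTumorCell) ? $div_tumor :",
                            "(CTL ? $clonal_exp_rate : 0)"))
  )
  rate_params <- pv[setdiff(names(pv), c("InitTumor", "InitDC", "InitT"))]
  net <- bp_network(nodes, params = rate_params,
                    death = "Death", division = "Division",
                    update_rules = list(
                      CALR_pop = "p(CALR)",
                      ATP_pop = "p(ATP)",
                      HMGB1_pop = "p(HMGB1)",
                      LNodeDC_pop = "p(LNodeDC)",
                      CTL_pop = "p(CTL)"))
  mix <- pv[c("InitTumor", "InitDC", "InitT")]
  mix <- mix / sum(mix)
  init <- bp_initial_condition(
    list(prob = mix[["InitTumor"]], pattern = c(TumorCell = 1L)),
    list(prob = mix[["InitDC"]], pattern = c(DC = 1L)),
    list(prob = mix[["InitT"]], pattern = integer(0)))  # naive T: all nodes 0
  celltypes <- list(
    Tumor = "TumorCell",
    DyingTumor = "TumorCell & DyingTumorCell",
    DC = "DC",
    ActDC = "ActDC",
    MigrDC = "MigrDC",
    LNodeDC = "LNodeDC",
    TCell = "TCell & !CTL",
    CTL = "CTL")
  bp_model(net, init, celltypes,
           settings = c(time_step = 2, horizon = 300),
           builder = function(params) build_phenomenological(params))
}

bp_override <- function(defaults, params) {
  if (is.null(params)) return(defaults)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults[names(params)] <- params
  defaults
}

#' Extended ICD model
#'
#' Fifty-seven entities covering four cell types (tumour cells, dendritic
#' cells, CD4+ and CD8+ T cells) with explicit ligand/receptor pairs
#' (cytokines as `*_o` nodes, receptors as `*_rec` nodes) and 98
#' parameters, of which 20 are updated at the population level and start
#' at 0 (receptor activation rates driven by ligand probabilities, the
#' perforin-mediated kill amplification, and contact-dependent perforin
#' loss).
#'
#' Adopted timings: protein mean activation 6 h (ATP and CALR 4 h);
#' protein mean degradation 12 min; fast cell-state activation 12 min for
#' aDC, cd4_Act, Th1/Th2/Th17/Treg and preCTL; CTL activation 2.4 h; tumour
#' mean division 100,000 h; chemotherapy half-life 3 days; ICD induction
#' 1 h after drug delivery; direct-cytotoxicity clearance scale 50,000 h;
#' lymphocyte division during clonal expansion 20 h (`clonal_exp_rate` =
#' 0.05); a tumour cell fully surrounded by perforin-armed CTLs dies in
#' 1 h; a CTL surrounded by tumour cells loses its perforin in 6 h; CTL
#' death after 10 days. Initial mix 80% tumour / 10% DC / 5% CD4 / 5% CD8
#' (`InitDC` = 0.1).
#'
#' @param params Optional named overrides (initial-composition parameters
#'   are normalized to sum to 1).
#' @return A [bp_model()].
#' @export
build_extended <- function(params = NULL) {
  defaults <- c(
    # activation rates (1/h)
    u_DyingTumorCell = 1,
    u_CALR = 1 / 4, u_ATP = 1 / 4, u_ANXA1 = 1 / 6, u_HMGB1 = 1 / 6,
    u_Antigen = 1 / 6, u_IFN1 = 1 / 6, u_CXCL10 = 1 / 6,
    u_aDC = 5, u_AgUptake = 1 / 6, u_CCR7 = 1 / 6,
    u_MHC_I = 1 / 6, u_MHC_II = 1 / 6, u_CD80 = 1 / 6, u_CD40 = 1 / 6,
    u_CD86 = 1 / 6,
    u_IL12 = 1 / 6, u_IL6 = 1 / 6, u_IL1B = 1 / 6, u_TNFa = 1 / 6,
    u_IL2 = 1 / 6, u_IL4 = 1 / 6, u_IFNg = 1 / 6, u_TGFb = 1 / 6,
    u_cd4_Act = 5, u_Th1 = 5, u_Th2 = 5, u_Th17 = 5, u_Treg = 5,
    u_preCTL = 5, u_CTL = 1 / 2.4, u_Perforin = 1 / 6,
    # degradation / decay rates (1/h)
    d_IFN1 = 5, d_CXCL10 = 5, d_IL12 = 5, d_IL6 = 5, d_IL1B = 5,
    d_TNFa = 5, d_IL2 = 5, d_IL4 = 5, d_IFNg = 5, d_TGFb = 5,
    d_ATP = 5,                      # extracellular ATP is hydrolysed fast
    d_CALR = 1 / 24, d_ANXA1 = 1 / 24, d_HMGB1 = 1 / 24, d_Antigen = 1 / 24,
    d_ChemoT = log(2) / 72,         # 3-day half-life in tumour tissue
    d_CTL = 1 / 240,                # CTL death after 10 days
    # receptor coupling scales (rate per unit ligand probability)
    s_P2X7R = 1, s_P2Y2R = 1, s_TLR4 = 1, s_FPR1 = 1, s_LRP1 = 0.05,
    s_IFN1_rec = 2, s_CXCR3 = 2, s_CD28 = 0.2, s_TCR_I = 1, s_TCR_II = 1,
    s_IL2_rec = 2, s_IL4_rec = 10, s_IL6_rec = 10, s_IL12_rec = 10,
    s_IL1B_rec = 10, s_TGFb_rec = 10, s_IFNg_rec = 2, s_TNFa_rec = 1,
    # cytokine-production enhancement by co-signals
    amp_IFNg = 2, amp_IL2 = 2,
    # population kill / perforin-loss scales
    kill_full = 1, perf_loss_full = 1 / 6,
    # cell dynamics
    u_TumorDiv = 1e-5, clonal_exp_rate = 0.05, direct_cyt = 1 / 50000,
    # initial composition
    InitTumor = 0.8, InitDC = 0.1, Initcd4 = 0.05, Initcd8 = 0.05,
    # population-updated parameters, initially 0
    k_P2X7R = 0, k_P2Y2R = 0, k_TLR4 = 0, k_FPR1 = 0, k_LRP1 = 0,
    k_IFN1_rec = 0, k_CXCR3 = 0, k_CD28 = 0, k_TCR_I = 0, k_TCR_II = 0,
    k_IL2_rec = 0, k_IL4_rec = 0, k_IL6_rec = 0, k_IL12_rec = 0,
    k_IL1B_rec = 0, k_TGFb_rec = 0, k_IFNg_rec = 0, k_TNFa_rec = 0,
    k_kill = 0, k_perf_loss = 0
  )
  pv <- bp_override(defaults, params)

  nodes <- list(
    # inputs
    bp_node("TumorCell"),
    bp_node("DC"),
    bp_node("cd4"),
    bp_node("cd8"),
    bp_node("ChemoT", rate_down = "$d_ChemoT"),
    # tumour side: dying state, DAMPs, antigen, interferon response
    bp_node("DyingTumorCell", rate_up = "(TumorCell & ChemoT) ? $u_DyingTumorCell : 0"),
    bp_node("CALR", rate_up = "DyingTumorCell ? $u_CALR : 0", rate_down = "$d_CALR"),
    bp_node("ATP", rate_up = "DyingTumorCell ? $u_ATP : 0", rate_down = "$d_ATP"),
    bp_node("ANXA1", rate_up = "DyingTumorCell ? $u_ANXA1 : 0", rate_down = "$d_ANXA1"),
    # HMGB1 release requires ANXA1 already in the milieu
    bp_node("HMGB1", rate_up = "(DyingTumorCell & ANXA1) ? $u_HMGB1 : 0",
            rate_down = "$d_HMGB1"),
    bp_node("Antigen", rate_up = "DyingTumorCell ? $u_Antigen : 0",
            rate_down = "$d_Antigen"),
    bp_node("IFN1_o", rate_up = "DyingTumorCell ? $u_IFN1 : 0", rate_down = "$d_IFN1"),
    bp_node("IFN1_rec", rate_up = "(TumorCell | DC) ? $k_IFN1_rec : 0"),
    bp_node("CXCL10_o", rate_up = "((TumorCell | aDC) & IFN1_rec) ? $u_CXCL10 : 0",
            rate_down = "$d_CXCL10"),
    # dendritic cell: DAMP receptors, activation, maturation
    bp_node("P2X7R", rate_up = "DC ? $k_P2X7R : 0"),
    bp_node("P2Y2R", rate_up = "DC ? $k_P2Y2R : 0"),
    bp_node("TLR4", rate_up = "DC ? $k_TLR4 : 0"),
    bp_node("FPR1", rate_up = "DC ? $k_FPR1 : 0"),
    bp_node("LRP1", rate_up = "DC ? $k_LRP1 : 0"),
    bp_node("aDC", rate_up = "(DC & P2X7R) ? $u_aDC : 0"),
    bp_node("AgUptake", rate_up = "(aDC & LRP1) ? $u_AgUptake : 0"),
    bp_node("CCR7", rate_up = "aDC ? $u_CCR7 : 0"),
    bp_node("MHC_I", rate_up = "(aDC & AgUptake & CCR7) ? $u_MHC_I : 0"),
    bp_node("MHC_II", rate_up = "(aDC & AgUptake & CCR7) ? $u_MHC_II : 0"),
    bp_node("CD80", rate_up = "(aDC & AgUptake & CCR7) ? $u_CD80 : 0"),
    bp_node("CD40", rate_up = "(aDC & AgUptake & CCR7) ? $u_CD40 : 0"),
    bp_node("CD86", rate_up = "(aDC & AgUptake & CCR7) ? $u_CD86 : 0"),
    bp_node("IL12_o", rate_up = "aDC ? $u_IL12 : 0", rate_down = "$d_IL12"),
    bp_node("IL6_o", rate_up = "aDC ? $u_IL6 : 0", rate_down = "$d_IL6"),
    bp_node("IL1B_o", rate_up = "aDC ? $u_IL1B : 0", rate_down = "$d_IL1B"),
    bp_node("TNFa_o", rate_up = "aDC ? $u_TNFa : 0", rate_down = "$d_TNFa"),
    bp_node("TNFa_rec", rate_up = "TumorCell ? $k_TNFa_rec : 0"),
    # T-cell surface receptors
    bp_node("CXCR3", rate_up = "(cd4 | cd8) ? $k_CXCR3 : 0"),
    bp_node("CD28", rate_up = "((cd4 | cd8) & CXCR3) ? $k_CD28 : 0"),
    bp_node("TCR_II", rate_up = "(CD28 & cd4) ? $k_TCR_II : 0"),
    bp_node("TCR_I", rate_up = "(CD28 & cd8) ? $k_TCR_I : 0"),
    # CD4 lineage
    bp_node("cd4_Act", rate_up = "(cd4 & TCR_II & CD28) ? $u_cd4_Act : 0"),
    bp_node("Th1", rate_up = "(cd4_Act & IL12_rec) ? $u_Th1 : 0"),
    bp_node("Th2", rate_up = "(cd4_Act & IL4_rec) ? $u_Th2 : 0"),
    bp_node("Th17", rate_up = "(cd4_Act & IL6_rec & TGFb_rec & IL1B_rec) ? $u_Th17 : 0"),
    bp_node("Treg", rate_up = "(cd4_Act & TGFb_rec) ? $u_Treg : 0"),
    # cytokines secreted by T cells and DCs
    bp_node("IL2_o",
            rate_up = paste("(aDC | cd4_Act | Th1 | Th2) ?",
                            "$u_IL2 * (((cd4_Act | Th1 | Th2) & CD28) ? $amp_IL2 : 1) : 0"),
            rate_down = "$d_IL2"),
    bp_node("IL4_o", rate_up = "(cd4_Act | Th2 | preCTL) ? $u_IL4 : 0",
            rate_down = "$d_IL4"),
    bp_node("IFNg_o",
            rate_up = paste("(cd4_Act | Th1 | CTL) ?",
                            "$u_IFNg * (IL12_rec ? $amp_IFNg : 1) : 0"),
            rate_down = "$d_IFNg"),
    bp_node("TGFb_o", rate_up = "(TumorCell | Treg) ? $u_TGFb : 0",
            rate_down = "$d_TGFb"),
    # cytokine receptors
    bp_node("IL2_rec", rate_up = "(cd4_Act | preCTL) ? $k_IL2_rec : 0"),
    bp_node("IL4_rec", rate_up = "cd4_Act ? $k_IL4_rec : 0"),
    bp_node("IL6_rec", rate_up = "cd4_Act ? $k_IL6_rec : 0"),
    bp_node("IL12_rec", rate_up = "cd4_Act ? $k_IL12_rec : 0"),
    bp_node("IL1B_rec", rate_up = "cd4_Act ? $k_IL1B_rec : 0"),
    bp_node("TGFb_rec", rate_up = "cd4_Act ? $k_TGFb_rec : 0"),
    bp_node("IFNg_rec", rate_up = "preCTL ? $k_IFNg_rec : 0"),
    # CD8 lineage
    bp_node("preCTL", rate_up = "(cd8 & TCR_I & CD28) ? $u_preCTL : 0"),
    bp_node("CTL", rate_up = "(preCTL & TCR_I & (IFNg_rec | IL2_rec)) ? $u_CTL : 0"),
    bp_node("Perforin", rate_up = "CTL ? $u_Perforin : 0",
            rate_down = "$k_perf_loss"),
    # population fates
    bp_node("Death",
            rate_up = paste("TumorCell ? $k_kill + (DyingTumorCell ? $direct_cyt : 0) :",
                            "(CTL ? $d_CTL : 0)")),
    bp_node("Division",
            rate_up = paste("(TumorCell & !DyingTumorCell) ? $u_TumorDiv :",
                            "((cd4_Act | Th1 | Th2 | Th17 | Treg | preCTL | CTL) ?",
                            "$clonal_exp_rate : 0)"))
  )

  # the initial-composition parameters are part of the model's 98-parameter
  # set (and of the sensitivity scan), even though no rate expression reads
  # them: they enter through the initial condition below
  net <- bp_network(nodes, params = pv,
                    death = "Death", division = "Division",
                    update_rules = list(
                      k_P2X7R = "$s_P2X7R * p(ATP)",
                      k_P2Y2R = "$s_P2Y2R * p(ATP)",
                      k_TLR4 = "$s_TLR4 * p(HMGB1)",
                      k_FPR1 = "$s_FPR1 * p(ANXA1)",
                      k_LRP1 = "$s_LRP1 * p(CALR)",
                      k_IFN1_rec = "$s_IFN1_rec * p(IFN1_o)",
                      k_CXCR3 = "$s_CXCR3 * p(CXCL10_o)",
                      k_CD28 = "$s_CD28 * p(CD80)",
                      k_TCR_I = "$s_TCR_I * p(MHC_I)",
                      k_TCR_II = "$s_TCR_II * p(MHC_II)",
                      k_IL2_rec = "$s_IL2_rec * p(IL2_o)",
                      k_IL4_rec = "$s_IL4_rec * p(IL4_o)",
                      k_IL6_rec = "$s_IL6_rec * p(IL6_o)",
                      k_IL12_rec = "$s_IL12_rec * p(IL12_o)",
                      k_IL1B_rec = "$s_IL1B_rec * p(IL1B_o)",
                      k_TGFb_rec = "$s_TGFb_rec * p(TGFb_o)",
                      k_IFNg_rec = "$s_IFNg_rec * p(IFNg_o)",
                      k_TNFa_rec = "$s_TNFa_rec * p(TNFa_o)",
                      k_kill = "$kill_full * p(CTL & Perforin)",
                      k_perf_loss = "$perf_loss_full * p(TumorCell)"))
  mix <- pv[c("InitTumor", "InitDC", "Initcd4", "Initcd8")]
  mix <- mix / sum(mix)
  init <- bp_initial_condition(
    list(prob = mix[["InitTumor"]], pattern = c(TumorCell = 1L, ChemoT = 1L)),
    list(prob = mix[["InitDC"]], pattern = c(DC = 1L)),
    list(prob = mix[["Initcd4"]], pattern = c(cd4 = 1L)),
    list(prob = mix[["Initcd8"]], pattern = c(cd8 = 1L)))
  celltypes <- list(
    Tumor = "TumorCell",
    DyingTumor = "TumorCell & DyingTumorCell",
    DC = "DC",
    aDC = "aDC",                       # aDC implies DC
    cd4_naive = "cd4 & !cd4_Act",
    cd4_Act = "cd4_Act",
    Th1 = "Th1", Th2 = "Th2", Th17 = "Th17", Treg = "Treg",
    cd8_naive = "cd8 & !preCTL",
    preCTL = "preCTL & !CTL",
    CTL = "CTL")
  bp_model(net, init, celltypes,
           settings = c(time_step = 2, horizon = 300),
           builder = function(params) build_extended(params))
}

# --- scenarios ---------------------------------------------------------------

#' Intervention scenario
#'
#' A named list of edits applied on top of a base model. Edit types:
#' `clamp_off` (force a node's activation rate to 0), `clamp_on` (zero the
#' deactivation rate and start the node ON in every initial pattern),
#' `scale_param` (multiply a parameter by `factor`), `set_param`, and
#' `set_rate_up` (replace a node's activation-rate expression).
#'
#' @param name Scenario name.
#' @param edits List of edits, each a `list(type = , ...)`.
#' @return An object of class `bp_scenario`.
#' @export
bp_scenario <- function(name, edits) {
  structure(list(name = name, edits = edits), class = "bp_scenario")
}

#' Built-in intervention scenarios
#'
#' * `cd28_ko` — complete CD28 knock-out: the CD28 node can never activate,
#'   so T-cell priming (and hence the whole adaptive response) is abolished.
#' * `il2_treatment` — exogenous IL-2: the IL-2 ligand node activates
#'   everywhere at five times its basal production rate, mimicking the
#'   strongest beneficial perturbation of the factor-5 scan.
#' * `no_clonal_expansion` — zeroes the lymphocyte division rate
#'   (phenomenological and extended).
#'
#' @return Named list of [bp_scenario()] objects.
#' @export
icd_scenarios <- function() {
  list(
    cd28_ko = bp_scenario("cd28_ko",
      list(list(type = "clamp_off", node = "CD28"))),
    il2_treatment = bp_scenario("il2_treatment",
      list(list(type = "set_rate_up", node = "IL2_o", expr = "5 * $u_IL2"))),
    no_clonal_expansion = bp_scenario("no_clonal_expansion",
      list(list(type = "set_param", param = "clonal_exp_rate", value = 0)))
  )
}

#' Apply a scenario to a model
#'
#' The original expressions/values of every edited component are stored in
#' the result (`attr(, "reverted")`), and [revert_scenario()] restores the
#' base model exactly.
#'
#' @param model A [bp_model()].
#' @param scenario A [bp_scenario()] (or a name from [icd_scenarios()]).
#' @return The edited [bp_model()].
#' @export
apply_scenario <- function(model, scenario) {
  if (is.character(scenario)) {
    all <- icd_scenarios()
    if (!scenario %in% names(all))
      stop(sprintf("unknown scenario '%s'; available: %s", scenario,
                   paste(names(all), collapse = ", ")), call. = FALSE)
    scenario <- all[[scenario]]
  }
  net <- model$network
  init <- model$initial
  reverted <- list()
  for (e in scenario$edits) {
    if (e$type %in% c("clamp_off", "clamp_on", "set_rate_up")) {
      if (!e$node %in% names(net$nodes))
        stop(sprintf("scenario edit targets missing node '%s'", e$node), call. = FALSE)
    }
    if (e$type %in% c("scale_param", "set_param")) {
      if (!e$param %in% names(net$params))
        stop(sprintf("scenario edit targets missing parameter '$%s'", e$param),
             call. = FALSE)
    }
    switch(e$type,
      clamp_off = {
        reverted[[length(reverted) + 1L]] <-
          list(what = "rate_up", node = e$node, old = net$nodes[[e$node]]$rate_up)
        net$nodes[[e$node]]$rate_up <- list(kind = "num", value = 0)
      },
      clamp_on = {
        reverted[[length(reverted) + 1L]] <-
          list(what = "rate_down", node = e$node, old = net$nodes[[e$node]]$rate_down,
               old_init = init)
        net$nodes[[e$node]]$rate_down <- list(kind = "num", value = 0)
        atoms <- lapply(init$atoms, function(a) {
          a$pattern[e$node] <- 1L
          a
        })
        init <- bp_initial_condition(atoms)
      },
      scale_param = {
        reverted[[length(reverted) + 1L]] <-
          list(what = "param", param = e$param, old = net$params[[e$param]])
        net$params[[e$param]] <- net$params[[e$param]] * e$factor
      },
      set_param = {
        reverted[[length(reverted) + 1L]] <-
          list(what = "param", param = e$param, old = net$params[[e$param]])
        net$params[[e$param]] <- e$value
      },
      set_rate_up = {
        reverted[[length(reverted) + 1L]] <-
          list(what = "rate_up", node = e$node, old = net$nodes[[e$node]]$rate_up)
        net$nodes[[e$node]]$rate_up <- bp_as_ast(e$expr)
      },
      stop(sprintf("unknown edit type '%s'", e$type), call. = FALSE)
    )
  }
  bp_validate_network(net)
  out <- bp_model(net, init, model$celltypes, model$settings, model$builder)
  attr(out, "reverted") <- reverted
  attr(out, "scenario") <- scenario$name
  out
}

#' Restore the base model after [apply_scenario()]
#' @param model A model returned by [apply_scenario()].
#' @return The base [bp_model()].
#' @export
revert_scenario <- function(model) {
  reverted <- attr(model, "reverted")
  if (is.null(reverted)) return(model)
  net <- model$network
  init <- model$initial
  for (r in rev(reverted)) {
    switch(r$what,
      rate_up = net$nodes[[r$node]]$rate_up <- r$old,
      rate_down = {
        net$nodes[[r$node]]$rate_down <- r$old
        init <- r$old_init
      },
      param = net$params[[r$param]] <- r$old)
  }
  bp_model(net, init, model$celltypes, model$settings, model$builder)
}

# --- running and summarising -------------------------------------------------

#' Run a shipped model's population simulation
#'
#' Convenience wrapper around [run_population()] that uses the model's
#' initial condition, cell-type predicates and settings.
#'
#' @param model A [bp_model()].
#' @param dt,n_windows Window length and count; default from the model
#'   settings (`time_step`, `horizon`).
#' @param n_traj Particles per window.
#' @param seed Integer seed.
#' @param params Optional parameter overrides.
#' @return A `bp_pop_timecourse` (see [run_population()]).
#' @export
run_icd <- function(model, dt = NULL, n_windows = NULL, n_traj = 5000,
                    seed = 1, params = NULL) {
  if (is.null(dt)) dt <- model$settings[["time_step"]]
  if (is.null(n_windows)) n_windows <- round(model$settings[["horizon"]] / dt)
  run_population(model$network, model$initial, dt = dt, n_windows = n_windows,
                 n_traj = n_traj, seed = seed, params = params,
                 predicates = model$celltypes)
}

#' Cell-type population curves and derived readouts
#'
#' Converts recorded cell-type probabilities into absolute population
#' curves (probability times population-size factor; initial total
#' population = 1) and computes, per curve, the clearance time (first time
#' the curve drops below `clear_frac` of its initial value) and the peak
#' time.
#'
#' @param tc A `bp_pop_timecourse` run with `predicates` (e.g. via
#'   [run_icd()]).
#' @param celltypes Optional character vector restricting the summary.
#' @param clear_frac Clearance threshold as a fraction of the initial value
#'   (default 0.01).
#' @return A list with `curves` (data frame `time`, `celltype`,
#'   `probability`, `absolute`) and `readouts` (data frame `celltype`,
#'   `initial`, `final`, `peak_time`, `clearance_time`).
#' @export
summarize_celltypes <- function(tc, celltypes = NULL, clear_frac = 0.01) {
  if (is.null(tc$celltype_probs))
    stop("the timecourse has no recorded cell-type probabilities; ",
         "pass `predicates` to run_population() or use run_icd()", call. = FALSE)
  probs <- tc$celltype_probs
  if (!is.null(celltypes)) {
    missing <- setdiff(celltypes, colnames(probs))
    if (length(missing))
      stop("cell types not recorded in this run: ",
           paste(missing, collapse = ", "), call. = FALSE)
    probs <- probs[, celltypes, drop = FALSE]
  }
  absolute <- probs * tc$size
  curves <- data.frame(
    time = rep(tc$time, ncol(probs)),
    celltype = rep(colnames(probs), each = nrow(probs)),
    probability = as.vector(probs),
    absolute = as.vector(absolute),
    stringsAsFactors = FALSE)
  readouts <- do.call(rbind, lapply(colnames(probs), function(ct) {
    a <- absolute[, ct]
    data.frame(celltype = ct, initial = a[1], final = a[length(a)],
               peak_time = peak_time(tc$time, a),
               clearance_time = clearance_time(tc$time, a, frac = clear_frac),
               stringsAsFactors = FALSE)
  }))
  list(curves = curves, readouts = readouts)
}

#' First time a curve drops below a fraction of its initial value
#' @param time Time grid.
#' @param curve Values on the grid.
#' @param frac Threshold fraction of `curve[1]`.
#' @return Time of first crossing, or `NA` if never.
#' @export
clearance_time <- function(time, curve, frac = 0.01) {
  if (curve[1] <= 0) return(NA_real_)
  idx <- which(curve < frac * curve[1])
  if (!length(idx)) return(NA_real_)
  time[idx[1]]
}

#' Time at which a curve attains its maximum
#' @param time Time grid.
#' @param curve Values on the grid.
#' @return Time of the (first) maximum.
#' @export
peak_time <- function(time, curve) time[which.max(curve)]

#' First time a curve reaches a fraction of its maximum
#'
#' Used as a population-level activation time: with sticky activation the
#' marginal ON-probability rises towards its plateau, and the half-maximum
#' crossing is a robust median activation time.
#'
#' @param time Time grid.
#' @param curve Values on the grid.
#' @param frac Fraction of the maximum (default 0.5).
#' @return Crossing time, or `NA` for an all-zero curve.
#' @export
activation_time <- function(time, curve, frac = 0.5) {
  m <- max(curve)
  if (m <= 0) return(NA_real_)
  thr <- frac * m
  i <- which(curve >= thr)[1]
  if (i == 1) return(time[1])
  # linear interpolation between the bracketing grid points gives sub-grid
  # resolution, so nearly simultaneous events can still be ordered
  time[i - 1] + (time[i] - time[i - 1]) * (thr - curve[i - 1]) /
    (curve[i] - curve[i - 1])
}
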