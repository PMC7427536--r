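# Curated core model of P. putida KT2440 ethanol metabolism.
#
# Scope: ethanol uptake via the periplasmic quinoprotein ethanol
# dehydrogenase (PedH, PQQ-dependent) or the cytoplasmic NAD+-dependent
# alcohol dehydrogenase (Adh), aldehyde dehydrogenase (AldB) and acetyl-CoA
# synthetase (AcsA) to acetyl-CoA; TCA cycle with the glyoxylate shunt;
# gluconeogenesis to glucose 6-phosphate; an Entner-Doudoroff lump for
# growth on glucose; lumped dTDP-L-rhamnose and beta-hydroxydecanoyl-ACP
# branches; oxidative phosphorylation with distinct proton translocation for
# NADH- versus PQQH2-level electron entry; a lumped biomass equation and
# growth-independent ATP maintenance.
#
# Bookkeeping convention: all species carry their neutral (fully protonated)
# formulas, so every internal reaction balances exactly for C, H, N, O, P, S
# with zero formal charges. Translocated protons appear explicitly as
# species (h_c / h_p) and balance as H.

# Proton economy defaults (configurable; see build_core_model):
#  - NADH dehydrogenase pumps 4 H+ and the quinol oxidase 6 H+ per electron
#    pair, so electrons entering as NADH translocate 10 H+ on the way to O2.
#  - PQQH2 donates at the quinone level, bypassing NADH dehydrogenase: 6 H+.
#  - The ATP synthase consumes 4 H+ per ATP (including phosphate transport),
#    giving effective P/O ratios of 2.5 (NADH) and 1.5 (PQQH2).

rf_core_metabolites <- function() {
  M <- function(id, name, formula, comp = "c")
    metabolite(id, name, formula, charge = 0L, compartment = comp)
  list(
    # extracellular
    M("etoh_e", "ethanol", "C2H6O", "e"),
    M("glc__D_e", "D-glucose", "C6H12O6", "e"),
    M("ac_e", "acetate", "C2H4O2", "e"),
    M("o2_e", "O2", "O2", "e"),
    M("co2_e", "CO2", "CO2", "e"),
    M("nh4_e", "ammonium (as NH3)", "H3N", "e"),
    M("pi_e", "phosphate", "H3O4P", "e"),
    M("h2o_e", "water", "H2O", "e"),
    # periplasm
    M("etoh_p", "ethanol", "C2H6O", "p"),
    M("acald_p", "acetaldehyde", "C2H4O", "p"),
    M("pqq_p", "pyrroloquinoline quinone", "C14H6N2O8", "p"),
    M("pqqh2_p", "pyrroloquinoline quinol", "C14H8N2O8", "p"),
    M("h_p", "periplasmic proton", "H", "p"),
    # cytoplasm
    M("etoh_c", "ethanol", "C2H6O"),
    M("acald_c", "acetaldehyde", "C2H4O"),
    M("ac_c", "acetate", "C2H4O2"),
    M("accoa_c", "acetyl-CoA", "C23H38N7O17P3S"),
    M("coa_c", "coenzyme A", "C21H36N7O16P3S"),
    M("pyr_c", "pyruvate", "C3H4O3"),
    M("pep_c", "phosphoenolpyruvate", "C3H5O6P"),
    M("oaa_c", "oxaloacetate", "C4H4O5"),
    M("cit_c", "citrate", "C6H8O7"),
    M("acon_c", "cis-aconitate", "C6H6O6"),
    M("icit_c", "isocitrate", "C6H8O7"),
    M("akg_c", "2-oxoglutarate", "C5H6O5"),
    M("succoa_c", "succinyl-CoA", "C25H40N7O19P3S"),
    M("succ_c", "succinate", "C4H6O4"),
    M("fum_c", "fumarate", "C4H4O4"),
    M("mal__L_c", "L-malate", "C4H6O5"),
    M("glx_c", "glyoxylate", "C2H2O3"),
    M("g6p_c", "D-glucose 6-phosphate", "C6H13O9P"),
    M("glc__D_c", "D-glucose", "C6H12O6"),
    M("nad_c", "NAD+", "C21H27N7O14P2"),
    M("nadh_c", "NADH", "C21H29N7O14P2"),
    M("nadp_c", "NADP+", "C21H28N7O17P3"),
    M("nadph_c", "NADPH", "C21H30N7O17P3"),
    M("atp_c", "ATP", "C10H16N5O13P3"),
    M("adp_c", "ADP", "C10H15N5O10P2"),
    M("amp_c", "AMP", "C10H14N5O7P"),
    M("pi_c", "phosphate", "H3O4P"),
    M("ppi_c", "diphosphate", "H4O7P2"),
    M("h2o_c", "water", "H2O"),
    M("o2_c", "O2", "O2"),
    M("co2_c", "CO2", "CO2"),
    M("nh4_c", "ammonium (as NH3)", "H3N"),
    M("h_c", "cytoplasmic proton", "H"),
    M("q8_c", "ubiquinone-8", "C49H74O4"),
    M("q8h2_c", "ubiquinol-8", "C49H76O4"),
    M("dtdp_c", "dTDP", "C10H16N2O11P2"),
    M("dttp_c", "dTTP", "C10H17N2O14P3"),
    M("dtdprmn_c", "dTDP-L-rhamnose", "C16H26N2O15P2"),
    M("ACP_c", "acyl carrier protein (pantetheine arm)", "C11H22N2O7PS"),
    M("3hdecACP_c", "(R)-3-hydroxydecanoyl-ACP", "C21H40N2O9PS"),
    # lumped biomass: 40.6 mmol C per g CDW (24.6 g per Cmol)
    metabolite("biomass_c", "biomass (1 g CDW)",
               c(C = 40.6, H = 71, O = 16, N = 8.1),
               charge = 0L, compartment = "c")
  )
}

rf_core_reactions <- function(h_nadh_dh, h_oxidase, h_atp, ngam, gam) {
  R <- function(id, name, st, lb = 0, ub = RF_FLUX_MAX,
                exchange = FALSE, pseudo = FALSE)
    reaction(id, st, lb, ub, name = name,
             is_exchange = exchange, is_pseudo = pseudo)
  FM <- RF_FLUX_MAX
  list(
    ## exchanges (negative flux = uptake); carbon uptakes closed by default
    R("EX_etoh_e", "ethanol exchange", c(etoh_e = -1), 0, FM, exchange = TRUE),
    R("EX_glc__D_e", "D-glucose exchange", c(glc__D_e = -1), 0, FM, exchange = TRUE),
    R("EX_ac_e", "acetate exchange", c(ac_e = -1), 0, FM, exchange = TRUE),
    R("EX_o2_e", "O2 exchange", c(o2_e = -1), -FM, FM, exchange = TRUE),
    R("EX_co2_e", "CO2 exchange", c(co2_e = -1), 0, FM, exchange = TRUE),
    R("EX_nh4_e", "ammonium exchange", c(nh4_e = -1), -FM, FM, exchange = TRUE),
    R("EX_pi_e", "phosphate exchange", c(pi_e = -1), -FM, FM, exchange = TRUE),
    R("EX_h2o_e", "water exchange", c(h2o_e = -1), -FM, FM, exchange = TRUE),
    ## transport
    R("ETOHt_ep", "ethanol diffusion (e->p)",
      c(etoh_e = -1, etoh_p = 1), -FM, FM),
    R("ETOHt_pc", "ethanol diffusion (p->c)",
      c(etoh_p = -1, etoh_c = 1), -FM, FM),
    R("ACALDt_pc", "acetaldehyde diffusion (p->c)",
      c(acald_p = -1, acald_c = 1), -FM, FM),
    R("GLCt", "glucose uptake (lumped)",
      c(glc__D_e = -1, glc__D_c = 1), 0, FM),
    R("ACt", "acetate transport",
      c(ac_c = -1, ac_e = 1), -FM, FM),
    R("O2t", "O2 diffusion", c(o2_e = -1, o2_c = 1), -FM, FM),
    R("CO2t", "CO2 diffusion", c(co2_c = -1, co2_e = 1), -FM, FM),
    R("NH4t", "ammonium transport", c(nh4_e = -1, nh4_c = 1), -FM, FM),
    R("PIt", "phosphate transport", c(pi_e = -1, pi_c = 1), -FM, FM),
    R("H2Ot", "water diffusion", c(h2o_c = -1, h2o_e = 1), -FM, FM),
    ## ethanol oxidation (the two cofactor routes)
    R("PEDH", "quinoprotein ethanol dehydrogenase (PedH, periplasm)",
      c(etoh_p = -1, pqq_p = -1, acald_p = 1, pqqh2_p = 1)),
    R("ADH", "NAD+-dependent alcohol dehydrogenase (Adh, cytoplasm)",
      c(etoh_c = -1, nad_c = -1, acald_c = 1, nadh_c = 1)),
    R("ALDB", "aldehyde dehydrogenase (AldB)",
      c(acald_c = -1, nad_c = -1, h2o_c = -1, ac_c = 1, nadh_c = 1)),
    R("ACS", "acetyl-CoA synthetase (AcsA)",
      c(ac_c = -1, atp_c = -1, coa_c = -1,
        accoa_c = 1, amp_c = 1, ppi_c = 1)),
    R("ADK1", "adenylate kinase",
      c(atp_c = -1, amp_c = -1, adp_c = 2), -FM, FM),
    R("PPA", "inorganic diphosphatase",
      c(ppi_c = -1, h2o_c = -1, pi_c = 2)),
    ## TCA cycle
    R("CS", "citrate synthase",
      c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1)),
    R("ACONTa", "aconitase (citrate -> cis-aconitate)",
      c(cit_c = -1, acon_c = 1, h2o_c = 1), -FM, FM),
    R("ACONTb", "aconitase (cis-aconitate -> isocitrate)",
      c(acon_c = -1, h2o_c = -1, icit_c = 1), -FM, FM),
    R("ICDHy", "isocitrate dehydrogenase (NADP+)",
      c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1)),
    R("AKGDH", "2-oxoglutarate dehydrogenase",
      c(akg_c = -1, coa_c = -1, nad_c = -1,
        succoa_c = 1, co2_c = 1, nadh_c = 1)),
    R("SUCOAS", "succinyl-CoA synthetase",
      c(succoa_c = -1, adp_c = -1, pi_c = -1,
        succ_c = 1, atp_c = 1, coa_c = 1)),
    R("SUCDH", "succinate dehydrogenase (quinone)",
      c(succ_c = -1, q8_c = -1, fum_c = 1, q8h2_c = 1)),
    R("FUM", "fumarase",
      c(fum_c = -1, h2o_c = -1, mal__L_c = 1), -FM, FM),
    R("MDH", "malate dehydrogenase",
      c(mal__L_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1), -FM, FM),
    ## glyoxylate shunt
    R("ICL", "isocitrate lyase",
      c(icit_c = -1, succ_c = 1, glx_c = 1)),
    R("MALS", "malate synthase",
      c(glx_c = -1, accoa_c = -1, h2o_c = -1, mal__L_c = 1, coa_c = 1)),
    ## anaplerosis / gluconeogenesis / glucose catabolism
    R("PPCK", "PEP carboxykinase",
      c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1)),
    R("PYK", "pyruvate kinase",
      c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1)),
    R("PC", "pyruvate carboxylase",
      c(pyr_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
        oaa_c = 1, adp_c = 1, pi_c = 1)),
    R("PDH", "pyruvate dehydrogenase",
      c(pyr_c = -1, coa_c = -1, nad_c = -1,
        accoa_c = 1, co2_c = 1, nadh_c = 1)),
    R("GLK", "glucokinase",
      c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1)),
    R("EDLUMP", "Entner-Doudoroff catabolism (lumped, glc -> 2 pyr)",
      c(glc__D_c = -1, nad_c = -1, nadp_c = -1, adp_c = -1, pi_c = -1,
        pyr_c = 2, nadh_c = 1, nadph_c = 1, atp_c = 1, h2o_c = 1)),
    R("GLUCONEO", "gluconeogenesis (lumped, 2 PEP -> G6P)",
      c(pep_c = -2, atp_c = -2, nadh_c = -2, h2o_c = -3,
        g6p_c = 1, adp_c = 2, nad_c = 2, pi_c = 3)),
    ## lumped biosynthetic branches
    R("DTDPRMN", "dTDP-L-rhamnose synthesis (lumped, from G6P)",
      c(g6p_c = -1, dttp_c = -1, nadph_c = -1,
        dtdprmn_c = 1, ppi_c = 1, nadp_c = 1, h2o_c = 1)),
    R("DTDPK", "dTDP kinase (carrier regeneration, ATP-lumped)",
      c(dtdp_c = -1, atp_c = -1, dttp_c = 1, adp_c = 1)),
    R("FAS100", "beta-hydroxydecanoyl-ACP synthesis (lumped FAS)",
      c(accoa_c = -5, atp_c = -4, nadph_c = -7, ACP_c = -1, h2o_c = -1,
        `3hdecACP_c` = 1, coa_c = 5, adp_c = 4, pi_c = 4, nadp_c = 7)),
    ## oxidative phosphorylation
    R("NADHDH", "NADH dehydrogenase I (proton pumping)",
      c(nadh_c = -1, q8_c = -1, h_c = -h_nadh_dh,
        nad_c = 1, q8h2_c = 1, h_p = h_nadh_dh)),
    R("PQQQ8", "PQQH2:quinone oxidoreduction (no pumping)",
      c(pqqh2_p = -1, q8_c = -1, pqq_p = 1, q8h2_c = 1)),
    R("CYO", "quinol oxidase (proton pumping)",
      c(q8h2_c = -1, o2_c = -0.5, h_c = -h_oxidase,
        q8_c = 1, h2o_c = 1, h_p = h_oxidase)),
    R("ATPS", "ATP synthase",
      c(adp_c = -1, pi_c = -1, h_p = -h_atp,
        atp_c = 1, h2o_c = 1, h_c = h_atp)),
    R("THD", "transhydrogenase",
      c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1), -FM, FM),
    ## pseudo-reactions
    R("ATPM", "growth-independent maintenance",
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
      lb = ngam, ub = FM, pseudo = TRUE),
    reaction("BIOMASS",
      c(g6p_c = -1.0, pep_c = -1.3, pyr_c = -2.8, oaa_c = -1.5,
        accoa_c = -8.15, nh4_c = -8.1, atp_c = -gam, nadph_c = -12,
        h2o_c = -35,
        biomass_c = 1, coa_c = 8.15, adp_c = gam, pi_c = gam, nadp_c = 12),
      0, FM, name = "biomass equation (1 g CDW per unit flux)",
      is_pseudo = TRUE),
    R("EX_biomass", "biomass drain", c(biomass_c = -1), 0, FM,
      exchange = TRUE)
  )
}

#' Build the curated core model of ethanol metabolism
#'
#' Constructs a ~50-reaction stoichiometric model of *Pseudomonas putida*
#' central carbon metabolism on ethanol (and glucose), with both the
#' periplasmic PQQ-dependent (PedH) and the cytoplasmic NAD+-dependent (Adh)
#' ethanol oxidation routes, the TCA cycle, glyoxylate shunt,
#' gluconeogenesis, lumped dTDP-L-rhamnose and beta-hydroxydecanoyl-ACP
#' branches, an electron transport chain in which NADH- and PQQH2-level
#' electron entry translocate different numbers of protons, ATP synthase,
#' maintenance and a lumped biomass equation. Every internal reaction is
#' elementally balanced (C, H, N, O, P, S) under the neutral-protonation
#' convention.
#'
#' All carbon-source exchange lower bounds start at 0 (nothing to eat);
#' open a substrate with [set_uptake()]. Acetate secretion is open by
#' default (`EX_ac_e` upper bound positive); close it with [set_bounds()]
#' if overflow is to be forbidden.
#'
#' @param h_nadh_dh Protons translocated by NADH dehydrogenase per electron
#'   pair (default 4; with the oxidase this gives 10 H+ per NADH).
#' @param h_oxidase Protons translocated by the terminal quinol oxidase per
#'   electron pair (default 6; PQQH2 electrons enter at the quinone level
#'   and see only this step).
#' @param h_atp Protons consumed per ATP by the ATP synthase (default 4).
#' @param ngam Growth-independent ATP maintenance, mmol gCDW^-1 h^-1
#'   (default 0.92).
#' @param gam Growth-associated ATP maintenance, mmol per g biomass
#'   (default 50).
#' @return A validated `stoich_model` with the biomass reaction as
#'   objective.
#' @examples
#' m <- build_core_model()
#' m
#' @export
build_core_model <- function(h_nadh_dh = 4, h_oxidase = 6, h_atp = 4,
                             ngam = 0.92, gam = 50) {
  model <- stoich_model(
    metabolites = rf_core_metabolites(),
    reactions = rf_core_reactions(h_nadh_dh, h_oxidase, h_atp, ngam, gam),
    objective = c(BIOMASS = 1),
    id = "ppu_ethanol_core"
  )
  validate_model(model)
  model
}

#' Extend a model with the mono-rhamnolipid pathway
#'
#' Adds the heterologous RhlA/RhlB route: RhlA condenses two
#' beta-hydroxydecanoyl-ACP into HAA (C20H38O5), RhlB transfers rhamnose
#' from dTDP-L-rhamnose onto HAA yielding mono-rhamnolipid Rha-C10-C10
#' (C26H48O9), plus export and exchange reactions for both products. The
#' precursor metabolite ids are configurable so that the same patch applies
#' to the core model and to a genome-scale SBML import.
#'
#' @param model A `stoich_model` containing the precursor metabolites.
#' @param precursor_ids Named list mapping the roles `hdacp`
#'   (beta-hydroxydecanoyl-ACP), `acp` (free ACP), `dtdprmn`
#'   (dTDP-L-rhamnose), `dtdp` (dTDP) and `h2o` to metabolite ids in
#'   `model`.
#' @param compartment Compartment for the new cytosolic product species.
#' @return The extended model; the ids of the added reactions are recorded
#'   in `attr(, "rl_added")`.
#' @export
extend_with_rhamnolipid_pathway <- function(
    model,
    precursor_ids = list(hdacp = "3hdecACP_c", acp = "ACP_c",
                         dtdprmn = "dtdprmn_c", dtdp = "dtdp_c",
                         h2o = "h2o_c"),
    compartment = "c") {
  need <- c("hdacp", "acp", "dtdprmn", "dtdp", "h2o")
  missing_roles <- setdiff(need, names(precursor_ids))
  if (length(missing_roles) > 0) {
    stop("precursor_ids must map: ", paste(missing_roles, collapse = ", "))
  }
  ids <- unlist(precursor_ids[need])
  absent <- ids[!ids %in% names(model$metabolites)]
  if (length(absent) > 0) {
    met_ids <- names(model$metabolites)
    sugg <- unlist(lapply(absent, function(a) {
      met_ids[agrepl(sub("_[cpe]$", "", a), met_ids, max.distance = 0.25)]
    }))
    stop("precursor metabolite(s) not found: ",
         paste(absent, collapse = ", "),
         if (length(sugg) > 0)
           paste0("; candidates: ",
                  paste(utils::head(unique(sugg), 10), collapse = ", ")))
  }
  mets <- list(
    metabolite("haa_c", "HAA (C10-C10)", "C20H38O5", 0L, compartment),
    metabolite("haa_e", "HAA (C10-C10)", "C20H38O5", 0L, "e"),
    metabolite("rhl_c", "mono-rhamnolipid (Rha-C10-C10)", "C26H48O9",
               0L, compartment),
    metabolite("rhl_e", "mono-rhamnolipid (Rha-C10-C10)", "C26H48O9",
               0L, "e")
  )
  st_rhla <- stats::setNames(
    c(-2, -1, 1, 2),
    c(precursor_ids$hdacp, precursor_ids$h2o, "haa_c", precursor_ids$acp))
  st_rhlb <- stats::setNames(
    c(-1, -1, 1, 1),
    c("haa_c", precursor_ids$dtdprmn, "rhl_c", precursor_ids$dtdp))
  rxns <- list(
    reaction("RHLA", st_rhla, 0, RF_FLUX_MAX,
             name = "RhlA: 2 beta-hydroxydecanoyl-ACP -> HAA + 2 ACP"),
    reaction("RHLB", st_rhlb, 0, RF_FLUX_MAX,
             name = "RhlB: HAA + dTDP-L-rhamnose -> mono-rhamnolipid + dTDP"),
    reaction("HAAt", c(haa_c = -1, haa_e = 1), 0, RF_FLUX_MAX,
             name = "HAA export"),
    reaction("RHLt", c(rhl_c = -1, rhl_e = 1), 0, RF_FLUX_MAX,
             name = "mono-rhamnolipid export"),
    reaction("EX_haa_e", c(haa_e = -1), 0, RF_FLUX_MAX,
             name = "HAA exchange", is_exchange = TRUE),
    reaction("EX_rhl_e", c(rhl_e = -1), 0, RF_FLUX_MAX,
             name = "mono-rhamnolipid exchange", is_exchange = TRUE)
  )
  out <- add_reactions(model, rxns, mets)
  attr(out, "rl_added") <- vapply(rxns, function(r) r$id, character(1))
  out
}

#' Cofactor scenario for ethanol oxidation
#'
#' @param mode `"PQQ"` (periplasmic quinoprotein route, wild-type-like) or
#'   `"NAD"` (cytoplasmic NAD+-dependent route, evolved-strain-like).
#' @return An object of class `cofactor_scenario`.
#' @export
cofactor_scenario <- function(mode = c("PQQ", "NAD")) {
  mode <- match.arg(toupper(mode), c("PQQ", "NAD"))
  structure(list(mode = mode), class = "cofactor_scenario")
}

#' Apply a cofactor scenario to a model
#'
#' Closes the non-selected ethanol-oxidation route (bounds set to 0,0);
#' the selected route keeps its original bounds, so exactly one
#' ethanol-to-acetaldehyde route has flux capacity.
#'
#' @param model A `stoich_model` containing both routes.
#' @param scenario A [cofactor_scenario()] or a mode string.
#' @param pqq_reaction,nad_reaction Reaction ids of the two routes
#'   (defaults match [build_core_model()]).
#' @return The constrained model.
#' @export
apply_scenario <- function(model, scenario,
                           pqq_reaction = "PEDH", nad_reaction = "ADH") {
  if (is.character(scenario)) scenario <- cofactor_scenario(scenario)
  stopifnot(inherits(scenario, "cofactor_scenario"))
  found <- c(pqq_reaction, nad_reaction) %in% names(model$reactions)
  if (!any(found)) {
    stop("neither ethanol-oxidation route found (looked for '",
         pqq_reaction, "', '", nad_reaction, "')")
  }
  if (!all(found)) {
    stop("ethanol-oxidation route missing: ",
         c(pqq_reaction, nad_reaction)[!found])
  }
  close_id <- if (scenario$mode == "PQQ") nad_reaction else pqq_reaction
  set_bounds(model, close_id, lower_bound = 0, upper_bound = 0)
}

#' Set the uptake rate of a substrate
#'
#' Sets the exchange lower bound of `substrate_id` to `-rate` (BiGG
#' convention: negative exchange flux is uptake) and closes uptake of every
#' other organic-carbon exchange (lower bound 0); CO2 is not treated as an
#' organic carbon source.
#'
#' @param model A `stoich_model`.
#' @param substrate_id Substrate (see [find_exchange()]).
#' @param rate Uptake rate in mmol gCDW^-1 h^-1 (>= 0).
#' @return The modified model.
#' @examples
#' m <- set_uptake(build_core_model(), "etoh", 10)
#' m$reactions$EX_etoh_e$lower_bound  # -10
#' @export
set_uptake <- function(model, substrate_id, rate) {
  if (rate < 0) stop("uptake rate must be >= 0")
  ex_id <- find_exchange(model, substrate_id)
  for (id in exchanges(model)) {
    r <- model$reactions[[id]]
    met <- names(r$stoichiometry)[1]
    carbons <- carbon_count(model$metabolites[[met]])
    organic <- length(carbons) == 1 && !is.na(carbons) && carbons > 0 &&
      !met %in% c("co2_e", "co2_c")
    if (organic && id != ex_id && r$lower_bound < 0) {
      model <- set_bounds(model, id, lower_bound = 0)
    }
  }
  set_bounds(model, ex_id, lower_bound = -rate)
}
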