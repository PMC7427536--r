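# Flux balance analysis: max c'v subject to S v = 0, lb <= v <= ub.
# LPs are solved with the package's bounded-variable revised simplex
# (R/simplex.R). The reported flux vector is disambiguated by a parsimonious
# secondary LP (minimise total absolute flux at the fixed optimal
# objective), so that individual fluxes - not only the optimum - are
# reproducible in the presence of alternate optima.

rf_solve_lp <- function(S, lb, ub, obj, maximize = TRUE, extra_eq = NULL) {
  # extra_eq: list(a = coef vector, b = rhs) appended as equality rows
  keep <- rowSums(abs(S)) > 0
  S <- S[keep, , drop = FALSE]
  # conserved moieties (cofactor pools etc.) make rows of S linearly
  # dependent; keep an independent row basis (the zero RHS stays consistent
  # since any left-null vector y of S satisfies y' 0 = 0)
  if (nrow(S) > 1) {
    qrS <- qr(t(S))
    S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  }
  Aeq <- S
  beq <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    Aeq <- rbind(Aeq, extra_eq$a)
    beq <- c(beq, extra_eq$b)
  }
  res <- rf_simplex(Aeq, beq, lb, ub, obj, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, value = NA_real_))
  }
  if (max(abs(res$x)) >= 0.99 * RF_SIMPLEX_BIG) {
    # solution rides the internal big box: the LP is unbounded in truth
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = res$x, value = res$value)
}

#' Flux balance analysis of a stoichiometric model
#'
#' Maximises the objective over the steady-state flux polytope
#' \{v : S v = 0, lb <= v <= ub\}. Among alternate optima the returned flux
#' vector is the parsimonious one: total absolute flux is minimised in a
#' secondary LP with the objective fixed at its optimum (pFBA-style
#' tie-break). The objective value itself is the contract; fluxes are the
#' reproducible representative.
#'
#' @param model A `stoich_model`.
#' @param objective Reaction id to maximise (default: the model objective).
#' @param parsimonious Apply the pFBA tie-break (default `TRUE`).
#' @return An object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value`, and
#'   `fluxes` (named numeric over all reactions). Non-optimal statuses are
#'   returned, never silent zeros.
#' @examples
#' m <- set_uptake(build_core_model(), "etoh", 10)
#' sol <- fba(apply_scenario(m, "NAD"))
#' sol$objective_value  # maximal growth rate, h^-1
#' @export
fba <- function(model, objective = NULL, parsimonious = TRUE) {
  stopifnot(inherits(model, "stoich_model"))
  rxns <- model$reactions
  n <- length(rxns)
  lb <- vapply(rxns, function(r) r$lower_bound, numeric(1))
  ub <- vapply(rxns, function(r) r$upper_bound, numeric(1))
  if (any(lb > ub)) {
    return(structure(list(status = "infeasible",
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  obj <- stats::setNames(numeric(n), names(rxns))
  if (is.null(objective)) {
    if (length(model$objective) == 0) stop("model has no objective")
    obj[names(model$objective)] <- model$objective
  } else {
    if (!objective %in% names(rxns)) {
      stop("objective reaction not found: ", objective)
    }
    obj[objective] <- 1
  }
  S <- stoich_matrix(model)
  prim <- rf_solve_lp(S, lb, ub, obj, maximize = TRUE)
  if (prim$status != "optimal") {
    return(structure(list(status = prim$status,
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  v <- prim$x
  if (parsimonious) {
    # min sum(p + q), v = p - q, with c'v fixed at the optimum.
    # Split-variable LP over [S -S; c' -c'] with box bounds carried over.
    S2 <- cbind(S, -S)
    lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
    ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
    obj2 <- rep(1, 2 * n)
    sec <- rf_solve_lp(S2, lb2, ub2, obj2, maximize = FALSE,
                       extra_eq = list(a = c(obj, -obj), b = prim$value))
    if (sec$status == "optimal") {
      v2 <- sec$x[seq_len(n)] - sec$x[n + seq_len(n)]
      # accept only if it respects the original problem
      if (max(abs(S %*% v2)) < 1e-6 &&
          all(v2 >= lb - 1e-6) && all(v2 <= ub + 1e-6)) {
        v <- pmin(pmax(v2, lb), ub)
      }
    }
  }
  structure(
    list(status = "optimal", objective_value = prim$value,
         fluxes = stats::setNames(as.numeric(v), names(rxns))),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective: ", format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

rf_require_optimal <- function(sol) {
  if (sol$status != "optimal") {
    stop("FBA did not reach an optimum (status: ", sol$status, ")")
  }
  sol
}

#' Maximal biomass yield on a substrate
#'
#' Applies the cofactor scenario, fixes the substrate uptake, maximises
#' growth, and converts the growth flux to the literature-style
#' "mmol biomass per mol substrate" number: growth flux (h^-1) divided by
#' uptake (mmol gCDW^-1 h^-1) times 1000, i.e. biomass counted as 1 g per
#' mmol. Both the converted yield and the raw growth flux are returned,
#' since the unit basis of the printed genome-scale values is inferred.
#'
#' @param model A `stoich_model` (rhamnolipid extension not required).
#' @param scenario A [cofactor_scenario()] or mode string, or `NULL` to
#'   leave both routes open.
#' @param substrate_id Substrate (default ethanol).
#' @param uptake Uptake rate, mmol gCDW^-1 h^-1 (default 10).
#' @param biomass_reaction Growth reaction id.
#' @param ... Passed to [apply_scenario()] (route reaction ids).
#' @return Numeric yield in mmol biomass per mol substrate, with attributes
#'   `growth_flux` (h^-1) and `solution`.
#' @export
biomass_yield <- function(model, scenario = NULL, substrate_id = "etoh",
                          uptake = 10, biomass_reaction = "BIOMASS", ...) {
  if (!is.null(scenario)) model <- apply_scenario(model, scenario, ...)
  model <- set_uptake(model, substrate_id, uptake)
  if (uptake == 0) {
    return(structure(0, growth_flux = 0, solution = NULL))
  }
  sol <- rf_require_optimal(fba(model, objective = biomass_reaction))
  mu <- sol$objective_value
  structure(mu / uptake * 1000, growth_flux = mu, solution = sol)
}

#' Maximal product yield (mol per mol substrate)
#'
#' Maximises the mono-rhamnolipid exchange flux at fixed substrate uptake;
#' growth is left free (at the product optimum it is zero) unless
#' `zero_growth` forces the growth bounds to (0,0) explicitly. Returns the
#' molar ratio product flux / uptake flux; the attribute `product_flux`
#' carries the optimal flux itself (mmol gCDW^-1 h^-1), which at the
#' conventional uptake of 10 is the number genome-scale studies print as
#' the "mmol per mmol" yield.
#'
#' @inheritParams biomass_yield
#' @param product_exchange Product exchange reaction id.
#' @param zero_growth Fix growth to zero before optimising.
#' @return Numeric mol product per mol substrate, with attributes
#'   `product_flux` and `solution`.
#' @export
product_yield <- function(model, scenario = NULL, substrate_id = "etoh",
                          uptake = 10, product_exchange = "EX_rhl_e",
                          biomass_reaction = "BIOMASS",
                          zero_growth = FALSE, ...) {
  if (!product_exchange %in% names(model$reactions)) {
    stop("product exchange not found: ", product_exchange,
         " (extend the model with the rhamnolipid pathway first)")
  }
  if (!is.null(scenario)) model <- apply_scenario(model, scenario, ...)
  model <- set_uptake(model, substrate_id, uptake)
  if (zero_growth) {
    model <- set_bounds(model, biomass_reaction, 0, 0)
  }
  if (uptake == 0) {
    return(structure(0, product_flux = 0, solution = NULL))
  }
  sol <- rf_require_optimal(fba(model, objective = product_exchange))
  vp <- sol$objective_value
  structure(vp / uptake, product_flux = vp, solution = sol)
}

#' Zero-growth carbon yield (Cmol product per Cmol substrate)
#'
#' Fixes the growth reaction to (0,0) (maintenance stays active),
#' maximises the product exchange, and converts the molar yield to a
#' carbon-mole basis using the formulas of the product and substrate
#' species.
#'
#' @inheritParams product_yield
#' @return Numeric Cmol/Cmol yield, with attribute `solution`.
#' @examples
#' m <- extend_with_rhamnolipid_pathway(build_core_model())
#' product_yield_zero_growth(m, substrate_id = "etoh")
#' @export
product_yield_zero_growth <- function(model, substrate_id = "etoh",
                                      uptake = 10,
                                      product_exchange = "EX_rhl_e",
                                      biomass_reaction = "BIOMASS") {
  y <- product_yield(model, scenario = NULL, substrate_id = substrate_id,
                     uptake = uptake, product_exchange = product_exchange,
                     biomass_reaction = biomass_reaction, zero_growth = TRUE)
  prod_met <- names(model$reactions[[product_exchange]]$stoichiometry)[1]
  sub_met <- names(model$reactions[[
    find_exchange(model, substrate_id)]]$stoichiometry)[1]
  cp <- carbon_count(model$metabolites[[prod_met]])
  cs <- carbon_count(model$metabolites[[sub_met]])
  if (cs == 0) stop("substrate has no carbon: ", sub_met)
  structure(as.numeric(y) * cp / cs, solution = attr(y, "solution"))
}

#' Extract named fluxes from a solution
#'
#' Reports the fluxes the genome-scale analysis discusses: O2 uptake,
#' aconitase (citrate -> cis-aconitate), CO2 evolution and substrate
#' uptake, or any other requested reactions. Values are reported as
#' magnitudes (`abs_flux`) alongside the signed flux; signs follow the
#' exchange convention (uptake negative).
#'
#' @param solution An optimal `flux_solution`.
#' @param reaction_ids Character vector of reaction ids.
#' @return A data frame with columns `reaction`, `flux`, `abs_flux`.
#' @export
flux_report <- function(solution,
                        reaction_ids = c("EX_o2_e", "ACONTa", "EX_co2_e",
                                         "EX_etoh_e")) {
  stopifnot(inherits(solution, "flux_solution"))
  rf_require_optimal(solution)
  missing <- setdiff(reaction_ids, names(solution$fluxes))
  if (length(missing) > 0) {
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  }
  v <- solution$fluxes[reaction_ids]
  data.frame(reaction = reaction_ids, flux = as.numeric(v),
             abs_flux = abs(as.numeric(v)), row.names = NULL)
}

#' Full yield report for one scenario
#'
#' Convenience wrapper computing the biomass yield, the product yield (free
#' growth) and the zero-growth Cmol yield for one cofactor scenario on one
#' substrate, in a single structure.
#'
#' @inheritParams product_yield
#' @return An object of class `yield_report`.
#' @export
fba_yield_report <- function(model, scenario, substrate_id = "etoh",
                             uptake = 10, product_exchange = "EX_rhl_e",
                             biomass_reaction = "BIOMASS") {
  by <- biomass_yield(model, scenario, substrate_id, uptake,
                      biomass_reaction)
  py <- product_yield(model, scenario, substrate_id, uptake,
                      product_exchange, biomass_reaction)
  cz <- product_yield_zero_growth(model, substrate_id, uptake,
                                  product_exchange, biomass_reaction)
  scen <- if (is.character(scenario)) cofactor_scenario(scenario) else scenario
  structure(
    list(
      scenario = scen$mode,
      substrate_id = substrate_id,
      uptake = uptake,
      biomass_yield_mmol_per_mol = as.numeric(by),
      growth_flux = attr(by, "growth_flux"),
      product_yield_mmol_per_mmol = as.numeric(py),
      product_flux = attr(py, "product_flux"),
      product_yield_cmol_per_cmol_zero_growth = as.numeric(cz)
    ),
    class = "yield_report"
  )
}

#' @export
print.yield_report <- function(x, ...) {
  cat("<yield_report> scenario ", x$scenario, ", substrate ", x$substrate_id,
      " (uptake ", x$uptake, " mmol/gCDW/h)\n", sep = "")
  cat(sprintf("  biomass yield: %.3g mmol/mol (growth flux %.4g 1/h)\n",
              x$biomass_yield_mmol_per_mol, x$growth_flux))
  cat(sprintf("  product yield: %.3g mmol/mmol (flux %.4g mmol/gCDW/h)\n",
              x$product_yield_mmol_per_mmol, x$product_flux))
  cat(sprintf("  zero-growth carbon yield: %.3g Cmol/Cmol\n",
              x$product_yield_cmol_per_cmol_zero_growth))
  invisible(x)
}
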