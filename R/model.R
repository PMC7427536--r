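# S3 containers for constraint-based metabolic models: metabolites, reactions
# and the assembled stoichiometric model. Flux units are mmol gCDW^-1 h^-1
# throughout (biomass flux in h^-1). Exchange convention is BiGG-style:
# negative exchange flux is uptake, positive is secretion.

#' Create a metabolite
#'
#' @param id Unique metabolite id (BiGG-style where one exists, e.g.
#'   `"etoh_c"`).
#' @param name Human-readable name.
#' @param formula Chemical formula string or named element-count vector
#'   (C, H, N, O, P, S). May be empty for pseudo-species such as biomass
#'   when carbon accounting is supplied explicitly.
#' @param charge Formal charge (integer; the curated core model uses the
#'   neutral protonation convention, so charges are 0).
#' @param compartment One of `"c"` (cytoplasm), `"p"` (periplasm),
#'   `"e"` (extracellular).
#' @return An object of class `rf_metabolite`.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = c("c", "p", "e")) {
  compartment <- match.arg(compartment)
  counts <- parse_formula(formula)
  if (any(counts < 0)) stop("element counts must be >= 0")
  structure(
    list(id = id, name = name, formula = counts,
         charge = as.integer(charge), compartment = compartment),
    class = "rf_metabolite"
  )
}

#' Carbon atoms per molecule of a metabolite
#' @param met An `rf_metabolite`.
#' @return Numeric carbon count.
#' @export
carbon_count <- function(met) {
  stopifnot(inherits(met, "rf_metabolite"))
  unname(met$formula[["C"]])
}

#' Create a reaction
#'
#' @param id Unique reaction id.
#' @param stoichiometry Named numeric vector mapping metabolite ids to signed
#'   coefficients (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound Flux bounds (mmol gCDW^-1 h^-1).
#' @param name Human-readable name.
#' @param is_exchange Logical; exchange reactions touch a single extracellular
#'   species and are exempt from balance checks.
#' @param is_pseudo Logical; pseudo-reactions (biomass, maintenance) are
#'   exempt from elemental balance checks.
#' @return An object of class `rf_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = RF_FLUX_MAX, name = id,
                     is_exchange = FALSE, is_pseudo = FALSE) {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a named vector of metabolite ids")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("duplicate metabolite in stoichiometry of ", id)
  }
  if (lower_bound > upper_bound) {
    stop("lower_bound > upper_bound in reaction ", id)
  }
  structure(
    list(id = id, name = name,
         stoichiometry = stoichiometry[stoichiometry != 0],
         lower_bound = lower_bound, upper_bound = upper_bound,
         is_exchange = isTRUE(is_exchange), is_pseudo = isTRUE(is_pseudo)),
    class = "rf_reaction"
  )
}

#' Default flux bound magnitude
#' @export
RF_FLUX_MAX <- 1000

#' Assemble a stoichiometric model
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects; every referenced metabolite
#'   must exist.
#' @param objective Named numeric vector (reaction id -> weight).
#' @param id Model id.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites = list(), reactions = list(),
                         objective = numeric(0), id = "model") {
  met_ids <- vapply(metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing) > 0) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
  }
  if (length(objective) > 0) {
    missing <- setdiff(names(objective), rxn_ids)
    if (length(missing) > 0) {
      stop("objective references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective = objective),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "   reactions: ", length(x$reactions), "\n", sep = "")
  if (length(x$objective) > 0) {
    cat("  objective:  ",
        paste(sprintf("%s (%g)", names(x$objective), x$objective),
              collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param model A `stoich_model`.
#' @return Dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  m <- length(model$metabolites)
  n <- length(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(names(model$metabolites),
                              names(model$reactions)))
  for (j in seq_len(n)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Add reactions (and any new metabolites) to a model
#' @param model A `stoich_model`.
#' @param reactions List of `rf_reaction` objects.
#' @param metabolites Optional list of `rf_metabolite` objects to add first.
#' @return The extended model.
#' @export
add_reactions <- function(model, reactions, metabolites = list()) {
  stoich_model(
    metabolites = c(model$metabolites, metabolites),
    reactions = c(model$reactions, reactions),
    objective = model$objective, id = model$id
  )
}

#' Remove reactions by id
#' @param model A `stoich_model`.
#' @param ids Character vector of reaction ids.
#' @return The reduced model (orphaned metabolites are retained).
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, names(model$reactions))
  if (length(missing) > 0) {
    stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  }
  model$reactions[ids] <- NULL
  model$objective <- model$objective[setdiff(names(model$objective), ids)]
  stoich_model(model$metabolites, model$reactions, model$objective, model$id)
}

#' Set flux bounds of a reaction
#' @param model A `stoich_model`.
#' @param id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  r <- model$reactions[[id]]
  if (!is.null(lower_bound)) r$lower_bound <- lower_bound
  if (!is.null(upper_bound)) r$upper_bound <- upper_bound
  if (r$lower_bound > r$upper_bound) {
    stop("lower_bound > upper_bound for ", id)
  }
  model$reactions[[id]] <- r
  model
}

#' Per-element imbalance of one reaction
#'
#' Computes sum(coefficient * element count) for each tracked element. A
#' balanced reaction returns (numerically) zero for every element.
#'
#' @param model A `stoich_model`.
#' @param id Reaction id.
#' @return Named numeric vector over C, H, N, O, P, S.
#' @export
element_balance <- function(model, id) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  st <- model$reactions[[id]]$stoichiometry
  out <- stats::setNames(numeric(length(RF_ELEMENTS)), RF_ELEMENTS)
  for (met in names(st)) {
    out <- out + st[[met]] * model$metabolites[[met]]$formula
  }
  out
}

#' Check elemental balance of all internal reactions
#'
#' Exchange and pseudo-reactions (biomass, maintenance) are skipped, all
#' other reactions must balance for C, H, N, O, P and S.
#'
#' @param model A `stoich_model`.
#' @param tol Numeric tolerance on element counts.
#' @return A data frame with one row per checked reaction: `reaction`,
#'   `balanced`, and the per-element residuals.
#' @export
check_balances <- function(model, tol = 1e-9) {
  ids <- names(model$reactions)
  keep <- vapply(model$reactions,
                 function(r) !r$is_exchange && !r$is_pseudo, logical(1))
  ids <- ids[keep]
  res <- t(vapply(ids, function(id) element_balance(model, id),
                  numeric(length(RF_ELEMENTS))))
  if (length(ids) == 0) {
    res <- matrix(numeric(0), 0, length(RF_ELEMENTS),
                  dimnames = list(NULL, RF_ELEMENTS))
  }
  data.frame(
    reaction = ids,
    balanced = apply(abs(res) < tol, 1, all),
    res,
    row.names = NULL
  )
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, dangling metabolite references,
#' objective references and elemental balance of internal reactions.
#'
#' @param model A `stoich_model`.
#' @param check_balance Also require elemental balance (default `TRUE`).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_model <- function(model, check_balance = TRUE) {
  # constructors enforce ids/references/bounds; re-run via re-assembly
  stoich_model(model$metabolites, model$reactions, model$objective, model$id)
  if (check_balance) {
    bal <- check_balances(model)
    if (any(!bal$balanced)) {
      stop("unbalanced internal reaction(s): ",
           paste(bal$reaction[!bal$balanced], collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Exchange reaction ids of a model
#' @param model A `stoich_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchanges <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r) r$is_exchange,
                                logical(1))]
}

#' Find the exchange reaction for a substrate
#'
#' Accepts a bare species id (`"etoh"`), a compartment-qualified id
#' (`"etoh_e"`) or a full exchange reaction id (`"EX_etoh_e"`).
#'
#' @param model A `stoich_model`.
#' @param substrate_id Substrate identifier.
#' @return The exchange reaction id.
#' @export
find_exchange <- function(model, substrate_id) {
  ex <- exchanges(model)
  cand <- c(substrate_id,
            paste0("EX_", substrate_id),
            paste0("EX_", substrate_id, "_e"))
  hit <- intersect(cand, ex)
  if (length(hit) == 0) {
    stop("no exchange reaction found for substrate '", substrate_id,
         "'; available: ", paste(ex, collapse = ", "))
  }
  hit[1]
}
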