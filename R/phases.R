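#' Phase constraints of the EBPR cycle
#'
#' Anaerobic conditions close the oxygen exchange to uptake (secretion stays
#' possible) and fix every electron-transport-chain (ETC) tagged reaction to
#' zero. Aerobic conditions reopen oxygen uptake to the model's configured
#' limit, block uptake through every carbon exchange (secretion stays
#' allowed), and open the storage sinks in the pool-consuming direction so
#' that PHA/glycogen/poly-P laid down anaerobically can fuel growth.
#' Both functions return a modified copy; both are idempotent.
#'
#' @param model a `gem_model`.
#' @return a modified copy of the model.
#' @name phase-constraints
NULL

#' @rdname phase-constraints
#' @export
apply_anaerobic <- function(model) {
  if (is.null(model$o2_exchange))
    stop("model has no o2_exchange defined")
  j <- match(model$o2_exchange, model$reactions$id)
  model$reactions$lower_bound[j] <- 0
  model$reactions$upper_bound[j] <- max(0, model$reactions$upper_bound[j])
  for (r in tagged_reactions(model, "ETC"))
    model <- set_bounds(model, r, lb = 0, ub = 0)
  model
}

#' @rdname phase-constraints
#' @export
apply_aerobic <- function(model) {
  if (!is.null(model$o2_exchange))
    model <- set_bounds(model, model$o2_exchange, lb = model$o2_uptake_limit)
  for (r in model$carbon_exchanges) {
    j <- match(r, model$reactions$id)
    model$reactions$lower_bound[j] <- max(0, model$reactions$lower_bound[j])
  }
  for (r in tagged_reactions(model, "storage_sink")) {
    j <- match(r, model$reactions$id)
    model$reactions$lower_bound[j] <-
      min(model$reactions$lower_bound[j], -1000)
  }
  model
}

#' Set the non-growth-associated maintenance demand
#'
#' Raises the lower bound of the maintenance (ATP hydrolysis) reaction to
#' `ngam`, forcing that much ATP turnover in every solve. The default of
#' 0.398 mmol ATP gDW^-1 h^-1 is the constant maintenance demand used for
#' all cycle simulations.
#'
#' @param model a `gem_model`.
#' @param ngam maintenance flux in mmol ATP gDW^-1 h^-1 (>= 0).
#' @return a modified copy of the model.
#' @export
set_maintenance <- function(model, ngam = 0.398) {
  if (!is.numeric(ngam) || length(ngam) != 1 || is.na(ngam) || ngam < 0)
    stop("ngam must be a single non-negative number")
  j <- match(model$maintenance_reaction, model$reactions$id)
  model$reactions$lower_bound[j] <- ngam
  if (model$reactions$upper_bound[j] < ngam)
    model$reactions$upper_bound[j] <- ngam
  model
}
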