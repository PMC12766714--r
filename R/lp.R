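#' Flux-balance analysis solves
#'
#' The linear programs behind the EBPR cycle simulator and the phenotype
#' screens. All solves share the steady-state constraint S v = 0 over every
#' metabolite outside the `pool` compartment (storage polymers are integrated
#' in time by the simulator, not balanced by the LP) together with the flux
#' bounds of the model.
#'
#' @name fba-solves
NULL

# cap for bounds the caller left infinite; generated models use +/-1000
.LP_BIGBOUND <- 1e6

.solve_lp <- function(S, b, cost, lb, ub, maximize = FALSE,
                      max_iter = 50000L) {
  lb <- pmax(lb, -.LP_BIGBOUND)
  ub <- pmin(ub, .LP_BIGBOUND)
  res <- .lp_simplex(as.matrix(S), b, if (maximize) -cost else cost, lb, ub,
                     max_iter)
  if (res$status == 2)
    stop("LP solver failed to converge (numerical trouble or iteration limit)")
  if (res$status == 1) return(list(status = "infeasible"))
  list(status = "optimal", x = as.numeric(res$x),
       objective = if (maximize) -res$objective else res$objective)
}

.balanced_matrix <- function(model) {
  keep <- model$metabolites$compartment != "pool"
  model$stoichiometry[keep, , drop = FALSE]
}

.flux_solution <- function(fluxes, objective_value, model,
                           status = "optimal", total_abs_flux = NA_real_) {
  growth <- if (status == "optimal")
    unname(fluxes[model$biomass_reaction]) else NA_real_
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 growth_rate = growth, status = status,
                 total_abs_flux = total_abs_flux),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution [", x$status, "]", sep = "")
  if (x$status == "optimal")
    cat("  objective:", signif(x$objective_value, 6),
        " growth:", signif(x$growth_rate, 6))
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Optimizes the flux through one reaction subject to steady state and the
#' model's bounds. Aerobic growth predictions use `sense = "max"` on the
#' biomass reaction; the resulting flux through that reaction is the
#' predicted specific growth rate mu (h^-1).
#'
#' @param model a `gem_model`.
#' @param objective reaction id to optimize (default: the biomass reaction).
#' @param sense `"max"` or `"min"`.
#' @return a `flux_solution` with fields `fluxes` (named), `objective_value`,
#'   `growth_rate` and `status` (`"optimal"` or `"infeasible"`).
#' @export
solve_fba <- function(model, objective = model$biomass_reaction,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- match(objective, model$reactions$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  S <- .balanced_matrix(model)
  n <- ncol(S)
  cost <- numeric(n); cost[j] <- 1
  res <- .solve_lp(S, numeric(nrow(S)), cost,
                   model$reactions$lower_bound, model$reactions$upper_bound,
                   maximize = (sense == "max"))
  if (res$status == "infeasible")
    return(.flux_solution(NULL, NA_real_, model, status = "infeasible"))
  v <- setNames(res$x, model$reactions$id)
  .flux_solution(v, res$objective, model,
                 total_abs_flux = sum(abs(v)))
}

# L1 flux minimization by reversible splitting: v = p - q with
# p in [max(lb,0), max(ub,0)], q in [max(-ub,0), max(-lb,0)], min sum(p+q).
.solve_l1 <- function(model) {
  S <- .balanced_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  lb <- pmax(lb, -.LP_BIGBOUND); ub <- pmin(ub, .LP_BIGBOUND)
  A <- cbind(as.matrix(S), -as.matrix(S))
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- .solve_lp(A, numeric(nrow(S)), rep(1, 2 * n), lo, hi)
  if (res$status == "infeasible") return(list(status = "infeasible"))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  list(status = "optimal", fluxes = setNames(v, model$reactions$id),
       total = res$objective)
}

#' Parsimonious FBA
#'
#' Maximizes biomass formation, then — with the biomass flux pinned to the
#' optimum (scaled by `1 - slack` to avoid numerical infeasibility) —
#' minimizes the total absolute flux sum over all reactions. The L1 norm is
#' implemented by the standard reversible-reaction split into two
#' irreversible halves.
#'
#' @param model a `gem_model`.
#' @param slack relative slack on the biomass optimum before the L1
#'   minimization (default 1e-6).
#' @return a `flux_solution`; `objective_value` and `growth_rate` are the
#'   achieved biomass flux, `total_abs_flux` the minimized flux sum.
#' @export
solve_pfba <- function(model, slack = 1e-6) {
  base <- solve_fba(model)
  if (base$status != "optimal") return(base)
  opt <- base$objective_value
  floor_mu <- opt - abs(opt) * slack
  m2 <- set_bounds(model, model$biomass_reaction, lb = floor_mu)
  l1 <- .solve_l1(m2)
  if (l1$status == "infeasible") {
    # should not happen given the slack; fall back to the FBA vertex
    return(base)
  }
  mu <- unname(l1$fluxes[model$biomass_reaction])
  .flux_solution(l1$fluxes, mu, model, total_abs_flux = l1$total)
}

#' Total-flux minimization under a fixed substrate uptake
#'
#' The anaerobic-phase objective of the EBPR cycle: with a carbon substrate's
#' exchange flux fixed to `-uptake_rate` (uptake), minimize the sum of
#' absolute fluxes subject to steady state, the model bounds and the
#' maintenance (NGAM) lower bound. This approximates energy-efficient storage
#' metabolism; the storage-sink fluxes of the solution are the instantaneous
#' pool accumulation rates (negative = pool consumption).
#'
#' @param model a `gem_model`.
#' @param substrate_exchange exchange reaction id; must belong to
#'   `model$carbon_exchanges`.
#' @param uptake_rate fixed uptake in mmol gDW^-1 h^-1 (>= 0).
#' @return a `flux_solution`; `objective_value` is the minimized total
#'   absolute flux. Infeasibility (e.g. a required cofactor absent) is
#'   returned as `status = "infeasible"`, not raised.
#' @export
solve_min_total_flux <- function(model, substrate_exchange, uptake_rate) {
  if (!substrate_exchange %in% model$carbon_exchanges)
    stop("substrate_exchange must be one of model$carbon_exchanges")
  if (uptake_rate < 0) stop("uptake_rate must be >= 0")
  m2 <- set_bounds(model, substrate_exchange,
                   lb = -uptake_rate, ub = -uptake_rate)
  l1 <- .solve_l1(m2)
  if (l1$status == "infeasible")
    return(.flux_solution(NULL, NA_real_, model, status = "infeasible"))
  .flux_solution(l1$fluxes, l1$total, model, total_abs_flux = l1$total)
}

#' Maximum steady-state residual of a flux solution
#'
#' @param solution an optimal `flux_solution`.
#' @param model the model it was solved on.
#' @return largest |S v| over balanced (non-pool) metabolites.
#' @export
steady_state_residual <- function(solution, model) {
  if (solution$status != "optimal") return(NA_real_)
  S <- .balanced_matrix(model)
  max(abs(as.numeric(S %*% solution$fluxes)))
}

#' Write fluxes of a solution as TSV
#'
#' Two columns, `reaction_id` and `flux`.
#' @param solution an optimal `flux_solution`.
#' @param path output file.
#' @export
write_flux_tsv <- function(solution, path) {
  df <- data.frame(reaction_id = names(solution$fluxes),
                   flux = unname(solution$fluxes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump a flux solution as JSON
#' @param solution a `flux_solution`.
#' @param path output file.
#' @export
write_solution_json <- function(solution, path) {
  jsonlite::write_json(
    list(status = solution$status,
         objective_value = solution$objective_value,
         growth_rate = solution$growth_rate,
         fluxes = as.list(solution$fluxes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
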