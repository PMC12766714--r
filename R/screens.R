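#' Apply the minimal screening medium
#'
#' Aerobic minimal medium with a single carbon source and inorganic ions:
#' every carbon exchange except `carbon_source` is closed to uptake, the
#' chosen source is opened at `carbon_bound`, oxygen uptake is opened to the
#' model's configured limit, and every amino-acid exchange lower bound is
#' set to `aa_bound` (negative = uptake allowed, 0 = blocked). Ion and gas
#' exchanges keep the bounds stored in the model.
#'
#' @param model a `gem_model`.
#' @param carbon_source exchange id of the carbon source; defaults to
#'   `EX_ac_e` if present, else the first carbon exchange.
#' @param carbon_bound uptake bound for the carbon source (default -10).
#' @param aa_bound lower bound applied to all amino-acid exchanges
#'   (default -10; use 0 to block amino-acid uptake).
#' @return a modified copy of the model.
#' @export
# storage pools are not balanced by the LP, so outside the time-resolved
# cycle (where amounts cap them) a pool-consuming sink would be a phantom
# carbon/ATP source; screens therefore block the consuming direction
.close_pool_consumption <- function(model) {
  for (r in tagged_reactions(model, "storage_sink")) {
    j <- match(r, model$reactions$id)
    p <- which(model$stoichiometry[, j] != 0 &
                 model$metabolites$compartment == "pool")
    if (model$stoichiometry[p, j] > 0)
      model$reactions$lower_bound[j] <-
        max(0, model$reactions$lower_bound[j])
    else
      model$reactions$upper_bound[j] <-
        min(0, model$reactions$upper_bound[j])
  }
  model
}

apply_minimal_medium <- function(model, carbon_source = NULL,
                                 carbon_bound = -10, aa_bound = -10) {
  if (is.null(carbon_source)) {
    carbon_source <- if ("EX_ac_e" %in% model$carbon_exchanges) "EX_ac_e"
      else model$carbon_exchanges[1]
  }
  if (!carbon_source %in% model$carbon_exchanges)
    stop("carbon_source must be one of model$carbon_exchanges")
  for (r in model$carbon_exchanges) {
    j <- match(r, model$reactions$id)
    model$reactions$lower_bound[j] <-
      if (r == carbon_source) carbon_bound
      else max(0, model$reactions$lower_bound[j])
  }
  if (!is.null(model$o2_exchange))
    model <- set_bounds(model, model$o2_exchange,
                        lb = model$o2_uptake_limit)
  for (r in model$amino_acid_exchanges)
    model <- set_bounds(model, r, lb = aa_bound)
  .close_pool_consumption(model)
}

#' Amino-acid auxotrophy screen
#'
#' Simulates the model aerobically in a minimal medium (single carbon
#' source plus inorganic ions) with all 20 amino-acid uptakes open, then
#' re-solves 20 times with exactly one amino-acid uptake blocked (lower
#' bound 0) and everything else unchanged. The model is called auxotrophic
#' for an amino acid when the predicted growth rate with that uptake blocked
#' drops below `threshold` (default 0.01 h^-1), prototrophic otherwise.
#'
#' @param model a `gem_model`.
#' @param threshold growth-rate cutoff in h^-1.
#' @param carbon_source,carbon_bound,aa_bound see [apply_minimal_medium()].
#' @return an `auxotrophy_profile`: `model_id`, `baseline_growth`,
#'   `per_aa_growth` (named), `calls` (named, auxotroph/prototroph) and
#'   `fully_prototrophic`.
#' @export
screen_auxotrophy <- function(model, threshold = 0.01, carbon_source = NULL,
                              carbon_bound = -10, aa_bound = -10) {
  if (!length(model$amino_acid_exchanges))
    stop("model has no amino_acid_exchanges")
  med <- apply_minimal_medium(model, carbon_source, carbon_bound, aa_bound)
  base <- solve_fba(med)
  if (base$status != "optimal")
    stop("medium cannot support the model (baseline FBA infeasible)")
  aas <- names(model$amino_acid_exchanges)
  per <- setNames(numeric(length(aas)), aas)
  for (a in aas) {
    m2 <- set_bounds(med, model$amino_acid_exchanges[[a]], lb = 0)
    sol <- solve_fba(m2)
    per[[a]] <- if (sol$status == "optimal") sol$growth_rate else 0
  }
  calls <- ifelse(per < threshold, "auxotroph", "prototroph")
  structure(list(model_id = model$id, baseline_growth = base$growth_rate,
                 per_aa_growth = per, calls = calls,
                 threshold = threshold,
                 fully_prototrophic = !any(calls == "auxotroph")),
            class = "auxotrophy_profile")
}

#' @export
print.auxotrophy_profile <- function(x, ...) {
  aux <- names(x$calls)[x$calls == "auxotroph"]
  cat("auxotrophy_profile for", x$model_id, "- baseline mu =",
      signif(x$baseline_growth, 4), "h^-1\n")
  cat(if (length(aux)) paste("  auxotrophic for:",
                             paste(aux, collapse = ", "))
      else "  fully prototrophic", "\n")
  invisible(x)
}

#' Amino-acid secretion screen
#'
#' With amino-acid uptake blocked in the minimal medium, fixes biomass
#' formation at `growth_fraction` of its optimum and then maximizes the
#' export flux of each amino-acid exchange in turn (flux-variability style).
#' An amino acid is secretable when its maximum export exceeds `flux_tol`.
#'
#' @param model a `gem_model`.
#' @param growth_fraction fraction of the growth optimum to retain.
#' @param flux_tol minimum export flux to call secretion.
#' @param carbon_source,carbon_bound see [apply_minimal_medium()].
#' @return a `secretion_profile`: `model_id`, `secretable` (character),
#'   `max_export` (named numeric), criterion metadata, and `reason` when the
#'   screen could not run (no growth on the medium).
#' @export
screen_secretion <- function(model, growth_fraction = 0.5,
                             flux_tol = 1e-6, carbon_source = NULL,
                             carbon_bound = -10) {
  out <- structure(list(model_id = model$id, secretable = character(),
                        max_export = numeric(),
                        growth_fraction = growth_fraction,
                        flux_tol = flux_tol, reason = NA_character_),
                   class = "secretion_profile")
  if (!length(model$amino_acid_exchanges)) return(out)
  med <- apply_minimal_medium(model, carbon_source, carbon_bound,
                              aa_bound = 0)
  base <- solve_fba(med)
  if (base$status != "optimal" || base$growth_rate <= 0) {
    out$reason <- "no growth on the minimal medium"
    return(out)
  }
  med <- set_bounds(med, med$biomass_reaction,
                    lb = growth_fraction * base$growth_rate)
  mx <- setNames(numeric(length(model$amino_acid_exchanges)),
                 names(model$amino_acid_exchanges))
  for (a in names(model$amino_acid_exchanges)) {
    sol <- solve_fba(med, objective = model$amino_acid_exchanges[[a]],
                     sense = "max")
    mx[[a]] <- if (sol$status == "optimal") sol$objective_value else 0
  }
  out$max_export <- mx
  out$secretable <- names(mx)[mx > flux_tol]
  out
}

# a substrate lacks transport when its extracellular metabolite is touched
# by no reaction other than the exchange itself
.has_transporter <- function(model, exchange) {
  j <- match(exchange, model$reactions$id)
  if (is.na(j)) return(FALSE)
  p <- which(model$stoichiometry[, j] != 0)
  sum(model$stoichiometry[p, ] != 0) > 1
}

#' Carbon-substrate utilization screen
#'
#' Runs [simulate_cycle()] for every model x substrate combination. A
#' substrate is utilizable when the cycle completes and the biomass yield
#' exceeds `yield_threshold`; failures are staged as `no_transporter` (the
#' exchange/transport pair is absent from the model), `anaerobic_infeasible`
#' (a cycle step had no feasible flux distribution) or `zero_yield`.
#'
#' @param models a named list of `gem_model`s (names default to model ids).
#' @param substrates named character vector mapping substrate names to
#'   exchange reaction ids (a bare character vector is used as both).
#' @param config a [cycle_config()].
#' @param yield_threshold minimum yield (gDW per C-mmol) to call
#'   utilization (default 1e-6, separating numerical zeros from real
#'   yields).
#' @return a data.frame with one row per model x substrate: `model`,
#'   `substrate`, `exchange`, `utilizable`, `yield`, `failure_stage`.
#' @export
screen_substrates <- function(models, substrates, config = cycle_config(),
                              yield_threshold = 1e-6) {
  if (inherits(models, "gem_model")) models <- list(models)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$id, character(1))
  if (is.null(names(substrates))) names(substrates) <- substrates
  rows <- list()
  for (mn in names(models)) {
    model <- models[[mn]]
    for (sn in names(substrates)) {
      ex <- substrates[[sn]]
      row <- list(model = mn, substrate = sn, exchange = ex,
                  utilizable = FALSE, yield = NA_real_,
                  failure_stage = "none")
      if (!ex %in% model$reactions$id || !.has_transporter(model, ex)) {
        row$failure_stage <- "no_transporter"
      } else {
        traj <- simulate_cycle(model, ex, config)
        if (traj$status != "complete") {
          row$failure_stage <- "anaerobic_infeasible"
        } else {
          y <- biomass_yield(traj, model)
          row$yield <- as.numeric(y)
          if (!is.na(y) && y > yield_threshold) {
            row$utilizable <- TRUE
          } else {
            row$failure_stage <- "zero_yield"
          }
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(model = character(), substrate = character(),
                      exchange = character(), utilizable = logical(),
                      yield = numeric(), failure_stage = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Model x substrate yield matrix from a substrate screen
#' @param report data.frame from [screen_substrates()].
#' @return numeric matrix, models in rows, substrates in columns.
#' @export
yield_matrix <- function(report) {
  models <- unique(report$model); subs <- unique(report$substrate)
  m <- matrix(NA_real_, length(models), length(subs),
              dimnames = list(models, subs))
  for (i in seq_len(nrow(report)))
    m[report$model[i], report$substrate[i]] <- report$yield[i]
  m
}

#' Summary of auxotrophy profiles across a model collection
#'
#' @param profiles list of `auxotrophy_profile`s.
#' @return list with `n`, `fraction_fully_prototrophic`, and
#'   `per_aa_auxotroph_counts` (named integer).
#' @export
prototrophy_summary <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  aas <- names(profiles[[1]]$calls)
  counts <- setNames(integer(length(aas)), aas)
  full <- 0L
  for (p in profiles) {
    if (p$fully_prototrophic) full <- full + 1L
    aux <- names(p$calls)[p$calls == "auxotroph"]
    counts[aux] <- counts[aux] + 1L
  }
  list(n = length(profiles),
       fraction_fully_prototrophic = full / length(profiles),
       per_aa_auxotroph_counts = counts)
}
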