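#' Configuration of one anaerobic-aerobic EBPR cycle
#'
#' Defaults follow the canonical cycle: a 1.5 h anaerobic phase, a 3.5 h
#' aerobic phase, integrated at 0.2 h per step, with a constant maintenance
#' demand of 0.398 mmol ATP gDW^-1 h^-1. The reactor volume is fixed at one
#' litre so extracellular mmol and mM coincide. Storage pool amounts are
#' absolute (C-mmol for PHA/glycogen, P-mmol for polyphosphate); biomass is
#' gDW in the unit volume.
#'
#' @param anaerobic_hours,aerobic_hours phase durations in h.
#' @param dt Euler step in h; must not exceed either phase duration.
#' @param uptake_rate anaerobic substrate uptake in mmol gDW^-1 h^-1.
#' @param ngam maintenance ATP demand in mmol gDW^-1 h^-1.
#' @param initial_substrate starting substrate amount (mmol in 1 L).
#' @param initial_glycogen,initial_polyP,initial_PHA starting pool amounts.
#' @param initial_biomass starting biomass (gDW in 1 L).
#' @param random_seed reserved; the cycle core is deterministic.
#' @return a `cycle_config` list.
#' @export
cycle_config <- function(anaerobic_hours = 1.5, aerobic_hours = 3.5,
                         dt = 0.2, uptake_rate = 3, ngam = 0.398,
                         initial_substrate = 15, initial_glycogen = 10,
                         initial_polyP = 10, initial_PHA = 0,
                         initial_biomass = 1, random_seed = 1L) {
  cfg <- list(anaerobic_hours = anaerobic_hours,
              aerobic_hours = aerobic_hours, dt = dt,
              uptake_rate = uptake_rate, ngam = ngam,
              initial_substrate = initial_substrate,
              initial_glycogen = initial_glycogen,
              initial_polyP = initial_polyP, initial_PHA = initial_PHA,
              initial_biomass = initial_biomass, random_seed = random_seed)
  if (cfg$anaerobic_hours <= 0 || cfg$aerobic_hours <= 0 || cfg$dt <= 0)
    stop("durations and dt must be positive")
  if (cfg$dt > min(cfg$anaerobic_hours, cfg$aerobic_hours))
    stop("dt must not exceed either phase duration")
  pools <- c(cfg$initial_substrate, cfg$initial_glycogen, cfg$initial_polyP,
             cfg$initial_PHA, cfg$initial_biomass)
  if (any(pools < 0)) stop("initial amounts must be non-negative")
  if (cfg$uptake_rate < 0 || cfg$ngam < 0)
    stop("uptake_rate and ngam must be non-negative")
  structure(cfg, class = "cycle_config")
}

#' Read a cycle configuration from YAML
#'
#' The YAML keys are exactly the [cycle_config()] argument names; missing
#' keys take the defaults.
#' @param path YAML file.
#' @return a `cycle_config`.
#' @export
read_cycle_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cycle_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown cycle config keys: ",
                        paste(bad, collapse = ", "))
  do.call(cycle_config, vals)
}

# step widths covering `hours` in chunks of dt, final step truncated
.phase_steps <- function(hours, dt) {
  n <- ceiling(hours / dt - 1e-9)
  w <- rep(dt, n)
  w[n] <- hours - dt * (n - 1)
  w
}

.pool_rows <- function(model) which(model$metabolites$compartment == "pool")

# Cap storage-sink bounds so no pool can be driven negative. `horizon` is
# the time over which the current amount may be spent: the bare Euler step
# anaerobically (rates there are set by the fixed uptake), but the
# remaining phase duration aerobically — growth maximization would
# otherwise exhaust every reserve in the first aerobic step and leave the
# maintenance demand infeasible for the rest of the phase; pacing
# mobilization over the remaining time spreads growth across the phase and
# keeps maintenance satisfiable to the end.
.cap_sinks <- function(model, pool_amt, X, delta, horizon = delta) {
  for (r in tagged_reactions(model, "storage_sink")) {
    j <- match(r, model$reactions$id)
    p <- which(model$stoichiometry[, j] != 0 &
                 model$metabolites$compartment == "pool")
    s <- model$stoichiometry[p, j]
    avail <- pool_amt[[model$metabolites$id[p]]]
    lim <- avail / (abs(s) * X * max(delta, horizon))
    if (s > 0) {
      model$reactions$lower_bound[j] <-
        max(model$reactions$lower_bound[j], -lim)
    } else {
      model$reactions$upper_bound[j] <-
        min(model$reactions$upper_bound[j], lim)
    }
    if (model$reactions$lower_bound[j] > model$reactions$upper_bound[j])
      model$reactions$lower_bound[j] <- model$reactions$upper_bound[j]
  }
  model
}

.find_co2_exchange <- function(model) {
  for (r in tagged_reactions(model, "exchange")) {
    j <- match(r, model$reactions$id)
    p <- which(model$stoichiometry[, j] != 0)
    met <- model$metabolites[p, ]
    if (met$role == "gas" && met$carbon_atoms > 0) return(r)
  }
  NULL
}

#' Simulate one anaerobic-aerobic EBPR cycle
#'
#' Time-resolved dynamic FBA. During the anaerobic phase the model is placed
#' under [apply_anaerobic()] constraints, biomass formation is fixed to zero
#' (storage metabolism, not growth), and each step solves
#' [solve_min_total_flux()] with the uptake capped by the substrate still
#' available: `min(uptake_rate, remaining / (X * dt))`. During the aerobic
#' phase the model is placed under [apply_aerobic()] constraints and each
#' step solves [solve_pfba()]. After every step each tracked extracellular
#' or storage quantity Q is advanced by forward Euler,
#' `Q(t + dt) = Q(t) + v_Q * X(t) * dt`, and biomass by
#' `X(t + dt) = X(t) * (1 + mu * dt)`. Storage-sink bounds are capped each
#' step so no pool goes negative. Every other carbon exchange and all
#' amino-acid uptakes are closed for the whole cycle so the substrate under
#' test is the sole external carbon source.
#'
#' An infeasible step terminates the trajectory with a status flag rather
#' than raising; the batch substrate screen interprets this as "not
#' utilizable".
#'
#' @param model a `gem_model`.
#' @param substrate exchange reaction id in `model$carbon_exchanges`.
#' @param config a [cycle_config()].
#' @param anaerobic_growth allow biomass formation anaerobically (default
#'   FALSE).
#' @return a `cycle_trajectory`: lists `times`, `phase`, `substrate`, `co2`,
#'   `glycogen`, `polyP`, `PHA`, `biomass`, per-step `step_fluxes`, and
#'   `status` (`"complete"` or `"infeasible"` with `infeasible_at`).
#' @export
simulate_cycle <- function(model, substrate, config = cycle_config(),
                           anaerobic_growth = FALSE) {
  if (!substrate %in% model$carbon_exchanges)
    stop("substrate must be one of model$carbon_exchanges")
  base <- set_maintenance(model, config$ngam)
  for (r in setdiff(base$carbon_exchanges, substrate)) {
    j <- match(r, base$reactions$id)
    base$reactions$lower_bound[j] <- max(0, base$reactions$lower_bound[j])
  }
  for (r in base$amino_acid_exchanges) {
    j <- match(r, base$reactions$id)
    base$reactions$lower_bound[j] <- max(0, base$reactions$lower_bound[j])
  }

  j_sub <- match(substrate, base$reactions$id)
  sub_met <- base$metabolites$id[which(base$stoichiometry[, j_sub] != 0)]
  co2_ex <- .find_co2_exchange(base)

  mets <- base$metabolites
  pool_ids <- mets$id[mets$compartment == "pool"]
  pool_amt <- as.list(setNames(numeric(length(pool_ids)), pool_ids))
  role_of <- setNames(mets$role, mets$id)
  init_by_role <- c(storage_glycogen = config$initial_glycogen,
                    storage_polyP = config$initial_polyP,
                    storage_PHA = config$initial_PHA)
  # initial amounts are divided equally among pool metabolites of a role
  for (role in names(init_by_role)) {
    ids <- pool_ids[role_of[pool_ids] == role]
    for (id in ids) pool_amt[[id]] <- init_by_role[[role]] / length(ids)
  }

  widths <- c(.phase_steps(config$anaerobic_hours, config$dt),
              .phase_steps(config$aerobic_hours, config$dt))
  phases <- c(rep("anaerobic", length(.phase_steps(config$anaerobic_hours,
                                                   config$dt))),
              rep("aerobic", length(.phase_steps(config$aerobic_hours,
                                                 config$dt))))
  nstep <- length(widths)

  sum_role <- function(role) {
    ids <- pool_ids[role_of[pool_ids] == role]
    if (!length(ids)) 0 else sum(unlist(pool_amt[ids]))
  }

  times <- numeric(nstep + 1)
  substrate_s <- numeric(nstep + 1); co2_s <- numeric(nstep + 1)
  gly_s <- numeric(nstep + 1); pp_s <- numeric(nstep + 1)
  pha_s <- numeric(nstep + 1); bio_s <- numeric(nstep + 1)
  phase_s <- character(nstep + 1)
  step_fluxes <- vector("list", nstep)

  X <- config$initial_biomass
  sub <- config$initial_substrate
  co2 <- 0
  record <- function(i) {
    substrate_s[i] <<- sub; co2_s[i] <<- co2
    gly_s[i] <<- sum_role("storage_glycogen")
    pp_s[i] <<- sum_role("storage_polyP")
    pha_s[i] <<- sum_role("storage_PHA")
    bio_s[i] <<- X
  }
  times[1] <- 0; phase_s[1] <- phases[1]; record(1)

  status <- "complete"; infeasible_at <- NA_integer_
  for (k in seq_len(nstep)) {
    delta <- widths[k]
    if (phases[k] == "anaerobic") {
      m <- apply_anaerobic(base)
      if (!anaerobic_growth)
        m <- set_bounds(m, m$biomass_reaction, lb = 0, ub = 0)
      m <- .cap_sinks(m, pool_amt, X, delta)
      eff <- min(config$uptake_rate, sub / (X * delta))
      eff <- max(0, eff)
      sol <- solve_min_total_flux(m, substrate, eff)
    } else {
      m <- apply_aerobic(base)
      t_rem <- sum(widths[k:nstep])
      m <- .cap_sinks(m, pool_amt, X, delta, horizon = t_rem)
      sol <- solve_pfba(m)
    }
    if (sol$status != "optimal") {
      status <- "infeasible"; infeasible_at <- k
      break
    }
    v <- sol$fluxes
    step_fluxes[[k]] <- sol
    sub <- max(0, sub + v[[substrate]] * X * delta)
    if (!is.null(co2_ex)) co2 <- co2 + v[[co2_ex]] * X * delta
    for (r in tagged_reactions(base, "storage_sink")) {
      j <- match(r, base$reactions$id)
      p <- which(base$stoichiometry[, j] != 0 &
                   base$metabolites$compartment == "pool")
      pid <- base$metabolites$id[p]
      pool_amt[[pid]] <- max(0, pool_amt[[pid]] +
                               base$stoichiometry[p, j] * v[[r]] * X * delta)
    }
    mu <- if (phases[k] == "aerobic" || anaerobic_growth)
      max(0, v[[base$biomass_reaction]]) else 0
    X <- X * (1 + mu * delta)
    times[k + 1] <- times[k] + delta
    phase_s[k + 1] <- phases[k]
    record(k + 1)
  }

  keep <- if (status == "complete") seq_len(nstep + 1) else seq_len(infeasible_at)
  structure(list(times = times[keep], phase = phase_s[keep],
                 substrate = substrate_s[keep], co2 = co2_s[keep],
                 glycogen = gly_s[keep], polyP = pp_s[keep],
                 PHA = pha_s[keep], biomass = bio_s[keep],
                 step_fluxes = step_fluxes[seq_len(min(length(keep),
                                                       nstep))],
                 status = status, infeasible_at = infeasible_at,
                 substrate_exchange = substrate, config = config),
            class = "cycle_trajectory")
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("cycle_trajectory [", x$status, "]: ", n - 1, " steps to t = ",
      x$times[n], " h\n", sep = "")
  cat("  biomass ", signif(x$biomass[1], 4), " -> ",
      signif(x$biomass[n], 4), " gDW; substrate ",
      signif(x$substrate[1], 4), " -> ", signif(x$substrate[n], 4),
      " mmol\n", sep = "")
  invisible(x)
}

#' Trajectory as a data frame / TSV
#'
#' Columns: time_h, phase, substrate_mmol, co2_mmol, glycogen, polyP, PHA,
#' biomass_gDW.
#' @param traj a `cycle_trajectory`.
#' @return a data.frame.
#' @export
trajectory_table <- function(traj) {
  data.frame(time_h = traj$times, phase = traj$phase,
             substrate_mmol = traj$substrate, co2_mmol = traj$co2,
             glycogen = traj$glycogen, polyP = traj$polyP, PHA = traj$PHA,
             biomass_gDW = traj$biomass)
}

#' @rdname trajectory_table
#' @param path output TSV file.
#' @export
write_trajectory_tsv <- function(traj, path) {
  write.table(trajectory_table(traj), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# net carbon consumed per unit biomass flux (C-mmol per gDW formed)
.biomass_carbon <- function(model) {
  j <- match(model$biomass_reaction, model$reactions$id)
  coef <- model$stoichiometry[, j]
  -sum(coef * model$metabolites$carbon_atoms)
}

#' Biomass yield on the cycle substrate
#'
#' `(final biomass - initial biomass) / C-mmol of substrate consumed`, where
#' C-mmol = mmol consumed times the substrate's carbon atoms.
#'
#' @param traj a completed `cycle_trajectory`.
#' @param model the model it was simulated on.
#' @param substrate exchange reaction id (default: the trajectory's).
#' @return yield in gDW per C-mmol, or `NA` with attribute `reason` when no
#'   substrate was consumed.
#' @export
biomass_yield <- function(traj, model,
                          substrate = traj$substrate_exchange) {
  j <- match(substrate, model$reactions$id)
  if (is.na(j)) stop("unknown substrate exchange: ", substrate)
  met <- which(model$stoichiometry[, j] != 0)
  catoms <- model$metabolites$carbon_atoms[met]
  if (catoms <= 0) stop("substrate metabolite has no carbon")
  n <- length(traj$substrate)
  consumed <- traj$substrate[1] - traj$substrate[n]
  if (consumed <= 1e-12)
    return(structure(NA_real_, reason = "no substrate consumed"))
  (traj$biomass[n] - traj$biomass[1]) / (consumed * catoms)
}

#' Carbon ledger of a cycle trajectory
#'
#' Verifies the Euler scheme: carbon in (substrate consumed plus glycogen
#' drawdown) against carbon out (CO2 plus net PHA accumulation plus biomass
#' carbon), all in C-mmol, with the residual expressed relative to the
#' inputs.
#'
#' @param traj a completed `cycle_trajectory`.
#' @param model the model it was simulated on.
#' @return a list with the individual terms, `residual` (C-mmol) and
#'   `residual_rel` (fraction of carbon input).
#' @export
carbon_balance <- function(traj, model) {
  j <- match(traj$substrate_exchange, model$reactions$id)
  met <- which(model$stoichiometry[, j] != 0)
  catoms <- model$metabolites$carbon_atoms[met]
  n <- length(traj$substrate)
  substrate_c <- (traj$substrate[1] - traj$substrate[n]) * catoms
  glycogen_drawdown <- traj$glycogen[1] - traj$glycogen[n]
  co2_c <- traj$co2[n] - traj$co2[1]
  pha_net <- traj$PHA[n] - traj$PHA[1]
  biomass_c <- (traj$biomass[n] - traj$biomass[1]) * .biomass_carbon(model)
  c_in <- substrate_c + glycogen_drawdown
  c_out <- co2_c + pha_net + biomass_c
  residual <- c_in - c_out
  list(substrate_c = substrate_c, glycogen_drawdown = glycogen_drawdown,
       co2_c = co2_c, pha_net = pha_net, biomass_c = biomass_c,
       c_in = c_in, c_out = c_out, residual = residual,
       residual_rel = if (abs(c_in) > 1e-12) residual / c_in else 0)
}
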