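# Independent oracles and tiny model builders used across the suite.
# These deliberately re-derive results by brute force, along code paths
# disjoint from the package implementation.

# -- tiny gem_model builder (adds the mandatory ATP/maintenance boilerplate)
tiny_model <- function(mets, rxns, ngam = 0, ...) {
  boiler_mets <- data.frame(
    id = "atp", name = "atp", compartment = "cytosol", carbon_atoms = 0,
    phosphorus_atoms = 0, role = "generic", stringsAsFactors = FALSE)
  if (!"atp" %in% mets$id) mets <- rbind(mets, boiler_mets)
  rxns <- c(rxns, list(list(id = "ATPM", stoich = c(atp = -1), lb = ngam,
                            ub = 1000, tags = "maintenance")))
  gem_from_reactions(mets, rxns, ...)
}

met_row <- function(id, compartment = "cytosol", carbon = 0, phosphorus = 0,
                    role = "generic") {
  data.frame(id = id, name = id, compartment = compartment,
             carbon_atoms = carbon, phosphorus_atoms = phosphorus,
             role = role, stringsAsFactors = FALSE)
}

# a linear chain: A_ext -(EX, lb=-uptake)-> A -> biomass, with an ATP
# source so maintenance demands can be made satisfiable or not
chain_model <- function(uptake = 10, ngam = 0, atp_supply = TRUE) {
  mets <- rbind(met_row("A_e", "extracellular", carbon = 1,
                        role = "carbon_substrate"),
                met_row("A", carbon = 1),
                met_row("atp"))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -uptake, ub = 1000,
         tags = "exchange"),
    list(id = "T_A", stoich = c(A_e = -1, A = 1), lb = 0, ub = 1000,
         tags = "transport"),
    list(id = "BIOMASS", stoich = c(A = -1), lb = 0, ub = 1000,
         tags = "biomass"))
  if (atp_supply)
    rxns <- c(rxns, list(list(id = "ATPS", stoich = c(A = -1, atp = 1),
                              lb = 0, ub = 1000, tags = "internal")))
  tiny_model(mets, rxns, ngam = ngam,
             biomass_reaction = "BIOMASS", maintenance_reaction = "ATPM",
             carbon_exchanges = "EX_A", id = "chain")
}

# -- LP vertex-enumeration oracle -------------------------------------------
# optimum of c'v over {S v = 0, lb <= v <= ub} by enumerating basic
# solutions: fix n-m variables at a bound, solve the square system.
enumerate_lp_optimum <- function(S, lb, ub, cost, maximize = TRUE,
                                 tol = 1e-9) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  stopifnot(n - m >= 0)
  best <- NULL
  free_sets <- combn(n, m, simplify = FALSE)
  for (basic in free_sets) {
    nonbasic <- setdiff(seq_len(n), basic)
    B <- S[, basic, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    k <- length(nonbasic)
    for (mask in seq_len(2^k) - 1) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      vN <- ifelse(at_ub, ub[nonbasic], lb[nonbasic])
      if (any(!is.finite(vN))) next
      rhs <- -S[, nonbasic, drop = FALSE] %*% vN
      vB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      if (any(vB < lb[basic] - tol) || any(vB > ub[basic] + tol)) next
      v <- numeric(n); v[basic] <- vB; v[nonbasic] <- vN
      obj <- sum(cost * v)
      if (is.null(best) || (maximize && obj > best) ||
          (!maximize && obj < best)) best <- obj
    }
  }
  best
}

# the same oracle on a gem_model's FBA problem
enumerate_fba_optimum <- function(model, objective = model$biomass_reaction,
                                  maximize = TRUE) {
  keep <- model$metabolites$compartment != "pool"
  S <- as.matrix(model$stoichiometry[keep, , drop = FALSE])
  cost <- as.numeric(model$reactions$id == objective)
  enumerate_lp_optimum(S, model$reactions$lower_bound,
                       model$reactions$upper_bound, cost, maximize)
}

# -- brute-force spacer scan oracle -----------------------------------------
# plain character-vector sliding window (with end overhangs), independent
# of Biostrings matching
oracle_scan <- function(spacers, votus, min_identity = 97,
                        min_coverage = 90, max_mismatch = 1) {
  revcomp <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  rows <- list()
  for (v in seq_along(votus)) {
    vc <- strsplit(votus[[v]], "")[[1]]
    L <- length(vc)
    for (s in seq_len(nrow(spacers))) {
      n <- nchar(spacers$sequence[s])
      min_aln <- max(1L, as.integer(ceiling(min_coverage / 100 * n - 1e-9)))
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") spacers$sequence[s] else
          revcomp(spacers$sequence[s])
        pc <- strsplit(pat, "")[[1]]
        for (start0 in seq.int(1L - (n - min_aln), L - min_aln + 1L)) {
          lo <- max(1L, start0); hi <- min(L, start0 + n - 1L)
          aligned <- hi - lo + 1L
          if (aligned < min_aln) next
          mism <- sum(vc[lo:hi] != pc[(lo - start0 + 1):(hi - start0 + 1)])
          identity <- (aligned - mism) / aligned * 100
          coverage <- aligned / n * 100
          if (mism <= max_mismatch && identity >= min_identity &&
              coverage >= min_coverage)
            rows[[length(rows) + 1]] <- data.frame(
              spacer_id = spacers$id[s], votu_id = names(votus)[v],
              strand = strand, start = lo - 1L, end = hi,
              mismatches = mism, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(data.frame(spacer_id = character(),
                                       votu_id = character(),
                                       strand = character(),
                                       start = integer(), end = integer(),
                                       mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(out$spacer_id, out$votu_id, out$strand, out$start), ]
}

# -- exhaustive Wagner parsimony oracle -------------------------------------
# minimum total cost over all internal-node labelings in 0..max_state
oracle_wagner_cost <- function(tree, tip_counts, gain = 2, loss = 1,
                               max_state = 2) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  states <- c(tip_counts[tree$tip.label], rep(NA, n_node))
  grid <- do.call(expand.grid, rep(list(0:max_state), n_node))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    states[n_tip + seq_len(n_node)] <- as.numeric(grid[i, ])
    d <- states[edge[, 2]] - states[edge[, 1]]
    cost <- sum(gain * pmax(0, d) + loss * pmax(0, -d))
    if (cost < best) best <- cost
  }
  best
}
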