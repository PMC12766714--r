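#' Seeded synthetic-data generators
#'
#' Every generator is a pure function of its arguments: a given seed yields
#' byte-identical output. One global seed fans out to per-generator
#' substreams through fixed documented offsets (PAO models use no
#' randomness; gene matrices +101, ANI fixtures +211, spacer fixtures
#' +307, abundance fixtures +401), so adding a generator never perturbs
#' existing fixtures.
#'
#' @name synthetic-data
NULL

.SEED_OFFSETS <- c(gene = 101L, ani = 211L, spacer = 307L,
                   abundance = 401L)

AA_NAMES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
              "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
              "Thr", "Trp", "Tyr", "Val")

#' Knockout catalog of the synthetic PAO model
#'
#' @return character vector of valid knockout names: one
#'   `<AA>-biosynthesis` per amino acid plus the transporter losses the
#'   substrate screen probes.
#' @export
pao_knockout_catalog <- function() {
  c(paste0(AA_NAMES, "-biosynthesis"),
    "lactate-transporter", "glycerol-transporter",
    "glucose-PTS-manX", "glucose-PTS-ptsG", "acetate-transporter")
}

#' Synthetic PAO-style genome-scale model
#'
#' Builds a compact (~90 reaction) stoichiometric model with the metabolic
#' architecture of a polyphosphate-accumulating organism: exchanges and
#' transporters for acetate, lactate, glycerol and glucose (the latter as
#' two redundant PTS variants), a condensed glycolysis /
#' gluconeogenesis / TCA / glyoxylate core, PHA, glycogen and
#' polyphosphate storage pools wired as reversible sink reactions,
#' ETC-tagged oxidative phosphorylation, an ATP maintenance reaction, and
#' a lumped biomass reaction drawing on all 20 amino acids, each with its
#' own biosynthesis reaction and exchange/transport pair. Anaerobically the
#' network can only regenerate ATP from polyphosphate while glycogen and
#' incoming carbon supply the redox for PHA synthesis, which reproduces the
#' canonical anaerobic EBPR phenotype (P release, PHA accumulation); ATP
#' from substrate-level phosphorylation is deliberately lumped into the
#' polyphosphate and ETC routes.
#'
#' @param knockouts character vector of names from
#'   [pao_knockout_catalog()]; the corresponding reactions are removed.
#' @param ngam maintenance lower bound applied at construction.
#' @param include_amino_acid_exchanges set FALSE to build a model without
#'   amino-acid exchange/transport reactions (secretion screens then see
#'   an empty candidate set).
#' @param o2_uptake_limit aerobic oxygen uptake bound.
#' @param id model id.
#' @return a validated `gem_model`.
#' @export
make_pao_model <- function(knockouts = character(), ngam = 0.398,
                           include_amino_acid_exchanges = TRUE,
                           o2_uptake_limit = -1000, id = "pao_model") {
  catalog <- pao_knockout_catalog()
  bad <- setdiff(knockouts, catalog)
  if (length(bad))
    stop("unknown knockout name(s): ", paste(bad, collapse = ", "),
         "\nvalid names: ", paste(catalog, collapse = ", "))

  met <- function(id, compartment, carbon = 0, phosphorus = 0,
                  role = "generic", name = id)
    data.frame(id = id, name = name, compartment = compartment,
               carbon_atoms = carbon, phosphorus_atoms = phosphorus,
               role = role, stringsAsFactors = FALSE)
  mets <- rbind(
    met("ac_e", "extracellular", 2, role = "carbon_substrate"),
    met("lac_e", "extracellular", 3, role = "carbon_substrate"),
    met("glyc_e", "extracellular", 3, role = "carbon_substrate"),
    met("glc_e", "extracellular", 6, role = "carbon_substrate"),
    met("o2_e", "extracellular", role = "gas"),
    met("co2_e", "extracellular", 1, role = "gas"),
    met("pi_e", "extracellular", phosphorus = 1, role = "ion"),
    met("nh4_e", "extracellular", role = "ion"),
    met("ac_c", "cytosol", 2),
    met("lac_c", "cytosol", 3),
    met("glyc_c", "cytosol", 3),
    met("g6p", "cytosol", 6),
    met("pyr", "cytosol", 3),
    met("accoa", "cytosol", 2),
    met("atp", "cytosol"), met("adp", "cytosol"),
    met("nad", "cytosol"), met("nadh", "cytosol"),
    met("pi_c", "cytosol", phosphorus = 1, role = "ion"),
    met("nh4_c", "cytosol", role = "ion"),
    met("o2_c", "cytosol", role = "gas"),
    met("co2_c", "cytosol", 1, role = "gas"),
    met("pha_p", "pool", 1, role = "storage_PHA",
        name = "polyhydroxyalkanoate (C units)"),
    met("glyco_p", "pool", 1, role = "storage_glycogen",
        name = "glycogen (C units)"),
    met("polyp_p", "pool", phosphorus = 1, role = "storage_polyP",
        name = "polyphosphate (P units)"))
  aa_lo <- tolower(AA_NAMES)
  for (a in aa_lo) {
    mets <- rbind(mets, met(paste0("aa_", a, "_c"), "cytosol", 3,
                            role = "amino_acid", name = a))
    if (include_amino_acid_exchanges)
      mets <- rbind(mets, met(paste0("aa_", a, "_e"), "extracellular", 3,
                              role = "amino_acid", name = a))
  }

  rx <- function(id, stoich, lb = 0, ub = 1000, tags = "internal")
    list(id = id, stoich = stoich, lb = lb, ub = ub, tags = tags)
  rxns <- list(
    rx("EX_ac_e", c(ac_e = -1), lb = -10, tags = "exchange"),
    rx("EX_lac_e", c(lac_e = -1), lb = -10, tags = "exchange"),
    rx("EX_glyc_e", c(glyc_e = -1), lb = -10, tags = "exchange"),
    rx("EX_glc_e", c(glc_e = -1), lb = -10, tags = "exchange"),
    rx("EX_o2_e", c(o2_e = -1), lb = o2_uptake_limit, tags = "exchange"),
    rx("EX_co2_e", c(co2_e = -1), tags = "exchange"),
    rx("EX_pi_e", c(pi_e = -1), lb = -1000, tags = "exchange"),
    rx("EX_nh4_e", c(nh4_e = -1), lb = -1000, tags = "exchange"),
    rx("ACt", c(ac_e = -1, ac_c = 1), tags = "transport"),
    rx("ACS", c(ac_c = -1, atp = -1, accoa = 1, adp = 1, pi_c = 1)),
    rx("LACt", c(lac_e = -1, lac_c = 1), tags = "transport"),
    rx("LDH", c(lac_c = -1, nad = -1, pyr = 1, nadh = 1)),
    rx("GLYCt", c(glyc_e = -1, glyc_c = 1), tags = "transport"),
    rx("GLYCDH", c(glyc_c = -1, nad = -1, pyr = 1, nadh = 1)),
    rx("GLCpts_manX", c(glc_e = -1, atp = -1, g6p = 1, adp = 1),
       tags = "transport"),
    rx("GLCpts_ptsG", c(glc_e = -1, atp = -1, g6p = 1, adp = 1),
       tags = "transport"),
    rx("GLYC", c(g6p = -1, nad = -2, pyr = 2, nadh = 2)),
    rx("GNG", c(pyr = -2, atp = -2, nadh = -2, g6p = 1, adp = 2,
                pi_c = 2, nad = 2)),
    rx("PDH", c(pyr = -1, nad = -1, accoa = 1, co2_c = 1, nadh = 1)),
    rx("GLYOX", c(accoa = -2, nad = -1, pyr = 1, co2_c = 1, nadh = 1)),
    rx("TCA", c(accoa = -1, nad = -4, co2_c = 2, nadh = 4)),
    rx("ETC", c(nadh = -1, o2_c = -0.5, adp = -2, pi_c = -2, nad = 1,
                atp = 2), tags = "ETC"),
    rx("O2t", c(o2_e = -1, o2_c = 1), tags = "transport"),
    rx("CO2t", c(co2_c = -1, co2_e = 1), tags = "transport"),
    rx("PIt", c(pi_e = -1, pi_c = 1), lb = -1000, tags = "transport"),
    rx("NH4t", c(nh4_e = -1, nh4_c = 1), tags = "transport"),
    rx("ATPM", c(atp = -1, adp = 1, pi_c = 1), lb = ngam,
       tags = "maintenance"),
    rx("SINK_POLYP", c(atp = -1, adp = 1, polyp_p = 1), lb = -1000,
       tags = "storage_sink"),
    rx("SINK_PHA", c(accoa = -1, nadh = -0.5, nad = 0.5, pha_p = 2),
       lb = -1000, tags = "storage_sink"),
    rx("SINK_GLYCO", c(g6p = -1, atp = -1, adp = 1, pi_c = 1,
                       glyco_p = 6), lb = -1000, tags = "storage_sink"))
  # 10 mmol amino acids (30 C-mmol) and 40 mmol ATP per gDW keeps predicted
  # growth rates on the usual h^-1 scale for chemoheterotrophs
  biomass_stoich <- c(setNames(rep(-0.5, 20), paste0("aa_", aa_lo, "_c")),
                      atp = -40, adp = 40, pi_c = 40)
  rxns <- c(rxns, list(rx("BIOMASS", biomass_stoich, tags = "biomass")))
  for (a in aa_lo) {
    rxns <- c(rxns, list(
      rx(paste0("AASYN_", a),
         setNames(c(-1, -1, -1, -1, 1, 1, 1, 1),
                  c("pyr", "nh4_c", "atp", "nadh",
                    paste0("aa_", a, "_c"), "adp", "pi_c", "nad")))))
    if (include_amino_acid_exchanges) {
      rxns <- c(rxns, list(
        rx(paste0("EX_aa_", a, "_e"),
           setNames(-1, paste0("aa_", a, "_e")), tags = "exchange"),
        rx(paste0("AAt_", a),
           setNames(c(-1, 1), paste0("aa_", a, c("_e", "_c"))),
           lb = -1000, tags = "transport")))
    }
  }

  drop_ids <- character()
  for (k in knockouts) {
    drop_ids <- c(drop_ids, switch(
      k,
      "lactate-transporter" = "LACt",
      "glycerol-transporter" = "GLYCt",
      "glucose-PTS-manX" = "GLCpts_manX",
      "glucose-PTS-ptsG" = "GLCpts_ptsG",
      "acetate-transporter" = "ACt",
      paste0("AASYN_", tolower(sub("-biosynthesis$", "", k)))))
  }
  rxns <- Filter(function(r) !r$id %in% drop_ids, rxns)

  aa_map <- if (include_amino_acid_exchanges)
    setNames(paste0("EX_aa_", aa_lo, "_e"), AA_NAMES) else character()
  gem_from_reactions(
    mets, rxns,
    biomass_reaction = "BIOMASS", maintenance_reaction = "ATPM",
    o2_exchange = "EX_o2_e",
    carbon_exchanges = c("EX_ac_e", "EX_lac_e", "EX_glyc_e", "EX_glc_e"),
    amino_acid_exchanges = aa_map, atp_metabolite = "atp",
    o2_uptake_limit = o2_uptake_limit, id = id)
}

#' Evolve a gene presence/absence matrix on a known tree
#'
#' Binary gene families evolve root-to-tips: a present family is lost along
#' a branch with probability `loss_rate`, an absent one gained with
#' probability `gain_rate`; the root is seeded present with probability
#' `root_presence`. Families absent from every tip are re-labelled as fresh
#' draws until the matrix has no all-zero row (rejection keeps the row count
#' exact). The returned truth records each family's root state and the
#' ancestral/derived label implied by the root (the simulation's LCA).
#'
#' @param tree an `ape::phylo`, or an integer number of tips (a random
#'   topology is then drawn under the same seed).
#' @param n_families number of gene families.
#' @param gain_rate,loss_rate per-branch event probabilities in \[0, 1\].
#' @param seed integer seed.
#' @param root_presence probability a family is present at the root.
#' @return list with `matrix` (a `presence_matrix`), `tree` (node-labeled),
#'   and `truth` (data.frame: family, root_state, class, gains, losses).
#' @export
make_gene_matrix <- function(tree, n_families = 500, gain_rate = 0.02,
                             loss_rate = 0.1, seed = 1,
                             root_presence = 0.6) {
  if (any(c(gain_rate, loss_rate) < 0 | c(gain_rate, loss_rate) > 1))
    stop("rates must be in [0, 1]")
  set.seed(as.integer(seed) + .SEED_OFFSETS[["gene"]])
  if (is.numeric(tree) && length(tree) == 1) tree <- ape::rtree(tree)
  tree <- .label_tree(tree)
  n_tip <- length(tree$tip.label)
  nv <- n_tip + tree$Nnode
  edge_pre <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: ape numbers internal nodes so parents precede children when
  # edges are walked from the root; use a reorder for safety
  edge_pre <- ape::reorder.phylo(tree, "cladewise")$edge

  sim_once <- function(n) {
    states <- matrix(0L, n, nv)
    states[, n_tip + 1L] <- rbinom(n, 1, root_presence)
    gains <- integer(n); losses <- integer(n)
    for (e in seq_len(nrow(edge_pre))) {
      p <- edge_pre[e, 1]; ch <- edge_pre[e, 2]
      sp <- states[, p]
      flip <- runif(n)
      child <- ifelse(sp == 1L, ifelse(flip < loss_rate, 0L, 1L),
                      ifelse(flip < gain_rate, 1L, 0L))
      gains <- gains + (child == 1L & sp == 0L)
      losses <- losses + (child == 0L & sp == 1L)
      states[, ch] <- child
    }
    list(states = states, gains = gains, losses = losses)
  }

  res <- sim_once(n_families)
  repeat {
    tip_sum <- rowSums(res$states[, seq_len(n_tip), drop = FALSE])
    dead <- which(tip_sum == 0)
    if (!length(dead)) break
    redo <- sim_once(length(dead))
    res$states[dead, ] <- redo$states
    res$gains[dead] <- redo$gains
    res$losses[dead] <- redo$losses
  }

  fam <- sprintf("fam_%04d", seq_len(n_families))
  counts <- res$states[, seq_len(n_tip), drop = FALSE]
  dimnames(counts) <- list(fam, tree$tip.label)
  clades <- setNames(rep("cladeA", n_tip), tree$tip.label)
  truth <- data.frame(
    family = fam, root_state = res$states[, n_tip + 1L],
    class = ifelse(res$states[, n_tip + 1L] > 0, "ancestral", "derived"),
    gains = res$gains, losses = res$losses, stringsAsFactors = FALSE)
  list(matrix = presence_matrix(counts, clades), tree = tree,
       truth = truth)
}

#' Block-structured ANI fixture with planted clusters
#'
#' @param cluster_sizes integer vector; genomes are named `g01`, `g02`, ...
#'   in cluster order.
#' @param within_ani,between_ani block ANI percentages (within must exceed
#'   between).
#' @param seed integer seed.
#' @param jitter half-width of the uniform noise added off-diagonal.
#' @param within_af,between_af aligned fractions for the two block types.
#' @return list with `ani` (an `ani_matrix`), `quality` (data.frame), and
#'   `truth` (named integer cluster membership).
#' @export
make_ani_fixture <- function(cluster_sizes, within_ani = 99.5,
                             between_ani = 90, seed = 1, jitter = 0.1,
                             within_af = 0.95, between_af = 0.4) {
  if (within_ani <= between_ani)
    stop("within_ani must exceed between_ani")
  set.seed(as.integer(seed) + .SEED_OFFSETS[["ani"]])
  n <- sum(cluster_sizes)
  g <- sprintf("g%02d", seq_len(n))
  member <- rep(seq_along(cluster_sizes), cluster_sizes)
  same <- outer(member, member, "==")
  ani <- matrix(between_ani, n, n, dimnames = list(g, g))
  ani[same] <- within_ani
  af <- matrix(between_af, n, n, dimnames = list(g, g))
  af[same] <- within_af
  if (jitter > 0) {
    noise <- matrix(runif(n * n, -jitter, jitter), n, n)
    noise <- (noise + t(noise)) / 2
    ani <- pmin(pmax(ani + noise, 0), 100)
  }
  diag(ani) <- 100; diag(af) <- 1
  quality <- genome_quality(g, completeness = runif(n, 85, 100),
                            contamination = runif(n, 0, 3))
  list(ani = ani_matrix(ani, af), quality = quality,
       truth = setNames(member, g))
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.revcomp <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

.mutate_base <- function(base) sample(setdiff(c("A", "C", "G", "T"), base),
                                      1)

#' Spacer/vOTU fixture with planted protospacers
#'
#' Plants spacers inside a random viral contig at controlled identity and
#' coverage: full-coverage plants sit in the contig interior with the
#' implied number of mismatches; sub-100% coverage plants overhang a contig
#' end. Remaining spacers are random decoys with no placement. Strands are
#' drawn at random.
#'
#' @param n_spacers total spacers (planted + decoys).
#' @param votu_length length of the single vOTU contig.
#' @param planted list of `c(identity, coverage)` pairs (percent).
#' @param seed integer seed.
#' @param spacer_length length of every spacer (default 34 nt).
#' @param n_hosts spacers are assigned round-robin to this many host
#'   genomes named `genome_1`, ...
#' @return list with `spacers` (a `spacer_set`), `votus` (named character),
#'   and `truth` (data.frame: spacer_id, planted, strand, start,
#'   mismatches, aligned, identity, coverage).
#' @export
make_spacer_fixture <- function(n_spacers = 10, votu_length = 20000,
                                planted = list(c(100, 100), c(97.06, 100)),
                                seed = 1, spacer_length = 34,
                                n_hosts = max(1L, n_spacers %/% 3L)) {
  if (length(planted) > n_spacers)
    stop("more planted hits than spacers")
  set.seed(as.integer(seed) + .SEED_OFFSETS[["spacer"]])
  votu <- .random_dna(votu_length)
  L <- votu_length; n <- spacer_length
  seqs <- character(n_spacers)
  truth <- data.frame(spacer_id = sprintf("spacer_%02d", seq_len(n_spacers)),
                      planted = FALSE, strand = NA_character_,
                      start = NA_integer_, mismatches = NA_integer_,
                      aligned = NA_integer_, identity = NA_real_,
                      coverage = NA_real_, stringsAsFactors = FALSE)
  used <- integer()
  for (i in seq_along(planted)) {
    idcov <- planted[[i]]
    identity <- idcov[1]; coverage <- idcov[2]
    aligned <- as.integer(round(coverage / 100 * n))
    mism <- as.integer(round(aligned * (1 - identity / 100)))
    strand <- sample(c("+", "-"), 1)
    if (coverage >= 100) {
      repeat {
        st <- sample.int(L - n + 1, 1)
        if (!any(abs(st - used) < 2 * n)) break
      }
      used <- c(used, st)
      region <- substring(votu, st, st + n - 1)
      spac <- region
      if (mism > 0) {
        pos <- sample.int(n, mism)
        sp <- strsplit(spac, "")[[1]]
        for (p in pos) sp[p] <- .mutate_base(sp[p])
        spac <- paste(sp, collapse = "")
      }
      truth[i, c("planted", "strand")] <- list(TRUE, strand)
      truth$start[i] <- st - 1L
    } else {
      # overhang the right contig end: last `aligned` bases of the spacer
      # fall outside
      region <- substring(votu, L - aligned + 1, L)
      tail_len <- n - aligned
      spac <- paste0(region, .random_dna(tail_len))
      if (mism > 0) {
        pos <- sample.int(aligned, mism)
        sp <- strsplit(spac, "")[[1]]
        for (p in pos) sp[p] <- .mutate_base(sp[p])
        spac <- paste(sp, collapse = "")
      }
      truth[i, c("planted", "strand")] <- list(TRUE, strand)
      truth$start[i] <- L - aligned
    }
    if (strand == "-") spac <- .revcomp(spac)
    seqs[i] <- spac
    truth$mismatches[i] <- mism
    truth$aligned[i] <- aligned
    truth$identity[i] <- (aligned - mism) / aligned * 100
    truth$coverage[i] <- aligned / n * 100
  }
  for (i in setdiff(seq_len(n_spacers), seq_along(planted)))
    seqs[i] <- .random_dna(n)
  hosts <- sprintf("genome_%d", ((seq_len(n_spacers) - 1) %% n_hosts) + 1)
  list(spacers = spacer_set(truth$spacer_id, hosts, seqs),
       votus = c(votu_1 = votu), truth = truth)
}

#' Abundance fixture with WWTP replicates and planted rank correlations
#'
#' Log-normal sample-by-taxon abundances. Taxa named in
#' `planted_correlations` are generated from a Gaussian copula across all
#' samples at the requested correlation; all other taxa get a
#' WWTP-specific base profile with multiplicative replicate jitter, which
#' gives the within-plant similarity the representative-sample selector
#' expects. Continents are assigned to WWTPs round-robin.
#'
#' @param n_wwtps,samples_per_wwtp sampling design.
#' @param n_taxa number of taxa (columns `taxon_01`, ...).
#' @param continents character vector of continent labels.
#' @param planted_correlations list of `list(pair = c(a, b), rho = r)`
#'   entries (taxon names).
#' @param seed integer seed.
#' @param jitter standard deviation of the replicate log-noise.
#' @return list with `table` (an `abundance_table`) and `truth`
#'   (the planted correlations and per-WWTP base profiles).
#' @export
make_abundance_fixture <- function(n_wwtps = 10, samples_per_wwtp = 3,
                                   n_taxa = 12,
                                   continents = c("Asia", "Europe",
                                                  "North America"),
                                   planted_correlations = list(),
                                   seed = 1, jitter = 0.1) {
  set.seed(as.integer(seed) + .SEED_OFFSETS[["abundance"]])
  n_samples <- n_wwtps * samples_per_wwtp
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  samples <- sprintf("s%03d", seq_len(n_samples))
  wwtp <- rep(sprintf("wwtp_%02d", seq_len(n_wwtps)),
              each = samples_per_wwtp)
  continent <- rep(continents, length.out = n_wwtps)[
    match(wwtp, sprintf("wwtp_%02d", seq_len(n_wwtps)))]

  planted_taxa <- unique(unlist(lapply(planted_correlations,
                                       function(p) p$pair)))
  bad <- setdiff(planted_taxa, taxa)
  if (length(bad)) stop("planted pair names outside taxa: ", bad[1])

  ab <- matrix(0, n_samples, n_taxa, dimnames = list(samples, taxa))
  base <- matrix(exp(rnorm(n_wwtps * n_taxa, 0, 1)), n_wwtps, n_taxa,
                 dimnames = list(unique(wwtp), taxa))
  for (t in taxa)
    ab[, t] <- base[wwtp, t] * exp(rnorm(n_samples, 0, jitter))
  for (p in planted_correlations) {
    z1 <- rnorm(n_samples)
    z2 <- p$rho * z1 + sqrt(max(0, 1 - p$rho^2)) * rnorm(n_samples)
    ab[, p$pair[1]] <- exp(z1)
    ab[, p$pair[2]] <- exp(z2)
  }
  ab <- ab / rowSums(ab)
  meta <- data.frame(sample = samples, wwtp = wwtp,
                     continent = continent, stringsAsFactors = FALSE)
  list(table = abundance_table(ab, meta),
       truth = list(planted = planted_correlations, base = base))
}

#' Generate the full miniature study scenario
#'
#' A single seeded scenario exercising every pipeline stage with known
#' truth: 12 PAO models with planted amino-acid and transporter knockouts,
#' a 20-leaf tree with 500 evolved gene families, a 3-cluster ANI fixture,
#' 40 spacers against one vOTU, and 10 WWTPs x 3 samples with one strongly
#' and one un-correlated taxon pair. Optionally writes everything to
#' `out_dir` in the formats the readers consume (SBML, TSV, Newick, FASTA).
#'
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return list with elements `models` (+ `model_truth`), `genes`, `ani`,
#'   `spacers`, `abundance`.
#' @export
make_paper_mini <- function(seed = 7, out_dir = NULL) {
  kos <- list(
    m01 = character(), m02 = "His-biosynthesis", m03 = "Thr-biosynthesis",
    m04 = c("His-biosynthesis", "Thr-biosynthesis"),
    m05 = "Trp-biosynthesis", m06 = "lactate-transporter",
    m07 = "glycerol-transporter",
    m08 = c("His-biosynthesis", "lactate-transporter"),
    m09 = "Met-biosynthesis",
    m10 = c("Leu-biosynthesis", "Val-biosynthesis"),
    m11 = character(),
    m12 = c("glucose-PTS-manX", "glucose-PTS-ptsG"))
  models <- lapply(names(kos), function(nm)
    make_pao_model(kos[[nm]], id = nm))
  names(models) <- names(kos)

  genes <- make_gene_matrix(20, n_families = 500, gain_rate = 0.02,
                            loss_rate = 0.1, seed = seed)
  ani <- make_ani_fixture(c(3, 2, 4), seed = seed)
  spacers <- make_spacer_fixture(
    n_spacers = 40, votu_length = 20000,
    planted = list(c(100, 100), c(97.06, 100), c(96.67, 100),
                   c(100, 91.2), c(100, 100), c(97.06, 100)),
    seed = seed)
  abundance <- make_abundance_fixture(
    n_wwtps = 10, samples_per_wwtp = 3, n_taxa = 12,
    planted_correlations = list(
      list(pair = c("taxon_01", "taxon_02"), rho = 0.85),
      list(pair = c("taxon_03", "taxon_04"), rho = 0)),
    seed = seed)

  out <- list(models = models, model_truth = kos, genes = genes,
              ani = ani, spacers = spacers, abundance = abundance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(models))
      write_sbml(models[[nm]], file.path(out_dir,
                                         paste0(nm, ".xml")))
    write.table(genes$matrix$counts,
                file.path(out_dir, "gene_families.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    ape::write.tree(genes$tree, file.path(out_dir, "tree.nwk"))
    write.table(data.frame(genome = names(ani$truth),
                           cluster = unname(ani$truth)),
                file.path(out_dir, "ani_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ani$ani$ani, file.path(out_dir, "ani.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write.table(ani$quality[, c("genome", "completeness",
                                "contamination")],
                file.path(out_dir, "quality.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sp <- Biostrings::DNAStringSet(spacers$spacers$sequence)
    names(sp) <- paste(spacers$spacers$id, spacers$spacers$host_genome)
    Biostrings::writeXStringSet(sp, file.path(out_dir, "spacers.fasta"))
    vo <- Biostrings::DNAStringSet(spacers$votus)
    Biostrings::writeXStringSet(vo, file.path(out_dir, "votus.fasta"))
    write.table(abundance$table$abund,
                file.path(out_dir, "abundance.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write.table(abundance$table$meta,
                file.path(out_dir, "abundance_meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
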