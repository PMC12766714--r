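#' Genome quality score
#'
#' `QS = completeness - 5 * contamination`, both CheckM-style percentages.
#'
#' @param completeness percent in \[0, 100\].
#' @param contamination percent >= 0.
#' @return the quality score (vectorized).
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must be in [0, 100]")
  if (any(contamination < 0)) stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Genome quality table
#'
#' @param genome character vector of genome ids.
#' @param completeness,contamination percentages (see [quality_score()]).
#' @return data.frame with columns genome, completeness, contamination, qs.
#' @export
genome_quality <- function(genome, completeness, contamination) {
  data.frame(genome = genome, completeness = completeness,
             contamination = contamination,
             qs = quality_score(completeness, contamination),
             stringsAsFactors = FALSE)
}

#' Read a CheckM-style quality TSV (genome, completeness, contamination)
#' @param path TSV file with a header.
#' @return a quality data.frame as from [genome_quality()].
#' @export
read_quality_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  genome_quality(df[[1]], df[[2]], df[[3]])
}

#' Pairwise ANI / aligned-fraction matrices
#'
#' Asymmetric query/reference pairs are symmetrized by taking the maximum of
#' the two orientations before thresholding; the diagonal is fixed at
#' 100% ANI / aligned fraction 1.
#'
#' @param ani square numeric matrix of ANI percentages with genome dimnames.
#' @param aligned_fraction square numeric matrix in \[0, 1\] (defaults to
#'   all-1 when alignment fractions are unknown).
#' @return an `ani_matrix`.
#' @export
ani_matrix <- function(ani, aligned_fraction = NULL) {
  ani <- as.matrix(ani)
  if (nrow(ani) != ncol(ani) || is.null(rownames(ani)))
    stop("ani must be square with genome dimnames")
  if (is.null(aligned_fraction))
    aligned_fraction <- matrix(1, nrow(ani), ncol(ani),
                               dimnames = dimnames(ani))
  af <- as.matrix(aligned_fraction)
  sym <- function(m) pmax(m, t(m))
  ani <- sym(ani); af <- sym(af)
  diag(ani) <- 100; diag(af) <- 1
  if (any(ani < 0 | ani > 100)) stop("ANI values must be in [0, 100]")
  if (any(af < 0 | af > 1)) stop("aligned fractions must be in [0, 1]")
  structure(list(ani = ani, af = af, genomes = rownames(ani)),
            class = "ani_matrix")
}

#' Read ANI input as FastANI-style pairs or a square matrix
#'
#' A 3- or 5-column headerless TSV (`genome1 genome2 ani [af1 af2]`) is read
#' as pairwise records (missing pairs default to 0 ANI); any other shape is
#' read as a square matrix with genome row/column names.
#'
#' @param path TSV file.
#' @return an `ani_matrix`.
#' @export
read_ani_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (length(first) %in% c(3L, 5L) &&
      suppressWarnings(is.na(as.numeric(first[1])))) {
    df <- read.table(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    g <- sort(unique(c(df[[1]], df[[2]])))
    ani <- matrix(0, length(g), length(g), dimnames = list(g, g))
    af <- matrix(0, length(g), length(g), dimnames = list(g, g))
    for (i in seq_len(nrow(df))) {
      a <- df[[1]][i]; b <- df[[2]][i]
      ani[a, b] <- max(ani[a, b], df[[3]][i])
      f <- if (ncol(df) >= 5) max(df[[4]][i], df[[5]][i]) else 1
      af[a, b] <- max(af[a, b], f)
    }
    ani_matrix(ani, af)
  } else {
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE))
    ani_matrix(m)
  }
}

.cluster_genomes <- function(ani, quality, ani_min, af_min) {
  if (!inherits(ani, "ani_matrix")) stop("need an ani_matrix")
  g <- ani$genomes
  miss <- setdiff(g, quality$genome)
  if (length(miss))
    stop("missing quality record for genome ", miss[1])
  adj <- ani$ani >= ani_min & ani$af >= af_min
  diag(adj) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(gr)$membership
  qs <- setNames(quality$qs[match(g, quality$genome)], g)
  clusters <- split(g, comp)
  # deterministic: order clusters by their lexicographically first member
  clusters <- clusters[order(vapply(clusters, function(x) min(sort(x)),
                                    character(1)))]
  names(clusters) <- paste0("cluster_", seq_along(clusters))
  reps <- vapply(clusters, function(members) {
    members <- sort(members)
    members[which.max(qs[members])]  # ties -> lexicographically smallest
  }, character(1))
  structure(list(clusters = clusters, representatives = reps,
                 qs = qs, ani_min = ani_min, af_min = af_min),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters over",
      length(unlist(x$clusters)), "genomes (ANI >=", x$ani_min,
      "%, AF >=", x$af_min, ")\n")
  invisible(x)
}

#' Dereplicate genomes at high identity
#'
#' Two genomes are joined when their (symmetrized) ANI and aligned fraction
#' both reach the thresholds; clusters are the connected components of that
#' graph (single linkage), and each cluster is represented by its
#' highest-quality-score genome (ties broken by lexicographic id). Defaults
#' are the dereplication parameters 99% ANI / 85% aligned fraction;
#' [species_cluster()] applies the species-level 95% / 30% parameters.
#' Boundary comparisons are inclusive (`>=`).
#'
#' @param ani an `ani_matrix`.
#' @param quality a quality data.frame from [genome_quality()] covering all
#'   genomes.
#' @param ani_min ANI threshold in percent.
#' @param af_min aligned-fraction threshold in \[0, 1\].
#' @return a `cluster_set` with `clusters` (named list of genome id
#'   vectors), `representatives`, and the parameters used.
#' @export
dereplicate <- function(ani, quality, ani_min = 99, af_min = 0.85) {
  .cluster_genomes(ani, quality, ani_min, af_min)
}

#' @rdname dereplicate
#' @export
species_cluster <- function(ani, quality, ani_min = 95, af_min = 0.30) {
  .cluster_genomes(ani, quality, ani_min, af_min)
}

#' Write a cluster set as TSV (`cluster_id genome representative_flag`)
#' @param clusters a `cluster_set`.
#' @param path output file.
#' @export
write_cluster_tsv <- function(clusters, path) {
  rows <- do.call(rbind, lapply(names(clusters$clusters), function(cl) {
    g <- sort(clusters$clusters[[cl]])
    data.frame(cluster_id = cl, genome = g,
               representative_flag = as.integer(
                 g == clusters$representatives[[cl]]))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
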