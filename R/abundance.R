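#' Sample x taxon relative-abundance table with site metadata
#'
#' @param abund numeric matrix, samples in rows, taxa in columns, relative
#'   abundances >= 0, with dimnames.
#' @param meta data.frame with columns `sample`, `wwtp`, `continent`
#'   covering every sample.
#' @return an `abundance_table`.
#' @export
abundance_table <- function(abund, meta) {
  abund <- as.matrix(abund)
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("abund must have sample rownames and taxon colnames")
  if (any(!is.finite(abund)) || any(abund < 0))
    stop("abundances must be finite and non-negative")
  need <- c("sample", "wwtp", "continent")
  if (!all(need %in% names(meta)))
    stop("meta must have columns sample, wwtp, continent")
  miss <- setdiff(rownames(abund), meta$sample)
  if (length(miss)) stop("metadata missing for sample ", miss[1])
  meta <- meta[match(rownames(abund), meta$sample), need]
  structure(list(abund = abund, meta = meta), class = "abundance_table")
}

#' Read an abundance TSV plus its metadata sidecar
#'
#' The main TSV holds samples in rows and taxa in columns (first column =
#' sample id); the sidecar TSV has columns sample, wwtp, continent.
#' @param path,meta_path TSV files.
#' @return an `abundance_table`.
#' @export
read_abundance_tsv <- function(path, meta_path) {
  abund <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE))
  meta <- read.table(meta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  abundance_table(abund, meta)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|a - b|) / sum(a + b)`: 0 for identical profiles, 1 for disjoint
#' support. Two all-zero vectors are defined as dissimilarity 0 with a
#' warning.
#'
#' @param a,b non-negative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  tot <- sum(a + b)
  if (tot == 0) {
    warning("both profiles all-zero; Bray-Curtis defined as 0")
    return(0)
  }
  sum(abs(a - b)) / tot
}

#' Representative sample per WWTP
#'
#' For every treatment plant with multiple samples, computes the arithmetic
#' mean abundance profile (centroid) and keeps the sample with the smallest
#' Bray-Curtis dissimilarity to it; single-sample plants return that sample.
#' Ties break to the lexicographically smallest sample id; a plant whose
#' profiles are all zero returns its first sample by id with a warning.
#'
#' @param table an `abundance_table`.
#' @return named character vector, wwtp -> chosen sample id.
#' @export
select_representative_samples <- function(table) {
  if (!inherits(table, "abundance_table")) stop("need an abundance_table")
  wwtps <- sort(unique(table$meta$wwtp))
  out <- setNames(character(length(wwtps)), wwtps)
  for (w in wwtps) {
    samples <- sort(table$meta$sample[table$meta$wwtp == w])
    if (length(samples) == 1) { out[[w]] <- samples; next }
    prof <- table$abund[samples, , drop = FALSE]
    if (sum(prof) == 0) {
      warning("all-zero profiles in wwtp ", w, "; taking first sample by id")
      out[[w]] <- samples[1]
      next
    }
    centroid <- colMeans(prof)
    d <- vapply(samples, function(s)
      suppressWarnings(bray_curtis(prof[s, ], centroid)), numeric(1))
    out[[w]] <- samples[which.min(d)]  # which.min takes the first tie
  }
  out
}

#' Per-continent clade composition
#'
#' For every continent, sums the relative abundance of each clade over all
#' of the continent's samples and divides by the summed abundance of all
#' focal taxa there, so rows sum to 1 (continents with zero total are
#' returned as all-zero rows and flagged in the `zero_total` attribute).
#'
#' @param table an `abundance_table` (typically restricted to the focal
#'   genus's species).
#' @param grouping named character vector taxon -> clade, covering all
#'   columns of the table.
#' @return continent x clade proportion matrix.
#' @export
continent_proportions <- function(table, grouping) {
  if (!inherits(table, "abundance_table")) stop("need an abundance_table")
  miss <- setdiff(colnames(table$abund), names(grouping))
  if (length(miss)) stop("grouping missing for taxon ", miss[1])
  clades <- sort(unique(unname(grouping[colnames(table$abund)])))
  continents <- sort(unique(table$meta$continent))
  out <- matrix(0, length(continents), length(clades),
                dimnames = list(continents, clades))
  zero <- character()
  for (ct in continents) {
    rows <- table$meta$continent == ct
    sums <- colSums(table$abund[rows, , drop = FALSE])
    by_clade <- tapply(sums, grouping[names(sums)], sum)
    tot <- sum(by_clade)
    if (tot > 0) out[ct, names(by_clade)] <- by_clade / tot
    else zero <- c(zero, ct)
  }
  attr(out, "zero_total") <- zero
  out
}

#' Genus co-occurrence network by Spearman correlation
#'
#' Tests every genus pair across samples with Spearman's rank correlation
#' (mid-ranks for ties; p-values from `stats::cor.test`, exact for small
#' tie-free samples and the t approximation otherwise), adjusts the
#' two-sided p-values with Benjamini-Hochberg across all tested pairs, and
#' retains edges with `|rho| > rho_min` and adjusted p < `q_max`.
#' Constant-abundance genera cannot be ranked and their pairs are skipped
#' with a reason. Genera with a positive retained correlation to
#' `focal_genus` are reported separately.
#'
#' @param genus_table an `abundance_table` aggregated to genus level, with
#'   at least 8 samples.
#' @param rho_min,q_max retention thresholds (defaults 0.3 and 0.05).
#' @param focal_genus column name of the focal genus (optional).
#' @return list with `edges` (data.frame taxon_a, taxon_b, spearman_rho,
#'   p_value, q_value), `tested`, `skipped` (data.frame pair, reason), and
#'   `focal_positive` (character).
#' @export
correlation_network <- function(genus_table, rho_min = 0.3, q_max = 0.05,
                                focal_genus = NULL) {
  if (!inherits(genus_table, "abundance_table"))
    stop("need an abundance_table")
  ab <- genus_table$abund
  if (nrow(ab) < 8)
    stop("need at least 8 samples for rank correlation")
  taxa <- colnames(ab)
  const <- apply(ab, 2, function(x) diff(range(x)) == 0)
  pairs <- t(combn(taxa, 2))
  keep <- !const[pairs[, 1]] & !const[pairs[, 2]]
  skipped <- if (any(!keep))
    data.frame(taxon_a = pairs[!keep, 1], taxon_b = pairs[!keep, 2],
               reason = "constant abundance", stringsAsFactors = FALSE)
  else data.frame(taxon_a = character(), taxon_b = character(),
                  reason = character())
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  rho <- numeric(n); pval <- numeric(n)
  for (i in seq_len(n)) {
    ct <- suppressWarnings(
      cor.test(ab[, pairs[i, 1]], ab[, pairs[i, 2]], method = "spearman"))
    rho[i] <- unname(ct$estimate); pval[i] <- ct$p.value
  }
  qval <- p.adjust(pval, method = "BH")
  edges <- data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
                      spearman_rho = rho, p_value = pval, q_value = qval,
                      stringsAsFactors = FALSE)
  retained <- edges[abs(edges$spearman_rho) > rho_min &
                      edges$q_value < q_max, , drop = FALSE]
  rownames(retained) <- NULL
  focal_positive <- character()
  if (!is.null(focal_genus)) {
    hit <- (retained$taxon_a == focal_genus |
              retained$taxon_b == focal_genus) & retained$spearman_rho > 0
    focal_positive <- setdiff(
      unique(c(retained$taxon_a[hit], retained$taxon_b[hit])), focal_genus)
  }
  list(edges = retained, tested = edges, skipped = skipped,
       focal_positive = focal_positive)
}

#' Write a correlation network edge list as TSV
#' @param network result of [correlation_network()].
#' @param path output file.
#' @export
write_network_tsv <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
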