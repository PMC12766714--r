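#' Gene-family presence matrix with clade labels
#'
#' @param counts integer matrix, families in rows (rownames = family ids),
#'   genomes in columns (colnames = genome ids), copy counts >= 0.
#' @param genome_clades named character vector mapping every genome id to a
#'   clade label.
#' @return a `presence_matrix`.
#' @export
presence_matrix <- function(counts, genome_clades) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have family rownames and genome colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("all-zero family rows are not allowed")
  miss <- setdiff(colnames(counts), names(genome_clades))
  if (length(miss)) stop("genomes without clade label: ",
                         paste(head(miss, 3), collapse = ", "))
  structure(list(counts = counts,
                 genome_clades = genome_clades[colnames(counts)]),
            class = "presence_matrix")
}

#' Read a gene-family count matrix from TSV
#'
#' Families as rows, genomes as columns (Panaroo/Roary-style count export);
#' first column holds family ids.
#' @param path TSV file.
#' @param genome_clades named character vector of clade labels.
#' @return a `presence_matrix`.
#' @export
read_presence_matrix <- function(path, genome_clades) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  presence_matrix(as.matrix(df), genome_clades)
}

#' Core gene families
#'
#' A family is core when present (count >= 1) in at least
#' `ceiling(threshold * n_genomes)` genomes. With 136 genomes and the
#' default 80% rule the minimum count is 109.
#'
#' @param matrix a `presence_matrix`.
#' @param threshold presence fraction, 0 < threshold <= 1 (default 0.8).
#' @return character vector of core family ids.
#' @export
classify_core <- function(matrix, threshold = 0.8) {
  if (!inherits(matrix, "presence_matrix")) stop("need a presence_matrix")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- ncol(matrix$counts)
  if (n == 0) stop("empty matrix")
  need <- core_min_genomes(n, threshold)
  pres <- rowSums(matrix$counts >= 1)
  rownames(matrix$counts)[pres >= need]
}

#' Minimum genome count implied by a presence threshold
#' @param n_genomes number of genomes.
#' @param threshold presence fraction.
#' @return integer, `ceiling(threshold * n_genomes)`.
#' @export
core_min_genomes <- function(n_genomes, threshold = 0.8) {
  # round to 9 decimals first so binary noise in threshold * n cannot push
  # an exact integer product up to the next integer
  as.integer(ceiling(round(n_genomes * threshold, 9)))
}

#' Clade-specific gene families
#'
#' A family is specific to clade `c` when present in strictly more than
#' `threshold * |c|` genomes of `c` and absent (count 0) from every genome
#' outside `c`.
#'
#' @param matrix a `presence_matrix`.
#' @param threshold within-clade presence fraction (default 0.75, strict
#'   inequality).
#' @return named list: clade -> character vector of family ids.
#' @export
classify_clade_specific <- function(matrix, threshold = 0.75) {
  if (!inherits(matrix, "presence_matrix")) stop("need a presence_matrix")
  clades <- unique(matrix$genome_clades)
  pres <- matrix$counts >= 1
  out <- list()
  for (cl in clades) {
    inside <- matrix$genome_clades == cl
    n_in <- rowSums(pres[, inside, drop = FALSE])
    n_out <- rowSums(pres[, !inside, drop = FALSE])
    keep <- n_in > threshold * sum(inside) & n_out == 0
    out[[cl]] <- rownames(matrix$counts)[keep]
  }
  out
}

# ---- Wagner parsimony ------------------------------------------------------

# ape::phylo helpers: deterministic labels for unnamed internal nodes
.label_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  if (is.null(tree$node.label) || any(tree$node.label == "") ||
      anyNA(tree$node.label)) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", n_node)
    empty <- lab == "" | is.na(lab)
    lab[empty] <- paste0("node", which(empty))
    tree$node.label <- make.unique(lab)
  }
  tree
}

#' Read a rooted Newick tree for gain/loss inference
#'
#' Unnamed internal nodes are auto-labeled `node<k>` deterministically.
#' @param path Newick file.
#' @return an `ape::phylo` tree with node labels.
#' @export
read_gainloss_tree <- function(path) .label_tree(ape::read.tree(path))

#' Ancestral gene-content reconstruction by asymmetric Wagner parsimony
#'
#' For each gene family, finds a minimum-cost assignment of ancestral copy
#' numbers (states `0..max_count`) to the internal nodes of a rooted tree,
#' where a change from `a` (parent) to `b` (child) along a branch costs
#' `gain_penalty * max(0, b - a) + loss_penalty * max(0, a - b)`. The
#' default penalties (gain 2, loss 1) bias reconstructions against
#' parallel gains. Solved by Sankoff-style dynamic programming; the root
#' state minimizes the total cost with no prior (ties broken toward the
#' smallest count, as is every backtrace tie, so output is deterministic).
#'
#' @param matrix a `presence_matrix`.
#' @param tree a rooted `ape::phylo` whose tip labels equal the matrix
#'   genome ids (internal nodes are auto-labeled when unnamed).
#' @param gain_penalty,loss_penalty per-copy event costs.
#' @param max_count cap on the ancestral state space; defaults to each
#'   family's observed maximum. Observed counts above the cap are truncated
#'   with a warning.
#' @return a `gainloss_result`: `states` (families x nodes matrix of
#'   reconstructed counts, tips included), `branch_gains` / `branch_losses`
#'   (families x edges), `total_cost`, `edge_labels`, and the penalties.
#' @export
wagner_gain_loss <- function(matrix, tree, gain_penalty = 2,
                             loss_penalty = 1, max_count = NULL) {
  if (!inherits(matrix, "presence_matrix")) stop("need a presence_matrix")
  tree <- .label_tree(tree)
  genomes <- colnames(matrix$counts)
  if (!setequal(tree$tip.label, genomes))
    stop("tree tips and matrix genomes differ: e.g. ",
         paste(head(c(setdiff(tree$tip.label, genomes),
                      setdiff(genomes, tree$tip.label)), 3),
               collapse = ", "))
  counts <- matrix$counts[, tree$tip.label, drop = FALSE]
  nfam <- nrow(counts)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  node_ids <- c(tree$tip.label, tree$node.label)

  cap <- if (is.null(max_count)) apply(counts, 1, max) else
    rep(as.integer(max_count), nfam)
  if (any(counts > cap)) {
    warning("counts above max_count truncated for ",
            sum(apply(counts > cap, 1, any)), " families")
    counts <- pmin(counts, cap)
  }
  K <- max(cap, 1L)  # global state-space upper bound
  states_all <- 0:K

  edge <- tree$edge  # parent, child (internal nodes numbered n_tip+1 ..)
  root <- n_tip + 1L
  edge_post <- ape::reorder.phylo(tree, "postorder")$edge

  ecost <- function(a, b)
    gain_penalty * pmax(0, b - a) + loss_penalty * pmax(0, a - b)
  # cost matrix C[a+1, b+1]
  Cmat <- outer(states_all, states_all, ecost)

  nv <- n_tip + n_node
  states <- matrix(0L, nfam, nv, dimnames = list(rownames(counts), node_ids))
  total_cost <- numeric(nfam)
  n_edge <- nrow(edge)
  branch_gains <- matrix(0L, nfam, n_edge)
  branch_losses <- matrix(0L, nfam, n_edge)

  for (f in seq_len(nfam)) {
    Kf <- max(cap[f], 1L)
    sf <- 0:Kf
    cost <- matrix(0, nv, Kf + 1)
    for (t in seq_len(n_tip)) {
      cost[t, ] <- Inf
      cost[t, counts[f, t] + 1] <- 0
    }
    # per-edge postorder accumulation: when edge (p, ch) is reached every
    # edge inside ch's subtree has been processed, so cost[ch, ] is final
    for (e in seq_len(nrow(edge_post))) {
      p <- edge_post[e, 1]; ch <- edge_post[e, 2]
      m <- Cmat[sf + 1, sf + 1, drop = FALSE] +
        matrix(cost[ch, ], Kf + 1, Kf + 1, byrow = TRUE)
      cost[p, ] <- cost[p, ] + apply(m, 1, min)
    }
    rs <- cost[root, ]
    best <- min(rs)
    total_cost[f] <- best
    states[f, root] <- which(rs == best)[1] - 1L  # smallest state on ties
    # preorder backtrace
    for (e in rev(seq_len(nrow(edge_post)))) {
      p <- edge_post[e, 1]; ch <- edge_post[e, 2]
      a <- states[f, p]
      cand <- Cmat[a + 1, sf + 1] + cost[ch, ]
      states[f, ch] <- which(cand == min(cand))[1] - 1L
    }
    d <- states[f, edge[, 2]] - states[f, edge[, 1]]
    branch_gains[f, ] <- pmax(0L, d)
    branch_losses[f, ] <- pmax(0L, -d)
  }

  edge_labels <- paste(node_ids[edge[, 1]], node_ids[edge[, 2]], sep = "->")
  colnames(branch_gains) <- colnames(branch_losses) <- edge_labels
  rownames(branch_gains) <- rownames(branch_losses) <- rownames(counts)
  structure(list(states = states, branch_gains = branch_gains,
                 branch_losses = branch_losses,
                 total_cost = setNames(total_cost, rownames(counts)),
                 edge_labels = edge_labels, gain_penalty = gain_penalty,
                 loss_penalty = loss_penalty, tree = tree),
            class = "gainloss_result")
}

#' @export
print.gainloss_result <- function(x, ...) {
  cat("gainloss_result:", nrow(x$states), "families,",
      length(x$edge_labels), "branches; total cost",
      sum(x$total_cost), "\n")
  invisible(x)
}

#' Ancestral vs derived classification of gene families
#'
#' A family is `ancestral` when its reconstructed copy number at the
#' designated last-common-ancestor node is positive, `derived` when it is
#' zero there but positive somewhere inside the LCA clade. Families absent
#' from the whole clade are excluded with a warning.
#'
#' @param result a `gainloss_result` from [wagner_gain_loss()].
#' @param tree the tree the result was computed on (defaults to the stored
#'   one).
#' @param lca_node label of the LCA node of the focal genus (default: the
#'   root).
#' @return named character vector, family -> "ancestral"/"derived";
#'   excluded families are dropped.
#' @export
classify_origin <- function(result, tree = result$tree,
                            lca_node = NULL) {
  tree <- .label_tree(tree)
  n_tip <- length(tree$tip.label)
  node_ids <- c(tree$tip.label, tree$node.label)
  if (is.null(lca_node)) lca_node <- tree$node.label[1]
  li <- match(lca_node, node_ids)
  if (is.na(li)) stop("unknown LCA node: ", lca_node)
  # nodes inside the LCA clade (including the LCA itself)
  inside <- li
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% inside, 2]
    new <- setdiff(kids, inside)
    if (!length(new)) break
    inside <- c(inside, new)
  }
  at_lca <- result$states[, li]
  below <- result$states[, setdiff(inside, li), drop = FALSE]
  anywhere <- at_lca > 0 | rowSums(below > 0) > 0
  if (any(!anywhere))
    warning(sum(!anywhere), " families absent at and below the LCA ",
            "were excluded")
  cls <- ifelse(at_lca > 0, "ancestral", "derived")[anywhere]
  setNames(cls, rownames(result$states)[anywhere])
}

#' Write gain/loss outputs as TSV
#'
#' `events_path` gets one row per branch (branch, gains, losses summed over
#' families); `origin_path` one row per family with its classification.
#' @param result a `gainloss_result`.
#' @param events_path,origin_path output files (NULL to skip).
#' @param ... passed to [classify_origin()].
#' @export
write_gainloss_tsv <- function(result, events_path = NULL,
                               origin_path = NULL, ...) {
  if (!is.null(events_path)) {
    df <- data.frame(branch = result$edge_labels,
                     gains = colSums(result$branch_gains),
                     losses = colSums(result$branch_losses))
    write.table(df, events_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(origin_path)) {
    cls <- classify_origin(result, ...)
    df <- data.frame(family = names(cls), origin = unname(cls))
    write.table(df, origin_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(NULL)
}
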