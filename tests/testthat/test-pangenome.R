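mk_pm <- function(counts, genomes = colnames(counts)) {
  presence_matrix(counts, setNames(rep("cladeA", length(genomes)), genomes))
}

test_that("core classification applies the ceiling presence rule", {
  # 136 genomes at the 80% rule: minimum presence count is 109
  expect_equal(core_min_genomes(136, 0.8), 109L)
  g <- sprintf("g%03d", 1:136)
  counts <- matrix(0L, 3, 136, dimnames = list(c("everywhere",
                                                 "in109", "in108"), g))
  counts["everywhere", ] <- 1L
  counts["in109", 1:109] <- 1L
  counts["in108", 1:108] <- 2L  # copy number > 1 still counts as present
  pm <- mk_pm(counts)
  core <- classify_core(pm)
  expect_true(all(c("everywhere", "in109") %in% core))
  expect_false("in108" %in% core)
  expect_error(classify_core(pm, threshold = 0), "threshold")
})

test_that("clade-specific families require strict majority and exclusivity", {
  g <- c(paste0("x", 1:4), paste0("y", 1:4))
  clades <- setNames(rep(c("X", "Y"), each = 4), g)
  counts <- matrix(0L, 3, 8, dimnames = list(c("all_x", "three_x",
                                               "leaky"), g))
  counts["all_x", 1:4] <- 1L          # 4/4 of X, absent in Y
  counts["three_x", 1:3] <- 1L        # 3/4 = 0.75, not > 0.75
  counts["leaky", c(1:4, 5)] <- 1L    # 4/4 of X but present in one Y
  pm <- presence_matrix(counts, clades)
  spec <- classify_clade_specific(pm)
  expect_equal(spec$X, "all_x")
  expect_length(spec$Y, 0)
})

test_that("partitioning is invariant to genome column order", {
  set.seed(11)
  g <- sprintf("g%02d", 1:10)
  counts <- matrix(rbinom(200, 1, 0.5), 20, 10,
                   dimnames = list(sprintf("f%02d", 1:20), g))
  counts[rowSums(counts) == 0, 1] <- 1L
  clades <- setNames(rep(c("A", "B"), each = 5), g)
  pm <- presence_matrix(counts, clades)
  perm <- sample(10)
  pm2 <- presence_matrix(counts[, perm], clades[perm])
  expect_setequal(classify_core(pm, 0.5), classify_core(pm2, 0.5))
  expect_equal(lapply(classify_clade_specific(pm), sort),
               lapply(classify_clade_specific(pm2), sort))
})

test_that("Wagner parsimony solves the three-leaf worked example", {
  tr <- ape::read.tree(text = "((A,B),C);")
  counts <- matrix(c(1L, 1L, 0L), 1, 3,
                   dimnames = list("f1", c("A", "B", "C")))
  res <- wagner_gain_loss(mk_pm(counts), tr)
  # ancestral presence with a single loss on the branch to C, cost 1
  expect_equal(unname(res$total_cost), 1)
  expect_equal(unname(res$states["f1", "node1"]), 1L)
  expect_equal(sum(res$branch_gains), 0L)
  expect_equal(sum(res$branch_losses), 1L)
  loss_edge <- res$edge_labels[which(res$branch_losses["f1", ] == 1)]
  expect_match(loss_edge, "->C$")
  expect_equal(unname(classify_origin(res)), "ancestral")

  # ubiquitous family: present at every node, zero events
  all1 <- matrix(1L, 1, 3, dimnames = list("f1", c("A", "B", "C")))
  res1 <- wagner_gain_loss(mk_pm(all1), tr)
  expect_true(all(res1$states == 1L))
  expect_equal(sum(res1$branch_gains) + sum(res1$branch_losses), 0L)

  # single-leaf family: derived with one terminal gain (gain penalty 2)
  single <- matrix(c(1L, 0L, 0L), 1, 3,
                   dimnames = list("f1", c("A", "B", "C")))
  ress <- wagner_gain_loss(mk_pm(single), tr)
  expect_equal(unname(ress$total_cost), 2)
  expect_equal(sum(ress$branch_gains), 1L)
  expect_match(ress$edge_labels[which(ress$branch_gains["f1", ] == 1)],
               "->A$")
  expect_equal(unname(classify_origin(ress)), "derived")

  expect_error(wagner_gain_loss(mk_pm(counts),
                                ape::read.tree(text = "((A,B),D);")),
               "differ")
})

test_that("DP cost equals exhaustive enumeration over small trees", {
  skip_if_not_installed("phangorn")
  # all rooted topologies for 3 and 4 leaves, every count vector <= 2
  for (n in 3:4) {
    tips <- LETTERS[seq_len(n)]
    trees <- phangorn::allTrees(n, rooted = TRUE, tip.label = tips)
    grids <- as.matrix(do.call(expand.grid, rep(list(0:2), n)))
    colnames(grids) <- tips
    grids <- grids[rowSums(grids) > 0, , drop = FALSE]
    keep <- seq(1, nrow(grids), by = 2)  # every other assignment
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]  # [[ restores tip labels on compressed multiPhylo
      for (i in keep) {
        counts <- matrix(as.integer(grids[i, ]), 1, n,
                         dimnames = list("f1", tips))
        res <- wagner_gain_loss(mk_pm(counts), tr, max_count = 2)
        oracle <- oracle_wagner_cost(tr, grids[i, ], gain = 2, loss = 1,
                                     max_state = 2)
        expect_equal(unname(res$total_cost), oracle)
      }
    }
  }
  # randomized 5- and 6-leaf instances
  set.seed(7)
  for (n in 5:6) {
    for (rep in 1:8) {
      tr <- ape::rtree(n, tip.label = letters[seq_len(n)])
      cnt <- sample(0:2, n, replace = TRUE)
      if (all(cnt == 0)) cnt[1] <- 1
      names(cnt) <- tr$tip.label
      counts <- matrix(as.integer(cnt[tr$tip.label]), 1, n,
                       dimnames = list("f1", tr$tip.label))
      res <- wagner_gain_loss(mk_pm(counts), tr, max_count = 2)
      expect_equal(unname(res$total_cost),
                   oracle_wagner_cost(tr, cnt, max_state = 2))
    }
  }
})

test_that("with equal unit penalties binary events match Fitch parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    counts <- matrix(rbinom(8 * 10, 1, 0.5), 10, 8,
                     dimnames = list(sprintf("f%02d", 1:10),
                                     tr$tip.label))
    counts[rowSums(counts) == 0, 1] <- 1L
    res <- wagner_gain_loss(mk_pm(counts), tr, gain_penalty = 1,
                            loss_penalty = 1)
    events <- rowSums(res$branch_gains) + rowSums(res$branch_losses)
    pd <- phangorn::phyDat(t(counts), type = "USER", levels = 0:1)
    fitch <- phangorn::parsimony(tr, pd, method = "fitch",
                                 site = "site")
    expect_equal(unname(events), unname(fitch))
  }
})

test_that("raising the gain penalty never increases inferred gains", {
  set.seed(17)
  tr <- ape::rtree(10)
  counts <- matrix(rbinom(10 * 30, 1, 0.4), 30, 10,
                   dimnames = list(sprintf("f%02d", 1:30), tr$tip.label))
  counts[rowSums(counts) == 0, 1] <- 1L
  pm <- mk_pm(counts)
  prev <- rep(Inf, 30)
  for (gp in c(1, 2, 4)) {
    res <- wagner_gain_loss(pm, tr, gain_penalty = gp)
    gains <- rowSums(res$branch_gains)
    expect_true(all(gains <= prev))
    prev <- gains
  }
})

test_that("simulated evolution is recovered at desk scale", {
  sim <- make_gene_matrix(20, n_families = 500, gain_rate = 0.02,
                          loss_rate = 0.1, seed = 99)
  res <- wagner_gain_loss(sim$matrix, sim$tree)
  cls <- suppressWarnings(classify_origin(res, sim$tree))
  truth <- setNames(sim$truth$class, sim$truth$family)[names(cls)]
  agreement <- mean(cls == truth)
  expect_gte(agreement, 0.9)
})

test_that("origin classification excludes families absent below the LCA", {
  tr <- ape::read.tree(text = "((A,B)n2,C)n1;")
  counts <- matrix(c(0L, 0L, 1L,
                     1L, 1L, 0L), 2, 3, byrow = TRUE,
                   dimnames = list(c("only_c", "ab"), c("A", "B", "C")))
  res <- wagner_gain_loss(mk_pm(counts), tr)
  expect_warning(cls <- classify_origin(res, tr, lca_node = "n2"),
                 "excluded")
  expect_false("only_c" %in% names(cls))
  expect_equal(unname(cls["ab"]), "ancestral")
})

test_that("gain/loss TSV export round-trips", {
  tr <- ape::read.tree(text = "((A,B),C);")
  counts <- matrix(c(1L, 1L, 0L), 1, 3,
                   dimnames = list("f1", c("A", "B", "C")))
  res <- wagner_gain_loss(mk_pm(counts), tr)
  ef <- withr::local_tempfile(fileext = ".tsv")
  of <- withr::local_tempfile(fileext = ".tsv")
  write_gainloss_tsv(res, ef, of)
  ev <- read.table(ef, header = TRUE, sep = "\t")
  expect_equal(sum(ev$losses), 1)
  or <- read.table(of, header = TRUE, sep = "\t")
  expect_equal(or$origin, "ancestral")
})
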