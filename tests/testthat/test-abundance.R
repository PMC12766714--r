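mk_table <- function(ab, wwtp = NULL, continent = NULL) {
  s <- rownames(ab)
  abundance_table(ab, data.frame(
    sample = s,
    wwtp = wwtp %||% rep("w1", length(s)),
    continent = continent %||% rep("Asia", length(s)),
    stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Bray-Curtis dissimilarity matches its definition and vegan", {
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_warning(z <- bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(bray_curtis(1:3, 1:2), "equal length")
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(runif(20), 4, 5)
  vd <- as.matrix(vegan::vegdist(m, method = "bray"))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(bray_curtis(m[i, ], m[j, ]), vd[i, j], tolerance = 1e-12)
})

test_that("representative samples minimize distance to the WWTP centroid", {
  # 3 samples, two sharing a duplicated profile: a duplicate wins
  ab <- rbind(sA = c(5, 1, 0, 2), sB = c(5, 1, 0, 2), sC = c(0, 9, 3, 0))
  colnames(ab) <- paste0("t", 1:4)
  tab <- mk_table(ab)
  rep <- select_representative_samples(tab)
  expect_equal(unname(rep), "sA")  # duplicated pair member, smallest id

  # single-sample plants return their sample; output covers all plants
  ab2 <- rbind(ab, sD = c(1, 1, 1, 1))
  tab2 <- mk_table(ab2, wwtp = c("w1", "w1", "w1", "w2"))
  rep2 <- select_representative_samples(tab2)
  expect_equal(length(rep2), 2)
  expect_equal(unname(rep2["w2"]), "sD")

  # all-zero plant falls back to the first sample with a warning
  ab3 <- rbind(sX = c(0, 0), sY = c(0, 0))
  colnames(ab3) <- c("t1", "t2")
  expect_warning(rep3 <- select_representative_samples(mk_table(ab3)),
                 "all-zero")
  expect_equal(unname(rep3), "sX")
})

test_that("continent proportions sum to one per continent", {
  ab <- rbind(s1 = c(3, 1), s2 = c(3, 1))
  colnames(ab) <- c("sp1", "sp2")
  tab <- mk_table(ab, wwtp = c("w1", "w2"),
                  continent = c("Asia", "Europe"))
  pr <- continent_proportions(tab, c(sp1 = "IIA", sp2 = "IIC"))
  expect_equal(pr["Asia", "IIA"], 0.75)
  expect_equal(pr["Asia", "IIC"], 0.25)
  expect_equal(unname(rowSums(pr)), c(1, 1), tolerance = 1e-12)

  # a zero-total continent is flagged
  ab0 <- rbind(s1 = c(1, 1), s2 = c(0, 0))
  colnames(ab0) <- c("sp1", "sp2")
  tab0 <- mk_table(ab0, wwtp = c("w1", "w2"),
                   continent = c("Asia", "Europe"))
  pr0 <- continent_proportions(tab0, c(sp1 = "IIA", sp2 = "IIC"))
  expect_equal(attr(pr0, "zero_total"), "Europe")
  expect_equal(unname(rowSums(pr0)["Europe"]), 0)
})

test_that("correlation network applies joint rho and FDR thresholds", {
  set.seed(9)
  n <- 20
  ab <- matrix(runif(n * 4, 0.1, 1), n,
               dimnames = list(sprintf("s%02d", 1:n), paste0("g", 1:4)))
  ab[, "g2"] <- seq_len(n) + runif(n, 0, 1e-3)   # monotone with index
  ab[, "g1"] <- seq_len(n)                        # perfectly monotone pair
  tab <- mk_table(ab, wwtp = rownames(ab))
  net <- correlation_network(tab)
  hit <- net$edges[net$edges$taxon_a == "g1" & net$edges$taxon_b == "g2", ]
  expect_equal(hit$spearman_rho, 1)
  expect_lt(hit$q_value, 0.05)

  # q-values are the Benjamini-Hochberg step-up of the tested p-values
  p <- net$tested$p_value
  n_p <- length(p)
  o <- order(p)
  manual <- numeric(n_p)
  manual[o] <- rev(cummin(rev(p[o] * n_p / seq_len(n_p))))
  expect_equal(net$tested$q_value, pmin(1, manual))

  # constant taxa are skipped with a reason
  ab2 <- cbind(ab, g5 = rep(0.5, n))
  net2 <- correlation_network(mk_table(ab2, wwtp = rownames(ab2)))
  expect_true(all(grepl("constant", net2$skipped$reason)))
  expect_equal(sum(net2$skipped$taxon_a == "g5" |
                     net2$skipped$taxon_b == "g5"), 4)
  expect_error(correlation_network(mk_table(ab[1:5, ])), "at least 8")
})

test_that("retained edges are invariant under monotone transforms", {
  fx <- make_abundance_fixture(
    n_wwtps = 10, samples_per_wwtp = 3, n_taxa = 8,
    planted_correlations = list(list(pair = c("taxon_01", "taxon_02"),
                                     rho = 0.85)),
    seed = 6)
  net <- correlation_network(fx$table)
  tab2 <- fx$table
  tab2$abund[, "taxon_01"] <- exp(tab2$abund[, "taxon_01"] * 3)
  net2 <- correlation_network(tab2)
  expect_equal(net$edges, net2$edges)
})

test_that("planted correlations are recovered and null pairs rejected", {
  fx <- make_abundance_fixture(
    n_wwtps = 20, samples_per_wwtp = 2, n_taxa = 10,
    planted_correlations = list(
      list(pair = c("taxon_01", "taxon_02"), rho = 0.85),
      list(pair = c("taxon_03", "taxon_04"), rho = 0)),
    seed = 12)
  net <- correlation_network(fx$table, focal_genus = "taxon_01")
  is_edge <- function(a, b) any(
    (net$edges$taxon_a == a & net$edges$taxon_b == b) |
      (net$edges$taxon_a == b & net$edges$taxon_b == a))
  expect_true(is_edge("taxon_01", "taxon_02"))
  expect_false(is_edge("taxon_03", "taxon_04"))
  expect_true("taxon_02" %in% net$focal_positive)
})

test_that("abundance TSVs round-trip with their metadata sidecar", {
  fx <- make_abundance_fixture(n_wwtps = 3, samples_per_wwtp = 2,
                               n_taxa = 4, seed = 3)
  d <- withr::local_tempdir()
  write.table(fx$table$abund, file.path(d, "ab.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(fx$table$meta, file.path(d, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- read_abundance_tsv(file.path(d, "ab.tsv"),
                             file.path(d, "meta.tsv"))
  expect_equal(back$abund, fx$table$abund)
  expect_equal(back$meta, fx$table$meta)
  expect_error(abundance_table(fx$table$abund,
                               fx$table$meta[-1, ]), "missing")
})
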