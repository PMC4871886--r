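make_otu <- function(counts, lineages = NULL) {
  meta <- toy_meta(1, 1, 1)
  colnames(counts) <- meta$sample_id[seq_len(ncol(counts))]
  toy_otu(counts, meta[seq_len(ncol(counts)), ], lineages)
}

test_that("lineage cleaning removes excluded whole-rank labels only", {
  counts <- matrix(5L, 3, 2, dimnames = list(c("o1", "o2", "o3"), NULL))
  ot <- make_otu(counts, c("Eukaryota;Metazoa;Arthropoda",
                           "Eukaryota;Alveolata;Dinophyceae",
                           "Eukaryota;Stramenopiles;metazoaN"))  # substring: kept
  out <- clean_protist_table(ot, c("Metazoa", "Fungi"))
  expect_identical(rownames(out$counts), c("o2", "o3"))
  expect_identical(clean_protist_table(ot, character(0))$counts, ot$counts)
  expect_warning(clean_protist_table(ot, c("Eukaryota")), "all OTUs removed")
})

test_that("rarefaction hits the exact depth and is identity at full depth", {
  counts <- matrix(c(50L, 50L, 30L, 10L), 2,
                   dimnames = list(c("A", "B"), NULL))
  ot <- make_otu(counts)
  r1 <- rarefy(ot, depth = 40, repeats = 1, seed = 1)
  expect_equal(colSums(r1$counts), c(T0_1 = 40L, C1 = 40L))
  # full depth for a 40-read sample leaves it untouched
  expect_equal(r1$counts[, "C1"], rarefy(ot, 40, 5, seed = 2)$counts[, "C1"])
  expect_equal(rarefy(ot, 0, 1, seed = 1)$counts,
               matrix(0L, 2, 2, dimnames = dimnames(ot$counts)))
  expect_error(rarefy(ot, 60, 1, seed = 1), "C1")
  expect_error(rarefy(ot, 10, 1), "seed")
})

test_that("rarefaction means follow the hypergeometric expectation", {
  counts <- matrix(c(50L, 50L), 2, 1, dimnames = list(c("A", "B"), NULL))
  ot <- make_otu(counts)
  acc <- 0
  reps <- 1000
  r <- rarefy(ot, 10, repeats = reps, seed = 42)
  # E[A] = depth * 50/100 = 5; SE of the mean over 1000 repeats
  p <- 0.5
  se <- sqrt(10 * p * (1 - p) * (100 - 10) / 99 / reps)
  expect_lt(abs(r$counts["A", 1] - 5), 2 * se + 0.5)  # +0.5 rounding slack
  # rounded column sums stay near the target depth
  expect_lte(abs(sum(r$counts[, 1]) - 10), 2)
})

test_that("shared-OTU filter equals the brute-force set intersection", {
  meta <- toy_meta(3, 3, 3)
  set.seed(9)
  counts <- matrix(rbinom(20 * 9, 1, 0.8) * rpois(20 * 9, 5), 20,
                   dimnames = list(sprintf("o%02d", 1:20), meta$sample_id))
  storage.mode(counts) <- "integer"
  ot <- toy_otu(counts, meta)
  groups <- split(meta$sample_id, paste(meta$timepoint, meta$condition))
  out <- shared_otu_filter(ot, groups)
  # oracle: intersection of per-sample presence sets
  present <- lapply(meta$sample_id, function(s) rownames(counts)[counts[, s] > 0])
  expect_setequal(rownames(out$counts), Reduce(intersect, present))
  # an OTU present in 8/9 samples is removed
  c2 <- counts; c2[1, ] <- 5L; c2[1, 4] <- 0L
  expect_false("o01" %in% rownames(shared_otu_filter(toy_otu(c2, meta), groups)$counts))
  expect_error(shared_otu_filter(ot, list(g1 = character(0))), "empty")
})

test_that("RA profiles aggregate by rank, lump <1% categories, sum to 100", {
  counts <- matrix(c(50L, 30L, 20L, 500L, 300L, 200L), 3,
                   dimnames = list(c("o1", "o2", "o3"), NULL))
  ot <- make_otu(counts, c("Euk;PhyA;ClsA", "Euk;PhyB;ClsB", "Euk;PhyB;ClsC"))
  prof <- relative_abundance_profile(ot, level = "phylum")
  expect_equal(prof[c("PhyA", "PhyB"), 1], c(PhyA = 50, PhyB = 50))
  prof2 <- relative_abundance_profile(ot, level = "class")
  expect_equal(prof2["ClsA", ], c(T0_1 = 50, C1 = 50))
  expect_equal(unname(colSums(prof2)), c(100, 100), tolerance = 1e-9)
  # rare category lumped into Others in all samples
  counts3 <- matrix(c(995L, 5L, 199L, 1L), 2,
                    dimnames = list(c("big", "tiny"), NULL))
  ot3 <- make_otu(counts3, c("Euk;Big", "Euk;Tiny"))
  prof3 <- relative_abundance_profile(ot3, level = 2, threshold = 1)
  expect_true("Others" %in% rownames(prof3))
  expect_false("Tiny" %in% rownames(prof3))
  expect_equal(unname(prof3["Others", ]), c(0.5, 0.5))
  # single OTU -> one 100% category; missing rank -> Unclassified
  ot4 <- make_otu(matrix(c(7L, 3L), 1, dimnames = list("solo", NULL)), "Euk")
  prof4 <- relative_abundance_profile(ot4, level = "phylum")
  expect_equal(unname(prof4["Unclassified", ]), c(100, 100))
  ot5 <- make_otu(matrix(c(0L, 5L), 1, dimnames = list("z", NULL)), "Euk;P")
  expect_error(relative_abundance_profile(ot5), "zero total")
})

test_that("Bray-Curtis matches hand examples and its invariances", {
  x <- cbind(a = c(1, 3), b = c(3, 1))
  s <- bray_curtis(x)
  expect_equal(s["a", "b"], 50)
  expect_equal(diag(unclass(s)), c(a = 100, b = 100))
  expect_equal(bray_curtis(cbind(a = 1:3, b = 1:3))["a", "b"], 100)
  expect_equal(bray_curtis(cbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 0)
  # symmetry, bounds and scale invariance on random data
  set.seed(3)
  m <- matrix(rexp(40), 8)
  colnames(m) <- letters[1:5]
  s2 <- unclass(bray_curtis(m))
  expect_equal(s2, t(s2))
  expect_true(all(s2 >= 0 & s2 <= 100))
  expect_equal(unclass(bray_curtis(m * 7)), s2)
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("UPGMA reproduces hand-computed merges and is monotone", {
  sim <- matrix(c(100, 90, 50, 90, 100, 50, 50, 50, 100), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(sim) <- c("similarity_matrix", class(sim))
  d <- upgma(sim)
  expect_equal(d$merges$similarity, c(90, 50))
  # two samples merge at their pairwise similarity
  sim2 <- matrix(c(100, 73, 73, 100), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(sim2)$merges$similarity, 73)
  # identical samples all merge at 100
  simI <- matrix(100, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  expect_equal(upgma(simI)$merges$similarity, c(100, 100))
  # weighted three-point case: C joins (A,B) at the size-weighted mean
  sim3 <- matrix(c(100, 90, 40, 90, 100, 60, 40, 60, 100), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(upgma(sim3)$merges$similarity, c(90, 50))
  # monotone heights on random matrices, agreeing with hclust average linkage
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rexp(6 * 9), 6)
    colnames(m) <- paste0("s", 1:9)
    s <- bray_curtis(m)
    u <- upgma(s)
    expect_true(all(diff(u$hclust$height) >= -1e-9))
    hc <- stats::hclust(stats::as.dist(100 - unclass(s)), method = "average")
    expect_equal(sort(u$hclust$height), sort(hc$height), tolerance = 1e-9)
  }
  # Newick export round-trips through ape with the right leaves
  tree <- ape::read.tree(text = write_newick(upgma(sim)))
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("ANOSIM matches its definition, brute force, and vegan", {
  # perfect separation: all between-dissimilarities exceed all within
  sim <- matrix(100, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sim["a", "b"] <- sim["b", "a"] <- 95
  sim["c", "d"] <- sim["d", "c"] <- 96
  sim["a", "c"] <- sim["c", "a"] <- 40
  sim["a", "d"] <- sim["d", "a"] <- 45
  sim["b", "c"] <- sim["c", "b"] <- 42
  sim["b", "d"] <- sim["d", "b"] <- 41
  class(sim) <- c("similarity_matrix", class(sim))
  res <- micrograze::anosim(sim, c("g1", "g1", "g2", "g2"), 999, seed = 1)
  expect_equal(res$r_statistic, 1)
  expect_equal(res$method, "exhaustive")
  # R equals the rank-definition oracle for every 2+2 labelling
  for (lab in partitions_2_2()) {
    r <- micrograze::anosim(sim, lab, 999, seed = 1)$r_statistic
    expect_equal(r, oracle_anosim_r(sim, lab))
  }
  # observed R is the maximum over the brute-force partition enumeration
  rs <- vapply(partitions_2_2(), function(lab) oracle_anosim_r(sim, lab), numeric(1))
  expect_equal(res$r_statistic, max(rs))
  # cross-check R against the independent vegan implementation
  set.seed(12)
  m <- matrix(rexp(6 * 8), 6)
  colnames(m) <- paste0("s", 1:8)
  s <- bray_curtis(m)
  lab <- rep(c("x", "y"), each = 4)
  mine <- micrograze::anosim(s, lab, 999, seed = 2)
  veg <- vegan::anosim(stats::as.dist(100 - unclass(s)), factor(lab), permutations = 99)
  expect_equal(mine$r_statistic, unname(veg$statistic), tolerance = 1e-12)
  expect_error(micrograze::anosim(s, c("x", rep("y", 7)), 99, 1), "fewer than 2")
})

test_that("permuted-label ANOSIM R values centre on zero", {
  set.seed(21)
  m <- matrix(rexp(6 * 8), 6)
  colnames(m) <- paste0("s", 1:8)
  s <- bray_curtis(m)
  labs <- rep(c("x", "y"), each = 4)
  rs <- replicate(300, oracle_anosim_r(s, sample(labs)))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("Mann-Whitney exact p equals enumeration, ties and all", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # shifted samples at m = n = 8: most extreme of C(16,8) arrangements
  expect_equal(mann_whitney(1:8, 101:108)$p_value, 2 / choose(16, 8))
  # randomized comparison against the independent pairwise-count oracle
  set.seed(17)
  for (i in 1:60) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:6, m, replace = TRUE)  # heavy ties on purpose
    y <- sample(1:6, n, replace = TRUE)
    got <- mann_whitney(x, y)
    want <- oracle_mann_whitney(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p_value)
  }
  # large-sample path agrees with the tie-corrected normal approximation in R
  set.seed(18)
  x <- rnorm(12); y <- rnorm(13, 0.5)
  got <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})
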