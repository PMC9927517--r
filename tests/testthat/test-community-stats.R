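test_that("Shannon index matches its closed forms and a direct summation", {
  uniform <- feature_table(matrix(c(10L, 10L, 10L, 10L), 4, 1,
                                  dimnames = list(paste0("t", 1:4), "s1")))
  expect_equal(unname(shannon_index(uniform)), log(4), tolerance = 1e-12)
  single <- feature_table(matrix(c(42L, 0L, 0L), 3, 1,
                                 dimnames = list(paste0("t", 1:3), "s1")))
  expect_equal(unname(shannon_index(single)), 0)
  # brute-force -sum(p log p) on a random 50-taxon sample
  ft <- table_from_prob(matrix(stats::runif(50), 50), reads = 5000, seed = 3)
  p <- ft$counts[, 1] / sum(ft$counts[, 1])
  p <- p[p > 0]
  expect_equal(unname(shannon_index(ft))[1], -sum(p * log(p)), tolerance = 1e-12)
  # invariant to taxon order
  shuf <- subset_table(ft, taxa = rev(taxon_ids(ft)))
  expect_equal(unname(shannon_index(shuf)), unname(shannon_index(ft)))
})

test_that("Bray-Curtis matches the hand formula and its boundary cases", {
  ident <- feature_table(matrix(c(3L, 7L, 3L, 7L), 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(as.numeric(bray_curtis(ident)), 0)
  disjoint <- feature_table(matrix(c(5L, 0L, 0L, 9L), 2,
                                   dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  # 3-sample toy table, hand computation on relative abundances
  counts <- matrix(c(4L, 4L, 2L,
                     8L, 0L, 2L,
                     0L, 5L, 5L), nrow = 3,
                   dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  ft <- feature_table(counts)
  ra <- sweep(counts, 2, colSums(counts), "/")
  hand <- function(j, k) sum(abs(ra[, j] - ra[, k])) / sum(ra[, j] + ra[, k])
  d <- as.matrix(bray_curtis(ft))
  expect_equal(d["s1", "s2"], hand(1, 2), tolerance = 1e-12)
  expect_equal(d["s1", "s3"], hand(1, 3), tolerance = 1e-12)
  expect_equal(d["s2", "s3"], hand(2, 3), tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean geometry and reports axis variance", {
  # 3 equidistant samples: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ord3 <- pcoa_ordination(d3, k = 2)
  eig <- ord3$eig[ord3$eig > 1e-10]
  expect_length(eig, 2)
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  # Euclidean distances are reproduced by the full embedding
  pts <- withr::with_seed(1, matrix(rnorm(6 * 4), 6))
  d <- stats::dist(pts)
  ord <- pcoa_ordination(d, k = 4)
  expect_equal(as.numeric(stats::dist(ord$points)), as.numeric(d),
               tolerance = 1e-8)
  expect_true(all(ord$prop_explained <= 1))
  # truncation warning when k exceeds the positive spectrum
  expect_warning(pcoa_ordination(d3, k = 3), "positive eigenvalue")
  k1 <- pcoa_ordination(d, k = 1)
  expect_lte(sum(k1$prop_explained), 1)
})

test_that("PERMANOVA endpoints: maximal separation, no effect, bad factors", {
  disjoint <- feature_table(matrix(c(9L, 8L, 0L, 0L,
                                     7L, 9L, 0L, 0L,
                                     0L, 0L, 9L, 8L,
                                     0L, 0L, 8L, 9L), nrow = 4,
                                   dimnames = list(paste0("t", 1:4), paste0("s", 1:4))))
  # replicate the disjoint pattern to 7 samples per group; the permutation
  # floor is then reached up to the rare chance of re-drawing the exact split
  big <- disjoint$counts[, c(rep(1:2, 4), rep(3:4, 4))][, 1:14]
  colnames(big) <- paste0("s", 1:14)
  md <- toy_metadata(paste0("s", 1:14), genotype = rep(c("wild", "cultivated"), each = 7))
  res <- permanova(bray_curtis(feature_table(big)), md, "genotype",
                   n_permutations = 999, seed = 1)
  expect_lte(res$p_value, 0.005)
  # duplicating every sample into both groups removes the effect
  counts <- withr::with_seed(2, matrix(rpois(10 * 6, 20), nrow = 10,
                                       dimnames = list(paste0("t", 1:10), paste0("s", 1:6))))
  dup <- cbind(counts, counts)
  colnames(dup) <- paste0("s", 1:12)
  md2 <- toy_metadata(paste0("s", 1:12),
                      genotype = rep(c("wild", "cultivated"), each = 6))
  res2 <- permanova(bray_curtis(feature_table(dup)), md2, "genotype",
                    n_permutations = 99, seed = 1)
  expect_lt(res2$R2, 0.05)
  expect_error(permanova(bray_curtis(disjoint), md, "site", 99, 1), "2 levels")
})

test_that("PERMANOVA R2 is invariant to relabeling samples within groups", {
  ft <- table_from_prob(matrix(stats::runif(20 * 8), 20), reads = 1000, seed = 7)
  md <- toy_metadata(sample_ids(ft), genotype = rep(c("wild", "cultivated"), each = 4))
  d <- bray_curtis(ft)
  r1 <- permanova(d, md, "genotype", 99, seed = 5)
  md_swapped <- md
  md_swapped$replicate <- rev(md$replicate)  # irrelevant column
  r2 <- permanova(d, md_swapped, "genotype", 99, seed = 5)
  expect_equal(r1$R2, r2$R2)
})

test_that("core taxa require full prevalence AND the abundance floor", {
  reads <- 10000L
  counts <- rbind(
    everywhere_abundant = rep(3000L, 5),
    absent_once         = c(0L, rep(3000L, 4)),
    everywhere_rare     = rep(5L, 5))        # mean relabund 5e-4 < 0.001
  counts <- rbind(counts, filler = reads - colSums(counts))
  colnames(counts) <- paste0("s", 1:5)
  core <- core_taxa(feature_table(counts))
  expect_true("everywhere_abundant" %in% core$taxon_id)
  expect_false("absent_once" %in% core$taxon_id)
  expect_false("everywhere_rare" %in% core$taxon_id)
  expect_true(all(core$prevalence == 1))
  # all-core case
  allc <- feature_table(matrix(c(5L, 5L, 6L, 4L), 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_setequal(core_taxa(allc)$taxon_id, c("a", "b"))
})

test_that("raising core thresholds never adds taxa", {
  ft <- table_from_prob(matrix(stats::runif(40 * 10)^3, 40), reads = 5000, seed = 9)
  base <- core_taxa(ft, prevalence_min = 0.8, abundance_min = 0.001)$taxon_id
  for (prev in c(0.9, 1.0))
    expect_true(all(core_taxa(ft, prev, 0.001)$taxon_id %in% base))
  for (ab in c(0.005, 0.02))
    expect_true(all(core_taxa(ft, 0.8, ab)$taxon_id %in% base))
})

test_that("enrichment classifies by |log2FC| > 2 and BH FDR < 0.01", {
  # identical groups: everything unchanged at log2FC 0
  counts <- withr::with_seed(4, matrix(rpois(20 * 6, 50), nrow = 20,
                                       dimnames = list(paste0("t", 1:20), paste0("s", 1:6))))
  same <- cbind(counts, counts)
  colnames(same) <- paste0("s", 1:12)
  md <- toy_metadata(colnames(same), genotype = rep(c("wild", "cultivated"), each = 6))
  res <- enrichment(feature_table(same), md, "genotype")
  expect_true(all(res$class == "unchanged"))
  expect_true(all(res$log2fc == 0))
  # BH adjustment equals the step-up formula computed directly
  praw <- sort(res$p_value)
  stepup <- rev(cummin(rev(praw * length(praw) / seq_along(praw))))
  expect_equal(sort(res$p_adjusted), pmin(stepup, 1))
  expect_error(enrichment(feature_table(counts),
                          toy_metadata(paste0("s", 1:6),
                                       genotype = c("wild", "wild", rep("cultivated", 4))),
               "genotype"), ">= 3 samples")
})

test_that("an 8-fold abundance shift is detected as enrichment", {
  # power check: taxon at 8x relative abundance in wild, 15 samples per group
  hits <- vapply(1:200, function(rep_i) {
    prob <- withr::with_seed(1000 + rep_i, {
      base <- stats::runif(40, 0.5, 1.5)
      cbind(vapply(1:15, function(i) { p <- base; p[1] <- p[1] * 8; p }, numeric(40)),
            vapply(1:15, function(i) base, numeric(40)))
    })
    ft <- table_from_prob(prob, reads = 5000, seed = 2000 + rep_i)
    md <- toy_metadata(sample_ids(ft),
                       genotype = rep(c("wild", "cultivated"), each = 15))
    enrichment(ft, md, "genotype")$class[1] == "wild_enriched"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
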