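neutral_fixture <- function(Nm = 50, n_rep = 30, reads = 2000L, n_taxa = 100L,
                            seed = 1L) {
  des <- design_spec(n_sites = 1, n_genotypes = 1, n_replicates = n_rep,
                     n_taxa = c(bacteria = n_taxa), reads_per_sample = reads,
                     seed = seed)
  pool <- simulate_metacommunity(n_taxa, shape = 1.5, seed = seed)
  simulate_neutral_counts(pool, Nm, des)
}

test_that("neutral fit enforces its preconditions and degrades gracefully", {
  expect_error(fit_neutral(toy_table()), ">= 10 samples")
  # saturated table: every taxon in every sample, no frequency variance
  sat <- feature_table(matrix(5L, 4, 12,
                              dimnames = list(paste0("t", 1:4), paste0("s", 1:12))))
  fit <- fit_neutral(sat)
  expect_true(is.na(fit$R2))
  expect_true(all(fit$taxa$obs_freq == 1))
})

test_that("neutral partition compares observed frequency to the Wilson band", {
  tb <- neutral_fixture(Nm = 20, seed = 3)
  fit <- fit_neutral(tb)
  with(fit$taxa, {
    expect_true(all(partition[obs_freq > upper] == "above"))
    expect_true(all(partition[obs_freq < lower] == "below"))
    expect_true(all(partition[obs_freq >= lower & obs_freq <= upper] == "within"))
  })
  expect_equal(fit$fraction_above + fit$fraction_below, fit$fraction_deviating)
  expect_equal(fit$m, fit$Nm / fit$N)
  # taxon present everywhere while the predicted band tops out below 1
  always <- fit$taxa[fit$taxa$obs_freq == 1 & fit$taxa$upper < 1, ]
  if (nrow(always)) expect_true(all(always$partition == "above"))
})

test_that("beta-MNTD closed forms and agreement with an independent implementation", {
  # identical communities: distance 0 whatever the tree
  counts <- matrix(c(3L, 7L, 3L, 7L), 2,
                   dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
  tree2 <- simulate_tree(2, seed = 1)
  expect_equal(unname(beta_mntd(feature_table(counts), tree2)["s1", "s2"]), 0)
  # one taxon per community on a two-tip tree: the tip-to-tip distance
  solo <- matrix(c(5L, 0L, 0L, 5L), 2,
                 dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
  tipdist <- stats::cophenetic(tree2)["ASV1", "ASV2"]
  expect_equal(unname(beta_mntd(feature_table(solo), tree2)["s1", "s2"]), tipdist)
  # random table: matches picante::comdistnt (abundance weighted)
  tb <- neutral_fixture(Nm = 30, n_rep = 6, n_taxa = 25L, seed = 7)
  tree <- simulate_tree(25, seed = 7)
  ours <- beta_mntd(tb, tree)
  ref <- as.matrix(picante::comdistnt(t(relative_abundance(tb)),
                                      stats::cophenetic(tree),
                                      abundance.weighted = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-10)
  expect_error(beta_mntd(tb, simulate_tree(10, seed = 1)), "missing taxa")
})

test_that("beta-NTI is scale-free in branch lengths and reproducible", {
  tb <- neutral_fixture(Nm = 30, n_rep = 8, n_taxa = 40L, seed = 9)
  tree <- simulate_tree(40, seed = 9)
  bn1 <- beta_nti(tb, tree, n_null = 99, seed = 5)
  tree10 <- tree
  tree10$edge.length <- tree10$edge.length * 10
  bn2 <- beta_nti(tb, tree10, n_null = 99, seed = 5)
  ut <- upper.tri(bn1$bnti)
  expect_equal(bn1$bnti[ut], bn2$bnti[ut], tolerance = 1e-8)
  expect_equal(bn1$bmntd_obs * 10, bn2$bmntd_obs, tolerance = 1e-10)
  bn3 <- beta_nti(tb, tree, n_null = 99, seed = 5)
  expect_identical(bn1$bnti, bn3$bnti)
})

test_that("beta-NTI reports undefined pairs when the null cannot vary", {
  # both samples contain every taxon: beta-MNTD is 0 under any tip shuffle
  full <- feature_table(matrix(5L, 10, 2,
                               dimnames = list(paste0("ASV", 1:10), c("s1", "s2"))))
  tree <- simulate_tree(10, seed = 2)
  expect_warning(bn <- beta_nti(full, tree, n_null = 19, seed = 1), "zero null SD")
  expect_true(is.na(bn$bnti["s1", "s2"]))
})

test_that("Raup-Crick is bounded, symmetric, seeded, and near -1 for near-identical samples", {
  # two samples share one concentrated pool; the other samples are diverse
  # and flat, so null communities spread mass across many taxa and the
  # shared-pool pair is far more similar than the null expects
  pool <- simulate_metacommunity(150, shape = 1.5, seed = 4)
  nbr <- vapply(1:8, function(i) withr::with_seed(10 + i, {
    w <- stats::runif(150); w / sum(w)
  }), numeric(150))
  prob <- cbind(pool, pool, nbr)
  dimnames(prob) <- list(paste0("ASV", 1:150), paste0("s", 1:10))
  tb <- table_from_prob(prob, reads = 1000, seed = 8)
  rc <- raup_crick_bray(tb, n_null = 199, seed = 3)
  expect_true(all(abs(rc[upper.tri(rc)]) <= 1))
  expect_equal(rc, t(rc))
  expect_lt(rc["s1", "s2"], -0.9)
  expect_identical(rc, raup_crick_bray(tb, n_null = 199, seed = 3))
  zero <- feature_table(matrix(c(1L, 0L), 1, 2,
                               dimnames = list("a", c("s1", "s2"))))
  expect_error(raup_crick_bray(zero), "richness 0")
})

test_that("process partition applies the two-step decision rule", {
  ids <- paste0("s", 1:4)
  mk <- function(val) matrix(val, 4, 4, dimnames = list(ids, ids))
  all_high <- partition_processes(mk(3), mk(0))
  expect_equal(unname(all_high$fractions[1]), 1)   # heterogeneous selection
  all_drift <- partition_processes(mk(0), mk(0))
  expect_equal(unname(all_drift$fractions[5]), 1)
  # boundary semantics: |bNTI| = cut is NOT selection; RC = cut is NOT dispersal
  edge <- partition_processes(mk(2), mk(0.95))
  expect_equal(unname(edge$fractions[5]), 1)
  disp <- partition_processes(mk(1), mk(0.96))
  expect_equal(unname(disp$fractions[3]), 1)
  homog <- partition_processes(mk(-1), mk(-0.96))
  expect_equal(unname(homog$fractions[4]), 1)
  expect_error(partition_processes(mk(0), matrix(0, 3, 3)), "aligned")
})

test_that("partition fractions sum to one, excluded pairs are counted, cuts are monotone", {
  ids <- paste0("s", 1:6)
  b <- withr::with_seed(2, matrix(rnorm(36, 0, 2), 6, dimnames = list(ids, ids)))
  b[2, 4] <- b[4, 2] <- NA
  r <- withr::with_seed(3, matrix(runif(36, -1, 1), 6, dimnames = list(ids, ids)))
  pf <- partition_processes(b, r)
  expect_equal(sum(pf$fractions), 1, tolerance = 1e-12)
  expect_equal(pf$n_excluded, 1)
  expect_equal(pf$n_pairs, 14)
  sel <- function(cut) {
    p <- partition_processes(b, r, nti_cut = cut)
    p$fractions[1] + p$fractions[2]
  }
  expect_true(sel(1) >= sel(2) && sel(2) >= sel(3))
})

test_that("Levins niche breadth matches its closed forms", {
  uniform <- feature_table(matrix(7L, 1, 10,
                                  dimnames = list("t", paste0("s", 1:10))))
  expect_equal(niche_breadth(uniform)$taxa$B, 10)
  onesample <- feature_table(matrix(c(9L, rep(0L, 9)), 1, 10,
                                    dimnames = list("t", paste0("s", 1:10))))
  expect_equal(niche_breadth(onesample)$taxa$B, 1)
  half <- feature_table(matrix(c(5L, 5L, 0L), 1, 3,
                               dimnames = list("t", paste0("s", 1:3))))
  expect_equal(niche_breadth(half)$taxa$B, 2)
  m <- rbind(t = c(5L, 5L, 0L), zero = c(0L, 0L, 0L), pad = c(1L, 1L, 1L))
  colnames(m) <- paste0("s", 1:3)
  mixed <- feature_table(m)
  expect_warning(nb <- niche_breadth(mixed), "all-zero")
  expect_setequal(nb$taxa$taxon_id, c("t", "pad"))
  expect_equal(nb$Bcom, mean(c(2, 3)))
})

test_that("neutral fit distinguishes neutral from selection-structured data", {
  r2 <- vapply(1:10, function(s) {
    des <- design_spec(n_sites = 1, n_genotypes = 2, n_replicates = 8,
                       n_taxa = c(bacteria = 60L), reads_per_sample = 1000L,
                       seed = s)
    neutral <- simulate_scenario(des, "neutral", list(Nm = 30))
    sel <- simulate_scenario(des, "heterogeneous_selection", list(pool_shape = 1))
    c(fit_neutral(neutral$table)$R2, fit_neutral(sel$table)$R2)
  }, numeric(2))
  expect_gt(stats::median(r2[1, ]), stats::median(r2[2, ]))
})
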