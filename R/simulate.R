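#' Study design specification for the synthetic-data generators
#'
#' Encodes the sampling design of the field survey the package emulates:
#' paired wild and cultivated rice stands at several sites with replicate
#' composite leaf samples. The default is the 3 sites x 2 genotypes x 5
#' replicates layout (30 samples). Taxon richness and sequencing depth are
#' desk-scale defaults; real ASV tables run to thousands of taxa.
#'
#' @param n_sites number of sampling sites (>= 1)
#' @param n_genotypes number of rice genotypes (>= 1); the first two are
#'   labelled `wild` and `cultivated`
#' @param n_replicates replicate samples per site x genotype cell
#' @param n_taxa named count vector of taxa per kingdom, e.g.
#'   `c(bacteria = 200, fungi = 150)`
#' @param reads_per_sample sequencing depth; every simulated sample has
#'   exactly this total count (uniform depth; rarefaction is a downstream
#'   option, not a generator feature)
#' @param seed integer seed from which all of a scenario's randomness flows
#' @return a `design_spec` list
#' @export
design_spec <- function(n_sites = 3L, n_genotypes = 2L, n_replicates = 5L,
                        n_taxa = c(bacteria = 200L, fungi = 150L),
                        reads_per_sample = 20000L, seed = 1L) {
  counts <- c(n_sites, n_genotypes, n_replicates, reads_per_sample)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("design counts must be integers >= 1", call. = FALSE)
  if (is.null(names(n_taxa)) || any(!names(n_taxa) %in% c("bacteria", "fungi")))
    stop("`n_taxa` must be named with kingdoms 'bacteria' and/or 'fungi'", call. = FALSE)
  if (any(n_taxa < 1)) stop("n_taxa entries must be >= 1", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 n_taxa = n_taxa,
                 reads_per_sample = as.integer(reads_per_sample),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' @rdname design_spec
#' @param design a `design_spec`
#' @export
n_design_samples <- function(design)
  design$n_sites * design$n_genotypes * design$n_replicates

site_names <- function(n) {
  base <- c("Qionghai", "Wenchang", "Wanning")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("Site", seq_len(n - 3) + 3))
}

genotype_names <- function(n) {
  base <- c("wild", "cultivated")
  if (n <= 2) base[seq_len(n)] else c(base, paste0("genotype", seq_len(n - 2) + 2))
}

#' Sample metadata implied by a design
#'
#' @param design a [design_spec()]
#' @return data.frame with `sample_id`, `site`, `genotype`, `replicate`,
#'   in site-major order matching all generator outputs.
#' @export
design_metadata <- function(design) {
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      genotype = genotype_names(design$n_genotypes),
                      site = site_names(design$n_sites),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("site", "genotype", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", abbreviate(grid$site, 2), grid$genotype,
                            grid$replicate)
  validate_metadata(grid[, c("sample_id", "site", "genotype", "replicate")])
}

#' Lognormal ranked-abundance metacommunity pool
#'
#' Draws a source-pool relative-abundance vector from a lognormal
#' species-abundance distribution, the canonical shape for ranked microbial
#' abundances. `shape` is the log-scale standard deviation: 0 gives a
#' uniform pool, values around 1.5 give the strong dominance typical of
#' phyllosphere communities.
#'
#' @param n_taxa number of taxa (>= 2)
#' @param shape lognormal sigma (>= 0)
#' @param seed integer seed
#' @return numeric vector of length `n_taxa`, strictly positive, summing to 1
#' @export
simulate_metacommunity <- function(n_taxa, shape = 1.5, seed = 1L) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 2 || n_taxa != round(n_taxa))
    stop("`n_taxa` must be a single integer >= 2", call. = FALSE)
  if (shape < 0) stop("`shape` must be >= 0", call. = FALSE)
  pool <- withr::with_seed(as.integer(seed), stats::rlnorm(n_taxa, 0, shape))
  pool / sum(pool)
}

new_count_table <- function(prob_by_sample, design, metadata, kingdom = NULL,
                            taxon_prefix = "ASV") {
  # prob_by_sample: taxa x samples matrix of per-sample sampling probabilities
  reads <- design$reads_per_sample
  if (reads < 1) stop("`reads_per_sample` must be >= 1", call. = FALSE)
  counts <- apply(prob_by_sample, 2, function(p) {
    s <- sum(p)
    if (s <= 0) stop("degenerate sample: all sampling probabilities zero", call. = FALSE)
    stats::rmultinom(1, reads, p / s)[, 1]
  })
  rownames(counts) <- paste0(taxon_prefix, seq_len(nrow(counts)))
  colnames(counts) <- metadata$sample_id
  feature_table(counts, kingdom = kingdom)
}

#' Neutral-assembly count tables (Sloan generative inverse)
#'
#' Generates communities under the stochastic birth-death-immigration model
#' behind the Sloan neutral fit: for a taxon with pool abundance `p`, its
#' per-sample relative abundance is Beta(Nm*p, Nm*(1-p)) — the stationary
#' distribution of the neutral model at immigration pressure `Nm` — after
#' which reads are drawn multinomially. Because this is the exact generative
#' inverse of [fit_neutral()], a simulate-then-fit round trip recovers `Nm`.
#'
#' @param pool metacommunity relative-abundance vector (see
#'   [simulate_metacommunity()])
#' @param Nm positive product of local community size and migration rate;
#'   large `Nm` means samples track the pool closely
#' @param design a [design_spec()]; only the sample count and depth are used
#' @param seed integer seed (defaults to the design's)
#' @return a [feature_table()] with `n_design_samples(design)` columns
#' @export
simulate_neutral_counts <- function(pool, Nm, design, seed = design$seed) {
  if (!is.numeric(Nm) || length(Nm) != 1 || !is.finite(Nm) || Nm <= 0)
    stop("`Nm` must be a single positive number", call. = FALSE)
  md <- design_metadata(design)
  n_s <- nrow(md)
  n_t <- length(pool)
  withr::with_seed(as.integer(seed), {
    prob <- matrix(stats::rbeta(n_t * n_s, shape1 = rep(Nm * pool, n_s),
                                shape2 = rep(Nm * (1 - pool), n_s)),
                   nrow = n_t, ncol = n_s)
    # guard the (measure-zero) case of an all-zero column
    zero <- colSums(prob) == 0
    if (any(zero)) prob[, zero] <- pool
    new_count_table(prob, design, md)
  })
}

#' Pure-birth phylogeny for simulated taxa
#'
#' Yule tree rescaled to unit root-to-tip depth, so Brownian trait variance
#' and environmental offsets are expressed in comparable units. Tip labels
#' are `ASV1..ASVn`, matching generator tables.
#'
#' @param n_taxa number of tips (>= 2)
#' @param seed integer seed
#' @return an [ape::phylo] object, binary and ultrametric
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 2 || n_taxa != round(n_taxa))
    stop("`n_taxa` must be a single integer >= 2", call. = FALSE)
  tree <- withr::with_seed(as.integer(seed), ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("ASV", seq_len(n_taxa))
  tree
}

#' Environmentally selected count tables
#'
#' Phylogenetically structured selection: a trait evolves by Brownian motion
#' along the tree (rate chosen so the root-to-tip trait standard deviation
#' is 1), each sample carries an environmental optimum, and a Gaussian
#' fitness filter `exp(-(trait - env)^2 / (2 * trait_sd^2))` reweights the
#' pool before multinomial read sampling. Samples with contrasting `env`
#' end up phylogenetically divergent, which the beta-NTI stage detects as
#' heterogeneous selection.
#'
#' @param pool metacommunity relative-abundance vector
#' @param tree phylogeny whose tips cover all taxa (names `ASV1..ASVn`)
#' @param env_per_sample numeric vector of environmental optima, one per
#'   design sample, in trait-SD units
#' @param trait_sd width of the Gaussian fitness filter in trait-SD units;
#'   small values mean strong selection (default 0.5)
#' @param design a [design_spec()]
#' @param seed integer seed
#' @export
simulate_selection_counts <- function(pool, tree, env_per_sample, trait_sd = 0.5,
                                      design, seed = design$seed) {
  md <- design_metadata(design)
  if (length(env_per_sample) == 0)
    stop("`env_per_sample` is empty", call. = FALSE)
  if (length(env_per_sample) != nrow(md))
    stop("`env_per_sample` must have one value per design sample (",
         nrow(md), ")", call. = FALSE)
  if (any(!is.finite(env_per_sample)))
    stop("`env_per_sample` must be finite", call. = FALSE)
  if (!is.numeric(trait_sd) || trait_sd <= 0)
    stop("`trait_sd` must be positive", call. = FALSE)
  taxa <- paste0("ASV", seq_along(pool))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tree is missing tip(s) for taxa: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)[taxa]
    prob <- vapply(env_per_sample, function(env) {
      w <- exp(-(trait - env)^2 / (2 * trait_sd^2))
      pool * w
    }, numeric(length(pool)))
    new_count_table(prob, design, md)
  })
}

#' Dispersal-limited count tables
#'
#' Restricted colonization with local drift: each site receives a subset of
#' the pool (a fraction `subsample_fraction` of taxa, drawn with probability
#' proportional to pool abundance, so widespread taxa colonize most sites)
#' and the colonists' abundances then drift independently per site by a
#' lognormal factor of scale `drift_sd`. Samples within a site are
#' multinomial draws from that site's drifted pool. Communities at different
#' sites therefore diverge in composition more than a well-mixed null
#' expects — the Raup-Crick signature of dispersal limitation acting with
#' drift — while samples within a site are more similar than the null
#' (homogenizing dispersal), and neither carries phylogenetic signal, so
#' |beta-NTI| stays small.
#'
#' @param pool metacommunity relative-abundance vector
#' @param subsample_fraction fraction of the pool reaching each site, in
#'   (0, 1]; default 0.25
#' @param drift_sd lognormal SD of per-site abundance drift (default 3,
#'   i.e. site pools typically diverge by more than an order of magnitude
#'   in their dominant members — a regime firmly dominated by dispersal
#'   limitation rather than drift alone)
#' @param design a [design_spec()]
#' @param seed integer seed
#' @export
simulate_dispersal_counts <- function(pool, subsample_fraction = 0.25,
                                      drift_sd = 3, design,
                                      seed = design$seed) {
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction > 1)
    stop("`subsample_fraction` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(drift_sd) || drift_sd < 0)
    stop("`drift_sd` must be >= 0", call. = FALSE)
  md <- design_metadata(design)
  n_t <- length(pool)
  k <- max(2L, round(subsample_fraction * n_t))
  withr::with_seed(as.integer(seed), {
    site_pools <- lapply(unique(md$site), function(s) {
      keep <- sample.int(n_t, k, prob = pool)
      p <- numeric(n_t)
      p[keep] <- pool[keep] * stats::rlnorm(k, 0, drift_sd)
      p
    })
    names(site_pools) <- unique(md$site)
    prob <- vapply(seq_len(nrow(md)), function(j)
      site_pools[[as.character(md$site[j])]], numeric(n_t))
    new_count_table(prob, design, md)
  })
}

#' Count tables with planted pairwise correlations
#'
#' Latent log-abundance model for benchmarking network recovery: every
#' planted pair (i, j, sign) shares a standard-normal per-sample factor,
#' added to taxon i's log abundance and (sign-flipped for negative edges)
#' to taxon j's; independent Gaussian noise of scale `noise_sd` is added to
#' every taxon, abundances are exponentiated around the pool and reads drawn
#' multinomially. With the default `noise_sd = 0.3` planted pairs have
#' latent Spearman correlations near 0.9 against an uncorrelated background.
#'
#' @param design a [design_spec()]
#' @param planted_edges data.frame with integer columns `i`, `j` and a
#'   `sign` column in `c(1, -1)`
#' @param noise_sd per-taxon log-abundance noise (> 0)
#' @param pool optional pool; defaults to a lognormal pool of the design's
#'   total taxon count with shape 1
#' @param seed integer seed
#' @return a [feature_table()] with kingdom labels from the design
#' @export
simulate_planted_network <- function(design, planted_edges, noise_sd = 0.3,
                                     pool = NULL, seed = design$seed) {
  n_t <- sum(design$n_taxa)
  if (!all(c("i", "j", "sign") %in% names(planted_edges)))
    stop("`planted_edges` needs columns i, j, sign", call. = FALSE)
  if (any(planted_edges$i == planted_edges$j))
    stop("self-edge planted: taxon ", planted_edges$i[planted_edges$i == planted_edges$j][1],
         call. = FALSE)
  if (any(planted_edges$i > n_t | planted_edges$j > n_t |
          planted_edges$i < 1 | planted_edges$j < 1))
    stop("planted taxon index out of range", call. = FALSE)
  if (!all(planted_edges$sign %in% c(-1, 1)))
    stop("planted signs must be +1 or -1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  md <- design_metadata(design)
  if (is.null(pool)) pool <- simulate_metacommunity(n_t, shape = 1, seed = seed)
  kingdom <- rep(names(design$n_taxa), design$n_taxa)
  withr::with_seed(as.integer(seed), {
    n_s <- nrow(md)
    loga <- matrix(rep(log(pool), n_s), nrow = n_t)
    for (e in seq_len(nrow(planted_edges))) {
      z <- stats::rnorm(n_s)
      loga[planted_edges$i[e], ] <- loga[planted_edges$i[e], ] + z
      loga[planted_edges$j[e], ] <- loga[planted_edges$j[e], ] + planted_edges$sign[e] * z
    }
    loga <- loga + matrix(stats::rnorm(n_t * n_s, 0, noise_sd), nrow = n_t)
    new_count_table(exp(loga), design, md, kingdom = kingdom)
  })
}

#' Study-like tables with known core and enriched taxa
#'
#' Builds a two-kingdom community in which a designated set of core taxa is
#' given enough pool mass to appear in every sample above the core-abundance
#' floor, and designated taxa are enriched in one genotype by a known log2
#' effect. Mild lognormal per-sample noise plus a site effect create the
#' site/genotype structure that ordination and PERMANOVA then recover.
#'
#' @param design a [design_spec()]
#' @param core_taxa data.frame with columns `taxon` (index) and
#'   `rel_abundance` (target pool relative abundance), or NULL
#' @param enriched_taxa data.frame with columns `taxon` (index), `genotype`
#'   (label) and `log2fc` (effect size), or NULL
#' @param site_sd lognormal SD of the per-site taxon effect (default 0.5)
#' @param noise_sd lognormal SD of per-sample taxon noise (default 0.3)
#' @param seed integer seed
#' @export
simulate_study_counts <- function(design, core_taxa = NULL, enriched_taxa = NULL,
                                  site_sd = 0.5, noise_sd = 0.3,
                                  seed = design$seed) {
  n_t <- sum(design$n_taxa)
  md <- design_metadata(design)
  pool <- simulate_metacommunity(n_t, shape = 1.5, seed = seed)
  if (!is.null(core_taxa)) {
    pool[core_taxa$taxon] <- core_taxa$rel_abundance
    pool <- pool / sum(pool)
  }
  kingdom <- rep(names(design$n_taxa), design$n_taxa)
  withr::with_seed(as.integer(seed) + 1L, {
    sites <- unique(md$site)
    site_eff <- matrix(stats::rnorm(n_t * length(sites), 0, site_sd), nrow = n_t,
                       dimnames = list(NULL, sites))
    prob <- vapply(seq_len(nrow(md)), function(j) {
      lp <- log(pool) + site_eff[, as.character(md$site[j])] +
        stats::rnorm(n_t, 0, noise_sd)
      if (!is.null(enriched_taxa)) {
        hit <- enriched_taxa$genotype == md$genotype[j]
        lp[enriched_taxa$taxon[hit]] <- lp[enriched_taxa$taxon[hit]] +
          log(2) * enriched_taxa$log2fc[hit]
      }
      exp(lp)
    }, numeric(n_t))
    new_count_table(prob, design, md, kingdom = kingdom)
  })
}

#' Dispatch a named simulation scenario
#'
#' Single entry point used by the pipeline and command line: builds the
#' pool (and tree where needed) and runs the generator for one of the named
#' regimes. Scenario parameters are supplied as a named list; defaults are
#' the regimes' documented values.
#'
#' @param design a [design_spec()]
#' @param scenario one of `neutral`, `heterogeneous_selection`,
#'   `dispersal_limitation`, `planted_network`, `core_and_enrichment`
#' @param params named list of scenario parameters (`Nm`, `trait_sd`,
#'   `env_values`, `subsample_fraction`, `planted_edges`, `noise_sd`,
#'   `core_taxa`, `enriched_taxa`, `pool_shape`)
#' @return list with `table`, `metadata`, `tree` (or NULL), `pool`, `truth`
#'   (scenario-specific ground-truth record)
#' @export
simulate_scenario <- function(design, scenario = "neutral", params = list()) {
  n_t <- sum(design$n_taxa)
  shape <- params$pool_shape %||% 1.5
  pool <- simulate_metacommunity(n_t, shape = shape, seed = design$seed)
  md <- design_metadata(design)
  kingdom <- rep(names(design$n_taxa), design$n_taxa)
  tree <- NULL
  truth <- list(scenario = scenario)
  table <- switch(
    scenario,
    neutral = {
      Nm <- params$Nm %||% 50
      truth$Nm <- Nm
      tb <- simulate_neutral_counts(pool, Nm, design)
      feature_table(tb$counts, kingdom = kingdom)
    },
    heterogeneous_selection = {
      tree <- simulate_tree(n_t, seed = design$seed)
      env <- params$env_values %||% ifelse(md$genotype == genotype_names(2)[1], 2, -2)
      trait_sd <- params$trait_sd %||% 0.5
      truth$env <- env; truth$trait_sd <- trait_sd
      tb <- simulate_selection_counts(pool, tree, env, trait_sd, design)
      feature_table(tb$counts, kingdom = kingdom)
    },
    dispersal_limitation = {
      frac <- params$subsample_fraction %||% 0.25
      drift_sd <- params$drift_sd %||% 3
      truth$subsample_fraction <- frac; truth$drift_sd <- drift_sd
      tb <- simulate_dispersal_counts(pool, frac, drift_sd, design)
      feature_table(tb$counts, kingdom = kingdom)
    },
    planted_network = {
      edges <- params$planted_edges
      if (is.null(edges)) stop("planted_network scenario needs `planted_edges`",
                               call. = FALSE)
      truth$planted_edges <- edges
      simulate_planted_network(design, edges, noise_sd = params$noise_sd %||% 0.3,
                               pool = pool)
    },
    core_and_enrichment = {
      truth$core_taxa <- params$core_taxa
      truth$enriched_taxa <- params$enriched_taxa
      simulate_study_counts(design, core_taxa = params$core_taxa,
                            enriched_taxa = params$enriched_taxa)
    },
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
  if (is.null(tree) && isTRUE(params$with_tree))
    tree <- simulate_tree(n_t, seed = design$seed)
  list(table = table, metadata = md, tree = tree, pool = pool, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
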