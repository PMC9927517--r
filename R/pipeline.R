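#' Assemble and validate a pipeline run configuration
#'
#' A run is fully described by one flat key-value configuration: either a
#' simulation scenario or paths to existing input tables, per-stage toggles,
#' the published analysis thresholds, permutation/null counts, a seed and
#' an output directory. Defaults are the thresholds of the analysis the
#' package implements: rare filter 1e-4, core prevalence 1 and abundance
#' 0.001, |log2FC| > 2 at FDR < 0.01, network |rho| > 0.6 at BH p < 0.01,
#' process cuts +/-2 (betaNTI) and +/-0.95 (RC).
#'
#' @param outdir output directory (created if needed)
#' @param seed integer master seed
#' @param scenario simulation scenario name (see [simulate_scenario()]), or
#'   NULL to read `table_path`/`metadata_path`/`taxonomy_path`/`tree_path`
#' @param table_path,metadata_path,taxonomy_path,tree_path input files used
#'   when `scenario` is NULL
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "core", "enrichment", "network", "assembly")`
#' @param design a [design_spec()] for simulated runs
#' @param scenario_params named list forwarded to [simulate_scenario()]
#' @param rare_min,prevalence_min,abundance_min,lfc_min,fdr_max,rho_min,p_max,nti_cut,rc_cut
#'   analysis thresholds (see the stage functions)
#' @param n_permutations PERMANOVA permutations (default 999)
#' @param n_null null draws for betaNTI and Raup-Crick (default 999)
#' @return a validated `run_config` list
#' @export
run_config <- function(outdir, seed = 1L, scenario = "core_and_enrichment",
                       table_path = NULL, metadata_path = NULL,
                       taxonomy_path = NULL, tree_path = NULL,
                       stages = c("diversity", "core", "enrichment", "network",
                                  "assembly"),
                       design = design_spec(seed = seed),
                       scenario_params = list(),
                       rare_min = 1e-4, prevalence_min = 1.0,
                       abundance_min = 0.001, lfc_min = 2, fdr_max = 0.01,
                       rho_min = 0.6, p_max = 0.01, nti_cut = 2, rc_cut = 0.95,
                       n_permutations = 999, n_null = 999) {
  known <- c("diversity", "core", "enrichment", "network", "assembly")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(scenario) && is.null(table_path))
    stop("either a simulation `scenario` or a `table_path` is required", call. = FALSE)
  checks <- list(rare_min = c(0, 1), prevalence_min = c(0, 1),
                 abundance_min = c(0, 1), fdr_max = c(0, 1), rho_min = c(0, 1),
                 p_max = c(0, 1), rc_cut = c(0, 1))
  vals <- mget(names(checks))
  for (nm in names(checks))
    if (vals[[nm]] < checks[[nm]][1] || vals[[nm]] > checks[[nm]][2])
      stop("`", nm, "` out of range [", checks[[nm]][1], ", ", checks[[nm]][2], "]",
           call. = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed), scenario = scenario,
                 table_path = table_path, metadata_path = metadata_path,
                 taxonomy_path = taxonomy_path, tree_path = tree_path,
                 stages = stages, design = design,
                 scenario_params = scenario_params, rare_min = rare_min,
                 prevalence_min = prevalence_min, abundance_min = abundance_min,
                 lfc_min = lfc_min, fdr_max = fdr_max, rho_min = rho_min,
                 p_max = p_max, nti_cut = nti_cut, rc_cut = rc_cut,
                 n_permutations = as.integer(n_permutations),
                 n_null = as.integer(n_null)),
            class = "run_config")
}

stage_log <- function(stage, msg) message("[", stage, "] ", msg)

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> diversity/ordination/
#' PERMANOVA -> core -> enrichment -> per-genotype networks -> per-genotype
#' assembly models, writing every stage's outputs as TSV/JSON under the
#' configured directory plus a run manifest with the seed, thresholds,
#' input checksums, per-stage record counts and output checksums. Reruns
#' of the same configuration produce identical checksums.
#'
#' @param config a [run_config()]
#' @return the manifest (invisibly also written to `manifest.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("phyllocom")),
                   seed = config$seed,
                   thresholds = config[c("rare_min", "prevalence_min",
                                         "abundance_min", "lfc_min", "fdr_max",
                                         "rho_min", "p_max", "nti_cut", "rc_cut")],
                   stages = list())

  # ---- inputs ----
  if (!is.null(config$scenario)) {
    stage_log("simulate", paste("scenario", config$scenario))
    params <- config$scenario_params
    if ("assembly" %in% config$stages) params$with_tree <- TRUE
    sim <- simulate_scenario(config$design, config$scenario, params)
    tab <- sim$table; md <- sim$metadata; tree <- sim$tree
    write_feature_table(tab, out("feature_table.tsv"))
    write_metadata(md, out("metadata.tsv"))
    if (!is.null(tab$kingdom))
      write_taxonomy(data.frame(taxon_id = taxon_ids(tab),
                                kingdom = unname(tab$kingdom)),
                     out("taxonomy.tsv"))
    if (!is.null(tree)) ape::write.tree(tree, out("tree.nwk"))
    manifest$stages$simulate <- list(scenario = config$scenario,
                                     n_taxa = n_taxa(tab), n_samples = n_samples(tab))
  } else {
    stage_log("load", config$table_path)
    tab <- read_feature_table(config$table_path, taxonomy = config$taxonomy_path)
    md <- read_metadata(config$metadata_path)
    tree <- if (!is.null(config$tree_path)) read_tree(config$tree_path) else NULL
    manifest$input_checksums <- as.list(tools::md5sum(
      stats::na.omit(c(config$table_path, config$metadata_path,
                       config$taxonomy_path, config$tree_path))))
  }
  md <- align_metadata(tab, md)
  if ("assembly" %in% config$stages && is.null(tree))
    stop("[assembly] requires a phylogenetic tree (tree_path or simulated)",
         call. = FALSE)

  # ---- diversity ----
  if ("diversity" %in% config$stages) {
    stage_log("diversity", "Shannon, Bray-Curtis, PCoA, PERMANOVA")
    H <- shannon_index(tab)
    d <- bray_curtis(tab)
    ord <- pcoa_ordination(d, k = 2)
    perm <- lapply(c("site", "genotype"), function(f)
      permanova(d, md, f, config$n_permutations, seed = config$seed))
    utils::write.table(data.frame(sample_id = names(H), shannon = unname(H)),
                       out("alpha_diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    coords <- data.frame(sample_id = rownames(ord$points), ord$points)
    utils::write.table(coords, out("pcoa_coordinates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    perm_df <- do.call(rbind, lapply(perm, as.data.frame))
    utils::write.table(perm_df, out("permanova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$diversity <- list(n_samples = length(H),
                                      permanova = perm_df)
  }

  # ---- core ----
  if ("core" %in% config$stages) {
    stage_log("core", "prevalence/abundance screen")
    core <- core_taxa(tab, config$prevalence_min, config$abundance_min)
    utils::write.table(core, out("core_taxa.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$core <- list(n_core = nrow(core))
  }

  # ---- enrichment ----
  if ("enrichment" %in% config$stages) {
    stage_log("enrichment", "wild vs cultivated differential abundance")
    enr <- enrichment(tab, md, "genotype", config$lfc_min, config$fdr_max)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$enrichment <- list(n_taxa = nrow(enr),
                                       n_enriched = sum(enr$class != "unchanged"))
  }

  # ---- network ----
  if ("network" %in% config$stages) {
    nets <- list()
    for (g in unique(as.character(md$genotype))) {
      stage_log("network", paste("genotype", g))
      sub <- subset_table(tab, samples = md$sample_id[md$genotype == g])
      sub <- filter_rare(sub, config$rare_min)
      corr <- spearman_matrix(relative_abundance(sub))
      net <- build_network(corr, kingdom = sub$kingdom,
                           rho_min = config$rho_min, p_max = config$p_max)
      write_network(net, out(paste0("network_", g, "_edges.tsv")),
                    out(paste0("network_", g, "_nodes.tsv")))
      s <- summarize_network(net)
      nets[[g]] <- list(n_nodes = s$n_nodes, n_edges = s$n_edges,
                        average_degree = s$average_degree,
                        modularity = s$modularity,
                        proportion_negative = s$proportion_negative)
    }
    manifest$stages$network <- nets
  }

  # ---- assembly ----
  if ("assembly" %in% config$stages) {
    asm <- list()
    for (g in unique(as.character(md$genotype))) {
      stage_log("assembly", paste("genotype", g))
      sub <- subset_table(tab, samples = md$sample_id[md$genotype == g])
      fit <- fit_neutral(sub)
      utils::write.table(fit$taxa, out(paste0("neutral_fit_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bn <- beta_nti(sub, tree, n_null = config$n_null, seed = config$seed)
      rc <- raup_crick_bray(sub, n_null = config$n_null, seed = config$seed)
      pf <- partition_processes(bn, rc, config$nti_cut, config$rc_cut)
      nb <- niche_breadth(sub)
      utils::write.table(
        data.frame(process = names(pf$counts), fraction = pf$fractions),
        out(paste0("process_fractions_", g, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(nb$taxa, out(paste0("niche_breadth_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      asm[[g]] <- list(m = fit$m, Nm = fit$Nm, R2 = fit$R2,
                       fraction_deviating = fit$fraction_deviating,
                       process_fractions = stats::setNames(
                         as.list(pf$fractions), names(pf$counts)),
                       Bcom = nb$Bcom)
    }
    manifest$stages$assembly <- asm
  }

  files <- setdiff(list.files(config$outdir, full.names = TRUE), out("manifest.json"))
  manifest$output_checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
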