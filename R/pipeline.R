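default_thresholds <- function() {
  list(min_coverage = 10, beta_q = c(0.01, 0.99), p_q = 0.01,
       max_gap = 40, min_cluster = 3, promoter = 2000,
       edge_confidence = 0.7, fdr = 0.05)
}

#' Validate and normalise a pipeline configuration
#'
#' A configuration is a named list (or YAML file path) with either a
#' `simulate` block (arguments for [sim_config()] plus `pedigree` arguments
#' `n_founders`/`n_generations`) or input paths (`cgmap` vector,
#' `sample_table`, `pedigree`); an `analyses` list of
#' `list(tissue =, predictor =)` pairs; optional `annotation`, `gmt`,
#' `edges` paths; `thresholds` overrides; `output_dir`; and `seed`.
#' Defaults follow the analysis conventions of the pipeline: 10x minimum
#' coverage, 1st/99th beta and 1st p percentiles, <40 bp cluster gap,
#' 3-site network clusters, 2 kb promoters, 0.7 edge confidence, 0.05 FDR.
#'
#' @param config Named list or YAML path.
#' @return The normalised config (class `pipeline_config`), or an error
#'   describing every violated rule.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  thr <- utils::modifyList(default_thresholds(),
                           if (is.null(config$thresholds)) list()
                           else config$thresholds)
  config$thresholds <- thr
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) config$output_dir <- tempfile("kinmeth_run")
  simulate <- !is.null(config$simulate)
  if (!simulate) {
    for (p in c("cgmap", "sample_table", "pedigree")) {
      if (is.null(config[[p]])) {
        errors <- c(errors, paste0("missing input: ", p))
      } else if (!all(file.exists(config[[p]]))) {
        errors <- c(errors, paste0("missing file(s) for ", p))
      }
    }
  }
  if (is.null(config$analyses) || !length(config$analyses)) {
    errors <- c(errors, "no analyses specified")
  } else {
    allowed <- list(Blood = "avg_litter_size",
                    Testes = c("avg_litter_size", "testes_firmness"),
                    Sperm = c("avg_litter_size", "sperm_count_per_ml"))
    for (a in config$analyses) {
      if (is.null(a$tissue) || is.null(a$predictor)) {
        errors <- c(errors, "analysis missing tissue or predictor")
        next
      }
      if (!a$tissue %in% names(allowed)) {
        errors <- c(errors, paste0("unknown tissue: ", a$tissue))
      } else if (!a$predictor %in% allowed[[a$tissue]]) {
        errors <- c(errors, sprintf("predictor %s is not defined for %s",
                                    a$predictor, a$tissue))
      }
    }
  }
  for (p in c("annotation", "gmt", "edges")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      errors <- c(errors, paste0("missing file: ", p))
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "))
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the full methylation association pipeline
#'
#' Orchestrates, per configured analysis (tissue x predictor): CGmap
#' reading (or simulation), conversion efficiency, CG-context restriction,
#' coverage filtering, sample uniting, PCA QC, the binomial mixed model
#' scan, dual-percentile DMS calling, DMcluster aggregation, and -- when
#' annotation / gene-set / edge-list inputs are configured -- genomic
#' annotation, hypergeometric enrichment and network assembly. All outputs
#' are written under `output_dir` with a JSON manifest echoing every
#' threshold and the seed.
#'
#' @param config A [validate_config()]-accepted configuration.
#' @return Invisibly, a list with per-analysis results (`association`,
#'   `dms`, `clusters`, `annotation`, `enrichment`, `network`), `qc`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  thr <- config$thresholds
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("kinmeth")),
    seed = config$seed, thresholds = thr, stages = list())
  set.seed(config$seed)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    ped_args <- list(n_founders = sim_args$n_founders %||% 6,
                     n_generations = sim_args$n_generations %||% 3,
                     seed = config$seed)
    sim_args$n_founders <- NULL
    sim_args$n_generations <- NULL
    sim_args$seed <- config$seed
    pedigree <- do.call(simulate_pedigree, ped_args)
    dataset <- simulate_dataset(do.call(sim_config, sim_args), pedigree)
    methylomes <- dataset$methylomes
    samples <- dataset$phenotypes
  } else {
    methylomes <- lapply(config$cgmap, read_cgmap)
    names(methylomes) <- vapply(methylomes, attr, character(1), "sample_id")
    samples <- read_samples_table(config$sample_table)
    pedigree <- read_pedigree(config$pedigree)
  }
  manifest$stages$input <- list(n_samples = length(methylomes))

  efficiencies <- vapply(methylomes, function(m) {
    tryCatch(conversion_efficiency(m), error = function(e) NA_real_)
  }, numeric(1))

  # CG-only, coverage-filtered methylomes (lambda spike-in removed with the
  # conversion summary already taken)
  filtered <- lapply(methylomes, function(m) {
    cg <- context_summary(m)$cg
    cg <- cg[cg$chrom != "lambda", , drop = FALSE]
    filter_coverage(cg, thr$min_coverage)
  })
  manifest$stages$filter <- list(
    min_coverage = thr$min_coverage,
    sites_in = vapply(methylomes, nrow, integer(1)),
    sites_out = vapply(filtered, nrow, integer(1)))

  # replicate resolution by conversion efficiency
  if (any(samples$replicate_flag)) {
    summ <- summarize_samples(samples, efficiencies)
    keep <- summ$retained
    filtered <- filtered[keep]
    samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
    manifest$stages$replicates <- summ$replicate_log
  }

  A <- additive_relationship(pedigree)

  full <- unite(filtered)
  qc <- list(conversion_efficiency = efficiencies)
  if (length(full$samples) >= 2L && nrow(full$sites) >= 2L) {
    pca <- pca_methylation(full)
    tissue <- samples$tissue[match(full$samples, samples$sample_id)]
    qc$pca_var_explained <- pca$var_explained[seq_len(
      min(5, length(pca$var_explained)))]
    if (length(unique(tissue)) >= 2L) {
      qc$pc1_tissue <- pc_covariate_association(pca$scores[, 1], tissue,
                                                "categorical")
    }
    eff_ok <- efficiencies[full$samples]
    if (!anyNA(eff_ok) && stats::sd(eff_ok) > 0) {
      qc$pc1_conversion <- pc_covariate_association(pca$scores[, 1],
                                                    eff_ok, "continuous")
    }
  }
  write_qc_report(qc, file.path(config$output_dir, "qc_report.json"))

  index <- if (!is.null(config$annotation)) {
    build_feature_index(config$annotation, promoter_width = thr$promoter)
  }
  gmt <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  edges <- if (!is.null(config$edges)) read_edges(config$edges)

  results <- list()
  for (a in config$analyses) {
    label <- paste(a$tissue, a$predictor, sep = "_")
    adir <- file.path(config$output_dir, label)
    dir.create(adir, showWarnings = FALSE)
    sel <- samples$sample_id[samples$tissue == a$tissue]
    mat <- unite(filtered[sel])
    cfg <- bmm_config(predictor = a$predictor)
    assoc <- fit_all_sites(mat, samples, A, cfg)
    write_association(assoc, file.path(adir, "association.tsv"))
    dms <- select_outliers(assoc, beta_q = thr$beta_q, p_q = thr$p_q,
                           label = label)
    write_dms_bed(dms, file.path(adir, "dms.bed"))
    clusters <- call_dmclusters(dms, max_gap = thr$max_gap,
                                min_sites = thr$min_cluster)
    write_cluster_bed(clusters, file.path(adir, "clusters.bed"),
                      label = label)
    res <- list(association = assoc, dms = dms, clusters = clusters)
    if (!is.null(index)) {
      res$annotation <- annotate_sites(dms$sites, index)
      write_annotation(dms$sites, res$annotation,
                       file.path(adir, "annotation.tsv"))
      cluster_genes <- annotate_clusters(clusters, index)
      res$cluster_genes <- cluster_genes
      if (!is.null(gmt) && length(cluster_genes$gene_universe)) {
        res$enrichment <- tryCatch(
          hypergeometric_enrichment(cluster_genes$gene_universe, gmt,
                                    fdr = thr$fdr),
          error = function(e) NULL)
        if (!is.null(res$enrichment)) {
          data.table::fwrite(res$enrichment$table,
                             file.path(adir, "enrichment.tsv"), sep = "\t")
        }
      }
      if (!is.null(edges) && length(cluster_genes$gene_universe)) {
        res$network <- build_network(edges, cluster_genes$gene_universe,
                                     min_confidence = thr$edge_confidence)
        write_network(res$network, file.path(adir, "network.json"))
      }
    }
    manifest$stages[[label]] <- list(
      n_samples = length(sel), n_sites = nrow(mat$sites),
      n_dms = nrow(dms$sites), n_clusters = nrow(clusters$clusters),
      n_network_clusters = nrow(clusters$network_input),
      inflation = assoc$inflation)
    results[[label]] <- res
  }
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(analyses = results, qc = qc, manifest = manifest,
                 samples = samples, kinship = A))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the packaged study sample table
#'
#' The 22-sample, 9-individual metadata table (tissue type, collection
#' date, age, lifetime average litter size, testes status, EEJ sperm count
#' per mL) shipped with the package.
#'
#' @return File path to the TSV fixture.
#' @export
study_samples_path <- function() {
  system.file("extdata", "study_samples.tsv", package = "kinmeth",
              mustWork = TRUE)
}
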