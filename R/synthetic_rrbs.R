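#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a small pedigreed
#' captive-bred population sampled across three tissues (8 blood, 9 testes,
#' 5 sperm samples from 9 individuals), read depth around 25x, high CG
#' methylation (mean ~0.5) against near-zero CHG/CHH methylation, bisulfite
#' conversion efficiency 99.4%, and an unmethylated lambda spike-in
#' chromosome.
#'
#' Per CG site i and sample j the methylated count is
#' Binomial(total_ij, pi_ij) with
#' logit(pi_ij) = b_i + x_j beta_i + age_j gamma + tissue shift + g_i + e_ij,
#' where per-site genetic effects g over individuals are jointly normal with
#' covariance sigma_g2 * A (A the additive relationship matrix) and e is
#' independent normal noise with variance sigma_e2. Unmethylated reads are
#' misread as methylated with probability 1 - conversion_efficiency.
#'
#' @param n_individuals Number of individuals drawn from the pedigree (the
#'   most recent generations, which carry kinship structure).
#' @param tissues Data frame with columns `label`, `shift` (logit-scale
#'   global methylation offset; defaults mirror the sperm-hypermethylation
#'   pattern while keeping the grand CG mean at the baseline) and `n`
#'   (samples of that tissue).
#' @param n_sites CG sites per scaffold; half as many CHG and CHH sites each
#'   are added per scaffold.
#' @param n_scaffolds Number of genomic scaffolds.
#' @param depth_mean Mean total reads per site (Poisson truncated at >= 1).
#' @param baseline_mf_cg Mean CG methylation fraction.
#' @param mf_chh_chg Mean non-CG methylation fraction.
#' @param site_sd Site-to-site SD of the baseline logit.
#' @param frac_causal Fraction of CG sites carrying a phenotype effect.
#' @param beta_causal Logit-scale effect per unit predictor at causal sites.
#' @param causal_predictor Phenotype driving causal sites.
#' @param sigma_g2,sigma_e2 Kinship and residual variance components
#'   (logit scale).
#' @param age_gamma Logit-scale effect of age (years).
#' @param conversion_efficiency Bisulfite conversion fraction in \[0, 1\].
#' @param n_lambda_sites CG sites on the unmethylated control chromosome.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 9,
                       tissues = data.frame(
                         label = c("Blood", "Testes", "Sperm"),
                         shift = c(-0.2, 0, 0.4),
                         n = c(8, 9, 5)),
                       n_sites = 500,
                       n_scaffolds = 2,
                       depth_mean = 25,
                       baseline_mf_cg = 0.5,
                       mf_chh_chg = 0.003,
                       site_sd = 1.0,
                       frac_causal = 0.05,
                       beta_causal = 1.0,
                       causal_predictor = "avg_litter_size",
                       sigma_g2 = 0.25,
                       sigma_e2 = 0.25,
                       age_gamma = 0.05,
                       conversion_efficiency = 0.994,
                       n_lambda_sites = 200,
                       seed = 1) {
  cfg <- list(n_individuals = n_individuals, tissues = tissues,
              n_sites = n_sites, n_scaffolds = n_scaffolds,
              depth_mean = depth_mean, baseline_mf_cg = baseline_mf_cg,
              mf_chh_chg = mf_chh_chg, site_sd = site_sd,
              frac_causal = frac_causal, beta_causal = beta_causal,
              causal_predictor = causal_predictor,
              sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              age_gamma = age_gamma,
              conversion_efficiency = conversion_efficiency,
              n_lambda_sites = n_lambda_sites, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c(cfg$baseline_mf_cg, cfg$mf_chh_chg, cfg$frac_causal,
             cfg$conversion_efficiency)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  counts <- c(cfg$n_individuals, cfg$n_sites, cfg$n_scaffolds,
              cfg$n_lambda_sites, cfg$tissues$n)
  if (any(counts < 1) || cfg$depth_mean <= 0) {
    stop("counts and depth must be positive")
  }
  if (any(cfg$sigma_g2 < 0, cfg$sigma_e2 < 0)) {
    stop("variance components must be non-negative")
  }
  invisible(cfg)
}

#' Simulate a breeding pedigree
#'
#' Founders (generation 0) are unrelated; each later generation adds
#' offspring whose sire and dam are sampled from earlier generations,
#' respecting sex. Individuals alternate sex by creation order so a mating
#' pair always exists.
#'
#' @param n_founders Number of founders (>= 2).
#' @param n_generations Generations after the founders (>= 0).
#' @param seed Integer seed.
#' @param offspring_per_generation Offspring added per generation; defaults
#'   to `n_founders`.
#' @return A pedigree `data.frame` with columns `id`, `sire`, `dam`,
#'   `sex`, `generation`; parents always precede offspring.
#' @export
simulate_pedigree <- function(n_founders, n_generations, seed = 1,
                              offspring_per_generation = n_founders) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (n_generations < 0) stop("n_generations must be >= 0")
  set.seed(seed)
  id <- paste0("I", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 0L, stringsAsFactors = FALSE)
  counter <- n_founders
  for (g in seq_len(n_generations)) {
    males <- ped$id[ped$sex == "M"]
    females <- ped$id[ped$sex == "F"]
    for (k in seq_len(offspring_per_generation)) {
      counter <- counter + 1L
      child <- paste0("I", counter)
      ped <- rbind(ped, data.frame(
        id = child,
        sire = sample(males, 1),
        dam = sample(females, 1),
        sex = if (counter %% 2L == 1L) "M" else "F",
        generation = g, stringsAsFactors = FALSE))
    }
  }
  rownames(ped) <- NULL
  ped
}

# truncated Poisson (>= 1) via inverse CDF on the conditional distribution
rtpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

#' Simulate an RRBS methylation dataset
#'
#' Draws phenotypes, per-site effects and read counts under the generative
#' model described in [sim_config()], producing per-sample methylomes in
#' CGmap layout, a phenotype table, and a truth table for recovery tests.
#' The lambda control chromosome carries truly unmethylated CG sites whose
#' apparent methylation reflects only conversion failure.
#'
#' @param config A [sim_config()].
#' @param pedigree A pedigree `data.frame` (e.g. [simulate_pedigree()]) with
#'   at least `config$n_individuals` rows.
#' @return A list of class `sim_dataset`: `methylomes` (named list of CGmap
#'   data.frames), `phenotypes` (sample table), `pedigree`, `truth`
#'   (`chrom`, `pos`, `context`, `is_causal`, `beta_true`, `baseline_logit`),
#'   and `kinship` (A restricted to simulated individuals).
#' @export
simulate_dataset <- function(config, pedigree) {
  validate_sim_config(config)
  if (nrow(pedigree) < config$n_individuals) {
    stop("pedigree smaller than n_individuals")
  }
  if (config$n_sites < 1 || sum(config$tissues$n) < 1) {
    stop("need at least one site and one sample")
  }
  set.seed(config$seed)
  A_full <- additive_relationship(pedigree)
  ids <- utils::tail(rownames(A_full), config$n_individuals)
  A <- A_full[ids, ids, drop = FALSE]
  n_ind <- length(ids)

  # individual-level phenotypes: zero-inflated litter size (0-5 kits),
  # log-normal sperm count (millions/mL), integer age in years
  litter <- ifelse(stats::runif(n_ind) < 0.3, 0,
                   round(stats::runif(n_ind, 0.5, 5), 1))
  sperm_count <- round(stats::rlnorm(n_ind, log(400), 0.8), 1)
  age <- sample(2:6, n_ind, replace = TRUE)
  names(litter) <- names(sperm_count) <- names(age) <- ids

  # sample sheet: first n_t individuals per tissue (recycled if needed)
  samples <- do.call(rbind, lapply(seq_len(nrow(config$tissues)), function(t) {
    lab <- config$tissues$label[t]
    nt <- config$tissues$n[t]
    ind <- rep(ids, length.out = nt)
    data.frame(
      sample_id = paste0(substr(lab, 1, 1), seq_len(nt), "_1"),
      studbook_no = ind,
      name = ind,
      tissue = lab,
      shift = config$tissues$shift[t],
      stringsAsFactors = FALSE)
  }))
  samples$collection_date <- format(as.Date("2018-01-01") +
                                      seq_len(nrow(samples)), "%m_%d_%Y")
  samples$age_at_sampling <- age[samples$studbook_no]
  samples$avg_litter_size <- litter[samples$studbook_no]
  samples$testes_status <- ifelse(stats::runif(nrow(samples)) < 2 / 3,
                                  "Firm", "Not_Firm")
  samples$sperm_count_per_ml <- ifelse(samples$tissue == "Sperm",
                                       sperm_count[samples$studbook_no],
                                       NA_real_)
  samples$replicate_flag <- FALSE
  n_samp <- nrow(samples)

  # genomic CG sites
  scafs <- paste0("scaf", seq_len(config$n_scaffolds))
  cg_sites <- do.call(rbind, lapply(scafs, function(sc) {
    pos <- sort(sample.int(config$n_sites * 100L, config$n_sites))
    data.frame(chrom = sc, pos = pos, context = "CG",
               stringsAsFactors = FALSE)
  }))
  n_cg <- nrow(cg_sites)
  is_causal <- stats::runif(n_cg) < config$frac_causal
  beta_true <- ifelse(is_causal, config$beta_causal, 0)
  base_logit <- stats::rnorm(n_cg, stats::qlogis(config$baseline_mf_cg),
                             config$site_sd)

  x <- predictor_vector(samples, config$causal_predictor)
  x[is.na(x)] <- 0
  # per-site genetic effects over individuals: G = Z L^T, cov sigma_g2 * A
  L <- chol(config$sigma_g2 * A + diag(1e-10, n_ind))
  G <- matrix(stats::rnorm(n_cg * n_ind), n_cg, n_ind) %*% L
  colnames(G) <- ids
  E <- matrix(stats::rnorm(n_cg * n_samp, sd = sqrt(config$sigma_e2)),
              n_cg, n_samp)
  # age enters centered so baseline_mf_cg stays the grand-mean anchor
  age_c <- samples$age_at_sampling - mean(samples$age_at_sampling)
  eta <- outer(base_logit, rep(1, n_samp)) +
    outer(beta_true, x) +
    matrix(rep(age_c * config$age_gamma + samples$shift, each = n_cg),
           n_cg, n_samp) +
    G[, samples$studbook_no, drop = FALSE] + E
  pi_cg <- stats::plogis(eta)

  # non-CG background: half as many CHG and CHH sites per scaffold
  n_h <- floor(config$n_sites / 2)
  noncg_sites <- do.call(rbind, lapply(scafs, function(sc) {
    pos <- sort(sample.int(config$n_sites * 100L, 2L * n_h))
    data.frame(chrom = sc, pos = pos,
               context = rep(c("CHG", "CHH"), n_h),
               stringsAsFactors = FALSE)
  }))
  pi_noncg <- matrix(config$mf_chh_chg, nrow(noncg_sites), n_samp)

  # lambda spike-in: truly unmethylated CG sites
  lam_sites <- data.frame(
    chrom = "lambda",
    pos = sort(sample.int(config$n_lambda_sites * 50L,
                          config$n_lambda_sites)),
    context = "CG", stringsAsFactors = FALSE)
  pi_lam <- matrix(0, config$n_lambda_sites, n_samp)

  sites <- rbind(cg_sites, noncg_sites, lam_sites)
  pi_all <- rbind(pi_cg, pi_noncg, pi_lam)
  n_tot <- nrow(sites)
  total <- matrix(rtpois(n_tot * n_samp, config$depth_mean), n_tot, n_samp)
  true_m <- matrix(stats::rbinom(n_tot * n_samp, total, pi_all),
                   n_tot, n_samp)
  fail <- 1 - config$conversion_efficiency
  obs_m <- true_m + matrix(stats::rbinom(n_tot * n_samp, total - true_m,
                                         fail), n_tot, n_samp)
  base_nt <- sample(c("C", "G"), n_tot, replace = TRUE)
  dinuc <- ifelse(sites$context == "CG", "CG", "CA")

  methylomes <- lapply(seq_len(n_samp), function(j) {
    df <- data.frame(chrom = sites$chrom, base = base_nt, pos = sites$pos,
                     context = sites$context, dinuc = dinuc,
                     level = round(obs_m[, j] / total[, j], 6),
                     m_count = obs_m[, j], total = total[, j],
                     stringsAsFactors = FALSE)
    ord <- order(df$chrom, df$pos, method = "radix")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "sample_id") <- samples$sample_id[j]
    df
  })
  names(methylomes) <- samples$sample_id

  truth <- data.frame(chrom = cg_sites$chrom, pos = cg_sites$pos,
                      context = "CG", is_causal = is_causal,
                      beta_true = beta_true, baseline_logit = base_logit,
                      stringsAsFactors = FALSE)
  phenotypes <- samples[, c("sample_id", "studbook_no", "name", "tissue",
                            "collection_date", "age_at_sampling",
                            "avg_litter_size", "testes_status",
                            "sperm_count_per_ml", "replicate_flag")]
  structure(list(methylomes = methylomes, phenotypes = phenotypes,
                 pedigree = pedigree, truth = truth, kinship = A),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' One CGmap file per sample plus phenotype, pedigree and truth TSVs.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @return A named list of written paths (`cgmap` vector, `phenotypes`,
#'   `pedigree`, `truth`).
#' @export
write_dataset <- function(dataset, directory) {
  if (!inherits(dataset, "sim_dataset") || length(dataset$methylomes) == 0L) {
    stop("empty or invalid dataset")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cgmap_paths <- vapply(names(dataset$methylomes), function(sid) {
    p <- file.path(directory, paste0(sid, ".CGmap"))
    write_cgmap(dataset$methylomes[[sid]], p)
    p
  }, character(1))
  pheno_path <- file.path(directory, "phenotypes.tsv")
  out_pheno <- dataset$phenotypes
  out_pheno$sperm_count_per_ml[is.na(out_pheno$sperm_count_per_ml)] <- "n/a"
  data.table::fwrite(out_pheno, pheno_path, sep = "\t", quote = FALSE)
  ped_path <- file.path(directory, "pedigree.tsv")
  data.table::fwrite(dataset$pedigree[, c("id", "sire", "dam")], ped_path,
                     sep = "\t", quote = FALSE, na = "NA")
  truth_path <- file.path(directory, "truth.tsv")
  data.table::fwrite(dataset$truth, truth_path, sep = "\t", quote = FALSE)
  list(cgmap = cgmap_paths, phenotypes = pheno_path, pedigree = ped_path,
       truth = truth_path)
}
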