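#' PCA of a methylation frequency matrix
#'
#' Principal component analysis of per-sample methylation frequencies
#' (samples as observations, sites as variables), centered per site and by
#' default unscaled. Sites with zero variance across samples are dropped
#' first (they contribute nothing and break scaling), with a logged count.
#'
#' @param mf_matrix Numeric sites x samples matrix from
#'   [methylation_frequency()], or a `CountMatrix`.
#' @param scale. Scale sites to unit variance; default `FALSE`.
#' @return A list: `scores` (samples x components), `var_explained`
#'   (fractions, non-increasing), `sdev`, `n_sites_used`,
#'   `n_zero_variance`.
#' @export
pca_methylation <- function(mf_matrix, scale. = FALSE) {
  if (inherits(mf_matrix, "CountMatrix")) {
    mf_matrix <- methylation_frequency(mf_matrix)
  }
  if (ncol(mf_matrix) < 2L) stop("PCA needs at least 2 samples")
  if (anyNA(mf_matrix)) stop("MF matrix has missing cells; unite first")
  X <- t(mf_matrix)  # samples x sites
  v <- apply(X, 2, stats::var)
  zero_var <- sum(v == 0)
  if (zero_var) {
    message(zero_var, " zero-variance site(s) dropped before PCA")
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) {
    # all-constant matrix: no variance anywhere
    return(list(scores = matrix(0, ncol(mf_matrix), 0),
                var_explained = numeric(0), sdev = numeric(0),
                n_sites_used = 0L, n_zero_variance = zero_var))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev,
       n_sites_used = ncol(X), n_zero_variance = zero_var)
}

#' Test association between a principal component and a covariate
#'
#' Categorical covariates use the Kruskal-Wallis rank test with the
#' chi-square approximation on (levels - 1) degrees of freedom (optionally
#' an exact permutation p for small n); continuous covariates use Pearson's
#' correlation with a two-sided t test on (n - 2) degrees of freedom.
#'
#' @param scores Numeric vector of one component's sample scores.
#' @param covariate Vector aligned with `scores`.
#' @param type `"categorical"` or `"continuous"`.
#' @param exact For categorical: compute an exact permutation p as well
#'   (feasible only for small n); default `FALSE`.
#' @param n_perm Permutations when `exact = TRUE` and complete enumeration
#'   is too large.
#' @return A list: `statistic` (H or t), `df`, `p`, `method`, `estimate`
#'   (Pearson r, continuous only), `p_exact` (if requested), `degenerate`
#'   flag for |r| = 1 cases where p underflows.
#' @export
pc_covariate_association <- function(scores, covariate, type, exact = FALSE,
                                     n_perm = 10000) {
  stopifnot(length(scores) == length(covariate))
  if (length(unique(covariate)) < 2L) stop("constant covariate")
  if (type == "categorical") {
    g <- factor(covariate)
    kw <- stats::kruskal.test(scores, g)
    out <- list(statistic = unname(kw$statistic),
                df = unname(kw$parameter),
                p = kw$p.value, method = "kruskal-wallis")
    if (exact) {
      obs <- unname(kw$statistic)
      set.seed(length(scores))
      perm <- replicate(n_perm, {
        unname(stats::kruskal.test(sample(scores), g)$statistic)
      })
      out$p_exact <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
    }
    out
  } else if (type == "continuous") {
    ct <- stats::cor.test(scores, covariate, method = "pearson")
    degenerate <- abs(unname(ct$estimate)) >= 1 - 1e-12
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = if (degenerate) .Machine$double.xmin else ct$p.value,
         estimate = unname(ct$estimate), method = "pearson",
         degenerate = degenerate)
  } else {
    stop("type must be 'categorical' or 'continuous'")
  }
}

#' Resolve sequencing replicate pairs
#'
#' Keeps one sample per replicate pair -- the one with higher bisulfite
#' conversion efficiency (ties broken by lexicographically first sample ID,
#' logged) -- and reports the Pearson concordance of methylation frequency
#' across shared sites for each pair.
#'
#' @param replicate_pairs List of length-2 character vectors of sample IDs.
#' @param efficiencies Named numeric conversion efficiencies.
#' @param mf_matrix Sites x samples MF matrix containing all pair members.
#' @return A list: `retained` (IDs to keep over all matrix samples),
#'   `dropped`, `concordance` (named Pearson r per pair), `log`.
#' @export
resolve_replicates <- function(replicate_pairs, efficiencies, mf_matrix) {
  all_samples <- colnames(mf_matrix)
  retained <- all_samples
  dropped <- character()
  conc <- numeric()
  log <- character()
  for (pair in replicate_pairs) {
    stopifnot(length(pair) == 2L)
    if (!all(pair %in% all_samples)) {
      stop("replicate pair member missing from matrix: ",
           paste(setdiff(pair, all_samples), collapse = ", "))
    }
    if (!all(pair %in% names(efficiencies))) {
      stop("missing conversion efficiency for ",
           paste(setdiff(pair, names(efficiencies)), collapse = ", "))
    }
    eff <- efficiencies[pair]
    keep <- pair[order(-eff, pair)][1]
    drop <- setdiff(pair, keep)
    if (eff[1] == eff[2]) {
      log <- c(log, sprintf("tie at %.4f: retained %s by sample ID", eff[1],
                            keep))
    } else {
      log <- c(log, sprintf("retained %s (%.4f > %.4f)", keep, max(eff),
                            min(eff)))
    }
    r <- stats::cor(mf_matrix[, pair[1]], mf_matrix[, pair[2]])
    conc[paste(pair, collapse = "/")] <- r
    retained <- setdiff(retained, drop)
    dropped <- c(dropped, drop)
  }
  list(retained = retained, dropped = dropped, concordance = conc,
       log = log)
}

#' Write a QC report as JSON
#'
#' @param qc Named list of QC results (PC-covariate tests, replicate
#'   resolution, conversion efficiencies, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
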