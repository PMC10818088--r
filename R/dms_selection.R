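#' Call significant DMS by the dual-percentile outlier rule
#'
#' Differentially methylated sites (DMS) are the joint extremes of the
#' per-analysis effect and significance distributions: sites whose effect
#' beta lies in the 1st or 99th percentile tails AND whose p-value lies in
#' the lowest 1st percentile. Thresholds are linear-interpolation quantiles
#' (R type 7) over the non-skipped sites of one analysis; ties at a
#' threshold are included.
#'
#' @param association Association table from [fit_all_sites()] (the
#'   `results` data.frame or the full list).
#' @param beta_q Lower/upper beta quantiles; default `c(0.01, 0.99)`.
#' @param p_q P-value quantile; default 0.01.
#' @param rank_cutoff If `TRUE`, use a strict rank cutoff (smallest
#'   `floor(q * m)` p-values) instead of the quantile threshold for p.
#' @param label Analysis label carried into exports.
#' @return A `DmsSet`: list with `sites` (selected rows of the association
#'   table), `thresholds` (`beta_lo`, `beta_hi`, `p_cut`), `label`, and
#'   `n_considered`.
#' @export
select_outliers <- function(association, beta_q = c(0.01, 0.99),
                            p_q = 0.01, rank_cutoff = FALSE,
                            label = "analysis") {
  res <- if (is.data.frame(association)) association else association$results
  ok <- res[res$skip_reason %in% c("none", "non-converged") &
              !is.na(res$beta) & !is.na(res$p), , drop = FALSE]
  if (nrow(ok) < 2L) stop("fewer than two usable sites; quantiles undefined")
  beta_lo <- stats::quantile(ok$beta, beta_q[1], type = 7, names = FALSE)
  beta_hi <- stats::quantile(ok$beta, beta_q[2], type = 7, names = FALSE)
  if (rank_cutoff) {
    k <- max(1L, floor(p_q * nrow(ok)))
    p_cut <- sort(ok$p)[k]
  } else {
    p_cut <- stats::quantile(ok$p, p_q, type = 7, names = FALSE)
  }
  sel <- (ok$beta <= beta_lo | ok$beta >= beta_hi) & ok$p <= p_cut
  sites <- ok[sel, , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos, method = "radix"), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 thresholds = c(beta_lo = beta_lo, beta_hi = beta_hi,
                                p_cut = p_cut),
                 label = label, n_considered = nrow(ok)),
            class = "DmsSet")
}

#' @export
print.DmsSet <- function(x, ...) {
  cat(sprintf("DmsSet '%s': %d DMS of %d sites (beta <= %.4g | >= %.4g, p <= %.3g)\n",
              x$label, nrow(x$sites), x$n_considered,
              x$thresholds["beta_lo"], x$thresholds["beta_hi"],
              x$thresholds["p_cut"]))
  invisible(x)
}

#' Aggregate DMS into distance-based clusters
#'
#' A single linear scan per scaffold: consecutive DMS are joined into one
#' DMcluster while the inter-cytosine distance stays strictly below
#' `max_gap` base pairs; a gap of exactly `max_gap` (or a scaffold change)
#' starts a new cluster. Clusters with at least `min_sites` members form
#' the network-input subset.
#'
#' @param dms A `DmsSet` (or a data.frame with `chrom` and `pos`).
#' @param max_gap Strict distance threshold in bp; default 40.
#' @param min_sites Minimum cluster size for the network subset; default 3.
#' @return A list with `clusters` (data.frame: `cluster_id`, `chrom`,
#'   `start`, `end`, `size`, 1-based inclusive span), `members` (per-DMS
#'   cluster assignment), `sites` (the sorted member table), and
#'   `network_input` (clusters with `size >= min_sites`).
#' @export
call_dmclusters <- function(dms, max_gap = 40, min_sites = 3) {
  sites <- if (inherits(dms, "DmsSet")) dms$sites else dms
  if (nrow(sites) == 0L) {
    empty <- data.frame(cluster_id = integer(), chrom = character(),
                        start = integer(), end = integer(), size = integer(),
                        stringsAsFactors = FALSE)
    return(list(clusters = empty, members = integer(0), sites = sites,
                network_input = empty))
  }
  ord <- order(sites$chrom, sites$pos, method = "radix")
  if (any(ord != seq_len(nrow(sites)))) {
    warning("DMS not sorted by (chrom, pos); sorting internally")
    sites <- sites[ord, , drop = FALSE]
  }
  new_cluster <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)] |
                     diff(sites$pos) >= max_gap)
  cid <- cumsum(new_cluster)
  grp <- split(seq_len(nrow(sites)), factor(cid, levels = unique(cid)))
  clusters <- data.frame(
    cluster_id = seq_along(grp),
    chrom = vapply(grp, function(i) sites$chrom[i[1]], character(1)),
    start = as.integer(vapply(grp, function(i) min(sites$pos[i]), numeric(1))),
    end = as.integer(vapply(grp, function(i) max(sites$pos[i]), numeric(1))),
    size = lengths(grp),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  list(clusters = clusters, members = cid, sites = sites,
       network_input = clusters[clusters$size >= min_sites, , drop = FALSE])
}

#' Venn partition of 2-3 labelled sets
#'
#' Counts every region of the 2- or 3-set Venn partition over arbitrary
#' element sets (DMS site keys, GO term IDs, gene IDs).
#'
#' @param labeled_sets Named list of 2 or 3 character vectors.
#' @return A list with `regions` (named counts; names are `+`-joined label
#'   combinations marking membership), `union_size`, and `intersection`
#'   (elements common to all sets).
#' @export
overlap_sets <- function(labeled_sets) {
  stopifnot(length(labeled_sets) %in% c(2L, 3L))
  labs <- names(labeled_sets)
  if (is.null(labs)) labs <- paste0("set", seq_along(labeled_sets))
  sets <- lapply(labeled_sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) {
    paste(labs[row], collapse = "+")
  })
  combos <- unlist(lapply(seq_along(labs), function(k) {
    utils::combn(labs, k, paste, collapse = "+")
  }))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions,
       union_size = length(universe),
       intersection = universe[rowSums(membership) == length(sets)])
}

#' Export DMS as BED
#'
#' 0-based half-open intervals, name = analysis label, score = -log10 p
#' (capped at 1000 per BED convention).
#'
#' @param dms A `DmsSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dms_bed <- function(dms, path) {
  s <- dms$sites
  bed <- data.frame(chrom = s$chrom, start = s$pos - 1L, end = s$pos,
                    name = rep(dms$label, nrow(s)),
                    score = round(pmin(-log10(s$p), 1000), 3),
                    stringsAsFactors = FALSE)
  if (nrow(bed) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export DMclusters as BED
#'
#' @param clusters Cluster table from [call_dmclusters()].
#' @param path Output path.
#' @param label Analysis label prefix for the name field.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path, label = "cluster") {
  cl <- if (is.data.frame(clusters)) clusters else clusters$clusters
  bed <- data.frame(chrom = cl$chrom, start = cl$start - 1L, end = cl$end,
                    name = if (nrow(cl)) paste0(label, "_n", cl$size)
                    else character(0),
                    stringsAsFactors = FALSE)
  if (nrow(bed) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
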