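CGMAP_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a CGmap methylation call file
#'
#' CGmap is the tab-separated per-cytosine output dialect of bisulfite
#' aligners: chromosome, nucleotide on the Watson strand (C or G), 1-based
#' position, context (CG/CHG/CHH), dinucleotide, methylation level,
#' methylated read count, total read count.
#'
#' @param path Path to a CGmap file (uncompressed TSV, no header).
#' @param sample_id Sample identifier attached to the result; defaults to the
#'   file name without extension.
#' @return A `data.frame` with columns `chrom`, `base`, `pos`, `context`,
#'   `dinuc`, `level`, `m_count`, `total` and attribute `sample_id`. Rows are
#'   validated: counts must satisfy `0 <= m_count <= total`, contexts must be
#'   CG/CHG/CHH, and `level` must equal `m_count/total` within 1e-6.
#' @export
read_cgmap <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("CGmap file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (file.size(path) == 0) {
    warning("empty CGmap file: ", path)
    return(empty_methylome(sample_id))
  }
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t",
    col.names = c("chrom", "base", "pos", "context", "dinuc", "level",
                  "m_count", "total"),
    colClasses = list(character = c(1, 2, 4, 5), numeric = 6,
                      integer = c(3, 7, 8)),
    data.table = FALSE
  )
  if (nrow(dt) == 0L) {
    warning("empty CGmap file: ", path)
    return(empty_methylome(sample_id))
  }
  bad_ctx <- which(!dt$context %in% CGMAP_CONTEXTS)
  if (length(bad_ctx)) {
    stop(sprintf("unknown context token '%s' at line %d of %s",
                 dt$context[bad_ctx[1]], bad_ctx[1], path))
  }
  bad_cnt <- which(dt$m_count > dt$total | dt$m_count < 0L | dt$total < 0L)
  if (length(bad_cnt)) {
    stop(sprintf("methylated count exceeds total (or negative) at line %d of %s",
                 bad_cnt[1], path))
  }
  with_reads <- dt$total > 0L
  bad_lvl <- which(with_reads &
                     abs(dt$level - dt$m_count / dt$total) > 1e-6)
  if (length(bad_lvl)) {
    stop(sprintf("methylation level inconsistent with counts at line %d of %s",
                 bad_lvl[1], path))
  }
  attr(dt, "sample_id") <- sample_id
  dt
}

empty_methylome <- function(sample_id = NA_character_) {
  dt <- data.frame(chrom = character(), base = character(), pos = integer(),
                   context = character(), dinuc = character(),
                   level = numeric(), m_count = integer(), total = integer(),
                   stringsAsFactors = FALSE)
  attr(dt, "sample_id") <- sample_id
  dt
}

#' Write a methylome to CGmap format
#'
#' Inverse of [read_cgmap()]: `read_cgmap(write_cgmap(x, f))` reproduces the
#' record table exactly.
#'
#' @param methylome A methylome `data.frame` as returned by [read_cgmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(methylome, path) {
  out <- methylome
  # canonical CGmap prints the level with up to 6 digits; regenerate from
  # counts so the round trip is exact
  out$level <- ifelse(out$total > 0, round(out$m_count / out$total, 6), 0)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Filter cytosines by minimum coverage
#'
#' Retains records whose total read count is at least `min_coverage`
#' (inclusive threshold, the usual methylKit semantics).
#'
#' @param methylome A methylome `data.frame`.
#' @param min_coverage Minimum total reads per site; default 10.
#' @return The filtered methylome.
#' @export
filter_coverage <- function(methylome, min_coverage = 10) {
  stopifnot(min_coverage >= 1)
  keep <- methylome$total >= min_coverage
  out <- methylome[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(methylome, "sample_id")
  out
}

site_key <- function(df) paste(df$chrom, df$pos, df$context, sep = ":")

#' Unite methylomes into a count matrix
#'
#' Intersects the site sets of all methylomes so that every retained cytosine
#' has adequate coverage in every sample, and assembles per-sample methylated
#' and total count matrices. Apply [filter_coverage()] per sample first.
#'
#' @param methylomes A list of methylome `data.frame`s; names (or their
#'   `sample_id` attributes) become sample IDs.
#' @return A `CountMatrix`: a list with `sites` (data.frame `chrom`, `pos`,
#'   `context`, ordered by chromosome then position), `m` and `total`
#'   (sites x samples integer matrices) and `samples`.
#' @export
unite <- function(methylomes) {
  stopifnot(length(methylomes) >= 1)
  ids <- names(methylomes)
  if (is.null(ids)) {
    ids <- vapply(methylomes, function(m) {
      id <- attr(m, "sample_id")
      if (is.null(id)) NA_character_ else id
    }, character(1))
  }
  if (anyNA(ids)) stop("every methylome needs a sample ID")
  if (anyDuplicated(ids)) stop("duplicated sample ID: ",
                               ids[duplicated(ids)][1])
  keys <- lapply(methylomes, site_key)
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    warning("no sites shared across all samples; empty count matrix")
  }
  first <- methylomes[[1]]
  idx1 <- match(common, keys[[1]])
  sites <- data.frame(chrom = first$chrom[idx1], pos = first$pos[idx1],
                      context = first$context[idx1], stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  common <- common[ord]
  m <- matrix(0L, nrow = length(common), ncol = length(ids),
              dimnames = list(NULL, ids))
  tot <- m
  for (j in seq_along(methylomes)) {
    idx <- match(common, keys[[j]])
    m[, j] <- methylomes[[j]]$m_count[idx]
    tot[, j] <- methylomes[[j]]$total[idx]
  }
  structure(list(sites = sites, m = m, total = tot, samples = ids),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  if (nrow(x$sites)) {
    cat("scaffolds:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a CountMatrix
#'
#' @param x A `CountMatrix`.
#' @param sites Integer/logical index over sites (optional).
#' @param samples Character or integer index over samples (optional).
#' @return The subset `CountMatrix`.
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!is.null(sites)) {
    x$sites <- x$sites[sites, , drop = FALSE]
    rownames(x$sites) <- NULL
    x$m <- x$m[sites, , drop = FALSE]
    x$total <- x$total[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    x$m <- x$m[, samples, drop = FALSE]
    x$total <- x$total[, samples, drop = FALSE]
    x$samples <- colnames(x$m)
  }
  x
}

#' Methylation frequency matrix
#'
#' Per-cell proportion of methylated reads out of total reads.
#'
#' @param matrix A `CountMatrix` (post-unite, so all totals are positive).
#' @return A numeric sites x samples matrix of fractions in \[0, 1\].
#' @export
methylation_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (any(matrix$total == 0L)) {
    stop("methylation frequency undefined at zero-coverage cells")
  }
  matrix$m / matrix$total
}

#' Bisulfite conversion efficiency from a spike-in control
#'
#' One minus the average apparent methylation frequency across the
#' unmethylated control chromosome (typically the lambda phage spike-in).
#' Any apparent methylation there reflects failed conversion.
#'
#' @param methylome A methylome `data.frame`.
#' @param control_chrom Scaffold ID of the unmethylated control; default
#'   `"lambda"`.
#' @param weighted If `TRUE`, weight per-site frequencies by read depth;
#'   default `FALSE` (unweighted mean over sites).
#' @return Conversion efficiency as a fraction in \[0, 1\].
#' @export
conversion_efficiency <- function(methylome, control_chrom = "lambda",
                                  weighted = FALSE) {
  ctrl <- methylome[methylome$chrom == control_chrom & methylome$total > 0, ,
                    drop = FALSE]
  if (nrow(ctrl) == 0L) {
    stop("no covered sites on control chromosome '", control_chrom,
         "'; spike-in absent?")
  }
  mf <- ctrl$m_count / ctrl$total
  if (weighted) {
    1 - sum(ctrl$m_count) / sum(ctrl$total)
  } else {
    1 - mean(mf)
  }
}

#' Per-context methylation summary
#'
#' Mean methylation frequency per sequence context (CG, CHG, CHH) and the
#' CG-only record subset used by all downstream CpG analyses; mammalian
#' methylation is overwhelmingly CG, so non-CG contexts are summarised and
#' set aside.
#'
#' @param methylome A methylome `data.frame`.
#' @return A list with `means` (named numeric over contexts present; absent
#'   contexts are `NA`), `n_sites` (named integer) and `cg` (the CG-only
#'   methylome).
#' @export
context_summary <- function(methylome) {
  covered <- methylome[methylome$total > 0, , drop = FALSE]
  mf <- covered$m_count / covered$total
  means <- vapply(CGMAP_CONTEXTS, function(ctx) {
    sel <- covered$context == ctx
    if (any(sel)) mean(mf[sel]) else NA_real_
  }, numeric(1))
  ns <- vapply(CGMAP_CONTEXTS, function(ctx) {
    sum(methylome$context == ctx)
  }, integer(1))
  cg <- methylome[methylome$context == "CG", , drop = FALSE]
  rownames(cg) <- NULL
  attr(cg, "sample_id") <- attr(methylome, "sample_id")
  list(means = means, n_sites = ns, cg = cg)
}

#' Export a methylation frequency matrix as TSV
#'
#' @param matrix A `CountMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mf_matrix <- function(matrix, path) {
  mf <- methylation_frequency(matrix)
  out <- cbind(matrix$sites, as.data.frame(mf))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
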