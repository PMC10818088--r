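TISSUE_LEVELS <- c("Blood", "Testes", "Sperm")

#' Read a sample/phenotype table
#'
#' Parses the study metadata table: one row per banked sample with the
#' individual's studbook number, tissue type, collection date, age at
#' sampling (years), lifetime average litter size (kits per litter), testes
#' status at collection (Firm/Not_Firm) and, for sperm samples only, the
#' electroejaculation sperm count per mL (in millions). `n/a` marks fields
#' that do not apply to a tissue.
#'
#' @param path TSV path with header columns `sample_id`, `studbook_no`,
#'   `name`, `tissue`, `collection_date`, `age_at_sampling`,
#'   `avg_litter_size`, `testes_status`, `sperm_count_per_ml`, and optional
#'   `replicate_flag`.
#' @return A validated `data.frame` of sample records; `sperm_count_per_ml`
#'   is `NA` outside sperm rows, `testes_status` may be `NA` where not
#'   recorded.
#' @export
read_samples_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("n/a", "NA", ""))
  required <- c("sample_id", "studbook_no", "tissue", "collection_date",
                "age_at_sampling", "avg_litter_size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_tissue <- which(!df$tissue %in% TISSUE_LEVELS)
  if (length(bad_tissue)) {
    stop("unknown tissue label '", df$tissue[bad_tissue[1]], "' in row ",
         bad_tissue[1])
  }
  if (any(df$avg_litter_size < 0, na.rm = TRUE)) {
    stop("avg_litter_size must be non-negative")
  }
  if (!is.null(df$sperm_count_per_ml)) {
    bad_sc <- which(!is.na(df$sperm_count_per_ml) & df$tissue != "Sperm")
    if (length(bad_sc)) {
      stop("sperm count recorded on non-sperm row ", bad_sc[1])
    }
  } else {
    df$sperm_count_per_ml <- NA_real_
  }
  if (!is.null(df$testes_status)) {
    ok_status <- is.na(df$testes_status) |
      df$testes_status %in% c("Firm", "Not_Firm")
    if (!all(ok_status)) {
      stop("testes_status must be Firm or Not_Firm")
    }
  }
  if (is.null(df$replicate_flag)) df$replicate_flag <- FALSE
  df$replicate_flag <- !is.na(df$replicate_flag) &
    (df$replicate_flag %in% c(TRUE, "TRUE", "yes", "1"))
  # collection dates in the studbook are MM_DD_YYYY
  df$collection_date <- as.Date(df$collection_date, format = "%m_%d_%Y")
  df
}

#' Summarise a sample table
#'
#' Counts samples per tissue and individuals, tabulates how many distinct
#' tissue types each individual contributed, and resolves sequencing
#' replicate pairs by keeping the copy with higher bisulfite conversion
#' efficiency (ties broken by lexicographically first sample ID, logged).
#'
#' @param records Sample table from [read_samples_table()].
#' @param efficiencies Named numeric of conversion efficiencies per sample
#'   ID; required if any sample is flagged as a replicate.
#' @return A list with `n_per_tissue`, `n_samples`, `n_individuals`,
#'   `tissues_per_individual` (named integer), `firmness_counts` (testes
#'   rows only), `retained` (sample IDs after replicate resolution) and
#'   `replicate_log`.
#' @export
summarize_samples <- function(records, efficiencies = NULL) {
  n_per_tissue <- vapply(TISSUE_LEVELS, function(t) sum(records$tissue == t),
                         integer(1))
  tissues_per_individual <- vapply(
    split(records$tissue, records$studbook_no),
    function(x) length(unique(x)), integer(1))
  testes <- records[records$tissue == "Testes", , drop = FALSE]
  firmness_counts <- c(Firm = sum(testes$testes_status == "Firm", na.rm = TRUE),
                       Not_Firm = sum(testes$testes_status == "Not_Firm",
                                      na.rm = TRUE))
  retained <- records$sample_id
  replicate_log <- character()
  flagged <- records$sample_id[records$replicate_flag]
  if (length(flagged)) {
    # replicate pairs share individual and tissue
    key <- paste(records$studbook_no, records$tissue)
    for (k in unique(key[records$replicate_flag])) {
      pair <- records$sample_id[key == k]
      if (length(pair) < 2L) next
      if (is.null(efficiencies) || !all(pair %in% names(efficiencies))) {
        stop("replicate pair ", paste(pair, collapse = "/"),
             " lacks conversion efficiencies")
      }
      eff <- efficiencies[pair]
      best <- pair[order(-eff, pair)][1]
      if (sum(eff == max(eff)) > 1L) {
        replicate_log <- c(replicate_log,
                           sprintf("tie at %.4f: retained %s", max(eff), best))
      } else {
        replicate_log <- c(replicate_log,
                           sprintf("retained %s (efficiency %.4f)", best,
                                   max(eff)))
      }
      retained <- setdiff(retained, setdiff(pair, best))
    }
  }
  list(n_per_tissue = n_per_tissue,
       n_samples = nrow(records),
       n_individuals = length(unique(records$studbook_no)),
       tissues_per_individual = tissues_per_individual,
       firmness_counts = firmness_counts,
       retained = retained,
       replicate_log = replicate_log)
}

#' Lifetime reproductive arithmetic
#'
#' From printed aggregates (or raw per-male records) of lifetime offspring
#' and litter size, derives the implied lifetime number of litters as
#' mean offspring / mean litter size.
#'
#' @param mean_offspring Mean lifetime offspring per proven sire, or a
#'   numeric vector of per-male lifetime offspring counts.
#' @param mean_litter_size Mean litter size (kits per litter), or a vector of
#'   per-litter sizes.
#' @param median_offspring Optional median lifetime offspring (reported
#'   through unchanged when aggregates are supplied).
#' @return A list with `mean_offspring`, `median_offspring`,
#'   `mean_litter_size` and `litters_ratio` (rounded to 2 decimals).
#' @export
reproductive_summary <- function(mean_offspring, mean_litter_size,
                                 median_offspring = NA_real_) {
  mo <- mean(mean_offspring)
  ml <- mean(mean_litter_size)
  if (length(mean_offspring) > 1L && is.na(median_offspring)) {
    median_offspring <- stats::median(mean_offspring)
  }
  if (ml == 0) stop("mean litter size is zero; ratio undefined")
  list(mean_offspring = mo,
       median_offspring = median_offspring,
       mean_litter_size = ml,
       litters_ratio = round(mo / ml, 2))
}

#' Read a pedigree table
#'
#' @param path TSV with columns `id`, `sire`, `dam`; `NA` marks founders.
#' @return A pedigree `data.frame` with character IDs.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped
}

order_pedigree <- function(pedigree) {
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicate individual ID in pedigree")
  unknown <- setdiff(c(stats::na.omit(pedigree$sire),
                       stats::na.omit(pedigree$dam)), ids)
  if (length(unknown)) stop("unknown parent ID: ", unknown[1])
  # Kahn topological sort; a leftover means a cycle
  placed <- character()
  remaining <- pedigree
  out <- pedigree[0, ]
  while (nrow(remaining)) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
      (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle")
    out <- rbind(out, remaining[ready, , drop = FALSE])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Additive relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix A by the tabular method:
#' founders have \eqn{a_{ii} = 1}; for a non-founder j with parents s and d,
#' \eqn{a_{ij} = (a_{is} + a_{id})/2} for earlier i, and
#' \eqn{a_{jj} = 1 + a_{sd}/2}, so the diagonal is \eqn{1 + F} with F the
#' inbreeding coefficient. A (not A/2) is used directly as the random-effect
#' covariance downstream; its scale is absorbed by the genetic variance
#' component.
#'
#' @param pedigree A `data.frame` with columns `id`, `sire`, `dam` (`NA` for
#'   unknown/founder parents). Any row order; a topological order is
#'   established internally.
#' @return A symmetric matrix with individual IDs as dimnames, positive
#'   semi-definite, diagonal >= 1.
#' @export
additive_relationship <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- ped$sire[j]
    d <- ped$dam[j]
    si <- if (is.na(s)) 0L else match(s, ped$id)
    di <- if (is.na(d)) 0L else match(d, ped$id)
    if (j > 1L) {
      for (i in seq_len(j - 1L)) {
        as_ <- if (si > 0L) A[i, si] else 0
        ad_ <- if (di > 0L) A[i, di] else 0
        A[i, j] <- (as_ + ad_) / 2
        A[j, i] <- A[i, j]
      }
    }
    A[j, j] <- 1 + (if (si > 0L && di > 0L) A[si, di] / 2 else 0)
  }
  A[pedigree$id, pedigree$id]
}

#' Write a kinship matrix as square TSV
#'
#' @param A Relationship matrix with ID dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(A, path) {
  out <- data.frame(id = rownames(A), A, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Numeric coding of phenotype predictors
#'
#' Maps a predictor name to the numeric vector used by the association
#' model: `avg_litter_size` and `sperm_count_per_ml` are taken as-is;
#' `testes_firmness` is coded Firm = 1, Not_Firm = 0.
#'
#' @param records Sample table rows (already restricted to one tissue).
#' @param predictor One of `"avg_litter_size"`, `"sperm_count_per_ml"`,
#'   `"testes_firmness"`.
#' @return Numeric vector aligned with `records` rows.
#' @export
predictor_vector <- function(records, predictor) {
  switch(predictor,
    avg_litter_size = records$avg_litter_size,
    sperm_count_per_ml = records$sperm_count_per_ml,
    testes_firmness = ifelse(records$testes_status == "Firm", 1, 0),
    stop("unknown predictor: ", predictor)
  )
}
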