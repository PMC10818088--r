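#' Build a feature index from a gene annotation
#'
#' Reads GFF3 (gene/mRNA/exon features) or BED12 and assembles the interval
#' sets needed for promoter / exon / intron / intergenic labelling: gene
#' spans, exons (unioned over a gene's transcripts), and promoter windows of
#' `promoter_width` bp immediately upstream of each transcription start
#' site on the transcript's strand (clipped at the scaffold start).
#' A symmetric window (upstream and downstream of the TSS) is available via
#' `symmetric`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED12 (`.bed`) annotation file.
#' @param promoter_width Window size in bp; default 2000.
#' @param symmetric If `TRUE`, the promoter covers `promoter_width` bp on
#'   both sides of the TSS; default upstream-only.
#' @return A `FeatureIndex`: list of `GRanges` (`genes`, `exons`,
#'   `promoters`, each carrying `gene_id` metadata) plus `promoter_width`.
#' @export
build_feature_index <- function(path, promoter_width = 2000,
                                symmetric = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  if (is_bed) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(!S4Vectors::decode(GenomicRanges::strand(gr)) %in% c("+", "-"))) {
      stop("BED features must have strand + or -")
    }
    gene_id <- if (!is.null(gr$name)) gr$name else paste0("feature",
                                                          seq_along(gr))
    genes <- gr
    genes$gene_id <- gene_id
    if (!is.null(gr$blocks)) {
      blocks <- gr$blocks
      ex <- unlist(GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
        b <- IRanges::shift(blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
        GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], b,
                               strand = GenomicRanges::strand(gr)[i])
      })))
      ex$gene_id <- rep(gene_id, lengths(blocks))
    } else {
      ex <- genes
    }
    tx <- genes
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    typ <- as.character(gr$type)
    genes <- gr[typ == "gene"]
    tx <- gr[typ %in% c("mRNA", "transcript")]
    ex <- gr[typ == "exon"]
    if (length(genes) == 0L) stop("no gene features in ", path)
    gid <- function(g) {
      id <- if (!is.null(g$gene_id)) g$gene_id else NULL
      if (is.null(id)) id <- g$ID
      if (is.null(id) && !is.null(g$Name)) id <- g$Name
      as.character(id)
    }
    genes$gene_id <- gid(genes)
    # map transcripts/exons to their gene via Parent chains
    id2gene <- stats::setNames(genes$gene_id, as.character(genes$ID))
    if (length(tx)) {
      tx$gene_id <- unname(id2gene[vapply(tx$Parent, `[`, character(1), 1)])
      tx2gene <- stats::setNames(tx$gene_id, as.character(tx$ID))
    } else {
      tx <- genes
      tx2gene <- id2gene
    }
    if (length(ex)) {
      parent <- vapply(ex$Parent, `[`, character(1), 1)
      ex$gene_id <- unname(ifelse(parent %in% names(tx2gene),
                                  tx2gene[parent], id2gene[parent]))
    } else {
      ex <- genes
    }
    if (any(!S4Vectors::decode(GenomicRanges::strand(genes)) %in%
              c("+", "-"))) {
      stop("gene features must have strand + or -")
    }
  }
  prom <- GenomicRanges::promoters(
    tx, upstream = promoter_width,
    downstream = if (symmetric) promoter_width else 0L)
  # clip at scaffold start (coordinate 1)
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  GenomicRanges::end(prom) <- pmax(GenomicRanges::end(prom), 0L)
  prom <- prom[GenomicRanges::width(prom) > 0]
  structure(list(genes = genes, exons = ex, promoters = prom,
                 promoter_width = promoter_width),
            class = "FeatureIndex")
}

overlap_genes <- function(query, subject) {
  # seqlevel mismatches (sites on unannotated scaffolds) are handled by the
  # caller; silence the merge notice
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE))
  split(subject$gene_id[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_along(query)))
}

#' Annotate sites against a feature index
#'
#' Labels each site as `promoter`, `exon`, `intron` or `intergenic`, with
#' precedence promoter > exon > intron (a site in an upstream promoter
#' overlapping a neighbour's intron is a promoter site). Intron = inside a
#' gene span but in no exon. Sites on scaffolds absent from the annotation
#' are intergenic, counted in `n_unannotated_scaffold`.
#'
#' @param sites Data frame with `chrom` and `pos` (1-based).
#' @param index A [build_feature_index()] result.
#' @return A list: `labels` (character per site), `gene_ids` (per-site list
#'   of gene IDs; empty for intergenic), `proportions` (per-category
#'   fractions), `n_unannotated_scaffold`.
#' @export
annotate_sites <- function(sites, index) {
  stopifnot(inherits(index, "FeatureIndex"))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  known <- as.character(GenomicRanges::seqnames(gr)) %in%
    as.character(unique(GenomicRanges::seqnames(index$genes)))
  in_prom <- overlap_genes(gr, index$promoters)
  in_exon <- overlap_genes(gr, index$exons)
  in_gene <- overlap_genes(gr, index$genes)
  n <- nrow(sites)
  labels <- character(n)
  gene_ids <- vector("list", n)
  for (i in seq_len(n)) {
    if (length(in_prom[[i]])) {
      labels[i] <- "promoter"
      gene_ids[[i]] <- unique(in_prom[[i]])
    } else if (length(in_exon[[i]])) {
      labels[i] <- "exon"
      gene_ids[[i]] <- unique(in_exon[[i]])
    } else if (length(in_gene[[i]])) {
      labels[i] <- "intron"
      gene_ids[[i]] <- unique(in_gene[[i]])
    } else {
      labels[i] <- "intergenic"
      gene_ids[[i]] <- character(0)
    }
  }
  cats <- c("promoter", "exon", "intron", "intergenic")
  props <- vapply(cats, function(k) mean(labels == k), numeric(1))
  n_unk <- sum(!known)
  if (n_unk) {
    warning(n_unk, " site(s) on scaffolds absent from the annotation")
  }
  list(labels = labels, gene_ids = gene_ids, proportions = props,
       n_unannotated_scaffold = n_unk)
}

#' Gene lists per DMcluster for network input
#'
#' A cluster contributes every gene whose promoter, exon or intron overlaps
#' ANY member site; clusters touching no gene are excluded (counted).
#'
#' @param clusters Result of [call_dmclusters()] (its `members`/`sites`
#'   elements identify the member cytosines), or a plain cluster table, in
#'   which case the cluster spans are used.
#' @param index A [build_feature_index()] result.
#' @return A list: `genes_per_cluster` (named list over retained cluster
#'   IDs), `gene_universe` (all contributing genes), `n_excluded`.
#' @export
annotate_clusters <- function(clusters, index) {
  cl <- if (is.data.frame(clusters)) clusters else clusters$network_input
  if (nrow(cl) == 0L) {
    return(list(genes_per_cluster = list(), gene_universe = character(0),
                n_excluded = 0L))
  }
  if (is.data.frame(clusters)) {
    per_cluster <- lapply(seq_len(nrow(cl)), function(i) {
      data.frame(chrom = cl$chrom[i], pos = seq(cl$start[i], cl$end[i]))
    })
    # span fallback: treat every position in the span as a member
  } else {
    per_cluster <- lapply(cl$cluster_id, function(id) {
      clusters$sites[clusters$members == id, c("chrom", "pos"),
                     drop = FALSE]
    })
  }
  genes <- lapply(per_cluster, function(ms) {
    gr <- GenomicRanges::GRanges(ms$chrom, IRanges::IRanges(ms$pos, ms$pos))
    hits <- unique(unlist(lapply(
      list(index$promoters, index$exons, index$genes),
      function(f) unlist(overlap_genes(gr, f)))))
    unname(hits[!is.na(hits)])
  })
  names(genes) <- as.character(cl$cluster_id)
  keep <- lengths(genes) > 0
  list(genes_per_cluster = genes[keep],
       gene_universe = unique(unlist(genes[keep])),
       n_excluded = sum(!keep))
}

#' Write annotated sites as TSV
#'
#' 1-based coordinates; multiple gene IDs are comma-joined.
#'
#' @param sites Site table (`chrom`, `pos`, ...).
#' @param annotation Result of [annotate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(sites, annotation, path) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    label = annotation$labels,
                    gene_id = vapply(annotation$gene_ids, paste,
                                     character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
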