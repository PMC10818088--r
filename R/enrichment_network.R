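#' Read a GMT gene-set collection
#'
#' @param path GMT file (term, description, member genes...).
#' @param universe Optional background gene universe; defaults to the union
#'   of all member genes.
#' @return A `GeneSetCollection`: list with `sets` (named list of gene
#'   vectors), `descriptions`, `universe`. Members outside the universe are
#'   dropped; empty terms are removed.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t")
  desc <- stats::setNames(vapply(lines, `[`, character(1), 2),
                          vapply(lines, `[`, character(1), 1))
  if (is.null(universe)) universe <- unique(unlist(sets))
  sets <- lapply(sets, function(g) intersect(unique(g), universe))
  keep <- lengths(sets) > 0
  list(sets = sets[keep], descriptions = desc[names(sets[keep])],
       universe = universe)
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the term's members, given
#' the background universe: with universe size N, term size K, query size n
#' and overlap k, p = P(X >= k). Fold enrichment is (k/n)/(K/N).
#'
#' @param query Character vector of gene IDs; members outside the universe
#'   are dropped (counted in `n_dropped`).
#' @param collection A [read_gmt()] collection (or compatible list).
#' @param fdr BH significance cutoff applied to the adjusted values.
#' @return A list with `table` (data.frame: `term`, `description`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`, `fold`, ordered by p), `significant`
#'   (term IDs with `p_adj <= fdr`), `n_dropped`.
#' @export
hypergeometric_enrichment <- function(query, collection, fdr = 0.05) {
  universe <- collection$universe
  q0 <- unique(query)
  q <- intersect(q0, universe)
  n_dropped <- length(q0) - length(q)
  if (length(q) == 0L) stop("no query genes remain in the universe")
  N <- length(universe)
  n <- length(q)
  terms <- names(collection$sets)
  K <- lengths(collection$sets)
  k <- vapply(collection$sets, function(s) length(intersect(q, s)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  tab <- data.frame(term = terms,
                    description = unname(collection$descriptions[terms]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p),
                    p_adj = unname(bh_adjust(p)$adjusted),
                    fold = unname(fold), stringsAsFactors = FALSE)
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, significant = tab$term[tab$p_adj <= fdr],
       n_dropped = n_dropped)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the significant
#' set at the given FDR.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param fdr Cutoff; default 0.05.
#' @return A list: `adjusted` (same order as input), `significant`
#'   (logical).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= fdr)
}

#' Read an interaction edge list
#'
#' @param path TSV with columns `geneA`, `geneB`, `confidence` (header
#'   optional when exactly three columns).
#' @return A data.frame with those columns; confidences validated in
#'   \[0, 1\].
#' @export
read_edges <- function(path) {
  edges <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(edges) < 3L) stop("edge list needs geneA, geneB, confidence")
  names(edges)[1:3] <- c("geneA", "geneB", "confidence")
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]")
  }
  edges
}

#' Assemble a confidence-filtered interaction network
#'
#' Drops edges below the confidence cutoff (strict: edges with confidence
#' >= `min_confidence` are kept) and self-loops, then reports the graph
#' around a set of seed genes: the directly-connected interactor set (seeds
#' plus their neighbours) and connected components. Seeds absent from the
#' filtered graph are retained as isolated nodes.
#'
#' @param edges Data frame with `geneA`, `geneB`, `confidence` (see
#'   [read_edges()]).
#' @param seed_genes Character vector of seed gene IDs.
#' @param min_confidence Cutoff; default 0.7.
#' @return A list: `graph` (igraph, undirected, edge attribute
#'   `confidence`), `interactors` (seeds and their neighbours),
#'   `components` (membership named by gene), `component_sizes`
#'   (descending), `n_isolated_seeds`.
#' @export
build_network <- function(edges, seed_genes, min_confidence = 0.7) {
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]")
  }
  keep <- edges$confidence >= min_confidence &
    edges$geneA != edges$geneB
  ef <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ef[, c("geneA", "geneB", "confidence")], directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "max")
  seeds <- unique(seed_genes)
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing)) {
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  nbrs <- unique(unlist(lapply(seeds, function(s) {
    igraph::neighbors(g, s)$name
  })))
  interactors <- sort(unique(c(seeds, nbrs)))
  comp <- igraph::components(g)
  list(graph = g,
       interactors = interactors,
       components = comp$membership,
       component_sizes = sort(comp$csize, decreasing = TRUE),
       n_isolated_seeds = length(missing))
}

#' Shared significant terms across analyses
#'
#' Intersects the significant term sets of several enrichment runs and
#' returns the full Venn partition (for 2-3 analyses).
#'
#' @param results Named list of [hypergeometric_enrichment()] results (or
#'   plain character vectors of significant term IDs).
#' @return A list: `shared` (terms significant in every analysis),
#'   `venn` ([overlap_sets()] partition when 2-3 analyses are given,
#'   otherwise `NULL`).
#' @export
term_overlap <- function(results) {
  stopifnot(length(results) >= 2L)
  sets <- lapply(results, function(r) {
    if (is.character(r)) r else r$significant
  })
  shared <- Reduce(intersect, sets)
  venn <- if (length(sets) %in% c(2L, 3L)) overlap_sets(sets) else NULL
  list(shared = shared, venn = venn)
}

#' Export a network as edge list + components JSON
#'
#' @param network A [build_network()] result.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_data_frame(network$graph, what = "edges")
  out <- list(edges = el,
              interactors = network$interactors,
              components = as.list(network$components),
              component_sizes = network$component_sizes,
              n_isolated_seeds = network$n_isolated_seeds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
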