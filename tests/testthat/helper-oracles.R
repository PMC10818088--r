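# Independent brute-force oracles used by the test suite. These deliberately
# re-derive results from first principles and never call the package code
# paths they are checking.

# dual-percentile DMS selection by direct filtering
oracle_select <- function(beta, p, beta_q = c(0.01, 0.99), p_q = 0.01) {
  lo <- stats::quantile(beta, beta_q[1], type = 7, names = FALSE)
  hi <- stats::quantile(beta, beta_q[2], type = 7, names = FALSE)
  pc <- stats::quantile(p, p_q, type = 7, names = FALSE)
  which((beta <= lo | beta >= hi) & p <= pc)
}

# O(n^2) brute-force pairwise chaining: link every same-scaffold pair closer
# than max_gap, take the transitive closure, and return the partition as a
# canonical list of "chrom:pos" vectors
oracle_clusters <- function(chrom, pos, max_gap = 40) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] &&
            abs(pos[i] - pos[j]) < max_gap) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  parts <- split(seq_len(n), comp)
  parts <- lapply(parts, function(i) {
    paste0(chrom[i][order(pos[i])], ":", sort(pos[i]))
  })
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# Venn region counts by direct inclusion-exclusion over elements
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  labs <- names(sets)
  pattern <- vapply(universe, function(el) {
    paste(labs[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  table(pattern)
}

# per-site annotation label by scanning every feature interval
oracle_annotate <- function(chrom, pos, features) {
  # features: data.frame(chrom, start, end, type) with 1-based inclusive
  # coords; precedence promoter > exon > gene-span (intron)
  vapply(seq_along(pos), function(i) {
    hit <- features$chrom == chrom[i] & features$start <= pos[i] &
      features$end >= pos[i]
    types <- features$type[hit]
    if ("promoter" %in% types) "promoter"
    else if ("exon" %in% types) "exon"
    else if ("gene" %in% types) "intron"
    else "intergenic"
  }, character(1))
}

# connected components by union-find over an edge list
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  stats::setNames(match(roots, unique(roots)), nodes)
}

# hypergeometric upper tail by explicit enumeration of the mass function
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- max(0, n + K - N):min(K, n)
  mass <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(mass[kk >= k])
}

# additive relationship by gene dropping: Monte-Carlo allele transmission
oracle_gene_drop <- function(pedigree, n_rep = 1e5, seed = 42) {
  set.seed(seed)
  ids <- pedigree$id
  n <- length(ids)
  alleles <- vector("list", n)  # each: n_rep x 2 matrix of founder alleles
  names(alleles) <- ids
  next_allele <- 0L
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (is.na(s)) {
      alleles[[i]] <- matrix(rep(next_allele + c(1L, 2L), each = n_rep),
                             n_rep, 2)
      next_allele <- next_allele + 2L
    } else {
      pick_s <- sample.int(2L, n_rep, replace = TRUE)
      pick_d <- sample.int(2L, n_rep, replace = TRUE)
      as_ <- alleles[[s]][cbind(seq_len(n_rep), pick_s)]
      ad_ <- alleles[[d]][cbind(seq_len(n_rep), pick_d)]
      alleles[[i]] <- cbind(as_, ad_)
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ai <- alleles[[i]]; aj <- alleles[[j]]
      if (i == j) {
        Fhat <- mean(ai[, 1] == ai[, 2])
        A[i, i] <- 1 + Fhat
      } else {
        # kinship: average IBD probability over the four allele pairings
        kin <- (mean(ai[, 1] == aj[, 1]) + mean(ai[, 1] == aj[, 2]) +
                  mean(ai[, 2] == aj[, 1]) + mean(ai[, 2] == aj[, 2])) / 4
        A[i, j] <- A[j, i] <- 2 * kin
      }
    }
  }
  A
}

# maximum likelihood for the binomial mixed model by Monte-Carlo integration
# over the joint random effect h ~ N(0, Sigma), common random numbers so the
# likelihood surface is smooth in the fixed effects
oracle_bmm_ml <- function(y, r, x, Sigma, n_draws = 40000, seed = 7) {
  set.seed(seed)
  n <- length(y)
  L <- chol(Sigma + diag(1e-10, n))
  Z <- matrix(stats::rnorm(n_draws * n), n_draws, n) %*% L  # draws of h
  negll <- function(par) {
    eta <- matrix(par[1] + par[2] * x, n_draws, n, byrow = TRUE) + Z
    pi_ <- stats::plogis(eta)
    ll_rep <- rowSums(stats::dbinom(matrix(y, n_draws, n, byrow = TRUE),
                                    matrix(r, n_draws, n, byrow = TRUE),
                                    pi_, log = TRUE))
    m <- max(ll_rep)
    -(m + log(mean(exp(ll_rep - m))))
  }
  fit <- stats::optim(c(0, 0), negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  list(mu = fit$par[1], beta = fit$par[2], negll = fit$value)
}

# mean silhouette width over a labelled score matrix (Euclidean)
mean_silhouette <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
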