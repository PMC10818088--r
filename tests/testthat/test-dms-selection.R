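mk_assoc <- function(beta, p, chrom = "scaf1", pos = seq_along(beta) * 100L) {
  data.frame(chrom = chrom, pos = pos, context = "CG", beta = beta,
             se = 1, p = p, beta_raw = beta, sigma_g2 = 0, sigma_e2 = 0,
             converged = TRUE, skip_reason = "none", stringsAsFactors = FALSE)
}

test_that("dual-percentile selection picks exactly the planted extremes", {
  beta <- 1:100
  p <- rep(0.5, 100)
  p[c(1, 100)] <- 0.001
  dms <- select_outliers(mk_assoc(beta, p))
  expect_equal(sort(dms$sites$beta), c(1, 100))
  # thresholds equal the documented interpolation quantiles
  expect_equal(unname(dms$thresholds["beta_lo"]),
               quantile(beta, 0.01, type = 7, names = FALSE))
})

test_that("degenerate beta distribution collapses to the p criterion", {
  beta <- rep(2, 50)
  p <- seq(0.001, 0.5, length.out = 50)
  dms <- select_outliers(mk_assoc(beta, p))
  pc <- quantile(p, 0.01, type = 7, names = FALSE)
  expect_equal(nrow(dms$sites), sum(p <= pc))
})

test_that("selection matches the brute-force filter on random tables", {
  set.seed(101)
  for (trial in 1:40) {
    m <- sample(50:400, 1)
    beta <- rnorm(m)
    p <- runif(m)
    assoc <- mk_assoc(beta, p, pos = sort(sample.int(m * 50L, m)))
    dms <- select_outliers(assoc)
    oracle <- oracle_select(beta, p)
    expect_setequal(paste(dms$sites$chrom, dms$sites$pos),
                    paste(assoc$chrom[oracle], assoc$pos[oracle]))
  }
})

test_that("selection ignores skipped sites and is row-order invariant", {
  assoc <- mk_assoc(rnorm(80), runif(80))
  assoc$skip_reason[1:10] <- "monomorphic"
  assoc$beta[1:10] <- NA
  assoc$p[1:10] <- NA
  d1 <- select_outliers(assoc)
  expect_equal(d1$n_considered, 70L)
  set.seed(3)
  d2 <- select_outliers(assoc[sample.int(80), ])
  expect_equal(d1$sites, d2$sites)
  expect_equal(d1$thresholds, d2$thresholds)
  all_skip <- assoc
  all_skip$skip_reason <- "monomorphic"
  all_skip$p <- NA
  expect_error(select_outliers(all_skip), "fewer than two")
})

test_that("cluster scan reproduces the definitional example and gap rule", {
  dms <- data.frame(chrom = c(rep("scaf1", 4), rep("scaf2", 3)),
                    pos = c(100L, 130L, 165L, 300L, 50L, 80L, 119L),
                    stringsAsFactors = FALSE)
  cl <- call_dmclusters(dms)
  expect_equal(cl$clusters$size, c(3L, 1L, 3L))
  expect_equal(cl$clusters$start, c(100L, 300L, 50L))
  expect_equal(cl$clusters$end, c(165L, 300L, 119L))
  expect_equal(cl$network_input$size, c(3L, 3L))

  # a gap of exactly 40 does NOT join (strict < 40)
  cl40 <- call_dmclusters(data.frame(chrom = "s", pos = c(100L, 140L)))
  expect_equal(nrow(cl40$clusters), 2L)
  cl39 <- call_dmclusters(data.frame(chrom = "s", pos = c(100L, 139L)))
  expect_equal(nrow(cl39$clusters), 1L)
})

test_that("clusters partition the DMS set and match pairwise chaining", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(5:60, 1)
    dms <- data.frame(
      chrom = sample(paste0("s", 1:3), n, replace = TRUE),
      pos = sample.int(1000L, n), stringsAsFactors = FALSE)
    dms <- dms[!duplicated(dms[c("chrom", "pos")]), ]
    dms <- dms[order(dms$chrom, dms$pos), ]
    cl <- call_dmclusters(dms)
    expect_equal(sum(cl$clusters$size), nrow(dms))  # partition
    got <- lapply(split(seq_len(nrow(cl$sites)), cl$members), function(i) {
      paste0(cl$sites$chrom[i], ":", cl$sites$pos[i])
    })
    got <- unname(got[order(vapply(got, `[`, character(1), 1))])
    expect_equal(got, oracle_clusters(dms$chrom, dms$pos))
  }
})

test_that("growing the gap threshold only merges clusters", {
  set.seed(5)
  dms <- data.frame(chrom = "s", pos = sort(sample.int(2000L, 60)),
                    stringsAsFactors = FALSE)
  for (gap in c(10, 40, 80, 200)) {
    n_small <- nrow(call_dmclusters(dms, max_gap = gap)$clusters)
    n_big <- nrow(call_dmclusters(dms, max_gap = gap * 2)$clusters)
    expect_lte(n_big, n_small)
  }
})

test_that("unsorted DMS input is sorted with a warning", {
  dms <- data.frame(chrom = "s", pos = c(300L, 100L, 130L),
                    stringsAsFactors = FALSE)
  expect_warning(cl <- call_dmclusters(dms), "not sorted")
  expect_equal(cl$clusters$size, c(2L, 1L))
})

test_that("Venn partitions match inclusion-exclusion on random sets", {
  v <- overlap_sets(list(x = c("A", "B"), y = c("B", "C"), z = c("B", "D")))
  expect_equal(unname(v$regions["x+y+z"]), 1L)
  expect_equal(v$intersection, "B")
  expect_equal(sum(v$regions), v$union_size)

  same <- overlap_sets(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(unname(same$regions["a+b"]), 5L)
  expect_equal(unname(same$regions["a"]), 0L)

  set.seed(9)
  for (trial in 1:40) {
    sets <- lapply(1:3, function(i) sample(letters, sample(3:20, 1)))
    names(sets) <- c("p", "q", "r")
    v <- overlap_sets(sets)
    oracle <- oracle_venn(sets)
    for (nm in names(oracle)) {
      expect_equal(unname(v$regions[nm]), unname(as.integer(oracle[nm])))
    }
    expect_equal(sum(v$regions), length(unique(unlist(sets))))
  }
})

test_that("BED exports use 0-based half-open coordinates", {
  assoc <- mk_assoc(c(-5, 0, 5), c(0.001, 0.5, 0.001), pos = c(10L, 20L, 30L))
  dms <- select_outliers(assoc, label = "toy")
  f <- tempfile(fileext = ".bed")
  write_dms_bed(dms, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, dms$sites$pos - 1L)
  expect_equal(bed$V3, dms$sites$pos)
  expect_true(all(bed$V4 == "toy"))
})
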