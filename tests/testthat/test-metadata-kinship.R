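test_that("the packaged sample table parses and validates", {
  rec <- read_samples_table(study_samples_path())
  expect_equal(nrow(rec), 22L)
  s1 <- rec[rec$sample_id == "S1_1", ]
  expect_equal(s1$sperm_count_per_ml, 407.1)
  expect_equal(s1$tissue, "Sperm")
  blood <- rec[rec$tissue == "Blood", ]
  expect_true(all(is.na(blood$sperm_count_per_ml)))
  expect_s3_class(rec$collection_date, "Date")
})

test_that("malformed sample tables are rejected", {
  rec <- read_samples_table(study_samples_path())
  f <- tempfile()
  bad <- rec
  bad$tissue[1] <- "Liver"
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_samples_table(f), "Liver")

  bad2 <- rec
  bad2$sperm_count_per_ml[bad2$tissue == "Blood"][1] <- 100
  write.table(bad2, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_samples_table(f), "non-sperm")
})

test_that("sample summary reproduces the study design counts", {
  rec <- read_samples_table(study_samples_path())
  eff <- stats::setNames(rep(0.994, nrow(rec)), rec$sample_id)
  s <- summarize_samples(rec, eff)
  expect_equal(unname(s$n_per_tissue), c(8L, 9L, 5L))
  expect_equal(s$n_samples, 22L)
  expect_equal(s$n_individuals, 9L)
  expect_equal(sum(rec$tissue == "Testes"), 9L)
  expect_true(all(s$tissues_per_individual >= 2))
  expect_equal(unname(s$firmness_counts), c(6L, 3L))
})

test_that("replicate resolution keeps the higher-efficiency copy", {
  rec <- data.frame(sample_id = c("X1_1", "X1_2"), studbook_no = 1,
                    name = "x", tissue = "Testes",
                    collection_date = as.Date("2018-01-01"),
                    age_at_sampling = 3, avg_litter_size = 2,
                    testes_status = "Firm", sperm_count_per_ml = NA,
                    replicate_flag = TRUE, stringsAsFactors = FALSE)
  s <- summarize_samples(rec, c(X1_1 = 0.994, X1_2 = 0.993))
  expect_equal(s$retained, "X1_1")
  expect_error(summarize_samples(rec, NULL), "efficiencies")
})

test_that("reproductive arithmetic derives the implied litters ratio", {
  r <- reproductive_summary(15.29, 4.18, median_offspring = 11)
  expect_equal(r$litters_ratio, 3.66)
  expect_equal(reproductive_summary(10, 2)$litters_ratio, 5.00)
  # raw per-male records: direct arithmetic oracle
  offspring <- c(4, 4, 4)
  litters <- c(4, 4, 4)  # each male sired one litter of 4
  r2 <- reproductive_summary(offspring, litters)
  expect_equal(r2$mean_offspring, 4)
  expect_equal(r2$litters_ratio, round(mean(offspring) / mean(litters), 2))
  expect_error(reproductive_summary(10, 0), "zero")
})

test_that("additive relationship reproduces textbook pedigree values", {
  ped <- data.frame(id = c("s", "d", "k1", "k2", "g"),
                    sire = c(NA, NA, "s", "s", "k1"),
                    dam = c(NA, NA, "d", "d", "k2"),
                    stringsAsFactors = FALSE)
  A <- additive_relationship(ped)
  expect_equal(A["s", "k1"], 0.5)      # parent-offspring
  expect_equal(A["k1", "k2"], 0.5)     # full sibs
  expect_equal(A["g", "g"], 1.25)      # offspring of full sibs: F = 0.25
  expect_equal(A["s", "s"], 1)
  expect_true(isSymmetric(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("founder block is identity and row order does not matter", {
  ped <- simulate_pedigree(5, 2, seed = 11)
  A <- additive_relationship(ped)
  founders <- ped$id[ped$generation == 0]
  expect_equal(A[founders, founders], diag(length(founders)),
               ignore_attr = TRUE)
  shuffled <- ped[rev(seq_len(nrow(ped))), ]
  A2 <- additive_relationship(shuffled)
  expect_equal(A2[rownames(A), colnames(A)], A)
})

test_that("pedigree errors: cycles and unknown parents", {
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(additive_relationship(cyc), "cycle")
  unk <- data.frame(id = "a", sire = "ghost", dam = NA,
                    stringsAsFactors = FALSE)
  expect_error(additive_relationship(unk), "unknown parent")
})

test_that("tabular method matches the gene-dropping estimate", {
  ped <- simulate_pedigree(5, 3, seed = 13)  # 20 individuals
  A <- additive_relationship(ped)
  A_mc <- oracle_gene_drop(ped, n_rep = 1e5, seed = 99)
  expect_lt(max(abs(A - A_mc)), 0.02)  # Monte-Carlo error at 1e5 replicates
})

test_that("predictor coding follows the documented conventions", {
  rec <- read_samples_table(study_samples_path())
  testes <- rec[rec$tissue == "Testes", ]
  firm <- predictor_vector(testes, "testes_firmness")
  expect_equal(firm, ifelse(testes$testes_status == "Firm", 1, 0))
  expect_error(predictor_vector(rec, "shoe_size"), "unknown predictor")
})
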