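# Shared fixtures, built in code at test time.

# small simulated dataset reused by several files (cached per session)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulate_pedigree(6, 3, seed = 5)
      cfg <- sim_config(n_sites = 120, n_scaffolds = 2, n_lambda_sites = 60,
                        seed = 17)
      cache <<- simulate_dataset(cfg, ped)
    }
    cache
  }
})

filter_cg <- function(methylome, min_coverage = 10, drop_lambda = TRUE) {
  cg <- context_summary(methylome)$cg
  if (drop_lambda) cg <- cg[cg$chrom != "lambda", , drop = FALSE]
  filter_coverage(cg, min_coverage)
}

# toy annotation: two genes on scaf1 (opposite strands), one on scaf2
write_test_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "scaf1\ttest\tgene\t5000\t9000\t.\t+\t.\tID=gene1;Name=GENE1",
    "scaf1\ttest\tmRNA\t5000\t9000\t.\t+\t.\tID=tx1;Parent=gene1",
    "scaf1\ttest\texon\t5000\t5500\t.\t+\t.\tID=ex1;Parent=tx1",
    "scaf1\ttest\texon\t8000\t9000\t.\t+\t.\tID=ex2;Parent=tx1",
    "scaf1\ttest\tgene\t12000\t15000\t.\t-\t.\tID=gene2;Name=GENE2",
    "scaf1\ttest\tmRNA\t12000\t15000\t.\t-\t.\tID=tx2;Parent=gene2",
    "scaf1\ttest\texon\t12000\t12400\t.\t-\t.\tID=ex3;Parent=tx2",
    "scaf1\ttest\texon\t14500\t15000\t.\t-\t.\tID=ex4;Parent=tx2",
    "scaf2\ttest\tgene\t100\t2000\t.\t+\t.\tID=gene3;Name=GENE3",
    "scaf2\ttest\tmRNA\t100\t2000\t.\t+\t.\tID=tx3;Parent=gene3",
    "scaf2\ttest\texon\t100\t2000\t.\t+\t.\tID=ex5;Parent=tx3"
  )
  writeLines(lines, path)
  path
}

# the flat interval table the annotation oracle scans (same toy annotation,
# promoter windows derived independently by hand: 2 kb strictly upstream)
test_gff_features <- function() {
  data.frame(
    chrom = c("scaf1", "scaf1", "scaf1", "scaf1", "scaf1", "scaf1",
              "scaf1", "scaf2", "scaf2", "scaf2"),
    start = c(5000, 5000, 8000, 3000, 12000, 12000, 14500, 100, 100, 1),
    end   = c(9000, 5500, 9000, 4999, 15000, 12400, 15000, 2000, 2000, 99),
    type  = c("gene", "exon", "exon", "promoter", "gene", "exon", "exon",
              "gene", "exon", "promoter"),
    stringsAsFactors = FALSE)
  # gene2 is - strand: promoter [15001, 17000]
}

test_gff_features_full <- function() {
  rbind(test_gff_features(),
        data.frame(chrom = "scaf1", start = 15001, end = 17000,
                   type = "promoter", stringsAsFactors = FALSE))
}

write_test_gmt <- function(path = tempfile(fileext = ".gmt")) {
  lines <- c(
    paste(c("GO:0001", "development", paste0("G", 1:5)), collapse = "\t"),
    paste(c("GO:0002", "reproduction", paste0("G", 4:10)), collapse = "\t"),
    paste(c("GO:0003", "metabolism", paste0("G", 8:20)), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

write_test_edges <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("geneA\tgeneB\tconfidence",
               "G1\tG2\t0.9", "G2\tG3\t0.8", "G3\tG4\t0.69",
               "G5\tG6\t0.75", "G7\tG7\t0.99"), path)
  path
}
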