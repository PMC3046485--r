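test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(divergence = 0.6), "divergence")
  expect_error(sim_config(fraction_At_deleted = 0.7,
                          fraction_Aa_deleted = 0.7), "fractions")
  expect_error(sim_config(probe_length = 0), "positive")
  expect_error(sim_config(n_replicates = 1), "replicates")
})

test_that("zero divergence yields identical parental sequences", {
  cfg <- sim_config(n_genes = 10L, divergence = 0, network_spec = NULL,
                    seed = 1L)
  seqs <- sim_parental_sequences(cfg)
  expect_identical(as.character(seqs$at), as.character(seqs$aa))
})

test_that("substitution counts match the binomial divergence model", {
  cfg <- sim_config(n_genes = 30L, divergence = 0.05,
                    network_spec = NULL, seed = 7L)
  seqs <- sim_parental_sequences(cfg)
  # independent oracle: position-wise comparison of the two sequences
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, as.character(seqs$at), as.character(seqs$aa))
  ci <- qbinom(c(0.005, 0.995), cfg$gene_length, 0.05)
  expect_true(all(mism >= ci[1] & mism <= ci[2]))
  # each substituted position holds a different base, never a gap
  expect_true(all(nchar(as.character(seqs$aa)) == cfg$gene_length))
})

test_that("identical configuration reproduces byte-identical FASTA", {
  cfg <- sim_config(n_genes = 8L, network_spec = NULL, seed = 3L)
  f <- replicate(2, {
    s <- sim_parental_sequences(cfg)
    paths <- c(tempfile(fileext = ".fa"), tempfile(fileext = ".fa"))
    write_ortholog_fasta(s, paths[1], paths[2])
    paths
  })
  expect_identical(unname(tools::md5sum(f[1, 1])),
                   unname(tools::md5sum(f[1, 2])))
  expect_identical(unname(tools::md5sum(f[2, 1])),
                   unname(tools::md5sum(f[2, 2])))
})

test_that("deletions force the true transcript share to the retained parent", {
  co <- small_cohort()
  tr <- co$seqs$truth
  expect_true(all(tr$expression_alpha_true[tr$retention_state ==
                                             "At_deleted"] == 1))
  expect_true(all(tr$expression_alpha_true[tr$retention_state ==
                                             "Aa_deleted"] == 0))
  expect_true(all(tr$divergence_rate >= 0 & tr$divergence_rate <= 0.5))
})

test_that("the fraction of probes carrying a mismatch matches 1 - (1-d)^25", {
  cfg <- sim_config(n_genes = 150L, probes_per_gene = 7,
                    network_spec = NULL, seed = 5L)
  seqs <- sim_parental_sequences(cfg)
  lay <- withr::with_seed(cfg$seed + 1L,
                          homoeobias:::probe_layout(cfg, seqs))
  # oracle: recount mismatches under each probe from the FASTA sequences
  at <- as.character(seqs$at)
  aa <- as.character(seqs$aa)
  recount <- mapply(function(g, off) {
    s1 <- substr(at[[g]], off + 1, off + cfg$probe_length)
    s2 <- substr(aa[[g]], off + 1, off + cfg$probe_length)
    sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  }, lay$gene_id, lay$offset)
  expect_identical(unname(recount), as.integer(lay$mismatches))
  p_expected <- 1 - (1 - cfg$divergence)^cfg$probe_length
  p_obs <- mean(lay$mismatches >= 1)
  se <- sqrt(p_expected * (1 - p_expected) / nrow(lay))
  expect_lt(abs(p_obs - p_expected), 3 * se)
})

test_that("F1 intensities are dose-additive between the parents", {
  cfg <- sim_config(n_genes = 15L, n_replicates = 60L,
                    network_spec = NULL, noise_sd = 0.1, seed = 9L)
  seqs <- sim_parental_sequences(cfg)
  tbl <- sim_probe_intensities(cfg, seqs,
                               assays = c("At_DNA", "Aa_DNA", "F1As_DNA"))
  at <- rowMeans(homoeobias:::assay_matrix(tbl, "At", "DNA"))
  aa <- rowMeans(homoeobias:::assay_matrix(tbl, "Aa", "DNA"))
  f1 <- rowMeans(homoeobias:::assay_matrix(tbl, "F1As", "DNA"))
  rel <- f1 / ((at + aa) / 2)
  # Monte-Carlo mean vs closed form: 60 replicates, so tight
  expect_lt(abs(mean(rel) - 1), 0.02)
})

test_that("conserved probes hybridize equally in both parents", {
  co <- small_cohort()
  lay <- co$layout
  cons <- lay$probe_id[!is.na(lay$gene_id) & lay$mismatches == 0]
  at <- rowMeans(homoeobias:::assay_matrix(co$tbl, "At", "DNA"))[cons]
  aa <- rowMeans(homoeobias:::assay_matrix(co$tbl, "Aa", "DNA"))[cons]
  expect_lt(abs(mean(log2(at / aa))), 0.02)
})

test_that("deleted homoeologs contribute nothing to As DNA", {
  co <- small_cohort()
  tr <- co$seqs$truth
  lay <- co$layout
  as_m <- rowMeans(homoeobias:::assay_matrix(co$tbl, "As", "DNA"))
  at_m <- rowMeans(homoeobias:::assay_matrix(co$tbl, "At", "DNA"))
  del <- tr$gene_id[tr$retention_state == "Aa_deleted"]
  expect_gt(length(del), 0)
  pid <- lay$probe_id[lay$gene_id %in% del]
  # Aa deleted: As signal is half the At-only signal at every probe
  # (background is negligible against the gene base intensity)
  expect_lt(abs(mean(as_m[pid] / at_m[pid]) - 0.5), 0.05)
})

test_that("read origins follow the true transcript share", {
  cfg <- sim_config(n_genes = 4L, fraction_unexpressed = 0,
                    fraction_At_deleted = 1, fraction_Aa_deleted = 0,
                    network_spec = NULL, reads_per_gene = 50L, seed = 2L)
  seqs <- sim_parental_sequences(cfg)
  reads <- sim_reads(cfg, seqs)
  expect_true(all(reads$origin == "Aa"))  # alpha forced to 1

  cfg2 <- sim_config(n_genes = 2L, fraction_unexpressed = 0,
                     fraction_At_deleted = 0, fraction_Aa_deleted = 0,
                     network_spec = NULL, reads_per_gene = 5000L,
                     read_error = 0, seed = 2L)
  seqs2 <- sim_parental_sequences(cfg2)
  seqs2$truth$expression_alpha_true[] <- 0.7
  reads2 <- sim_reads(cfg2, seqs2)
  n <- nrow(reads2)
  ci <- qbinom(c(0.005, 0.995), n, 0.7) / n
  expect_gt(mean(reads2$origin == "Aa"), ci[1])
  expect_lt(mean(reads2$origin == "Aa"), ci[2])

  # determinism: same config, byte-identical FASTQ
  r1 <- tempfile(fileext = ".fq"); r2 <- tempfile(fileext = ".fq")
  r1b <- tempfile(fileext = ".fq"); r2b <- tempfile(fileext = ".fq")
  write_reads_fastq(sim_reads(cfg2, seqs2), r1, r2)
  write_reads_fastq(sim_reads(cfg2, seqs2), r1b, r2b)
  expect_identical(unname(tools::md5sum(r1)), unname(tools::md5sum(r1b)))
  expect_identical(unname(tools::md5sum(r2)), unname(tools::md5sum(r2b)))
})

test_that("reads from undiverged error-free genes match both orthologs", {
  cfg <- sim_config(n_genes = 2L, divergence = 0, read_error = 0,
                    fraction_unexpressed = 0, fraction_At_deleted = 0,
                    fraction_Aa_deleted = 0, network_spec = NULL,
                    reads_per_gene = 20L, seed = 4L)
  seqs <- sim_parental_sequences(cfg)
  reads <- sim_reads(cfg, seqs)
  at <- as.character(seqs$at)
  hits <- mapply(function(r, g) grepl(r, at[[g]], fixed = TRUE),
                 reads$read1, reads$gene_id)
  expect_true(all(hits))  # identical orthologs: no diagnostic sites
})

test_that("network co-bias strength controls pair concordance in truth", {
  mk <- function(cb, seed) {
    cfg <- sim_config(n_genes = 500L, fraction_unexpressed = 0,
                      network_spec = list(n_networks = 40L,
                                          genes_per_network = 5L,
                                          co_bias = cb), seed = seed)
    seqs <- sim_parental_sequences(cfg)
    net <- sim_network(cfg, seqs$truth)
    tr <- seqs$truth
    dir <- setNames(tr$bias_direction, tr$gene_id)
    innet <- net[net$connectedness >= 0.7, ]
    mean(dir[innet$gene_a] == dir[innet$gene_b])
  }
  expect_equal(mk(1, 11L), 1)
  expect_lt(abs(mk(0.5, 12L) - 0.5), 0.08)
  # determinism of the edge list
  cfg <- sim_config(n_genes = 200L, seed = 6L)
  tr <- sim_parental_sequences(cfg)$truth
  expect_identical(sim_network(cfg, tr), sim_network(cfg, tr))
})
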