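test_that("identical orthologs align with no variants", {
  al <- align_ortholog_pair("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(nrow(al$variants), 0)
  expect_equal(al$divergence, 0)
  expect_equal(al$score, 10)
  expect_error(align_ortholog_pair("ACGU", "ACGT"), "A/C/G/T/N")
})

test_that("a single substitution is reported as one SNP", {
  al <- align_ortholog_pair("ACGTACGT", "ACGAACGT")
  expect_equal(nrow(al$variants), 1)
  expect_equal(al$variants$type, "SNP")
  expect_equal(al$variants$at_pos, 3)
  expect_equal(al$variants$at_allele, "T")
  expect_equal(al$variants$aa_allele, "A")
  expect_equal(al$divergence, 1 / 8)
})

test_that("a one-base gap is one deletion variant with the right score", {
  al <- align_ortholog_pair("ACGTACGT", "ACGACGT")
  expect_equal(al$variants$type, "deletion")
  expect_equal(nchar(al$variants$at_allele), 1)
  expect_equal(al$score,
               brute_force_align_score("ACGTACGT", "ACGACGT"))
})

test_that("alignment scores equal brute-force enumeration on short pairs", {
  set.seed(13)
  for (i in 1:25) {
    a <- random_seq(sample(4:10, 1))
    b <- random_seq(sample(4:10, 1))
    expect_equal(align_ortholog_pair(a, b)$score,
                 brute_force_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("N bases never become variants", {
  al <- align_ortholog_pair("ACNTAC", "ACGTAC")
  expect_equal(nrow(al$variants), 0)
  expect_equal(al$divergence, 0)
})

test_that("divergence is the variant-column fraction", {
  expect_equal(homoeolog_divergence(strrep("ACGT", 25),
                                    strrep("ACGT", 25)), 0)
  a <- random_seq(100)
  b <- paste0("T", substr(a, 2, 100))
  a <- paste0("A", substr(a, 2, 100))
  expect_equal(homoeolog_divergence(a, b), 1 / 100)
})

test_that("estimated divergence recovers the generator rate", {
  cfg <- sim_config(n_genes = 20L, divergence = 0.04,
                    network_spec = NULL, seed = 19L)
  seqs <- sim_parental_sequences(cfg)
  d <- mapply(homoeolog_divergence, as.character(seqs$at),
              as.character(seqs$aa))
  # substitutions only; aligned length = gene length
  ci <- qbinom(c(0.005, 0.995), 20 * cfg$gene_length, 0.04) /
    (20 * cfg$gene_length)
  expect_gt(mean(d), ci[1])
  expect_lt(mean(d), ci[2])
})

test_that("reads vote by diagnostic sites and calls follow the majority", {
  set.seed(31)
  at <- random_seq(60)
  aa_ch <- strsplit(at, "")[[1]]
  for (p in c(6, 12, 55)) {  # plant three SNPs (1-based)
    aa_ch[p] <- setdiff(c("A", "C", "G", "T"), aa_ch[p])[1]
  }
  aa <- paste(aa_ch, collapse = "")
  al <- list(g1 = align_ortholog_pair(at, aa))
  expect_equal(nrow(al$g1$variants), 3)
  refs <- list(at = c(g1 = at), aa = c(g1 = aa))
  reads <- data.frame(
    read_id = c("r_aa", "r_at", "r_none"),
    gene_id = "g1",
    read1 = c(substr(aa, 1, 20),   # covers two Aa alleles
              substr(at, 1, 20),   # covers two At alleles
              substr(at, 20, 50)), # covers no diagnostic site
    stringsAsFactors = FALSE)
  asg <- assign_reads(reads, al, refs)
  expect_equal(asg$call[asg$read_id == "r_aa"], "Aa")
  expect_equal(asg$call[asg$read_id == "r_at"], "At")
  expect_equal(asg$call[asg$read_id == "r_none"], "ambiguous")
  expect_equal(asg$informative_sites[asg$read_id == "r_none"], 0)
  # symmetry: swapping the parental references swaps every call
  al_sw <- list(g1 = align_ortholog_pair(aa, at))
  refs_sw <- list(at = c(g1 = aa), aa = c(g1 = at))
  asg_sw <- assign_reads(reads, al_sw, refs_sw)
  map <- c(At = "Aa", Aa = "At", ambiguous = "ambiguous",
           conflicting = "conflicting", unmapped = "unmapped")
  expect_equal(unname(map[asg$call]), asg_sw$call)
})

test_that("simulated reads are assigned back to their true origin", {
  cfg <- sim_config(n_genes = 25L, indel_rate = 0.005,
                    fraction_unexpressed = 0, network_spec = NULL,
                    reads_per_gene = 40L, seed = 23L)
  seqs <- sim_parental_sequences(cfg)
  reads <- sim_reads(cfg, seqs)
  al <- align_ortholog_pairs(seqs$at, seqs$aa)
  asg <- assign_reads(reads, al, seqs)
  informative <- asg$informative_sites >= 1
  called <- asg$call %in% c("At", "Aa")
  expect_gte(mean(called[informative]), 0.95)
  truth <- reads$origin[match(asg$read_id, reads$read_id)]
  expect_gte(mean(asg$call[called] == truth[called]), 0.99)
})

test_that("FPK is length-normalised fragment counting", {
  asg <- data.frame(
    read_id = sprintf("r%03d", 1:130), gene_id = "g1",
    informative_sites = 1,
    at_support = c(rep(1, 100), rep(0, 28), 0, 1),
    aa_support = c(rep(0, 100), rep(1, 28), 0, 1),
    call = c(rep("At", 100), rep("Aa", 28), "ambiguous", "conflicting"),
    stringsAsFactors = FALSE)
  lens <- data.frame(gene_id = c("g1", "g2"),
                     at_length = c(1000, 500), aa_length = c(700, 500))
  fpk <- fpk_quantify(asg, lens)
  expect_equal(fpk$at_fpk[1], 100)
  expect_equal(fpk$aa_fpk[1], 28 / 0.7)
  expect_equal(fpk$n_ambiguous[1], 1)
  expect_equal(fpk$n_conflicting[1], 1)
  expect_equal(fpk$ratio[1], 40 / 140)
  # a gene with no assigned reads is flagged, not dropped
  expect_true(fpk$no_reads[2])
  expect_true(is.na(fpk$ratio[2]))
  # doubling the exon length halves FPK
  lens2 <- transform(lens, at_length = at_length * 2)
  expect_equal(fpk_quantify(asg, lens2)$at_fpk[1], 50)
  expect_error(fpk_quantify(asg, transform(lens, at_length = 0)),
               "zero-length")
})

test_that("read-array concordance fits only with enough genes", {
  fpk <- data.frame(gene_id = sprintf("g%02d", 1:15),
                    ratio = seq(0.1, 0.9, length.out = 15))
  alpha <- data.frame(gene_id = fpk$gene_id, alpha1 = fpk$ratio)
  cc <- concordance_with_array(fpk, alpha)
  expect_equal(cc$r_squared, 1)
  small <- concordance_with_array(fpk[1:5, ], alpha[1:5, ])
  expect_true(is.na(small$r_squared))
  expect_equal(nrow(small$table), 5)
})

test_that("SAM input reproduces the internal read representation", {
  cfg <- sim_config(n_genes = 3L, fraction_unexpressed = 0,
                    network_spec = NULL, reads_per_gene = 5L, seed = 29L)
  seqs <- sim_parental_sequences(cfg)
  reads <- sim_reads(cfg, seqs)
  # write a minimal SAM of the fragments against their gene
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (g in names(seqs$at)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", g,
                       Biostrings::width(seqs$at)[names(seqs$at) == g]),
               con)
  }
  for (i in seq_len(nrow(reads))) {
    qn <- gsub("[|=]", "_", reads$read_id[i])
    writeLines(sprintf("%s\t65\t%s\t1\t60\t72M\t*\t0\t0\t%s\t*",
                       qn, reads$gene_id[i], reads$read1[i]), con)
    writeLines(sprintf(
      "%s\t129\t%s\t1\t60\t72M\t*\t0\t0\t%s\t*",
      qn, reads$gene_id[i],
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$read2[i])))), con)
  }
  close(con)
  back <- read_sam_reads(sam)
  expect_equal(nrow(back), nrow(reads))
  m <- match(gsub("[|=]", "_", reads$read_id), back$read_id)
  expect_equal(back$gene_id[m], reads$gene_id)
  expect_equal(back$read1[m], reads$read1)
  expect_equal(back$read2[m], reads$read2)
})
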