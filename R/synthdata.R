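# Synthetic-data generator: parental ortholog sequences, tiling-array probe
# intensities for four genotypes (plus allotetraploid RNA), paired-end reads
# from the allotetraploid transcriptome, and a gene-interaction network --
# all with recorded ground truth for parameter-recovery tests.
#
# The two parental species are called At (the array's reference genome) and
# Aa; As is the evolved natural allotetraploid and F1As the resynthesised
# first-generation allotetraploid with exactly equal homoeolog dose.

.ASSAYS <- c("At_DNA", "Aa_DNA", "F1As_DNA", "As_DNA", "As_RNA")

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulation with validation. The defaults
#' describe the study system the pipeline targets: two parental genomes
#' diverged at about 1 substitution per 20 bases, 25-base probes tiled
#' every 35 bases (about 7 probes per gene body), three biological
#' replicates per array, an F1 allotetraploid with exactly equal
#' homoeolog dose, and an evolved allotetraploid carrying homoeolog
#' deletions, silenced homoeologs, optional clustered alterations, and
#' network-correlated expression bias.
#'
#' @param n_genes number of genes.
#' @param gene_length length of each gene/transcript in bases.
#' @param probes_per_gene mean of the (Poisson) per-gene probe count;
#'   counts are floored at 5 and capped by what fits in the gene. The
#'   default tiles the whole 1-kb gene body at the 35-base step, as a
#'   genome-tiling design does.
#' @param probe_length probe length in bases (25-mers).
#' @param tiling_step spacing between consecutive probe starts in bases.
#' @param n_replicates biological replicates per array.
#' @param divergence per-base substitution rate between parental orthologs
#'   (must lie in `[0, 0.5]`).
#' @param indel_rate per-base short-indel rate between orthologs. Off by
#'   default: the array simulation assumes colinearity. Turn on (e.g.
#'   0.005) when generating inputs for the read-partitioning module.
#' @param signal_loss_per_mismatch mean multiplicative hybridisation
#'   attenuation per mismatched base under a probe (must exceed 2/3).
#'   Per-mismatch factors are drawn from a Beta-tailed continuum with
#'   this mean (see the layout internals), fixed across genotypes and
#'   replicates, mimicking position- and context-dependent mismatch
#'   effects: conserved probes form a sharp intensity-ratio peak while
#'   mismatched probes taper into a smooth one-sided tail.
#' @param noise_sd standard deviation of the multiplicative log2-normal
#'   intensity noise.
#' @param base_log2_mean,base_log2_sd distribution of per-gene DNA base
#'   intensity (log2 scale).
#' @param expr_log2_mean,expr_log2_sd distribution of per-gene RNA base
#'   intensity for expressed genes (log2 scale).
#' @param background additive optical/background intensity common to all
#'   probes (arbitrary fluorescence units).
#' @param n_intergenic number of background control probes (no gene
#'   assignment, no signal in any assay). They anchor the low-quantile
#'   background estimate of the preprocessing and the intergenic
#'   threshold of the expression call; the default keeps them a sizable
#'   minority of all probes.
#' @param n_chrom number of chromosomes genes are split across.
#' @param fraction_At_deleted,fraction_Aa_deleted fractions of genes whose
#'   At (resp. Aa) homoeolog is deleted in the evolved allotetraploid.
#' @param fraction_unexpressed fraction of genes with no transcription.
#' @param cluster_spec optional list of planted multi-gene alterations;
#'   each element is `list(chrom =, start_index =, length =, state =)`
#'   with `state` one of `"At_deleted"`, `"Aa_deleted"` and `start_index`
#'   the 1-based gene index within the chromosome.
#' @param network_spec `list(n_networks, genes_per_network, co_bias)`;
#'   `co_bias` is the probability that a network member adopts the
#'   network's shared bias direction.
#' @param read_length,fragment_length paired-end read geometry (bases).
#' @param read_error per-base sequencing substitution error rate.
#' @param reads_per_gene fragments simulated per expressed gene.
#' @param seed integer seed; the same configuration (including seed)
#'   reproduces every output byte for byte.
#' @return a validated `homoeo_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length = 1000L,
                       probes_per_gene = 28,
                       probe_length = 25L,
                       tiling_step = 35L,
                       n_replicates = 3L,
                       divergence = 0.05,
                       indel_rate = 0,
                       signal_loss_per_mismatch = 0.8,
                       noise_sd = 0.12,
                       base_log2_mean = 12,
                       base_log2_sd = 1,
                       expr_log2_mean = 11,
                       expr_log2_sd = 1,
                       background = 120,
                       n_intergenic = ceiling(0.3 * n_genes * probes_per_gene),
                       n_chrom = 2L,
                       fraction_At_deleted = 0.1,
                       fraction_Aa_deleted = 0.1,
                       fraction_unexpressed = 0.5,
                       cluster_spec = NULL,
                       network_spec = list(n_networks = 20L,
                                           genes_per_network = 5L,
                                           co_bias = 0.9),
                       read_length = 72L,
                       fragment_length = 250L,
                       read_error = 0.005,
                       reads_per_gene = 100L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    probes_per_gene = probes_per_gene,
    probe_length = as.integer(probe_length),
    tiling_step = as.integer(tiling_step),
    n_replicates = as.integer(n_replicates),
    divergence = divergence, indel_rate = indel_rate,
    signal_loss_per_mismatch = signal_loss_per_mismatch,
    noise_sd = noise_sd,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    expr_log2_mean = expr_log2_mean, expr_log2_sd = expr_log2_sd,
    background = background, n_intergenic = as.integer(n_intergenic),
    n_chrom = as.integer(n_chrom),
    fraction_At_deleted = fraction_At_deleted,
    fraction_Aa_deleted = fraction_Aa_deleted,
    fraction_unexpressed = fraction_unexpressed,
    cluster_spec = cluster_spec, network_spec = network_spec,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    read_error = read_error, reads_per_gene = as.integer(reads_per_gene),
    seed = as.integer(seed))
  if (cfg$divergence < 0 || cfg$divergence > 0.5) {
    stop("divergence must lie in [0, 0.5]")
  }
  if (cfg$probe_length <= 0 || cfg$tiling_step <= 0) {
    stop("probe_length and tiling_step must be positive")
  }
  if (cfg$probe_length > cfg$gene_length) {
    stop("probe_length exceeds gene_length")
  }
  fr <- c(cfg$fraction_At_deleted, cfg$fraction_Aa_deleted)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("deletion fractions must lie in [0,1] and sum to at most 1")
  }
  if (cfg$fraction_unexpressed < 0 || cfg$fraction_unexpressed > 1) {
    stop("fraction_unexpressed must lie in [0, 1]")
  }
  if (cfg$n_replicates < 2L) stop("need at least 2 replicates")
  if (!is.null(cfg$network_spec) && cfg$network_spec$genes_per_network < 2) {
    stop("networks need at least 2 genes")
  }
  class(cfg) <- "homoeo_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, divergence, indel_rate) {
  alphabet <- c("A", "C", "G", "T")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hit <- which(stats::runif(n) < divergence)
  if (length(hit)) {
    # substitute by a uniformly chosen one of the three other bases
    code <- match(bases[hit], alphabet) - 1L
    bases[hit] <- alphabet[((code + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    # apply from the right so earlier coordinates stay valid
    for (i in rev(ev)) {
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        del <- i:min(i + len - 1L, length(bases))
        bases <- bases[-del]
      } else {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        bases <- append(bases, ins, after = i)
      }
    }
  }
  paste(bases, collapse = "")
}

#' Generate parental ortholog sequences and ground truth
#'
#' Draws an At sequence per gene and derives the Aa ortholog by random
#' substitutions at rate `divergence` (plus optional short indels), then
#' assigns the evolved-allotetraploid ground truth: retention state
#' (both homoeologs retained / At deleted / Aa deleted, with optional
#' planted contiguous alteration clusters), true Aa transcript share
#' `expression_alpha_true` (forced to 1 when the At homoeolog is deleted
#' and 0 when Aa is deleted), expression status, and network membership
#' with network-correlated bias directions.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `at` and `aa` ([Biostrings::DNAStringSet]) and
#'   `truth`, a data.frame with one row per gene (gene_id, chrom, start,
#'   end, retention_state, expression_alpha_true, expressed,
#'   in_alteration_cluster, network_id, bias_direction, divergence_rate).
#' @export
sim_parental_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "homoeo_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%04d", seq_len(n))
    at <- vapply(seq_len(n), function(i) random_dna(cfg$gene_length), "")
    aa <- vapply(at, mutate_sequence, "", divergence = cfg$divergence,
                 indel_rate = cfg$indel_rate, USE.NAMES = FALSE)

    # genome layout: genes split into contiguous chromosome blocks
    chrom_of <- rep(sprintf("chr%d", seq_len(cfg$n_chrom)),
                    each = ceiling(n / cfg$n_chrom))[seq_len(n)]
    idx_in_chrom <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
    start <- (idx_in_chrom - 1L) * (cfg$gene_length + 500L)

    retention <- sample(
      c("both", "At_deleted", "Aa_deleted"), n, replace = TRUE,
      prob = c(1 - cfg$fraction_At_deleted - cfg$fraction_Aa_deleted,
               cfg$fraction_At_deleted, cfg$fraction_Aa_deleted))
    in_cluster <- rep(FALSE, n)
    for (cl in cfg$cluster_spec) {
      sel <- which(chrom_of == cl$chrom &
                     idx_in_chrom >= cl$start_index &
                     idx_in_chrom < cl$start_index + cl$length)
      retention[sel] <- cl$state
      in_cluster[sel] <- TRUE
    }

    expressed <- stats::runif(n) >= cfg$fraction_unexpressed
    alpha <- stats::runif(n)

    # network membership drawn from genes retained in both genomes;
    # members adopt the network's bias direction with probability co_bias
    network_id <- rep(NA_character_, n)
    ns <- cfg$network_spec
    if (!is.null(ns) && ns$n_networks > 0) {
      eligible <- which(retention == "both" & !in_cluster)
      need <- ns$n_networks * ns$genes_per_network
      if (length(eligible) >= need) {
        members <- sample(eligible, need)
        network_id[members] <- rep(sprintf("net%03d", seq_len(ns$n_networks)),
                                   each = ns$genes_per_network)
        net_dir <- sample(c("At", "Aa"), ns$n_networks, replace = TRUE)
        for (k in seq_len(ns$n_networks)) {
          memb <- members[seq_len(ns$genes_per_network) +
                            (k - 1L) * ns$genes_per_network]
          adopt <- stats::runif(length(memb)) < ns$co_bias
          dir <- ifelse(adopt, net_dir[k],
                        ifelse(net_dir[k] == "Aa", "At", "Aa"))
          alpha[memb] <- ifelse(dir == "Aa",
                                stats::runif(length(memb), 0.75, 1),
                                stats::runif(length(memb), 0, 0.25))
          expressed[memb] <- TRUE
        }
      } else {
        warning("not enough eligible genes for the requested networks")
      }
    }

    alpha[retention == "At_deleted"] <- 1
    alpha[retention == "Aa_deleted"] <- 0

    truth <- data.frame(
      gene_id = gene_id, chrom = chrom_of, start = start,
      end = start + cfg$gene_length,
      retention_state = retention,
      expression_alpha_true = alpha,
      expressed = expressed,
      in_alteration_cluster = in_cluster,
      network_id = network_id,
      bias_direction = ifelse(alpha > 0.5, "Aa", "At"),
      divergence_rate = cfg$divergence,
      stringsAsFactors = FALSE)

    list(at = Biostrings::DNAStringSet(stats::setNames(at, gene_id)),
         aa = Biostrings::DNAStringSet(stats::setNames(aa, gene_id)),
         truth = truth)
  })
}

# per-gene probe layout and mismatch counts under each 25-mer; requires
# colinear orthologs (the array simulation keeps indel_rate = 0)
probe_layout <- function(cfg, seqs) {
  truth <- seqs$truth
  at <- as.character(seqs$at)
  aa <- as.character(seqs$aa)
  n_cap <- (cfg$gene_length - cfg$probe_length) %/% cfg$tiling_step + 1L
  out <- vector("list", nrow(truth))
  for (g in seq_len(nrow(truth))) {
    k <- min(max(5L, stats::rpois(1L, cfg$probes_per_gene)), n_cap)
    off <- (seq_len(k) - 1L) * cfg$tiling_step
    a1 <- strsplit(at[[g]], "", fixed = TRUE)[[1]]
    a2 <- strsplit(aa[[g]], "", fixed = TRUE)[[1]]
    mm <- vapply(off, function(s) {
      w <- (s + 1L):(s + cfg$probe_length)
      sum(a1[w] != a2[w])
    }, 0)
    # hybridization loss varies per mismatch (position and context
    # effects: terminal mismatches barely perturb the duplex, central
    # ones can be severe). Per-mismatch factors follow 1 - (1 - floor) *
    # Beta(2, 4), a continuum with mean signal_loss_per_mismatch and
    # floor 1 - 3 * (1 - loss) whose density vanishes both at zero loss
    # and at the maximum; factors are fixed per probe. Conserved probes
    # thus form a sharp ratio peak with a smooth one-sided tail of
    # diverged probes -- the structure the mode-based scaling and the
    # normality screen assume.
    lo <- 1 - 3 * (1 - cfg$signal_loss_per_mismatch)
    attn <- vapply(mm, function(m) {
      if (m == 0) 1 else prod(1 - (1 - lo) * stats::rbeta(m, 2, 4))
    }, 0)
    out[[g]] <- data.frame(
      gene_id = truth$gene_id[g], chrom = truth$chrom[g],
      pos = truth$start[g] + off, offset = off, mismatches = mm,
      attenuation = attn, stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, out)
  layout$probe_id <- sprintf("p%06d", seq_len(nrow(layout)))
  layout
}

#' Generate probe-level tiling-array intensities
#'
#' Places probes on the At reference every `tiling_step` bases, computes
#' the mismatch count of each 25-mer between the parental orthologs, and
#' draws replicate intensities under a multiplicative log-normal noise
#' model. Expected signals: At DNA hybridises fully; Aa DNA is attenuated
#' by `signal_loss_per_mismatch` per mismatched base under the probe;
#' F1As DNA is the average of the two parental expectations (equal dose);
#' As DNA respects the retention state (a deleted homoeolog contributes
#' nothing); As RNA mixes the homoeolog signals with weights
#' `(1 - alpha, alpha)` where `alpha` is the true Aa transcript share.
#' Intergenic probes carry DNA signal but no RNA signal.
#'
#' @param cfg a [sim_config()] object.
#' @param seqs output of [sim_parental_sequences()].
#' @param assays subset of assays to generate (noise draws are seeded per
#'   assay, so a subset reproduces exactly the rows of the full table).
#' @return a probe intensity table: long-format data.frame with columns
#'   probe_id, chrom, pos, gene_id, genotype, sample_type, replicate,
#'   intensity.
#' @export
sim_probe_intensities <- function(cfg, seqs, assays = .ASSAYS) {
  stopifnot(inherits(cfg, "homoeo_config"))
  assays <- match.arg(assays, .ASSAYS, several.ok = TRUE)
  if (cfg$indel_rate > 0) {
    stop("array simulation requires colinear orthologs (indel_rate = 0)")
  }
  if (!setequal(seqs$truth$gene_id, names(seqs$at))) {
    stop("missing sequence for some gene")
  }
  layout <- withr::with_seed(cfg$seed + 1L, probe_layout(cfg, seqs))
  truth <- seqs$truth

  withr::with_seed(cfg$seed + 2L, {
    base <- 2^stats::rnorm(nrow(truth), cfg$base_log2_mean, cfg$base_log2_sd)
    ebase <- ifelse(truth$expressed,
                    2^stats::rnorm(nrow(truth), cfg$expr_log2_mean,
                                   cfg$expr_log2_sd), 0)
  })

  gi <- match(layout$gene_id, truth$gene_id)
  attn <- layout$attenuation
  dose_at <- as.numeric(truth$retention_state[gi] != "At_deleted")
  dose_aa <- as.numeric(truth$retention_state[gi] != "Aa_deleted")
  alpha <- truth$expression_alpha_true[gi]

  expectation <- list(
    At_DNA = base[gi],
    Aa_DNA = base[gi] * attn,
    F1As_DNA = base[gi] * (1 + attn) / 2,
    As_DNA = base[gi] * (dose_at + dose_aa * attn) / 2,
    As_RNA = ebase[gi] * ((1 - alpha) + alpha * attn))

  # background control probes: no signal in any assay (gene_id NA).
  # They anchor the low-quantile background estimate of the "shift"
  # correction and the intergenic threshold of the expression call.
  if (cfg$n_intergenic > 0L) {
    ig <- data.frame(
      gene_id = NA_character_, chrom = "chr1",
      pos = max(layout$pos) + cfg$tiling_step * seq_len(cfg$n_intergenic),
      offset = NA_integer_, mismatches = 0L, attenuation = 1,
      probe_id = sprintf("ig%05d", seq_len(cfg$n_intergenic)),
      stringsAsFactors = FALSE)
    layout <- rbind(layout, ig)
    for (a in .ASSAYS) {
      expectation[[a]] <- c(expectation[[a]], rep(0, cfg$n_intergenic))
    }
  }

  out <- vector("list", length(assays))
  for (k in seq_along(assays)) {
    a <- assays[[k]]
    mu <- expectation[[a]] + cfg$background
    reps <- withr::with_seed(
      cfg$seed + 10L + match(a, .ASSAYS),
      vapply(seq_len(cfg$n_replicates), function(j) {
        mu * 2^stats::rnorm(length(mu), 0, cfg$noise_sd)
      }, numeric(length(mu))))
    gt <- sub("_(DNA|RNA)$", "", a)
    st <- sub("^.*_", "", a)
    out[[k]] <- data.frame(
      probe_id = rep(layout$probe_id, cfg$n_replicates),
      chrom = rep(layout$chrom, cfg$n_replicates),
      pos = rep(layout$pos, cfg$n_replicates),
      gene_id = rep(layout$gene_id, cfg$n_replicates),
      genotype = gt, sample_type = st,
      replicate = rep(seq_len(cfg$n_replicates), each = nrow(layout)),
      intensity = as.vector(reps),
      stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  tbl
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate paired-end reads from the allotetraploid transcriptome
#'
#' Draws sequencing fragments per expressed gene; each fragment originates
#' from the Aa homoeolog with probability `expression_alpha_true` and from
#' the At homoeolog otherwise. 72-base mates are taken from the two
#' fragment ends (mate 2 reverse-complemented), with substitution errors
#' at `read_error`. The true origin is recorded in the read name so that
#' read-partitioning accuracy can be checked against ground truth.
#'
#' @param cfg a [sim_config()] object.
#' @param seqs output of [sim_parental_sequences()].
#' @return data.frame with read_id, gene_id, origin ("At"/"Aa"), start,
#'   read1, read2.
#' @export
sim_reads <- function(cfg, seqs) {
  stopifnot(inherits(cfg, "homoeo_config"))
  if (cfg$read_length > cfg$gene_length) {
    stop("read length exceeds transcript length")
  }
  truth <- seqs$truth
  at <- as.character(seqs$at)
  aa <- as.character(seqs$aa)
  withr::with_seed(cfg$seed + 3L, {
    keep <- which(truth$expressed)
    out <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      g <- keep[ii]
      nfrag <- cfg$reads_per_gene
      origin <- ifelse(
        stats::runif(nfrag) < truth$expression_alpha_true[g], "Aa", "At")
      src <- ifelse(origin == "Aa", aa[[g]], at[[g]])
      len <- nchar(src)
      flen <- pmin(cfg$fragment_length, len)
      fstart <- vapply(len - flen + 1L,
                       function(m) sample.int(m, 1L), 0L)
      r1 <- substr(src, fstart, fstart + cfg$read_length - 1L)
      fend <- fstart + flen - 1L
      r2 <- revcomp(substr(src, fend - cfg$read_length + 1L, fend))
      r1 <- apply_read_errors(r1, cfg$read_error)
      r2 <- apply_read_errors(r2, cfg$read_error)
      out[[ii]] <- data.frame(
        read_id = sprintf("frag_%s_%05d|origin=%s",
                          truth$gene_id[g], seq_len(nfrag), origin),
        gene_id = truth$gene_id[g], origin = origin, start = fstart,
        read1 = r1, read2 = r2, stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    reads
  })
}

#' Generate a gene-interaction table with co-bias structure
#'
#' Emits all within-network gene pairs with high connectedness scores and
#' an equal number of random background pairs with low scores. Bias
#' concordance within networks is already encoded in the ground truth
#' (members adopt the network direction with probability `co_bias`), so
#' the edge list here only carries the connectedness structure.
#'
#' @param cfg a [sim_config()] object.
#' @param truth the truth table from [sim_parental_sequences()].
#' @return data.frame with gene_a, gene_b, connectedness.
#' @export
sim_network <- function(cfg, truth) {
  stopifnot(inherits(cfg, "homoeo_config"))
  withr::with_seed(cfg$seed + 4L, {
    nets <- split(truth$gene_id[!is.na(truth$network_id)],
                  truth$network_id[!is.na(truth$network_id)])
    edges <- do.call(rbind, lapply(nets, function(g) {
      if (length(g) < 2L) stop("network size < 2")
      cmb <- utils::combn(sort(g), 2L)
      data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
    edges$connectedness <- stats::runif(nrow(edges), 0.7, 1)
    # background: random pairs between genes, low connectedness
    nbg <- nrow(edges)
    a <- sample(truth$gene_id, nbg, replace = TRUE)
    b <- sample(truth$gene_id, nbg, replace = TRUE)
    ok <- a != b
    bg <- data.frame(gene_a = pmin(a[ok], b[ok]),
                     gene_b = pmax(a[ok], b[ok]),
                     connectedness = stats::runif(sum(ok), 0, 0.3),
                     stringsAsFactors = FALSE)
    out <- rbind(edges, bg)
    out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
  })
}

#' Write ortholog pairs to FASTA files
#'
#' @param seqs output of [sim_parental_sequences()].
#' @param at_path,aa_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_ortholog_fasta <- function(seqs, at_path, aa_path) {
  Biostrings::writeXStringSet(seqs$at, at_path)
  Biostrings::writeXStringSet(seqs$aa, aa_path)
  invisible(c(at_path, aa_path))
}

#' Write simulated paired reads to FASTQ files
#'
#' @param reads data.frame from [sim_reads()].
#' @param r1_path,r2_path output FASTQ paths for the two mates.
#' @return invisibly, the two paths.
#' @export
write_reads_fastq <- function(reads, r1_path, r2_path) {
  for (m in 1:2) {
    x <- Biostrings::DNAStringSet(reads[[paste0("read", m)]])
    names(x) <- paste0(reads$read_id, "/", m)
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(
      x, if (m == 1) r1_path else r2_path, format = "fastq", qualities = q)
  }
  invisible(c(r1_path, r2_path))
}
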