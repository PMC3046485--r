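# Multi-gene alteration scan: per-gene paired Wilcoxon tests of As vs
# F1As hybridization followed by a sliding-window search for regions in
# which almost all genes shift in the same direction.
#
# Note on the test: the per-gene comparison is a Wilcoxon signed-rank
# test on the paired per-probe mean differences (a rank-sum test is
# unpaired by definition, so the paired reading is the only coherent
# one). Zero differences are dropped before ranking, the exact null is
# used for up to 25 non-zero pairs and the normal approximation with
# continuity correction above that.

#' Per-gene paired Wilcoxon test of As vs F1As hybridization
#'
#' For every gene with at least `min_probes` probes, replicate-averaged
#' probe intensities of the evolved allotetraploid (As) are paired with
#' those of the resynthesised F1 (F1As) and tested with a Wilcoxon
#' signed-rank test. The signed statistic is the sum of signed ranks of
#' the non-zero differences; its sign gives the direction. Genes with too
#' few probes are marked untestable and excluded from the FDR adjustment.
#'
#' @param tbl preprocessed probe intensity table containing As DNA and
#'   F1As DNA assays.
#' @param min_probes minimum probes per gene for a testable call.
#' @param fdr Benjamini-Hochberg FDR threshold stored alongside calls.
#' @return data.frame with gene_id, chrom, pos (gene's first probe),
#'   n_probes, statistic, p_value, q_value, direction
#'   (higher_in_As / higher_in_F1As / none), testable.
#' @export
gene_diff_test <- function(tbl, min_probes = 5L, fdr = 0.05) {
  as_m <- assay_matrix(tbl, "As", "DNA")
  f1_m <- assay_matrix(tbl, "F1As", "DNA")
  common <- intersect(rownames(as_m), rownames(f1_m))
  meta <- unique(tbl[tbl$probe_id %in% common & !is.na(tbl$gene_id),
                     c("probe_id", "gene_id", "chrom", "pos")])
  x <- rowMeans(as_m[meta$probe_id, , drop = FALSE])
  y <- rowMeans(f1_m[meta$probe_id, , drop = FALSE])
  genes <- split(seq_len(nrow(meta)), meta$gene_id)
  res <- lapply(genes, function(ix) {
    d <- x[ix] - y[ix]
    chrom <- meta$chrom[ix[1]]
    pos <- min(meta$pos[ix])
    n <- length(d)
    if (n < min_probes) {
      return(data.frame(chrom = chrom, pos = pos, n_probes = n,
                        statistic = NA_real_, p_value = NA_real_,
                        direction = "none", testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    dn <- d[d != 0]
    if (!length(dn)) {
      stat <- 0
      p <- 1
      dir <- "none"
    } else {
      stat <- sum(sign(dn) * rank(abs(dn)))
      p <- suppressWarnings(stats::wilcox.test(
        dn, exact = length(dn) <= 25L, correct = TRUE)$p.value)
      dir <- if (stat > 0) "higher_in_As" else if (stat < 0)
        "higher_in_F1As" else "none"
    }
    data.frame(chrom = chrom, pos = pos, n_probes = n, statistic = stat,
               p_value = p, direction = dir, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene_id = names(genes), out)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  out$q_value[out$testable] <- stats::p.adjust(out$p_value[out$testable],
                                               method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Sliding-window scan for multi-gene alteration regions
#'
#' Slides a `window`-gene window (step 1) along each chromosome in gene
#' order and flags windows in which at least `min_same_dir` testable
#' genes shift in one direction and at least `min_sig` of those are
#' significant at the stored FDR threshold. Overlapping flagged windows
#' of equal direction are merged; region coordinates span the first to
#' the last gene of the merged run. The defaults (30 genes, 27
#' unidirectional, 9 significant) are the published thresholds.
#'
#' Chromosomes with fewer testable genes than `window` yield no regions.
#'
#' @param calls output of [gene_diff_test()].
#' @param window window size in genes.
#' @param min_same_dir minimum same-direction genes per window.
#' @param min_sig minimum significant same-direction genes per window.
#' @return data.frame of merged regions: chrom, start_gene_index,
#'   end_gene_index (1-based inclusive, in testable-gene order within the
#'   chromosome), start_bp, end_bp, n_genes, n_same_direction,
#'   n_significant, direction.
#' @export
scan_alteration_windows <- function(calls, window = 30L, min_same_dir = 27L,
                                    min_sig = 9L) {
  calls <- calls[calls$testable, , drop = FALSE]
  out <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    n <- nrow(cc)
    if (n < window) next
    run_count <- function(flag) {
      cs <- c(0, cumsum(flag))
      cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
    }
    for (dir in c("higher_in_As", "higher_in_F1As")) {
      nd <- run_count(cc$direction == dir)
      ns <- run_count(cc$direction == dir & cc$significant)
      hit <- which(nd >= min_same_dir & ns >= min_sig)
      if (!length(hit)) next
      # merge overlapping flagged windows of this direction
      grp <- cumsum(c(TRUE, diff(hit) >= window))
      for (g in split(hit, grp)) {
        s <- min(g)
        e <- max(g) + window - 1L
        span <- s:e
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_gene_index = s, end_gene_index = e,
          start_bp = cc$pos[s], end_bp = cc$pos[e],
          n_genes = length(span),
          n_same_direction = sum(cc$direction[span] == dir),
          n_significant = sum(cc$direction[span] == dir &
                                cc$significant[span]),
          direction = dir, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_gene_index = integer(),
                      end_gene_index = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_genes = integer(),
                      n_same_direction = integer(),
                      n_significant = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_gene_index), , drop = FALSE]
}

#' Export alteration regions as BED
#'
#' @param regions output of [scan_alteration_windows()].
#' @param path output BED path (0-based half-open intervals).
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start_bp,
                    regions$end_bp + 1L, regions$direction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
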