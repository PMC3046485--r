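# Chromosomal clusters of concordantly biased transcripts: centered
# running averages of the per-gene bias shift (delta alpha) along each
# chromosome, with significance from a genome-wide permutation null.

#' Centered running average of delta alpha along a chromosome
#'
#' @param delta numeric vector of per-gene delta-alpha values ordered by
#'   gene start coordinate.
#' @param w odd window size in genes.
#' @return numeric vector of length `length(delta) - w + 1`; ends are
#'   truncated (no padding).
#' @export
running_delta_alpha <- function(delta, w = 11L) {
  stopifnot(w %% 2L == 1L, w >= 1L)
  if (length(delta) < w) {
    return(numeric(0))
  }
  as.numeric(stats::filter(delta, rep(1 / w, w), sides = 2))[
    ((w - 1L) %/% 2L + 1L):(length(delta) - (w - 1L) %/% 2L)]
}

#' Genome-wide permutation test for clusters of biased transcripts
#'
#' Builds the null by shuffling delta-alpha values across all gene
#' positions genome-wide and recording, for each permutation, the global
#' maximum of the absolute running average. Observed clusters are maximal
#' runs where the absolute running average exceeds the `level` quantile
#' (default 97.5th percentile) of that null; each cluster's empirical p
#' is the fraction of permutations whose global maximum reaches the
#' cluster's mean running average (add-one estimator, so p is in (0, 1]).
#'
#' Positive delta alpha marks Aa-enriched transcription, negative marks
#' At-enriched. Chromosomes with fewer genes than the window are skipped.
#'
#' @param bias data.frame with columns chrom, pos, delta_alpha (one row
#'   per gene).
#' @param w odd running-average window (genes).
#' @param n_perm number of genome-wide permutations (at least 100).
#' @param level null quantile defining the cluster threshold.
#' @param seed integer seed.
#' @return list with `clusters` (chrom, start_index, end_index,
#'   start_bp, end_bp, n_genes, mean_delta, direction, p_value),
#'   `threshold`, and `tracks` (per-chromosome running averages).
#' @export
permutation_cluster_test <- function(bias, w = 11L, n_perm = 10000L,
                                     level = 0.975, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  bias <- bias[order(bias$chrom, bias$pos), , drop = FALSE]
  sizes <- table(bias$chrom)
  use <- names(sizes)[sizes >= w]
  chrom_ix <- lapply(use, function(ch) which(bias$chrom == ch))
  names(chrom_ix) <- use
  delta <- bias$delta_alpha

  tracks <- lapply(chrom_ix, function(ix) running_delta_alpha(delta[ix], w))

  perm_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      d <- sample(delta)
      max(vapply(chrom_ix, function(ix) {
        max(abs(running_delta_alpha(d[ix], w)))
      }, 0))
    }, 0)
  })
  thr <- stats::quantile(perm_max, level, names = FALSE)

  half <- (w - 1L) %/% 2L
  out <- list()
  for (ch in use) {
    tr <- tracks[[ch]]
    over <- abs(tr) > thr
    if (!any(over)) next
    # split exceeding centers into runs of identical sign
    centers <- which(over)
    grp <- cumsum(c(TRUE, diff(centers) > 1L |
                      sign(tr[centers[-1]]) !=
                        sign(tr[centers[-length(centers)]])))
    ix <- chrom_ix[[ch]]
    for (g in split(centers, grp)) {
      mean_delta <- mean(tr[g])
      s <- min(g)
      e <- max(g) + w - 1L  # full span of contributing genes
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_index = s, end_index = e,
        start_bp = bias$pos[ix[s]], end_bp = bias$pos[ix[e]],
        n_genes = e - s + 1L, mean_delta = mean_delta,
        direction = if (mean_delta > 0) "Aa_enriched" else "At_enriched",
        p_value = (1 + sum(perm_max >= abs(mean_delta))) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(chrom = character(), start_index = integer(),
               end_index = integer(), start_bp = numeric(),
               end_bp = numeric(), n_genes = integer(),
               mean_delta = numeric(), direction = character(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  list(clusters = clusters, threshold = thr, tracks = tracks)
}
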