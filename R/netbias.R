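# Network co-bias analysis: do interacting genes share the parent whose
# homoeolog they preferentially express? Two complementary views are
# provided, because "co-biased pairs" and "partitioned networks" are both
# natural readings of the question: (i) concordance of labelled gene
# pairs binned by connectedness, and (ii) a chi-square test of whole
# networks partitioned into co-At / mixed / co-Aa against a per-network
# binomial expectation.

#' Pair concordance by connectedness bin
#'
#' Keeps the gene pairs where both partners carry a significant bias
#' label, sorts them into `n_bins` equal-count bins of connectedness,
#' and reports the concordant fraction per bin (both At-like or both
#' Aa-like) with an ordinary least-squares fit of the fraction on the
#' bin's mean connectedness. Bins smaller than `min_bin` pairs are merged
#' with their left neighbour. A flat response (zero variance across bins)
#' is reported as a zero-slope fit with R-squared 0.
#'
#' @param pairs data.frame with gene_a, gene_b, connectedness.
#' @param labels data.frame with gene_id and label ("At_like",
#'   "Aa_like", anything else = not significantly biased).
#' @param n_bins number of equal-count bins.
#' @param min_bin minimum pairs per bin before merging.
#' @return list with `bins` (bin, n_pairs, mean_connectedness,
#'   fraction_concordant), `slope`, `r_squared`, `p_value`, `n_pairs`.
#' @export
concordance_by_bin <- function(pairs, labels, n_bins = 20L, min_bin = 5L) {
  lab <- stats::setNames(labels$label, labels$gene_id)
  la <- lab[pairs$gene_a]
  lb <- lab[pairs$gene_b]
  keep <- !is.na(la) & !is.na(lb) &
    la %in% c("At_like", "Aa_like") & lb %in% c("At_like", "Aa_like")
  pp <- pairs[keep, , drop = FALSE]
  if (!nrow(pp)) stop("no pairs with two significantly biased genes")
  conc <- la[keep] == lb[keep]
  o <- order(pp$connectedness)
  pp <- pp[o, , drop = FALSE]
  conc <- conc[o]
  n <- nrow(pp)
  bin <- floor((seq_len(n) - 1L) * n_bins / n) + 1L
  # merge undersized bins leftward
  repeat {
    cnt <- table(bin)
    small <- names(cnt)[cnt < min_bin]
    if (!length(small) || length(cnt) == 1L) break
    b <- as.integer(small[1])
    bin[bin == b] <- if (b > min(bin)) {
      max(bin[bin < b])
    } else {
      min(bin[bin > b])
    }
  }
  bins <- data.frame(
    bin = as.integer(names(table(bin))),
    n_pairs = as.integer(table(bin)),
    mean_connectedness = as.numeric(tapply(pp$connectedness, bin, mean)),
    fraction_concordant = as.numeric(tapply(conc, bin, mean)),
    row.names = NULL)
  if (stats::var(bins$fraction_concordant) == 0 || nrow(bins) < 3L) {
    return(list(bins = bins, slope = 0, r_squared = 0, p_value = NA_real_,
                n_pairs = n))
  }
  fit <- stats::lm(fraction_concordant ~ mean_connectedness, data = bins)
  sm <- summary(fit)
  list(bins = bins, slope = stats::coef(fit)[[2]],
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n_pairs = n)
}

#' Partition networks by homoeolog co-bias and test against expectation
#'
#' Networks are the connected components of the interaction graph
#' thresholded at `threshold` connectedness. Every network with at least
#' two significantly biased genes is classified co-At (all biased
#' members At-like), co-Aa, or mixed. Expected counts come from a
#' per-network binomial model: with `p` the global fraction of At-like
#' genes among all biased genes, a network with k biased members
#' contributes `p^k` to the co-At expectation, `(1-p)^k` to co-Aa, and
#' the remainder to mixed, so expected counts sum to the number of
#' classified networks by construction. The chi-square statistic with
#' df = 2 tests the observed partition against that expectation (see
#' [cobias_chisq()] for the test on externally supplied counts).
#'
#' @param pairs data.frame with gene_a, gene_b, connectedness.
#' @param labels data.frame with gene_id, label.
#' @param threshold connectedness threshold defining network edges.
#' @return list with `observed` (co_At, mixed, co_Aa), `expected`,
#'   `chi2`, `df`, `p_value`, `p_at` (global At fraction), `n_networks`,
#'   and `networks` (per-network membership and class).
#' @export
partition_networks <- function(pairs, labels, threshold = 0.5) {
  lab <- stats::setNames(labels$label, labels$gene_id)
  ed <- pairs[pairs$connectedness >= threshold, , drop = FALSE]
  if (!nrow(ed)) stop("no edges above the connectedness threshold")
  g <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)

  biased_all <- lab[!is.na(lab) & lab %in% c("At_like", "Aa_like")]
  p_at <- mean(biased_all == "At_like")
  if (p_at == 0 || p_at == 1) {
    stop("degenerate global bias fraction; test refused")
  }

  cls <- character(0)
  ks <- integer(0)
  nets <- list()
  for (i in seq_along(memb)) {
    gl <- lab[memb[[i]]]
    gl <- gl[!is.na(gl) & gl %in% c("At_like", "Aa_like")]
    if (length(gl) < 2L) next
    k <- length(gl)
    cl <- if (all(gl == "At_like")) "co_At" else
      if (all(gl == "Aa_like")) "co_Aa" else "mixed"
    cls <- c(cls, cl)
    ks <- c(ks, k)
    nets[[length(nets) + 1L]] <- data.frame(
      network = i, n_biased = k, class = cl, stringsAsFactors = FALSE)
  }
  if (!length(cls)) stop("no networks with >= 2 biased genes")
  observed <- c(co_At = sum(cls == "co_At"), mixed = sum(cls == "mixed"),
                co_Aa = sum(cls == "co_Aa"))
  e_at <- sum(p_at^ks)
  e_aa <- sum((1 - p_at)^ks)
  expected <- c(co_At = e_at, mixed = length(ks) - e_at - e_aa,
                co_Aa = e_aa)
  test <- cobias_chisq(observed, expected)
  c(test, list(p_at = p_at, n_networks = length(ks),
               networks = do.call(rbind, nets)))
}

#' Chi-square goodness of fit for a co-bias partition
#'
#' Computes `sum((obs - exp)^2 / exp)` with df = 2 and the upper-tail
#' p-value for a (co-At, mixed, co-Aa) partition. Accepts externally
#' supplied expected counts (e.g. a published table), so the test does
#' not depend on how the expectation was derived.
#'
#' @param observed,expected numeric vectors of length 3; the sums must
#'   agree within rounding (1% of the total).
#' @return list with `observed`, `expected`, `chi2`, `df`, `p_value`.
#' @export
cobias_chisq <- function(observed, expected) {
  stopifnot(length(observed) == 3L, length(expected) == 3L,
            all(expected > 0))
  if (abs(sum(observed) - sum(expected)) > 0.01 * sum(observed)) {
    stop("observed and expected totals disagree beyond rounding")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  list(observed = observed, expected = expected, chi2 = chi2, df = 2L,
       p_value = stats::pchisq(chi2, 2L, lower.tail = FALSE))
}
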