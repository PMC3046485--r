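# Gene-wise cross-genotype scaling and diagnostic-feature (DF) detection.
#
# For every gene the per-probe ratio of replicate-mean intensities
# X_i = T_i / A_i (At over Aa) forms a unimodal distribution whose peak
# is driven by probes conserved between the parents; that peak is the
# scaling factor applied to all Aa intensities of the gene. Genes whose
# log2 ratio distribution fails a Shapiro-Wilk normality screen are
# disregarded, as are genes with too few probes or where nearly every
# probe is a DF (the fastest-evolving genes cannot be normalized this
# way). DFs are probes whose log2 intensities differ between the
# genotypes by a Welch t-test under genome-wide Benjamini-Hochberg
# control, with the additional replicate-robustness requirement that the
# sign of the difference is unanimous across every replicate pairing.

#' Gene-wise scaling factor from the mode of the probe-ratio distribution
#'
#' @param a_mat,t_mat probes x replicates intensity matrices for the Aa
#'   and At genotype (same probe order).
#' @param min_probes minimum number of probes required.
#' @param alpha_norm significance level of the Shapiro-Wilk normality
#'   screen applied to the log2 ratios.
#' @return list with `x_max` (scaling factor), `ratios`, `shapiro_p`, and
#'   `passed`. A degenerate ratio distribution (all equal) passes with
#'   `shapiro_p = NA`.
#' @export
scaling_factor <- function(a_mat, t_mat, min_probes = 5L,
                           alpha_norm = 0.05) {
  stopifnot(nrow(a_mat) == nrow(t_mat))
  if (nrow(a_mat) < min_probes) stop("fewer than min_probes probes")
  A <- rowMeans(a_mat)
  T_ <- rowMeans(t_mat)
  if (any(A <= 0) || any(T_ <= 0)) stop("intensities must be positive")
  ratios <- T_ / A
  x_max <- ratio_mode(ratios)
  sp <- shapiro_p(log2(ratios))
  list(x_max = x_max, ratios = ratios, shapiro_p = sp,
       passed = is.na(sp) || sp >= alpha_norm)
}

#' Identify diagnostic features between the parental genotypes
#'
#' Runs the full scaling + DF stage over a preprocessed probe table:
#' per-gene scaling of the Aa intensities by the mode of the probe-ratio
#' distribution, the normality screen, a per-probe Welch t-test of log2
#' values (At vs scaled Aa) with genome-wide BH control (set
#' `fdr_scope = "gene"` for per-gene control), and the unanimous-sign
#' replicate-robustness rule. Genes where more than `max_df_fraction` of
#' probes are DFs are dropped as un-normalizable.
#'
#' On a parental-reference array a diagnostic feature arises from
#' mismatches weakening the hybridization of the non-reference parent,
#' so by default only probes where the reference (At) signal is the
#' stronger one are called DFs (`df_sign = "reference_stronger"`); this
#' also makes the calls robust to small errors in the gene scaling
#' factor, which can only push conserved probes toward the opposite
#' sign. Set `df_sign = "both"` to admit either direction.
#'
#' Every input gene is accounted for exactly once in the exclusion
#' ledger: analyzed, too_few_probes, failed_normality, or too_many_dfs.
#'
#' @param tbl preprocessed probe intensity table with At DNA and Aa DNA.
#' @param min_probes minimum probes per gene.
#' @param alpha_norm Shapiro-Wilk screen level.
#' @param max_df_fraction maximum tolerated DF fraction per gene.
#' @param fdr BH FDR threshold for DF calls.
#' @param fdr_scope `"genome"` (default) or `"gene"`.
#' @param df_sign `"reference_stronger"` (default) or `"both"`.
#' @return list with `probes` (per-probe statistics: gene_id, probe_id,
#'   t_mean, a_mean_scaled, statistic, p_value, q_value, sign, is_df),
#'   `genes` (per-gene ledger: gene_id, n_probes, x_max, shapiro_p,
#'   status, n_df), and `params`.
#' @export
find_diagnostic_features <- function(tbl, min_probes = 5L,
                                     alpha_norm = 0.05,
                                     max_df_fraction = 0.8, fdr = 0.05,
                                     fdr_scope = c("genome", "gene"),
                                     df_sign = c("reference_stronger",
                                                 "both")) {
  fdr_scope <- match.arg(fdr_scope)
  df_sign <- match.arg(df_sign)
  at_m <- assay_matrix(tbl, "At", "DNA")
  aa_m <- assay_matrix(tbl, "Aa", "DNA")
  meta <- unique(tbl[!is.na(tbl$gene_id),
                     c("probe_id", "gene_id")])
  meta <- meta[meta$probe_id %in% rownames(at_m) &
                 meta$probe_id %in% rownames(aa_m), , drop = FALSE]
  genes <- split(meta$probe_id, meta$gene_id)

  gene_rows <- list()
  probe_rows <- list()
  for (g in names(genes)) {
    pid <- genes[[g]]
    n <- length(pid)
    if (n < min_probes) {
      gene_rows[[g]] <- data.frame(
        gene_id = g, n_probes = n, x_max = NA_real_, shapiro_p = NA_real_,
        status = "too_few_probes", stringsAsFactors = FALSE)
      next
    }
    sf <- scaling_factor(aa_m[pid, , drop = FALSE],
                         at_m[pid, , drop = FALSE],
                         min_probes = min_probes, alpha_norm = alpha_norm)
    status <- if (sf$passed) "analyzed" else "failed_normality"
    gene_rows[[g]] <- data.frame(
      gene_id = g, n_probes = n, x_max = sf$x_max,
      shapiro_p = sf$shapiro_p, status = status, stringsAsFactors = FALSE)
    if (status != "analyzed") next
    a_scaled <- sf$x_max * aa_m[pid, , drop = FALSE]
    lt <- log2(at_m[pid, , drop = FALSE])
    la <- log2(a_scaled)
    w <- welch_rows(lt, la)
    probe_rows[[g]] <- data.frame(
      gene_id = g, probe_id = pid,
      t_mean = rowMeans(at_m[pid, , drop = FALSE]),
      a_mean_scaled = rowMeans(a_scaled),
      statistic = w$statistic, p_value = w$p_value,
      sign = ifelse(w$mean_diff > 0, 1L, ifelse(w$mean_diff < 0, -1L, 0L)),
      unanimous = unanimous_sign_rows(lt, la),
      stringsAsFactors = FALSE)
  }
  gene_tab <- do.call(rbind, gene_rows)
  rownames(gene_tab) <- NULL
  probe_tab <- do.call(rbind, probe_rows)
  if (is.null(probe_tab)) {
    probe_tab <- data.frame(gene_id = character(), probe_id = character(),
                            t_mean = numeric(), a_mean_scaled = numeric(),
                            statistic = numeric(), p_value = numeric(),
                            sign = integer(), unanimous = logical(),
                            q_value = numeric(), is_df = logical())
  } else {
    rownames(probe_tab) <- NULL
    ok <- !is.na(probe_tab$p_value)
    probe_tab$q_value <- NA_real_
    if (fdr_scope == "genome") {
      probe_tab$q_value[ok] <- stats::p.adjust(probe_tab$p_value[ok], "BH")
    } else {
      probe_tab$q_value[ok] <- stats::ave(
        probe_tab$p_value[ok], probe_tab$gene_id[ok],
        FUN = function(p) stats::p.adjust(p, "BH"))
    }
    probe_tab$is_df <- !is.na(probe_tab$q_value) &
      probe_tab$q_value < fdr & probe_tab$unanimous
    if (df_sign == "reference_stronger") {
      probe_tab$is_df <- probe_tab$is_df & probe_tab$sign > 0L
    }
  }

  ndf <- tapply(probe_tab$is_df, probe_tab$gene_id, sum)
  gene_tab$n_df <- as.integer(ndf[gene_tab$gene_id])
  gene_tab$n_df[is.na(gene_tab$n_df)] <- 0L
  too_many <- gene_tab$status == "analyzed" &
    gene_tab$n_df > max_df_fraction * gene_tab$n_probes
  gene_tab$status[too_many] <- "too_many_dfs"
  drop_genes <- gene_tab$gene_id[too_many]
  probe_tab$is_df[probe_tab$gene_id %in% drop_genes] <- FALSE

  list(probes = probe_tab, genes = gene_tab,
       params = list(min_probes = min_probes, alpha_norm = alpha_norm,
                     max_df_fraction = max_df_fraction, fdr = fdr,
                     fdr_scope = fdr_scope, df_sign = df_sign))
}
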