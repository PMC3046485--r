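# Shared fixtures: one small simulated cohort with its pipeline stages,
# built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_genes = 250L, seed = 42L)
    seqs <- sim_parental_sequences(cfg)
    tbl <- sim_probe_intensities(cfg, seqs)
    pp <- preprocess_probe_table(tbl)
    dfres <- find_diagnostic_features(pp)
    layout <- withr::with_seed(cfg$seed + 1L,
                               homoeobias:::probe_layout(cfg, seqs))
    .fixture_env$cohort <- list(cfg = cfg, seqs = seqs, tbl = tbl,
                                pp = pp, dfres = dfres, layout = layout)
  }
  .fixture_env$cohort
}

# brute-force affine-gap global alignment score by recursive enumeration
# (oracle for short sequences; same convention as align_ortholog_pair:
# a gap of length L costs gap_open + (L - 1) * gap_extend)
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = 3, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  sub_score <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  # state: position i in a, j in b, last move (0 none, 1 gap-in-a,
  # 2 gap-in-b); plain exponential recursion, fine for <= 10 bases
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) {
      return(0)
    }
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, sub_score(a[i], b[j]) + rec(i + 1, j + 1, 0L))
    }
    if (j <= length(b)) {
      cost <- if (last == 1L) gap_extend else gap_open
      best <- max(best, -cost + rec(i, j + 1, 1L))
    }
    if (i <= length(a)) {
      cost <- if (last == 2L) gap_extend else gap_open
      best <- max(best, -cost + rec(i + 1, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force minimizer of a 1-d sum-of-squares objective: coarse grid
# scan followed by an exact parabola-vertex polish (the objective is
# quadratic in the parameter, so the vertex through the three best grid
# points is exact to machine precision). Knows nothing of the closed form.
brute_force_minimize <- function(f, lower = -10, upper = 10,
                                 n_grid = 2001L) {
  xs <- seq(lower, upper, length.out = n_grid)
  ys <- vapply(xs, f, 0)
  i <- which.min(ys)
  i <- min(max(i, 2L), n_grid - 1L)
  x1 <- xs[i - 1]; x2 <- xs[i]; x3 <- xs[i + 1]
  f1 <- ys[i - 1]; f2 <- ys[i]; f3 <- ys[i + 1]
  num <- (x2 - x1)^2 * (f2 - f3) - (x2 - x3)^2 * (f2 - f1)
  den <- (x2 - x1) * (f2 - f3) - (x2 - x3) * (f2 - f1)
  x2 - 0.5 * num / den
}

# minimal probe intensity table for hand-constructed cases: one row per
# probe x genotype x sample x replicate from a named list of
# probes x replicates matrices, e.g. list(At_DNA = m1, Aa_DNA = m2)
toy_probe_table <- function(assays, gene_id = "g1", chrom = "chr1") {
  rows <- list()
  for (a in names(assays)) {
    m <- assays[[a]]
    gt <- sub("_(DNA|RNA)$", "", a)
    st <- sub("^.*_", "", a)
    for (j in seq_len(ncol(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = sprintf("p%03d", seq_len(nrow(m))),
        chrom = chrom, pos = seq_len(nrow(m)) * 35L,
        gene_id = gene_id, genotype = gt, sample_type = st,
        replicate = j, intensity = m[, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
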