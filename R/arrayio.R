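# Probe-table I/O and cross-array preprocessing (background correction,
# quantile normalization). Probe intensity tables are long-format
# data.frames with one row per (probe, genotype, sample_type, replicate);
# coordinates are 0-based reference positions of probe starts.

PROBE_TABLE_COLS <- c("probe_id", "chrom", "pos", "gene_id", "genotype",
                      "sample_type", "replicate", "intensity")

#' Validate a probe intensity table
#'
#' Checks the column contract, strictly positive numeric intensities,
#' uniqueness of (probe, genotype, sample_type, replicate) rows, and that
#' every probe maps to at most one gene.
#'
#' @param tbl data.frame to validate.
#' @return the table, invisibly, on success; otherwise an error naming
#'   the first offending row or column.
#' @export
validate_probe_table <- function(tbl) {
  miss <- setdiff(PROBE_TABLE_COLS, names(tbl))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(tbl$intensity)) stop("non-numeric intensity column")
  bad <- which(!is.finite(tbl$intensity) | tbl$intensity <= 0)
  if (length(bad)) {
    stop("non-positive intensity at row ", bad[1])
  }
  key <- paste(tbl$probe_id, tbl$genotype, tbl$sample_type, tbl$replicate)
  d <- which(duplicated(key))
  if (length(d)) {
    stop("duplicate (probe, genotype, sample_type, replicate) at row ", d[1])
  }
  map <- unique(tbl[, c("probe_id", "gene_id")])
  multi <- map$probe_id[duplicated(map$probe_id)]
  if (length(multi)) {
    stop("probe assigned to more than one gene: ", multi[1])
  }
  invisible(tbl)
}

#' Read a probe intensity table from a tab-delimited file
#'
#' @param path file path (plain or gzipped tab-delimited text with a
#'   header row).
#' @return validated probe intensity table.
#' @export
read_probe_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  tbl$gene_id <- as.character(tbl$gene_id)
  validate_probe_table(tbl)
  tbl
}

#' Write a probe intensity table to a tab-delimited file
#'
#' @param tbl probe intensity table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_probe_table <- function(tbl, path) {
  validate_probe_table(tbl)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize a set of arrays
#'
#' Makes the empirical intensity distribution of every array identical
#' (each sorted vector becomes the cross-array rank-wise mean) while
#' preserving within-array rank order. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param m numeric matrix, probes in rows, arrays in columns.
#' @return normalized matrix of the same shape.
#' @examples
#' quantile_normalize(cbind(c(1, 2, 3), c(4, 5, 6)))
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("intensities must be finite")
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Background-correct one array
#'
#' Method `"shift"` subtracts a low-quantile floor (an estimate of the
#' additive optical background) and re-floors the result at a small
#' positive constant so downstream log2 transforms stay defined; method
#' `"none"` is the identity. The exact convolution background model of
#' RMA is deliberately not reimplemented: the downstream statistics only
#' require comparable positive intensities.
#'
#' @param x numeric vector of positive intensities.
#' @param method `"shift"` or `"none"`.
#' @param floor_quantile quantile used as the background estimate.
#' @param floor_value positive constant used to re-floor.
#' @return corrected vector, strictly positive.
#' @export
background_correct <- function(x, method = c("shift", "none"),
                               floor_quantile = 0.05, floor_value = 1) {
  method <- match.arg(method)
  if (method == "none") {
    return(x)
  }
  pmax(x - stats::quantile(x, floor_quantile, names = FALSE), floor_value)
}

# pivot the long table into a probes x replicates matrix for one assay
assay_matrix <- function(tbl, genotype, sample_type) {
  sel <- tbl$genotype == genotype & tbl$sample_type == sample_type
  sub <- tbl[sel, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for assay ", genotype, " ", sample_type)
  reps <- sort(unique(sub$replicate))
  probes <- unique(sub$probe_id)
  m <- matrix(NA_real_, length(probes), length(reps),
              dimnames = list(probes, paste0("rep", reps)))
  for (j in seq_along(reps)) {
    r <- sub[sub$replicate == reps[j], ]
    m[match(r$probe_id, probes), j] <- r$intensity
  }
  if (anyNA(m)) stop("unbalanced replicates for ", genotype, " ", sample_type)
  m
}

#' Preprocess a probe intensity table
#'
#' Background-corrects every array and quantile-normalizes arrays in
#' groups. By default only the biological replicates of each (genotype,
#' sample type) are normalized together: replicates are exchangeable, so
#' forcing identical distributions is exactly right there. Setting
#' `join_as_f1as = TRUE` additionally normalizes the As and F1As DNA
#' arrays jointly; that grouping assumes the two genotypes share the
#' same intensity distribution, which is violated when an appreciable
#' fraction of genes changed copy number in the evolved allotetraploid
#' -- the joint quantile map then distorts exactly the As-vs-F1As
#' contrasts under study, so it is off by default. RNA arrays are
#' normalized separately from DNA by default (set `rna_with_dna = TRUE`
#' to pool the As RNA and As DNA arrays instead; the gene-wise dose
#' rescaling downstream makes this choice a second-order effect).
#'
#' @param tbl probe intensity table.
#' @param background background-correction method, see
#'   [background_correct()].
#' @param join_as_f1as normalize As DNA and F1As DNA arrays together.
#' @param rna_with_dna normalize As RNA arrays together with As DNA.
#' @param floor_quantile,floor_value passed to [background_correct()].
#' @return the table with intensities replaced by preprocessed values.
#' @export
preprocess_probe_table <- function(tbl, background = c("shift", "none"),
                                   join_as_f1as = FALSE,
                                   rna_with_dna = FALSE,
                                   floor_quantile = 0.05, floor_value = 1) {
  background <- match.arg(background)
  validate_probe_table(tbl)
  arr_key <- paste(tbl$genotype, tbl$sample_type, tbl$replicate, sep = ".")
  group <- paste(tbl$genotype, tbl$sample_type, sep = ".")
  if (join_as_f1as) {
    group[group %in% c("As.DNA", "F1As.DNA")] <- "As+F1As.DNA"
  }
  if (rna_with_dna) {
    group[group %in% c("As.RNA", if (join_as_f1as) "As+F1As.DNA" else
      "As.DNA")] <- "As.DNA+RNA"
  }
  out <- tbl
  for (g in unique(group)) {
    rows <- which(group == g)
    arrays <- unique(arr_key[rows])
    # probes x arrays matrix within the group
    probes <- unique(tbl$probe_id[rows])
    m <- matrix(NA_real_, length(probes), length(arrays),
                dimnames = list(probes, arrays))
    idx <- cbind(match(tbl$probe_id[rows], probes),
                 match(arr_key[rows], arrays))
    m[idx] <- tbl$intensity[rows]
    if (anyNA(m)) stop("arrays in group ", g, " differ in probe content")
    for (j in seq_len(ncol(m))) {
      m[, j] <- background_correct(m[, j], background,
                                   floor_quantile, floor_value)
    }
    m <- quantile_normalize(m)
    out$intensity[rows] <- m[idx]
  }
  out
}

#' Write gene models to GFF3
#'
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open coordinates; converted to 1-based closed GFF3 on output).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    ID = genes$gene_id, type = "gene")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' @param path GFF3 (uses the ID attribute) or BED (uses the name
#'   column) file of gene models.
#' @return data.frame with gene_id, chrom, start, end in 0-based
#'   half-open coordinates.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  id <- if (!is.null(gr$ID)) gr$ID else gr$name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
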