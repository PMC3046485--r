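# Read-based validation: global alignment of ortholog pairs to extract
# diagnostic variants, assignment of reads to their parental homoeolog by
# variant voting, length-normalised quantification (FPK), and per-gene
# homoeolog divergence.
#
# Scoring convention: match +1, mismatch -1; a gap of length L costs
# gap_open + (L - 1) * gap_extend (default 3 + (L-1)*1). N matches
# nothing and nothing matches N (score 0), and N columns never become
# variants.

nuc_submat <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

check_nucleotides <- function(x) {
  if (!grepl("^[ACGTN]+$", x)) {
    stop("sequences must contain only A/C/G/T/N")
  }
}

#' Globally align an ortholog pair and extract diagnostic variants
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment()])
#' of the At and Aa orthologs of one gene. Mismatch columns become SNP
#' variants, runs of gap columns become insertion/deletion variants
#' (insertions are bases present only in Aa, deletions bases present only
#' in At). Positions are 0-based coordinates on the respective ungapped
#' sequence; for indels, the position of the sequence lacking the bases
#' is the position of the last base before the gap. Divergence is the
#' fraction of aligned columns that are variant columns (mismatch or
#' gap); N columns are never variants.
#'
#' @param at_seq,aa_seq nucleotide strings (A/C/G/T/N).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; the
#'   first gapped base costs `gap_open`, each further base `gap_extend`.
#' @return an `ortholog_alignment` list: at_seq, aa_seq, score,
#'   aligned_at, aligned_aa, n_columns, variants (data.frame: type,
#'   at_pos, aa_pos, at_allele, aa_allele), n_variant_columns,
#'   divergence.
#' @export
align_ortholog_pair <- function(at_seq, aa_seq, match = 1, mismatch = -1,
                                gap_open = 3, gap_extend = 1) {
  at_seq <- toupper(as.character(at_seq))
  aa_seq <- toupper(as.character(aa_seq))
  check_nucleotides(at_seq)
  check_nucleotides(aa_seq)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(at_seq), Biostrings::DNAString(aa_seq),
    type = "global", substitutionMatrix = nuc_submat(match, mismatch),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  a1 <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  n_col <- length(a1)

  i_at <- cumsum(a1 != "-")  # 1-based position on At at each column
  i_aa <- cumsum(a2 != "-")
  is_gap <- a1 == "-" | a2 == "-"
  is_snp <- !is_gap & a1 != a2 & a1 != "N" & a2 != "N"

  vars <- list()
  if (any(is_snp)) {
    w <- which(is_snp)
    vars[[1]] <- data.frame(
      type = "SNP", at_pos = i_at[w] - 1L, aa_pos = i_aa[w] - 1L,
      at_allele = a1[w], aa_allele = a2[w], stringsAsFactors = FALSE)
  }
  if (any(is_gap)) {
    w <- which(is_gap)
    grp <- cumsum(c(TRUE, diff(w) > 1L |
                      (a1[w][-1] == "-") != (a1[w][-length(w)] == "-")))
    for (g in split(w, grp)) {
      if (a1[g[1]] == "-") {  # bases present only in Aa: insertion
        vars[[length(vars) + 1L]] <- data.frame(
          type = "insertion", at_pos = i_at[g[1]] - 1L,
          aa_pos = i_aa[g[1]] - 1L, at_allele = "-",
          aa_allele = paste(a2[g], collapse = ""),
          stringsAsFactors = FALSE)
      } else {              # bases present only in At: deletion in Aa
        vars[[length(vars) + 1L]] <- data.frame(
          type = "deletion", at_pos = i_at[g[1]] - 1L,
          aa_pos = i_aa[g[1]] - 1L,
          at_allele = paste(a1[g], collapse = ""), aa_allele = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(vars)) {
    v <- do.call(rbind, vars)
    v[order(v$at_pos, v$aa_pos), , drop = FALSE]
  } else {
    data.frame(type = character(), at_pos = integer(),
               aa_pos = integer(), at_allele = character(),
               aa_allele = character(), stringsAsFactors = FALSE)
  }
  n_var_col <- sum(is_snp) + sum(is_gap)
  structure(list(
    at_seq = at_seq, aa_seq = aa_seq, score = Biostrings::score(pa),
    aligned_at = paste(a1, collapse = ""),
    aligned_aa = paste(a2, collapse = ""), n_columns = n_col,
    variants = variants, n_variant_columns = n_var_col,
    divergence = n_var_col / n_col), class = "ortholog_alignment")
}

#' Align every ortholog pair of two sequence sets
#'
#' @param at_set,aa_set named [Biostrings::DNAStringSet] objects (or
#'   character vectors) with matching gene names.
#' @param ... passed to [align_ortholog_pair()].
#' @return named list of `ortholog_alignment` objects.
#' @export
align_ortholog_pairs <- function(at_set, aa_set, ...) {
  at <- stats::setNames(as.character(at_set), names(at_set))
  aa <- stats::setNames(as.character(aa_set), names(aa_set))
  genes <- intersect(names(at), names(aa))
  if (!length(genes)) stop("no shared gene names between the two sets")
  stats::setNames(
    lapply(genes, function(g) align_ortholog_pair(at[[g]], aa[[g]], ...)),
    genes)
}

#' Per-gene divergence between two alignable sequences
#'
#' Convenience wrapper around [align_ortholog_pair()] returning only the
#' variant-column fraction; used e.g. to measure how far a homoeolog
#' within the allotetraploid has drifted from its parental reference.
#'
#' @param seq_a,seq_b nucleotide strings.
#' @param ... passed to [align_ortholog_pair()].
#' @return divergence in `[0, 1]` (variant columns / aligned columns).
#' @export
homoeolog_divergence <- function(seq_a, seq_b, ...) {
  align_ortholog_pair(seq_a, seq_b, ...)$divergence
}

# read base at a given ungapped subject position, from the aligned
# pattern/subject strings of one global-local alignment
read_base_at <- function(pat_chars, sub_chars, sub_start, positions) {
  sub_pos <- sub_start - 1L + cumsum(sub_chars != "-")
  vapply(positions, function(p) {
    col <- match(p, sub_pos * (sub_chars != "-"))
    if (is.na(col)) NA_character_ else pat_chars[col]
  }, "")
}

#' Assign reads to their parental homoeolog by diagnostic-variant voting
#'
#' Each mate is placed on both orthologs of its gene by global-local
#' alignment; reads whose best placement has more than `max_mismatches`
#' mismatches are dropped as unmapped. At every diagnostic SNP overlapped
#' by the placement (in the frame of the better-scoring ortholog), the
#' read base votes At or Aa according to which allele it matches; votes
#' from the two mates are pooled per fragment. Indel variants do not
#' vote (SNP votes carry essentially all of the signal at realistic
#' divergence). Calls: `At` when at_support >= 1 and aa_support is at or
#' below `conflict_tol` (and symmetrically `Aa`); `ambiguous` when no
#' diagnostic site is overlapped; `conflicting` when both sides exceed
#' the tolerance.
#'
#' @param reads data.frame with read_id, gene_id, read1, read2 (read2
#'   may be NA for single-end fragments; mate 2 is assumed
#'   reverse-complemented, as sequenced).
#' @param alignments named list from [align_ortholog_pairs()].
#' @param refs list with `at` and `aa` named sequence sets.
#' @param max_mismatches mismatch cap for a valid placement.
#' @param conflict_tol opposing votes tolerated before a call flips to
#'   `conflicting`.
#' @return data.frame with read_id, gene_id, informative_sites,
#'   at_support, aa_support, call (At / Aa / ambiguous / conflicting /
#'   unmapped).
#' @export
assign_reads <- function(reads, alignments, refs, max_mismatches = 10L,
                         conflict_tol = 0L) {
  at <- stats::setNames(as.character(refs$at), names(refs$at))
  aa <- stats::setNames(as.character(refs$aa), names(refs$aa))
  sm <- nuc_submat()
  out <- vector("list", length(unique(reads$gene_id)))
  k <- 0L
  for (g in unique(reads$gene_id)) {
    if (is.null(alignments[[g]])) next
    vr <- alignments[[g]]$variants
    snp <- vr[vr$type == "SNP", , drop = FALSE]
    rr <- reads[reads$gene_id == g, , drop = FALSE]
    mates <- list(rr$read1,
                  if ("read2" %in% names(rr)) rr$read2 else NULL)
    at_votes <- aa_votes <- info <- nmm_best <- rep(0L, nrow(rr))
    for (mate in seq_along(mates)) {
      m <- mates[[mate]]
      if (is.null(m)) next
      ok <- which(!is.na(m) & nzchar(m))
      if (!length(ok)) next
      seqs <- if (mate == 2L) revcomp(m[ok]) else m[ok]
      pats <- Biostrings::DNAStringSet(seqs)
      al_at <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(at[[g]]), type = "global-local",
        substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
      al_aa <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(aa[[g]]), type = "global-local",
        substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
      sc_at <- Biostrings::score(al_at)
      sc_aa <- Biostrings::score(al_aa)
      use_at <- sc_at >= sc_aa
      nmm <- pmin(Biostrings::nmismatch(al_at), Biostrings::nmismatch(al_aa))
      nmm_best[ok] <- pmax(nmm_best[ok], nmm)
      p_at <- as.character(Biostrings::pattern(al_at))
      s_at <- as.character(Biostrings::subject(al_at))
      st_at <- Biostrings::start(Biostrings::subject(al_at))
      p_aa <- as.character(Biostrings::pattern(al_aa))
      s_aa <- as.character(Biostrings::subject(al_aa))
      st_aa <- Biostrings::start(Biostrings::subject(al_aa))
      if (!nrow(snp)) next
      for (j in seq_along(ok)) {
        i <- ok[j]
        if (use_at[j]) {
          b <- read_base_at(strsplit(p_at[j], "")[[1]],
                            strsplit(s_at[j], "")[[1]], st_at[j],
                            snp$at_pos + 1L)
        } else {
          b <- read_base_at(strsplit(p_aa[j], "")[[1]],
                            strsplit(s_aa[j], "")[[1]], st_aa[j],
                            snp$aa_pos + 1L)
        }
        hit <- !is.na(b) & b != "-"
        info[i] <- info[i] + sum(hit)
        at_votes[i] <- at_votes[i] + sum(hit & b == snp$at_allele)
        aa_votes[i] <- aa_votes[i] + sum(hit & b == snp$aa_allele)
      }
    }
    call <- rep("ambiguous", nrow(rr))
    call[at_votes >= 1L & aa_votes <= conflict_tol] <- "At"
    call[aa_votes >= 1L & at_votes <= conflict_tol] <- "Aa"
    call[at_votes > conflict_tol & aa_votes > conflict_tol] <- "conflicting"
    call[info == 0L] <- "ambiguous"
    call[nmm_best > max_mismatches] <- "unmapped"
    k <- k + 1L
    out[[k]] <- data.frame(
      read_id = rr$read_id, gene_id = g, informative_sites = info,
      at_support = at_votes, aa_support = aa_votes, call = call,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Length-normalised homoeolog read counts (FPK)
#'
#' Counts called fragments per homoeolog and normalises by the exon
#' model length in kilobases (fragments per kilobase). There is
#' deliberately no per-million term: FPK compares the two orthologs of
#' one gene within a single library, where the library-size factor
#' cancels. Ambiguous and conflicting fragments are excluded from both
#' counts but reported.
#'
#' @param assignments output of [assign_reads()].
#' @param lengths data.frame with gene_id, at_length, aa_length (bases,
#'   positive).
#' @return data.frame per gene: at_reads, aa_reads, n_ambiguous,
#'   n_conflicting, at_fpk, aa_fpk, ratio (aa share; NA when no called
#'   fragments).
#' @export
fpk_quantify <- function(assignments, lengths) {
  if (any(lengths$at_length <= 0 | lengths$aa_length <= 0)) {
    stop("zero-length exon model")
  }
  out <- lengths[, "gene_id", drop = FALSE]
  cnt <- function(what) {
    v <- tapply(assignments$call == what, assignments$gene_id, sum)
    ifelse(is.na(v[out$gene_id]), 0L, v[out$gene_id])
  }
  out$at_reads <- as.integer(cnt("At"))
  out$aa_reads <- as.integer(cnt("Aa"))
  out$n_ambiguous <- as.integer(cnt("ambiguous"))
  out$n_conflicting <- as.integer(cnt("conflicting"))
  out$at_fpk <- out$at_reads / (lengths$at_length / 1000)
  out$aa_fpk <- out$aa_reads / (lengths$aa_length / 1000)
  tot <- out$at_fpk + out$aa_fpk
  out$ratio <- ifelse(tot > 0, out$aa_fpk / tot, NA_real_)
  out$no_reads <- out$at_reads + out$aa_reads == 0L
  rownames(out) <- NULL
  out
}

#' Concordance between read-based and array-based bias estimates
#'
#' Ordinary least-squares fit of the read-derived Aa share
#' (`aa_fpk / (aa_fpk + at_fpk)`) on the array-derived alpha estimate
#' across genes measured by both platforms. With fewer than `min_genes`
#' complete genes only the merged table is returned (no fit).
#'
#' @param fpk output of [fpk_quantify()].
#' @param alpha data.frame with gene_id and alpha1 (array estimates).
#' @param min_genes minimum genes required to fit.
#' @return list with `table` (gene_id, array_alpha, read_ratio),
#'   `r_squared`, `p_value`, `slope`, `n` (fit fields NA below
#'   `min_genes`).
#' @export
concordance_with_array <- function(fpk, alpha, min_genes = 10L) {
  m <- merge(fpk[, c("gene_id", "ratio")],
             alpha[, c("gene_id", "alpha1")], by = "gene_id")
  m <- m[is.finite(m$ratio) & is.finite(m$alpha1), , drop = FALSE]
  tab <- data.frame(gene_id = m$gene_id, array_alpha = m$alpha1,
                    read_ratio = m$ratio, stringsAsFactors = FALSE)
  if (nrow(tab) < min_genes) {
    return(list(table = tab, r_squared = NA_real_, p_value = NA_real_,
                slope = NA_real_, n = nrow(tab)))
  }
  fit <- stats::lm(read_ratio ~ array_alpha, data = tab)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(table = tab, r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], slope = stats::coef(fit)[[2]],
       n = nrow(tab))
}

#' Load pre-mapped reads from a SAM/BAM file
#'
#' Alternative entry to the internal read placement: accepts alignments
#' produced by an external mapper against the ortholog sequences (one
#' reference per gene, reference names = gene ids). Records are grouped
#' into fragments by query name; the first mate's bases are kept in
#' reference orientation and the second mate's are reverse-complemented
#' back to sequencing orientation, matching the layout produced by
#' [sim_reads()], so the result feeds directly into [assign_reads()]
#' (which re-places each mate on both orthologs).
#'
#' @param path SAM or BAM file path.
#' @return data.frame with read_id, gene_id, read1, read2.
#' @export
read_sam_reads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "seq")))[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  qn <- b$qname[mapped]
  rn <- as.character(b$rname)[mapped]
  sq <- as.character(b$seq)[mapped]
  second <- bitwAnd(b$flag[mapped], 128L) > 0L
  sq[second] <- revcomp(sq[second])
  frag <- split(seq_along(qn), qn)
  out <- lapply(names(frag), function(q) {
    ix <- frag[[q]]
    i1 <- ix[!second[ix]][1]
    i2 <- ix[second[ix]][1]
    data.frame(read_id = q, gene_id = rn[ix[1]],
               read1 = if (is.na(i1)) sq[i2] else sq[i1],
               read2 = if (is.na(i1) || is.na(i2)) NA_character_ else
                 sq[i2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
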