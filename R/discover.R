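# Full-length copy discovery: paired-LTR scanning with family size windows,
# internal-CDS validation and TSD extraction/filtering.

# Seed-and-extend search for LTR consensus hits on one strand of a sequence.
# Exact k-mer seeds are clustered by projected start position; each cluster is
# refined with a local affine-gap alignment of the consensus against a window.
find_ltr_hits <- function(subject_chr, ltr, min_identity, min_coverage,
                          k = 12L, min_seeds = 5L) {
  L <- nchar(ltr)
  if (L < k) stop("LTR consensus shorter than seed length")
  kmers <- Biostrings::DNAStringSet(substring(ltr, 1:(L - k + 1), k:L))
  keep <- !grepl("N", as.character(kmers), fixed = TRUE)
  offs <- which(keep)
  pd <- Biostrings::PDict(kmers[keep])
  subj <- Biostrings::DNAString(subject_chr)
  mt <- Biostrings::matchPDict(pd, subj)
  starts <- IRanges::start(mt)
  nhit <- S4Vectors::elementNROWS(mt)
  if (sum(nhit) == 0L) return(NULL)
  proj <- unlist(starts, use.names = FALSE) - rep(offs, nhit) + 1L
  proj <- sort(proj)
  gap_tol <- max(30L, round(0.2 * L))
  cl <- cumsum(c(1L, diff(proj) > gap_tol))
  submat <- dna_submat()
  hits <- list()
  slen <- nchar(subject_chr)
  for (g in split(proj, cl)) {
    if (length(g) < min_seeds) next
    est <- round(stats::median(g))
    pad <- max(30L, round(0.15 * L))
    w0 <- max(1L, est - pad)
    w1 <- min(slen, est + L - 1L + pad)
    win <- Biostrings::subseq(subj, w0, w1)
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ltr), win,
      type = "local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    cols <- Biostrings::nchar(aln)
    identity <- Biostrings::nmatch(aln) / cols
    coverage <- IRanges::width(Biostrings::pattern(aln)) / L
    if (identity < min_identity || coverage < min_coverage) next
    # extend to full consensus coverage: local alignment trims mutated
    # terminal bases, which would shift element boundaries and TSD windows
    ps <- IRanges::start(Biostrings::pattern(aln))
    pe <- IRanges::end(Biostrings::pattern(aln))
    s <- max(1L, w0 + IRanges::start(Biostrings::subject(aln)) - 1L - (ps - 1L))
    e <- min(slen, w0 + IRanges::end(Biostrings::subject(aln)) - 1L + (L - pe))
    hits[[length(hits) + 1L]] <- data.frame(
      start = s, end = e, score = Biostrings::score(aln),
      identity = identity, coverage = coverage)
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  # drop redundant overlapping hits, best score first
  h <- h[order(-h$score, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      later <- (i + 1):nrow(h)
      ov <- pmin(h$end[later], h$end[i]) - pmax(h$start[later], h$start[i]) + 1
      keep[later][ov > 0.5 * pmin(h$end[later] - h$start[later] + 1,
                                  h$end[i] - h$start[i] + 1)] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

# Anchored local alignment of the internal consensus against a candidate
# internal region, in chunks (keeps the dynamic program near-linear in the
# element length). Returns aggregate coverage and identity.
validate_cds <- function(region_chr, internal, chunk = 1500L, margin = 300L) {
  ilen <- nchar(internal)
  rlen <- nchar(region_chr)
  if (rlen < 1L) return(list(coverage = 0, identity = 0))
  submat <- dna_submat()
  starts <- seq(1L, ilen, by = chunk)
  aligned <- 0; matched <- 0; cols_total <- 0
  for (s in starts) {
    e <- min(ilen, s + chunk - 1L)
    r0 <- max(1L, s - margin)
    r1 <- min(rlen, e + margin)
    if (r1 < r0) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(internal, s, e)),
      Biostrings::DNAString(substr(region_chr, r0, r1)),
      type = "local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    aligned <- aligned + IRanges::width(Biostrings::pattern(aln))
    matched <- matched + Biostrings::nmatch(aln)
    cols_total <- cols_total + Biostrings::nchar(aln)
  }
  list(coverage = aligned / ilen,
       identity = if (cols_total > 0) matched / cols_total else 0)
}

#' Find full-length retrotransposon copies by paired-LTR scanning
#'
#' Scans both strands of a genome for hits of the family LTR consensus, pairs
#' hits on the same strand whose total span (5' LTR start to 3' LTR end)
#' falls in one of the family's size windows, and validates candidates by
#' local alignment of the internal region against the internal consensus
#' (discarding cases in which two LTRs happen to lie at the right distance by
#' chance). Overlapping candidates are resolved greedily by descending
#' combined LTR alignment score (ties to the leftmost start).
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param family A [family_model].
#' @param min_ltr_identity,min_ltr_coverage Identity and consensus-coverage
#'   thresholds for individual LTR hits (defaults 0.8 each).
#' @param cds_min_coverage,cds_min_identity Internal-region validation
#'   thresholds: the internal consensus must align over at least this
#'   fraction of its length (default 0.5) at at least this identity
#'   (default 0.7).
#' @return A [GenomicRanges::GRanges] of full-length copies with metadata
#'   columns `copy_id`, `family`, LTR sub-interval coordinates
#'   (`ltr5_start`..`ltr3_end`, genomic), `ltr_score`, `cds_identity`,
#'   `cds_coverage` and `cds_validated`. Minus-strand copies are reported in
#'   genomic coordinates with `strand == "-"`.
#' @export
find_full_length_copies <- function(genome, family,
                                    min_ltr_identity = 0.8,
                                    min_ltr_coverage = 0.8,
                                    cds_min_coverage = 0.5,
                                    cds_min_identity = 0.7) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet") || length(genome) == 0L ||
      any(Biostrings::width(genome) == 0L))
    stop("genome must be a non-empty DNAStringSet (or FASTA path)")
  if (!inherits(family, "family_model")) stop("family must be a family_model")
  win <- family$size_windows
  max_span <- max(win[, 2])
  out <- list()
  for (chrom in names(genome)) {
    chr_fwd <- as.character(genome[[chrom]])
    glen <- nchar(chr_fwd)
    for (strand in c("+", "-")) {
      subject_chr <- if (strand == "+") chr_fwd else revcomp_chr(chr_fwd)
      hits <- find_ltr_hits(subject_chr, family$ltr_consensus,
                            min_ltr_identity, min_ltr_coverage)
      if (is.null(hits) || nrow(hits) < 2L) next
      cand <- list()
      for (i in seq_len(nrow(hits) - 1L)) {
        for (j in (i + 1L):nrow(hits)) {
          span <- hits$end[j] - hits$start[i] + 1
          if (span > max_span) break
          if (hits$start[j] <= hits$end[i]) next
          if (!any(span >= win[, 1] & span <= win[, 2])) next
          region <- substr(subject_chr, hits$end[i] + 1L, hits$start[j] - 1L)
          v <- validate_cds(region, family$internal_consensus)
          if (v$coverage < cds_min_coverage || v$identity < cds_min_identity)
            next
          cand[[length(cand) + 1L]] <- data.frame(
            start = hits$start[i], end = hits$end[j],
            l5s = hits$start[i], l5e = hits$end[i],
            l3s = hits$start[j], l3e = hits$end[j],
            score = hits$score[i] + hits$score[j],
            cds_identity = v$identity, cds_coverage = v$coverage)
        }
      }
      if (!length(cand)) next
      cd <- do.call(rbind, cand)
      cd <- cd[order(-cd$score, cd$start), , drop = FALSE]
      keep <- rep(TRUE, nrow(cd))
      for (i in seq_len(nrow(cd))) {
        if (!keep[i]) next
        if (i < nrow(cd)) {
          later <- (i + 1):nrow(cd)
          keep[later][cd$start[later] <= cd$end[i] &
                        cd$end[later] >= cd$start[i]] <- FALSE
        }
      }
      cd <- cd[keep, , drop = FALSE]
      # map to forward-strand genomic coordinates; in the scanned orientation
      # the left hit is the element's 5' LTR
      if (strand == "+") {
        df <- data.frame(chrom = chrom, start = cd$start, end = cd$end,
                         strand = strand,
                         ltr5_start = cd$l5s, ltr5_end = cd$l5e,
                         ltr3_start = cd$l3s, ltr3_end = cd$l3e,
                         ltr_score = cd$score,
                         cds_identity = cd$cds_identity,
                         cds_coverage = cd$cds_coverage)
      } else {
        flip <- function(p) glen - p + 1L
        df <- data.frame(chrom = chrom, start = flip(cd$end),
                         end = flip(cd$start), strand = strand,
                         ltr5_start = flip(cd$l5e), ltr5_end = flip(cd$l5s),
                         ltr3_start = flip(cd$l3e), ltr3_end = flip(cd$l3s),
                         ltr_score = cd$score,
                         cds_identity = cd$cds_identity,
                         cds_coverage = cd$cds_coverage)
      }
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  span <- df$end - df$start + 1
  stopifnot(all(vapply(span, function(s)
    any(s >= win[, 1] & s <= win[, 2]), TRUE)))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- data.frame(
    copy_id = sprintf("%s_c%04d", family$name, seq_len(nrow(df))),
    family = family$name,
    df[, c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
           "ltr_score", "cds_identity", "cds_coverage")],
    cds_validated = TRUE)
  GenomeInfoDb::seqlengths(gr)[names(genome)] <- Biostrings::width(genome)
  gr
}

#' Extract target-site duplications flanking annotated copies
#'
#' Reads `tsd_length` bases immediately 5' and 3' of each element on the
#' forward genomic strand (regardless of element strand) and reports their
#' Hamming distance. Copies whose flank is truncated by a contig edge get
#' `tsd_mismatches = NA` and are flagged.
#'
#' @param copies A `GRanges` of copies (e.g. from
#'   [find_full_length_copies()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param tsd_length TSD length in bp (default 5).
#' @return `copies` with metadata columns `tsd5`, `tsd3`, `tsd_mismatches`
#'   and `tsd_truncated` added.
#' @export
extract_tsd <- function(copies, genome, tsd_length = 5L) {
  n <- length(copies)
  tsd5 <- tsd3 <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  trunc <- rep(FALSE, n)
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(copies)[i])
    chr <- genome[[chrom]]
    s <- IRanges::start(copies)[i]; e <- IRanges::end(copies)[i]
    if (s - tsd_length < 1L || e + tsd_length > length(chr)) {
      trunc[i] <- TRUE
      next
    }
    tsd5[i] <- as.character(Biostrings::subseq(chr, s - tsd_length, s - 1L))
    tsd3[i] <- as.character(Biostrings::subseq(chr, e + 1L, e + tsd_length))
    mm[i] <- hamming(tsd5[i], tsd3[i])
  }
  copies$tsd5 <- tsd5
  copies$tsd3 <- tsd3
  copies$tsd_mismatches <- mm
  copies$tsd_truncated <- trunc
  copies
}

#' Filter copies by TSD similarity
#'
#' Retains copies whose 5'/3' target-site duplications differ at no more than
#' `max_mismatch` positions (default 1, which removes recombinant or
#' rearranged copies). Copies with undefined TSD mismatch (truncated flanks)
#' are removed. Input order is preserved.
#'
#' @param copies A `GRanges` carrying a `tsd_mismatches` metadata column
#'   (see [extract_tsd()]).
#' @param max_mismatch Maximum allowed Hamming distance between the TSDs.
#' @return The filtered `GRanges`.
#' @export
filter_by_tsd <- function(copies, max_mismatch = 1L) {
  if (length(copies) == 0L) return(copies)
  mm <- copies$tsd_mismatches
  if (is.null(mm)) stop("copies carry no tsd_mismatches; run extract_tsd() first")
  copies[!is.na(mm) & mm <= max_mismatch]
}

#' Compare discovered copies with simulation ground truth
#'
#' Matches discovered copies to non-decoy truth implants of the same family
#' whose boundaries agree within `tol` bp, and reports recall and precision.
#'
#' @param found `GRanges` of discovered copies (with `family`).
#' @param truth `GRanges` of truth implants (with `family`, `is_decoy`).
#' @param tol Boundary tolerance in bp (default 5).
#' @return List with `recall`, `precision`, `n_truth`, `n_found`,
#'   `n_matched`.
#' @export
discovery_metrics <- function(found, truth, tol = 5L) {
  tr <- truth[!truth$is_decoy]
  matched_truth <- logical(length(tr))
  matched_found <- logical(length(found))
  for (i in seq_along(tr)) {
    cand <- which(!matched_found &
                    found$family == tr$family[i] &
                    as.character(GenomicRanges::seqnames(found)) ==
                      as.character(GenomicRanges::seqnames(tr)[i]) &
                    abs(IRanges::start(found) - IRanges::start(tr)[i]) <= tol &
                    abs(IRanges::end(found) - IRanges::end(tr)[i]) <= tol)
    if (length(cand)) {
      matched_truth[i] <- TRUE
      matched_found[cand[1]] <- TRUE
    }
  }
  list(recall = if (length(tr)) mean(matched_truth) else NA_real_,
       precision = if (length(found)) mean(matched_found) else NA_real_,
       n_truth = length(tr), n_found = length(found),
       n_matched = sum(matched_truth))
}

#' Write copy annotations as GFF3 and BED
#'
#' @param copies `GRanges` of copies.
#' @param gff3,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_copies <- function(copies, gff3 = NULL, bed = NULL) {
  paths <- character()
  if (!is.null(gff3)) {
    gr <- copies
    S4Vectors::mcols(gr)$type <- "transposable_element"
    S4Vectors::mcols(gr)$ID <- gr$copy_id
    rtracklayer::export(gr, gff3, format = "gff3")
    paths <- c(paths, gff3)
  }
  if (!is.null(bed)) {
    gr <- copies
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = copies$copy_id)
    rtracklayer::export(gr, bed, format = "bed")
    paths <- c(paths, bed)
  }
  invisible(paths)
}
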