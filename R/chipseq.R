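# CENH3 ChIP-seq hot-spot detection, TE-family classification, per-family
# normalisation and projection of per-base coverage onto family consensus
# coordinates.

#' Average depth over a set of regions
#'
#' Mean per-base depth over the union of the regions (overlapping regions do
#' not double-count bases).
#'
#' @param track A [coverage_track].
#' @param regions `GRanges` of regions (within track bounds).
#' @return Mean depth (reads/bp).
#' @export
region_average <- function(track, regions) {
  if (length(regions) == 0L) stop("empty region set")
  red <- GenomicRanges::reduce(regions)
  total <- 0; bases <- 0
  for (i in seq_along(red)) {
    chrom <- as.character(GenomicRanges::seqnames(red)[i])
    d <- track_chrom(track, chrom)
    s <- IRanges::start(red)[i]; e <- IRanges::end(red)[i]
    if (s < 1L || e > length(d)) stop("region outside track bounds")
    total <- total + sum(as.numeric(d[s:e]))
    bases <- bases + (e - s + 1)
  }
  total / bases
}

#' Detect CENH3 hot spots
#'
#' Reports maximal runs of bases, inside the given regions, where the
#' experimental depth is at least `fold` times the baseline (the average
#' experimental coverage over the regions) AND at least `fold` times the sum
#' of all control and mock depths at that base; runs shorter than `min_len`
#' are discarded.
#'
#' @param exp Experimental [coverage_track].
#' @param controls List of control/mock [coverage_track]s.
#' @param regions `GRanges` restricting the search (e.g. predicted
#'   centromeres, or a control chromosome arm). The baseline is computed over
#'   these regions, mirroring the separate centromere/control-arm averages.
#' @param min_len Minimum hot-spot length in bp (default 100).
#' @param fold Fold threshold (default 5).
#' @param max_len Optional maximum length (default off).
#' @param baseline Override the baseline (reads/bp); default
#'   `region_average(exp, regions)`.
#' @return `GRanges` of peaks with metadata `mean_exp`, `baseline`,
#'   `fold_over_baseline` and `control_sum_max`.
#' @export
detect_hotspots <- function(exp, controls, regions, min_len = 100L,
                            fold = 5, max_len = NULL, baseline = NULL) {
  baseline <- baseline %||% region_average(exp, regions)
  if (baseline <= 0) stop("degenerate track: zero baseline coverage")
  red <- GenomicRanges::reduce(regions)
  peaks <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(red)))) {
    d <- as.numeric(track_chrom(exp, chrom))
    csum <- numeric(length(d))
    for (ct in controls) csum <- csum + as.numeric(track_chrom(ct, chrom))
    ok <- d >= fold * baseline & d >= fold * csum
    mask <- logical(length(d))
    sub <- red[as.character(GenomicRanges::seqnames(red)) == chrom]
    for (i in seq_along(sub))
      mask[IRanges::start(sub)[i]:IRanges::end(sub)[i]] <- TRUE
    r <- rle(ok & mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= min_len
    if (!is.null(max_len)) sel <- sel & r$lengths <= max_len
    if (!any(sel)) next
    s <- starts[sel]; e <- ends[sel]
    peaks[[length(peaks) + 1L]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(s, e),
      mean_exp = vapply(seq_along(s), function(i) mean(d[s[i]:e[i]]), 0),
      baseline = baseline,
      fold_over_baseline = vapply(seq_along(s), function(i)
        mean(d[s[i]:e[i]]) / baseline, 0),
      control_sum_max = vapply(seq_along(s), function(i)
        max(csum[s[i]:e[i]]), 0))
  }
  if (!length(peaks)) return(GenomicRanges::GRanges())
  sort(do.call(c, peaks))
}

#' Classify a peak sequence against a TE family library
#'
#' Best local alignment of the peak (both orientations) against each family
#' sequence; the family is assigned only if the best alignment spans at
#' least `min_len` columns at identity at least `min_identity` (the blastn
#' style rule: alignments >= 90 bp and >= 70% identity). Ties go to the
#' higher identity, then the alphabetically first family.
#'
#' @param peak_seq DNA sequence of the peak.
#' @param te_library Named [Biostrings::DNAStringSet] of family consensus
#'   sequences.
#' @param min_len Minimum alignment length in bp (default 90).
#' @param min_identity Minimum identity fraction (default 0.70).
#' @return List with `family` (label or `NA`) and `identity` (fraction or
#'   `NA`).
#' @export
classify_peak <- function(peak_seq, te_library, min_len = 90L,
                          min_identity = 0.70) {
  if (length(te_library) == 0L) stop("te_library must be non-empty")
  s <- toupper(as.character(peak_seq))
  submat <- dna_submat()
  best_family <- NA_character_; best_identity <- NA_real_
  for (fam in sort(names(te_library))) {
    for (query in c(s, revcomp_chr(s))) {
      aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(query),
        te_library[[fam]], type = "local", substitutionMatrix = submat,
        gapOpening = 10, gapExtension = 0.5)
      len <- Biostrings::nchar(aln)
      identity <- if (len > 0) Biostrings::nmatch(aln) / len else 0
      if (len >= min_len && identity >= min_identity &&
          (is.na(best_identity) || identity > best_identity)) {
        best_family <- fam
        best_identity <- identity
      }
    }
  }
  list(family = best_family, identity = best_identity)
}

#' Classify detected hot spots to TE families
#'
#' @param peaks `GRanges` from [detect_hotspots()].
#' @param genome [Biostrings::DNAStringSet].
#' @param te_library Named [Biostrings::DNAStringSet].
#' @param min_len,min_identity Classification thresholds (see
#'   [classify_peak()]).
#' @return `peaks` with `family` and `identity` metadata columns added.
#' @export
classify_hotspots <- function(peaks, genome, te_library, min_len = 90L,
                              min_identity = 0.70) {
  fam <- rep(NA_character_, length(peaks))
  idy <- rep(NA_real_, length(peaks))
  for (i in seq_along(peaks)) {
    chrom <- as.character(GenomicRanges::seqnames(peaks)[i])
    s <- as.character(Biostrings::subseq(genome[[chrom]],
      IRanges::start(peaks)[i], IRanges::end(peaks)[i]))
    cl <- classify_peak(s, te_library, min_len, min_identity)
    fam[i] <- cl$family; idy[i] <- cl$identity
  }
  peaks$family <- fam
  peaks$identity <- idy
  peaks
}

#' Peak density per family, normalised by annotated family length
#'
#' @param peak_counts Named vector of peak counts per family.
#' @param family_genomic_bp Named vector of total annotated bp per family.
#' @return data.frame with `family`, `peaks`, `genomic_mb`, `peaks_per_mb`.
#'   Families with zero annotated bp are excluded with a warning.
#' @export
family_enrichment <- function(peak_counts, family_genomic_bp) {
  fams <- names(peak_counts)
  bp <- family_genomic_bp[fams]
  zero <- is.na(bp) | bp <= 0
  if (any(zero)) {
    warning("excluding families with zero annotated bp: ",
            paste(fams[zero], collapse = ", "))
    fams <- fams[!zero]; bp <- bp[!zero]
  }
  data.frame(family = fams,
             peaks = as.numeric(peak_counts[fams]),
             genomic_mb = as.numeric(bp) / 1e6,
             peaks_per_mb = as.numeric(peak_counts[fams]) / (as.numeric(bp) / 1e6),
             row.names = NULL)
}

#' Project genomic coverage of one copy onto consensus coordinates
#'
#' The copy is aligned to the family consensus (insertions in the copy are
#' omitted); the genomic depth at each aligned copy base is transferred to
#' its consensus column. Consensus positions deleted in the copy receive no
#' contribution. Minus-strand copies are projected in consensus orientation.
#'
#' @param copy Single-range `GRanges` (with strand).
#' @param genome [Biostrings::DNAStringSet].
#' @param consensus Consensus sequence.
#' @param track A [coverage_track].
#' @param gap_open,gap_extend Affine gap penalties for the copy-to-consensus
#'   alignment (defaults 50 / 0.1).
#' @param min_align_frac Minimum fraction of the consensus the alignment
#'   must cover (default 0.3); below it, an error is thrown.
#' @return Numeric vector of depths, one per consensus position.
#' @export
project_coverage <- function(copy, genome, consensus, track,
                             gap_open = 50, gap_extend = 0.1,
                             min_align_frac = 0.3) {
  stopifnot(length(copy) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(copy))
  if (!chrom %in% names(track$depths))
    stop("track/annotation chromosome mismatch: '", chrom, "'")
  cons <- toupper(as.character(consensus))
  clen <- nchar(cons)
  d <- track_chrom(track, chrom)
  s <- IRanges::start(copy); e <- IRanges::end(copy)
  depth <- as.numeric(d[s:e])
  seq <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
  if (as.character(GenomicRanges::strand(copy)) == "-") {
    seq <- revcomp_chr(seq)
    depth <- rev(depth)
  }
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq),
    Biostrings::DNAString(cons), type = "local",
    substitutionMatrix = dna_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
  sr <- Biostrings::subject(aln)
  if (IRanges::width(sr) < min_align_frac * clen)
    stop("alignment covers less than ", round(100 * min_align_frac),
         "% of the consensus")
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(sr), "")[[1]]
  profile <- numeric(clen)
  ppos <- IRanges::start(Biostrings::pattern(aln)) - 1L
  spos <- IRanges::start(sr) - 1L
  for (col in seq_along(pa)) {
    if (pa[col] != "-") ppos <- ppos + 1L
    if (sa[col] != "-") spos <- spos + 1L
    if (pa[col] != "-" && sa[col] != "-")
      profile[spos] <- profile[spos] + depth[ppos]
  }
  profile
}

#' Compile per-copy projections into consensus coverage profiles
#'
#' Sums projections across copies per experiment and forms the
#' experimental/mock ratio with a pseudocount of 1 on the denominator.
#'
#' @param projections Named list (one entry per experiment label) of lists of
#'   per-copy projection vectors (from [project_coverage()]).
#' @param exp_label,mock_label Experiment labels used for the ratio profile.
#' @return Object of class `consensus_profile`: list with `profiles` (named
#'   list of summed per-position depth vectors), `copy_count`, and `ratio`
#'   (`exp / (mock + 1)`, or `NULL` if either label is absent).
#' @export
compile_profile <- function(projections, exp_label = "CENH3",
                            mock_label = "CENH3_mock") {
  if (!length(projections) || !length(projections[[1]]))
    stop("need at least one projection")
  profiles <- lapply(projections, function(pl) Reduce(`+`, pl))
  ratio <- NULL
  if (exp_label %in% names(profiles) && mock_label %in% names(profiles))
    ratio <- profiles[[exp_label]] / (profiles[[mock_label]] + 1)
  structure(list(profiles = profiles,
                 copy_count = length(projections[[1]]),
                 ratio = ratio),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile: %d experiment(s), %d copies, %d positions\n",
              length(x$profiles), x$copy_count, length(x$profiles[[1]])))
  invisible(x)
}

#' Project and compile coverage profiles for a set of copies
#'
#' Convenience wrapper: projects every copy onto the consensus for each
#' track and compiles the summed profiles. Copies whose alignment covers too
#' little of the consensus are skipped with a warning.
#'
#' @param copies `GRanges` of copies of one family.
#' @param genome [Biostrings::DNAStringSet].
#' @param consensus Family consensus sequence.
#' @param tracks List of [coverage_track]s (experimental, controls, mocks).
#' @param ... Passed to [project_coverage()].
#' @inheritParams compile_profile
#' @return A `consensus_profile`.
#' @export
consensus_profiles <- function(copies, genome, consensus, tracks,
                               exp_label = "CENH3",
                               mock_label = "CENH3_mock", ...) {
  labels <- vapply(tracks, `[[`, "", "label")
  projections <- stats::setNames(
    lapply(tracks, function(tr) {
      out <- list()
      for (i in seq_along(copies)) {
        p <- tryCatch(project_coverage(copies[i], genome, consensus, tr, ...),
                      error = function(e) {
                        warning("copy ", copies$copy_id[i], ": ",
                                conditionMessage(e))
                        NULL
                      })
        if (!is.null(p)) out[[length(out) + 1L]] <- p
      }
      out
    }), labels)
  compile_profile(projections, exp_label, mock_label)
}

#' Write consensus coverage profiles as TSV
#'
#' @param profile A [compile_profile()] result.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_profile <- function(profile, file) {
  df <- data.frame(position = seq_along(profile$profiles[[1]]),
                   profile$profiles, check.names = FALSE)
  if (!is.null(profile$ratio)) df$ratio <- profile$ratio
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
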