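# Insertion dating from 5'/3' LTR divergence under the Kimura two-parameter
# model. At integration the two LTRs of a copy are identical; substitutions
# accumulate independently in each, so the corrected pairwise distance d
# relates to the insertion age T through d = 2 * r * T for substitution rate
# r per site per year.

#' Align the two LTRs of a copy
#'
#' Best local alignment under +5/-4 match/mismatch scoring with affine gap
#' penalties (open 10, extend 0.5), the EMBOSS `water` defaults.
#'
#' @param ltr5,ltr3 DNA sequences (character or [Biostrings::DNAString]).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param match,mismatch Match/mismatch scores.
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings, no all-gap column), `score`,
#'   `gap_open`, `gap_extend`.
#' @export
#' @examples
#' aln <- align_ltr_pair("ACGTACGT", "ACGTACGT")
#' aln$score
align_ltr_pair <- function(ltr5, ltr3, gap_open = 10, gap_extend = 0.5,
                           match = 5, mismatch = -4) {
  a <- toupper(as.character(ltr5)); b <- toupper(as.character(ltr3))
  if (!nzchar(a) || !nzchar(b)) stop("LTR sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(aligned_a = as.character(Biostrings::pattern(aln)),
                 aligned_b = as.character(Biostrings::subject(aln)),
                 score = Biostrings::score(aln),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, score %.1f\n",
              nchar(x$aligned_a), x$score))
  invisible(x)
}

#' Count ungapped sites, transitions and transversions in an alignment
#'
#' Only columns with an unambiguous base in both rows are counted. A<->G and
#' C<->T differences are transitions; all other differing base pairs are
#' transversions. Columns containing N are excluded.
#'
#' @param aln A [align_ltr_pair()] result, or any list with `aligned_a` and
#'   `aligned_b`.
#' @return Named list: `ungapped_sites`, `transitions`, `transversions`.
#' @export
count_site_patterns <- function(aln) {
  va <- strsplit(toupper(aln$aligned_a), "")[[1]]
  vb <- strsplit(toupper(aln$aligned_b), "")[[1]]
  stopifnot(length(va) == length(vb))
  ok <- va %in% DNA_BASES & vb %in% DNA_BASES
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  ts <- diff & TRANSITION[va] == vb
  list(ungapped_sites = length(va),
       transitions = sum(ts),
       transversions = sum(diff & !ts))
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with transition proportion
#' `P = transitions/sites` and transversion proportion
#' `Q = transversions/sites`. The correction accounts for multiple hits, so
#' `d >= P + Q` always.
#'
#' @param ungapped_sites,transitions,transversions Site-pattern counts (see
#'   [count_site_patterns()]).
#' @return Distance in substitutions per site.
#' @export
#' @examples
#' k2p_distance(100, 2, 1)   # ~0.0307
k2p_distance <- function(ungapped_sites, transitions, transversions) {
  if (ungapped_sites <= 0) stop("ungapped_sites must be > 0")
  P <- transitions / ungapped_sites
  Q <- transversions / ungapped_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation: K2P distance undefined for P = ", signif(P, 4),
         ", Q = ", signif(Q, 4))
  -0.5 * log(w1 * sqrt(w2))
}

#' Convert a divergence distance to an insertion age
#'
#' Both LTRs accumulate substitutions after insertion, so
#' `age = distance / (2 * rate)`.
#'
#' @param distance Substitutions per site.
#' @param rate Substitution rate per site per year (default 1.3e-8, the rate
#'   proposed for intergenic regions in grasses).
#' @return Age in years.
#' @export
#' @examples
#' date_insertion(2.6e-3)  # 100,000 years
date_insertion <- function(distance, rate = 1.3e-8) {
  if (any(distance < 0)) stop("distance must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  distance / (2 * rate)
}

#' Drop the oldest tail of an age distribution
#'
#' Retains ages at or below the given empirical percentile (default 99), as
#' used for displaying insertion-age distributions without extreme outliers.
#'
#' @param ages Numeric vector of ages.
#' @param percentile Percentile in (0, 100].
#' @return Filtered ages (order preserved).
#' @export
age_percentile_filter <- function(ages, percentile = 99) {
  if (!length(ages)) stop("ages must be non-empty")
  ages[ages <= quantile(ages, percentile / 100)]
}

#' Estimate insertion ages for annotated copies
#'
#' Runs the full dating chain per copy: extract the two LTR sequences, align
#' them locally, count site patterns, apply the Kimura two-parameter
#' correction and convert to years. Copies whose LTR alignment covers less
#' than `min_ltr_coverage` of the shorter LTR, or whose distance is
#' saturated, get `NA` with a warning.
#'
#' @param copies `GRanges` with LTR sub-interval columns (from
#'   [find_full_length_copies()] or a simulation truth set).
#' @param genome [Biostrings::DNAStringSet].
#' @param rate Substitution rate per site per year.
#' @param min_ltr_coverage Minimum fraction of the shorter LTR that must be
#'   aligned (default 0.5).
#' @return data.frame with columns `copy_id`, `ungapped_sites`,
#'   `transitions`, `transversions`, `distance`, `age`, `rate`.
#' @export
estimate_ages <- function(copies, genome, rate = 1.3e-8,
                          min_ltr_coverage = 0.5) {
  n <- length(copies)
  out <- data.frame(copy_id = copies$copy_id,
                    ungapped_sites = NA_integer_, transitions = NA_integer_,
                    transversions = NA_integer_, distance = NA_real_,
                    age = NA_real_, rate = rate)
  for (i in seq_len(n)) {
    m <- S4Vectors::mcols(copies)[i, ]
    if (is.na(m$ltr5_start) || is.na(m$ltr3_start)) next
    chr <- genome[[as.character(GenomicRanges::seqnames(copies)[i])]]
    l5 <- as.character(Biostrings::subseq(chr, m$ltr5_start, m$ltr5_end))
    l3 <- as.character(Biostrings::subseq(chr, m$ltr3_start, m$ltr3_end))
    aln <- align_ltr_pair(l5, l3)
    if (nchar(aln$aligned_a) < min_ltr_coverage * min(nchar(l5), nchar(l3))) {
      warning("copy ", copies$copy_id[i], ": partial LTR alignment, skipped")
      next
    }
    cnt <- count_site_patterns(aln)
    d <- tryCatch(k2p_distance(cnt$ungapped_sites, cnt$transitions,
                               cnt$transversions),
                  error = function(e) {
                    warning("copy ", copies$copy_id[i], ": ",
                            conditionMessage(e))
                    NA_real_
                  })
    out$ungapped_sites[i] <- cnt$ungapped_sites
    out$transitions[i] <- cnt$transitions
    out$transversions[i] <- cnt$transversions
    out$distance[i] <- d
    out$age[i] <- if (is.na(d)) NA_real_ else date_insertion(d, rate)
  }
  out
}

#' Write per-copy age estimates as TSV
#'
#' @param ages data.frame from [estimate_ages()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_ages <- function(ages, file) {
  write.table(ages, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
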