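#' Per-base read-depth track
#'
#' A light container for per-base integer read depth, one vector per
#' chromosome, as produced by `samtools depth` style counting and consumed by
#' the hot-spot caller and the consensus projection.
#'
#' @param label Experiment name, e.g. `"CENH3"`, `"CENH3_mock"`, `"H3K4me3"`.
#' @param depths Named list of non-negative integer vectors, one per
#'   chromosome; vector length equals chromosome length.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(label, depths) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.list(depths) || is.null(names(depths)) || any(!nzchar(names(depths))))
    stop("depths must be a named list of per-chromosome vectors")
  depths <- lapply(depths, function(d) {
    d <- as.integer(d)
    if (anyNA(d) || any(d < 0L)) stop("depths must be non-negative integers")
    d
  })
  structure(list(label = label, depths = depths), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chromosome(s), %s bp total\n",
              x$label, length(x$depths),
              format(sum(vapply(x$depths, length, 0L)), big.mark = ",")))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Emits standard 4-column bedGraph (0-based, half-open) via rtracklayer.
#'
#' @param track A [coverage_track].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_bedgraph <- function(track, file) {
  grl <- lapply(names(track$depths), function(chrom) {
    r <- rle(track$depths[[chrom]])
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = ends - r$lengths + 1L, end = ends),
      score = r$values)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a bedGraph file into a coverage track
#'
#' @param file bedGraph path.
#' @param seqlengths Named integer vector of chromosome lengths (bases not
#'   covered by any record get depth 0).
#' @param label Experiment name for the track.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(file, seqlengths, label = basename(file)) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  depths <- lapply(names(seqlengths), function(chrom) {
    d <- integer(seqlengths[[chrom]])
    sub <- gr[GenomicRanges::seqnames(gr) == chrom]
    if (length(sub)) {
      for (i in seq_along(sub)) {
        d[IRanges::start(sub)[i]:IRanges::end(sub)[i]] <- as.integer(sub$score[i])
      }
    }
    d
  })
  names(depths) <- names(seqlengths)
  coverage_track(label, depths)
}

# depth vector for one chromosome, with bounds check
track_chrom <- function(track, chrom) {
  if (!chrom %in% names(track$depths))
    stop("track '", track$label, "' has no chromosome '", chrom, "'")
  track$depths[[chrom]]
}
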