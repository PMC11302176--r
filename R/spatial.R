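# Relating genetic distance between copies to their physical position
# relative to the centromere midpoint.

#' Define a centromere
#'
#' @param chrom Chromosome label.
#' @param start,end Centromere boundaries in bp (1-based, inclusive).
#' @param midpoint Midpoint in bp; defaults to the interval centre.
#' @return Object of class `centromere_def`.
#' @export
centromere_def <- function(chrom, start, end, midpoint = (start + end) / 2) {
  if (!(start < midpoint && midpoint < end))
    stop("need start < midpoint < end")
  structure(list(chrom = chrom, start = start, end = end,
                 midpoint = midpoint),
            class = "centromere_def")
}

#' Positional difference relative to the centromere midpoint
#'
#' The position of each copy is expressed as its distance from the
#' centromere midpoint; the positional difference between two copies is the
#' absolute difference of those distances, in Mb. Two copies equidistant
#' from the midpoint on opposite sides (e.g. 245 Mb and 255 Mb around a
#' midpoint at 250 Mb) have positional difference 0.
#'
#' @param pos_i,pos_j Positions in bp (vectors recycle).
#' @param cen A [centromere_def()].
#' @param chrom_i,chrom_j Optional chromosome labels to check against
#'   `cen$chrom`.
#' @return Positional difference in Mb.
#' @export
#' @examples
#' cen <- centromere_def("chr1", 190e6, 210e6, midpoint = 200e6)
#' positional_difference(180e6, 210e6, cen)  # 10
positional_difference <- function(pos_i, pos_j, cen,
                                  chrom_i = NULL, chrom_j = NULL) {
  stopifnot(inherits(cen, "centromere_def"))
  for (ch in list(chrom_i, chrom_j)) {
    if (!is.null(ch) && any(ch != cen$chrom))
      stop("chromosome mismatch: copies must lie on ", cen$chrom)
  }
  abs(abs(pos_i - cen$midpoint) - abs(pos_j - cen$midpoint)) / 1e6
}

#' Pairwise positional distance matrix
#'
#' @param positions Named vector of copy positions in bp (names = copy ids).
#' @param cen A [centromere_def()].
#' @return Symmetric matrix of positional differences in Mb.
#' @export
positional_distance_matrix <- function(positions, cen) {
  d <- abs(positions - cen$midpoint)
  m <- abs(outer(d, d, `-`)) / 1e6
  dimnames(m) <- list(names(positions), names(positions))
  m
}

#' Mantel test between two distance matrices
#'
#' Computes the rank (Spearman) correlation between the corresponding
#' off-diagonal entries of two distance matrices and assesses it by jointly
#' permuting rows and columns of the second matrix. The one-sided p-value
#' uses the add-one correction,
#' `p = (1 + #permuted statistics >= observed) / (permutations + 1)`, so it
#' is never exactly zero. Missing entries are dropped pairwise.
#'
#' @param genetic,positional Symmetric distance matrices of equal dimension
#'   (>= 3) with zero diagonals.
#' @param method Correlation method (default `"spearman"`).
#' @param permutations Number of permutations (default 9999).
#' @param seed Seed for the permutations.
#' @return Object of class `mantel_result`: list with `statistic`,
#'   `p_value`, `permutations`, `method`.
#' @export
mantel_test <- function(genetic, positional, method = "spearman",
                        permutations = 9999L, seed = NULL) {
  n <- nrow(genetic)
  if (!is.matrix(genetic) || !is.matrix(positional) ||
      n != ncol(genetic) || !all(dim(positional) == n) || n < 3L)
    stop("need two square matrices of equal dimension >= 3")
  if (any(abs(diag(genetic)) > 1e-12, na.rm = TRUE) ||
      any(abs(diag(positional)) > 1e-12, na.rm = TRUE))
    stop("distance matrices must have zero diagonals")
  if (max(abs(genetic - t(genetic)), na.rm = TRUE) > 1e-8 ||
      max(abs(positional - t(positional)), na.rm = TRUE) > 1e-8)
    stop("distance matrices must be symmetric")
  lt <- lower.tri(genetic)
  v1 <- genetic[lt]
  corr <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("degenerate input: zero variance in a distance triangle")
    cor(a[ok], b[ok], method = method)
  }
  observed <- corr(v1, positional[lt])
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(permutations)) {
      p <- sample.int(n)
      cnt <- cnt + (corr(v1, positional[p, p][lt]) >= observed)
    }
    cnt
  })
  structure(list(statistic = observed,
                 p_value = (1 + exceed) / (permutations + 1),
                 permutations = as.integer(permutations),
                 method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d permutations): r = %.4f, p = %.4g\n",
              x$method, x$permutations, x$statistic, x$p_value))
  invisible(x)
}

#' Filter copies by genomic region and maximum age
#'
#' Retains copies whose interval midpoint lies within `region` and whose
#' estimated insertion age is at most `max_age` — the rule used to ask which
#' copies inserted into a newly formed (neo)centromere.
#'
#' @param copies `GRanges` with an `age` metadata column.
#' @param region Numeric `c(start, end)` in bp, or a `GRanges` of length 1.
#' @param max_age Maximum age in years.
#' @return The filtered `GRanges`.
#' @export
filter_region_age <- function(copies, region, max_age) {
  if (methods::is(region, "GRanges"))
    region <- c(IRanges::start(region)[1], IRanges::end(region)[1])
  mid <- (IRanges::start(copies) + IRanges::end(copies)) / 2
  age <- copies$age
  if (is.null(age)) stop("copies carry no 'age' metadata column")
  copies[!is.na(age) & mid >= region[1] & mid <= region[2] & age <= max_age]
}
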