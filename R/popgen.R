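# Population analysis of full-length copies: subfamily consensus building,
# copy-to-consensus variant calling, PCA and pairwise SNP distances.

#' Extract element sequences in 5'->3' orientation
#'
#' @param copies `GRanges` of copies.
#' @param genome [Biostrings::DNAStringSet].
#' @return [Biostrings::DNAStringSet] named by `copy_id`; minus-strand copies
#'   are reverse-complemented.
#' @export
copy_sequences <- function(copies, genome) {
  seqs <- vapply(seq_along(copies), function(i) {
    chr <- genome[[as.character(GenomicRanges::seqnames(copies)[i])]]
    s <- as.character(Biostrings::subseq(chr, IRanges::start(copies)[i],
                                         IRanges::end(copies)[i]))
    if (as.character(GenomicRanges::strand(copies)[i]) == "-")
      revcomp_chr(s) else s
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- copies$copy_id
  out
}

#' Build a family consensus from randomly sampled copies
#'
#' Samples `min(sample_n, available)` copies without replacement (seeded),
#' aligns them with a built-in centre-star multiple aligner (every copy is
#' globally aligned to the most representative copy, chosen by shared 8-mer
#' content), and returns the column-majority base. Ties are broken
#' alphabetically; columns where the majority of copies carry a gap are
#' dropped.
#'
#' @param copies [Biostrings::DNAStringSet] of element sequences (>= 2).
#' @param sample_n Number of copies to sample (default 30).
#' @param seed Seed for the sampling.
#' @return A [Biostrings::DNAString] consensus.
#' @export
build_consensus <- function(copies, sample_n = 30L, seed = NULL) {
  if (length(copies) < 2L) stop("need >= 2 copies to build a consensus")
  idx <- with_seed(seed,
    sort(sample.int(length(copies), min(sample_n, length(copies)))))
  sel <- copies[idx]
  # centre = copy with the highest total shared 8-mer content
  of <- Biostrings::oligonucleotideFrequency(sel, width = 8)
  sim <- of %*% t(of)
  center_i <- which.max(rowSums(sim))
  center <- sel[[center_i]]
  clen <- length(center)
  mat <- matrix("-", nrow = length(sel), ncol = clen)
  mat[center_i, ] <- strsplit(as.character(center), "")[[1]]
  submat <- dna_submat()
  for (i in seq_along(sel)) {
    if (i == center_i) next
    aln <- Biostrings::pairwiseAlignment(sel[[i]], center, type = "global",
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    keep <- sa != "-"           # drop insertions relative to the centre
    mat[i, ] <- pa[keep]
  }
  cons <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = c(DNA_BASES, "-")))
    if (counts[["-"]] > length(col) / 2) return(NA_character_)
    base_counts <- counts[DNA_BASES]
    names(base_counts)[which.max(base_counts)]  # which.max: first = alphabetical
  })
  Biostrings::DNAString(paste(cons[!is.na(cons)], collapse = ""))
}

#' Call variants of copies against a family consensus
#'
#' Each copy is locally aligned to the consensus (affine gaps, open 50,
#' extend 0.1). Copy bases in inserted (non-consensus) columns are
#' discarded; consensus positions deleted in a copy, or outside its aligned
#' range, are missing for that copy. A site is retained if, among non-missing
#' calls, the second-most-common allele has frequency at least `maf` and the
#' missing fraction is at most `missing_cutoff`; individual alternate alleles
#' rarer than `maf` are recoded as missing first.
#'
#' @param copies [Biostrings::DNAStringSet] of element sequences (named).
#' @param consensus Consensus sequence (character or
#'   [Biostrings::DNAString]).
#' @param maf Minor-allele-frequency threshold (default 0.01).
#' @param missing_cutoff Maximum allowed per-site missing fraction
#'   (default 0.90).
#' @param gap_open,gap_extend Affine gap penalties for the copy-to-consensus
#'   alignment.
#' @param min_align_frac Copies aligning over less than this fraction of the
#'   consensus are dropped with a warning (default 0.3).
#' @param consensus_id Label used as the VCF contig name.
#' @return An object of class `variant_table`: list with `consensus_id`,
#'   `sites` (data.frame `pos`, `ref`, `alt` — comma-separated alternate
#'   alleles), `geno` (copies x sites integer matrix of allele indices, 0 =
#'   reference, `NA` = missing) and `copy_ids`.
#' @export
call_variants <- function(copies, consensus, maf = 0.01,
                          missing_cutoff = 0.90, gap_open = 50,
                          gap_extend = 0.1, min_align_frac = 0.3,
                          consensus_id = "consensus") {
  cons <- toupper(as.character(consensus))
  if (!nzchar(cons)) stop("consensus must be non-empty")
  clen <- nchar(cons)
  cons_v <- strsplit(cons, "")[[1]]
  ids <- names(copies) %||% sprintf("copy_%04d", seq_along(copies))
  submat <- dna_submat()
  calls <- matrix(NA_character_, nrow = length(copies), ncol = clen)
  keep_copy <- rep(TRUE, length(copies))
  cons_dna <- Biostrings::DNAString(cons)
  for (i in seq_along(copies)) {
    aln <- Biostrings::pairwiseAlignment(copies[[i]], cons_dna,
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    sr <- Biostrings::subject(aln)
    if (IRanges::width(sr) < min_align_frac * clen) {
      warning("copy '", ids[i], "' aligns over less than ",
              round(100 * min_align_frac), "% of the consensus; dropped")
      keep_copy[i] <- FALSE
      next
    }
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    sa <- strsplit(as.character(sr), "")[[1]]
    cpos <- IRanges::start(sr) - 1L
    for (col in seq_along(sa)) {
      if (sa[col] == "-") next           # insertion in the copy: ignored
      cpos <- cpos + 1L
      if (pa[col] != "-") calls[i, cpos] <- pa[col]
      # deletion in the copy: stays NA (missing)
    }
  }
  calls <- calls[keep_copy, , drop = FALSE]
  ids <- ids[keep_copy]
  n <- nrow(calls)
  if (n == 0L) stop("no copies aligned to the consensus")

  site_pos <- integer(); site_ref <- character(); site_alt <- list()
  geno_cols <- list()
  for (pos in seq_len(clen)) {
    col <- calls[, pos]
    nm <- !is.na(col)
    if (!any(nm)) next
    if (mean(!nm) > missing_cutoff) next
    freq <- table(col[nm]) / sum(nm)
    # alternate alleles rarer than maf are recoded missing
    rare <- names(freq)[names(freq) != cons_v[pos] & freq < maf]
    if (length(rare)) {
      col[col %in% rare] <- NA
      nm <- !is.na(col)
      if (!any(nm) || mean(!nm) > missing_cutoff) next
      freq <- table(col[nm]) / sum(nm)
    }
    if (length(freq) < 2L) next
    if (sort(freq, decreasing = TRUE)[2] < maf) next
    alt <- names(sort(freq[names(freq) != cons_v[pos]], decreasing = TRUE))
    if (!length(alt)) next
    g <- match(col, c(cons_v[pos], alt)) - 1L
    site_pos <- c(site_pos, pos)
    site_ref <- c(site_ref, cons_v[pos])
    site_alt[[length(site_alt) + 1L]] <- alt
    geno_cols[[length(geno_cols) + 1L]] <- g
  }
  geno <- if (length(geno_cols)) do.call(cbind, geno_cols) else
    matrix(integer(), nrow = n, ncol = 0)
  rownames(geno) <- ids
  sites <- data.frame(pos = site_pos, ref = site_ref,
                      alt = vapply(site_alt, paste, "", collapse = ","),
                      stringsAsFactors = FALSE)
  structure(list(consensus_id = consensus_id, sites = sites, geno = geno,
                 copy_ids = ids),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table '%s': %d copies x %d sites (%.1f%% missing)\n",
              x$consensus_id, length(x$copy_ids), nrow(x$sites),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Principal component analysis of a variant table
#'
#' Genotypes (allele indices) are encoded numerically, missing calls are
#' mean-imputed per site, and the centred matrix is decomposed by SVD.
#' Coordinates are deterministic up to component sign.
#'
#' @param table A [call_variants()] result.
#' @return Object of class `te_pca`: list with `coordinates` (copies x
#'   components), `explained_variance` (per component) and `loadings`
#'   (sites x components).
#' @export
run_pca <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  g <- table$geno
  if (nrow(g) < 2L || ncol(g) < 1L) stop("need >= 2 copies and >= 1 site")
  num <- apply(g, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    col
  })
  num <- matrix(num, nrow = nrow(g))
  cen <- scale(num, center = TRUE, scale = FALSE)
  if (sum(cen^2) == 0)
    stop("degenerate input: zero total variance (identical copies)")
  pc <- prcomp(num, center = TRUE, scale. = FALSE)
  structure(list(coordinates = pc$x,
                 explained_variance = pc$sdev^2,
                 loadings = pc$rotation,
                 copy_ids = table$copy_ids),
            class = "te_pca")
}

#' @export
print.te_pca <- function(x, ...) {
  ev <- x$explained_variance / sum(x$explained_variance)
  cat(sprintf("te_pca: %d copies, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$coordinates), ncol(x$coordinates), 100 * ev[1],
              if (length(ev) > 1) 100 * ev[2] else 0))
  invisible(x)
}

#' Pairwise SNP distances between copies
#'
#' Entry (i, j) is the number of retained sites at which both copies have a
#' non-missing call and the calls differ.
#'
#' @param table A [call_variants()] result.
#' @return Symmetric integer matrix with zero diagonal, dimnames = copy ids.
#' @export
pairwise_snp_distance <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  g <- table$geno
  n <- nrow(g)
  d <- matrix(0L, n, n, dimnames = list(table$copy_ids, table$copy_ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    gi <- g[i, ]
    for (j in (i + 1L):n) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      d[i, j] <- d[j, i] <- sum(gi[ok] != gj[ok])
    }
  }
  d
}

#' Purity of k-means clusters on the first two principal components
#'
#' Clusters copies by k-means on PC1/PC2 (k = number of distinct true
#' labels) and reports the fraction of copies whose cluster's majority label
#' matches their own.
#'
#' @param pca A [run_pca()] result.
#' @param labels True subfamily labels, parallel to the copies.
#' @param seed Seed for the k-means initialisation.
#' @return Purity in (0, 1].
#' @export
pca_cluster_purity <- function(pca, labels, seed = 1) {
  stopifnot(inherits(pca, "te_pca"))
  k <- length(unique(labels))
  co <- pca$coordinates[, seq_len(min(2L, ncol(pca$coordinates))), drop = FALSE]
  cl <- with_seed(seed, stats::kmeans(co, centers = k, nstart = 10)$cluster)
  sum(vapply(split(labels, cl), function(l) max(table(l)), 0)) / length(labels)
}

#' Write PCA coordinates as TSV
#'
#' @param pca A [run_pca()] result.
#' @param file Output path.
#' @param n_components Number of components to write.
#' @return Invisibly, `file`.
#' @export
write_pca <- function(pca, file, n_components = 10L) {
  k <- min(n_components, ncol(pca$coordinates))
  df <- data.frame(copy_id = pca$copy_ids,
                   pca$coordinates[, seq_len(k), drop = FALSE])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a square distance matrix as TSV
#'
#' @param d Square matrix with dimnames.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_distance_matrix <- function(d, file) {
  df <- data.frame(copy_id = rownames(d), d, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a square distance matrix from TSV
#'
#' @param file TSV written by [write_distance_matrix()].
#' @return Numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
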