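#' Define a retrotransposon family model
#'
#' A family model bundles the information needed to find and analyse
#' full-length copies of one LTR retrotransposon family: the LTR consensus
#' sequence, the internal-region consensus (between the two LTRs), one or more
#' acceptable full-length size windows, and the expected target-site
#' duplication (TSD) length. For the wheat centromeric families the size
#' windows are 7,700-8,000 bp (RLG_Cereba) and 4,300-4,500 plus 4,700-4,800 bp
#' (RLG_Quinta).
#'
#' @param name Family label, e.g. `"RLG_Cereba"`.
#' @param ltr_consensus LTR consensus sequence (character or
#'   [Biostrings::DNAString]).
#' @param internal_consensus Internal-region consensus sequence.
#' @param size_windows Numeric matrix or list of `c(min, max)` pairs giving
#'   acceptable total element lengths (5' LTR start to 3' LTR end) in bp.
#' @param tsd_length Target-site duplication length in bp (default 5, the
#'   canonical value for Gypsy elements).
#'
#' @return An object of class `family_model`.
#' @export
#' @examples
#' fam <- family_model("toy", strrep("ACGT", 25), strrep("GATTACA", 40),
#'                     size_windows = list(c(400, 500)))
#' fam
family_model <- function(name, ltr_consensus, internal_consensus,
                         size_windows, tsd_length = 5L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ltr <- toupper(as.character(ltr_consensus))
  internal <- toupper(as.character(internal_consensus))
  for (s in c(ltr, internal)) {
    if (!nzchar(s) || grepl("[^ACGTN]", s))
      stop("family '", name, "': consensus sequences must be non-empty and over A/C/G/T/N")
  }
  if (is.list(size_windows)) size_windows <- do.call(rbind, size_windows)
  size_windows <- matrix(as.numeric(size_windows), ncol = 2)
  if (nrow(size_windows) < 1L || any(!is.finite(size_windows)) ||
      any(size_windows[, 1] >= size_windows[, 2]))
    stop("family '", name, "': size windows must be non-empty (min, max) pairs with min < max")
  tsd_length <- as.integer(tsd_length)
  if (tsd_length < 2L) stop("family '", name, "': tsd_length must be >= 2")
  structure(list(name = name, ltr_consensus = ltr,
                 internal_consensus = internal,
                 size_windows = size_windows, tsd_length = tsd_length),
            class = "family_model")
}

#' @export
print.family_model <- function(x, ...) {
  win <- paste(apply(x$size_windows, 1, function(w)
    sprintf("%g-%g", w[1], w[2])), collapse = ", ")
  cat(sprintf("family_model '%s': LTR %d bp, internal %d bp, windows %s bp, TSD %d bp\n",
              x$name, nchar(x$ltr_consensus), nchar(x$internal_consensus),
              win, x$tsd_length))
  invisible(x)
}

#' Load a family library from FASTA plus a window configuration table
#'
#' The FASTA file holds one LTR and one internal consensus per family, named
#' `<family>_LTR` and `<family>_INT`. The configuration table (TSV with
#' columns `family`, `min`, `max` and optionally `tsd_length`; one row per
#' size window) defines the size windows.
#'
#' @param fasta Path to the consensus FASTA file.
#' @param config Path to the TSV window configuration, or a data.frame.
#' @return A named list of [family_model] objects.
#' @export
load_family_library <- function(fasta, config) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  cfg <- if (is.data.frame(config)) config else
    read.table(config, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("family", "min", "max")
  if (!all(need %in% names(cfg)))
    stop("family config must have columns: ", paste(need, collapse = ", "))
  fams <- unique(cfg$family)
  out <- lapply(fams, function(f) {
    rows <- cfg[cfg$family == f, , drop = FALSE]
    ltr_id <- paste0(f, "_LTR"); int_id <- paste0(f, "_INT")
    for (id in c(ltr_id, int_id)) {
      if (!id %in% names(seqs))
        stop("family '", f, "': sequence id '", id, "' missing from ", fasta)
    }
    tsd <- if ("tsd_length" %in% names(rows)) rows$tsd_length[1] else 5L
    family_model(f, as.character(seqs[[ltr_id]]), as.character(seqs[[int_id]]),
                 size_windows = as.matrix(rows[, c("min", "max")]),
                 tsd_length = tsd)
  })
  extra <- setdiff(names(seqs), c(paste0(fams, "_LTR"), paste0(fams, "_INT")))
  if (length(extra))
    stop("FASTA ids not referenced by any configured family: ",
         paste(extra, collapse = ", "))
  names(out) <- fams
  out
}

#' Write a family library to FASTA + TSV config
#'
#' Inverse of [load_family_library()].
#'
#' @param families Named list of [family_model] objects.
#' @param fasta,config Output paths.
#' @return Invisibly, the two paths.
#' @export
write_family_library <- function(families, fasta, config) {
  seqs <- Biostrings::DNAStringSet(unlist(unname(lapply(families, function(f)
    stats::setNames(c(f$ltr_consensus, f$internal_consensus),
                    paste0(f$name, c("_LTR", "_INT")))))))
  Biostrings::writeXStringSet(seqs, fasta)
  cfg <- do.call(rbind, lapply(families, function(f)
    data.frame(family = f$name, min = f$size_windows[, 1],
               max = f$size_windows[, 2], tsd_length = f$tsd_length)))
  write.table(cfg, config, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, config))
}
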