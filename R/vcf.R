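# VCF 4.2 round-trip for copy-to-consensus variant tables. The family
# consensus plays the role of the contig; copies are haploid samples.

#' Write a variant table as VCF 4.2
#'
#' The consensus is the contig, positions are 1-based, genotypes are haploid
#' allele indices and missing calls are `.`.
#'
#' @param table A [call_variants()] result.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_vcf <- function(table, file) {
  stopifnot(inherits(table, "variant_table"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=retropop",
    sprintf("##contig=<ID=%s>", table$consensus_id),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype (allele index)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$copy_ids), collapse = "\t")), con)
  if (nrow(table$sites)) {
    gt <- apply(table$geno, 2, function(col)
      ifelse(is.na(col), ".", as.character(col)))
    gt <- matrix(gt, ncol = nrow(table$sites))
    lines <- vapply(seq_len(nrow(table$sites)), function(i) {
      paste(c(table$consensus_id, table$sites$pos[i],
              sprintf("site%d", i), table$sites$ref[i], table$sites$alt[i],
              ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(file)
}

#' Read a VCF written by [write_vcf()] back into a variant table
#'
#' @param file VCF path.
#' @return A `variant_table` (sites, genotypes and copy ids round-trip
#'   exactly).
#' @export
read_vcf <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("malformed VCF: no #CHROM header in ", file)
  cols <- strsplit(hdr, "\t")[[1]]
  copy_ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    contig <- sub("##contig=<ID=([^>,]+).*", "\\1",
                  grep("^##contig", lines, value = TRUE)[1])
    return(structure(list(consensus_id = contig,
                          sites = data.frame(pos = integer(),
                                             ref = character(),
                                             alt = character()),
                          geno = matrix(integer(), nrow = length(copy_ids),
                                        ncol = 0,
                                        dimnames = list(copy_ids, NULL)),
                          copy_ids = copy_ids),
                     class = "variant_table"))
  }
  parts <- strsplit(body, "\t")
  consensus_id <- parts[[1]][1]
  sites <- data.frame(
    pos = vapply(parts, function(p) as.integer(p[2]), 0L),
    ref = vapply(parts, `[`, "", 4),
    alt = vapply(parts, `[`, "", 5),
    stringsAsFactors = FALSE)
  geno <- vapply(parts, function(p) {
    g <- p[-(1:9)]
    out <- suppressWarnings(as.integer(g))
    out
  }, integer(length(copy_ids)))
  geno <- matrix(geno, nrow = length(copy_ids),
                 dimnames = list(copy_ids, NULL))
  structure(list(consensus_id = consensus_id, sites = sites, geno = geno,
                 copy_ids = copy_ids),
            class = "variant_table")
}
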