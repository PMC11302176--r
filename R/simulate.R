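#' Configuration for the synthetic-genome simulator
#'
#' Defines the study conditions for a simulated chromosome carrying implanted
#' full-length LTR retrotransposons with known ground truth: a centromeric
#' interval, per-family copy numbers, subfamily haplotypes distinguished by
#' diagnostic SNPs, per-copy insertion ages realised as LTR divergence,
#' 5' and 3' target-site duplications (TSDs), decoy solo LTRs, truncated
#' copies and recombinant copies with mutated TSDs, and the parameters of the
#' ChIP coverage tracks built on top ([simulate_chip_tracks()]).
#'
#' @param genome_length Chromosome length in bp.
#' @param centromere `c(start, end)` of the centromeric interval (1-based,
#'   inclusive). Non-decoy copies are implanted inside it.
#' @param families Named list of [family_model] objects, or `NULL` to use
#'   [default_families()] generated from `seed`.
#' @param copies_per_family Number of non-decoy full-length implants per
#'   family.
#' @param subfamily_count Number of subfamilies per family.
#' @param subfamily_diagnostic_sites Number of fixed diagnostic SNPs that
#'   define each subfamily haplotype (in the internal region).
#' @param age_range `c(min, max)` insertion ages in years.
#' @param substitution_rate Substitutions per site per year used to convert
#'   age into LTR divergence (default 1.3e-8, the rate proposed for
#'   intergenic regions in grasses).
#' @param ts_tv_ratio Ratio of transitions to transversions among simulated
#'   substitutions.
#' @param age_position_gradient If `TRUE`, younger copies are placed nearer
#'   the centromere midpoint (true age increases with distance from the
#'   midpoint).
#' @param decoy_solo_ltrs,decoy_truncated,decoy_recombinant Number of decoys
#'   per family: lone solo LTRs, 5'-truncated copies, and full-length copies
#'   whose 3' TSD carries >= 2 mismatches (recombinant mimics).
#' @param tsd_length TSD length in bp (default 5).
#' @param chip_enrichment_fold Fold elevation of the experimental ChIP track
#'   over background inside enrichment segments.
#' @param chip_background_mean Mean background read depth (reads/bp).
#' @param chip_enriched_families Family name(s) whose LTRs carry ChIP
#'   enrichment; default the first family.
#' @param seed Integer seed; all simulator output is bit-reproducible for a
#'   fixed seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6,
                       centromere = round(c(0.3, 0.7) * genome_length),
                       families = NULL,
                       copies_per_family = 50,
                       subfamily_count = 2,
                       subfamily_diagnostic_sites = 20,
                       age_range = c(1e4, 2e6),
                       substitution_rate = 1.3e-8,
                       ts_tv_ratio = 2,
                       age_position_gradient = TRUE,
                       decoy_solo_ltrs = 5,
                       decoy_truncated = 5,
                       decoy_recombinant = 5,
                       tsd_length = 5,
                       chip_enrichment_fold = 30,
                       chip_background_mean = 10,
                       chip_enriched_families = NULL,
                       seed = 1) {
  cfg <- list(genome_length = as.numeric(genome_length),
              centromere = as.numeric(centromere),
              families = families,
              copies_per_family = as.integer(copies_per_family),
              subfamily_count = as.integer(subfamily_count),
              subfamily_diagnostic_sites = as.integer(subfamily_diagnostic_sites),
              age_range = as.numeric(age_range),
              substitution_rate = as.numeric(substitution_rate),
              ts_tv_ratio = as.numeric(ts_tv_ratio),
              age_position_gradient = isTRUE(age_position_gradient),
              decoy_solo_ltrs = as.integer(decoy_solo_ltrs),
              decoy_truncated = as.integer(decoy_truncated),
              decoy_recombinant = as.integer(decoy_recombinant),
              tsd_length = as.integer(tsd_length),
              chip_enrichment_fold = as.numeric(chip_enrichment_fold),
              chip_background_mean = as.numeric(chip_background_mean),
              chip_enriched_families = chip_enriched_families,
              seed = as.integer(seed))
  cen_len <- cfg$centromere[2] - cfg$centromere[1] + 1
  if (!(cfg$genome_length > cen_len && cen_len > 0))
    stop("need genome_length > centromere length > 0")
  if (cfg$centromere[1] < 1 || cfg$centromere[2] > cfg$genome_length)
    stop("centromere interval outside genome bounds")
  if (cfg$age_range[1] < 0 || cfg$age_range[1] > cfg$age_range[2])
    stop("age_range must satisfy 0 <= min <= max")
  if (cfg$substitution_rate <= 0) stop("substitution_rate must be > 0")
  if (cfg$tsd_length < 2L) stop("tsd_length must be >= 2")
  if (cfg$copies_per_family < 0L || cfg$subfamily_count < 1L)
    stop("copies_per_family must be >= 0 and subfamily_count >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Default synthetic family models
#'
#' Two families with sizes mirroring the wheat centromeric families: family
#' `famA` builds 7,850 bp elements (window 7,700-8,000 bp, as for RLG_Cereba)
#' and family `famB` builds 4,400 bp elements (windows 4,300-4,500 and
#' 4,700-4,800 bp, as for RLG_Quinta). Consensus sequences are random DNA
#' drawn from the seed.
#'
#' @param seed Integer seed.
#' @param ltr_lengths,internal_lengths Per-family sequence lengths in bp.
#' @return Named list of two [family_model] objects.
#' @export
default_families <- function(seed = 1, ltr_lengths = c(500, 400),
                             internal_lengths = c(6850, 3600)) {
  with_seed(seed, {
    a <- family_model("famA", random_dna(ltr_lengths[1]),
                      random_dna(internal_lengths[1]),
                      size_windows = list(c(7700, 8000)))
    b <- family_model("famB", random_dna(ltr_lengths[2]),
                      random_dna(internal_lengths[2]),
                      size_windows = list(c(4300, 4500), c(4700, 4800)))
    list(famA = a, famB = b)
  })
}

# Apply random substitutions to a sequence: per-site Bernoulli(p), transition
# with probability ts_tv/(ts_tv+1), transversion to one of the two remaining
# bases otherwise. Returns the mutated character string.
mutate_sequence <- function(seq, p, ts_tv_ratio = 2) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < p)
  if (!length(hit)) return(seq)
  is_ts <- runif(length(hit)) < ts_tv_ratio / (ts_tv_ratio + 1)
  for (i in seq_along(hit)) {
    b <- v[hit[i]]
    if (is_ts[i]) {
      v[hit[i]] <- TRANSITION[[b]]
    } else {
      v[hit[i]] <- sample(setdiff(DNA_BASES, c(b, TRANSITION[[b]])), 1L)
    }
  }
  paste(v, collapse = "")
}

# Subfamily haplotypes: fixed alternative bases at diagnostic internal sites.
make_subfamilies <- function(internal, k, n_sites) {
  len <- nchar(internal)
  v <- strsplit(internal, "")[[1]]
  lapply(seq_len(k), function(i) {
    pos <- sort(sample.int(len, n_sites))
    alt <- vapply(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    list(positions = pos, alt = unname(alt))
  })
}

apply_haplotype <- function(seq, hap) {
  v <- strsplit(seq, "")[[1]]
  v[hap$positions] <- hap$alt
  paste(v, collapse = "")
}

#' Simulate a chromosome with implanted retrotransposons and ground truth
#'
#' Builds a random chromosome and implants full-length elements of each
#' configured family, together with decoys. Each implanted copy carries an
#' identical flanking TSD pair (mutated for recombinant decoys), and its two
#' LTRs are independently mutated copies of the family LTR consensus so that
#' the expected pairwise LTR divergence is `2 * substitution_rate * true_age`.
#' Subfamily haplotypes differ at fixed diagnostic sites in the internal
#' region. With `age_position_gradient` on, true age increases with distance
#' from the centromere midpoint.
#'
#' @param config A [sim_config].
#' @return An object of class `te_simulation` with elements:
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] with one chromosome `chr1`.}
#'     \item{truth}{[GenomicRanges::GRanges] of implanted elements (TSDs
#'       excluded from the interval) with metadata columns `copy_id`,
#'       `family`, `subfamily`, `true_age`, `is_decoy`, `decoy_type`,
#'       `tsd5`, `tsd3`, and LTR sub-interval coordinates.}
#'     \item{element_seqs}{[Biostrings::DNAStringSet] of the implanted
#'       sequences (genomic forward strand), named by `copy_id`.}
#'     \item{families}{the family models used.}
#'     \item{config}{the configuration.}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, copies_per_family = 3,
#'                   decoy_solo_ltrs = 1, decoy_truncated = 1,
#'                   decoy_recombinant = 1,
#'                   families = default_families(1, c(60, 50), c(280, 200)),
#'                   seed = 7)
#' \dontrun{sim <- simulate_population(cfg)}
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    families <- config$families %||% default_families(sub_seed(config$seed, 1))
    # adjust default size windows if custom families fall outside them: the
    # caller is responsible; we only validate non-decoy implant lengths below.
    plan <- list(); idx <- 0L
    subfams <- lapply(families, function(f)
      make_subfamilies(f$internal_consensus, config$subfamily_count,
                       min(config$subfamily_diagnostic_sites,
                           nchar(f$internal_consensus))))
    for (fam in families) {
      lens <- list(
        full = nchar(fam$ltr_consensus) * 2 + nchar(fam$internal_consensus),
        solo = nchar(fam$ltr_consensus),
        trunc = nchar(fam$ltr_consensus) +
          floor(nchar(fam$internal_consensus) / 2))
      kinds <- c(rep("full", config$copies_per_family),
                 rep("solo", config$decoy_solo_ltrs),
                 rep("trunc", config$decoy_truncated),
                 rep("recomb", config$decoy_recombinant))
      for (kind in kinds) {
        idx <- idx + 1L
        plan[[idx]] <- list(
          family = fam$name, kind = kind,
          len = lens[[if (kind == "recomb") "full" else kind]],
          is_decoy = kind != "full")
      }
    }
    n <- length(plan)
    if (n == 0L) stop("nothing to implant: zero copies and zero decoys")
    lens <- vapply(plan, `[[`, 0, "len")
    occupied <- sum(lens) + n * 2 * config$tsd_length
    min_gap <- 100
    if (occupied + (n + 1) * min_gap > config$genome_length)
      stop("implant overflow: requested copies cannot fit in genome_length ",
           config$genome_length)
    is_decoy <- vapply(plan, `[[`, TRUE, "is_decoy")
    # target start positions: non-decoys inside the centromere, decoys anywhere
    target <- numeric(n)
    target[!is_decoy] <- runif(sum(!is_decoy), config$centromere[1],
                               config$centromere[2] - lens[!is_decoy])
    target[is_decoy] <- runif(sum(is_decoy), 1,
                              config$genome_length - lens[is_decoy])
    ord <- order(target)
    plan <- plan[ord]; lens <- lens[ord]; target <- target[ord]
    is_decoy <- is_decoy[ord]

    # resolve actual, non-overlapping placements left to right
    actual <- numeric(n); prev_end <- 0
    for (i in seq_len(n)) {
      actual[i] <- max(round(target[i]), prev_end + min_gap + 1)
      prev_end <- actual[i] + lens[i] + 2 * config$tsd_length - 1
    }
    if (prev_end + min_gap > config$genome_length)
      stop("implant overflow: requested copies cannot fit in genome_length ",
           config$genome_length)

    # ages: per family, uniform over age_range; with the gradient, ranks of
    # age follow ranks of distance from the centromere midpoint (non-decoys)
    mid <- mean(config$centromere)
    true_age <- runif(n, config$age_range[1], config$age_range[2])
    if (config$age_position_gradient) {
      centers <- actual + lens / 2
      for (fname in names(families)) {
        sel <- which(!is_decoy &
                       vapply(plan, `[[`, "", "family") == fname)
        if (length(sel) > 1) {
          d <- abs(centers[sel] - mid)
          true_age[sel] <- sort(true_age[sel])[rank(d, ties.method = "first")]
        }
      }
    }

    # subfamilies are temporal waves: copies of similar age share a
    # subfamily haplotype (different subfamilies were active at different
    # times), so subfamily index follows the age rank within each family
    fam_of <- vapply(plan, `[[`, "", "family")
    sub_idx <- integer(n)
    for (fname in names(families)) {
      sel <- which(fam_of == fname)
      r <- rank(true_age[sel], ties.method = "first")
      sub_idx[sel] <- pmin(config$subfamily_count,
                           ceiling(r / length(sel) * config$subfamily_count))
    }

    # wave templates: copies are drawn from a master lineage that drifts at
    # the substitution rate between amplification waves (the master-copy
    # model of retrotransposon bursts), so copies of similar age share
    # template sequence in addition to their subfamily diagnostics; each
    # copy then accumulates private substitutions after insertion
    t_ts0 <- config$ts_tv_ratio / (config$ts_tv_ratio + 1)
    templates <- list()
    for (fname in names(families)) {
      fam <- families[[fname]]
      sel <- fam_of == fname
      K <- config$subfamily_count
      mean_age <- vapply(seq_len(K), function(k) {
        a <- true_age[sel & sub_idx == k]
        if (length(a)) mean(a) else NA_real_
      }, 0)
      ltr_t <- fam$ltr_consensus
      int_t <- fam$internal_consensus
      tl <- vector("list", K)
      prev_age <- NULL
      for (k in order(-mean_age, na.last = TRUE)) {
        if (!is.na(mean_age[k])) {
          if (!is.null(prev_age)) {
            dp <- config$substitution_rate * (prev_age - mean_age[k])
            ltr_t <- mutate_sequence(ltr_t, dp, config$ts_tv_ratio)
            int_t <- mutate_sequence(int_t, dp, config$ts_tv_ratio)
          }
          prev_age <- mean_age[k]
        }
        tl[[k]] <- list(
          ltr = ltr_t,
          internal = apply_haplotype(int_t, subfams[[fname]][[k]]))
      }
      templates[[fname]] <- tl
    }

    # build sequences and the genome. The per-LTR per-site mutation
    # probability q is calibrated so that the expected observed pairwise
    # difference proportion between the two independently mutated LTRs equals
    # exactly d = 2 * rate * age: with both sites mutated, the two LTRs end
    # up identical with probability Ps = t^2 + (1-t)^2/2 (t = transition
    # probability), so E[diff] = 2q - q^2 (1 + Ps); solve for q.
    t_ts <- config$ts_tv_ratio / (config$ts_tv_ratio + 1)
    Ps <- t_ts^2 + (1 - t_ts)^2 / 2
    p_of <- function(age) {
      d <- 2 * config$substitution_rate * age
      if ((1 + Ps) * d >= 1)
        stop("age_range too large for the substitution rate: ",
             "expected divergence saturates")
      (1 - sqrt(1 - (1 + Ps) * d)) / (1 + Ps)
    }
    tsd_alphabet <- DNA_BASES
    pieces <- character(2 * n + 1)
    truth <- vector("list", n)
    eseqs <- character(n)
    prev_end <- 0
    counter <- stats::setNames(integer(length(families)), names(families))
    for (i in seq_len(n)) {
      fam <- families[[plan[[i]]$family]]
      kind <- plan[[i]]$kind
      age <- true_age[i]
      p <- p_of(age)
      sub_i <- sub_idx[i]
      tmpl <- templates[[fam$name]][[sub_i]]
      ltr_len <- nchar(fam$ltr_consensus)
      if (kind %in% c("full", "recomb")) {
        ltr5 <- mutate_sequence(tmpl$ltr, p, config$ts_tv_ratio)
        ltr3 <- mutate_sequence(tmpl$ltr, p, config$ts_tv_ratio)
        internal <- mutate_sequence(tmpl$internal, p, config$ts_tv_ratio)
        elem <- paste0(ltr5, internal, ltr3)
        ltr5_off <- c(1L, ltr_len)
        ltr3_off <- c(nchar(elem) - ltr_len + 1L, nchar(elem))
      } else if (kind == "solo") {
        elem <- mutate_sequence(tmpl$ltr, p, config$ts_tv_ratio)
        ltr5_off <- c(1L, ltr_len); ltr3_off <- c(NA_integer_, NA_integer_)
      } else { # trunc: second half of the internal region plus the 3' LTR
        internal <- mutate_sequence(tmpl$internal, p, config$ts_tv_ratio)
        half <- substr(internal, nchar(internal) - plan[[i]]$len + ltr_len + 1L,
                       nchar(internal))
        ltr3 <- mutate_sequence(tmpl$ltr, p, config$ts_tv_ratio)
        elem <- paste0(half, ltr3)
        ltr5_off <- c(NA_integer_, NA_integer_)
        ltr3_off <- c(nchar(elem) - ltr_len + 1L, nchar(elem))
      }
      strand <- sample(c("+", "-"), 1L)
      inserted <- if (strand == "-") revcomp_chr(elem) else elem
      tsd <- paste(sample(tsd_alphabet, config$tsd_length, replace = TRUE),
                   collapse = "")
      tsd3 <- tsd
      if (kind == "recomb") { # mutate the 3' TSD at 2 positions
        v <- strsplit(tsd3, "")[[1]]
        pos <- sample.int(length(v), 2L)
        for (j in pos) v[j] <- sample(setdiff(DNA_BASES, v[j]), 1L)
        tsd3 <- paste(v, collapse = "")
      }
      gap_len <- actual[i] - prev_end - 1
      pieces[2 * i - 1] <- random_dna(gap_len)
      pieces[2 * i] <- paste0(tsd, inserted, tsd3)
      elem_start <- actual[i] + config$tsd_length
      elem_end <- elem_start + nchar(elem) - 1L
      # genomic coordinates of the LTR sub-intervals (element-local offsets
      # flipped for minus-strand implants)
      to_genomic <- function(off) {
        if (anyNA(off)) return(c(NA_integer_, NA_integer_))
        if (strand == "+") elem_start + off - 1L
        else c(elem_end - off[2] + 1L, elem_end - off[1] + 1L)
      }
      g5 <- to_genomic(ltr5_off); g3 <- to_genomic(ltr3_off)
      counter[fam$name] <- counter[fam$name] + 1L
      cid <- sprintf("%s_%03d", fam$name, counter[fam$name])
      truth[[i]] <- data.frame(
        chrom = "chr1", start = elem_start, end = elem_end, strand = strand,
        copy_id = cid, family = fam$name,
        subfamily = paste0(fam$name, "_s", sub_i),
        true_age = age, is_decoy = is_decoy[i],
        decoy_type = if (kind == "full") "none" else kind,
        tsd5 = tsd, tsd3 = tsd3,
        ltr5_start = g5[1], ltr5_end = g5[2],
        ltr3_start = g3[1], ltr3_end = g3[2],
        stringsAsFactors = FALSE)
      eseqs[i] <- inserted
      prev_end <- actual[i] + nchar(inserted) + 2 * config$tsd_length - 1
    }
    pieces[2 * n + 1] <- random_dna(config$genome_length - prev_end)
    genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- "chr1"
    tdf <- do.call(rbind, truth)
    gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(tdf$start, tdf$end), strand = tdf$strand)
    GenomeInfoDb::seqlengths(gr) <- c(chr1 = as.integer(config$genome_length))
    S4Vectors::mcols(gr) <- tdf[, setdiff(names(tdf),
                                          c("chrom", "start", "end", "strand"))]
    es <- Biostrings::DNAStringSet(eseqs)
    names(es) <- tdf$copy_id
    # non-overlap among implants is by construction; assert anyway
    stopifnot(!any(IRanges::overlapsAny(gr, drop.self = TRUE)))
    structure(list(genome = genome, truth = gr, element_seqs = es,
                   families = families, config = config),
              class = "te_simulation")
  })
}

#' @export
print.te_simulation <- function(x, ...) {
  cat(sprintf(
    "te_simulation: %s bp genome, %d implants (%d non-decoy, %d decoy), %d families\n",
    format(sum(Biostrings::width(x$genome)), big.mark = ","), length(x$truth),
    sum(!x$truth$is_decoy), sum(x$truth$is_decoy), length(x$families)))
  invisible(x)
}

#' Simulate ChIP-seq coverage tracks over a simulated genome
#'
#' Produces an experimental track elevated by `fold` over background inside
#' enrichment segments (by default the LTR intervals of non-decoy copies of
#' the enriched families), plus background-only control and mock tracks.
#' Depths are per-base Poisson counts.
#'
#' @param sim A [simulate_population()] result.
#' @param fold Enrichment fold (>= 1) inside segments; default from the
#'   simulation config.
#' @param background_mean Background mean depth; default from the config.
#' @param enriched_families Families whose non-decoy LTRs are enriched;
#'   default from the config (first family if unset).
#' @param seed Seed for the Poisson draws; default derived from the config
#'   seed.
#' @return A list with `experimental` (a [coverage_track], label `CENH3`),
#'   `controls` (list with one `H3K4me3` track), `mocks` (list with one
#'   `CENH3_mock` track), and `segments` (a `GRanges` of enrichment segments
#'   with the true `fold`).
#' @export
simulate_chip_tracks <- function(sim, fold = NULL, background_mean = NULL,
                                 enriched_families = NULL, seed = NULL) {
  stopifnot(inherits(sim, "te_simulation"))
  cfg <- sim$config
  fold <- fold %||% cfg$chip_enrichment_fold
  background_mean <- background_mean %||% cfg$chip_background_mean
  enriched_families <- enriched_families %||%
    (cfg$chip_enriched_families %||% names(sim$families)[1])
  seed <- seed %||% sub_seed(cfg$seed, 2)
  if (fold < 1) stop("chip_enrichment_fold must be >= 1")
  glen <- Biostrings::width(sim$genome)[1]
  tr <- sim$truth
  sel <- !tr$is_decoy & tr$family %in% enriched_families
  seg <- list()
  for (cols in list(c("ltr5_start", "ltr5_end"), c("ltr3_start", "ltr3_end"))) {
    s <- S4Vectors::mcols(tr)[[cols[1]]][sel]
    e <- S4Vectors::mcols(tr)[[cols[2]]][sel]
    ok <- !is.na(s)
    seg[[length(seg) + 1L]] <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(s[ok], e[ok]))
  }
  segments <- sort(do.call(c, seg))
  segments$fold <- fold
  with_seed(seed, {
    lambda <- rep(background_mean, glen)
    for (i in seq_along(segments)) {
      lambda[IRanges::start(segments)[i]:IRanges::end(segments)[i]] <-
        background_mean * fold
    }
    experimental <- coverage_track("CENH3", list(chr1 = rpois(glen, lambda)))
    control <- coverage_track("H3K4me3",
                              list(chr1 = rpois(glen, background_mean)))
    mock <- coverage_track("CENH3_mock",
                           list(chr1 = rpois(glen, background_mean)))
    list(experimental = experimental, controls = list(control),
         mocks = list(mock), segments = segments)
  })
}

#' Write simulation artifacts to disk
#'
#' Writes the genome as FASTA, the truth as GFF3 (1-based, inclusive, with
#' `true_age`, `subfamily`, `tsd5`, `tsd3` attributes) and as a tab-separated
#' truth table.
#'
#' @param sim A [simulate_population()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "truth.gff3")
  tsv <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa)
  gr <- sim$truth
  S4Vectors::mcols(gr)$type <- "transposable_element"
  S4Vectors::mcols(gr)$ID <- gr$copy_id
  rtracklayer::export(gr, gff, format = "gff3")
  df <- as.data.frame(sim$truth)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genome = fa, gff3 = gff, truth = tsv))
}
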