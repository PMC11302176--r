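# End-to-end orchestration: simulate -> discover -> date -> popgen -> chip ->
# mantel, with every threshold in one auditable configuration object and a
# machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain with its default:
#' minor allele frequency 0.01, per-site missing cutoff 0.90, hot-spot fold 5
#' and minimum length 100 bp, peak classification >= 90 bp at >= 70%
#' identity, TSD filter at 1 mismatch, substitution rate 1.3e-8 per site per
#' year, 9999 Mantel permutations and 30-copy consensus sampling.
#'
#' @param sim A [sim_config()] describing the synthetic input (or `NULL`
#'   when running on external files).
#' @param maf,missing_cutoff Variant-site thresholds.
#' @param hotspot_fold,hotspot_min_len Hot-spot caller thresholds.
#' @param peak_min_len,peak_min_identity Peak classification thresholds.
#' @param tsd_max_mismatch TSD filter threshold.
#' @param rate Substitution rate per site per year.
#' @param permutations Mantel permutations.
#' @param consensus_sample Copies sampled for consensus building.
#' @param min_ltr_identity,min_ltr_coverage LTR hit thresholds.
#' @param seed Master seed for all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            maf = 0.01, missing_cutoff = 0.90,
                            hotspot_fold = 5, hotspot_min_len = 100L,
                            peak_min_len = 90L, peak_min_identity = 0.70,
                            tsd_max_mismatch = 1L, rate = 1.3e-8,
                            permutations = 9999L, consensus_sample = 30L,
                            min_ltr_identity = 0.8, min_ltr_coverage = 0.8,
                            seed = 1L) {
  cfg <- list(sim = sim, maf = maf, missing_cutoff = missing_cutoff,
              hotspot_fold = hotspot_fold,
              hotspot_min_len = as.integer(hotspot_min_len),
              peak_min_len = as.integer(peak_min_len),
              peak_min_identity = peak_min_identity,
              tsd_max_mismatch = as.integer(tsd_max_mismatch),
              rate = rate, permutations = as.integer(permutations),
              consensus_sample = as.integer(consensus_sample),
              min_ltr_identity = min_ltr_identity,
              min_ltr_coverage = min_ltr_coverage,
              seed = as.integer(seed))
  stopifnot(maf >= 0, maf <= 1, missing_cutoff >= 0, missing_cutoff <= 1,
            hotspot_fold >= 1, hotspot_min_len >= 1, peak_min_len >= 1,
            peak_min_identity >= 0, peak_min_identity <= 1,
            tsd_max_mismatch >= 0, rate > 0, permutations >= 1,
            consensus_sample >= 2,
            min_ltr_identity > 0, min_ltr_identity <= 1,
            min_ltr_coverage > 0, min_ltr_coverage <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a synthetic genome
#'
#' Simulates a genome with ground truth, discovers full-length copies of
#' every family, applies the TSD filter, dates insertions, calls variants and
#' runs PCA per family, detects and classifies CENH3 hot spots, compiles
#' consensus coverage profiles and performs the centromere-midpoint Mantel
#' test. All artifacts (FASTA, GFF3, BED, bedGraph, VCF, TSVs and a JSON run
#' manifest listing versions, seeds, thresholds and per-stage counts) are
#' written to `out_dir`. Idempotent for fixed seeds.
#'
#' @param config A [pipeline_config()] with a non-`NULL` `sim`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `tracks`, `copies`, `ages`, `popgen`, `peaks`, `enrichment`,
#'   `profiles`, `mantel`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(config$sim))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  sim <- run_stage("simulate", {
    s <- simulate_population(config$sim)
    write_simulation(s, out_dir)
    write_family_library(s$families, file.path(out_dir, "families.fa"),
                         file.path(out_dir, "families.tsv"))
    s
  })
  counts$implants <- length(sim$truth)

  tracks <- run_stage("chip_tracks", {
    tr <- simulate_chip_tracks(sim)
    write_bedgraph(tr$experimental, file.path(out_dir, "cenh3.bedgraph"))
    write_bedgraph(tr$controls[[1]], file.path(out_dir, "control.bedgraph"))
    write_bedgraph(tr$mocks[[1]], file.path(out_dir, "mock.bedgraph"))
    tr
  })

  copies <- run_stage("discover", {
    found <- lapply(sim$families, function(fam)
      find_full_length_copies(sim$genome, fam,
                              min_ltr_identity = config$min_ltr_identity,
                              min_ltr_coverage = config$min_ltr_coverage))
    all <- sort(do.call(c, unname(found)))
    all <- extract_tsd(all, sim$genome,
                       tsd_length = sim$families[[1]]$tsd_length)
    counts$discovered <- length(all)
    filtered <- filter_by_tsd(all, config$tsd_max_mismatch)
    counts$tsd_filtered <- length(filtered)
    write_copies(filtered, gff3 = file.path(out_dir, "copies.gff3"),
                 bed = file.path(out_dir, "copies.bed"))
    filtered
  })
  message(sprintf("discover: %d copies (%d after TSD filter)",
                  counts$discovered, counts$tsd_filtered))

  ages <- run_stage("date", {
    a <- estimate_ages(copies, sim$genome, rate = config$rate)
    write_ages(a, file.path(out_dir, "ages.tsv"))
    a
  })
  counts$dated <- sum(!is.na(ages$age))

  popgen <- run_stage("popgen", {
    out <- list()
    for (fname in names(sim$families)) {
      fc <- copies[copies$family == fname]
      if (length(fc) < 2L) next
      seqs <- copy_sequences(fc, sim$genome)
      cons <- build_consensus(seqs, sample_n = config$consensus_sample,
                              seed = sub_seed(config$seed, 10))
      vt <- call_variants(seqs, cons, maf = config$maf,
                          missing_cutoff = config$missing_cutoff,
                          consensus_id = fname)
      write_vcf(vt, file.path(out_dir, paste0(fname, ".vcf")))
      pca <- if (nrow(vt$sites) >= 1L) run_pca(vt) else NULL
      if (!is.null(pca))
        write_pca(pca, file.path(out_dir, paste0(fname, "_pca.tsv")))
      dmat <- pairwise_snp_distance(vt)
      write_distance_matrix(dmat, file.path(out_dir,
                                            paste0(fname, "_snpdist.tsv")))
      out[[fname]] <- list(consensus = cons, variants = vt, pca = pca,
                           snp_dist = dmat, copies = fc)
    }
    out
  })
  counts$variant_sites <- vapply(popgen, function(p) nrow(p$variants$sites), 0L)

  cen_gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(config$sim$centromere[1], config$sim$centromere[2]))
  chip <- run_stage("chip", {
    lib <- Biostrings::DNAStringSet(vapply(sim$families, function(f)
      paste0(f$ltr_consensus, f$internal_consensus, f$ltr_consensus), ""))
    names(lib) <- names(sim$families)
    peaks <- detect_hotspots(tracks$experimental,
                             c(tracks$controls, tracks$mocks), cen_gr,
                             min_len = config$hotspot_min_len,
                             fold = config$hotspot_fold)
    peaks <- classify_hotspots(peaks, sim$genome, lib,
                               min_len = config$peak_min_len,
                               min_identity = config$peak_min_identity)
    if (length(peaks)) {
      bedp <- peaks
      S4Vectors::mcols(bedp) <- S4Vectors::DataFrame(
        name = ifelse(is.na(peaks$family), "unclassified", peaks$family))
      rtracklayer::export(bedp, file.path(out_dir, "hotspots.bed"),
                          format = "bed")
      write.table(as.data.frame(peaks), file.path(out_dir, "hotspots.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    fam_bp <- tapply(IRanges::width(copies), copies$family, sum)
    pk_counts <- table(factor(peaks$family, levels = names(sim$families)))
    enr <- family_enrichment(stats::setNames(as.numeric(pk_counts),
                                             names(pk_counts)), fam_bp)
    write.table(enr, file.path(out_dir, "family_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profiles <- list()
    for (fname in names(popgen)) {
      pr <- consensus_profiles(popgen[[fname]]$copies, sim$genome,
                               popgen[[fname]]$consensus,
                               c(list(tracks$experimental), tracks$controls,
                                 tracks$mocks))
      write_profile(pr, file.path(out_dir, paste0(fname, "_profile.tsv")))
      profiles[[fname]] <- pr
    }
    list(peaks = peaks, enrichment = enr, profiles = profiles)
  })
  counts$hotspots <- length(chip$peaks)

  mantel <- run_stage("mantel", {
    cen <- centromere_def("chr1", config$sim$centromere[1],
                          config$sim$centromere[2])
    out <- list()
    for (fname in names(popgen)) {
      fc <- popgen[[fname]]$copies
      keep <- fc$copy_id %in% rownames(popgen[[fname]]$snp_dist)
      fc <- fc[keep]
      pos <- stats::setNames((IRanges::start(fc) + IRanges::end(fc)) / 2,
                             fc$copy_id)
      pmat <- positional_distance_matrix(pos, cen)
      gmat <- popgen[[fname]]$snp_dist[names(pos), names(pos)]
      out[[fname]] <- mantel_test(gmat, pmat,
                                  permutations = config$permutations,
                                  seed = sub_seed(config$seed, 20))
    }
    df <- data.frame(family = names(out),
                     statistic = vapply(out, `[[`, 0, "statistic"),
                     p_value = vapply(out, `[[`, 0, "p_value"),
                     permutations = vapply(out, `[[`, 0L, "permutations"),
                     row.names = NULL)
    write.table(df, file.path(out_dir, "mantel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  })

  manifest <- list(
    package = "retropop",
    version = as.character(utils::packageVersion("retropop")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, sim_seed = config$sim$seed,
    thresholds = config[setdiff(names(config), c("sim", "seed"))],
    sim = config$sim[setdiff(names(config$sim), "families")],
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, tracks = tracks, copies = copies, ages = ages,
                 popgen = popgen, peaks = chip$peaks,
                 enrichment = chip$enrichment, profiles = chip$profiles,
                 mantel = mantel, manifest = manifest))
}
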