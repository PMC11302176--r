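flat_track <- function(label, depth, len = 2000) {
  coverage_track(label, list(chr1 = rep(depth, len)))
}

test_that("region averages use union semantics", {
  tr <- flat_track("x", 7)
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 500), c(100, 800)))
  expect_equal(region_average(tr, r), 7)

  d <- rep(0L, 2000); d[101:200] <- 10L; d[301:400] <- 20L
  tr2 <- coverage_track("y", list(chr1 = d))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 400)))
  expect_equal(region_average(tr2, r2), 15)

  # overlapping regions do not double-count
  r3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 151), c(200, 200)))
  expect_equal(region_average(tr2, r3), 10)
  expect_error(region_average(tr, GenomicRanges::GRanges()), "empty")
})

test_that("hot-spot caller applies both fold rules with exact boundaries", {
  len <- 3000
  d <- rep(10L, len)
  d[1001:1120] <- 60L          # 120 bp qualifying run
  exp <- coverage_track("CENH3", list(chr1 = d))
  ctl <- flat_track("ctl", 6, len)   # control sum 12 with two tracks of 6
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, len))
  base <- 10
  pk <- detect_hotspots(exp, list(ctl, ctl), regions, baseline = base)
  expect_length(pk, 1)
  expect_equal(IRanges::start(pk), 1001)
  expect_equal(IRanges::end(pk), 1120)
  expect_equal(pk$mean_exp, 60)
  expect_equal(pk$fold_over_baseline, 6)
  expect_equal(pk$control_sum_max, 12)

  # a 90 bp qualifying run is below the minimum length
  d2 <- rep(10L, len); d2[1001:1090] <- 60L
  pk2 <- detect_hotspots(coverage_track("CENH3", list(chr1 = d2)),
                         list(ctl, ctl), regions, baseline = base)
  expect_length(pk2, 0)

  # experimental identical to control: zero peaks
  pk3 <- detect_hotspots(flat_track("CENH3", 6, len), list(ctl), regions)
  expect_length(pk3, 0)

  expect_error(detect_hotspots(flat_track("CENH3", 0, len), list(ctl),
                               regions), "baseline")
})

test_that("hot-spot boundaries equal a brute-force per-base oracle", {
  withr::with_seed(33, {
    for (rep in 1:3) {
      len <- 5000
      d <- rpois(len, 10)
      # implant a few strong spikes of random lengths
      for (k in 1:4) {
        s <- sample(len - 400, 1); w <- sample(60:250, 1)
        d[s:(s + w - 1)] <- rpois(w, 120)
      }
      exp <- coverage_track("CENH3", list(chr1 = as.integer(d)))
      c1 <- coverage_track("c1", list(chr1 = rpois(len, 8)))
      c2 <- coverage_track("c2", list(chr1 = rpois(len, 8)))
      regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, len - 100))
      base <- region_average(exp, regions)
      pk <- detect_hotspots(exp, list(c1, c2), regions)
      mask <- logical(len); mask[101:(len - 100)] <- TRUE
      runs <- hotspot_oracle(d, c1$depths$chr1 + c2$depths$chr1, mask, base)
      expect_equal(length(pk), length(runs))
      if (length(runs)) {
        expect_equal(IRanges::start(pk), vapply(runs, `[`, 0, 1))
        expect_equal(IRanges::end(pk), vapply(runs, `[`, 0, 2))
      }
    }
  })
})

test_that("peaks classify by alignment length and identity thresholds", {
  fams <- small_families()
  lib <- Biostrings::DNAStringSet(vapply(fams, function(f)
    paste0(f$ltr_consensus, f$internal_consensus, f$ltr_consensus), ""))
  names(lib) <- names(fams)

  exact <- substr(as.character(lib[["famA"]]), 201, 300)
  cl <- classify_peak(exact, lib)
  expect_identical(cl$family, "famA")
  expect_equal(cl$identity, 1.0)

  # ~65% identity over 95 bp: below the 70% rule everywhere
  v <- strsplit(substr(as.character(lib[["famA"]]), 201, 295), "")[[1]]
  idx <- seq(1, 95, by = 3)
  for (p in idx) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  cl2 <- classify_peak(paste(v, collapse = ""), lib)
  expect_true(is.na(cl2$family))

  cl3 <- classify_peak(random_seq(150, seed = 12), lib)
  expect_true(is.na(cl3$family))
  expect_error(classify_peak("ACGT", Biostrings::DNAStringSet()), "non-empty")
})

test_that("family enrichment normalises by annotated megabases", {
  enr <- family_enrichment(c(famA = 10), c(famA = 1e6))
  expect_equal(enr$peaks_per_mb, 10)
  enr2 <- family_enrichment(c(famA = 10), c(famA = 2e6))
  expect_equal(enr2$peaks_per_mb, 5)
  expect_warning(family_enrichment(c(famA = 10, famB = 3), c(famA = 1e6, famB = 0)),
                 "famB")
})

test_that("projection conserves depth and omits insertions", {
  cons <- random_seq(600, seed = 13)
  genome_chr <- paste0(random_seq(100, seed = 14), cons,
                       random_seq(100, seed = 15))
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_chr))
  track <- flat_track("CENH3", 10, nchar(genome_chr))
  copy <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 700),
                                 strand = "+", copy_id = "c1")
  pr <- project_coverage(copy, genome, cons, track)
  expect_equal(pr, rep(10, 600))

  # 50 bp insertion: total projected depth = 10 * (copy length - 50)
  ins_chr <- paste0(random_seq(100, seed = 16), substr(cons, 1, 300),
                    random_seq(50, seed = 17), substr(cons, 301, 600),
                    random_seq(100, seed = 18))
  genome2 <- Biostrings::DNAStringSet(c(chr1 = ins_chr))
  copy2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 750),
                                  strand = "+", copy_id = "c2")
  pr2 <- project_coverage(copy2, genome2, cons,
                          flat_track("CENH3", 10, nchar(ins_chr)))
  expect_equal(sum(pr2), 10 * (650 - 50))

  # deletion spanning consensus 200-250: zero contribution there
  del_chr <- paste0(random_seq(100, seed = 19), substr(cons, 1, 199),
                    substr(cons, 251, 600), random_seq(100, seed = 20))
  genome3 <- Biostrings::DNAStringSet(c(chr1 = del_chr))
  copy3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 649),
                                  strand = "+", copy_id = "c3")
  pr3 <- project_coverage(copy3, genome3, cons,
                          flat_track("CENH3", 10, nchar(del_chr)))
  expect_equal(pr3[200:250], rep(0, 51))
  expect_equal(sum(pr3), 10 * 549)

  expect_error(project_coverage(
    GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10)), genome, cons,
    track), "chromosome mismatch")
})

test_that("minus-strand copies project in consensus orientation", {
  cons <- random_seq(400, seed = 21)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  chr <- paste0(random_seq(50, seed = 22), rc, random_seq(50, seed = 23))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  d <- rep(1L, nchar(chr)); d[51:450] <- as.integer(1:400)  # gradient depth
  track <- coverage_track("CENH3", list(chr1 = d))
  copy <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 450),
                                 strand = "-", copy_id = "c1")
  pr <- project_coverage(copy, genome, cons, track)
  # genomic position 450 (depth 400) is the copy's first base = consensus 1
  expect_equal(pr, rev(1:400))
})

test_that("profiles compile additively with a mock-ratio track", {
  p1 <- list(rep(2, 100)); p2 <- list(rep(3, 100))
  prof <- compile_profile(list(CENH3 = c(p1, p2),
                               CENH3_mock = list(rep(1, 100), rep(1, 100))))
  expect_equal(prof$profiles$CENH3, rep(5, 100))
  expect_equal(prof$ratio, rep(5 / 3, 100))
  one <- compile_profile(list(CENH3 = p1))
  expect_equal(one$profiles$CENH3, p1[[1]])
  expect_error(compile_profile(list()), "at least one")
})

test_that("ratio profile maxima fall inside LTR coordinates of the consensus", {
  fams <- small_families()
  cfg <- sim_config(genome_length = 4e5, copies_per_family = 10,
                    families = fams["famA"], decoy_solo_ltrs = 0,
                    decoy_truncated = 0, decoy_recombinant = 0,
                    age_range = c(1e4, 2e5), seed = 27)
  sim <- simulate_population(cfg)
  tracks <- simulate_chip_tracks(sim)
  fc <- sim$truth
  seqs <- copy_sequences(fc, sim$genome)
  cons <- build_consensus(seqs, seed = 1)
  prof <- consensus_profiles(fc, sim$genome, cons,
                             c(list(tracks$experimental), tracks$controls,
                               tracks$mocks))
  ltr_len <- nchar(fams$famA$ltr_consensus)
  clen <- length(prof$ratio)
  in_ltr <- c(seq_len(ltr_len), (clen - ltr_len + 1):clen)
  # the top decile of ratio positions must lie in the LTRs
  top <- order(prof$ratio, decreasing = TRUE)[seq_len(round(clen / 10))]
  expect_true(all(top %in% in_ltr))
})
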