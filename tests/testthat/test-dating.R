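test_that("identical LTRs align full length with zero differences", {
  s <- random_seq(500, seed = 1)
  aln <- align_ltr_pair(s, s)
  expect_equal(nchar(aln$aligned_a), 500)
  cnt <- count_site_patterns(aln)
  expect_equal(cnt, list(ungapped_sites = 500L, transitions = 0L,
                         transversions = 0L))
})

test_that("local alignment matches an independent dynamic-programming oracle", {
  withr::with_seed(2, {
    for (rep in 1:8) {
      core <- random_seq(60)
      v <- strsplit(core, "")[[1]]
      pos <- sample(60, 3)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      core2 <- paste(v, collapse = "")
      # unrelated (cross-unalignable) tails flanking the shared core
      a <- paste0(strrep("A", 25), core, strrep("G", 25))
      b <- paste0(strrep("C", 25), core2, strrep("T", 25))
      aln <- align_ltr_pair(a, b)
      expect_equal(aln$score, sw_oracle(a, b))
      # the aligned region covers (essentially) the shared core, not the tails
      cnt <- count_site_patterns(aln)
      expect_gte(cnt$ungapped_sites, 50)
      expect_lte(nchar(aln$aligned_a), 64)
    }
  })
})

test_that("alignment is symmetric under argument order", {
  a <- random_seq(200, seed = 3)
  v <- strsplit(a, "")[[1]]; v[c(20, 50, 90)] <- c("A", "C", "G")
  b <- paste(v, collapse = "")
  f <- align_ltr_pair(a, b)
  r <- align_ltr_pair(b, a)
  expect_identical(f$aligned_a, r$aligned_b)
  expect_identical(f$aligned_b, r$aligned_a)
  expect_equal(f$score, r$score)
})

test_that("site patterns distinguish transitions from transversions", {
  mk <- function(a, b) list(aligned_a = a, aligned_b = b)
  base <- strrep("A", 97)
  aln <- mk(paste0(base, "A", "C", "A"), paste0(base, "G", "T", "C"))
  expect_equal(count_site_patterns(aln),
               list(ungapped_sites = 100L, transitions = 2L,
                    transversions = 1L))
  # gap and N columns are excluded
  aln <- mk("AC-GT", "ACCGT")
  expect_equal(count_site_patterns(aln)$ungapped_sites, 4L)
  aln <- mk("ACNGT", "ACCGT")
  expect_equal(count_site_patterns(aln)$ungapped_sites, 4L)
})

test_that("K2P distance matches the closed form and its properties", {
  expect_equal(k2p_distance(100, 0, 0), 0)
  expect_equal(k2p_distance(100, 2, 1), 0.030697, tolerance = 1e-4)
  withr::with_seed(4, {
    for (i in 1:1000) {
      P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.3)
      if (2 * P + Q >= 0.95 || 2 * Q >= 0.95) next
      d <- k2p_distance(1e6, round(P * 1e6), round(Q * 1e6))
      Pr <- round(P * 1e6) / 1e6; Qr <- round(Q * 1e6) / 1e6
      expect_equal(d, k2p_oracle(Pr, Qr), tolerance = 1e-12)
      expect_gte(d, Pr + Qr - 1e-12)
    }
  })
  expect_error(k2p_distance(100, 40, 30), "saturation")
  expect_error(k2p_distance(0, 0, 0), "ungapped_sites")
})

test_that("K2P distance agrees with ape's K80 model", {
  skip_if_not_installed("ape")
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- 2000
      a <- sample(c("a", "c", "g", "t"), n, replace = TRUE)
      b <- a
      ts_pos <- sample(n, 30); tv_pos <- sample(setdiff(seq_len(n), ts_pos), 15)
      tsmap <- c(a = "g", g = "a", c = "t", t = "c")
      b[ts_pos] <- tsmap[b[ts_pos]]
      tvmap <- c(a = "c", c = "a", g = "t", t = "g")
      b[tv_pos] <- tvmap[b[tv_pos]]
      bin <- ape::as.DNAbin(rbind(a = a, b = b))
      ape_d <- as.numeric(ape::dist.dna(bin, model = "K80"))
      ours <- k2p_distance(n, length(ts_pos), length(tv_pos))
      expect_equal(ours, ape_d, tolerance = 1e-9)
    }
  })
})

test_that("distance converts to age linearly", {
  expect_equal(date_insertion(0), 0)
  expect_equal(date_insertion(2.6e-3, 1.3e-8), 1e5)
  d <- runif(5)
  expect_equal(date_insertion(2 * d), 2 * date_insertion(d))
  expect_error(date_insertion(0.1, rate = 0), "rate")
  expect_error(date_insertion(-0.1), "distance")
})

test_that("age percentile filter drops the upper tail", {
  expect_equal(age_percentile_filter(1:100, 99), 1:99)
  expect_equal(age_percentile_filter(rep(7, 10)), rep(7, 10))
  expect_equal(age_percentile_filter(1:100, 100), 1:100)
  expect_error(age_percentile_filter(numeric(0)), "non-empty")
})

test_that("the dating chain is strand invariant", {
  withr::with_seed(6, {
    l5 <- random_seq(400)
    v <- strsplit(l5, "")[[1]]
    pos <- sample(400, 10)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    l3 <- paste(v, collapse = "")
  })
  chain <- function(a, b) {
    cnt <- count_site_patterns(align_ltr_pair(a, b))
    d <- k2p_distance(cnt$ungapped_sites, cnt$transitions, cnt$transversions)
    c(unlist(cnt), distance = d, age = date_insertion(d))
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(chain(l5, l3), chain(rc(l5), rc(l3)))
})

test_that("estimate_ages recovers implanted ages from truth annotations", {
  fams <- default_families(3, c(1000, 80), c(200, 300))
  cfg <- sim_config(genome_length = 8e5, copies_per_family = 100,
                    families = fams["famA"], decoy_solo_ltrs = 0,
                    decoy_truncated = 0, decoy_recombinant = 0,
                    age_range = c(1e6, 1e6), age_position_gradient = FALSE,
                    seed = 31)
  sim <- simulate_population(cfg)
  ages <- estimate_ages(sim$truth, sim$genome)
  expect_true(all(!is.na(ages$age)))
  expect_lt(abs(mean(ages$age) / 1e6 - 1), 0.1)
})
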