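make_copies <- function(base, edits) {
  # edits: list of per-copy lists of c(pos, base) substitutions
  seqs <- vapply(edits, function(ed) {
    v <- strsplit(base, "")[[1]]
    for (e in ed) v[as.integer(e[1])] <- e[2]
    paste(v, collapse = "")
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("copy_%03d", seq_along(seqs))
  out
}

test_that("consensus building is majority rule, seeded and deterministic", {
  base <- random_seq(300, seed = 1)
  ident <- make_copies(base, replicate(30, list(), simplify = FALSE))
  expect_identical(as.character(build_consensus(ident, seed = 1)), base)

  # 20 copies carry G and 10 carry A at one column -> consensus has G
  p <- regexpr("T", base)[1]   # a column whose reference base is neither G nor A
  edits <- c(replicate(20, list(c(as.character(p), "G")), simplify = FALSE),
             replicate(10, list(c(as.character(p), "A")), simplify = FALSE))
  copies <- make_copies(base, edits)
  cons <- as.character(build_consensus(copies, sample_n = 30, seed = 2))
  expect_identical(substr(cons, p, p), "G")

  c1 <- build_consensus(copies, sample_n = 10, seed = 3)
  c2 <- build_consensus(copies, sample_n = 10, seed = 3)
  expect_identical(as.character(c1), as.character(c2))
  expect_error(build_consensus(copies[1]), ">= 2")
})

test_that("variant calling counts alleles and applies the MAF rule", {
  base <- random_seq(400, seed = 2)
  p <- 99 + regexpr("T", substr(base, 100, 400))[1]   # site position, ref T
  edits <- c(replicate(5, list(c(as.character(p), "G")), simplify = FALSE),
             replicate(5, list(), simplify = FALSE))
  copies <- make_copies(base, edits)
  vt <- call_variants(copies, base)
  expect_equal(vt$sites$pos, p)
  expect_identical(vt$sites$ref, substr(base, p, p))
  expect_identical(vt$sites$alt, "G")
  expect_equal(sum(vt$geno[, 1] == 1), 5)
  expect_equal(sum(vt$geno[, 1] == 0), 5)
})

test_that("a singleton below 1% frequency among 200 copies is dropped", {
  base <- random_seq(300, seed = 3)
  edits <- c(list(list(c("150", if (substr(base, 150, 150) == "A") "C" else "A"))),
             replicate(199, list(), simplify = FALSE))
  copies <- make_copies(base, edits)
  vt <- call_variants(copies, base, maf = 0.01)
  expect_equal(nrow(vt$sites), 0)
  # at 1% exactly (2/200) the site is retained
  edits2 <- c(replicate(2, list(c("150", if (substr(base, 150, 150) == "A") "C" else "A")),
                        simplify = FALSE),
              replicate(198, list(), simplify = FALSE))
  vt2 <- call_variants(make_copies(base, edits2), base, maf = 0.01)
  expect_equal(vt2$sites$pos, 150)
})

test_that("insertions are ignored and deletions are missing data", {
  base <- random_seq(600, seed = 4)
  alt <- if (substr(base, 100, 100) == "A") "C" else "A"
  plain <- make_copies(base, c(replicate(5, list(c("100", alt)),
                                         simplify = FALSE),
                               replicate(4, list(), simplify = FALSE)))
  # one copy with a 50 bp insertion after position 300
  ins <- paste0(substr(base, 1, 300), random_seq(50, seed = 5),
                substr(base, 301, 600))
  # and a deletion removing consensus positions 96-110 (spanning the site)
  del <- paste0(substr(base, 1, 95), substr(base, 111, 600))
  copies <- c(plain, Biostrings::DNAStringSet(c(ins_copy = ins, del_copy = del)))
  vt <- call_variants(copies, base)
  expect_equal(vt$sites$pos, 100)        # no site from inserted bases
  expect_equal(ncol(vt$geno), 1)
  expect_true(is.na(vt$geno["del_copy", 1]))   # deletion -> missing
  expect_false(is.na(vt$geno["ins_copy", 1]))
  # poorly aligning copies are dropped with a warning
  expect_warning(
    call_variants(c(plain, Biostrings::DNAStringSet(c(junk = random_seq(600, seed = 6)))),
                  base),
    "dropped")
})

test_that("every retained site satisfies the MAF and missingness bounds", {
  sim <- simulate_population(small_sim_config(seed = 17, copies = 40, genome = 9e5))
  fc <- sim$truth[!sim$truth$is_decoy & sim$truth$family == "famA"]
  seqs <- copy_sequences(fc, sim$genome)
  cons <- build_consensus(seqs, seed = 1)
  vt <- call_variants(seqs, cons, maf = 0.05)
  expect_gt(nrow(vt$sites), 0)
  for (j in seq_len(ncol(vt$geno))) {
    col <- vt$geno[, j]
    expect_lte(mean(is.na(col)), 0.90)
    freq <- table(col[!is.na(col)]) / sum(!is.na(col))
    expect_gte(sort(freq, decreasing = TRUE)[2], 0.05)
  }
  expect_true(all(diff(vt$sites$pos) > 0))
})

test_that("VCF round-trips exactly and parses with an external reader", {
  sim <- simulate_population(small_sim_config(seed = 19, copies = 12, genome = 4e5))
  fc <- sim$truth[!sim$truth$is_decoy & sim$truth$family == "famB"]
  seqs <- copy_sequences(fc, sim$genome)
  vt <- call_variants(seqs, build_consensus(seqs, seed = 2),
                      consensus_id = "famB")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, f)
  vt2 <- read_vcf(f)
  expect_identical(vt2$sites, vt$sites)
  expect_identical(vt2$geno, vt$geno)
  expect_identical(vt2$copy_ids, vt$copy_ids)
  expect_identical(vt2$consensus_id, vt$consensus_id)

  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), vt$sites$pos)
  expect_identical(unname(v@fix[, "REF"]), vt$sites$ref)
  expect_identical(unname(v@fix[, "ALT"]), vt$sites$alt)
})

test_that("PCA separates constructed subfamilies with perfect purity", {
  base <- random_seq(500, seed = 7)
  v <- strsplit(base, "")[[1]]
  sitesA <- seq(10, 200, by = 10)    # 20 diagnostic sites for subfamily A
  editsA <- lapply(sitesA, function(p)
    c(as.character(p), setdiff(c("A", "C", "G", "T"), v[p])[1]))
  edits <- c(replicate(15, editsA, simplify = FALSE),
             replicate(15, list(), simplify = FALSE))
  copies <- make_copies(base, edits)
  vt <- call_variants(copies, base)
  expect_equal(nrow(vt$sites), 20)
  pca <- run_pca(vt)
  labels <- rep(c("A", "B"), each = 15)
  expect_equal(pca_cluster_purity(pca, labels), 1.0)
  # PC1 fully separates the groups
  pc1 <- pca$coordinates[, 1]
  expect_true(max(pc1[1:15]) < min(pc1[16:30]) ||
                min(pc1[1:15]) > max(pc1[16:30]))
  ev <- pca$explained_variance
  expect_true(all(diff(ev) <= 1e-8))
  tot <- sum(apply(scale(apply(vt$geno, 2, as.numeric), scale = FALSE), 2,
                   function(x) sum(x^2))) / (nrow(vt$geno) - 1)
  expect_lte(sum(ev), tot + 1e-8)
})

test_that("PCA on identical copies fails as degenerate", {
  base <- random_seq(200, seed = 8)
  alt <- if (substr(base, 50, 50) == "A") "C" else "A"
  copies <- make_copies(base, replicate(10, list(c("50", alt)),
                                        simplify = FALSE))
  vt <- call_variants(copies, base)
  expect_error(run_pca(vt))
})

test_that("pairwise SNP distances count differing non-missing sites", {
  base <- random_seq(400, seed = 9)
  v <- strsplit(base, "")[[1]]
  alt_at <- function(p) setdiff(c("A", "C", "G", "T"), v[p])[1]
  # copies 1-5 carry alternates at 3 sites; copies 6-10 are reference
  edits <- c(replicate(5, lapply(c(50, 150, 250), function(p)
    c(as.character(p), alt_at(p))), simplify = FALSE),
    replicate(5, list(), simplify = FALSE))
  copies <- make_copies(base, edits)
  vt <- call_variants(copies, base)
  d <- pairwise_snp_distance(vt)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 6], 3)

  skip_if_not_installed("ape")
  chars <- apply(vt$geno, c(1, 2), function(g) letters[g + 1])
  ape_d <- as.matrix(ape::dist.gene(chars, method = "pairwise"))
  expect_equal(unname(d), unname(ape_d[rownames(d), colnames(d)]),
               ignore_attr = TRUE)
})

test_that("missing calls contribute zero to SNP distances", {
  vt <- structure(list(consensus_id = "c", copy_ids = c("a", "b"),
                       sites = data.frame(pos = c(1L, 2L), ref = "A",
                                          alt = "C"),
                       geno = matrix(c(0L, 0L, NA, 1L), nrow = 2, byrow = TRUE,
                                     dimnames = list(c("a", "b"), NULL))),
                  class = "variant_table")
  d <- pairwise_snp_distance(vt)
  expect_equal(d["a", "b"], 1)
})
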