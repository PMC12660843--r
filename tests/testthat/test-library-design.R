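test_that("soft mixtures follow the 70/10/10/10 doping rule", {
  m <- soft_mixture("A", 0.7)
  expect_equal(unname(m[c("A", "C", "G", "T")]), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(sum(m), 1)
  m1 <- soft_mixture("G", 1.0)
  expect_equal(unname(m1["G"]), 1)
  expect_equal(sum(m1[c("A", "C", "T")]), 0)
  expect_equal(as.numeric(soft_mixture("T", 0.25)), rep(0.25, 4))
  expect_error(soft_mixture("X"), "invalid base")
  expect_error(soft_mixture("A", 0), "wt_fraction")
})

test_that("codon amino-acid distributions match closed forms and the oracle", {
  sm <- function(b) soft_mixture(b, 0.7)
  d_met <- codon_aa_distribution(sm("A"), sm("T"), sm("G"))
  expect_equal(d_met[["M"]], 0.343)
  d_lys <- codon_aa_distribution(sm("A"), sm("A"), sm("A"))
  expect_equal(d_lys[["K"]], 0.392)
  d_gly <- codon_aa_distribution(sm("G"), sm("G"), sm("A"))
  expect_equal(d_gly[["G"]], 0.490)
  # independent brute-force enumeration agrees exactly
  for (codon in c("ATG", "AAA", "GGA", "TAC", "TGG", "CTG")) {
    b <- strsplit(codon, "")[[1]]
    d_pkg <- codon_aa_distribution(sm(b[1]), sm(b[2]), sm(b[3]))
    d_or <- oracle_codon_dist(sm(b[1]), sm(b[2]), sm(b[3]))
    for (aa in names(d_or)) {
      expect_equal(d_pkg[[aa]], d_or[[aa]], tolerance = 1e-12, info = codon)
    }
  }
})

test_that("every distribution sums to one (sense + stop conservation)", {
  set.seed(42)
  for (rep in 1:20) {
    codon <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    w <- runif(1, 0.3, 1)
    d <- codon_aa_distribution(soft_mixture(codon[1], w),
                               soft_mixture(codon[2], w),
                               soft_mixture(codon[3], w))
    expect_equal(sum(d), 1, tolerance = 1e-12)
    stop_p <- stop_probability(soft_mixture(codon[1], w),
                               soft_mixture(codon[2], w),
                               soft_mixture(codon[3], w))
    expect_equal(stop_p, 1 - sum(d[names(d) != "STOP"]), tolerance = 1e-12)
  }
})

test_that("stop probability of doped TAC is 0.105 and zero for pure GGG", {
  sm <- function(b) soft_mixture(b, 0.7)
  expect_equal(stop_probability(sm("T"), sm("A"), sm("C")), 0.105)
  u <- function(b) soft_mixture(b, 1.0)
  expect_equal(stop_probability(u("G"), u("G"), u("G")), 0)
})

test_that("wild-type retention averages roughly one half at 70% doping", {
  w <- wt_retention_stats(0.7)
  expect_equal(nrow(w$table), 61)
  expect_equal(w$table$retention[w$table$codon == "TGG"], 0.343)
  expect_gt(w$mean, 0.40)
  expect_lt(w$mean, 0.55)
  w1 <- wt_retention_stats(1.0)
  expect_true(all(w1$table$retention == 1))
})

test_that("retention is monotone non-decreasing in the doping fraction", {
  fractions <- c(0.4, 0.55, 0.7, 0.85, 1.0)
  rets <- sapply(fractions, function(f) wt_retention_stats(f)$table$retention)
  expect_true(all(diff(t(rets)) >= -1e-12))
})

test_that("stop templates interrupt translation at each mutagenized region", {
  cds <- paste(rep("GCT", 20), collapse = "")
  st <- build_stop_template(cds, list(c(5, 7)))
  expect_equal(nchar(st), nchar(cds))
  expect_equal(substr(st, 16, 18), "TAA")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(st)))
  expect_equal(regexpr("\\*", prot)[1], 6)
  expect_equal(build_stop_template(cds, list()), cds)
  expect_error(build_stop_template(cds, list(c(2, 5), c(4, 8))), "overlapping")
})

test_that("oligo specs carry exact flanks and restore the reading frame", {
  cds <- paste(rep(c("GCT", "AAA", "GGC"), 10), collapse = "")
  design <- library_design(cds, diversified_codons = c(8, 9), flank_length = 15)
  oligo <- design_oligo(design, c(8, 9))
  expect_equal(nchar(oligo$flank5), 15)
  expect_equal(oligo$flank5, substr(cds, 10, 24))
  expect_equal(oligo$flank3, substr(cds, 31, 45))
  expect_true(all(grepl("/", oligo$positions$mixture)))
  # repairing the stop template restores an open reading frame
  st <- build_stop_template(cds, list(c(8, 9)))
  repaired <- st
  substr(repaired, 25, 30) <- substr(cds, 25, 30)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(repaired)))
  expect_false(grepl("\\*", prot))
  expect_error(design_oligo(design, c(0, 1)), "flank extends past CDS")
})

test_that("all-fixed oligo region reproduces the template substring", {
  cds <- paste(rep("GCA", 20), collapse = "")
  design <- library_design(cds, diversified_codons = 15, flank_length = 6)
  oligo <- design_oligo(design, c(8, 9))
  expect_equal(paste(oligo$positions$mixture, collapse = ""),
               substr(cds, 25, 30))
})

test_that("library sampling is seeded, deterministic and unbiased", {
  cds <- paste(c("ATG", rep("GCT", 9)), collapse = "")
  design <- library_design(cds, diversified_codons = 0)
  c1 <- sample_library(design, 200, seed = 5)
  c2 <- sample_library(design, 200, seed = 5)
  expect_identical(c1$dna, c2$dna)
  # wt_fraction 1 keeps clones identical to template
  d1 <- library_design(cds, diversified_codons = 0, wt_fraction = 1)
  all_wt <- sample_library(d1, 50, seed = 1)
  expect_true(all(all_wt$dna == cds))
  # empirical Met frequency near its closed form 0.343
  big <- sample_library(design, 50000, seed = 7)
  p_met <- mean(substr(big$protein, 1, 1) == "M")
  expect_lt(abs(p_met - 0.343), 0.01)
})

test_that("sampled amino-acid frequencies match the exact distribution", {
  cds <- paste(c("AAA", rep("GGT", 9)), collapse = "")
  design <- library_design(cds, diversified_codons = 0)
  clones <- sample_library(design, 50000, seed = 11)
  sm <- function(b) soft_mixture(b, 0.7)
  expected <- codon_aa_distribution(sm("A"), sm("A"), sm("A"))
  obs_aa <- substr(clones$protein, 1, 1)
  obs_aa[obs_aa == "*"] <- "STOP"
  obs <- table(factor(obs_aa, levels = names(expected)))
  keep <- expected > 5 / 50000
  chi <- stats::chisq.test(as.integer(obs[keep]), p = expected[keep] / sum(expected[keep]))
  expect_gt(chi$p.value, 0.001)
})

test_that("diversity report counts the combinatorial amino-acid support", {
  cds <- paste(rep("GCT", 10), collapse = "")
  design <- library_design(cds, diversified_codons = c(2, 3))
  rep_ <- diversity_report(design, n = 1000)
  sm <- function(b) soft_mixture(b, 0.7)
  per_pos <- sum(codon_aa_distribution(sm("G"), sm("C"), sm("T")) > 0)
  expect_equal(rep_$n_possible_aa, per_pos^2)
  expect_true(rep_$expected_distinct > 0 &&
                rep_$expected_distinct <= rep_$n_possible_aa)
})
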