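template_protein <- function() substr(reference_vdomain("H"), 1, 30)

template_numbering <- function() {
  nc <- number_chain(reference_vdomain("H"), "H", "kabat")
  nc[1:30, ]
}

test_that("substitution matrices count non-template residues by position", {
  tmpl <- template_protein()
  nc <- template_numbering()
  pool <- clone_pool(rep(tmpl, 3), tmpl)
  sm <- build_substitution_matrix(pool, nc)
  expect_equal(nrow(substitution_table(sm)), 0)
  # single clone with one substitution at label "12"
  mutant <- tmpl
  substr(mutant, 12, 12) <- "W"
  pool2 <- clone_pool(c(tmpl, mutant, tmpl), tmpl)
  tab <- substitution_table(build_substitution_matrix(pool2, nc))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$label, "12")
  expect_equal(tab$aa, "W")
  expect_equal(tab$count, 1)
})

test_that("column counts always sum to the pool size (exchangeable order)", {
  tmpl <- template_protein()
  nc <- template_numbering()
  set.seed(3)
  clones <- replicate(40, {
    s <- strsplit(tmpl, "")[[1]]
    i <- sample(30, 2)
    s[i] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], s[i]), 2)
    paste(s, collapse = "")
  })
  pool <- clone_pool(clones, tmpl)
  sm <- build_substitution_matrix(pool, nc)
  aa_cols <- as.matrix(sm[, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]])
  expect_true(all(rowSums(aa_cols) == 40))
  sm2 <- build_substitution_matrix(clone_pool(rev(clones), tmpl), nc)
  expect_equal(substitution_table(sm2), substitution_table(sm))
})

test_that("indel clones are excluded with a count; length mismatch errors", {
  tmpl <- template_protein()
  expect_message(pool <- clone_pool(c(tmpl, substr(tmpl, 1, 29)), tmpl),
                 "excluded 1")
  expect_equal(length(pool$clones), 1)
  nc <- number_chain(reference_vdomain("H"), "H", "kabat")
  expect_error(build_substitution_matrix(pool, nc), "does not match")
})

test_that("template fraction covers the detection-of-template use cases", {
  tmpl <- template_protein()
  mutant <- sub("^.", "W", tmpl)
  expect_equal(template_fraction(clone_pool(rep(mutant, 5), tmpl)), 0)
  expect_equal(template_fraction(clone_pool(rep(tmpl, 5), tmpl)), 1)
  expect_equal(template_fraction(clone_pool(c(tmpl, rep(mutant, 3)), tmpl)), 0.25)
})

test_that("fold change is the plain absorbance ratio, vectorized", {
  expect_equal(fold_change(0.8, 0.4), 2)
  expect_equal(fold_change(0.37, 0.37), 1)
  v <- fold_change(c(0.2, 0.4, 0.8), 0.4)
  expect_equal(v, c(0.5, 1, 2))
  expect_error(fold_change(1, 0), "> 0")
})

test_that("binding association reproduces the exact hypergeometric p-value", {
  tmpl <- template_protein()
  mutant <- sub("^.", "W", tmpl)
  # substitution in all 5 binders, none of 5 non-binders: 2x2 = [[5,0],[0,5]]
  pool <- clone_pool(c(rep(mutant, 5), rep(tmpl, 5)), tmpl)
  nc <- template_numbering()
  res <- substitution_binding_association(pool, nc,
                                          binder = rep(c(TRUE, FALSE), each = 5))
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-10)  # 0.0079365
  expect_gt(res$odds_ratio, 1)

  pool10 <- clone_pool(c(rep(mutant, 10), rep(tmpl, 10)), tmpl)
  res10 <- substitution_binding_association(pool10, nc,
                                            binder = rep(c(TRUE, FALSE), each = 10))
  expect_lt(res10$p, 0.01)
  expect_error(substitution_binding_association(pool, nc, rep(TRUE, 10)),
               "no contrast")
})

test_that("null substitutions give calibrated (conservative) p-values", {
  # Fisher exact p-values are discrete, hence conservative: under the
  # null the rejection rate at any level must not exceed that level.
  tmpl <- substr(template_protein(), 1, 10)
  nc <- template_numbering()[1:10, ]
  set.seed(99)
  pvals <- replicate(300, {
    has_sub <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    clones <- ifelse(has_sub, sub("^.", "W", tmpl), tmpl)
    binder <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    res <- substitution_binding_association(clone_pool(clones, tmpl), nc, binder)
    res$p[1]
  })
  expect_lte(mean(pvals <= 0.05), 0.07)
  expect_lte(mean(pvals <= 0.20), 0.23)
  expect_gt(stats::median(pvals), 0.2)
})

test_that("neutral selection preserves substitution frequencies on average", {
  tmpl <- substr(template_protein(), 1, 10)
  mutant <- sub("^.", "W", tmpl)
  init <- clone_pool(c(rep(mutant, 300), rep(tmpl, 700)), tmpl)
  freqs <- vapply(1:200, function(s) {
    mdl <- enrichment_model(data.frame(position = 1, aa = "W", factor = 1),
                            rounds = 3, seed = s)
    rounds <- simulate_selection(init, mdl)
    substitution_trajectory(rounds, 1, "W")[[4]]
  }, 0)
  expect_equal(mean(freqs), 0.3, tolerance = 0.02)
})

test_that("an enriched substitution follows the expectation recursion", {
  tmpl <- substr(template_protein(), 1, 10)
  mutant <- sub("^.", "W", tmpl)
  f0 <- 0.05
  n <- 10000
  init <- clone_pool(c(rep(mutant, f0 * n), rep(tmpl, (1 - f0) * n)), tmpl)
  mdl <- enrichment_model(data.frame(position = 1, aa = "W", factor = 3),
                          rounds = 5, seed = 4)
  rounds <- simulate_selection(init, mdl)
  traj <- substitution_trajectory(rounds, 1, "W")
  expect_true(all(diff(traj) > 0))
  f_expect <- f0
  for (r in 1:5) f_expect <- c(f_expect, 3 * f_expect[r] / (1 + 2 * f_expect[r]))
  expect_equal(unname(traj), unname(f_expect), tolerance = 0.05)
  # matrix-based recovery matches the trajectory count
  nc <- template_numbering()[1:10, ]
  sm <- build_substitution_matrix(rounds[[6]], nc)
  expect_equal(sm$W[1] / attr(sm, "n_clones"), traj[[6]])
})

test_that("injected enrichment factors are recovered within 15%", {
  tmpl <- substr(template_protein(), 1, 10)
  mutant <- sub("^.", "W", tmpl)
  init <- clone_pool(c(rep(mutant, 500), rep(tmpl, 9500)), tmpl)
  mdl <- enrichment_model(data.frame(position = 1, aa = "W", factor = 3),
                          rounds = 5, seed = 21)
  traj <- substitution_trajectory(simulate_selection(init, mdl), 1, "W")
  s_hat <- estimate_enrichment(traj)
  expect_lt(abs(s_hat - 3) / 3, 0.15)
})

test_that("a disfavored template is driven out of the pool", {
  tmpl <- substr(template_protein(), 1, 10)
  mutant <- sub("^.", "W", tmpl)
  init <- clone_pool(c(rep(mutant, 2000), rep(tmpl, 8000)), tmpl)
  mdl <- enrichment_model(data.frame(position = 1, aa = "W", factor = 4),
                          rounds = 5, seed = 8)
  rounds <- simulate_selection(init, mdl)
  tf <- vapply(rounds, template_fraction, 0)
  expect_lt(tf[[6]], 0.02)
  expect_equal(tf[[1]], 0.8)
})
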