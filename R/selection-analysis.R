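# Analysis of clone pools from phage affinity selections.
#
# Pools are sets of equal-length translated clones aligned to the parental
# template.  The substitution matrix counts non-template residues per
# scheme position; enrichment of substitutions over selection rounds is
# simulated with a seeded multiplicative-fitness resampler for end-to-end
# testing of the analyzers.

#' Load a clone pool
#'
#' Clones whose length differs from the template (indel clones) are
#' excluded with a message reporting the count.
#'
#' @param clones Character vector of translated clone sequences (or data
#'   frame from [read_fasta()]).
#' @param template Template protein string.
#' @param pool_id Pool label (e.g. `"a"`).
#' @return A `clone_pool` list with `pool_id`, `clones`, `template`,
#'   `n_rejected`.
#' @export
clone_pool <- function(clones, template, pool_id = "a") {
  if (is.data.frame(clones)) clones <- clones$residues
  keep <- nchar(clones) == nchar(template)
  n_rej <- sum(!keep)
  if (n_rej > 0) {
    message("excluded ", n_rej, " clone(s) with indels relative to template")
  }
  out <- list(pool_id = pool_id, clones = clones[keep], template = template,
              n_rejected = n_rej)
  class(out) <- "clone_pool"
  out
}

#' Per-position substitution counts for a pool
#'
#' @param pool A `clone_pool`.
#' @param numbering A `numbered_chain` for the template (its length must
#'   equal the template length); positions key the matrix rows.
#' @return A `substitution_matrix`: data frame with columns `label`,
#'   `template_aa`, one count column per observed amino acid, plus
#'   attributes `pool_id` and `n_clones`.
#' @export
build_substitution_matrix <- function(pool, numbering) {
  tmpl <- strsplit(pool$template, "")[[1]]
  if (nrow(numbering) != length(tmpl)) {
    stop("template length (", length(tmpl),
         ") does not match numbering length (", nrow(numbering), ")")
  }
  n <- length(pool$clones)
  if (n == 0) stop("empty pool")
  mat <- do.call(rbind, strsplit(pool$clones, ""))
  counts <- matrix(0L, nrow = length(tmpl), ncol = length(AA_ALPHABET),
                   dimnames = list(numbering$label, AA_ALPHABET))
  for (j in seq_along(tmpl)) {
    tb <- table(factor(mat[, j], levels = AA_ALPHABET))
    counts[j, ] <- as.integer(tb)
  }
  out <- data.frame(label = numbering$label, template_aa = tmpl,
                    counts, stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "pool_id") <- pool$pool_id
  attr(out, "n_clones") <- n
  class(out) <- c("substitution_matrix", "data.frame")
  out
}

#' Non-template substitution counts in long form
#'
#' @param sm A `substitution_matrix`.
#' @return Data frame `label`, `template_aa`, `aa`, `count` for every
#'   non-template amino acid with count > 0.
#' @export
substitution_table <- function(sm) {
  out <- list()
  for (i in seq_len(nrow(sm))) {
    for (aa in AA_ALPHABET) {
      cnt <- sm[[aa]][i]
      if (aa != sm$template_aa[i] && cnt > 0) {
        out[[length(out) + 1]] <- data.frame(
          label = sm$label[i], template_aa = sm$template_aa[i],
          aa = aa, count = cnt, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(label = character(), template_aa = character(),
                      aa = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Fraction of clones identical to the template
#'
#' @param pool A `clone_pool`.
#' @return Fraction in `[0, 1]`.
#' @export
template_fraction <- function(pool) {
  if (length(pool$clones) == 0) stop("empty pool")
  mean(pool$clones == pool$template)
}

#' Fold change in absorbance over a reference
#'
#' @param absorbance_variant Numeric vector of variant absorbances.
#' @param absorbance_reference Reference absorbance(s), must be > 0.
#' @return `absorbance_variant / absorbance_reference`, preserving order.
#' @export
fold_change <- function(absorbance_variant, absorbance_reference) {
  if (any(absorbance_reference <= 0)) stop("reference absorbance must be > 0")
  absorbance_variant / absorbance_reference
}

#' Association between substitutions and binding labels
#'
#' For every substitution observed in the pool, builds the 2x2 table of
#' clones with/without the substitution against binder/non-binder labels,
#' and reports the Haldane-corrected odds ratio, the two-sided Fisher
#' exact p-value and Benjamini-Hochberg q-values across substitutions.
#'
#' @param pool A `clone_pool`.
#' @param numbering `numbered_chain` for the template.
#' @param binder Logical vector, one per clone (TRUE = binder).
#' @return Data frame: `label`, `aa`, counts `n11` (sub & binder), `n10`,
#'   `n01`, `n00`, `odds_ratio`, `p`, `q`.
#' @export
substitution_binding_association <- function(pool, numbering, binder) {
  if (length(binder) != length(pool$clones)) {
    stop("one binder label required per clone")
  }
  if (length(unique(binder)) < 2) stop("no contrast: single-class labels")
  tmpl <- strsplit(pool$template, "")[[1]]
  mat <- do.call(rbind, strsplit(pool$clones, ""))
  rows <- list()
  for (j in seq_along(tmpl)) {
    subs <- setdiff(unique(mat[, j]), tmpl[j])
    for (aa in subs) {
      has <- mat[, j] == aa
      n11 <- sum(has & binder); n10 <- sum(has & !binder)
      n01 <- sum(!has & binder); n00 <- sum(!has & !binder)
      or <- ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
      p <- stats::fisher.test(matrix(c(n11, n10, n01, n00), 2, byrow = TRUE),
                              alternative = "two.sided")$p.value
      rows[[length(rows) + 1]] <- data.frame(
        label = numbering$label[j], aa = aa, n11 = n11, n10 = n10,
        n01 = n01, n00 = n00, odds_ratio = or, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(label = character(), aa = character(), n11 = integer(),
                      n10 = integer(), n01 = integer(), n00 = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Enrichment model for simulated selections
#'
#' @param factors Data frame with columns `position` (1-based residue
#'   index), `aa`, `factor` (strictly positive per-round enrichment
#'   factor of carrying that substitution).
#' @param rounds Number of selection rounds.
#' @param seed RNG seed.
#' @return An `enrichment_model` list.
#' @export
enrichment_model <- function(factors, rounds = 5L, seed = 1L) {
  if (nrow(factors) > 0 && any(factors$factor <= 0)) {
    stop("enrichment factors must be strictly positive")
  }
  out <- list(factors = factors, rounds = as.integer(rounds),
              seed = as.integer(seed))
  class(out) <- "enrichment_model"
  out
}

clone_fitness <- function(clones, model) {
  w <- rep(1, length(clones))
  if (nrow(model$factors) == 0) return(w)
  mat <- do.call(rbind, strsplit(clones, ""))
  for (i in seq_len(nrow(model$factors))) {
    pos <- model$factors$position[i]
    hit <- mat[, pos] == model$factors$aa[i]
    w[hit] <- w[hit] * model$factors$factor[i]
  }
  w
}

#' Simulate multi-round affinity selection
#'
#' Each round resamples the pool (with replacement, constant size) with
#' probability proportional to the product of enrichment factors of the
#' substitutions each clone carries.  Deterministic for a fixed seed.
#'
#' @param pool Initial `clone_pool` (e.g. translated [sample_library()]
#'   clones).
#' @param model An `enrichment_model`.
#' @return List of `clone_pool`s, one per round (round 0 = input first).
#' @export
simulate_selection <- function(pool, model) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(model$seed)
  n <- length(pool$clones)
  rounds <- vector("list", model$rounds + 1L)
  rounds[[1]] <- pool
  current <- pool$clones
  for (r in seq_len(model$rounds)) {
    w <- clone_fitness(current, model)
    current <- sample(current, n, replace = TRUE, prob = w / sum(w))
    p <- clone_pool(current, pool$template,
                    pool_id = paste0(pool$pool_id, "_r", r))
    rounds[[r + 1]] <- p
  }
  names(rounds) <- paste0("round", 0:model$rounds)
  rounds
}

#' Substitution frequency across simulated rounds
#'
#' @param rounds List of pools from [simulate_selection()].
#' @param position 1-based residue index.
#' @param aa Substituted amino acid.
#' @return Numeric vector of per-round frequencies.
#' @export
substitution_trajectory <- function(rounds, position, aa) {
  vapply(rounds, function(p) {
    mean(substr(p$clones, position, position) == aa)
  }, 0)
}

#' Estimate an enrichment factor from round-over-round frequencies
#'
#' Under multiplicative selection the allele frequency follows
#' f' = s f / (1 + (s - 1) f); each round therefore gives an estimate
#' s_hat = (f'/(1-f')) / (f/(1-f)), i.e. the odds ratio of consecutive
#' rounds.  The geometric mean over rounds is returned.
#'
#' @param trajectory Per-round frequencies (round 0 first).
#' @return Estimated per-round enrichment factor.
#' @export
estimate_enrichment <- function(trajectory) {
  f <- trajectory
  ok <- f > 0 & f < 1
  odds <- f / (1 - f)
  ratios <- odds[-1] / odds[-length(odds)]
  ratios <- ratios[ok[-1] & ok[-length(f)]]
  if (length(ratios) == 0) stop("trajectory has no informative rounds")
  exp(mean(log(ratios)))
}
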