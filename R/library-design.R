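# Soft-randomization library mathematics.
#
# Each diversified nucleotide position is synthesized as a doped mixture:
# the wild-type base at fraction w (default 0.7) and each other base at
# (1 - w)/3 (default 0.1).  Exact per-codon amino-acid distributions follow
# from enumerating all 64 codons under per-base independence and the
# standard genetic code; with w = 0.7 the wild-type amino acid is retained
# roughly half the time on average over the sense codons.

GENETIC_CODE_TABLE <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = ifelse(gc == "*", "STOP", unname(gc)),
             stringsAsFactors = FALSE)
}

#' Soft-randomization nucleotide mixture
#'
#' @param wt_base Wild-type base (`"A"`, `"C"`, `"G"` or `"T"`).
#' @param wt_fraction Fraction assigned to the wild-type base (default
#'   0.7); the other three bases share the remainder equally.
#' @return Named numeric vector of length 4 over `A`, `C`, `G`, `T`,
#'   summing to 1, with attribute `wt_base`.
#' @export
soft_mixture <- function(wt_base, wt_fraction = 0.7) {
  if (!wt_base %in% DNA_ALPHABET) stop("invalid base: ", wt_base)
  if (!(wt_fraction > 0 && wt_fraction <= 1)) {
    stop("wt_fraction must be in (0, 1]")
  }
  m <- rep((1 - wt_fraction) / 3, 4)
  names(m) <- DNA_ALPHABET
  m[wt_base] <- wt_fraction
  attr(m, "wt_base") <- wt_base
  m
}

check_mixture <- function(m) {
  if (!is.numeric(m) || length(m) != 4 || is.null(names(m)) ||
      !setequal(names(m), DNA_ALPHABET)) {
    stop("a nucleotide mixture is a named numeric vector over A,C,G,T")
  }
  if (any(m < 0) || abs(sum(m) - 1) > 1e-12) {
    stop("mixture probabilities must be >= 0 and sum to 1")
  }
  m[DNA_ALPHABET]
}

#' Exact amino-acid distribution of a doped codon
#'
#' Enumerates all 64 codons; the probability of each amino acid (plus
#' `STOP`) is the sum over its codons of the product of per-position base
#' probabilities.
#'
#' @param m1,m2,m3 Nucleotide mixtures for the three codon positions
#'   (see [soft_mixture()]).
#' @return Named numeric vector over the 20 amino acids and `"STOP"`,
#'   summing to 1.
#' @export
codon_aa_distribution <- function(m1, m2, m3) {
  m1 <- check_mixture(m1); m2 <- check_mixture(m2); m3 <- check_mixture(m3)
  gc <- GENETIC_CODE_TABLE()
  b1 <- substr(gc$codon, 1, 1); b2 <- substr(gc$codon, 2, 2)
  b3 <- substr(gc$codon, 3, 3)
  p <- m1[b1] * m2[b2] * m3[b3]
  out <- tapply(p, gc$aa, sum)
  full <- stats::setNames(numeric(21), c(AA_ALPHABET, "STOP"))
  full[names(out)] <- out
  if (abs(sum(full) - 1) > 1e-9) stop("distribution does not sum to 1")
  full
}

#' Probability of retaining the wild-type amino acid, per sense codon
#'
#' @param wt_fraction Doping fraction for the wild-type base.
#' @return List with `table` (data frame: codon, aa, retention over the 61
#'   sense codons), `mean` and `median`.
#' @export
wt_retention_stats <- function(wt_fraction = 0.7) {
  gc <- GENETIC_CODE_TABLE()
  sense <- gc[gc$aa != "STOP", ]
  ret <- vapply(seq_len(nrow(sense)), function(i) {
    codon <- strsplit(sense$codon[i], "")[[1]]
    d <- codon_aa_distribution(soft_mixture(codon[1], wt_fraction),
                               soft_mixture(codon[2], wt_fraction),
                               soft_mixture(codon[3], wt_fraction))
    d[[sense$aa[i]]]
  }, 0)
  tab <- data.frame(codon = sense$codon, aa = sense$aa, retention = ret,
                    stringsAsFactors = FALSE)
  list(table = tab, mean = mean(ret), median = stats::median(ret))
}

#' Stop-codon probability of a doped codon
#'
#' @inheritParams codon_aa_distribution
#' @return `P(TAA) + P(TAG) + P(TGA)` under the mixtures.
#' @export
stop_probability <- function(m1, m2, m3) {
  codon_aa_distribution(m1, m2, m3)[["STOP"]]
}

translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Define a soft-randomization library design
#'
#' @param template_cds In-frame template DNA string (no internal stops).
#' @param diversified_codons Integer vector of 0-based codon indices to
#'   diversify.
#' @param wt_fraction Doping fraction (default 0.7).
#' @param flank_length Fixed-flank length in nucleotides for oligo design.
#' @return A `library_design` list with per-diversified-codon mixtures.
#' @export
library_design <- function(template_cds, diversified_codons,
                           wt_fraction = 0.7, flank_length = 15L) {
  template_cds <- toupper(template_cds)
  if (grepl("[^ACGT]", template_cds)) stop("template contains non-ACGT characters")
  prot <- translate_cds(template_cds)
  internal <- substr(prot, 1, nchar(prot) - 1)
  if (grepl("\\*", internal)) stop("template translates with an internal stop")
  n_codons <- nchar(template_cds) / 3
  dv <- as.integer(diversified_codons)
  if (anyDuplicated(dv)) stop("diversified codon indices must be unique")
  if (any(dv < 0 | dv >= n_codons)) stop("diversified codon index out of range")
  mixtures <- lapply(dv, function(ci) {
    codon <- substr(template_cds, ci * 3 + 1, ci * 3 + 3)
    lapply(strsplit(codon, "")[[1]], soft_mixture, wt_fraction = wt_fraction)
  })
  names(mixtures) <- as.character(dv)
  out <- list(template_cds = template_cds, diversified_codons = dv,
              mixtures = mixtures, wt_fraction = wt_fraction,
              flank_length = as.integer(flank_length))
  class(out) <- "library_design"
  out
}

#' Build a stop template for library construction
#'
#' Replaces the first codon of each region to be mutagenized with TAA so
#' that un-mutagenized clones translate as truncated, non-displayed
#' product.
#'
#' @param template_cds In-frame template DNA.
#' @param regions List of 0-based codon index ranges `c(start, end)`
#'   (inclusive).
#' @return DNA string of the same length with stop codons introduced.
#' @export
build_stop_template <- function(template_cds, regions) {
  template_cds <- toupper(template_cds)
  n_codons <- nchar(template_cds) / 3
  if (length(regions) == 0) return(template_cds)
  spans <- do.call(rbind, lapply(regions, function(r) c(r[1], r[2])))
  if (any(spans[, 1] > spans[, 2])) stop("region start after end")
  if (any(spans < 0) || any(spans >= n_codons)) stop("region outside CDS")
  ord <- order(spans[, 1])
  spans <- spans[ord, , drop = FALSE]
  if (nrow(spans) > 1 && any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
    stop("overlapping regions")
  }
  out <- template_cds
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, 1] * 3 + 1
    substr(out, s, s + 2) <- "TAA"
  }
  out
}

#' Mutagenic oligonucleotide specification for one region
#'
#' Emits the exact 5' and 3' template flanks plus a per-position mixture
#' table for the diversified span.  Soft-randomized positions cannot be
#' expressed in IUPAC codes, so mixtures are serialized as explicit
#' percentages (e.g. `"A70/C10/G10/T10"`).
#'
#' @param design A `library_design`.
#' @param region 0-based codon index range `c(start, end)` (inclusive).
#' @param reverse_complement Emit the oligo on the complementary strand.
#' @return List with `flank5`, `positions` (data frame: nt_index 0-based,
#'   wt_base, mixture string), `flank3`, `sequence_spec`.
#' @export
design_oligo <- function(design, region, reverse_complement = FALSE) {
  cds <- design$template_cds
  fl <- design$flank_length
  s_nt <- region[1] * 3 + 1
  e_nt <- (region[2] + 1) * 3
  if (s_nt - fl < 1 || e_nt + fl > nchar(cds)) {
    stop("flank extends past CDS")
  }
  flank5 <- substr(cds, s_nt - fl, s_nt - 1)
  flank3 <- substr(cds, e_nt + 1, e_nt + fl)
  nt_idx <- (s_nt:e_nt) - 1L
  base <- strsplit(substr(cds, s_nt, e_nt), "")[[1]]
  mix_str <- character(length(nt_idx))
  for (k in seq_along(nt_idx)) {
    ci <- nt_idx[k] %/% 3
    if (ci %in% design$diversified_codons) {
      m <- design$mixtures[[as.character(ci)]][[nt_idx[k] %% 3 + 1]]
      mix_str[k] <- paste(sprintf("%s%g", DNA_ALPHABET, round(100 * m[DNA_ALPHABET], 6)),
                          collapse = "/")
    } else {
      mix_str[k] <- base[k]
    }
  }
  out <- list(flank5 = flank5,
              positions = data.frame(nt_index = nt_idx, wt_base = base,
                                     mixture = mix_str, stringsAsFactors = FALSE),
              flank3 = flank3)
  if (reverse_complement) {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out <- list(flank5 = rc(flank3),
                positions = out$positions[rev(seq_len(nrow(out$positions))), ],
                flank3 = rc(flank5))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    out$positions$wt_base <- comp[out$positions$wt_base]
    rownames(out$positions) <- NULL
  }
  out$sequence_spec <- paste0(out$flank5, "[",
                              paste(out$positions$mixture, collapse = "|"),
                              "]", out$flank3)
  out
}

#' Sample clones from a library design
#'
#' Each diversified base is drawn independently from its mixture; fixed
#' positions are copied from the template.  Deterministic for a fixed
#' seed.
#'
#' @param design A `library_design`.
#' @param n_clones Number of clones to draw.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `id`, `dna`, `protein`.
#' @export
sample_library <- function(design, n_clones, seed = 1L) {
  stopifnot(n_clones >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  tmpl <- strsplit(design$template_cds, "")[[1]]
  dna <- matrix(rep(tmpl, n_clones), nrow = n_clones, byrow = TRUE)
  for (ci in design$diversified_codons) {
    for (p in 1:3) {
      m <- design$mixtures[[as.character(ci)]][[p]]
      dna[, ci * 3 + p] <- sample(DNA_ALPHABET, n_clones, replace = TRUE,
                                  prob = m[DNA_ALPHABET])
    }
  }
  dna_str <- apply(dna, 1, paste, collapse = "")
  prot <- vapply(dna_str, translate_cds, "", USE.NAMES = FALSE)
  data.frame(id = sprintf("clone%06d", seq_len(n_clones)),
             dna = dna_str, protein = prot, stringsAsFactors = FALSE)
}

#' Library diversity report
#'
#' Counts amino-acid sequences with non-zero probability (combinatorial
#' product of per-position support sizes) and a Poissonization estimate of
#' the expected number of distinct protein sequences among `n` sampled
#' clones (approximation: positions treated independently using the exact
#' per-codon amino-acid distributions).
#'
#' @param design A `library_design`.
#' @param n Sample size for the expected-distinct estimate.
#' @return List with `n_possible_aa` and `expected_distinct`.
#' @export
diversity_report <- function(design, n = 1e6) {
  dists <- lapply(design$diversified_codons, function(ci) {
    ms <- design$mixtures[[as.character(ci)]]
    d <- codon_aa_distribution(ms[[1]], ms[[2]], ms[[3]])
    d[d > 0]
  })
  n_possible <- prod(vapply(dists, length, 0L))
  # enumerate joint support if small, else Monte-Carlo-free bound via
  # independent-position expectation on marginal probabilities
  if (n_possible <= 2e5) {
    probs <- Reduce(function(a, b) as.vector(outer(a, b)), dists, accumulate = FALSE)
    expected <- sum(1 - exp(-n * probs))
  } else {
    expected <- NA_real_
  }
  list(n_possible_aa = n_possible, expected_distinct = expected)
}
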