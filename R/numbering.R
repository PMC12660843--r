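# Kabat / IMGT numbering of antibody variable domains.
#
# Numbering works by global alignment of the query against a shipped,
# curated reference V-domain (germline-consensus style; heavy reference
# covers Kabat H1-H113 with no insertion codes, kappa light reference
# covers L1-L107), followed by transfer of positions across aligned
# columns.  Residues that align into a CDR are then renumbered with the
# scheme's canonical insertion anchors so that loop-length variation
# produces insertion codes (e.g. 100a, 100b after Kabat H100) instead of
# alignment-dependent placements.

#' Shipped reference V-domain sequences
#'
#' Curated germline-consensus-style sequences used as numbering profiles.
#' The heavy reference is 113 residues (Kabat 1-113, no insertions); the
#' kappa light reference is 107 residues (Kabat 1-107).
#'
#' @param chain_kind `"H"` or `"L"`.
#' @return A single amino-acid string.
#' @export
reference_vdomain <- function(chain_kind = c("H", "L")) {
  chain_kind <- match.arg(chain_kind)
  if (chain_kind == "H") {
    paste0(
      "EVQLLESGGGLVQPGGSLRLSCAASGFTFS",  # FR1  Kabat 1-30
      "SYAMS",                           # CDR-H1 31-35
      "WVRQAPGKGLEWVS",                  # FR2  36-49
      "AISGSGGSTYYADSVK",                # CDR-H2 50-65
      "GRFTISRDNSKNTLYLQMNSLRAEYYCAR",   # FR3  66-94
      "DYGGYFDY",                        # CDR-H3 95-102
      "WGQGTLVTVSS"                      # FR4  103-113
    )
  } else {
    paste0(
      "DIQMTQSPSSLSASVGDRVTITC",          # FR1  Kabat 1-23
      "RASQSISSYLN",                      # CDR-L1 24-34
      "WYQQKPGKAPKLLIY",                  # FR2  35-49
      "AASSLQS",                          # CDR-L2 50-56
      "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", # FR3  57-88
      "QQSYSTPLT",                        # CDR-L3 89-97
      "FGQGTKVEIK"                        # FR4  98-107
    )
  }
}

# Kabat region intervals (inclusive), per chain kind.
KABAT_REGIONS <- list(
  H = list(FR1 = c(1, 30), CDR1 = c(31, 35), FR2 = c(36, 49),
           CDR2 = c(50, 65), FR3 = c(66, 94), CDR3 = c(95, 102),
           FR4 = c(103, 113)),
  L = list(FR1 = c(1, 23), CDR1 = c(24, 34), FR2 = c(35, 49),
           CDR2 = c(50, 56), FR3 = c(57, 88), CDR3 = c(89, 97),
           FR4 = c(98, 107))
)

# IMGT region intervals (IMGT standard boundaries).
IMGT_REGIONS <- list(
  H = list(FR1 = c(1, 26), CDR1 = c(27, 38), FR2 = c(39, 55),
           CDR2 = c(56, 65), FR3 = c(66, 104), CDR3 = c(105, 117),
           FR4 = c(118, 128)),
  L = list(FR1 = c(1, 26), CDR1 = c(27, 38), FR2 = c(39, 55),
           CDR2 = c(56, 65), FR3 = c(66, 104), CDR3 = c(105, 117),
           FR4 = c(118, 128))
)

# Canonical Kabat insertion anchors inside each CDR.
KABAT_CDR_ANCHOR <- list(
  H = c(CDR1 = 35, CDR2 = 52, CDR3 = 100),
  L = c(CDR1 = 27, CDR2 = 54, CDR3 = 95)
)

# Reference position tables: residue index -> kabat number and imgt number.
# The IMGT labels for the shipped references are fixed curated mappings
# anchored on the conserved residues (Cys23->23, Trp at FR2 start ->41 for
# kappa, Cys H22->23, Cys H92/L88->104, FR4 start W/F -> 118), with IMGT
# gap positions placed per the both-ends loop filling rule.
reference_table <- function(chain_kind = c("H", "L")) {
  chain_kind <- match.arg(chain_kind)
  seq_str <- reference_vdomain(chain_kind)
  n <- nchar(seq_str)
  kabat <- seq_len(n)
  if (chain_kind == "H") {
    # 113 residues into IMGT slots (128 minus 15 gaps)
    imgt <- c(
      1:9, 11:23,              # Kabat 1-22  (gap at IMGT 10)
      24:26,                   # Kabat 23-25
      27:31, 34:38,            # Kabat 26-35 CDR1 loop (gaps 32,33)
      39:55,                   # Kabat 36-52
      56:58, 64:65,            # Kabat 53-57 CDR2 loop (gaps 59-63)
      66:72, 74:80, 84:104,    # Kabat 58-92 FR3 (gaps 73, 81-83)
      105:109, 113:117,        # Kabat 93-102 CDR3 loop (gaps 110-112)
      118:128                  # Kabat 103-113 FR4
    )
  } else {
    imgt <- c(
      1:23,                    # Kabat 1-23
      24:26,                   # Kabat 24-26
      27:30, 35:38,            # Kabat 27-34 CDR1 loop (gaps 31-34)
      41:55,                   # Kabat 35-49 FR2 (gaps 39,40)
      56:57, 65,               # Kabat 50-52 CDR2 loop
      66:72, 74:80, 83:104,    # Kabat 53-88 (gaps 73, 81, 82)
      105:109, 114:117,        # Kabat 89-97 CDR3 loop
      118:127                  # Kabat 98-107 FR4
    )
  }
  stopifnot(length(imgt) == n)
  data.frame(index = seq_len(n),
             aa = strsplit(seq_str, "")[[1]],
             kabat = kabat, imgt = imgt,
             stringsAsFactors = FALSE)
}

#' Create a numbered position
#'
#' @param number Positive integer scheme position.
#' @param insertion Insertion code (`""` or a single lower-case letter).
#' @return Character label such as `"100"` or `"100a"`.
#' @export
position_label <- function(number, insertion = "") {
  paste0(number, insertion)
}

#' Parse a position label into number and insertion code
#'
#' @param label Labels such as `"100a"`.
#' @return Data frame with columns `number` and `insertion`.
#' @export
parse_position <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([a-z]?)$", label))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) stop("malformed position label: ", label[bad][1])
  data.frame(number = as.integer(vapply(m, `[`, "", 2)),
             insertion = vapply(m, `[`, "", 3),
             stringsAsFactors = FALSE)
}

# Total order on positions: number ascending, no-insertion before 'a' < 'b'.
position_rank <- function(number, insertion) {
  ins_rank <- ifelse(insertion == "", 0L, match(insertion, letters))
  number * 100 + ins_rank
}

#' Number an antibody V-domain sequence
#'
#' Assigns scheme positions (with insertion codes) to every residue by
#' profile alignment against the shipped reference for the chain kind.
#'
#' @param seq Amino-acid string, or a one-row data frame from
#'   [read_fasta()].
#' @param chain_kind `"H"` or `"L"`.
#' @param scheme `"kabat"` or `"imgt"`.
#' @return A `numbered_chain`: data frame with columns `number`,
#'   `insertion`, `label`, `aa`, plus attributes `chain_kind` and `scheme`.
#' @export
number_chain <- function(seq, chain_kind = c("H", "L"),
                         scheme = c("kabat", "imgt")) {
  chain_kind <- match.arg(chain_kind)
  scheme <- match.arg(scheme)
  if (is.data.frame(seq)) seq <- seq$residues[[1]]
  n <- nchar(seq)
  if (n < 60 || n > 150) {
    stop("not a V-domain: sequence length ", n, " outside 60-150")
  }
  ref <- reference_table(chain_kind)
  ref_seq <- paste(ref$aa, collapse = "")

  mat <- "BLOSUM62"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(ref_seq),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  self <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(ref_seq),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  if (Biostrings::score(aln) < 0.4 * Biostrings::score(self)) {
    stop("not a V-domain: alignment score below threshold for chain ",
         chain_kind)
  }

  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  # Transfer reference positions across aligned columns.
  qi <- 0L; ri <- 0L
  num <- integer(n); ins <- character(n)
  last_num <- 0L; pending_ins <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-" && ra[k] != "-") {
      qi <- qi + 1L; ri <- ri + 1L
      num[qi] <- if (scheme == "kabat") ref$kabat[ri] else ref$imgt[ri]
      ins[qi] <- ""
      last_num <- num[qi]; pending_ins <- 0L
    } else if (qa[k] != "-") {       # insertion relative to reference
      qi <- qi + 1L
      pending_ins <- pending_ins + 1L
      num[qi] <- max(last_num, 1L)
      ins[qi] <- letters[pending_ins]
    } else {                          # deletion: reference position skipped
      ri <- ri + 1L
    }
  }

  nc <- data.frame(number = num, insertion = ins, aa = strsplit(seq, "")[[1]],
                   stringsAsFactors = FALSE)

  if (scheme == "kabat") nc <- renumber_cdr_loops(nc, chain_kind)

  nc$label <- position_label(nc$number, nc$insertion)
  rk <- position_rank(nc$number, nc$insertion)
  if (any(diff(rk) <= 0)) {
    stop("internal numbering error: positions not strictly increasing")
  }
  attr(nc, "chain_kind") <- chain_kind
  attr(nc, "scheme") <- scheme
  class(nc) <- c("numbered_chain", "data.frame")
  nc
}

# Renumber residues falling inside each Kabat CDR using the canonical
# insertion anchor: positions fill from the region start up to the anchor,
# extra residues get insertion codes at the anchor, and the tail of the
# region is filled from its end backwards.
renumber_cdr_loops <- function(nc, chain_kind) {
  regions <- KABAT_REGIONS[[chain_kind]]
  anchors <- KABAT_CDR_ANCHOR[[chain_kind]]
  rk <- position_rank(nc$number, nc$insertion)
  for (rg in names(anchors)) {
    lo <- regions[[rg]][1]; hi <- regions[[rg]][2]
    # the loop segment: everything after the framework residue lo-1
    # (including insertion codes the aligner attached to it) up to hi
    idx <- which(rk > (lo - 1) * 100 & rk < (hi + 1) * 100)
    if (length(idx) == 0L) next
    if (any(diff(idx) != 1L)) next    # non-contiguous: leave as aligned
    L <- length(idx)
    pos_all <- lo:hi
    R <- length(pos_all)
    a <- match(anchors[[rg]], pos_all)
    tail_n <- min(L, R - a)
    head_n <- L - tail_n
    new_num <- integer(L); new_ins <- character(L)
    if (tail_n > 0) {
      new_num[(L - tail_n + 1):L] <- pos_all[(R - tail_n + 1):R]
      new_ins[(L - tail_n + 1):L] <- ""
    }
    if (head_n <= a) {
      if (head_n > 0) {
        new_num[1:head_n] <- pos_all[1:head_n]
        new_ins[1:head_n] <- ""
      }
    } else {
      new_num[1:a] <- pos_all[1:a]
      new_ins[1:a] <- ""
      extra <- head_n - a
      new_num[(a + 1):(a + extra)] <- anchors[[rg]]
      new_ins[(a + 1):(a + extra)] <- letters[seq_len(extra)]
    }
    nc$number[idx] <- new_num
    nc$insertion[idx] <- new_ins
  }
  nc
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("numbered_chain: %s chain, %s scheme, %d residues (%s..%s)\n",
              attr(x, "chain_kind"), attr(x, "scheme"), nrow(x),
              x$label[1], x$label[nrow(x)]))
  invisible(x)
}

#' Reconstruct the amino-acid sequence of a numbered chain
#'
#' @param nc A `numbered_chain`.
#' @return Single amino-acid string (round-trips [number_chain()]).
#' @export
render_chain <- function(nc) {
  paste(nc$aa, collapse = "")
}

#' Partition a numbered chain into framework and CDR regions
#'
#' @param nc A `numbered_chain`.
#' @param cdr_definition `"kabat"` or `"imgt"`. Must match the numbering
#'   scheme of `nc`.
#' @return A `region_map`: named list of inclusive `c(lo, hi)` scheme
#'   intervals (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4) with attributes, plus
#'   a `region` assignment for each residue accessible via
#'   [assign_regions()].
#' @export
extract_regions <- function(nc, cdr_definition = c("kabat", "imgt")) {
  cdr_definition <- match.arg(cdr_definition)
  if (attr(nc, "scheme") != cdr_definition) {
    stop("chain numbered under '", attr(nc, "scheme"),
         "' but cdr_definition is '", cdr_definition, "'")
  }
  ck <- attr(nc, "chain_kind")
  regions <- if (cdr_definition == "kabat") KABAT_REGIONS[[ck]] else IMGT_REGIONS[[ck]]
  out <- regions
  attr(out, "chain_kind") <- ck
  attr(out, "cdr_definition") <- cdr_definition
  class(out) <- "region_map"
  out
}

#' Assign each residue of a numbered chain to its region
#'
#' @param nc A `numbered_chain`.
#' @param rm A `region_map` from [extract_regions()].
#' @return Character vector of region names, one per residue. Insertions
#'   fall inside the interval of their base number.
#' @export
assign_regions <- function(nc, rm) {
  region_of <- function(number) {
    for (nm in names(rm)) {
      if (number >= rm[[nm]][1] && number <= rm[[nm]][2]) return(nm)
    }
    NA_character_
  }
  out <- vapply(nc$number, region_of, "")
  if (anyNA(out)) {
    stop("position ", nc$label[which(is.na(out))[1]],
         " not covered by any region interval")
  }
  out
}

#' Positions of a numbered chain falling in a given region
#'
#' @param nc A `numbered_chain`.
#' @param rm A `region_map`.
#' @param region Region name, e.g. `"CDR3"`.
#' @return Subset of `nc` rows in that region.
#' @export
region_residues <- function(nc, rm, region) {
  nc[assign_regions(nc, rm) == region, , drop = FALSE]
}
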