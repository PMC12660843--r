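# CDR grafting and Vernier-zone back-mutation planning.
#
# Grafting takes donor residues at every CDR position (donor insertions
# carried over, so loop lengths can change) and acceptor residues at every
# framework position.  Back-mutations restore donor (typically rabbit)
# residues at framework positions that position the CDR loops.

#' Graft donor CDRs onto an acceptor framework
#'
#' @param donor,acceptor `numbered_chain` objects of the same chain kind
#'   and scheme.
#' @param cdr_definition `"kabat"` or `"imgt"`.
#' @return A `graft_plan`: list with `donor_id`, `acceptor_id`,
#'   `chain_kind`, `cdr_definition`, `chain` (the grafted
#'   `numbered_chain`), `grafted_sequence` and `back_mutations` (data frame,
#'   initially empty).
#' @export
graft_cdrs <- function(donor, acceptor, cdr_definition = c("kabat", "imgt")) {
  cdr_definition <- match.arg(cdr_definition)
  ck <- attr(acceptor, "chain_kind")
  if (attr(donor, "chain_kind") != ck) stop("chain_kind mismatch")
  if (attr(donor, "scheme") != attr(acceptor, "scheme")) {
    stop("donor and acceptor numbered under different schemes")
  }
  rm_acc <- extract_regions(acceptor, cdr_definition)
  acc_regions <- assign_regions(acceptor, rm_acc)
  don_regions <- assign_regions(donor, rm_acc)

  cdrs <- c("CDR1", "CDR2", "CDR3")
  pieces <- list()
  order_regions <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  for (rg in order_regions) {
    src <- if (rg %in% cdrs) donor else acceptor
    src_rg <- if (rg %in% cdrs) don_regions else acc_regions
    pieces[[rg]] <- src[src_rg == rg, c("number", "insertion", "aa"), drop = FALSE]
  }
  nc <- do.call(rbind, pieces)
  rownames(nc) <- NULL
  nc$label <- position_label(nc$number, nc$insertion)
  attr(nc, "chain_kind") <- ck
  attr(nc, "scheme") <- attr(acceptor, "scheme")
  class(nc) <- c("numbered_chain", "data.frame")

  plan <- list(
    donor_id = attr(donor, "id") %||% "donor",
    acceptor_id = attr(acceptor, "id") %||% "acceptor",
    chain_kind = ck,
    cdr_definition = cdr_definition,
    chain = nc,
    grafted_sequence = render_chain(nc),
    back_mutations = data.frame(label = character(), from_aa = character(),
                                to_aa = character(), stringsAsFactors = FALSE)
  )
  class(plan) <- "graft_plan"
  plan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.graft_plan <- function(x, ...) {
  cat(sprintf("graft_plan: %s CDRs (%s) from %s onto %s framework\n",
              x$chain_kind, x$cdr_definition, x$donor_id, x$acceptor_id))
  if (nrow(x$back_mutations) > 0) {
    cat("back mutations:", paste(mutation_notation(x$back_mutations, x$chain_kind),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render back-mutations in from-position-to notation
#'
#' @param bm Data frame with `label`, `from_aa`, `to_aa`.
#' @param chain_kind `"H"` or `"L"` chain tag suffix.
#' @return Character vector such as `"L46R^L"`.
#' @export
mutation_notation <- function(bm, chain_kind) {
  if (nrow(bm) == 0) return(character())
  paste0(bm$from_aa, bm$label, bm$to_aa, "^", chain_kind)
}

#' Curated Vernier-zone framework positions (Kabat)
#'
#' The classic framework positions that sit beneath the CDR loops and
#' modulate their conformation (Foote-Winter derived set), shipped as an
#' editable table in `inst/extdata/vernier_kabat.csv` so that users can
#' supply their own set.
#'
#' @param chain_kind `"H"` or `"L"`.
#' @param file Optional path to an alternative CSV with columns
#'   `chain_kind`, `position`.
#' @return Character vector of Kabat position labels.
#' @export
default_vernier_set <- function(chain_kind = c("H", "L"), file = NULL) {
  chain_kind <- match.arg(chain_kind)
  if (is.null(file)) {
    file <- system.file("extdata", "vernier_kabat.csv", package = "phabkit")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c("character", "character"))
  tab$position[tab$chain_kind == chain_kind]
}

#' Apply framework back-mutations to a graft plan
#'
#' Sets the grafted chain to the donor residue at each requested framework
#' position.  Positions where donor and acceptor residues already agree are
#' silently skipped; requesting a CDR position is an error.
#'
#' @param plan A `graft_plan`.
#' @param positions Character vector of position labels (e.g. `"46"`,
#'   `"100a"`).
#' @param donor The donor `numbered_chain`.
#' @return The updated `graft_plan`.
#' @export
apply_back_mutations <- function(plan, positions, donor) {
  nc <- plan$chain
  rm_map <- extract_regions(nc, plan$cdr_definition)
  regions <- assign_regions(nc, rm_map)
  for (pos in positions) {
    i <- which(nc$label == pos)
    j <- which(donor$label == pos)
    if (length(i) == 0L) stop("position ", pos, " absent from grafted chain")
    if (length(j) == 0L) stop("position ", pos, " absent from donor chain")
    if (grepl("^CDR", regions[i])) {
      stop("position ", pos, " is not a framework position")
    }
    from_aa <- nc$aa[i]
    to_aa <- donor$aa[j]
    if (from_aa == to_aa) next
    nc$aa[i] <- to_aa
    plan$back_mutations <- rbind(
      plan$back_mutations,
      data.frame(label = pos, from_aa = from_aa, to_aa = to_aa,
                 stringsAsFactors = FALSE))
  }
  plan$chain <- nc
  plan$grafted_sequence <- render_chain(nc)
  plan
}

#' Positionwise difference between two numbered chains
#'
#' @param a,b `numbered_chain` objects with equal chain kind and scheme.
#' @return Data frame with columns `label`, `aa_a`, `aa_b`, sorted by
#'   position order; positions present in only one chain are reported with
#'   a `"-"` gap marker.
#' @export
diff_chains <- function(a, b) {
  if (attr(a, "scheme") != attr(b, "scheme")) stop("scheme mismatch")
  if (attr(a, "chain_kind") != attr(b, "chain_kind")) stop("chain_kind mismatch")
  all_lab <- union(a$label, b$label)
  pp <- parse_position(all_lab)
  ord <- order(position_rank(pp$number, pp$insertion))
  all_lab <- all_lab[ord]
  aa_a <- a$aa[match(all_lab, a$label)]
  aa_b <- b$aa[match(all_lab, b$label)]
  aa_a[is.na(aa_a)] <- "-"
  aa_b[is.na(aa_b)] <- "-"
  keep <- aa_a != aa_b
  data.frame(label = all_lab[keep], aa_a = aa_a[keep], aa_b = aa_b[keep],
             stringsAsFactors = FALSE)
}
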