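AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a plain
#' data frame of records and validates the residue alphabet.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"` (default) or `"DNA"`; controls alphabet validation.
#' @return A data.frame with columns `id`, `description`, `residues`
#'   (upper-case), one row per record, in file order.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    warning("duplicate ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  alphabet <- if (type == "AA") AA_ALPHABET else DNA_ALPHABET
  for (i in seq_along(res)) {
    chars <- strsplit(res[[i]], "")[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad) > 0L) {
      stop(sprintf("record '%s': invalid %s character '%s' at position %d",
                   ids[[i]], type, chars[bad[1]], bad[1]))
    }
  }
  data.frame(id = ids, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[[i]]
    if (!is.null(records$description) && nzchar(records$description[[i]])) {
      hdr <- paste(hdr, records$description[[i]])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$residues[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a structure from a fixed-column PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a `structure_model`: a list
#' with an `atoms` data frame carrying serial, name, element, residue name,
#' residue number + insertion code, chain id, coordinates, occupancy and
#' B-factor. Waters (residue name HOH/WAT) are flagged.
#'
#' @param path Path to a PDB file.
#' @return A `structure_model` object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_elem)) {
    warning("element column missing for ", sum(missing_elem),
            " atoms; inferring from atom names")
    elem[missing_elem] <- substr(gsub("[0-9]", "", trimws(a$elety[missing_elem])), 1, 1)
  }
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = trimws(elem),
    resname = trimws(a$resid),
    resseq = a$resno,
    ins = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    is_water = trimws(a$resid) %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  structure_model(atoms)
}

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `ins`, `chain`, `x`, `y`, `z`, `occ`, `b`,
#'   `is_water`.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms) {
  needed <- c("serial", "name", "element", "resname", "resseq", "chain",
              "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$is_water)) atoms$is_water <- atoms$resname %in% c("HOH", "WAT")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  obj <- list(atoms = atoms)
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (%s), %d waters\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              sum(x$atoms$is_water)))
  invisible(x)
}

#' Write a structure model to a fixed-column PDB file
#'
#' Coordinates are written at 3-decimal PDB precision.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    rec <- if (a$is_water[i] || !a$resname[i] %in% names(RESIDUE_3TO1)) "HETATM" else "ATOM  "
    nm <- a$name[i]
    # PDB atom-name column convention: element right-justified in cols 13-14
    nm_fmt <- if (nchar(nm) < 4 && nchar(a$element[i]) == 1) paste0(" ", nm) else nm
    line <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, a$serial[i], nm_fmt, "", a$resname[i], a$chain[i],
                    a$resseq[i], a$ins[i], a$x[i], a$y[i], a$z[i],
                    a$occ[i], a$b[i], a$element[i])
    writeLines(line, con)
  }
  writeLines("END", con)
  invisible(path)
}

RESIDUE_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Default run configuration
#'
#' Every tunable parameter of the toolkit with its documented default.
#'
#' @return Named list of stage parameter lists.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    numbering = list(scheme = "kabat", score_threshold = 0.4),
    library = list(wt_fraction = 0.7, flank_length = 15L),
    kinetics = list(restarts = 3L),
    contacts = list(
      hbond_da_max = 2.5, hbond_donor_angle_min = 120, hbond_donor_angle_max = 180,
      hbond_acceptor_angle_min = 120, hbond_acceptor_angle_max = 180,
      bridge_da_max = 2.8, pi_cation_max = 4.5,
      pi_pi_min = 3.5, pi_pi_max = 5.0
    ),
    sasa = list(probe = 1.7, n_points = 960L)
  )
}

#' Read a YAML run configuration
#'
#' Values in the file override the documented defaults; unknown stage or
#' parameter keys are an error.
#'
#' @param path Path to YAML file, or `NULL` for pure defaults.
#' @return Named list as [default_config()].
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (stage in names(user)) {
    if (!stage %in% names(cfg)) stop("unknown config key: ", stage)
    if (stage == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    for (key in names(user[[stage]])) {
      if (!key %in% names(cfg[[stage]])) {
        stop("unknown config key: ", stage, ".", key)
      }
      cfg[[stage]][[key]] <- user[[stage]][[key]]
    }
  }
  cfg
}

log_stage <- function(stage, params, seed = NULL) {
  flat <- paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","), ""),
                sep = "=", collapse = " ")
  message(sprintf("[%s] %s%s", stage, flat,
                  if (is.null(seed)) "" else paste0(" seed=", seed)))
}

format_num <- function(x) signif(x, 6)
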