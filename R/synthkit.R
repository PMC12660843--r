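# Deterministic synthetic fixture generators.
#
# Every module is testable offline: chains are edits of the shipped
# reference V-domains with known ground-truth numbering; interfaces are
# built constructively so that each detector's criteria hold by design
# (the constructive inverse of the contact detectors).  All fixture
# sequences and coordinates are synthetic.

#' Build a synthetic V-domain chain with known numbering
#'
#' Starts from the shipped reference and applies point edits at Kabat
#' positions and insertions after Kabat anchors, emitting ground-truth
#' numbering alongside.
#'
#' @param chain_kind `"H"` or `"L"`.
#' @param edits Named character vector: names are Kabat position labels,
#'   values replacement amino acids (e.g. `c("97" = "T")`).
#' @param insertions Named character vector: names are Kabat anchor
#'   labels, values the inserted residues (e.g. `c("100" = "VF")` inserts
#'   100a = V, 100b = F).
#' @param n_random_cdr_edits Additional random CDR substitutions.
#' @param seed RNG seed for random edits.
#' @return List with `sequence`, `truth` (data frame `label`, `aa`), and
#'   `id`.
#' @export
make_chain <- function(chain_kind = c("H", "L"), edits = character(),
                       insertions = character(), n_random_cdr_edits = 0,
                       seed = 1L) {
  chain_kind <- match.arg(chain_kind)
  ref <- reference_table(chain_kind)
  truth <- data.frame(label = as.character(ref$kabat), aa = ref$aa,
                      stringsAsFactors = FALSE)
  for (pos in names(edits)) {
    i <- which(truth$label == pos)
    if (length(i) == 0) stop("edit outside domain: position ", pos)
    truth$aa[i] <- edits[[pos]]
  }
  if (n_random_cdr_edits > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    regions <- KABAT_REGIONS[[chain_kind]]
    cdr_pos <- unlist(lapply(c("CDR1", "CDR2", "CDR3"), function(rg) {
      regions[[rg]][1]:regions[[rg]][2]
    }))
    cdr_idx <- which(as.integer(truth$label) %in% cdr_pos)
    pick <- sample(cdr_idx, min(n_random_cdr_edits, length(cdr_idx)))
    for (i in pick) {
      truth$aa[i] <- sample(setdiff(AA_ALPHABET, truth$aa[i]), 1)
    }
  }
  for (anchor in names(insertions)) {
    i <- which(truth$label == anchor)
    if (length(i) == 0) stop("insertion anchor outside domain: ", anchor)
    res <- strsplit(insertions[[anchor]], "")[[1]]
    ins_rows <- data.frame(label = paste0(anchor, letters[seq_along(res)]),
                           aa = res, stringsAsFactors = FALSE)
    tail_rows <- if (i < nrow(truth)) truth[(i + 1):nrow(truth), ] else truth[0, ]
    truth <- rbind(truth[1:i, ], ins_rows, tail_rows)
  }
  rownames(truth) <- NULL
  list(id = paste0("synthetic_", chain_kind),
       sequence = paste(truth$aa, collapse = ""), truth = truth)
}

rotate_about_y <- function(coords, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
              byrow = TRUE)
  coords %*% t(R)
}

hexagon <- function(radius = 1.39) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

new_atom <- function(serial, name, element, resname, resseq, chain, xyz,
                     is_water = FALSE) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resseq = resseq, ins = "", chain = chain,
             x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
             is_water = is_water, stringsAsFactors = FALSE)
}

ring_atoms_df <- function(coords, resseq, chain, start_serial) {
  names6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  do.call(rbind, lapply(seq_len(6), function(k) {
    new_atom(start_serial + k - 1, names6[k], "C", "PHE", resseq, chain,
             coords[k, ])
  }))
}

#' Build a synthetic interface with prescribed contact geometry
#'
#' Supported kinds:
#' * `pi_pi`: two phenyl rings with requested centroid distance (A),
#'   interplanar angle (deg) and lateral offset (A).
#' * `hbond`: an N-H donor against a C=O acceptor at requested
#'   donor-acceptor distance and donor/acceptor angles.
#' * `water_bridge`: a water whose two legs have the requested distances.
#' * `pi_cation`: a phenyl ring with a lysine-like NZ at the requested
#'   centroid distance.
#'
#' @param kind One of `"pi_pi"`, `"hbond"`, `"water_bridge"`,
#'   `"pi_cation"`.
#' @param ... Geometry parameters: `dist`, `angle`, `offset` (pi_pi);
#'   `d_da`, `donor_angle`, `acceptor_angle` (hbond); `d1`, `d2`
#'   (water_bridge); `dist` (pi_cation).
#' @return A `structure_model` with chains `A` (antibody side) and `B`
#'   (ligand side), plus waters on chain `W` where applicable.
#' @export
make_interface <- function(kind = c("pi_pi", "hbond", "water_bridge",
                                    "pi_cation"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  get <- function(nm, default) if (!is.null(p[[nm]])) p[[nm]] else default
  atoms <- switch(kind,
    pi_pi = {
      d <- get("dist", 5.0); ang <- get("angle", 75); off <- get("offset", 0)
      if (d <= 0 || off < 0 || off > d) stop("unrealizable geometry")
      ring_a <- hexagon()
      vertical <- sqrt(d^2 - off^2)
      ring_b <- rotate_about_y(hexagon(), ang)
      ring_b <- sweep(ring_b, 2, c(off, 0, vertical), "+")
      rbind(ring_atoms_df(ring_a, 1, "A", 1),
            ring_atoms_df(ring_b, 1, "B", 7))
    },
    hbond = {
      d_da <- get("d_da", 2.4)
      dang <- get("donor_angle", 165); aang <- get("acceptor_angle", 150)
      if (d_da <= 1) stop("unrealizable geometry")
      Dn <- c(0, 0, 0)                       # donor N
      H <- c(1.0, 0, 0)
      phi <- (180 - dang) * pi / 180
      u <- c(cos(phi), sin(phi), 0)
      # solve |H + r u| = d_da for r > 0
      bq <- 2 * sum(H * u); cq <- sum(H * H) - d_da^2
      r <- (-bq + sqrt(bq^2 - 4 * cq)) / 2
      A <- H + r * u                          # acceptor O
      # antecedent carbon: angle H...A-X = aang
      ah <- (H - A) / vnorm(H - A)
      perp <- c(-ah[2], ah[1], 0)
      psi <- aang * pi / 180
      X <- A + 1.23 * (cos(psi) * ah + sin(psi) * perp)
      rbind(new_atom(1, "N", "N", "ALA", 1, "A", Dn),
            new_atom(2, "H", "H", "ALA", 1, "A", H),
            new_atom(3, "O", "O", "LIG", 1, "B", A),
            new_atom(4, "C", "C", "LIG", 1, "B", X))
    },
    water_bridge = {
      d1 <- get("d1", 2.7); d2 <- get("d2", 2.7)
      if (d1 <= 1 || d2 <= 1) stop("unrealizable geometry")
      # side A donates to water; water donates to side B
      OA <- c(0, 0, 0)
      HA <- c(0.96, 0, 0)
      CA_ <- c(-0.8, -0.9, 0)                # antecedent of OA
      OW <- c(d1, 0, 0)
      HW1 <- OW + c(0.96, 0, 0)
      HW2 <- OW + 0.96 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)
      NB <- c(d1 + d2, 0, 0)
      # antecedent at 150 deg from the incoming N...H direction (-x)
      CB <- NB + 1.47 * c(cos(30 * pi / 180), sin(30 * pi / 180), 0)
      rbind(new_atom(1, "O", "O", "SER", 1, "A", OA),
            new_atom(2, "H", "H", "SER", 1, "A", HA),
            new_atom(3, "C", "C", "SER", 1, "A", CA_),
            new_atom(4, "O", "O", "HOH", 100, "W", OW, is_water = TRUE),
            new_atom(5, "H1", "H", "HOH", 100, "W", HW1, is_water = TRUE),
            new_atom(6, "H2", "H", "HOH", 100, "W", HW2, is_water = TRUE),
            new_atom(7, "N", "N", "LIG", 1, "B", NB),
            new_atom(8, "C", "C", "LIG", 1, "B", CB))
    },
    pi_cation = {
      d <- get("dist", 4.2)
      if (d <= 0) stop("unrealizable geometry")
      ring <- hexagon()
      rbind(ring_atoms_df(ring, 1, "B", 1),
            new_atom(7, "NZ", "N", "LYS", 2, "A", c(0, 0, d)))
    })
  structure_model(atoms)
}

#' Write a full benchmark fixture suite
#'
#' Emits FASTA/PDB/CSV fixtures plus a JSON manifest of every ground
#' truth value, deterministically for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Path to the manifest JSON, invisibly.
#' @export
make_benchmark_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, fixtures = list())
  add <- function(name, file, truth) {
    manifest$fixtures[[name]] <<- list(file = file, truth = truth)
  }

  # chains
  ch_h <- make_chain("H", edits = c("97" = "T", "99" = "S"),
                     insertions = c("100" = "VF"), seed = seed)
  ch_l <- make_chain("L", edits = c("32" = "F"), seed = seed)
  write_fasta(data.frame(id = c(ch_h$id, ch_l$id), description = "",
                         residues = c(ch_h$sequence, ch_l$sequence)),
              file.path(dir, "chains.fasta"))
  add("chain_H", "chains.fasta",
      list(n_insertions = 2, insertion_labels = c("100a", "100b")))
  add("chain_L", "chains.fasta", list(edit = "N32F"))

  # library + pool
  lib_cds <- paste(rep("GCT", 30), collapse = "")
  design <- library_design(lib_cds, diversified_codons = c(5, 6, 7),
                           wt_fraction = 0.7)
  clones <- sample_library(design, 200, seed = seed)
  write_fasta(data.frame(id = clones$id, description = "",
                         residues = clones$protein),
              file.path(dir, "pool.fasta"))
  add("pool", "pool.fasta",
      list(n_clones = 200, diversified_codons = c(5, 6, 7),
           wt_fraction = 0.7))

  # sensorgram at the engineered-variant rate constants
  traces <- lapply(c(2e-8, 5e-8, 2e-7), function(C) {
    simulate_sensorgram(2.40e5, 4.20e-3, C, 1, noise_sd = 0.005,
                        seed = seed)
  })
  tab <- do.call(rbind, traces)
  utils::write.csv(tab, file.path(dir, "sensorgrams.csv"),
                   row.names = FALSE)
  add("sensorgrams", "sensorgrams.csv",
      list(ka = 2.40e5, kd = 4.20e-3, KD = 4.20e-3 / 2.40e5))

  # interfaces
  geoms <- list(
    pi_pi = list(dist = 5.0, angle = 75, offset = 1.5),
    hbond = list(d_da = 2.4, donor_angle = 165, acceptor_angle = 150),
    water_bridge = list(d1 = 2.7, d2 = 2.7),
    pi_cation = list(dist = 4.2))
  for (kind in names(geoms)) {
    m <- do.call(make_interface, c(list(kind = kind), geoms[[kind]]))
    f <- paste0("interface_", kind, ".pdb")
    write_pdb(m, file.path(dir, f))
    add(paste0("interface_", kind), f, geoms[[kind]])
  }

  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
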