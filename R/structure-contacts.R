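# Interface geometry on 3D structures.
#
# Contact detection follows explicit geometric criteria: hydrogen bonds
# at a donor-acceptor distance of 2.5 A with donor (D-H...A) and acceptor
# (H...A-X) angles in 120-180 degrees; water bridges use the same angle
# windows with a 2.8 A distance; pi-cation contacts within 4.5 A of a
# ring centroid; pi-pi stacking with centroid distances in 3.5-5 A,
# classified parallel (< 30 deg interplanar), T-shaped (> 60 deg) or
# intermediate.  The 2.5 A heavy-atom H-bond cutoff is unusually short by
# field convention; it is the documented default here and fully
# configurable (a conventional 3.5 A profile is available).

#' Contact detection criteria
#'
#' @param hbond_da_max H-bond donor-acceptor distance cutoff (A).
#' @param hbond_donor_angle,hbond_acceptor_angle Length-2 angle windows in
#'   degrees.
#' @param bridge_da_max Water-bridge leg distance cutoff (A).
#' @param pi_cation_max Cation to ring-centroid cutoff (A).
#' @param pi_pi_range Centroid-centroid distance window (A).
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(hbond_da_max = 2.5,
                             hbond_donor_angle = c(120, 180),
                             hbond_acceptor_angle = c(120, 180),
                             bridge_da_max = 2.8,
                             pi_cation_max = 4.5,
                             pi_pi_range = c(3.5, 5.0)) {
  stopifnot(hbond_da_max > 0, bridge_da_max > 0, pi_cation_max > 0,
            pi_pi_range[1] < pi_pi_range[2])
  out <- list(hbond_da_max = hbond_da_max,
              hbond_donor_angle = hbond_donor_angle,
              hbond_acceptor_angle = hbond_acceptor_angle,
              bridge_da_max = bridge_da_max,
              pi_cation_max = pi_cation_max,
              pi_pi_range = pi_pi_range)
  class(out) <- "contact_criteria"
  out
}

#' Conventional (relaxed) H-bond criteria profile
#'
#' Heavy-atom D-A distance up to 3.5 A, the field's common convention.
#' @return A `contact_criteria` list.
#' @export
conventional_criteria <- function() {
  contact_criteria(hbond_da_max = 3.5, bridge_da_max = 3.5)
}

vnorm <- function(v) sqrt(sum(v^2))
angle_deg <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

atom_xyz <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

# Atoms covalently bonded to atom i (same residue, distance-based).
bonded_atoms <- function(atoms, i, max_dist = 1.8) {
  same <- which(atoms$resseq == atoms$resseq[i] &
                  atoms$chain == atoms$chain[i] &
                  atoms$ins == atoms$ins[i] &
                  seq_len(nrow(atoms)) != i)
  if (length(same) == 0) return(integer())
  p <- atom_xyz(atoms, i)
  d <- sqrt((atoms$x[same] - p[1])^2 + (atoms$y[same] - p[2])^2 +
              (atoms$z[same] - p[3])^2)
  lim <- ifelse(atoms$element[same] == "H" | atoms$element[i] == "H", 1.3, max_dist)
  same[d <= lim]
}

# Polar heavy atoms (N, O, S) that carry at least one hydrogen (donors)
# or not (acceptor candidates: N and O).
polar_atoms <- function(model) {
  atoms <- model$atoms
  idx <- which(atoms$element %in% c("N", "O", "S"))
  has_h <- vapply(idx, function(i) {
    nb <- bonded_atoms(atoms, i)
    any(atoms$element[nb] == "H")
  }, TRUE)
  list(idx = idx, has_h = has_h)
}

group_of <- function(atoms, groups) {
  g <- rep(NA_character_, nrow(atoms))
  for (nm in names(groups)) g[atoms$chain %in% groups[[nm]]] <- nm
  g
}

default_groups <- function(model) {
  ch <- unique(model$atoms$chain[!model$atoms$is_water])
  if (length(ch) < 2) stop("need two chain groups to define an interface")
  list(A = ch[-length(ch)], B = ch[length(ch)])
}

# Test one candidate hydrogen bond donor(i, with hydrogens hs) -> acceptor j.
hbond_geometry <- function(atoms, i, j, hs, crit, da_max) {
  D <- atom_xyz(atoms, i); A <- atom_xyz(atoms, j)
  dDA <- vnorm(A - D)
  if (dDA > da_max) return(NULL)
  if (length(hs) == 0) return(list(dist = dDA, donor_angle = NA, acceptor_angle = NA))
  for (h in hs) {
    H <- atom_xyz(atoms, h)
    dang <- angle_deg(D - H, A - H)
    anteced <- bonded_atoms(atoms, j)
    aang <- if (length(anteced) == 0) NA else {
      max(vapply(anteced, function(x) angle_deg(H - A, atom_xyz(atoms, x) - A), 0))
    }
    ok_d <- dang >= crit$hbond_donor_angle[1] & dang <= crit$hbond_donor_angle[2]
    ok_a <- is.na(aang) ||
      (aang >= crit$hbond_acceptor_angle[1] & aang <= crit$hbond_acceptor_angle[2])
    if (ok_d && ok_a) {
      return(list(dist = dDA, donor_angle = dang, acceptor_angle = aang))
    }
  }
  NULL
}

#' Detect hydrogen bonds across an interface
#'
#' Donors are N/O/S atoms carrying a hydrogen; acceptors are N/O atoms.
#' When the structure lacks hydrogens the angle tests are skipped with a
#' warning (distance-only fallback).
#'
#' @param model A `structure_model` (polar hydrogens present for full
#'   angle checks).
#' @param criteria A `contact_criteria` (default: [contact_criteria()]).
#' @param groups Named list of two chain-id vectors defining the two
#'   molecules (default: last chain vs the rest).
#' @return Data frame of contacts: kind, donor/acceptor descriptors,
#'   distance and angles.
#' @export
detect_hbonds <- function(model, criteria = contact_criteria(),
                          groups = default_groups(model)) {
  atoms <- model$atoms
  grp <- group_of(atoms, groups)
  pol <- polar_atoms(model)
  donors <- pol$idx[pol$has_h]
  acceptors <- pol$idx[atoms$element[pol$idx] %in% c("N", "O")]
  if (length(donors) == 0 && any(atoms$element %in% c("N", "O", "S"))) {
    warning("no hydrogens found: angle tests skipped (distance-only fallback)")
    donors <- pol$idx
  }
  out <- list()
  for (i in donors) {
    if (is.na(grp[i]) || atoms$is_water[i]) next
    hs <- bonded_atoms(atoms, i)
    hs <- hs[atoms$element[hs] == "H"]
    for (j in acceptors) {
      if (is.na(grp[j]) || atoms$is_water[j] || grp[i] == grp[j]) next
      g <- hbond_geometry(atoms, i, j, hs, criteria, criteria$hbond_da_max)
      if (!is.null(g)) {
        out[[length(out) + 1]] <- data.frame(
          kind = "hbond",
          donor = atom_id(atoms, i), acceptor = atom_id(atoms, j),
          dist = g$dist, donor_angle = g$donor_angle,
          acceptor_angle = g$acceptor_angle, stringsAsFactors = FALSE)
      }
    }
  }
  bind_contacts(out)
}

atom_id <- function(atoms, i) {
  sprintf("%s/%s%d%s/%s", atoms$chain[i], atoms$resname[i], atoms$resseq[i],
          atoms$ins[i], atoms$name[i])
}

bind_contacts <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(kind = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Detect water-bridged interactions across an interface
#'
#' A water bridges the two molecules when it forms a criteria-satisfying
#' hydrogen bond (distance cutoff `bridge_da_max`, same angle windows) to
#' a polar atom on each side.
#'
#' @inheritParams detect_hbonds
#' @return Data frame of contacts with the two leg distances.
#' @export
detect_water_bridges <- function(model, criteria = contact_criteria(),
                                 groups = default_groups(model)) {
  atoms <- model$atoms
  grp <- group_of(atoms, groups)
  waters <- which(atoms$is_water & atoms$element == "O")
  polar <- which(atoms$element %in% c("N", "O", "S") & !atoms$is_water &
                   !is.na(grp))
  out <- list()
  for (w in waters) {
    W <- atom_xyz(atoms, w)
    d <- sqrt((atoms$x[polar] - W[1])^2 + (atoms$y[polar] - W[2])^2 +
                (atoms$z[polar] - W[3])^2)
    near <- polar[d <= criteria$bridge_da_max]
    dn <- d[d <= criteria$bridge_da_max]
    if (length(near) < 2) next
    legs_ok <- vapply(seq_along(near), function(k) {
      i <- near[k]
      # either the protein/ligand atom donates to the water or vice versa;
      # check angles when hydrogens exist on either side
      hs_i <- bonded_atoms(atoms, i); hs_i <- hs_i[atoms$element[hs_i] == "H"]
      hs_w <- bonded_atoms(atoms, w); hs_w <- hs_w[atoms$element[hs_w] == "H"]
      if (length(hs_i) == 0 && length(hs_w) == 0) return(TRUE)
      g1 <- if (length(hs_i)) hbond_geometry(atoms, i, w, hs_i, criteria, criteria$bridge_da_max) else NULL
      g2 <- if (length(hs_w)) hbond_geometry(atoms, w, i, hs_w, criteria, criteria$bridge_da_max) else NULL
      !is.null(g1) || !is.null(g2)
    }, TRUE)
    near <- near[legs_ok]; dn <- dn[legs_ok]
    sides <- split(seq_along(near), grp[near])
    if (length(sides) < 2) next
    for (ia in sides[[1]]) for (ib in sides[[2]]) {
      out[[length(out) + 1]] <- data.frame(
        kind = "water_bridge",
        water = atom_id(atoms, w),
        partner_a = atom_id(atoms, near[ia]),
        partner_b = atom_id(atoms, near[ib]),
        dist_a = dn[ia], dist_b = dn[ib], stringsAsFactors = FALSE)
    }
  }
  bind_contacts(out)
}

RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

#' Extract aromatic rings from a structure
#'
#' Rings come from His/Phe/Tyr/Trp templates (Trp contributes two rings)
#' plus any residue whose name appears in `extra_templates`.
#'
#' @param model A `structure_model`.
#' @param extra_templates Named list of character vectors of ring atom
#'   names for non-standard (ligand) residues.
#' @return List of `aromatic_ring` objects: `residue`, `atoms`, `centroid`,
#'   `normal` (unit).
#' @export
extract_rings <- function(model, extra_templates = list()) {
  atoms <- model$atoms
  templates <- RING_TEMPLATES
  for (nm in names(extra_templates)) {
    tpl <- extra_templates[[nm]]
    templates[[nm]] <- if (is.list(tpl)) tpl else list(tpl)
  }
  res_key <- paste(atoms$chain, atoms$resseq, atoms$ins, atoms$resname)
  rings <- list()
  for (key in unique(res_key)) {
    rows <- which(res_key == key)
    rn <- atoms$resname[rows[1]]
    if (!rn %in% names(templates)) next
    for (tpl in templates[[rn]]) {
      sel <- rows[match(tpl, atoms$name[rows])]
      if (anyNA(sel)) next
      coords <- cbind(atoms$x[sel], atoms$y[sel], atoms$z[sel])
      rings[[length(rings) + 1]] <- make_ring(coords,
        residue = sprintf("%s/%s%d%s", atoms$chain[rows[1]], rn,
                          atoms$resseq[rows[1]], atoms$ins[rows[1]]),
        chain = atoms$chain[rows[1]])
    }
  }
  rings
}

make_ring <- function(coords, residue = "ring", chain = "") {
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  sv <- svd(cc)
  normal <- sv$v[, 3]
  normal <- normal / vnorm(normal)
  # coplanarity check: rms out-of-plane displacement
  oop <- cc %*% normal
  if (max(abs(oop)) > 0.2) stop("degenerate ring: atoms not coplanar")
  out <- list(residue = residue, chain = chain, coords = coords,
              centroid = centroid, normal = normal)
  class(out) <- "aromatic_ring"
  out
}

#' Centroid distance, interplanar angle and lateral offset of two rings
#'
#' @param ringA,ringB `aromatic_ring` objects (see [extract_rings()]).
#' @return Named vector `dist` (A), `angle` (deg in \[0, 90\]), `offset`
#'   (A; in-plane displacement of ring B's centroid projected onto ring
#'   A's plane).
#' @export
ring_geometry <- function(ringA, ringB) {
  v <- ringB$centroid - ringA$centroid
  d <- vnorm(v)
  ang <- acos(pmin(abs(sum(ringA$normal * ringB$normal)), 1)) * 180 / pi
  inplane <- v - sum(v * ringA$normal) * ringA$normal
  c(dist = d, angle = ang, offset = vnorm(inplane))
}

classify_pi_pi <- function(angle) {
  if (angle < 30) "parallel" else if (angle > 60) "T-shaped" else "intermediate"
}

#' Detect pi-pi stacking contacts across an interface
#'
#' @inheritParams detect_hbonds
#' @param extra_templates Passed to [extract_rings()].
#' @return Data frame of contacts with distance, interplanar angle,
#'   offset and shape classification.
#' @export
detect_pi_pi <- function(model, criteria = contact_criteria(),
                         groups = default_groups(model),
                         extra_templates = list()) {
  rings <- extract_rings(model, extra_templates)
  grp <- vapply(rings, function(r) {
    g <- NA_character_
    for (nm in names(groups)) if (r$chain %in% groups[[nm]]) g <- nm
    g
  }, "")
  out <- list()
  if (length(rings) >= 2) {
    for (i in seq_along(rings)) for (j in seq_along(rings)) {
      if (i >= j) next
      if (is.na(grp[i]) || is.na(grp[j]) || grp[i] == grp[j]) next
      g <- ring_geometry(rings[[i]], rings[[j]])
      if (g["dist"] >= criteria$pi_pi_range[1] &&
          g["dist"] <= criteria$pi_pi_range[2]) {
        out[[length(out) + 1]] <- data.frame(
          kind = "pi_pi", ring_a = rings[[i]]$residue,
          ring_b = rings[[j]]$residue,
          dist = g[["dist"]], angle = g[["angle"]], offset = g[["offset"]],
          shape = classify_pi_pi(g[["angle"]]), stringsAsFactors = FALSE)
      }
    }
  }
  bind_contacts(out)
}

# Cationic group positions: Lys NZ, Arg guanidinium centroid, plus any
# nitrogen atom of a non-water HETATM-style residue lacking a template
# (primary amines on ligands).
cation_sites <- function(model) {
  atoms <- model$atoms
  out <- list()
  res_key <- paste(atoms$chain, atoms$resseq, atoms$ins)
  for (key in unique(res_key)) {
    rows <- which(res_key == key)
    rn <- atoms$resname[rows[1]]
    if (rn == "LYS") {
      i <- rows[atoms$name[rows] == "NZ"]
      if (length(i)) out[[length(out) + 1]] <- list(
        id = atom_id(atoms, i[1]), chain = atoms$chain[i[1]],
        xyz = atom_xyz(atoms, i[1]))
    } else if (rn == "ARG") {
      sel <- rows[atoms$name[rows] %in% c("CZ", "NH1", "NH2")]
      if (length(sel) == 3) out[[length(out) + 1]] <- list(
        id = sprintf("%s/ARG%d/guanidinium", atoms$chain[sel[1]], atoms$resseq[sel[1]]),
        chain = atoms$chain[sel[1]],
        xyz = c(mean(atoms$x[sel]), mean(atoms$y[sel]), mean(atoms$z[sel])))
    } else if (!rn %in% names(RESIDUE_3TO1) && !atoms$is_water[rows[1]]) {
      for (i in rows[atoms$element[rows] == "N"]) {
        out[[length(out) + 1]] <- list(id = atom_id(atoms, i),
                                       chain = atoms$chain[i],
                                       xyz = atom_xyz(atoms, i))
      }
    }
  }
  out
}

#' Detect pi-cation contacts across an interface
#'
#' @inheritParams detect_pi_pi
#' @return Data frame of contacts with cation-centroid distances.
#' @export
detect_pi_cation <- function(model, criteria = contact_criteria(),
                             groups = default_groups(model),
                             extra_templates = list()) {
  rings <- extract_rings(model, extra_templates)
  cations <- cation_sites(model)
  grp_ring <- vapply(rings, function(r) {
    g <- NA_character_
    for (nm in names(groups)) if (r$chain %in% groups[[nm]]) g <- nm
    g
  }, "")
  out <- list()
  for (ct in cations) {
    gc_ <- NA_character_
    for (nm in names(groups)) if (ct$chain %in% groups[[nm]]) gc_ <- nm
    if (is.na(gc_)) next
    for (k in seq_along(rings)) {
      if (is.na(grp_ring[k]) || grp_ring[k] == gc_) next
      d <- vnorm(ct$xyz - rings[[k]]$centroid)
      if (d <= criteria$pi_cation_max) {
        out[[length(out) + 1]] <- data.frame(
          kind = "pi_cation", cation = ct$id, ring = rings[[k]]$residue,
          dist = d, stringsAsFactors = FALSE)
      }
    }
  }
  bind_contacts(out)
}

#' Detect all contact types at once
#'
#' @inheritParams detect_pi_pi
#' @return Named list of contact data frames (`hbond`, `water_bridge`,
#'   `pi_pi`, `pi_cation`).
#' @export
detect_contacts <- function(model, criteria = contact_criteria(),
                            groups = default_groups(model),
                            extra_templates = list()) {
  list(hbond = detect_hbonds(model, criteria, groups),
       water_bridge = detect_water_bridges(model, criteria, groups),
       pi_pi = detect_pi_pi(model, criteria, groups, extra_templates),
       pi_cation = detect_pi_cation(model, criteria, groups, extra_templates))
}

#' Kabsch least-squares superposition
#'
#' @param reference,mobile n x 3 coordinate matrices, paired rows, n >= 3.
#' @return List with `rotation` (3x3 proper rotation), `translation`
#'   (length-3; the transform is `mobile %*% t(R) + t`), `rmsd` (A),
#'   `n_atoms`.
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n != nrow(mobile)) stop("coordinate sets must be paired")
  if (n < 3) stop("need at least 3 atom pairs")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  if (min(svd(Q)$d) < 1e-8 && min(svd(P)$d) < 1e-8) {
    stop("degenerate (collinear) coordinates")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  translation <- cr - as.vector(R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd, n_atoms = n)
}

#' Apply a superposition transform to coordinates
#'
#' @param sup Result of [kabsch_superpose()].
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' C-alpha RMSD after optimal superposition
#'
#' @param model_ref,model_mob `structure_model`s.
#' @param chain Chain id to align (e.g. the heavy-chain variable domain).
#' @return The superposition result of the paired CA atoms.
#' @export
ca_superpose <- function(model_ref, model_mob, chain) {
  get_ca <- function(m) {
    a <- m$atoms[m$atoms$chain == chain & m$atoms$name == "CA", ]
    a[order(a$resseq, a$ins), ]
  }
  ar <- get_ca(model_ref); am <- get_ca(model_mob)
  key_r <- paste(ar$resseq, ar$ins); key_m <- paste(am$resseq, am$ins)
  common <- intersect(key_r, key_m)
  ar <- ar[match(common, key_r), ]; am <- am[match(common, key_m), ]
  kabsch_superpose(cbind(ar$x, ar$y, ar$z), cbind(am$x, am$y, am$z))
}

#' Residues proximal to an antigen selection
#'
#' @param model A `structure_model`.
#' @param antigen_chains Chain ids forming the antigen/ligand selection.
#' @param radius Distance cutoff in A (default 10) for `mode = "radius"`
#'   (any side-chain atom within `radius` of any antigen atom).
#' @param mode `"radius"` or `"contacts"` (residues appearing in any
#'   detected contact).
#' @param criteria Used in contacts mode.
#' @return Character vector of residue descriptors `chain/RES###`.
#' @export
paratope_shell <- function(model, antigen_chains, radius = 10,
                           mode = c("radius", "contacts"),
                           criteria = contact_criteria()) {
  mode <- match.arg(mode)
  atoms <- model$atoms
  ag <- which(atoms$chain %in% antigen_chains & !atoms$is_water)
  if (length(ag) == 0) stop("empty antigen selection")
  if (mode == "radius") {
    side <- which(!atoms$chain %in% antigen_chains & !atoms$is_water &
                    !atoms$name %in% c("N", "CA", "C", "O") &
                    atoms$element != "H")
    res <- character()
    for (i in side) {
      p <- atom_xyz(atoms, i)
      d2 <- (atoms$x[ag] - p[1])^2 + (atoms$y[ag] - p[2])^2 +
        (atoms$z[ag] - p[3])^2
      if (min(d2) <= radius^2) {
        res <- c(res, sprintf("%s/%s%d%s", atoms$chain[i], atoms$resname[i],
                              atoms$resseq[i], atoms$ins[i]))
      }
    }
    unique(res)
  } else {
    ab_chains <- setdiff(unique(atoms$chain[!atoms$is_water]), antigen_chains)
    cts <- detect_contacts(model, criteria,
                           groups = list(A = ab_chains, B = antigen_chains))
    res <- character()
    # atom ids have chain/res/atom; ring ids are already chain/res
    take_res <- function(id) {
      ifelse(lengths(gregexpr("/", id)) >= 2, sub("/[^/]*$", "", id), id)
    }
    for (tab in cts) {
      if (nrow(tab) == 0) next
      for (col in intersect(c("donor", "acceptor", "partner_a", "partner_b",
                              "ring_a", "ring_b", "cation", "ring"),
                            names(tab))) {
        ids <- take_res(tab[[col]])
        ch <- sub("/.*", "", ids)
        res <- c(res, ids[ch %in% ab_chains])
      }
    }
    unique(res)
  }
}

#' Find GXGX motifs in a numbered segment
#'
#' Scans the amino-acid sequence of a numbered chain (or segment) for the
#' phosphoryl-binding nest pattern G-x-G-x and reports the scheme
#' positions of the motif glycines.
#'
#' @param nc A `numbered_chain` (or subset of its rows).
#' @return Data frame with one row per match: `start_label`,
#'   `gly1_label`, `gly2_label`, `segment`.
#' @export
find_gxgx <- function(nc) {
  aa <- nc$aa
  out <- list()
  n <- length(aa)
  for (i in seq_len(max(n - 3, 0))) {
    if (aa[i] == "G" && aa[i + 2] == "G") {
      out[[length(out) + 1]] <- data.frame(
        start_label = nc$label[i],
        gly1_label = nc$label[i],
        gly2_label = nc$label[i + 2],
        segment = paste(aa[i:(i + 3)], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  bind_contacts(out)
}

VDW_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Deterministic quasi-uniform sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA with a probe of radius `probe` (default 1.7 A, matching
#' buried-surface analyses of Fab complexes) and `n_points` test points
#' per atom on a golden-spiral lattice.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius (A).
#' @param n_points Test points per atom.
#' @param include_h Include hydrogens (default FALSE).
#' @return Numeric vector of per-atom areas (A^2) named by atom serial;
#'   total in attribute `total`.
#' @export
sasa <- function(model, probe = 1.7, n_points = 960L, include_h = FALSE) {
  atoms <- model$atoms
  if (!include_h) atoms <- atoms[atoms$element != "H", ]
  n <- nrow(atoms)
  if (n == 0) stop("no atoms")
  r <- VDW_RADII[toupper(atoms$element)]
  if (anyNA(r)) {
    warning("unknown elements given carbon radius: ",
            paste(unique(atoms$element[is.na(r)]), collapse = ","))
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  R <- r + probe
  pts <- sphere_points(n_points)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    test <- sweep(pts * R[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dij2 >= (R[i] + R[j])^2) next
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > R[j]^2
      if (!any(accessible)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(accessible)
  }
  names(areas) <- atoms$serial
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried surface area of a two-part complex
#'
#' `buried = SASA(A) + SASA(B) - SASA(AB)`; halve with `per_side = TRUE`.
#'
#' @param model Complex `structure_model`.
#' @param chains_a,chains_b Chain ids of the two parts.
#' @param per_side Report the per-side (halved) buried area.
#' @inheritParams sasa
#' @return Buried area in A^2.
#' @export
buried_surface <- function(model, chains_a, chains_b, probe = 1.7,
                           n_points = 960L, per_side = FALSE) {
  sub <- function(ch) structure_model(model$atoms[model$atoms$chain %in% ch, ])
  sa <- attr(sasa(sub(chains_a), probe, n_points), "total")
  sb <- attr(sasa(sub(chains_b), probe, n_points), "total")
  sab <- attr(sasa(sub(c(chains_a, chains_b)), probe, n_points), "total")
  b <- sa + sb - sab
  if (per_side) b / 2 else b
}
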