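random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, 0, 5))
}

transform_model <- function(model, rt) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rt$R)
  xyz <- sweep(xyz, 2, rt$t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

test_that("Kabsch superposition handles identity, translation and noise", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  s0 <- kabsch_superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)

  Y <- sweep(X, 2, c(5, 0, 0), "+")
  s1 <- kabsch_superpose(X, Y)
  expect_equal(s1$rmsd, 0, tolerance = 1e-10)
  expect_equal(s1$translation, c(-5, 0, 0), tolerance = 1e-8)

  rmsds <- vapply(1:10, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(300), 100, 3)
    th <- 30 * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    Y <- X %*% t(R) + matrix(rnorm(300, 0, 0.3 / sqrt(3)), 100, 3)
    kabsch_superpose(X, Y)$rmsd
  }, 0)
  expect_true(all(rmsds > 0.25 & rmsds < 0.45))
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("Kabsch rmsd equals brute-force recomputation and bio3d agrees", {
  set.seed(7)
  X <- matrix(rnorm(90), 30, 3)
  rt <- random_rigid(3)
  Y <- sweep(X %*% t(rt$R), 2, rt$t, "+")
  s <- kabsch_superpose(X, Y)
  expect_equal(s$rmsd, oracle_rmsd(s, X, Y), tolerance = 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  # independent oracle: bio3d least-squares fit of the same pairing
  xyz_fit <- suppressWarnings(  # bio3d notes "using all positions" as a warning
    bio3d::fit.xyz(fixed = as.vector(t(X)), mobile = as.vector(t(Y))))
  rmsd_bio3d <- sqrt(mean(colSums(matrix((xyz_fit - as.vector(t(X)))^2, 3))))
  expect_equal(s$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("hydrogen bonds obey the 2.5 A / 120-180 degree criteria", {
  expect_equal(nrow(detect_hbonds(make_interface("hbond", d_da = 2.4,
                                                 donor_angle = 165,
                                                 acceptor_angle = 150))), 1)
  expect_equal(nrow(detect_hbonds(make_interface("hbond", d_da = 2.6))), 0)
  expect_equal(nrow(detect_hbonds(make_interface("hbond", d_da = 2.4,
                                                 donor_angle = 100))), 0)
  ct <- detect_hbonds(make_interface("hbond", d_da = 2.4, donor_angle = 165,
                                     acceptor_angle = 150))
  expect_equal(ct$dist, 2.4, tolerance = 1e-6)
  expect_equal(ct$donor_angle, 165, tolerance = 1e-4)
  expect_equal(ct$acceptor_angle, 150, tolerance = 1e-4)
  # the relaxed conventional profile admits longer bonds
  expect_equal(nrow(detect_hbonds(make_interface("hbond", d_da = 3.2),
                                  conventional_criteria())), 1)
})

test_that("water bridges require both legs within 2.8 A and a water", {
  expect_equal(nrow(detect_water_bridges(make_interface("water_bridge",
                                                        d1 = 2.7, d2 = 2.7))), 1)
  expect_equal(nrow(detect_water_bridges(make_interface("water_bridge",
                                                        d1 = 3.0, d2 = 2.7))), 0)
  m <- make_interface("water_bridge", d1 = 2.7, d2 = 2.7)
  dry <- structure_model(m$atoms[!m$atoms$is_water, ])
  expect_equal(nrow(detect_water_bridges(dry)), 0)
  ct <- detect_water_bridges(m)
  expect_equal(c(ct$dist_a, ct$dist_b), c(2.7, 2.7), tolerance = 1e-6)
})

test_that("ring geometry returns centroid distance, angle and offset", {
  mk_ring <- function(coords) phabkit:::make_ring(coords)
  hexa <- function() {
    ang <- seq(0, by = pi / 3, length.out = 6)
    cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  }
  rA <- mk_ring(hexa())
  rB <- mk_ring(sweep(hexa(), 2, c(0, 0, 3.6), "+"))
  g <- ring_geometry(rA, rB)
  expect_equal(unname(g), c(3.6, 0, 0), tolerance = 1e-9)

  m <- make_interface("pi_pi", dist = 5.0, angle = 75, offset = 1.5)
  rings <- extract_rings(m)
  g2 <- ring_geometry(rings[[1]], rings[[2]])
  expect_equal(g2[["dist"]], 5.0, tolerance = 1e-6)
  expect_equal(g2[["angle"]], 75, tolerance = 1e-6)
  expect_equal(g2[["offset"]], 1.5, tolerance = 1e-6)

  rC <- mk_ring(sweep(hexa(), 2, c(1.5, 0, 3.4), "+"))
  g3 <- ring_geometry(rA, rC)
  expect_equal(g3[["dist"]], sqrt(3.4^2 + 1.5^2), tolerance = 1e-9)  # 3.716
  expect_equal(g3[["angle"]], 0, tolerance = 1e-9)
  expect_equal(g3[["offset"]], 1.5, tolerance = 1e-9)
})

test_that("pi-pi detection classifies shape and enforces the 3.5-5 A window", {
  ct <- detect_pi_pi(make_interface("pi_pi", dist = 5.0, angle = 75, offset = 1.5))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$shape, "T-shaped")
  ct2 <- detect_pi_pi(make_interface("pi_pi", dist = 3.6, angle = 0, offset = 0))
  expect_equal(ct2$shape, "parallel")
  expect_equal(nrow(detect_pi_pi(make_interface("pi_pi", dist = 5.3, angle = 0))), 0)
  ct3 <- detect_pi_pi(make_interface("pi_pi", dist = 4.5, angle = 45))
  expect_equal(ct3$shape, "intermediate")
})

test_that("pi-cation contacts respect the 4.5 A centroid cutoff", {
  expect_equal(nrow(detect_pi_cation(make_interface("pi_cation", dist = 4.2))), 1)
  expect_equal(nrow(detect_pi_cation(make_interface("pi_cation", dist = 4.8))), 0)
})

test_that("detectors are invariant under global rigid transforms", {
  for (seed in 1:3) {
    rt <- random_rigid(seed)
    m1 <- make_interface("pi_pi", dist = 4.6, angle = 70, offset = 1.0)
    g1 <- detect_pi_pi(m1); g2 <- detect_pi_pi(transform_model(m1, rt))
    expect_equal(g2$dist, g1$dist, tolerance = 1e-8)
    expect_equal(g2$angle, g1$angle, tolerance = 1e-6)
    expect_equal(g2$offset, g1$offset, tolerance = 1e-6)

    h1 <- make_interface("hbond", d_da = 2.4, donor_angle = 160,
                         acceptor_angle = 140)
    c1 <- detect_hbonds(h1); c2 <- detect_hbonds(transform_model(h1, rt))
    expect_equal(c2$dist, c1$dist, tolerance = 1e-8)
    expect_equal(c2$donor_angle, c1$donor_angle, tolerance = 1e-6)
  }
})

test_that("every emitted contact re-validates against its criteria", {
  crit <- contact_criteria()
  m <- make_interface("pi_pi", dist = 4.9, angle = 80, offset = 1.2)
  for (ct in split(detect_pi_pi(m, crit), seq_len(nrow(detect_pi_pi(m, crit))))) {
    expect_true(ct$dist >= crit$pi_pi_range[1] && ct$dist <= crit$pi_pi_range[2])
  }
  h <- detect_hbonds(make_interface("hbond", d_da = 2.45, donor_angle = 170,
                                    acceptor_angle = 160), crit)
  expect_true(all(h$dist <= crit$hbond_da_max))
  expect_true(all(h$donor_angle >= 120 & h$donor_angle <= 180))
})

test_that("the paratope shell applies the 10 A side-chain rule", {
  mk_res <- function(serial, resseq, chain, x, name = "CB", resname = "ALA") {
    data.frame(serial = serial, name = name, element = substr(name, 1, 1),
               resname = resname, resseq = resseq, ins = "", chain = chain,
               x = x, y = 0, z = 0, occ = 1, b = 0, is_water = FALSE,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk_res(1, 1, "B", 0, name = "P1", resname = "LIG"),
                 mk_res(2, 10, "A", 9.5),
                 mk_res(3, 11, "A", 10.5),
                 mk_res(4, 12, "A", 9.9, name = "CA"))  # backbone: ignored
  m <- structure_model(atoms)
  shell <- paratope_shell(m, "B", radius = 10)
  expect_true("A/ALA10" %in% shell)
  expect_false("A/ALA11" %in% shell)
  expect_false("A/ALA12" %in% shell)
  expect_error(paratope_shell(m, "Z"), "empty antigen selection")
})

test_that("contact-mode paratope is a subset of the 10 A shell", {
  m <- make_interface("pi_pi", dist = 4.8, angle = 75, offset = 1.0)
  shell <- paratope_shell(m, "B", radius = 10)
  contacts <- paratope_shell(m, "B", mode = "contacts")
  expect_true(all(contacts %in% shell))
})

test_that("GXGX scanning reports the motif glycines at Kabat 96 and 98", {
  seg <- function(aas) {
    nc <- data.frame(number = 95:99, insertion = "", aa = strsplit(aas, "")[[1]],
                     label = as.character(95:99), stringsAsFactors = FALSE)
    attr(nc, "chain_kind") <- "H"; attr(nc, "scheme") <- "kabat"
    class(nc) <- c("numbered_chain", "data.frame")
    nc
  }
  hits <- find_gxgx(seg("LGSGN"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gly1_label, "96")
  expect_equal(hits$gly2_label, "98")
  hits2 <- find_gxgx(seg("LGTGS"))
  expect_equal(hits2$gly1_label, "96")
  expect_equal(hits2$gly2_label, "98")
  none <- find_gxgx(seg("AAAAA"))
  expect_equal(nrow(none), 0)
})

test_that("SASA reproduces the isolated-sphere and two-sphere analytics", {
  one <- structure_model(data.frame(
    serial = 1, name = "C", element = "C", resname = "LIG", resseq = 1,
    ins = "", chain = "A", x = 0, y = 0, z = 0, occ = 1, b = 0,
    is_water = FALSE, stringsAsFactors = FALSE))
  a <- sasa(one, probe = 1.7, n_points = 960)
  expect_equal(attr(a, "total"), 4 * pi * 3.4^2, tolerance = 0.01)

  two_far <- structure_model(data.frame(
    serial = 1:2, name = "C", element = "C", resname = "LIG", resseq = 1:2,
    ins = "", chain = c("A", "B"), x = c(0, 100), y = 0, z = 0, occ = 1,
    b = 0, is_water = FALSE, stringsAsFactors = FALSE))
  expect_equal(buried_surface(two_far, "A", "B"), 0, tolerance = 1e-9)

  d <- 3.0
  two_near <- structure_model(data.frame(
    serial = 1:2, name = "C", element = "C", resname = "LIG", resseq = 1:2,
    ins = "", chain = "A", x = c(0, d), y = 0, z = 0, occ = 1, b = 0,
    is_water = FALSE, stringsAsFactors = FALSE))
  total <- attr(sasa(two_near, probe = 1.7, n_points = 960), "total")
  expect_equal(total, oracle_two_sphere_sasa(3.4, 3.4, d), tolerance = 0.02)
})

test_that("CA superposition of a rigidly moved model reports ~0 rmsd", {
  ch <- make_chain("H")
  n <- 30
  set.seed(5)
  atoms <- data.frame(
    serial = 1:n, name = "CA", element = "C", resname = "GLY",
    resseq = 1:n, ins = "", chain = "H",
    x = cumsum(rnorm(n, 3.8, 0.1)), y = rnorm(n, 0, 2), z = rnorm(n, 0, 2),
    occ = 1, b = 0, is_water = FALSE, stringsAsFactors = FALSE)
  m1 <- structure_model(atoms)
  m2 <- transform_model(m1, random_rigid(11))
  s <- ca_superpose(m1, m2, "H")
  expect_equal(s$rmsd, 0, tolerance = 1e-8)
  expect_equal(s$n_atoms, n)
})
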