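# Independent oracles used across tests.

# Brute-force amino-acid distribution of a doped codon via expand.grid
# over all 64 codons (independent of the package's tapply-based path).
oracle_codon_dist <- function(m1, m2, m3) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  out <- new.env()
  for (i in seq_len(nrow(grid))) {
    codon <- paste0(grid$b1[i], grid$b2[i], grid$b3[i])
    aa <- gc[[codon]]
    if (aa == "*") aa <- "STOP"
    p <- m1[[grid$b1[i]]] * m2[[grid$b2[i]]] * m3[[grid$b3[i]]]
    prev <- if (is.null(out[[aa]])) 0 else out[[aa]]
    out[[aa]] <- prev + p
  }
  vals <- mget(ls(out), envir = out)
  unlist(vals)
}

# Brute-force RMSD after applying a transform.
oracle_rmsd <- function(sup, reference, mobile) {
  moved <- sweep(as.matrix(mobile) %*% t(sup$rotation), 2,
                 sup$translation, "+")
  sqrt(mean(rowSums((moved - as.matrix(reference))^2)))
}

# Analytic SASA of two overlapping spheres of expanded radius R1, R2 at
# centre distance d (spherical-cap formula).
oracle_two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- (R2^2 - (d - R1)^2) / (2 * d)   # cap height on sphere 1
  h2 <- (R1^2 - (d - R2)^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

make_flat_traces <- function(ka, kd, Rmax, conc, noise_sd = 0, seed = 1) {
  lapply(seq_along(conc), function(i) {
    simulate_sensorgram(ka, kd, conc[i], Rmax, noise_sd = noise_sd,
                        seed = seed + i)
  })
}
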