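# Independent brute-force oracles used across tests.

# Spin matrices (Sz, S+, S-) for spin S in the |S, m> basis, m = S..-S
spin_matrices <- function(S) {
  m <- seq(S, -S, by = -1)
  n <- length(m)
  Sz <- diag(m)
  Sp <- matrix(0, n, n)
  for (i in 2:n) Sp[i - 1, i] <- sqrt(S * (S + 1) - m[i] * (m[i] + 1))
  list(Sz = Sz, Sp = Sp, Sm = t(Sp), n = n)
}

# Product-basis Hamiltonian J * S1.S2 (J = 1) and total Sz for a spin pair
dimer_operators <- function(S1, S2) {
  a <- spin_matrices(S1); b <- spin_matrices(S2)
  I1 <- diag(a$n); I2 <- diag(b$n)
  S1z <- kronecker(a$Sz, I2); S2z <- kronecker(I1, b$Sz)
  S1p <- kronecker(a$Sp, I2); S2p <- kronecker(I1, b$Sp)
  S1m <- kronecker(a$Sm, I2); S2m <- kronecker(I1, b$Sm)
  H <- S1z %*% S2z + 0.5 * (S1p %*% S2m + S1m %*% S2p)
  list(H = H, Sz = S1z + S2z, S1z = S1z)
}

# Eigen-decompose J*S1.S2 and return per-multiplet energy, degeneracy and
# projection coefficient c1 = <S1z>/M evaluated in the |S',M> eigenstates.
brute_force_ladder <- function(S1, S2, J = 1) {
  op <- dimer_operators(S1, S2)
  ev <- eigen(J * op$H, symmetric = TRUE)
  vals <- round(ev$values, 9)
  out <- NULL
  for (u in sort(unique(vals))) {
    idx <- which(vals == u)
    V <- ev$vectors[, idx, drop = FALSE]
    # diagonalize Sz within the degenerate multiplet
    szs <- eigen(t(V) %*% op$Sz %*% V, symmetric = TRUE)
    M <- round(szs$values, 9)
    W <- V %*% szs$vectors
    deg <- length(idx)
    Stot <- (deg - 1) / 2
    # c1 from any M != 0 state
    c1 <- NA_real_
    k <- which(abs(M) > 1e-6)
    if (length(k)) {
      k <- k[1]
      c1 <- as.numeric(t(W[, k]) %*% op$S1z %*% W[, k]) / M[k]
    }
    out <- rbind(out, data.frame(S_tot = Stot, energy = u - min(vals),
                                 degeneracy = deg, c1 = c1))
  }
  # energies relative to ground multiplet, like ladder()
  out$energy <- out$energy - min(out$energy)
  out[order(out$S_tot), ]
}

# Minimal two-residue backbone fragment with ideal planar geometry, for
# amide-proton construction tests. Returns PDB text lines.
tripeptide_pdb <- function() {
  # residue 1: C at origin-ish; residue 2: N, CA placed in the xy plane
  atoms <- list(
    c("ATOM", "C",  "ALA", 1, 0.000, 0.000, 0.000, "C"),
    c("ATOM", "O",  "ALA", 1, 0.600, 1.060, 0.000, "O"),
    c("ATOM", "CA", "ALA", 1, -1.520, 0.100, 0.000, "C"),
    c("ATOM", "N",  "GLY", 2, 0.700, -1.150, 0.000, "N"),
    c("ATOM", "CA", "GLY", 2, 2.140, -1.250, 0.000, "C"),
    c("ATOM", "C",  "GLY", 2, 2.800, -2.600, 0.000, "C"))
  vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    sprintf("%-6s%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a[1], i, a[2], a[3], as.integer(a[4]),
            as.numeric(a[5]), as.numeric(a[6]), as.numeric(a[7]), 1, 0,
            substr(a[2], 1, 1))
  }, character(1))
}

# random rigid transform (proper rotation + translation)
random_rigid_transform <- function(xyz) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t(q %*% t(xyz)) + matrix(stats::rnorm(3, sd = 10), nrow(xyz), 3,
                           byrow = TRUE)
}

fixture_path <- function(which) {
  system.file("extdata",
              switch(which, signals = "mitoneet_signals.tsv",
                     distances = "mitoneet_distances.tsv"),
              package = "clusterblind")
}
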