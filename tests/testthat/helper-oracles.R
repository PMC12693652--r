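# Independent oracles and fixture builders used across the suite. Each is
# deliberately naive and shares no code with the implementation it checks.

# Normalized mutual information by direct joint counting: equal weights,
# no pseudocount, no gaps.
mi_oracle <- function(ci, cj) {
  joint <- table(ci, cj) / length(ci)
  pi <- rowSums(joint); pj <- colSums(joint)
  mi <- 0
  for (a in rownames(joint)) {
    for (b in colnames(joint)) {
      p <- joint[a, b]
      if (p > 0) mi <- mi + p * log2(p / (pi[a] * pj[b]))
    }
  }
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hmin <- min(h(pi), h(pj))
  if (hmin == 0) 0 else mi / hmin
}

# Brute-force average-linkage agglomeration; returns the cophenetic
# distance matrix (the merge structure it encodes is what we compare).
avg_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, j, i)
      }
    }
    a <- clusters[[best[2]]]; b <- clusters[[best[3]]]
    coph[a, b] <- coph[b, a] <- best[1]
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[3]]] <- NULL
  }
  coph
}

# Minimal NeRF chain builder: backbone N/CA/C coordinates realizing given
# phi/psi (and trans omega) torsions with ideal geometry.
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  as.numeric(c + cbind(bc, m, n) %*% d)
}

build_backbone <- function(phi, psi, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  atoms <- list(N1 = c(0, 0, 0), CA1 = c(1.458, 0, 0))
  # C1 in the xy-plane at the ideal N-CA-C angle
  ang <- 111.2 * pi / 180
  atoms$C1 <- atoms$CA1 + 1.525 * c(-cos(ang), sin(ang), 0)
  coords <- list(data.frame(resno = 1L,
                            atom = c("N", "CA", "C"),
                            x = c(atoms$N1[1], atoms$CA1[1], atoms$C1[1]),
                            y = c(atoms$N1[2], atoms$CA1[2], atoms$C1[2]),
                            z = 0))
  prevN <- atoms$N1; prevCA <- atoms$CA1; prevC <- atoms$C1
  for (i in seq_len(n)[-1]) {
    Ni <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, psi[i - 1L])
    CAi <- place_atom(prevCA, prevC, Ni, 1.458, 121.7, omega)
    Ci <- place_atom(prevC, Ni, CAi, 1.525, 111.2, phi[i])
    coords[[i]] <- data.frame(resno = i,
                              atom = c("N", "CA", "C"),
                              x = c(Ni[1], CAi[1], Ci[1]),
                              y = c(Ni[2], CAi[2], Ci[2]),
                              z = c(Ni[3], CAi[3], Ci[3]))
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  df <- do.call(rbind, coords)
  df$chain <- "A"; df$resname <- "ALA"
  df
}

# Apply a random rigid motion (proper rotation + translation) to n x 3
# coordinates.
rigid_motion <- function(m) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(m %*% q, 2L, rnorm(3, sd = 10), `+`)
}

# A toy isoform record embedding the C28 context around a given window.
toy_record <- function(window = "WFRGLNRIQTQIKVVKAF", label = "toy",
                       flank_left = "MA", flank_right = "GG") {
  protein <- paste0(flank_left, "LRRGQIL", window, "HSS", flank_right)
  set.seed(99)
  isoform_record("GENE1", label, "SYN0000", protein,
                 cds_seq = reverse_translate(protein))
}
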