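# Linear (P1) axisymmetric finite-element assembly on triangles.
#
# All integrals carry the axisymmetric weight r (the 2*pi factor cancels
# from both sides of the discrete equations).  The mass matrix and the
# Robin boundary matrix are row-sum lumped, which keeps the implicit
# system an M-matrix on reasonable meshes and so preserves the discrete
# maximum principle.

# Per-element geometric quantities reused by every assembly call.
.fem_precompute <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  r <- cbind(n[e[, 1], 1], n[e[, 2], 1], n[e[, 3], 1])
  z <- cbind(n[e[, 1], 2], n[e[, 2], 2], n[e[, 3], 2])
  area <- 0.5 * ((r[, 2] - r[, 1]) * (z[, 3] - z[, 1]) -
                   (r[, 3] - r[, 1]) * (z[, 2] - z[, 1]))
  # grad phi_i = (b_i, c_i) / (2A)
  b <- cbind(z[, 2] - z[, 3], z[, 3] - z[, 1], z[, 1] - z[, 2])
  cc <- cbind(r[, 3] - r[, 2], r[, 1] - r[, 3], r[, 2] - r[, 1])
  list(e = e, r = r, area = area, b = b, c = cc,
       rbar = rowMeans(r), nn = nrow(n),
       region = mesh$region)
}

# Stiffness matrix: sum_e coeff_e * rbar_e / (4A) * (b_i b_j + c_i c_j)
.stiffness <- function(fp, coeff) {
  ne <- length(fp$area)
  fac <- coeff * fp$rbar / (4 * fp$area)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (bq in 1:3) {
    k <- k + 1L
    ii[[k]] <- fp$e[, a]
    jj[[k]] <- fp$e[, bq]
    xx[[k]] <- fac * (fp$b[, a] * fp$b[, bq] + fp$c[, a] * fp$c[, bq])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(fp$nn, fp$nn))
}

# Lumped mass vector: m_i = sum_e coeff_e * A/12 * (2 r_i + r_j + r_k)
.lumped_mass <- function(fp, coeff) {
  rs <- rowSums(fp$r)
  m <- numeric(fp$nn)
  for (a in 1:3) {
    w <- coeff * fp$area / 12 * (rs + fp$r[, a])
    tab <- rowsum(w, fp$e[, a])
    idx <- as.integer(rownames(tab))
    m[idx] <- m[idx] + tab[, 1]
  }
  m
}

# Lumped Robin boundary vector over an edge list:
# b_i += coeff * len/6 * (2 r_i + r_j)
.robin_lump <- function(mesh, edges, coeff) {
  n <- mesh$nodes
  p <- edges[, 1]; q <- edges[, 2]
  len <- sqrt((n[p, 1] - n[q, 1])^2 + (n[p, 2] - n[q, 2])^2)
  bv <- numeric(nrow(n))
  w1 <- coeff * len / 6 * (2 * n[p, 1] + n[q, 1])
  w2 <- coeff * len / 6 * (n[p, 1] + 2 * n[q, 1])
  t1 <- rowsum(w1, p); t2 <- rowsum(w2, q)
  bv[as.integer(rownames(t1))] <- bv[as.integer(rownames(t1))] + t1[, 1]
  bv[as.integer(rownames(t2))] <- bv[as.integer(rownames(t2))] + t2[, 1]
  bv
}

# r-weighted nodal integration weights per region:
# w_i = sum_{e in region} A/12 (2 r_i + r_j + r_k); sum(w) = int_region r dA
.region_node_weights <- function(fp, region) {
  sel <- fp$region == region
  rs <- rowSums(fp$r)
  w <- numeric(fp$nn)
  for (a in 1:3) {
    ww <- (fp$area / 12 * (rs + fp$r[, a]))[sel]
    tab <- rowsum(ww, fp$e[sel, a])
    idx <- as.integer(rownames(tab))
    w[idx] <- w[idx] + tab[, 1]
  }
  w
}
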