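# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and bio3d) so agreement is informative.

# Optimal rigid superposition by Horn's quaternion method: returns the
# coordinates of `mobile` (n x 3) superposed onto `fixed` using the atoms
# in `fit_idx`, plus the resulting RMSD over `measure_idx`.
oracle_superpose_rmsd <- function(fixed, mobile, fit_idx, measure_idx) {
  A <- fixed[fit_idx, , drop = FALSE]
  B <- mobile[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  M <- t(Bc) %*% Ac
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  moved <- sweep(sweep(mobile, 2, cb) %*% t(R), 2, ca, `+`)
  d <- moved[measure_idx, , drop = FALSE] - fixed[measure_idx, , drop = FALSE]
  list(coords = moved, rmsd = sqrt(mean(rowSums(d^2))))
}

# Brute-force pocket membership: all-pairs double loop.
oracle_pocket_residues <- function(atoms, lig, cutoff) {
  keep <- character(0)
  for (r in unique(paste(atoms$chain, atoms$resno))) {
    res <- atoms[paste(atoms$chain, atoms$resno) == r, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((res$x[i] - lig[j, 1])^2 + (res$y[i] - lig[j, 2])^2 +
                    (res$z[i] - lig[j, 3])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) keep <- c(keep, r)
  }
  sort(keep)
}

# Brute-force interface rows: double loop over atom pairs, then sort.
oracle_interface_rows <- function(prot, lig, cutoff) {
  rows <- NULL
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        rows <- rbind(rows, data.frame(i = i, j = j, d = d))
      }
    }
  }
  if (is.null(rows)) return(rows)
  rows[order(rows$d, rows$i, rows$j), , drop = FALSE]
}

# Brute-force enrichment counting.
oracle_enrichment <- function(scores, active, cutoff) {
  n_c <- 0L; nn_c <- 0L
  for (k in seq_along(scores)) {
    if (scores[k] > cutoff) {
      nn_c <- nn_c + 1L
      if (active[k]) n_c <- n_c + 1L
    }
  }
  tpr <- n_c / sum(active)
  rnd <- nn_c / length(scores)
  list(n_c = n_c, nn_c = nn_c, tpr = tpr, random_rate = rnd,
       ratio = tpr / rnd)
}

# Brute-force hydrogen-bond triple count for one frame.
oracle_hbond_count <- function(xyz, donors, acceptors, d_max, angle_min) {
  n <- 0L
  for (k in seq_len(nrow(donors))) {
    D <- xyz[donors$d[k], ]; H <- xyz[donors$h[k], ]
    for (a in acceptors) {
      if (a == donors$d[k] || a == donors$h[k]) next
      A <- xyz[a, ]
      if (sqrt(sum((D - A)^2)) > d_max) next
      v1 <- D - H; v2 <- A - H
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      if (acos(max(-1, min(1, cosang))) * 180 / pi >= angle_min) n <- n + 1L
    }
  }
  n
}

# Random toy structure: n_res residues of n_atom_range atoms each.
make_toy_structure <- function(n_res, n_atom_range = c(1L, 4L),
                               spread = 12) {
  rows <- NULL
  for (r in seq_len(n_res)) {
    na <- sample(seq(n_atom_range[1], n_atom_range[2]), 1L)
    center <- runif(3, -spread, spread)
    for (a in seq_len(na)) {
      rows <- rbind(rows, data.frame(
        element = sample(c("C", "N", "O", "S"), 1L), name = "X",
        resname = "TOY", resno = r, chain = "A",
        x = center[1] + rnorm(1), y = center[2] + rnorm(1),
        z = center[3] + rnorm(1), stringsAsFactors = FALSE))
    }
  }
  structure_model(rows)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
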