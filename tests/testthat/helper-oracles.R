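# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Kearsley quaternion method: best-fit RMSD from the smallest eigenvalue
# of the 4x4 key matrix (no SVD involved).
oracle_rmsd_quaternion <- function(ref, mobile) {
  n <- nrow(ref)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(ref, 2, colMeans(ref))
  m <- P - Q
  p <- P + Q
  xm <- m[, 1]; ym <- m[, 2]; zm <- m[, 3]
  xp <- p[, 1]; yp <- p[, 2]; zp <- p[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  K[1, 2] <- K[2, 1] <- sum(yp * zm - ym * zp)
  K[1, 3] <- K[3, 1] <- sum(xm * zp - xp * zm)
  K[1, 4] <- K[4, 1] <- sum(xp * ym - xm * yp)
  K[2, 2] <- sum(yp^2 + zp^2 + xm^2)
  K[2, 3] <- K[3, 2] <- sum(xm * ym - xp * yp)
  K[2, 4] <- K[4, 2] <- sum(xm * zm - xp * zp)
  K[3, 3] <- sum(xp^2 + zp^2 + ym^2)
  K[3, 4] <- K[4, 3] <- sum(ym * zm - yp * zp)
  K[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, lam) / n)
}

# exhaustive all-pairs minimum distance between two coordinate blocks
oracle_min_distance <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# brute-force water-density double sum: for every grid point, count
# (frame, water) combinations within r, divide by T * V_r
oracle_density_grid <- function(water_frames, origin, dims, spacing, r) {
  T <- length(water_frames)
  counts <- array(0, dim = dims)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (iz in seq_len(dims[3])) {
      ci <- origin + (c(ix, iy, iz) - 1) * spacing
      n <- 0L
      for (t in seq_len(T)) {
        w <- water_frames[[t]]
        for (j in seq_len(nrow(w)))
          if (sum((w[j, ] - ci)^2) <= r^2) n <- n + 1L
      }
      counts[ix, iy, iz] <- n
    }
  counts / (T * (4 / 3) * pi * r^3)
}

# independent donor/acceptor table (restated from standard biochemistry,
# not shared with the package internals)
.oracle_don <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1",
                    ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
                    SER = "OG", THR = "OG1", TYR = "OH")
.oracle_acc <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                    ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
                    SER = "OG", THR = "OG1", TYR = "OH")

oracle_donors <- function(res) {
  out <- .oracle_don[[res]]
  if (res != "PRO") out <- c("N", out)
  out
}
oracle_acceptors <- function(res) c("O", "OXT", .oracle_acc[[res]])

# brute-force interface scan: classify every inter-chain residue pair by
# looping over atoms directly on the atom table
oracle_contacts <- function(s, chain_a, chain_b, hbond_cutoff = 3.5,
                            vdw_cutoff = 4.5) {
  a <- s$atoms[!s$atoms$is_h, ]
  recs <- list()
  for (ra in unique(a$resno[a$chain == chain_a])) {
    for (rb in unique(a$resno[a$chain == chain_b])) {
      at_a <- a[a$chain == chain_a & a$resno == ra, ]
      at_b <- a[a$chain == chain_b & a$resno == rb, ]
      dmin <- Inf; da_min <- Inf
      for (i in seq_len(nrow(at_a))) for (j in seq_len(nrow(at_b))) {
        d <- sqrt(sum((c(at_a$x[i], at_a$y[i], at_a$z[i]) -
                         c(at_b$x[j], at_b$y[j], at_b$z[j]))^2))
        if (d < dmin) dmin <- d
        valid <- (at_a$elety[i] %in% oracle_donors(at_a$resid[1]) &&
                    at_b$elety[j] %in% oracle_acceptors(at_b$resid[1])) ||
          (at_a$elety[i] %in% oracle_acceptors(at_a$resid[1]) &&
             at_b$elety[j] %in% oracle_donors(at_b$resid[1]))
        if (valid && d < da_min) da_min <- d
      }
      if (da_min <= hbond_cutoff) {
        recs[[length(recs) + 1L]] <- data.frame(
          res_a = ra, res_b = rb, type = "hbond", dist = da_min)
      } else if (dmin <= vdw_cutoff) {
        recs[[length(recs) + 1L]] <- data.frame(
          res_a = ra, res_b = rb, type = "vdw", dist = dmin)
      }
    }
  }
  if (!length(recs)) return(NULL)
  out <- do.call(rbind, recs)
  out[order(out$type, out$res_a, out$res_b), ]
}

# random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

transform_structure <- function(s, R, t) {
  set_structure_coords(s, apply_rigid(structure_coords(s), R, t))
}

transform_trajectory <- function(traj, R, t) {
  new_trajectory(traj$topology, lapply(traj$frames, apply_rigid, R = R, t = t))
}
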