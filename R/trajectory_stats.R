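# Per-frame trajectory statistics: RMSD and minimum-distance time series,
# hydrogen-bond formation probability, and the grid-based water-occupancy
# density estimator
#
#   rho_i = 1/(T * V_r) * sum_t sum_j H(r - |x_{j,t} - c_i|)
#
# where T is the number of snapshots, the inner sum runs over water oxygen
# positions x_{j,t}, c_i is grid point i, V_r = (4/3) pi r^3 and H is the
# Heaviside step (H(0) := 1 here; the boundary has measure zero for real
# coordinates). A water contributes to every grid point within r: rho is a
# local density, not a partition of the waters.

#' Hydrogen-bond criterion
#'
#' Distance-and-angle rule: donor-acceptor heavy-atom distance within
#' `donor_acceptor_cutoff` and, when hydrogens are available, the
#' hydrogen-donor-acceptor angle within `angle_cutoff`. These defaults
#' (0.35 nm, 30 degrees) are the documented defaults of the standard
#' trajectory hbond tools; without hydrogens the distance term alone is
#' applied, flagged in the result.
#'
#' @param donor_acceptor_cutoff Angstrom.
#' @param angle_cutoff degrees (hydrogen-donor-acceptor).
#' @param require_hydrogens error instead of falling back to distance-only
#'   when the topology lacks hydrogens.
#' @export
hbond_criterion <- function(donor_acceptor_cutoff = 3.5, angle_cutoff = 30,
                            require_hydrogens = FALSE) {
  if (donor_acceptor_cutoff <= 0 || angle_cutoff <= 0)
    stop("hbond criterion cutoffs must be positive")
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff = angle_cutoff,
                 require_hydrogens = require_hydrogens),
            class = "hbond_criterion")
}

#' Per-frame RMSD time series
#'
#' For each frame, the `fit_idx` atoms are superposed onto their positions
#' in frame 1 and the RMSD of the `report_idx` atoms (after applying the
#' fitted transform) is reported.
#'
#' @param traj a `gpcr_trajectory`.
#' @param fit_idx,report_idx atom index vectors into the topology;
#'   `report_idx` defaults to `fit_idx`.
#' @return data.frame with columns `frame`, `value` (Angstrom).
#' @export
rmsd_series <- function(traj, fit_idx, report_idx = fit_idx) {
  if (!length(fit_idx)) stop("empty fit selection")
  if (!length(report_idx)) stop("empty report selection")
  ref_fit <- traj$frames[[1]][fit_idx, , drop = FALSE]
  ref_rep <- traj$frames[[1]][report_idx, , drop = FALSE]
  vals <- vapply(seq_len(frame_count(traj)), function(t) {
    sp <- superpose(ref_fit, traj$frames[[t]][fit_idx, , drop = FALSE])
    moved <- apply_superposition(sp, traj$frames[[t]][report_idx, , drop = FALSE])
    sqrt(mean(rowSums((moved - ref_rep)^2)))
  }, numeric(1))
  data.frame(frame = seq_along(vals), value = vals)
}

#' Minimum heavy-atom distance time series for a residue pair
#'
#' @param traj a `gpcr_trajectory`.
#' @param res_a,res_b residue ids ("chain:resno").
#' @return data.frame with columns `frame`, `value` (Angstrom).
#' @export
min_distance_series <- function(traj, res_a, res_b) {
  top <- traj$topology
  ia <- residue_atom_idx(top, res_a); ia <- ia[!top$atoms$is_h[ia]]
  ib <- residue_atom_idx(top, res_b); ib <- ib[!top$atoms$is_h[ib]]
  if (!length(ia)) stop("residue has no heavy atoms: ", res_a)
  if (!length(ib)) stop("residue has no heavy atoms: ", res_b)
  vals <- vapply(seq_len(frame_count(traj)), function(t) {
    xa <- traj$frames[[t]][ia, , drop = FALSE]
    xb <- traj$frames[[t]][ib, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  data.frame(frame = seq_along(vals), value = vals)
}

#' Hydrogen-bond formation probability over a trajectory
#'
#' Fraction of frames in which any qualifying donor/acceptor combination
#' between the two residues satisfies the criterion. With hydrogens in the
#' topology, a hydrogen within 1.25 Angstrom of the donor heavy atom is
#' taken as its bonded hydrogen and the hydrogen-donor-acceptor angle term
#' applies; otherwise the heavy-atom distance term alone is used.
#'
#' @param traj a `gpcr_trajectory`.
#' @param donor_res,acceptor_res residue ids.
#' @param criterion an [hbond_criterion()].
#' @return probability in [0, 1], with attribute `"angle_term"` saying
#'   whether the angle criterion was applied.
#' @export
hbond_probability <- function(traj, donor_res, acceptor_res,
                              criterion = hbond_criterion()) {
  top <- traj$topology
  id <- residue_atom_idx(top, donor_res)
  ia <- residue_atom_idx(top, acceptor_res)
  don_names <- donor_atoms(top$atoms$resid[id[1]], backbone = TRUE)
  acc_names <- acceptor_atoms(top$atoms$resid[ia[1]], backbone = TRUE)
  d_idx <- id[top$atoms$elety[id] %in% don_names]
  a_idx <- ia[top$atoms$elety[ia] %in% acc_names]
  if (!length(d_idx)) stop("no donor atoms in residue ", donor_res)
  if (!length(a_idx)) stop("no acceptor atoms in residue ", acceptor_res)
  h_idx <- id[top$atoms$is_h[id]]
  have_h <- length(h_idx) > 0L
  if (criterion$require_hydrogens && !have_h)
    stop("criterion requires hydrogens but the topology has none on ", donor_res)
  cut2 <- criterion$donor_acceptor_cutoff^2
  cos_cut <- cos(criterion$angle_cutoff * pi / 180)
  bonded <- sum(vapply(seq_len(frame_count(traj)), function(t) {
    xyz <- traj$frames[[t]]
    for (d in d_idx) for (a in a_idx) {
      dd <- sum((xyz[d, ] - xyz[a, ])^2)
      if (dd > cut2) next
      if (!have_h) return(TRUE)
      # angle term: any hydrogen bonded to this donor
      hs <- h_idx[rowSums(sweep(xyz[h_idx, , drop = FALSE], 2,
                                xyz[d, ])^2) <= 1.25^2]
      if (!length(hs)) return(TRUE)  # no bonded H found: distance term only
      for (h in hs) {
        v1 <- xyz[h, ] - xyz[d, ]; v2 <- xyz[a, ] - xyz[d, ]
        cang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        if (cang >= cos_cut) return(TRUE)
      }
    }
    FALSE
  }, logical(1)))
  out <- bonded / frame_count(traj)
  attr(out, "angle_term") <- have_h
  out
}

#' Water-occupancy density grid over a trajectory
#'
#' Exact evaluation of the occupancy-density estimator at every grid point
#' of a cubic lattice spanning `region`. When `fit_idx` is given, every
#' frame is first superposed onto frame 1 over those atoms (the receptor
#' C-alpha set, typically) and the fitted transform is applied to the water
#' oxygens before counting.
#'
#' @param traj a `gpcr_trajectory` containing water residues (HOH/WAT).
#' @param region list with `min` and `max` 3-vectors (Angstrom) bounding the
#'   grid.
#' @param spacing grid spacing in Angstrom (default 0.4).
#' @param r counting-sphere radius in Angstrom (default 1).
#' @param fit_idx optional atom indices for per-frame pre-superposition.
#' @param bulk_density reference bulk water density in waters per cubic
#'   Angstrom (default 0.0334), stored for [high_density_regions()].
#' @return a `density_grid`.
#' @export
water_density_grid <- function(traj, region, spacing = 0.4, r = 1.0,
                               fit_idx = NULL, bulk_density = 0.0334) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (r <= 0) stop("counting radius r must be positive")
  top <- traj$topology
  w_idx <- which(is_water(top$atoms$resid) & top$atoms$elesy == "O")
  dims <- pmax(1L, as.integer(floor((region$max - region$min) / spacing)) + 1L)
  counts <- array(0, dim = dims)
  if (!length(w_idx)) {
    warning("trajectory contains no water oxygens: returning all-zero grid")
    return(new_density_grid(region$min, spacing, counts,
                            params = list(r = r, T = frame_count(traj), N = 0L,
                                          bulk_density = bulk_density)))
  }
  origin <- as.numeric(region$min)
  m <- as.integer(ceiling(r / spacing))
  offs <- as.matrix(expand.grid(ix = -m:m, iy = -m:m, iz = -m:m))
  nbin <- prod(dims)
  ref_fit <- if (!is.null(fit_idx)) traj$frames[[1]][fit_idx, , drop = FALSE]
  counts_vec <- numeric(nbin)
  for (t in seq_len(frame_count(traj))) {
    xyz <- traj$frames[[t]]
    wat <- xyz[w_idx, , drop = FALSE]
    if (!is.null(fit_idx)) {
      sp <- superpose(ref_fit, xyz[fit_idx, , drop = FALSE])
      wat <- apply_superposition(sp, wat)
    }
    li_all <- integer(0)
    for (j in seq_len(nrow(wat))) {
      w <- wat[j, ]
      base <- as.integer(floor((w - origin) / spacing)) + 1L
      cand <- sweep(offs, 2, base, "+")
      keep <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
        cand[, 2] >= 1L & cand[, 2] <= dims[2] &
        cand[, 3] >= 1L & cand[, 3] <= dims[3]
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      cx <- origin[1] + (cand[, 1] - 1L) * spacing
      cy <- origin[2] + (cand[, 2] - 1L) * spacing
      cz <- origin[3] + (cand[, 3] - 1L) * spacing
      within <- (cx - w[1])^2 + (cy - w[2])^2 + (cz - w[3])^2 <= r^2
      cand <- cand[within, , drop = FALSE]
      if (!nrow(cand)) next
      li_all <- c(li_all, cand[, 1] + dims[1] * (cand[, 2] - 1L) +
                    dims[1] * dims[2] * (cand[, 3] - 1L))
    }
    if (length(li_all))
      counts_vec <- counts_vec + tabulate(li_all, nbins = nbin)
  }
  v_r <- (4 / 3) * pi * r^3
  rho <- array(counts_vec / (frame_count(traj) * v_r), dim = dims)
  new_density_grid(origin, spacing, rho,
                   params = list(r = r, T = frame_count(traj),
                                 N = length(w_idx), bulk_density = bulk_density))
}

#' High-density regions of a density grid
#'
#' 26-connected components of grid points whose density is at least
#' `k` times the bulk density, sorted by decreasing peak density ratio.
#'
#' @param grid a `density_grid` whose params carry `bulk_density` (or pass
#'   `bulk_density` explicitly).
#' @param k density-ratio threshold (default 2: twice bulk).
#' @param bulk_density override for the stored bulk density.
#' @return list of clusters, each a list with `indices` (matrix of grid
#'   indices), `size`, `peak_ratio`, `peak_index`.
#' @export
high_density_regions <- function(grid, k = 2.0, bulk_density = NULL) {
  bulk <- bulk_density %||% grid$params$bulk_density
  if (is.null(bulk) || !is.finite(bulk) || bulk <= 0)
    stop("bulk density unset and not estimable")
  d <- grid$dims
  mask <- grid$values >= k * bulk
  lin <- function(i) i[, 1] + d[1] * (i[, 2] - 1L) + d[1] * d[2] * (i[, 3] - 1L)
  visited <- array(FALSE, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  clusters <- list()
  seeds <- which(mask & !visited, arr.ind = TRUE)
  while (nrow(seeds)) {
    queue <- seeds[1, , drop = FALSE]
    visited[queue] <- TRUE
    members <- queue
    while (nrow(queue)) {
      nxt <- do.call(rbind, lapply(seq_len(nrow(queue)), function(q)
        sweep(offs, 2, queue[q, ], "+")))
      keep <- nxt[, 1] >= 1L & nxt[, 1] <= d[1] &
        nxt[, 2] >= 1L & nxt[, 2] <= d[2] &
        nxt[, 3] >= 1L & nxt[, 3] <= d[3]
      nxt <- unique(nxt[keep, , drop = FALSE])
      if (nrow(nxt)) {
        ok <- mask[nxt] & !visited[nxt]
        nxt <- nxt[ok, , drop = FALSE]
      }
      if (nrow(nxt)) {
        visited[nxt] <- TRUE
        members <- rbind(members, nxt)
      }
      queue <- nxt
    }
    ratios <- grid$values[members] / bulk
    pk <- which.max(ratios)
    clusters[[length(clusters) + 1L]] <-
      list(indices = members, size = nrow(members),
           peak_ratio = ratios[pk], peak_index = members[pk, ])
    seeds <- which(mask & !visited, arr.ind = TRUE)
  }
  ord <- order(vapply(clusters, `[[`, numeric(1), "peak_ratio"),
               decreasing = TRUE)
  clusters[ord]
}

#' Write a time series as TSV (frame, value)
#' @param series data.frame from [rmsd_series()] or [min_distance_series()].
#' @param path output path.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
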