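# Rigid-body geometry primitives: least-squares superposition (proper
# rotations only), RMSD after fitting, minimum inter-residue distances,
# helix axes and axial displacement projections.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `ref`. Reflections are excluded by flipping the sign of
#' the smallest singular direction when the determinant is negative.
#'
#' @param ref,mobile n x 3 matrices of paired points, n >= 3, non-collinear.
#' @return a `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_atoms`. The fitted
#'   transform maps mobile points as `x %*% t(rotation) + translation`.
#' @export
superpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (nrow(ref) != nrow(mobile))
    stop("point count mismatch: ", nrow(ref), " vs ", nrow(mobile))
  n <- nrow(ref)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  C <- crossprod(X, Y)  # 3x3 covariance
  sv <- svd(C)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate point set: collinear or coincident points")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- cr - as.vector(R %*% cm)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp a `superposition`.
#' @param xyz n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}

# pair atoms between two structures by (chain, resno, insert, elety)
pair_atoms <- function(ref, mobile, ref_idx, mob_idx) {
  key <- function(s, idx) paste(s$atoms$chain[idx], s$atoms$resno[idx],
                                s$atoms$insert[idx], s$atoms$elety[idx],
                                sep = "|")
  kr <- key(ref, ref_idx); km <- key(mobile, mob_idx)
  common <- intersect(kr, km)
  list(ref = ref_idx[match(common, kr)],
       mobile = mob_idx[match(common, km)],
       dropped = length(kr) + length(km) - 2L * length(common))
}

#' RMSD of one selection after superposing on another
#'
#' Fits `mobile` onto `ref` using the atoms of `fit_sel`, then reports the
#' RMSD over `report_sel`. Atoms are paired by (chain, resno, insert, atom
#' name); unpaired atoms are dropped, with an error if fewer than 3 fit
#' pairs remain. With `fit_sel == report_sel` this is the ordinary best-fit
#' RMSD.
#'
#' @param ref,mobile `gpcr_structure` objects.
#' @param fit_sel,report_sel atom index vectors into `ref` and `mobile`
#'   respectively, given as lists `list(ref=, mobile=)`; or NULL to use all
#'   C-alpha atoms.
#' @return RMSD in Angstrom.
#' @export
rmsd_after_superposition <- function(ref, mobile, fit_sel = NULL,
                                     report_sel = NULL) {
  if (is.null(fit_sel))
    fit_sel <- list(ref = atom_select(ref, elety = "CA"),
                    mobile = atom_select(mobile, elety = "CA"))
  if (is.null(report_sel)) report_sel <- fit_sel
  fp <- pair_atoms(ref, mobile, fit_sel$ref, fit_sel$mobile)
  if (length(fp$ref) < 3L)
    stop("fewer than 3 paired fit atoms remain after matching")
  sp <- superpose(structure_coords(ref)[fp$ref, , drop = FALSE],
                  structure_coords(mobile)[fp$mobile, , drop = FALSE])
  rp <- pair_atoms(ref, mobile, report_sel$ref, report_sel$mobile)
  if (!length(rp$ref)) stop("no paired report atoms")
  moved <- apply_superposition(sp, structure_coords(mobile)[rp$mobile, , drop = FALSE])
  sqrt(mean(rowSums((moved - structure_coords(ref)[rp$ref, , drop = FALSE])^2)))
}

#' Minimum inter-residue distance
#'
#' Minimum Euclidean distance over all atom pairs of two residues; the
#' convention used for reported inter-motif distances is the minimum over
#' heavy atoms.
#'
#' @param s a `gpcr_structure`.
#' @param res_a,res_b residue ids ("chain:resno").
#' @param atoms "heavy" (default) or "all".
#' @return list with `distance` (Angstrom) and `atom_pair` (names).
#' @export
min_residue_distance <- function(s, res_a, res_b, atoms = c("heavy", "all")) {
  atoms <- match.arg(atoms)
  ia <- residue_atom_idx(s, res_a); ib <- residue_atom_idx(s, res_b)
  if (atoms == "heavy") {
    ia <- ia[!s$atoms$is_h[ia]]; ib <- ib[!s$atoms$is_h[ib]]
  }
  if (!length(ia)) stop("residue has no qualifying atoms: ", res_a)
  if (!length(ib)) stop("residue has no qualifying atoms: ", res_b)
  xyz <- structure_coords(s)
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  d2[d2 < 0] <- 0
  k <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[k]),
       atom_pair = c(s$atoms$elety[ia[k[1]]], s$atoms$elety[ib[k[2]]]))
}

#' Principal axis of a helix from its C-alpha coordinates
#'
#' The trace is first smoothed with a 4-residue moving average
#' (approximately one alpha-helical turn), which cancels the helical
#' winding so the principal component of the smoothed points follows the
#' axis rather than being biased by the phase ramp of the spiral.
#'
#' @param ca n x 3 matrix of C-alpha positions in residue order, n >= 5.
#' @return a `helix_axis`: list with `origin` (centroid), `direction`
#'   (unit vector oriented from first to last residue), `length`.
#' @export
helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 5L) stop("helix axis needs at least 5 C-alpha positions")
  n <- nrow(ca)
  w <- min(4L, n - 1L)
  sm <- t(vapply(seq_len(n - w + 1L), function(i)
    colMeans(ca[i:(i + w - 1L), , drop = FALSE]), numeric(3)))
  ctr <- colMeans(ca)
  X <- sweep(sm, 2, colMeans(sm))
  sv <- svd(X)
  dir <- sv$v[, 1]
  if (sum(dir * (ca[nrow(ca), ] - ca[1, ])) < 0) dir <- -dir
  proj <- X %*% dir
  structure(list(origin = ctr, direction = dir,
                 length = diff(range(proj))),
            class = "helix_axis")
}

#' Signed displacement of a point along an axis
#'
#' @param point_ref,point_new 3-vectors.
#' @param axis unit 3-vector.
#' @return signed displacement in Angstrom, `dot(point_new - point_ref, axis)`.
#' @export
displacement_along_axis <- function(point_ref, point_new, axis) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6) stop("axis must be a unit vector")
  sum((point_new - point_ref) * axis)
}

#' Principal axis of an arbitrary point cloud (no helical smoothing)
#'
#' Unlike [helix_axis()], no moving-average smoothing is applied: this is
#' the raw first principal component, appropriate for multi-helix bundles
#' where averaging across chain boundaries would mix helices.
#'
#' @param pts n x 3 matrix, n >= 3, non-collinear spread along one axis.
#' @return a `helix_axis` (direction sign arbitrary; callers orient it).
#' @export
principal_axis <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  dir <- sv$v[, 1]
  proj <- X %*% dir
  structure(list(origin = ctr, direction = dir, length = diff(range(proj))),
            class = "helix_axis")
}

#' Angle between two direction vectors, folded into [0, 90] degrees
#' @param a,b 3-vectors (need not be unit length).
#' @export
axis_angle <- function(a, b) {
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(min(1, ca)) * 180 / pi
}
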