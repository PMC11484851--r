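# ---- Structure class --------------------------------------------------------

#' Construct a Structure from an atom table
#'
#' A `gpcr_structure` is the coordinate data model consumed by every other
#' layer of the package: a flat atom table grouped by residue, with author
#' residue numbering preserved verbatim (all residue references in reports,
#' e.g. L386, use author numbers).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter residue name), `elety` (atom name), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom), `o` (occupancy), `is_h` (logical hydrogen flag).
#' @param model_id integer model identifier.
#' @param metadata free-form named list.
#' @return An object of class `gpcr_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L, metadata = list()) {
  required <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "is_h")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: structure must contain atoms")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elesy)))
    stop("empty element symbol in atom table")
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 metadata = metadata),
            class = "gpcr_structure")
}

#' @export
print.gpcr_structure <- function(x, ...) {
  cat(sprintf("<gpcr_structure> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), length(unique(residue_ids(x))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Residue identifiers ("chain:resno" or "chain:resno:insert")
#'
#' @param s a `gpcr_structure`.
#' @return character vector, one id per atom.
#' @export
residue_ids <- function(s) {
  a <- s$atoms
  ifelse(nzchar(a$insert),
         paste(a$chain, a$resno, a$insert, sep = ":"),
         paste(a$chain, a$resno, sep = ":"))
}

#' Atom coordinates as an n x 3 matrix
#' @param s a `gpcr_structure`.
#' @export
structure_coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param s a `gpcr_structure`.
#' @param xyz n x 3 matrix.
#' @export
set_structure_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Select atom indices by chain, residue number, atom name
#'
#' @param s a `gpcr_structure`.
#' @param chain,resno,elety optional filters (vectors allowed).
#' @param heavy if TRUE, keep heavy atoms only.
#' @param water one of "exclude" (default), "only", "include".
#' @return integer atom indices.
#' @export
atom_select <- function(s, chain = NULL, resno = NULL, elety = NULL,
                        heavy = FALSE, water = c("exclude", "only", "include")) {
  water <- match.arg(water)
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy) keep <- keep & !a$is_h
  wat <- is_water(a$resid)
  if (water == "exclude") keep <- keep & !wat
  if (water == "only") keep <- keep & wat
  which(keep)
}

#' Water residue test
#' @param resid character vector of 3-letter residue names.
#' @export
is_water <- function(resid) resid %in% c("HOH", "WAT")

#' Atom rows of a single residue
#'
#' @param s a `gpcr_structure`.
#' @param residue residue id string "chain:resno" (optionally ":insert").
#' @return integer atom indices.
#' @export
residue_atom_idx <- function(s, residue) {
  idx <- which(residue_ids(s) == residue)
  if (!length(idx)) stop("residue not found: ", residue)
  idx
}

# ---- reading ----------------------------------------------------------------

bio3d_to_structure <- function(atom, model_id = 1L, metadata = list()) {
  elesy <- atom$elesy
  bad <- which(is.na(elesy) | !nzchar(elesy))
  if (length(bad)) elesy[bad] <- guess_element(atom$elety[bad])
  df <- data.frame(
    chain = ifelse(is.na(atom$chain), "", atom$chain),
    resno = as.integer(atom$resno),
    insert = ifelse(is.na(atom$insert), "", atom$insert),
    resid = atom$resid,
    elety = atom$elety,
    elesy = elesy,
    x = atom$x, y = atom$y, z = atom$z,
    o = ifelse(is.na(atom$o), 1, atom$o),
    stringsAsFactors = FALSE
  )
  df$is_h <- df$elesy == "H"
  df <- resolve_altlocs(df, alt = atom$alt)
  new_structure(df, model_id = model_id, metadata = metadata)
}

guess_element <- function(elety) {
  # fallback when the element column is absent: strip digits, take the
  # leading letter; two-letter elements rarely occur in protein models
  stripped <- sub("^[0-9]*", "", elety)
  toupper(substr(stripped, 1, 1))
}

resolve_altlocs <- function(df, alt) {
  if (is.null(alt)) return(df)
  alt[is.na(alt)] <- ""
  if (!any(nzchar(alt))) return(df)
  # keep the highest-occupancy conformer per (chain, resno, insert, elety);
  # ties broken by altloc identifier order for determinism
  orig <- seq_len(nrow(df))
  key <- paste(df$chain, df$resno, df$insert, df$elety, sep = "\r")
  ord <- order(key, -df$o, alt)
  df <- df[ord, ]; key <- key[ord]; orig <- orig[ord]
  keep <- !duplicated(key)
  df <- df[keep, ]; orig <- orig[keep]
  df[order(orig), , drop = FALSE]
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Author residue numbering is preserved; when alternate locations are
#' present only the highest-occupancy conformer is retained (ties broken by
#' altloc identifier). Hydrogens, when present, are kept and flagged.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return a `gpcr_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                       rm.alt = FALSE))
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                          rm.alt = FALSE)),
    error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE)
  )
  if (is.null(obj$atom) || nrow(obj$atom) == 0L)
    stop("empty model in ", path)
  bio3d_to_structure(obj$atom, metadata = list(source = path, format = format))
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL record becomes one frame; a file without MODEL records is a
#' single-frame trajectory. Every frame must carry exactly the topology's
#' atom count.
#'
#' @param path multi-model PDB path.
#' @param topology optional `gpcr_structure` giving the fixed topology; when
#'   NULL the first model is used.
#' @return a `gpcr_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  n_atoms_per_frame <- if (length(model_starts)) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    vapply(seq_along(model_starts), function(i) {
      blk <- lines[model_starts[i]:model_ends[i]]
      sum(grepl("^(ATOM  |HETATM)", blk))
    }, integer(1))
  } else {
    sum(grepl("^(ATOM  |HETATM)", lines))
  }
  if (length(unique(n_atoms_per_frame)) > 1L) {
    bad <- which(n_atoms_per_frame != n_atoms_per_frame[1])[1]
    stop(sprintf("atom count mismatch in frame %d: %d atoms vs %d in frame 1",
                 bad, n_atoms_per_frame[bad], n_atoms_per_frame[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  top <- bio3d_to_structure(pdb$atom, metadata = list(source = path))
  if (!is.null(topology)) {
    if (nrow(topology$atoms) != nrow(top$atoms))
      stop(sprintf("trajectory atom count (%d) does not match topology (%d)",
                   nrow(top$atoms), nrow(topology$atoms)))
    top <- topology
  }
  frames <- lapply(seq_len(nrow(xyz)), function(t)
    matrix(xyz[t, ], ncol = 3, byrow = TRUE))
  new_trajectory(top, frames)
}

# ---- Trajectory class -------------------------------------------------------

#' Construct a trajectory over a fixed topology
#'
#' @param topology a `gpcr_structure`.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @return a `gpcr_trajectory`.
#' @export
new_trajectory <- function(topology, frames) {
  if (!inherits(topology, "gpcr_structure")) stop("topology must be a gpcr_structure")
  if (!length(frames)) stop("trajectory must contain at least one frame")
  n <- nrow(topology$atoms)
  for (t in seq_along(frames)) {
    if (!is.matrix(frames[[t]]) || nrow(frames[[t]]) != n ||
        ncol(frames[[t]]) != 3)
      stop(sprintf("frame %d has wrong atom count (expected %d)", t, n))
  }
  structure(list(topology = topology, frames = frames),
            class = "gpcr_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `gpcr_trajectory`.
#' @export
frame_count <- function(traj) length(traj$frames)

#' @export
print.gpcr_trajectory <- function(x, ...) {
  cat(sprintf("<gpcr_trajectory> %d frames x %d atoms\n",
              frame_count(x), nrow(x$topology$atoms)))
  invisible(x)
}

# ---- writing ----------------------------------------------------------------

#' Write a structure as PDB
#' @param s a `gpcr_structure`.
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure_coords(s))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(nzchar(a$insert), a$insert, ""),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  invisible(path)
}

#' Write a trajectory as multi-model PDB
#' @param traj a `gpcr_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  out <- character(0)
  for (t in seq_len(frame_count(traj))) {
    s <- set_structure_coords(traj$topology, traj$frames[[t]])
    write_structure(s, tmp)
    body <- readLines(tmp)
    body <- body[!grepl("^END", body)]
    out <- c(out, sprintf("MODEL     %4d", t), body, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- DensityGrid + OpenDX ---------------------------------------------------

#' Construct a water-density grid
#'
#' @param origin 3-vector, coordinates of grid point (1,1,1), Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param values 3-d array of densities (waters per cubic Angstrom),
#'   indexed `[ix, iy, iz]`.
#' @param params named list of estimator metadata (r, T, N, bulk_density).
#' @return a `density_grid`.
#' @export
new_density_grid <- function(origin, spacing, values, params = list()) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-d array")
  if (any(values < 0)) stop("densities must be non-negative")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dim(values), values = values, params = params),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d, spacing %.3g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Write a density grid as an OpenDX scalar field
#'
#' Values are emitted in DX order (last index fastest), three per line.
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @export
write_density_grid <- function(grid, path) {
  if (!inherits(grid, "density_grid")) stop("grid must be a density_grid")
  d <- grid$dims
  if (prod(d) == 0L) stop("zero-size grid")
  # DX layout: x slowest, z fastest
  v <- numeric(prod(d))
  k <- 1L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    v[k:(k + d[3] - 1L)] <- grid$values[ix, iy, ]
    k <- k + d[3]
  }
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  vp <- c(v, rep(NA_real_, pad))
  m <- matrix(vp, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(formatC(r[!is.na(r)], format = "g", digits = 10), collapse = " "))
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.10g %.10g %.10g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.10g 0 0", grid$spacing),
    sprintf("delta 0 %.10g 0", grid$spacing),
    sprintf("delta 0 0 %.10g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  )
  writeLines(c(hdr, rows,
               'attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), path)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_density_grid()]
#' @param path OpenDX file path.
#' @return a `density_grid`.
#' @export
read_density_grid <- function(path) {
  lines <- readLines(path)
  gp <- grep("gridpositions", lines, value = TRUE)[1]
  d <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), " +")[[1]]), numeric(3)))
  spacing <- dmat[1, 1]
  data_start <- grep("data follows", lines)[1] + 1L
  vals <- numeric(0)
  i <- data_start
  while (i <= length(lines) && !grepl("^(attribute|object)", lines[i])) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), " +")[[1]]))
    i <- i + 1L
  }
  arr <- array(0, dim = d)
  k <- 1L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    arr[ix, iy, ] <- vals[k:(k + d[3] - 1L)]
    k <- k + d[3]
  }
  new_density_grid(org, spacing, arr)
}
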