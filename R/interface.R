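# Receptor / G-alpha interface analysis: enumerate residue-residue contacts
# across two chains, classify them as hydrogen bonds (donor-acceptor N/O
# pair within cutoff) or van der Waals contacts (any heavy-atom pair within
# cutoff that is not already a hydrogen bond), annotate with BW/CGN labels,
# and quantify the insertion angle of the alpha5 helix.

label_for <- function(map, residue) {
  if (is.null(map)) return(NA_character_)
  out <- tryCatch(lookup(map, residue), error = function(e) NA_character_)
  out
}

#' Enumerate receptor-G-alpha interface contacts
#'
#' One record per residue pair: a pair whose minimum donor-acceptor
#' heavy-atom distance is within `hbond_cutoff` is a hydrogen bond; any
#' other pair with a heavy-atom distance within `vdw_cutoff` is a van der
#' Waals contact. Ionic pairs (Asp/Glu vs Arg/Lys/His) whose charged-group
#' N/O distance is within `salt_bridge_cutoff` are additionally flagged in
#' the notes column. No pair is double-counted as both types.
#'
#' @param s a `gpcr_structure` holding the complex.
#' @param receptor_chain,galpha_chain chain ids.
#' @param receptor_map,galpha_map optional numbering maps (BW/loop and CGN);
#'   contacts without labels are still reported, unlabeled.
#' @param hbond_cutoff,vdw_cutoff,salt_bridge_cutoff Angstrom.
#' @return an `interface_report`: list with `contacts` (data.frame),
#'   `hbond_count`, `vdw_count`.
#' @export
detect_contacts <- function(s, receptor_chain, galpha_chain,
                            receptor_map = NULL, galpha_map = NULL,
                            hbond_cutoff = 3.5, vdw_cutoff = 4.5,
                            salt_bridge_cutoff = 4.0) {
  if (identical(receptor_chain, galpha_chain))
    stop("receptor and G-alpha chains must differ")
  ri <- atom_select(s, chain = receptor_chain, heavy = TRUE)
  gi <- atom_select(s, chain = galpha_chain, heavy = TRUE)
  if (!length(ri)) stop("empty receptor chain selection: ", receptor_chain)
  if (!length(gi)) stop("empty G-alpha chain selection: ", galpha_chain)
  xyz <- structure_coords(s)
  rid <- residue_ids(s)
  # residue-pair candidates: any heavy-atom pair within vdw_cutoff
  d2 <- outer(rowSums(xyz[ri, , drop = FALSE]^2),
              rowSums(xyz[gi, , drop = FALSE]^2), "+") -
    2 * xyz[ri, , drop = FALSE] %*% t(xyz[gi, , drop = FALSE])
  d2[d2 < 0] <- 0
  hit <- which(d2 <= vdw_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) {
    out <- list(contacts = empty_contacts(), hbond_count = 0L, vdw_count = 0L)
    class(out) <- "interface_report"
    return(out)
  }
  pair_key <- paste(rid[ri[hit[, 1]]], rid[gi[hit[, 2]]], sep = "~")
  rows <- lapply(unique(pair_key), function(pk) {
    parts <- strsplit(pk, "~", fixed = TRUE)[[1]]
    res_r <- parts[1]; res_g <- parts[2]
    idx_r <- residue_atom_idx(s, res_r); idx_r <- idx_r[!s$atoms$is_h[idx_r]]
    idx_g <- residue_atom_idx(s, res_g); idx_g <- idx_g[!s$atoms$is_h[idx_g]]
    hb <- min_donor_acceptor_distance(s, idx_r, idx_g, backbone = TRUE)
    heavy <- min_atomset_distance(s, idx_r, idx_g,
                                  unique(s$atoms$elety[idx_r]),
                                  unique(s$atoms$elety[idx_g]))
    sb <- min_salt_bridge_distance(s, idx_r, idx_g)
    is_hb <- is.finite(hb$distance) && hb$distance <= hbond_cutoff
    notes <- if (is.finite(sb$distance) && sb$distance <= salt_bridge_cutoff)
      "salt_bridge" else ""
    data.frame(
      receptor_res = res_r,
      receptor_resid = s$atoms$resid[idx_r[1]],
      receptor_label = label_for(receptor_map, res_r),
      ga_res = res_g,
      ga_resid = s$atoms$resid[idx_g[1]],
      ga_label = label_for(galpha_map, res_g),
      type = if (is_hb) "hbond" else "vdw",
      min_dist = if (is_hb) hb$distance else heavy$distance,
      atom_pair = if (is_hb) paste(hb$atom_pair, collapse = "-")
      else paste(heavy$atom_pair, collapse = "-"),
      notes = notes,
      stringsAsFactors = FALSE
    )
  })
  contacts <- do.call(rbind, rows)
  contacts <- contacts[order(contacts$type, contacts$receptor_res,
                             contacts$ga_res), , drop = FALSE]
  rownames(contacts) <- NULL
  out <- list(contacts = contacts,
              hbond_count = sum(contacts$type == "hbond"),
              vdw_count = sum(contacts$type == "vdw"))
  class(out) <- "interface_report"
  out
}

empty_contacts <- function() {
  data.frame(receptor_res = character(0), receptor_resid = character(0),
             receptor_label = character(0), ga_res = character(0),
             ga_resid = character(0), ga_label = character(0),
             type = character(0), min_dist = numeric(0),
             atom_pair = character(0), notes = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> %d hydrogen bond(s), %d van der Waals contact(s)\n",
              x$hbond_count, x$vdw_count))
  if (nrow(x$contacts)) print(x$contacts[, c("receptor_res", "receptor_label",
                                             "ga_res", "ga_label", "type",
                                             "min_dist")])
  invisible(x)
}

#' Receptor residues forming the alpha5 anchor pocket
#'
#' Returns the BW labels of all receptor residues whose minimum heavy-atom
#' distance to any of the named G-alpha residues (default the two leucines
#' of the alpha5 C-terminus, H5.20 and H5.25) is within `cutoff`.
#'
#' @param s a `gpcr_structure` holding the complex.
#' @param receptor_chain receptor chain id.
#' @param receptor_map,galpha_map numbering maps.
#' @param galpha_labels CGN labels of the probe residues.
#' @param cutoff Angstrom.
#' @return character vector of receptor labels (BW where mapped, otherwise
#'   residue ids), sorted and unique.
#' @export
pocket_composition <- function(s, receptor_chain, receptor_map, galpha_map,
                               galpha_labels = c("H5.20", "H5.25"),
                               cutoff = 4.5) {
  ga_res <- vapply(galpha_labels, function(l) {
    tryCatch(lookup(galpha_map, l),
             error = function(e) stop("label not in CGN map: ", l, call. = FALSE))
  }, "")
  ri <- atom_select(s, chain = receptor_chain, heavy = TRUE)
  xyz <- structure_coords(s)
  rid <- residue_ids(s)
  found <- character(0)
  for (gr in ga_res) {
    gidx <- residue_atom_idx(s, gr); gidx <- gidx[!s$atoms$is_h[gidx]]
    d2 <- outer(rowSums(xyz[ri, , drop = FALSE]^2),
                rowSums(xyz[gidx, , drop = FALSE]^2), "+") -
      2 * xyz[ri, , drop = FALSE] %*% t(xyz[gidx, , drop = FALSE])
    hits <- unique(rid[ri[which(d2 <= cutoff^2, arr.ind = TRUE)[, 1]]])
    found <- union(found, hits)
  }
  labs <- vapply(found, function(r) {
    l <- label_for(receptor_map, r)
    if (is.na(l)) r else l
  }, "")
  sort(unname(labs))
}

#' Insertion angle of the alpha5 helix relative to the receptor bundle
#'
#' Angle, in [0, 90] degrees, between the principal axis of the alpha5
#' C-alpha trace and the receptor bundle axis; 0 degrees is a fully
#' vertical (axis-parallel) insertion.
#'
#' @param s a `gpcr_structure` holding the complex.
#' @param a5_ca n x 3 matrix of alpha5 C-alpha coordinates (n >= 5), or an
#'   atom index vector into `s`.
#' @param bundle either a `helix_axis`, a unit 3-vector, or an n x 3 matrix
#'   of receptor C-alpha coordinates (n >= 5).
#' @return angle in degrees.
#' @export
alpha5_tilt <- function(s, a5_ca, bundle) {
  if (is.numeric(a5_ca) && is.null(dim(a5_ca)))
    a5_ca <- structure_coords(s)[a5_ca, , drop = FALSE]
  ax5 <- helix_axis(a5_ca)
  bdir <- if (inherits(bundle, "helix_axis")) bundle$direction
  else if (is.matrix(bundle)) helix_axis(bundle)$direction
  else bundle
  axis_angle(ax5$direction, bdir)
}

#' Write an interface report as CSV
#' @param report an `interface_report`.
#' @param path output path.
#' @export
write_contacts_csv <- function(report, path) {
  utils::write.csv(report$contacts, path, row.names = FALSE)
  invisible(path)
}
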