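# Activation-hallmark metrics of a class-A GPCR structure, measured on a
# generically numbered receptor: the DRY 3.49-3.50 salt bridge (broken on
# activation), the 3.50-5.58 hydrogen bond that stabilises the rotated
# R3.50, the 3.46-7.53 gap (<= 4.5 A in receptors with the canonical
# Y7.53; widened when TM7 shifts toward the intracellular side), and --
# against an inactive reference -- the TM6 outward movement and the axial
# (intracellular-positive) displacement of the TM7 NPxxY/NPxxL motif.

resolve_label <- function(map, label) {
  tryCatch(lookup(map, label),
           error = function(e) stop("cannot resolve generic label '", label,
                                    "': ", conditionMessage(e), call. = FALSE))
}

#' Gap between two generically numbered residues, with contact flag
#'
#' Minimum heavy-atom distance between the residues at `label_a` and
#' `label_b`; `contact` is TRUE when the distance is within `contact_cutoff`
#' (default 4.5 Angstrom, the conventional threshold for hydrophobic or van
#' der Waals interaction).
#'
#' @param s a `gpcr_structure`.
#' @param map a `numbering_map` covering both labels.
#' @param label_a,label_b generic labels (defaults "3.46", "7.53").
#' @param contact_cutoff Angstrom.
#' @return list with `distance`, `contact`, `residues`, `atom_pair`.
#' @export
motif_gap <- function(s, map, label_a = "3.46", label_b = "7.53",
                      contact_cutoff = 4.5) {
  ra <- resolve_label(map, label_a); rb <- resolve_label(map, label_b)
  md <- min_residue_distance(s, ra, rb, atoms = "heavy")
  list(distance = md$distance, contact = md$distance <= contact_cutoff,
       residues = c(ra, rb), atom_pair = md$atom_pair)
}

#' Polar-contact state of a residue pair (hydrogen bond or salt bridge)
#'
#' Heavy-atom distance criterion only (deposited models lack hydrogens):
#' hydrogen bond when the minimum donor-acceptor N/O distance is within
#' `cutoff` (default 3.5 Angstrom); salt bridge when the minimum
#' charged-group N/O distance is within `cutoff` (default 4.0 Angstrom).
#'
#' @param s a `gpcr_structure`.
#' @param map a `numbering_map`.
#' @param pair character vector of two generic labels.
#' @param criterion "hbond" or "salt_bridge".
#' @param cutoff Angstrom; defaults 3.5 (hbond) / 4.0 (salt bridge).
#' @param backbone include backbone N/O in the hydrogen-bond atom sets.
#' @return list with `distance`, `present`, `residues`, `atom_pair`.
#' @export
salt_bridge_or_hbond <- function(s, map, pair,
                                 criterion = c("hbond", "salt_bridge"),
                                 cutoff = NULL, backbone = FALSE) {
  criterion <- match.arg(criterion)
  if (is.null(cutoff)) cutoff <- if (criterion == "hbond") 3.5 else 4.0
  ra <- resolve_label(map, pair[1]); rb <- resolve_label(map, pair[2])
  ia <- residue_atom_idx(s, ra); ib <- residue_atom_idx(s, rb)
  md <- if (criterion == "hbond")
    min_donor_acceptor_distance(s, ia, ib, backbone = backbone)
  else min_salt_bridge_distance(s, ia, ib)
  if (!is.finite(md$distance))
    stop("residue pair ", ra, " / ", rb, " lacks qualifying polar atoms for ",
         criterion)
  list(distance = md$distance, present = md$distance <= cutoff,
       residues = c(ra, rb), atom_pair = md$atom_pair)
}

#' Receptor bundle axis, oriented extracellular to intracellular
#'
#' Principal axis of all BW-mapped C-alpha atoms. Orientation is fixed so
#' that the intracellular side is positive, using the mean position of
#' loop-tagged residues whose label starts with "ICL" (or an explicit
#' `ic_point`).
#'
#' @param s a `gpcr_structure`.
#' @param map a `numbering_map` with BW entries (and ideally ICL loop tags).
#' @param ic_point optional 3-vector on the intracellular side, used when no
#'   ICL-tagged residues are present.
#' @return a `helix_axis` whose direction points intracellularly.
#' @export
bundle_axis <- function(s, map, ic_point = NULL) {
  e <- map$entries
  bw <- e[e$scheme == "BW" & grepl("^[1-7]\\.", e$label), , drop = FALSE]
  idx <- atom_select(s, resno = bw$resno, chain = unique(bw$chain), elety = "CA")
  if (length(idx) < 5L) stop("too few BW-mapped C-alpha atoms for a bundle axis")
  ca <- structure_coords(s)[idx, , drop = FALSE]
  ax <- principal_axis(ca)
  if (is.null(ic_point)) {
    icl <- e[e$scheme == "loop" & grepl("^ICL", e$label), , drop = FALSE]
    if (nrow(icl)) {
      li <- atom_select(s, resno = icl$resno, chain = unique(icl$chain),
                        elety = "CA")
      if (length(li)) ic_point <- colMeans(structure_coords(s)[li, , drop = FALSE])
    }
  }
  if (is.null(ic_point))
    stop("cannot orient bundle axis: no ICL-tagged residues and no ic_point")
  if (sum(ax$direction * (ic_point - ax$origin)) < 0)
    ax$direction <- -ax$direction
  ax
}

core_pair_ca <- function(active, inactive, map_active, map_inactive,
                         core_labels) {
  ra <- vapply(core_labels, function(l) resolve_label(map_active, l), "")
  ri <- vapply(core_labels, function(l) resolve_label(map_inactive, l), "")
  ca_a <- t(vapply(ra, function(r) {
    i <- residue_atom_idx(active, r)
    i <- i[active$atoms$elety[i] == "CA"]
    structure_coords(active)[i[1], ]
  }, numeric(3)))
  ca_i <- t(vapply(ri, function(r) {
    i <- residue_atom_idx(inactive, r)
    i <- i[inactive$atoms$elety[i] == "CA"]
    structure_coords(inactive)[i[1], ]
  }, numeric(3)))
  list(active = ca_a, inactive = ca_i)
}

default_core_labels <- function(map_active, map_inactive) {
  # all TM1-TM4 BW labels present in both maps
  both <- intersect(map_active$entries$label[map_active$entries$scheme == "BW"],
                    map_inactive$entries$label[map_inactive$entries$scheme == "BW"])
  both[substr(both, 1, 2) %in% c("1.", "2.", "3.", "4.")]
}

probe_ca <- function(s, map, label) {
  r <- resolve_label(map, label)
  i <- residue_atom_idx(s, r)
  i <- i[s$atoms$elety[i] == "CA"]
  if (!length(i)) stop("probe residue ", r, " has no C-alpha atom")
  structure_coords(s)[i[1], ]
}

#' TM6 outward movement relative to an inactive reference
#'
#' After superposing the inactive structure onto the active one over a
#' core C-alpha set (default: all shared TM1-TM4 positions), reports the
#' in-membrane-plane displacement of the probe C-alpha (component
#' orthogonal to the bundle axis; default probe 6.30, the intracellular end
#' of TM6).
#'
#' @param active,inactive `gpcr_structure` objects.
#' @param map_active,map_inactive numbering maps for each.
#' @param probe_label BW label of the probe residue.
#' @param core_labels BW labels of the fit set; default TM1-TM4.
#' @return displacement in Angstrom (non-negative).
#' @export
tm6_outward <- function(active, inactive, map_active,
                        map_inactive = map_active, probe_label = "6.30",
                        core_labels = NULL) {
  if (is.null(core_labels))
    core_labels <- default_core_labels(map_active, map_inactive)
  cp <- core_pair_ca(active, inactive, map_active, map_inactive, core_labels)
  sp <- superpose(cp$active, cp$inactive)
  p_act <- probe_ca(active, map_active, probe_label)
  p_ina <- as.vector(apply_superposition(
    sp, matrix(probe_ca(inactive, map_inactive, probe_label), nrow = 1)))
  ax <- bundle_axis(active, map_active)
  v <- p_act - p_ina
  v_in_plane <- v - sum(v * ax$direction) * ax$direction
  sqrt(sum(v_in_plane^2))
}

#' Axial displacement of the TM7 NPxxY/NPxxL motif
#'
#' Mean signed displacement of the probe C-alpha positions (default
#' 7.49-7.53) along the bundle axis after core superposition;
#' intracellular-positive, so a downward (cytoplasmic) shift of TM7 upon
#' activation is positive.
#'
#' @inheritParams tm6_outward
#' @param probe_labels BW labels of the probe residues.
#' @return mean signed displacement in Angstrom.
#' @export
tm7_downward <- function(active, inactive, map_active,
                         map_inactive = map_active,
                         probe_labels = c("7.49", "7.50", "7.51", "7.52", "7.53"),
                         core_labels = NULL) {
  ok <- vapply(probe_labels, function(l) {
    !inherits(tryCatch(resolve_label(map_active, l), error = identity),
              "error") &&
      !inherits(tryCatch(resolve_label(map_inactive, l), error = identity),
                "error")
  }, logical(1))
  probe_labels <- probe_labels[ok]
  if (length(probe_labels) < 2L)
    stop("fewer than 2 probe residues resolvable for the TM7 displacement")
  if (is.null(core_labels))
    core_labels <- default_core_labels(map_active, map_inactive)
  cp <- core_pair_ca(active, inactive, map_active, map_inactive, core_labels)
  sp <- superpose(cp$active, cp$inactive)
  ax <- bundle_axis(active, map_active)
  disp <- vapply(probe_labels, function(l) {
    pa <- probe_ca(active, map_active, l)
    pi_ <- as.vector(apply_superposition(
      sp, matrix(probe_ca(inactive, map_inactive, l), nrow = 1)))
    displacement_along_axis(pi_, pa, ax$direction)
  }, numeric(1))
  mean(disp)
}

#' Full activation-hallmark report
#'
#' Aggregates the per-metric operations; reference-requiring metrics (TM6
#' outward, TM7 axial) are NA when no inactive structure is supplied. The
#' sign convention (intracellular-positive axis) is recorded in the notes.
#'
#' @param active a `gpcr_structure`.
#' @param map_active its `numbering_map`.
#' @param inactive optional inactive-reference `gpcr_structure`.
#' @param map_inactive its map (defaults to `map_active`).
#' @param salt_bridge_cutoff,hbond_cutoff,contact_cutoff Angstrom.
#' @return a `hallmark_report` list.
#' @export
hallmark_report <- function(active, map_active, inactive = NULL,
                            map_inactive = map_active,
                            salt_bridge_cutoff = 4.0, hbond_cutoff = 3.5,
                            contact_cutoff = 4.5) {
  dry <- salt_bridge_or_hbond(active, map_active, c("3.49", "3.50"),
                              criterion = "salt_bridge",
                              cutoff = salt_bridge_cutoff)
  ry <- salt_bridge_or_hbond(active, map_active, c("3.50", "5.58"),
                             criterion = "hbond", cutoff = hbond_cutoff)
  gap <- motif_gap(active, map_active, "3.46", "7.53",
                   contact_cutoff = contact_cutoff)
  have_ref <- !is.null(inactive)
  rep <- list(
    dry_salt_bridge_distance = dry$distance,
    dry_salt_bridge_present = dry$present,
    r350_y558_hbond_distance = ry$distance,
    r350_y558_hbond_present = ry$present,
    gap_346_753 = gap$distance,
    contact_346_753 = gap$contact,
    tm6_outward = if (have_ref)
      tm6_outward(active, inactive, map_active, map_inactive) else NA_real_,
    tm7_downward = if (have_ref)
      tm7_downward(active, inactive, map_active, map_inactive) else NA_real_,
    cavity_residues = c("3.46", "3.50", "7.49", "7.53"),
    notes = c(
      distances = "minimum heavy-atom inter-residue distances",
      axis = "bundle axis oriented extracellular->intracellular; downward displacement positive",
      reference = if (have_ref) "inactive reference supplied"
      else "no inactive reference: TM6/TM7 displacement metrics unavailable",
      cutoffs = sprintf("salt bridge %.1f A, hbond %.1f A, contact %.1f A",
                        salt_bridge_cutoff, hbond_cutoff, contact_cutoff)
    ),
    schema_version = "1.0"
  )
  class(rep) <- "hallmark_report"
  rep
}

#' @export
print.hallmark_report <- function(x, ...) {
  cat("<hallmark_report>\n")
  cat(sprintf("  DRY 3.49-3.50 salt bridge: %.2f A (%s)\n",
              x$dry_salt_bridge_distance,
              if (x$dry_salt_bridge_present) "formed" else "broken"))
  cat(sprintf("  3.50-5.58 hydrogen bond:   %.2f A (%s)\n",
              x$r350_y558_hbond_distance,
              if (x$r350_y558_hbond_present) "present" else "absent"))
  cat(sprintf("  3.46-7.53 gap:             %.2f A (%s)\n", x$gap_346_753,
              if (x$contact_346_753) "in contact" else "no direct contact"))
  if (!is.na(x$tm6_outward))
    cat(sprintf("  TM6 outward movement:      %.2f A\n", x$tm6_outward))
  if (!is.na(x$tm7_downward))
    cat(sprintf("  TM7 axial displacement:    %+.2f A (intracellular-positive)\n",
                x$tm7_downward))
  invisible(x)
}

#' Serialize a hallmark report to JSON (round-trippable)
#' @param report a `hallmark_report`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @export
hallmark_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}
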