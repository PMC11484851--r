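# Generic residue numbering: Ballesteros-Weinstein (BW) labels for receptor
# transmembrane helices ("t.nn", anchored at the most conserved x.50 residue
# of each helix) and CGN labels for G-alpha (table-driven, e.g. "H5.25").
# Loop residues (ICL/ECL) carry free-text tags in the same map.

#' Construct a numbering map from explicit rows
#'
#' @param rows data.frame with columns `chain`, `resno`, `label`, and
#'   optionally `insert`, `scheme` (per-entry: "BW", "CGN" or "loop").
#' @param scheme map-level scheme, "BW" or "CGN".
#' @return a `numbering_map`.
#' @export
numbering_map <- function(rows, scheme = c("BW", "CGN")) {
  scheme <- match.arg(scheme)
  if (is.null(rows$insert)) rows$insert <- rep("", nrow(rows))
  if (is.null(rows$scheme)) rows$scheme <- rep(scheme, nrow(rows))
  rows$residue <- ifelse(nzchar(rows$insert),
                         paste(rows$chain, rows$resno, rows$insert, sep = ":"),
                         paste(rows$chain, rows$resno, sep = ":"))
  if (anyDuplicated(rows$residue))
    stop("duplicate residues in numbering map: ",
         paste(rows$residue[duplicated(rows$residue)], collapse = ", "))
  strict <- rows$scheme %in% c("BW", "CGN")
  if (anyDuplicated(rows$label[strict]))
    stop("duplicate labels in numbering map: ",
         paste(unique(rows$label[strict][duplicated(rows$label[strict])]),
               collapse = ", "))
  rownames(rows) <- NULL
  structure(list(entries = rows, scheme = scheme), class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("<numbering_map> %s, %d entries\n", x$scheme, nrow(x$entries)))
  invisible(x)
}

#' Build a Ballesteros-Weinstein map from anchors and segment ranges
#'
#' Each transmembrane segment is anchored at its most conserved residue
#' (label x.50 by convention, but any anchor label is accepted); every other
#' residue in the segment range is labelled by plain sequence offset
#' (`minor = anchor_minor + resno - anchor_resno`). Helix bulges and
#' deletions are not handled: labels are strictly offset-computed.
#'
#' @param structure a `gpcr_structure`; only residues present are mapped.
#' @param anchors data.frame with columns `segment`, `anchor_resno`,
#'   `anchor_label` (e.g. "7.50").
#' @param segments data.frame with columns `segment`, `chain`, `start`, `end`
#'   (author residue numbers, inclusive).
#' @return a `numbering_map` with scheme "BW".
#' @export
build_bw_map <- function(structure, anchors, segments) {
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments$segment[i]
    an <- anchors[anchors$segment == seg, , drop = FALSE]
    if (nrow(an) != 1L) stop("need exactly one anchor for segment ", seg)
    if (an$anchor_resno < segments$start[i] || an$anchor_resno > segments$end[i])
      stop("anchor ", an$anchor_resno, " lies outside segment ", seg)
    parts <- strsplit(an$anchor_label, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
      stop("BW anchor label must parse as integer.integer: ", an$anchor_label)
    major <- as.integer(parts[1]); anchor_minor <- as.integer(parts[2])
    in_seg <- structure$atoms$chain == segments$chain[i] &
      structure$atoms$resno >= segments$start[i] &
      structure$atoms$resno <= segments$end[i]
    resnos <- sort(unique(structure$atoms$resno[in_seg]))
    if (!length(resnos)) next
    minor <- anchor_minor + (resnos - an$anchor_resno)
    if (any(minor <= 0L | minor >= 100L))
      stop("segment ", seg, " range too wide: computed minor index outside (0, 100)")
    rows[[seg]] <- data.frame(chain = segments$chain[i], resno = resnos,
                              insert = "", label = sprintf("%d.%02d", major, minor),
                              scheme = "BW", stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no residues mapped")
  numbering_map(do.call(rbind, rows), scheme = "BW")
}

#' Build a CGN map from an explicit mapping table
#'
#' CGN positions are not offset-computable, so the map is purely
#' table-driven; table rows referencing residues absent from the chain are
#' dropped.
#'
#' @param structure a `gpcr_structure` holding the G-alpha chain.
#' @param table data.frame with columns `chain`, `resno`, `label`
#'   (e.g. "H5.25", "h4s6.12").
#' @return a `numbering_map` with scheme "CGN".
#' @export
build_cgn_map <- function(structure, table) {
  if (any(!nzchar(table$label))) stop("CGN labels must be non-empty")
  present <- paste(table$chain, table$resno) %in%
    paste(structure$atoms$chain, structure$atoms$resno)
  table <- table[present, , drop = FALSE]
  table$scheme <- rep("CGN", nrow(table))
  numbering_map(table, scheme = "CGN")
}

#' Append rows (e.g. loop tags, helix-8 labels) to a numbering map
#'
#' Loop tags (per-entry scheme "loop") may share a label across residues;
#' shared labels are excluded from reverse lookup.
#'
#' @param map a `numbering_map`.
#' @param rows data.frame with columns `chain`, `resno`, `label` and
#'   optionally `scheme` (defaults to "loop").
#' @export
map_add_rows <- function(map, rows) {
  if (is.null(rows$scheme)) rows$scheme <- rep("loop", nrow(rows))
  if (is.null(rows$insert)) rows$insert <- rep("", nrow(rows))
  combined <- rbind(map$entries[, c("chain", "resno", "insert", "label", "scheme")],
                    rows[, c("chain", "resno", "insert", "label", "scheme")])
  numbering_map(combined, scheme = map$scheme)
}

#' Look up a generic label or a residue id
#'
#' A query containing ":" is treated as a residue id ("chain:resno") and
#' returns its label; any other query is treated as a label and returns the
#' residue id. Inverse-consistent: `lookup(map, lookup(map, x)) == x` for
#' every uniquely-labelled entry.
#'
#' @param map a `numbering_map`.
#' @param query label string (e.g. "7.53") or residue id (e.g. "R:386").
#' @return residue id or label string.
#' @export
lookup <- function(map, query) {
  e <- map$entries
  if (grepl(":", query, fixed = TRUE)) {
    hit <- which(e$residue == query)
    if (!length(hit)) stop("residue not found in numbering map: ", query)
    return(e$label[hit[1]])
  }
  hit <- which(e$label == query)
  if (!length(hit)) stop("label not found in numbering map: ", query)
  if (length(hit) > 1L)
    stop("label '", query, "' is a shared loop tag; reverse lookup is ambiguous")
  e$residue[hit]
}

#' Read a numbering table (anchors or CGN rows) from TSV
#'
#' Expected columns: `chain`, `resno`, `label` (and optionally `scheme`).
#'
#' @param path TSV path.
#' @export
read_numbering_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Packaged CGN table for the G-alpha-i1 alpha5 helix and wavy hook
#'
#' Covers T340 (H5.12) through F354 (H5.26) plus E318 (h4s6.12). H5.24 is
#' G352 and H5.25 is L353, consistent with the 352-GLF-354 wavy hook.
#'
#' @param chain chain id to assign (default "A").
#' @return data.frame with columns `chain`, `resno`, `label`, `resid`.
#' @export
cgn_gai1_table <- function(chain = "A") {
  path <- system.file("extdata", "cgn_gai1.tsv", package = "gpcrprofiler")
  tab <- read_numbering_tsv(path)
  tab$chain <- chain
  tab
}
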