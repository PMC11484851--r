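# Residue template tables: hydrogen-bond donor/acceptor heavy atoms (N/O)
# and charged-group atoms for salt-bridge detection. Static cryo-EM/crystal
# models usually lack hydrogens, so all criteria here are heavy-atom
# distance rules without an angle term.

.sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH"
)

.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH"
)

.charged_positive <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                          HIS = c("ND1", "NE2"))
.charged_negative <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Hydrogen-bond donor heavy atoms of a residue type
#'
#' @param resid 3-letter residue name.
#' @param backbone include the backbone amide N (absent for PRO).
#' @return character vector of atom names.
#' @export
donor_atoms <- function(resid, backbone = TRUE) {
  sc <- .sidechain_donors[[resid]]
  bb <- if (backbone && resid != "PRO") "N" else character(0)
  c(bb, sc)
}

#' Hydrogen-bond acceptor heavy atoms of a residue type
#'
#' @param resid 3-letter residue name.
#' @param backbone include the backbone carbonyl O (and terminal OXT).
#' @return character vector of atom names.
#' @export
acceptor_atoms <- function(resid, backbone = TRUE) {
  sc <- .sidechain_acceptors[[resid]]
  bb <- if (backbone) c("O", "OXT") else character(0)
  c(bb, sc)
}

#' Charged-group atoms of a residue type (for salt bridges)
#' @param resid 3-letter residue name.
#' @return list with `pos` and `neg` atom-name vectors (possibly empty).
#' @export
charged_atoms <- function(resid) {
  list(pos = .charged_positive[[resid]] %||% character(0),
       neg = .charged_negative[[resid]] %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimum distance between two named-atom subsets of two residues;
# returns Inf when either subset is empty
min_atomset_distance <- function(s, idx_a, idx_b, names_a, names_b) {
  ia <- idx_a[s$atoms$elety[idx_a] %in% names_a]
  ib <- idx_b[s$atoms$elety[idx_b] %in% names_b]
  if (!length(ia) || !length(ib))
    return(list(distance = Inf, atom_pair = c(NA_character_, NA_character_)))
  xyz <- structure_coords(s)
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  d2[d2 < 0] <- 0
  k <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[k]),
       atom_pair = c(s$atoms$elety[ia[k[1]]], s$atoms$elety[ib[k[2]]]))
}

# minimum donor->acceptor heavy-atom distance between residues a and b,
# considering both donor(a)/acceptor(b) and donor(b)/acceptor(a)
min_donor_acceptor_distance <- function(s, idx_a, idx_b, backbone = TRUE) {
  ra <- s$atoms$resid[idx_a[1]]; rb <- s$atoms$resid[idx_b[1]]
  d1 <- min_atomset_distance(s, idx_a, idx_b,
                             donor_atoms(ra, backbone), acceptor_atoms(rb, backbone))
  d2 <- min_atomset_distance(s, idx_a, idx_b,
                             acceptor_atoms(ra, backbone), donor_atoms(rb, backbone))
  if (d1$distance <= d2$distance) d1 else d2
}

# minimum charged-group N/O distance (salt bridge geometry)
min_salt_bridge_distance <- function(s, idx_a, idx_b) {
  ra <- s$atoms$resid[idx_a[1]]; rb <- s$atoms$resid[idx_b[1]]
  ca <- charged_atoms(ra); cb <- charged_atoms(rb)
  d1 <- min_atomset_distance(s, idx_a, idx_b, ca$pos, cb$neg)
  d2 <- min_atomset_distance(s, idx_a, idx_b, ca$neg, cb$pos)
  if (d1$distance <= d2$distance) d1 else d2
}
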