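#' Pseudo-C-beta points from a C-alpha trace
#'
#' Approximates the side-chain direction of each residue from C-alpha-only
#' coordinates. For three consecutive C-alphas C1, C2, C3 the image B of C2
#' on the line C1-C3 is found by orthogonal projection, and the pseudo-C-beta
#' is placed 2 Angstrom from C2 along the direction from B to C2 (away from
#' the local backbone line). Terminal residues, and interior residues whose
#' flanking C-alphas are (near-)collinear with their own (|C2 - B| < 1e-6 A),
#' fall back to the C-alpha position itself so that every residue stays
#' eligible for contacts.
#'
#' @param coords numeric matrix, one row per residue (sequential 1-based
#'   numbering), three columns (x, y, z) of C-alpha positions in Angstrom.
#' @return numeric matrix of the same shape: pseudo-C-beta coordinates.
#' @export
pseudo_cbeta <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be a numeric matrix with 3 columns")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (n < 3L) stop("pseudo-C-beta derivation needs at least 3 residues")
  out <- coords
  fallback <- 0L
  for (r in 2:(n - 1L)) {
    c1 <- coords[r - 1L, ]; c2 <- coords[r, ]; c3 <- coords[r + 1L, ]
    v <- c3 - c1
    vv <- sum(v * v)
    if (vv < 1e-12) { fallback <- fallback + 1L; next } # identical flanking CAs
    b <- c1 + v * (sum((c2 - c1) * v) / vv)
    d <- c2 - b
    nd <- sqrt(sum(d * d))
    if (nd < 1e-6) { fallback <- fallback + 1L; next } # collinear triple
    out[r, ] <- c2 + 2 * d / nd
  }
  if (fallback > 0L)
    warning(fallback, " degenerate (collinear) triple(s); C-alpha used as pseudo-C-beta")
  out
}

#' Derive contacts from a C-alpha structure
#'
#' Computes pseudo-C-beta points ([pseudo_cbeta]) and reports every residue
#' pair whose pseudo-C-beta distance is at or below `threshold` (default 8 A,
#' the conventional contact cutoff). Contacts are scored as minus the
#' distance so that the shortest distances rank first; any monotone score
#' gives the same top-N selection.
#'
#' @param coords C-alpha coordinate matrix as for [pseudo_cbeta].
#' @param threshold contact distance cutoff in Angstrom.
#' @return A [contact_list] covering all qualifying pairs `i < j`.
#' @export
derive_structure_contacts <- function(coords, threshold = 8.0) {
  pcb <- pseudo_cbeta(coords)
  d <- as.matrix(stats::dist(pcb))
  n <- nrow(pcb)
  idx <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], score = -d[idx])
  contact_list(df, length = n)
}

#' Read C-alpha coordinates for one chain of a PDB file
#'
#' Uses bio3d to parse ATOM records, selects C-alpha atoms of the requested
#' chain, and renumbers residues sequentially from 1 in observation order
#' (author numbering and insertion codes are collapsed). Gaps in the author
#' numbering are reported via a message.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default: first chain present).
#' @return numeric matrix of C-alpha coordinates, one row per residue.
#' @export
read_ca_coords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1L]
  sel <- atoms$elety == "CA" & atoms$chain == chain & atoms$type == "ATOM"
  atoms <- atoms[sel, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no C-alpha atoms found for chain '", chain, "'")
  # one CA per residue: drop altloc duplicates, keep first occurrence
  key <- paste(atoms$resno, atoms$insert)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  resno <- atoms$resno
  if (any(diff(resno) > 1L))
    message("chain '", chain, "': ", sum(diff(resno) > 1L),
            " numbering gap(s); residues renumbered sequentially")
  m <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' @param coords C-alpha coordinate matrix (rows = residues).
#' @param path output path.
#' @param chain chain identifier to write.
#' @export
write_ca_pdb <- function(coords, path, chain = "A") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = rep("ATOM", n),
                   resno = seq_len(n),
                   resid = rep("ALA", n),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(chain, n))
  invisible(path)
}
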