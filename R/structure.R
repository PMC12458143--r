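#' Read a protein chain into an `ncle_structure`
#'
#' Parses a PDB or mmCIF file with bio3d, keeps one chain, drops hydrogens
#' and alternate locations other than the first, and indexes residues on the
#' numbering recorded in the file (assumed canonical). Missing interior
#' residues remain as gaps in `seq_index`; downstream entanglement detection
#' splits the chain at gaps because Gauss sums require a continuous curve.
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param chain single chain identifier.
#' @param protein_id optional accession; defaults to the file stem.
#' @param resolution,plddt_mean,disorder_fraction,identity,gap_fraction,evalue
#'   optional metadata consumed by [structure_passes_filters()].
#' @param source "crystal" or "alphafold"; selects which quality filters apply.
#' @return An object of class `ncle_structure`: a list with `residues`
#'   (data.frame seq_index, aa, x, y, z), `atoms` (heavy atoms with their
#'   residue index), and the metadata fields.
#' @export
read_structure <- function(path, chain, protein_id = NULL,
                           resolution = NA_real_, plddt_mean = NA_real_,
                           disorder_fraction = NA_real_, identity = NA_real_,
                           gap_fraction = NA_real_, evalue = NA_real_,
                           source = c("crystal", "alphafold")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: ", chain)
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A", "1"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) ) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- substr(elem, 1, 1)
  }
  elem <- toupper(trimws(elem))
  heavy <- elem != "H" & elem != "D"
  at <- at[heavy, , drop = FALSE]; elem <- elem[heavy]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("chain has no C-alpha atoms: ", chain)
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  residues <- data.frame(
    seq_index = ca$resno,
    aa = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    seq_index = at$resno, elety = at$elety, elem = elem,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$seq_index %in% residues$seq_index, , drop = FALSE]
  new_structure(protein_id = protein_id %||% sub("\\.[^.]*$", "", basename(path)),
                chain_id = chain, residues = residues, atoms = atoms,
                resolution = resolution, plddt_mean = plddt_mean,
                disorder_fraction = disorder_fraction, identity = identity,
                gap_fraction = gap_fraction, evalue = evalue, source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an `ncle_structure` from residue/atom tables
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' generators. Validates the invariants: strictly increasing `seq_index`,
#' finite coordinates, a C-alpha position for every residue.
#'
#' @param protein_id,chain_id identifiers.
#' @param residues data.frame with seq_index, aa, x, y, z.
#' @param atoms optional heavy-atom data.frame (seq_index, elety, elem, x, y, z).
#' @param ... metadata fields (resolution, plddt_mean, disorder_fraction,
#'   identity, gap_fraction, evalue, source).
#' @export
new_structure <- function(protein_id, chain_id, residues, atoms = NULL, ...) {
  stopifnot(all(c("seq_index", "aa", "x", "y", "z") %in% names(residues)))
  if (is.unsorted(residues$seq_index, strictly = TRUE)) {
    stop("residue seq_index must be strictly increasing")
  }
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop("non-finite C-alpha coordinates")
  }
  meta <- list(...)
  s <- c(list(protein_id = protein_id, chain_id = chain_id,
              residues = residues, atoms = atoms), meta)
  if (is.null(s$source)) s$source <- "crystal"
  class(s) <- "ncle_structure"
  s
}

#' @export
print.ncle_structure <- function(x, ...) {
  cat(sprintf("<ncle_structure> %s chain %s: %d residues (%d-%d), %s heavy atoms\n",
              x$protein_id, x$chain_id, nrow(x$residues),
              min(x$residues$seq_index), max(x$residues$seq_index),
              if (is.null(x$atoms)) "no" else nrow(x$atoms)))
  invisible(x)
}

ca_matrix <- function(s) as.matrix(s$residues[, c("x", "y", "z")])

# Runs of consecutive seq_index values: list of row-index vectors.
structure_segments <- function(s) {
  si <- s$residues$seq_index
  grp <- cumsum(c(1L, diff(si) != 1L))
  split(seq_along(si), grp)
}

#' Quality filters for candidate structures
#'
#' Crystal structures must have resolution <= 3 A, sequence identity to the
#' canonical sequence >= 95%, gaps <= 5%, alignment E-value <= 1e-5 and at
#' most 50% sequence disorder (all boundaries inclusive). AlphaFold models
#' must instead have mean pLDDT strictly greater than 70, plus the disorder
#' cap. Absent metadata fails the criterion under the strict policy and skips
#' it under the permissive policy.
#'
#' @param s an `ncle_structure`.
#' @param policy "strict" or "permissive" handling of absent metadata.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
structure_passes_filters <- function(s, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  reasons <- character()
  check <- function(value, ok, name) {
    if (is.null(value) || is.na(value)) {
      if (policy == "strict") reasons <<- c(reasons, paste0(name, " (missing)"))
    } else if (!ok(value)) {
      reasons <<- c(reasons, name)
    }
  }
  if (identical(s$source, "alphafold")) {
    check(s$plddt_mean, function(v) v > 70, "plddt")
  } else {
    check(s$resolution, function(v) v <= 3, "resolution")
    check(s$identity, function(v) v >= 0.95, "identity")
    check(s$gap_fraction, function(v) v <= 0.05, "gaps")
    check(s$evalue, function(v) v <= 1e-5, "evalue")
  }
  check(s$disorder_fraction, function(v) v <= 0.5, "disorder")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Residue pairs in heavy-atom contact
#'
#' Two residues are in contact when any of their heavy atoms lie within
#' `cutoff` (default 4.5 A) of each other. These contacts define candidate
#' loop-closing contacts for entanglement detection.
#'
#' @param s `ncle_structure` with heavy atoms.
#' @param cutoff A, default 4.5.
#' @param min_sep minimum sequence separation |j - i| to report (default 0,
#'   all pairs).
#' @return data.frame (i, j, criterion, min_distance) with i < j on
#'   seq_index numbering.
#' @export
heavy_atom_contacts <- function(s, cutoff = 4.5, min_sep = 0L) {
  if (is.null(s$atoms) || nrow(s$atoms) == 0) {
    stop("structure has no heavy atoms; use ca_native_contacts() for C-alpha mode")
  }
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- a$seq_index
  n <- nrow(xyz)
  pairs_min <- new.env(parent = emptyenv())
  # block the O(n^2) distance computation to bound memory
  bs <- 1500L
  starts <- seq(1L, n, by = bs)
  for (p in starts) for (q in starts) {
    if (q < p) next
    ip <- p:min(p + bs - 1L, n); iq <- q:min(q + bs - 1L, n)
    dx <- outer(xyz[ip, 1], xyz[iq, 1], "-")
    dy <- outer(xyz[ip, 2], xyz[iq, 2], "-")
    dz <- outer(xyz[ip, 3], xyz[iq, 3], "-")
    d2 <- dx * dx + dy * dy + dz * dz
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    ri <- res[ip[hit[, 1]]]; rj <- res[iq[hit[, 2]]]
    keep <- ri < rj & (rj - ri) >= max(min_sep, 1L)
    if (!any(keep)) next
    dd <- sqrt(d2[hit[keep, , drop = FALSE]])
    key <- paste(ri[keep], rj[keep])
    for (k in seq_along(key)) {
      cur <- pairs_min[[key[k]]]
      if (is.null(cur) || dd[k] < cur) pairs_min[[key[k]]] <- dd[k]
    }
  }
  keys <- ls(pairs_min)
  if (!length(keys)) {
    return(data.frame(i = integer(), j = integer(),
                      criterion = character(), min_distance = numeric()))
  }
  ij <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    criterion = "heavy_4p5",
                    min_distance = vapply(keys, function(k) pairs_min[[k]], 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Contacts between C-alpha positions of a plain coordinate matrix; indices are
# row numbers.
ca_contacts_matrix <- function(xyz, cutoff = 8, min_sep = 4L) {
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(), j = integer(), min_distance = numeric()))
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx)) idx <- idx[idx[, 2] - idx[, 1] >= min_sep, , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2], min_distance = d[idx])
}

#' C-alpha native contacts
#'
#' Residue pairs whose C-alpha atoms lie within `cutoff` (default 8 A) and are
#' at least `min_sep` residues apart along the chain (default 4, i.e. the
#' inner sum of the native-contact order parameter starts at j = i + 4).
#'
#' @param s `ncle_structure` (or plain n x 3 matrix of C-alpha coordinates).
#' @param cutoff A, default 8.
#' @param min_sep minimum |j - i|, default 4.
#' @return data.frame (i, j, criterion, min_distance); i, j on seq_index
#'   numbering for structures, row numbers for matrices.
#' @export
ca_native_contacts <- function(s, cutoff = 8, min_sep = 4L) {
  if (inherits(s, "ncle_structure")) {
    xyz <- ca_matrix(s)
    cc <- ca_contacts_matrix(xyz, cutoff, min_sep = 1L)
    si <- s$residues$seq_index
    cc$i <- si[cc$i]; cc$j <- si[cc$j]
    cc <- cc[cc$j - cc$i >= min_sep, , drop = FALSE]
  } else {
    cc <- ca_contacts_matrix(as_xyz_matrix(s), cutoff, min_sep)
  }
  if (nrow(cc)) cc$criterion <- "ca_8" else cc$criterion <- character()
  rownames(cc) <- NULL
  cc[, c("i", "j", "criterion", "min_distance")]
}

# van der Waals radii (A) pinned for reproducible SASA.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)
.vdw_default <- 1.70

# Deterministic quasi-uniform sphere points (golden-section spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent accessible surface area
#'
#' Shrake-Rupley rolling-probe SASA: each heavy atom is covered with
#' `n_points` quasi-uniform test points on its probe-expanded sphere; a point
#' is accessible if it is outside every neighbouring atom's expanded sphere.
#' Atom areas are summed per residue.
#'
#' @param s `ncle_structure` with heavy atoms.
#' @param probe_radius probe radius in A (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return data.frame (seq_index, sasa) in A^2.
#' @export
compute_sasa <- function(s, probe_radius = 1.4, n_points = 960L) {
  if (is.null(s$atoms) || nrow(s$atoms) == 0) stop("structure has no heavy atoms")
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- unname(.vdw_radii[a$elem])
  rad[is.na(rad)] <- .vdw_default
  rext <- rad + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  maxr <- max(rext)
  for (k in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[k, 1])^2 + (xyz[, 2] - xyz[k, 2])^2 + (xyz[, 3] - xyz[k, 3])^2
    nb <- which(d2 < (rext[k] + maxr)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < rext[k] + rext[nb]]
    test <- sweep(pts * rext[k], 2, xyz[k, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (m in nb) {
        if (!any(acc)) break
        dd <- (test[acc, 1] - xyz[m, 1])^2 + (test[acc, 2] - xyz[m, 2])^2 +
          (test[acc, 3] - xyz[m, 3])^2
        acc[acc] <- dd >= rext[m]^2
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    area[k] <- frac * 4 * pi * rext[k]^2
  }
  out <- stats::aggregate(area, list(seq_index = a$seq_index), sum)
  names(out)[2] <- "sasa"
  # residues with no heavy atoms recorded get NA
  res <- data.frame(seq_index = s$residues$seq_index)
  merge(res, out, all.x = TRUE)
}
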