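#' Detect raw non-covalent lasso entanglements
#'
#' For every loop-closing contact (a heavy-atom contact pair (i, j)), the
#' partial linking numbers of the N- and C-terminal tails with the loop
#' i..j are computed ([partial_linking()]); the loop is flagged entangled
#' when |gN| >= `g_threshold` or |gC| >= `g_threshold` (default 0.6).
#' Crossing residues of the entangled termini are located with
#' [find_crossings()]. Chains with interior gaps are split into continuous
#' segments; loops spanning a gap are discarded.
#'
#' @param s `ncle_structure`.
#' @param contacts optional precomputed contact table (default
#'   [heavy_atom_contacts()] at 4.5 A).
#' @param g_threshold entanglement threshold on |g| (default 0.6).
#' @param min_loop minimum loop span j - i to consider (default 10).
#' @return list of `raw_ncle` objects; each is a list with `loop` = c(i, j),
#'   `gN`, `gC`, and `crossings` (data.frame residue, sign, terminus).
#'   Indices are on the canonical `seq_index` numbering.
#' @export
detect_raw_ncles <- function(s, contacts = NULL, g_threshold = 0.6, min_loop = 10L) {
  if (is.null(contacts)) contacts <- heavy_atom_contacts(s)
  si <- s$residues$seq_index
  xyz_all <- ca_matrix(s)
  segs <- structure_segments(s)
  out <- list()
  for (seg in segs) {
    if (length(seg) < min_loop + 10L) next
    seg_si <- si[seg]
    cc <- contacts[contacts$i %in% seg_si & contacts$j %in% seg_si, , drop = FALSE]
    cc <- cc[cc$j - cc$i >= min_loop, , drop = FALSE]
    if (!nrow(cc)) next
    xyz <- xyz_all[seg, , drop = FALSE]
    lp <- linking_prefix(xyz)
    # local (1-based within segment) indices
    li <- match(cc$i, seg_si); lj <- match(cc$j, seg_si)
    for (k in seq_len(nrow(cc))) {
      g <- partial_linking_prefix(lp, li[k], lj[k])
      if (abs(g["gN"]) < g_threshold && abs(g["gC"]) < g_threshold) next
      cr <- find_crossings(xyz, c(li[k], lj[k]))
      keep <- (cr$terminus == "N" & abs(g["gN"]) >= g_threshold) |
        (cr$terminus == "C" & abs(g["gC"]) >= g_threshold)
      cr <- cr[keep, , drop = FALSE]
      cr$residue <- seg_si[cr$residue]
      r <- list(loop = c(i = cc$i[k], j = cc$j[k]),
                gN = unname(g["gN"]), gC = unname(g["gC"]),
                crossings = cr)
      class(r) <- "raw_ncle"
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' @export
print.raw_ncle <- function(x, ...) {
  cat(sprintf("<raw_ncle> loop (%d, %d)  gN=%.3f gC=%.3f  crossings: %s\n",
              x$loop[1], x$loop[2], x$gN, x$gC,
              if (nrow(x$crossings)) paste0(ifelse(x$crossings$sign > 0, "+", "-"),
                                            x$crossings$residue, collapse = ", ")
              else "none"))
  invisible(x)
}

# Key describing the (terminus, sign) pattern of a raw NCLE's crossings.
crossing_pattern <- function(r) {
  cr <- r$crossings
  if (!nrow(cr)) return("none")
  cr <- cr[order(cr$terminus, cr$residue), , drop = FALSE]
  paste(cr$terminus, cr$sign, sep = ":", collapse = "|")
}

#' Cluster raw NCLEs into unique topological entanglements
#'
#' Two raw NCLEs represent the same topology when they have the same
#' crossing-terminus and sign pattern and their matched crossing residues lie
#' within `window` residues of each other (single-linkage closure). The
#' representative of each cluster is the member with the minimal loop length
#' j - i (ties: smaller i).
#'
#' @param raw list of `raw_ncle` from [detect_raw_ncles()].
#' @param window residue window for matching crossings (default 10).
#' @return list of `unique_ncle` objects: `representative`, `members`,
#'   `cluster_id`.
#' @export
cluster_ncles <- function(raw, window = 10L) {
  if (!length(raw)) return(list())
  n <- length(raw)
  pat <- vapply(raw, crossing_pattern, "")
  same <- function(a, b) {
    if (pat[a] != pat[b]) return(FALSE)
    ca <- raw[[a]]$crossings; cb <- raw[[b]]$crossings
    if (nrow(ca) != nrow(cb)) return(FALSE)
    if (!nrow(ca)) return(TRUE)
    ca <- ca[order(ca$terminus, ca$residue), , drop = FALSE]
    cb <- cb[order(cb$terminus, cb$residue), , drop = FALSE]
    all(abs(ca$residue - cb$residue) <= window)
  }
  # single-linkage via union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (same(a, b)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- list()
  for (r in unique(roots)) {
    members <- raw[roots == r]
    span <- vapply(members, function(m) m$loop[2] - m$loop[1], 0)
    starts <- vapply(members, function(m) m$loop[1], 0)
    rep_idx <- order(span, starts)[1]
    u <- list(representative = members[[rep_idx]], members = members,
              cluster_id = length(out) + 1L)
    class(u) <- "unique_ncle"
    out[[length(out) + 1L]] <- u
  }
  out
}

#' @export
print.unique_ncle <- function(x, ...) {
  cat(sprintf("<unique_ncle> cluster %d: %d member(s), representative ",
              x$cluster_id, length(x$members)))
  print(x$representative)
  invisible(x)
}

#' Topological feature vector of a unique NCLE
#'
#' Eighteen named structural features of an entanglement, designed to capture
#' loop geometry, threading depth and linking complexity. The exact set is
#' this package's documented, versioned choice (feature-set v1); see the
#' methods vignette for definitions.
#'
#' @param u `unique_ncle`.
#' @param s the `ncle_structure` it was detected in.
#' @return named numeric vector of length 18.
#' @export
compute_features <- function(u, s) {
  r <- u$representative
  n <- nrow(s$residues)
  first <- min(s$residues$seq_index); last <- max(s$residues$seq_index)
  i <- r$loop[1]; j <- r$loop[2]
  cr <- r$crossings
  ncr <- nrow(cr)
  ncr_n <- sum(cr$terminus == "N"); ncr_c <- sum(cr$terminus == "C")
  depth_n <- if (ncr_n) min(cr$residue[cr$terminus == "N"] - first + 1L) else 0
  depth_c <- if (ncr_c) min(last - cr$residue[cr$terminus == "C"] + 1L) else 0
  sep <- if (ncr) min(pmin(abs(cr$residue - i), abs(cr$residue - j))) else 0
  g_spread <- if (length(u$members) > 1) {
    stats::sd(vapply(u$members, function(m) max(abs(m$gN), abs(m$gC)), 0))
  } else 0
  c(
    loop_length        = unname(j - i),
    loop_start_rel     = unname((i - first) / max(n - 1, 1)),
    loop_end_rel       = unname((j - first) / max(n - 1, 1)),
    tail_length_N      = unname(i - first),
    tail_length_C      = unname(last - j),
    abs_gN             = abs(r$gN),
    abs_gC             = abs(r$gC),
    max_abs_g          = max(abs(r$gN), abs(r$gC)),
    num_crossings      = ncr,
    num_crossings_N    = ncr_n,
    num_crossings_C    = ncr_c,
    net_crossing_sign  = if (ncr) sum(cr$sign) else 0,
    crossing_depth_N   = depth_n,
    crossing_depth_C   = depth_c,
    loop_thread_sep    = sep,
    cluster_size       = length(u$members),
    protein_length     = n,
    g_spread           = g_spread
  )
}

#' Annotate residues with NCLE region membership
#'
#' A residue belongs to the native NCLE region when it lies inside the
#' representative loop [i, j] of any unique NCLE (region "loop"), or within
#' `thread_pad` residues of any crossing residue (region "thread"). Loop
#' membership takes precedence over thread on overlap.
#'
#' @param s `ncle_structure`.
#' @param ncles list of `unique_ncle` from [cluster_ncles()].
#' @param thread_pad residues padded around each crossing (default 10).
#' @param sasa optional data.frame from [compute_sasa()] to join.
#' @return data.frame (seq_index, in_ncle_region, region_kind, sasa).
#' @export
annotate_regions <- function(s, ncles, thread_pad = 10L, sasa = NULL) {
  si <- s$residues$seq_index
  kind <- rep("none", length(si))
  for (u in ncles) {
    r <- u$representative
    for (cr in r$crossings$residue) {
      kind[si >= cr - thread_pad & si <= cr + thread_pad & kind == "none"] <- "thread"
    }
  }
  for (u in ncles) {
    r <- u$representative
    kind[si >= r$loop[1] & si <= r$loop[2]] <- "loop"
  }
  out <- data.frame(seq_index = si, in_ncle_region = kind != "none",
                    region_kind = kind, stringsAsFactors = FALSE)
  if (!is.null(sasa)) out <- merge(out, sasa, by = "seq_index", all.x = TRUE)
  out
}

#' NCLE feature table for a set of structures
#'
#' Convenience wrapper: detect, cluster and featurise NCLEs across
#' structures, returning one row per unique NCLE.
#'
#' @param structures list of `ncle_structure`.
#' @param ... passed to [detect_raw_ncles()].
#' @return data.frame with protein_id, loop_i, loop_j, gN, gC, n_crossings,
#'   cluster_id and the 18 feature columns.
#' @export
ncle_feature_table <- function(structures, ...) {
  rows <- list()
  for (s in structures) {
    u <- cluster_ncles(detect_raw_ncles(s, ...))
    for (uu in u) {
      f <- compute_features(uu, s)
      r <- uu$representative
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = s$protein_id, loop_i = r$loop[1], loop_j = r$loop[2],
        gN = r$gN, gC = r$gC, n_crossings = nrow(r$crossings),
        cluster_id = uu$cluster_id, t(f), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
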