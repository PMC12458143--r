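#' Discrete Gauss linking kernel between two sets of bonds
#'
#' Each backbone bond l between consecutive points r_l, r_{l+1} is represented
#' by its midpoint R_l = (r_l + r_{l+1})/2 and gradient dR_l = r_{l+1} - r_l.
#' The kernel entry for bonds (m, n) is
#' ((R_m - R_n)/|R_m - R_n|^3) . (dR_m x dR_n) / (4 pi),
#' the summand of the discretised Gauss double integral.
#'
#' @param mid1,grad1 n1 x 3 matrices of bond midpoints and gradients.
#' @param mid2,grad2 n2 x 3 matrices; defaults reuse the first curve.
#' @return n1 x n2 matrix of kernel values (0 on coincident midpoints).
#' @keywords internal
gauss_kernel <- function(mid1, grad1, mid2 = mid1, grad2 = grad1) {
  n1 <- nrow(mid1); n2 <- nrow(mid2)
  dx <- outer(mid1[, 1], mid2[, 1], "-")
  dy <- outer(mid1[, 2], mid2[, 2], "-")
  dz <- outer(mid1[, 3], mid2[, 3], "-")
  # dR_m x dR_n for all pairs, component-wise outer products
  cx <- outer(grad1[, 2], grad2[, 3]) - outer(grad1[, 3], grad2[, 2])
  cy <- outer(grad1[, 3], grad2[, 1]) - outer(grad1[, 1], grad2[, 3])
  cz <- outer(grad1[, 1], grad2[, 2]) - outer(grad1[, 2], grad2[, 1])
  r2 <- dx * dx + dy * dy + dz * dz
  r3 <- r2 * sqrt(r2)
  num <- dx * cx + dy * cy + dz * cz
  k <- ifelse(r3 > 0, num / r3, 0)
  k / (4 * pi)
}

bond_midpoints <- function(xyz) (xyz[-nrow(xyz), , drop = FALSE] + xyz[-1, , drop = FALSE]) / 2
bond_gradients <- function(xyz) xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE]

close_curve <- function(xyz) {
  if (!isTRUE(all.equal(xyz[1, ], xyz[nrow(xyz), ]))) xyz <- rbind(xyz, xyz[1, ])
  xyz
}

#' Gauss linking number of two curves
#'
#' Full discretised Gauss double sum between two polylines. For two closed
#' curves this approximates the (integer) topological linking number; for open
#' curves it is the real-valued Gaussian entanglement of the pair.
#'
#' @param curve1,curve2 n x 3 coordinate matrices (ordered points, Angstrom).
#' @param closed logical; if `TRUE` (default) each curve is closed by joining
#'   its last point back to its first before discretisation.
#' @return A single real number.
#' @examples
#' rings <- make_interlocked_rings(60)
#' gauss_linking(rings$ring1, rings$ring2) # ~ +/- 1
#' @export
gauss_linking <- function(curve1, curve2, closed = TRUE) {
  curve1 <- as_xyz_matrix(curve1); curve2 <- as_xyz_matrix(curve2)
  if (closed) { curve1 <- close_curve(curve1); curve2 <- close_curve(curve2) }
  k <- gauss_kernel(bond_midpoints(curve1), bond_gradients(curve1),
                    bond_midpoints(curve2), bond_gradients(curve2))
  sum(k)
}

as_xyz_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must be an n x 3 matrix")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  storage.mode(x) <- "double"
  x
}

#' Partial linking numbers of terminal tails with a backbone loop
#'
#' For a loop closed by a native contact at residues (i, j) of an N-residue
#' chain, the N-terminal partial linking number gN sums the Gauss kernel over
#' tail bonds m = 6..i-5 against loop bonds n = i..j-1; the C-terminal gC uses
#' tail bonds m = j+6..N-5. Five residues at each chain end and flanking the
#' loop are excluded from the tail sums; an empty tail range yields 0.
#'
#' @param curve n x 3 matrix of ordered C-alpha coordinates.
#' @param loop integer pair `c(i, j)`, 1-based residue indices, i < j.
#' @return Named numeric vector `c(gN = ..., gC = ...)`.
#' @examples
#' lasso <- make_lasso_curve(loop_radius = 8, n_loop_points = 40,
#'                           thread_length = 15, pierce_offset = 0)
#' partial_linking(lasso$xyz, lasso$ground_truth$loop)
#' @export
partial_linking <- function(curve, loop) {
  curve <- as_xyz_matrix(curve)
  n <- nrow(curve)
  i <- as.integer(loop[1]); j <- as.integer(loop[2])
  if (i < 1 || j > n || j - i < 2) stop("invalid loop: need 1 <= i, j <= N and j - i >= 2")
  mids <- bond_midpoints(curve); grads <- bond_gradients(curve)
  loop_idx <- seq.int(i, j - 1)
  sum_range <- function(lo, hi) {
    if (lo > hi) return(0)
    sum(gauss_kernel(mids[lo:hi, , drop = FALSE], grads[lo:hi, , drop = FALSE],
                     mids[loop_idx, , drop = FALSE], grads[loop_idx, , drop = FALSE]))
  }
  c(gN = sum_range(6L, i - 5L), gC = sum_range(j + 6L, n - 5L))
}

# Cumulative 2D prefix sums of the full bond-pair kernel, so the partial
# linking of any loop is an O(1) rectangle sum. Used by detect_raw_ncles and
# the trajectory G order parameter, where many loops share one curve.
linking_prefix <- function(curve) {
  curve <- as_xyz_matrix(curve)
  mids <- bond_midpoints(curve); grads <- bond_gradients(curve)
  k <- gauss_kernel(mids, grads)
  list(n = nrow(curve), pre = apply(apply(k, 2, cumsum), 1, cumsum))
  # pre[q, p] = sum over m <= p, n <= q (transposed by second apply)
}

rect_sum <- function(pre, m_lo, m_hi, n_lo, n_hi) {
  if (m_lo > m_hi || n_lo > n_hi) return(0)
  p <- function(a, b) if (a < 1 || b < 1) 0 else pre[b, a]
  p(m_hi, n_hi) - p(m_lo - 1L, n_hi) - p(m_hi, n_lo - 1L) + p(m_lo - 1L, n_lo - 1L)
}

partial_linking_prefix <- function(lp, i, j) {
  c(gN = rect_sum(lp$pre, 6L, i - 5L, i, j - 1L),
    gC = rect_sum(lp$pre, j + 6L, lp$n - 5L, i, j - 1L))
}

#' Residues at which terminal tails cross the loop surface
#'
#' Spans the closed loop (the backbone i..j plus the closing contact segment
#' j -> i) with a triangle fan from the loop centroid and intersects every
#' tail bond with that surface. Each intersection is a crossing; its sign is
#' the right-hand-rule orientation of the tail bond relative to the loop
#' traversal, and its residue is the bond endpoint nearer the piercing point.
#' Tail bonds immediately flanking the loop are excluded, mirroring the
#' bounds of the partial-linking tail sums (N-tail bonds up to i - 5, C-tail
#' bonds from j + 6), which suppresses grazing intersections at the loop
#' boundary.
#'
#' @param curve n x 3 C-alpha coordinate matrix.
#' @param loop integer pair `c(i, j)` of the loop-closing contact.
#' @return data.frame with columns `residue`, `sign` (+1/-1), `terminus`
#'   ("N" or "C"); zero rows when no tail pierces the surface.
#' @export
find_crossings <- function(curve, loop) {
  curve <- as_xyz_matrix(curve)
  n <- nrow(curve)
  i <- as.integer(loop[1]); j <- as.integer(loop[2])
  if (j - i < 2) stop("loop must span at least 2 bonds")
  poly <- curve[i:j, , drop = FALSE]
  centroid <- colMeans(poly)
  if (svd(sweep(poly, 2, centroid))$d[2] < 1e-9) stop("degenerate (collinear) loop")
  # triangles (centroid, poly[k], poly[k+1]), with closing edge poly[last]->poly[1]
  nv <- nrow(poly)
  v1 <- poly
  v2 <- poly[c(2:nv, 1), , drop = FALSE]
  out <- list()
  tail_bonds <- function(lo, hi, terminus) {
    if (lo > hi) return()
    for (b in lo:hi) {
      hit <- segment_fan_intersections(curve[b, ], curve[b + 1L, ], centroid, v1, v2)
      if (nrow(hit)) {
        res <- ifelse(hit$t <= 0.5, b, b + 1L)
        out[[length(out) + 1L]] <<- data.frame(residue = res, sign = hit$sign,
                                               terminus = terminus)
      }
    }
  }
  tail_bonds(1L, i - 5L, "N")
  tail_bonds(j + 6L, n - 1L, "C")
  if (!length(out)) {
    return(data.frame(residue = integer(), sign = integer(), terminus = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$residue), , drop = FALSE]
}

# Moeller-Trumbore intersection of segment a->b with the fan triangles
# (c, v1[k,], v2[k,]). Returns data.frame(t = parameter along segment, sign).
segment_fan_intersections <- function(a, b, c, v1, v2) {
  dir <- b - a
  e1 <- sweep(v1, 2, c)          # c -> v1
  e2 <- sweep(v2, 2, c)          # c -> v2
  # h = dir x e2 per triangle
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  det <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  s1 <- a[1] - c[1]; s2 <- a[2] - c[2]; s3 <- a[3] - c[3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / det
  # q = s x e1 per triangle
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  v <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / det
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
  ok <- is.finite(det) & abs(det) > 1e-12 &
    u >= 0 & v >= 0 & (u + v) <= 1 & tt >= 0 & tt <= 1
  if (!any(ok)) return(data.frame(t = numeric(), sign = integer()))
  # sign: direction of the bond against the oriented triangle normal e1 x e2
  nx <- e1[ok, 2] * e2[ok, 3] - e1[ok, 3] * e2[ok, 2]
  ny <- e1[ok, 3] * e2[ok, 1] - e1[ok, 1] * e2[ok, 3]
  nz <- e1[ok, 1] * e2[ok, 2] - e1[ok, 2] * e2[ok, 1]
  s <- sign(dir[1] * nx + dir[2] * ny + dir[3] * nz)
  out <- data.frame(t = tt[ok], sign = as.integer(s))
  # a piercing exactly on a shared triangle edge registers in both triangles;
  # collapse hits at (numerically) the same point along the segment
  out <- out[order(out$t), , drop = FALSE]
  keep <- c(TRUE, diff(out$t) > 1e-9)
  out[keep, , drop = FALSE]
}
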