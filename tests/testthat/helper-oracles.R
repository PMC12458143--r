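# Independent oracles, written naively and kept free of the package's own
# computational paths.

# Direct double-loop discrete Gauss integral between two polylines (closed
# by repeating the first point). O(n^2) scalar loops on purpose.
naive_gauss_linking <- function(p1, p2, close1 = TRUE, close2 = TRUE) {
  if (close1) p1 <- rbind(p1, p1[1, ])
  if (close2) p2 <- rbind(p2, p2[1, ])
  total <- 0
  for (m in seq_len(nrow(p1) - 1)) {
    rm_ <- (p1[m, ] + p1[m + 1, ]) / 2
    dm <- p1[m + 1, ] - p1[m, ]
    for (n in seq_len(nrow(p2) - 1)) {
      rn <- (p2[n, ] + p2[n + 1, ]) / 2
      dn <- p2[n + 1, ] - p2[n, ]
      diff <- rm_ - rn
      r <- sqrt(sum(diff^2))
      if (r == 0) next
      cr <- c(dm[2] * dn[3] - dm[3] * dn[2],
              dm[3] * dn[1] - dm[1] * dn[3],
              dm[1] * dn[2] - dm[2] * dn[1])
      total <- total + sum(diff * cr) / r^3
    }
  }
  total / (4 * pi)
}

# Partial linking by the printed tail/loop index bounds, via the naive kernel.
naive_partial_linking <- function(curve, i, j) {
  n <- nrow(curve)
  seg <- function(lo, hi) {
    # open polyline bonds lo..hi as point list lo..hi+1
    curve[lo:(hi + 1), , drop = FALSE]
  }
  g_of <- function(m_lo, m_hi) {
    if (m_lo > m_hi) return(0)
    naive_gauss_linking(seg(m_lo, m_hi), seg(i, j - 1),
                        close1 = FALSE, close2 = FALSE)
  }
  c(gN = g_of(6, i - 5), gC = g_of(j + 6, n - 5))
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
brute_fisher_p <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  xs <- max(0, row1 - (n - col1)):min(row1, col1)
  probs <- stats::dhyper(xs, col1, n - col1, row1)
  p_obs <- stats::dhyper(a, col1, n - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up BH adjustment written from the definition.
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- Inf
  for (k in n:1) {
    cummin_rev <- min(cummin_rev, p[o[k]] * n / k)
    adj[o[k]] <- min(1, cummin_rev)
  }
  adj
}

# All residue pairs whose minimum interatomic distance is <= cutoff,
# by complete scalar enumeration.
brute_min_dist_pairs <- function(atoms, cutoff) {
  res <- sort(unique(atoms$seq_index))
  out <- NULL
  for (a in seq_along(res)) for (b in seq_along(res)) {
    if (b <= a) next
    pa <- atoms[atoms$seq_index == res[a], c("x", "y", "z")]
    pb <- atoms[atoms$seq_index == res[b], c("x", "y", "z")]
    dmin <- Inf
    for (u in seq_len(nrow(pa))) for (v in seq_len(nrow(pb))) {
      dmin <- min(dmin, sqrt(sum((pa[u, ] - pb[v, ])^2)))
    }
    if (dmin <= cutoff) out <- rbind(out, data.frame(i = res[a], j = res[b],
                                                     min_distance = dmin))
  }
  out
}

# Sliding-window motif match oracle for the basic/hydrophobic class word.
brute_motif_positions <- function(seq, pattern = "BHHHHHB",
                                  B = c("R", "K"),
                                  H = c("A", "V", "L", "I", "M", "F", "W", "Y")) {
  ch <- strsplit(seq, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  hits <- integer()
  if (length(ch) < length(pat)) return(hits)
  for (s in 1:(length(ch) - length(pat) + 1)) {
    ok <- TRUE
    for (k in seq_along(pat)) {
      cls <- if (pat[k] == "B") B else if (pat[k] == "H") H else pat[k]
      if (!(ch[s + k - 1] %in% cls)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Minimal PDB writer for C-alpha + dummy side-chain fixtures.
write_fixture_pdb <- function(path, residues, chain = "A") {
  lines <- character()
  serial <- 1L
  for (k in seq_len(nrow(residues))) {
    r <- residues[k, ]
    for (at in c("CA", "CB")) {
      off <- if (at == "CA") c(0, 0, 0) else c(0.8, 0.4, 0)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, at, r$resid, chain, r$resno,
        r$x + off[1], r$y + off[2], r$z + off[3]))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

rigid_transform <- function(xyz, angles = c(0.3, 1.1, -0.7), shift = c(5, -3, 12)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  sweep(xyz %*% t(R), 2, shift, "+")
}
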