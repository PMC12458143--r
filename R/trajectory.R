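#' Trajectory container
#'
#' Ordered C-alpha coordinate frames at a fixed frame interval.
#'
#' @param frames list of n x 3 coordinate matrices (constant residue count).
#' @param frame_interval ns between frames (default 0.075).
#' @param protein_id identifier.
#' @param kind "reference" (native-state control run) or "quench".
#' @return `ncle_trajectory` object.
#' @export
new_trajectory <- function(frames, frame_interval = 0.075, protein_id = "traj",
                           kind = c("quench", "reference")) {
  kind <- match.arg(kind)
  stopifnot(length(frames) > 0, frame_interval > 0)
  nres <- vapply(frames, nrow, 0L)
  if (length(unique(nres)) != 1) stop("residue count must be constant across frames")
  structure(list(protein_id = protein_id, frames = frames,
                 frame_interval = frame_interval, kind = kind),
            class = "ncle_trajectory")
}

#' @export
print.ncle_trajectory <- function(x, ...) {
  cat(sprintf("<ncle_trajectory> %s (%s): %d frames x %d residues, dt = %g ns\n",
              x$protein_id, x$kind, length(x$frames), nrow(x$frames[[1]]),
              x$frame_interval))
  invisible(x)
}

#' Native contact set of a reference structure
#'
#' C-alpha contacts of the reference conformation (distance <= `cutoff`,
#' sequence separation >= `min_sep`), with reference distances and, for each
#' contact treated as a loop-closing contact, the reference partial linking
#' values of both termini and their rounded (integer) entanglement states.
#' The fraction-of-native-contacts order parameter Q uses only contacts whose
#' residues are both inside the secondary-structure set `ss`; the
#' entanglement-change order parameter G uses all contacts.
#'
#' @param ref_xyz n x 3 reference C-alpha coordinates.
#' @param cutoff contact cutoff in A (default 8).
#' @param min_sep minimum |j - i| (default 4).
#' @param ss optional integer vector of residue indices assigned to secondary
#'   structure; NULL applies no filter.
#' @return `native_contact_set`: data.frame of contacts (i, j, d_ref, in_ss,
#'   g_ref_N, g_ref_C, state_ref_N, state_ref_C) plus attributes.
#' @export
native_contact_set <- function(ref_xyz, cutoff = 8, min_sep = 4L, ss = NULL) {
  ref_xyz <- as_xyz_matrix(ref_xyz)
  cc <- ca_contacts_matrix(ref_xyz, cutoff, min_sep)
  if (!nrow(cc)) stop("reference structure has no native contacts")
  lp <- linking_prefix(ref_xyz)
  g <- t(vapply(seq_len(nrow(cc)),
                function(k) partial_linking_prefix(lp, cc$i[k], cc$j[k]),
                c(gN = 0, gC = 0)))
  ncs <- data.frame(i = cc$i, j = cc$j, d_ref = cc$min_distance,
                    in_ss = if (is.null(ss)) TRUE else (cc$i %in% ss & cc$j %in% ss),
                    g_ref_N = g[, "gN"], g_ref_C = g[, "gC"],
                    state_ref_N = round(g[, "gN"]), state_ref_C = round(g[, "gC"]))
  structure(ncs, class = c("native_contact_set", "data.frame"),
            n_res = nrow(ref_xyz))
}

#' Fraction of native contacts Q
#'
#' Q is the fraction of reference native contacts (restricted to the
#' secondary-structure subset fixed at set construction) whose current
#' C-alpha distance is at most 1.2 x the reference distance.
#'
#' @param frame n x 3 C-alpha coordinates.
#' @param ncs [native_contact_set()].
#' @return fraction in [0, 1].
#' @export
compute_Q <- function(frame, ncs) {
  frame <- as_xyz_matrix(frame)
  sel <- ncs$in_ss
  if (!any(sel)) stop("empty native contact set after secondary-structure filter")
  i <- ncs$i[sel]; j <- ncs$j[sel]
  d <- sqrt(rowSums((frame[i, , drop = FALSE] - frame[j, , drop = FALSE])^2))
  mean(d <= 1.2 * ncs$d_ref[sel])
}

# Rounded linking states of every native-contact loop in a frame.
frame_linking_states <- function(frame, ncs) {
  lp <- linking_prefix(frame)
  g <- t(vapply(seq_len(nrow(ncs)),
                function(k) partial_linking_prefix(lp, ncs$i[k], ncs$j[k]),
                c(gN = 0, gC = 0)))
  cbind(state_N = round(g[, "gN"]), state_C = round(g[, "gC"]),
        gN = g[, "gN"], gC = g[, "gC"])
}

#' Fraction of native contacts with changed entanglement status G
#'
#' G is the fraction of native contacts whose N- or C-terminal partial
#' linking value, discretised to the nearest integer (capturing both
#' magnitude and sign changes), differs from the reference state. No
#' secondary-structure filter is applied.
#'
#' @param frame n x 3 C-alpha coordinates.
#' @param ncs [native_contact_set()].
#' @return fraction in [0, 1].
#' @export
compute_G <- function(frame, ncs) {
  st <- frame_linking_states(as_xyz_matrix(frame), ncs)
  mean(st[, "state_N"] != ncs$state_ref_N | st[, "state_C"] != ncs$state_ref_C)
}

#' Per-frame order parameters of a trajectory
#'
#' @param traj `ncle_trajectory`.
#' @param ncs [native_contact_set()].
#' @return data.frame (frame, time_ns, Q, G).
#' @export
trajectory_order_params <- function(traj, ncs) {
  q <- vapply(traj$frames, compute_Q, 0, ncs = ncs)
  g <- vapply(traj$frames, compute_G, 0, ncs = ncs)
  data.frame(frame = seq_along(q),
             time_ns = seq_along(q) * traj$frame_interval, Q = q, G = g)
}

# Mode of values binned at `binwidth` (values snapped to the bin grid); ties
# resolved toward the smaller value for determinism.
binned_mode <- function(x, binwidth) {
  xb <- round(x / binwidth) * binwidth
  tab <- table(xb)
  as.numeric(names(tab)[which.max(tab)])
}

#' Native-state thresholds on Q and G from reference simulations
#'
#' Each reference trajectory is cut into consecutive 15-ns (default) windows;
#' the mode of Q and of G is taken in each window (binned at 1/N_ref, the
#' natural resolution of a fraction over N_ref contacts). Thresholds are
#' mean(modes) - 3 sd(modes) for Q and mean(modes) + 3 sd(modes) for G.
#'
#' @param ref_ops list of per-reference order-parameter data.frames from
#'   [trajectory_order_params()] (must carry `Q`, `G`, `time_ns`).
#' @param window_ns sliding-window size in ns (default 15).
#' @param n_ref number of native contacts (sets the mode bin width 1/n_ref).
#' @return list(q_threshold, g_threshold, q_modes, g_modes).
#' @export
reference_thresholds <- function(ref_ops, window_ns = 15, n_ref = 100L) {
  bw <- 1 / n_ref
  qm <- c(); gm <- c()
  for (op in ref_ops) {
    dt <- diff(op$time_ns[1:2])
    w <- max(1L, round(window_ns / dt))
    if (w > nrow(op)) stop("window longer than trajectory")
    starts <- seq(1L, nrow(op) - w + 1L, by = w)
    for (s in starts) {
      idx <- s:(s + w - 1L)
      qm <- c(qm, binned_mode(op$Q[idx], bw))
      gm <- c(gm, binned_mode(op$G[idx], bw))
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(q_threshold = mean(qm) - 3 * sd0(qm),
       g_threshold = mean(gm) + 3 * sd0(gm),
       q_modes = qm, g_modes = gm)
}

#' Classify frames as native or non-native
#'
#' A frame is native when Q >= q_threshold and G <= g_threshold (both
#' boundaries inclusive); everything else is non-native.
#'
#' @param op order-parameter data.frame with Q and G.
#' @param th thresholds from [reference_thresholds()].
#' @return logical vector, TRUE = native.
#' @export
classify_frames <- function(op, th) {
  op$Q >= th$q_threshold & op$G <= th$g_threshold
}

#' Misfolding propensity over the final trajectory window
#'
#' Fraction of non-native frames in the last `last_fraction` of each quench
#' trajectory, pooled across trajectories, with a basic bootstrap CI over
#' trajectories.
#'
#' @param quench_ops list of order-parameter data.frames (one per quench
#'   trajectory).
#' @param th thresholds.
#' @param last_fraction final fraction of frames analysed (default 0.1,
#'   i.e. the last 200 ns of a 2-mus quench).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return list(propensity, ci, per_trajectory).
#' @export
misfolding_propensity <- function(quench_ops, th, last_fraction = 0.1,
                                  n_boot = 10000, seed = 1) {
  frac <- vapply(quench_ops, function(op) {
    n <- nrow(op)
    idx <- seq.int(max(1L, n - ceiling(last_fraction * n) + 1L), n)
    mean(!classify_frames(op[idx, , drop = FALSE], th))
  }, 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  list(propensity = mean(frac),
       ci = if (length(frac) > 1) basic_bootstrap_ci(frac, n_boot)
            else c(low = mean(frac), high = mean(frac)),
       per_trajectory = frac)
}

#' Mean lifetime of the misfolded state
#'
#' Mean length (in frames) of maximal runs of consecutive non-native frames,
#' multiplied by the frame interval. Zero when no frame is misfolded.
#'
#' @param native logical per-frame vector (TRUE = native).
#' @param frame_interval ns per frame (default 0.075).
#' @return lifetime in ns.
#' @export
misfolded_lifetime <- function(native, frame_interval = 0.075) {
  r <- rle(!native)
  runs <- r$lengths[r$values]
  if (!length(runs)) return(0)
  mean(runs) * frame_interval
}

# ---- Mechanism classification -------------------------------------------

ncle_windows <- function(loop, crossings, pad = 3L) {
  anchors <- c(loop, crossings)
  cbind(lo = anchors - pad, hi = anchors + pad)
}

windows_overlap <- function(w1, w2) {
  for (a in seq_len(nrow(w1))) for (b in seq_len(nrow(w2))) {
    if (w1[a, "lo"] <= w2[b, "hi"] && w2[b, "lo"] <= w1[a, "hi"]) return(TRUE)
  }
  FALSE
}

#' Reference entanglement state for mechanism analysis
#'
#' Detects the unique native NCLEs of the reference conformation using the
#' C-alpha native-contact loops, recording for each its representative loop,
#' crossings and rounded linking states.
#'
#' @param ref_xyz reference C-alpha coordinates.
#' @param ncs [native_contact_set()] of the same reference.
#' @param g_threshold entanglement threshold (default 0.6).
#' @return list of reference NCLE descriptors.
#' @export
reference_ncles <- function(ref_xyz, ncs, g_threshold = 0.6) {
  ref_xyz <- as_xyz_matrix(ref_xyz)
  ent <- which(abs(ncs$g_ref_N) >= g_threshold | abs(ncs$g_ref_C) >= g_threshold)
  raw <- lapply(ent, function(k) {
    cr <- find_crossings(ref_xyz, c(ncs$i[k], ncs$j[k]))
    keep <- (cr$terminus == "N" & abs(ncs$g_ref_N[k]) >= g_threshold) |
      (cr$terminus == "C" & abs(ncs$g_ref_C[k]) >= g_threshold)
    r <- list(loop = c(i = ncs$i[k], j = ncs$j[k]),
              gN = ncs$g_ref_N[k], gC = ncs$g_ref_C[k],
              crossings = cr[keep, , drop = FALSE])
    class(r) <- "raw_ncle"
    r
  })
  cluster_ncles(raw)
}

#' Classify the misfolding mechanism of a frame
#'
#' Losses are reference unique NCLEs whose rounded linking state at the
#' representative loop has changed in the frame (the native entanglement is
#' absent); gains are native-contact loops that are entangled in the frame
#' (|g| >= threshold) but were not in the reference (rounded state changed
#' from the reference state). Gains are clustered into unique NCLEs. The
#' class is loss_only / gain_only / both / native by set emptiness.
#'
#' @param frame C-alpha coordinates of the frame.
#' @param ncs [native_contact_set()].
#' @param ref_ncles output of [reference_ncles()].
#' @param g_threshold entanglement threshold (default 0.6).
#' @return `mechanism_call`: list(class, lost, gained).
#' @export
classify_mechanism <- function(frame, ncs, ref_ncles, g_threshold = 0.6) {
  frame <- as_xyz_matrix(frame)
  st <- frame_linking_states(frame, ncs)
  key <- paste(ncs$i, ncs$j)
  lost <- list()
  for (u in ref_ncles) {
    r <- u$representative
    k <- match(paste(r$loop[1], r$loop[2]), key)
    changed <- st[k, "state_N"] != ncs$state_ref_N[k] ||
      st[k, "state_C"] != ncs$state_ref_C[k]
    if (changed) lost[[length(lost) + 1L]] <- r
  }
  gained_idx <- which((abs(st[, "gN"]) >= g_threshold &
                         st[, "state_N"] != ncs$state_ref_N) |
                        (abs(st[, "gC"]) >= g_threshold &
                           st[, "state_C"] != ncs$state_ref_C))
  gained_raw <- lapply(gained_idx, function(k) {
    cr <- find_crossings(frame, c(ncs$i[k], ncs$j[k]))
    r <- list(loop = c(i = ncs$i[k], j = ncs$j[k]),
              gN = st[k, "gN"], gC = st[k, "gC"], crossings = cr)
    class(r) <- "raw_ncle"
    r
  })
  gained <- lapply(cluster_ncles(gained_raw), function(u) u$representative)
  cls <- if (length(lost) && length(gained)) "both"
  else if (length(lost)) "loss_only"
  else if (length(gained)) "gain_only"
  else "native"
  structure(list(class = cls, lost = lost, gained = gained),
            class = "mechanism_call")
}

#' Mechanism probabilities across trajectories
#'
#' Within each trajectory, counts of misfolded structures exhibiting only a
#' loss of native NCLE, only a gain of non-native NCLE, or both, are
#' normalised by their sum; probabilities are then averaged over
#' trajectories. Trajectories with no misfolded structure are excluded.
#'
#' @param calls_per_traj list (per trajectory) of lists of `mechanism_call`.
#' @return named vector c(only_loss, only_gain, both), summing to 1 when any
#'   misfolded structure exists.
#' @export
mechanism_probabilities <- function(calls_per_traj) {
  per <- lapply(calls_per_traj, function(calls) {
    cl <- vapply(calls, function(x) x$class, "")
    n <- c(only_loss = sum(cl == "loss_only"), only_gain = sum(cl == "gain_only"),
           both = sum(cl == "both"))
    if (sum(n) == 0) NULL else n / sum(n)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (!length(per)) stop("no misfolded structures in any trajectory")
  Reduce(`+`, per) / length(per)
}

#' Structural interdependence of NCLE losses and gains
#'
#' Over structures containing both a loss and a gain, the conditional
#' probability that a lost native NCLE shares primary-structure windows
#' (loop-closing contact residues +/- 3 and crossing residues +/- 3) with at
#' least one gained non-native NCLE in the same structure; per-trajectory
#' fractions are averaged over trajectories.
#'
#' @param calls_per_traj list (per trajectory) of lists of `mechanism_call`.
#' @param pad window half-width (default 3).
#' @return probability, or NA_real_ when no structure has both.
#' @export
interdependence_probability <- function(calls_per_traj, pad = 3L) {
  per <- vapply(calls_per_traj, function(calls) {
    n_loss <- 0L; n_overlap <- 0L
    for (x in calls) {
      if (x$class != "both") next
      gw <- lapply(x$gained, function(g)
        ncle_windows(g$loop, g$crossings$residue, pad))
      for (l in x$lost) {
        lw <- ncle_windows(l$loop, l$crossings$residue, pad)
        n_loss <- n_loss + 1L
        if (any(vapply(gw, function(w2) windows_overlap(lw, w2), TRUE))) {
          n_overlap <- n_overlap + 1L
        }
      }
    }
    if (n_loss == 0) NA_real_ else n_overlap / n_loss
  }, 0)
  if (all(is.na(per))) return(NA_real_)
  mean(per, na.rm = TRUE)
}
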