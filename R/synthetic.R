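# Seeded generators for every input class the pipeline consumes. Each
# returns its data plus a recorded ground truth, and is bit-reproducible
# from its arguments (one RNG stream, seeded explicitly; caller RNG state is
# restored on exit).

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

pseudo_heavy_atoms <- function(residues) {
  # four dummy heavy atoms per residue on a fixed local frame, so heavy-atom
  # contact logic is exercised without side-chain modelling
  offs <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5))
  n <- nrow(residues)
  data.frame(
    seq_index = rep(residues$seq_index, each = 4),
    elety = rep(c("CA", "CB", "CG", "CD"), n),
    elem = "C",
    x = rep(residues$x, each = 4) + rep(offs[, 1], n),
    y = rep(residues$y, each = 4) + rep(offs[, 2], n),
    z = rep(residues$z, each = 4) + rep(offs[, 3], n),
    stringsAsFactors = FALSE
  )
}

xyz_to_structure <- function(xyz, protein_id = "synthetic", heavy = TRUE) {
  residues <- data.frame(seq_index = seq_len(nrow(xyz)), aa = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE)
  new_structure(protein_id, "A", residues,
                atoms = if (heavy) pseudo_heavy_atoms(residues) else NULL,
                source = "crystal")
}

#' Synthetic lasso curve with known threading topology
#'
#' Builds a backbone polyline consisting of an N-terminal straight thread
#' descending through (or past) a planar circular loop, a 4-residue
#' connector routed outside the loop, and the loop itself, whose first and
#' last residues close it (pseudo heavy atoms guarantee the 4.5 A closing
#' contact). The thread pierces the loop plane at a known residue when
#' `pierce_offset < loop_radius`; larger offsets give an unthreaded control.
#'
#' @param loop_radius loop radius in A (default 8).
#' @param n_loop_points residues on the loop (default 40).
#' @param thread_length thread residues (default 15; >= 15 keeps the
#'   piercing bond inside the tail Gauss-sum bounds).
#' @param pierce_offset lateral offset of the thread from the loop centre, A.
#' @param mirror reflect the curve (flips chirality and crossing sign).
#' @param jitter_sd Gaussian positional noise in A (default 0).
#' @param seed RNG seed (used only when jitter_sd > 0).
#' @return list: `xyz`, `structure` (`ncle_structure` with pseudo heavy
#'   atoms), `ground_truth` (loop indices, expected entanglement, expected
#'   crossing residue).
#' @export
make_lasso_curve <- function(loop_radius = 8, n_loop_points = 40,
                             thread_length = 15, pierce_offset = 0,
                             mirror = FALSE, jitter_sd = 0, seed = 1) {
  if (loop_radius <= 0 || n_loop_points < 12 || thread_length < 15) {
    stop("degenerate geometry: need loop_radius > 0, n_loop_points >= 12, thread_length >= 15")
  }
  tc <- floor(thread_length / 2) + 1L  # bond crossing the loop plane
  zk <- 3.8 * (tc - seq_len(thread_length)) + 1.9
  tail <- cbind(pierce_offset, 0, zk)
  z_end <- zk[thread_length]
  rr <- loop_radius
  conn <- rbind(c(pierce_offset + (rr + 4 - pierce_offset) * 0.4, 0, z_end * 0.8),
                c(rr + 4, 0, z_end * 0.5),
                c(rr + 4, 0, z_end * 0.15),
                c(rr + 4, 0, 0))
  th <- 2 * pi * (seq_len(n_loop_points) - 1) / n_loop_points
  loop <- cbind(rr * cos(th), rr * sin(th), 0)
  xyz <- rbind(tail, conn, loop)
  if (mirror) xyz[, 2] <- -xyz[, 2]
  if (jitter_sd > 0) {
    xyz <- xyz + with_seed(seed, matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                                        ncol = 3))
  }
  i <- thread_length + 5L
  j <- thread_length + 4L + n_loop_points
  gt <- list(loop = c(i = i, j = j),
             entangled = abs(pierce_offset) < loop_radius,
             crossing_residue = if (abs(pierce_offset) < loop_radius) tc else NA_integer_,
             terminus = "N")
  list(xyz = xyz, structure = xyz_to_structure(xyz, "lasso"), ground_truth = gt)
}

#' Two interlocked (Hopf-link) or separated rings
#'
#' Classic Gauss-linking oracle geometry: two circles of equal radius, the
#' second lying in a perpendicular plane through the first's circumference
#' (linking number +/- 1), or displaced far away (`separated = TRUE`,
#' linking ~ 0).
#'
#' @param n_points points per ring (>= 20).
#' @param radius ring radius, A (default 5).
#' @param separated displace the second ring so the rings are unlinked.
#' @param reverse reverse the second ring's traversal (flips the sign).
#' @return list(ring1, ring2): n x 3 coordinate matrices (open point lists;
#'   [gauss_linking()] closes them).
#' @export
make_interlocked_rings <- function(n_points = 100, radius = 5,
                                   separated = FALSE, reverse = FALSE) {
  if (n_points < 20) stop("n_points must be >= 20")
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  ring1 <- cbind(radius * cos(th), radius * sin(th), 0)
  cx <- if (separated) 4 * radius else radius
  ring2 <- cbind(cx + radius * cos(th), 0, radius * sin(th))
  if (reverse) ring2 <- ring2[rev(seq_len(n_points)), ]
  list(ring1 = ring1, ring2 = ring2)
}

#' Synthetic treated/untreated peptide abundance table
#'
#' Emulates a LiP-MS experiment: per protein, proteinase-K cut-sites are
#' scattered on a 200-residue sequence whose residues 51-120 form the
#' planted "NCLE region". A site is planted as affected with base
#' probability `base_rate` outside the region and with the probability that
#' realises `planted_region_or` on the odds scale inside it. Affected sites'
#' treated abundances are shifted by `effect_fold` (in at least one
#' timepoint; with probability `shared_fraction` in all three). Untreated
#' abundances are log-normal; replicates add small log-normal noise.
#'
#' @param n_proteins number of proteins (default 50).
#' @param sites_per_protein cut-sites per protein (default 10).
#' @param planted_region_or planted odds ratio of being affected given
#'   region membership (>= 1).
#' @param effect_fold fold change applied to affected sites (default 4).
#' @param n_replicates replicates per condition (default 3).
#' @param base_rate P(affected | non-region) (default 0.15).
#' @param shared_fraction probability an affected site is affected in all
#'   timepoints (default 0.72).
#' @param spa_meanlog,spa_sdlog log-normal abundance law (defaults 10, 1).
#' @param seed RNG seed.
#' @return list(peptides = data.frame in the pipeline's input format,
#'   lengths, ground_truth = per-site truth table).
#' @export
simulate_peptide_table <- function(n_proteins = 50, sites_per_protein = 10,
                                   planted_region_or = 2, effect_fold = 4,
                                   n_replicates = 3, base_rate = 0.15,
                                   shared_fraction = 0.72,
                                   spa_meanlog = 10, spa_sdlog = 1, seed = 1) {
  if (planted_region_or < 1) stop("planted_region_or must be >= 1")
  odds0 <- base_rate / (1 - base_rate)
  p1 <- planted_region_or * odds0 / (1 + planted_region_or * odds0)
  if (p1 >= 1) stop("infeasible odds ratio for this base rate")
  L <- 200L; region <- 51:120
  tps <- c("1min", "5min", "2h")
  with_seed(seed, {
    rows <- list(); truth <- list()
    for (p in seq_len(n_proteins)) {
      pid <- sprintf("P%04d", p)
      sites <- sort(sample(5:(L - 5), sites_per_protein))
      in_region <- sites %in% region
      affected <- stats::rbinom(sites_per_protein, 1,
                                ifelse(in_region, p1, base_rate)) == 1
      base_ab <- stats::rlnorm(sites_per_protein, spa_meanlog, spa_sdlog)
      for (s in seq_along(sites)) {
        tp_affected <- if (affected[s] && effect_fold != 1) {
          if (stats::runif(1) < shared_fraction) tps else sample(tps, 1)
        } else character()
        for (r in seq_len(n_replicates)) {
          noise <- function() stats::rlnorm(1, 0, 0.1)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, start = sites[s] - 4L, end = sites[s] + 5L,
            half_tryptic = TRUE, pk_site = sites[s], condition = "untreated",
            timepoint = NA_character_, replicate = r,
            abundance = base_ab[s] * noise(), stringsAsFactors = FALSE)
          for (tp in tps) {
            fold <- if (tp %in% tp_affected) effect_fold else 1
            rows[[length(rows) + 1L]] <- data.frame(
              protein_id = pid, start = sites[s] - 4L, end = sites[s] + 5L,
              half_tryptic = TRUE, pk_site = sites[s], condition = "treated",
              timepoint = tp, replicate = r,
              abundance = base_ab[s] * fold * noise(), stringsAsFactors = FALSE)
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = pid, residue = sites[s], in_region = in_region[s],
          affected = affected[s], stringsAsFactors = FALSE)
      }
    }
    list(peptides = do.call(rbind, rows),
         lengths = stats::setNames(rep(L, n_proteins),
                                   sprintf("P%04d", seq_len(n_proteins))),
         ground_truth = do.call(rbind, truth))
  })
}

#' Synthetic residue dataset with a planted region log-odds effect
#'
#' Generates residue rows (protein_id, residue, x_region, aa, sasa,
#' y_cutsite) from the logistic model
#' logit P(y = 1) = beta0 + beta_region x_region + beta_aa(aa) [+ confound],
#' optionally with a SASA-mediated confounding channel: NCLE-region residues
#' are systematically more buried, and burial itself raises the cut-site
#' log-odds, so the crude region OR exceeds the planted one.
#'
#' @param n_residues total rows (default 10000).
#' @param beta_region planted region log-odds (default 0).
#' @param beta0 intercept (default -2).
#' @param aa_effects named log-odds per amino acid (default all 0).
#' @param burial_confounding logical; enable the SASA channel.
#' @param burial_shift mean SASA deficit (A^2) of region residues when
#'   confounded (default 15).
#' @param confound_strength log-odds per SD of burial (default 0.8).
#' @param region_rate P(x_region = 1) (default 0.3).
#' @param residues_per_protein block size for protein ids (default 200).
#' @param seed RNG seed.
#' @return list(data = data.frame, ground_truth).
#' @export
simulate_residue_dataset <- function(n_residues = 10000, beta_region = 0,
                                     beta0 = -2, aa_effects = NULL,
                                     burial_confounding = FALSE,
                                     burial_shift = 15,
                                     confound_strength = 0.8,
                                     region_rate = 0.3,
                                     residues_per_protein = 200L, seed = 1) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  eff <- stats::setNames(rep(0, 20), aas)
  if (!is.null(aa_effects)) eff[names(aa_effects)] <- aa_effects
  with_seed(seed, {
    x <- stats::rbinom(n_residues, 1, region_rate)
    aa <- sample(aas, n_residues, replace = TRUE)
    mu_sasa <- 80 - ifelse(burial_confounding & x == 1, burial_shift, 0)
    sasa <- pmax(0, stats::rnorm(n_residues, mu_sasa, 25))
    lin <- beta0 + beta_region * x + eff[aa]
    if (burial_confounding) lin <- lin + confound_strength * (65 - sasa) / 25
    y <- stats::rbinom(n_residues, 1, stats::plogis(lin))
    pid <- sprintf("P%04d", (seq_len(n_residues) - 1) %/% residues_per_protein + 1)
    d <- data.frame(protein_id = pid,
                    residue = (seq_len(n_residues) - 1) %% residues_per_protein + 1,
                    x_region = x, aa = aa, sasa = sasa, y_cutsite = y,
                    stringsAsFactors = FALSE)
    list(data = d,
         ground_truth = list(beta_region = beta_region, beta0 = beta0,
                             aa_effects = eff,
                             burial_confounding = burial_confounding))
  })
}

#' Synthetic NCLE feature table with planted class separation
#'
#' Eighteen standard-normal features; labels drawn from a logistic link on
#' the first `informative_features` of them with slope `effect_size`.
#'
#' @param n rows (default 500).
#' @param informative_features count of informative features (<= 18).
#' @param effect_size log-odds slope per informative feature (default 2).
#' @param seed RNG seed.
#' @return list(features = n x 18 matrix, labels, ground_truth).
#' @export
simulate_feature_table <- function(n = 500, informative_features = 1,
                                   effect_size = 2, seed = 1) {
  if (informative_features > 18) stop("at most 18 informative features")
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * 18), n, 18,
                dimnames = list(NULL, paste0("f", sprintf("%02d", 1:18))))
    lin <- if (informative_features > 0) {
      x[, seq_len(informative_features), drop = FALSE] %*%
        rep(effect_size, informative_features)
    } else rep(0, n)
    y <- stats::rbinom(n, 1, stats::plogis(lin))
    # guard against degenerate single-class draws at extreme effects
    if (length(unique(y)) == 1) y[1:2] <- c(0L, 1L)
    list(features = x, labels = y,
         ground_truth = list(informative = colnames(x)[seq_len(informative_features)],
                             effect_size = effect_size))
  })
}

# Reference two-loop curve used by simulate_trajectory: an N-terminal thread
# that (optionally) pierces loop A, a connector, loop A, a connector, loop B.
two_loop_curve <- function(thread_length = 25L, loop_points = 30L, radius = 8,
                           thread_at = c(0, 0), crossing_residue = 13L,
                           conn2_length = 4L) {
  zk <- 3.8 * (crossing_residue - seq_len(thread_length)) + 1.9
  tail <- cbind(thread_at[1], thread_at[2], zk)
  z_end <- zk[thread_length]
  # connector from the (movable) thread end to a fixed anchor outside loop A:
  # first step is perpendicular to the thread (so thread and connector never
  # come within C-alpha contact range at sequence separation >= 4), then the
  # path rises to the anchor staying below the loop plane
  tail_end <- c(thread_at[1], thread_at[2], z_end)
  anchor <- c(radius + 4, 0, 0)
  conn1 <- rbind(tail_end + c(8, 0, 2),
                 c(radius + 5, thread_at[2] * 0.5, z_end * 0.55),
                 c(radius + 5, thread_at[2] * 0.15, z_end * 0.18),
                 anchor)
  th <- 2 * pi * (seq_len(loop_points) - 1) / loop_points
  loopA <- cbind(radius * cos(th), radius * sin(th), 0)
  endA <- loopA[loop_points, ]
  # route the inter-loop connector above the loop plane, clear of both loop
  # surfaces and of the movable thread/connector paths
  xs <- seq(radius + 2, 30 - radius - 2, length.out = conn2_length)
  zs <- c(4, rep(9, max(0L, conn2_length - 2L)), 4)[seq_len(conn2_length)]
  conn2 <- cbind(xs, c(endA[2] / 2, rep(0, conn2_length - 1L)), zs)
  loopB <- cbind(30 + radius * cos(pi + th), radius * sin(pi + th), 0)
  xyz <- rbind(tail, conn1, loopA, conn2, loopB)
  iA <- thread_length + 5L; jA <- thread_length + 4L + loop_points
  iB <- jA + conn2_length + 1L; jB <- iB + loop_points - 1L
  list(xyz = xyz, loopA = c(iA, jA), loopB = c(iB, jB),
       thread_length = thread_length)
}

#' Scripted misfolding trajectory with known mechanism ground truth
#'
#' The reference conformation is a two-loop curve whose N-terminal thread
#' pierces loop A (when `native_threaded`). Scripted events switch the
#' conformation at given times: `retract_thread` moves the thread out of
#' loop A (a loss of the native NCLE), `rethread` threads it through loop B
#' (a gain of a non-native NCLE; combined with a prior retraction the frame
#' class is "both"), and `break_contacts` uniformly expands the chain
#' (breaking native contacts without changing entanglement). Gaussian
#' positional noise is added per frame.
#'
#' @param n_frames frames (default 100).
#' @param events list of `list(time_ns =, kind =)` with kind in
#'   "retract_thread", "rethread", "break_contacts"; `rethread` accepts
#'   `crossing_residue` (default 13, the native crossing; larger values move
#'   the gained crossing away along the thread).
#' @param frame_interval ns per frame (default 0.075).
#' @param noise_sd Gaussian coordinate noise, A (default 0.05).
#' @param native_threaded native thread pierces loop A (default TRUE).
#' @param conn2_length residues in the connector between the two loops
#'   (default 4; >= 10 separates the loops' +/- 3 windows so a rethread at a
#'   distant crossing residue plants a non-interdependent loss-gain event).
#' @param seed RNG seed.
#' @return list: `reference` (xyz), `trajectory` (`ncle_trajectory`),
#'   `ground_truth` (per-frame class), `loops`.
#' @export
simulate_trajectory <- function(n_frames = 100, events = list(),
                                frame_interval = 0.075, noise_sd = 0.05,
                                native_threaded = TRUE, conn2_length = 4L,
                                seed = 1) {
  times <- vapply(events, function(e) e$time_ns, 0)
  if (is.unsorted(times)) stop("events must be ordered in time")
  ref <- two_loop_curve(thread_at = if (native_threaded) c(0, 0) else c(0, -20),
                        conn2_length = conn2_length)
  T_ <- ref$thread_length
  tail_rows <- seq_len(T_ + 4L)  # thread plus its connector follow the events
  retracted_tail <- two_loop_curve(thread_at = c(0, -20))$xyz[tail_rows, ]
  state <- list(retracted = FALSE, rethreaded = FALSE, scale = 1,
                rethread_cross = 13L)
  gt_class <- character(n_frames)
  gt_native <- logical(n_frames)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    t_ns <- f * frame_interval
    for (e in events) {
      if (t_ns >= e$time_ns) {
        if (e$kind == "retract_thread") state$retracted <<- TRUE
        if (e$kind == "rethread") {
          state$rethreaded <<- TRUE
          state$rethread_cross <<- e$crossing_residue %||% 13L
        }
        if (e$kind == "break_contacts") state$scale <<- 1.5
      }
    }
    xyz <- ref$xyz
    if (state$rethreaded) {
      xyz[tail_rows, ] <- two_loop_curve(
        thread_at = c(30, 0),
        crossing_residue = state$rethread_cross)$xyz[tail_rows, ]
    } else if (state$retracted) {
      xyz[tail_rows, ] <- retracted_tail
    }
    xyz <- xyz * state$scale
    lost <- native_threaded && (state$retracted || state$rethreaded)
    gained <- state$rethreaded
    gt_class[f] <<- if (lost && gained) "both" else if (lost) "loss_only"
    else if (gained) "gain_only" else "native"
    gt_native[f] <<- gt_class[f] == "native" && state$scale == 1
    xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd), ncol = 3)
  }))
  traj <- new_trajectory(frames, frame_interval, "scripted",
                         kind = if (length(events)) "quench" else "reference")
  list(reference = ref$xyz, trajectory = traj,
       ground_truth = data.frame(frame = seq_len(n_frames),
                                 time_ns = seq_len(n_frames) * frame_interval,
                                 class = gt_class, native = gt_native),
       loops = list(A = ref$loopA, B = ref$loopB))
}
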