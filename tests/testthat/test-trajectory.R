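# shared reference geometry for the trajectory tests
traj_ref <- simulate_trajectory(n_frames = 2, noise_sd = 0, seed = 1)$reference
traj_ncs <- native_contact_set(traj_ref)

test_that("Q and G are exact on the reference and bounded in general", {
  expect_equal(compute_Q(traj_ref, traj_ncs), 1)
  expect_equal(compute_G(traj_ref, traj_ncs), 0)
  # fully extended chain: all distances exceed 1.2 x native
  n <- nrow(traj_ref)
  extended <- cbind(3.8 * seq_len(n), 0, 0)
  expect_equal(compute_Q(extended, traj_ncs), 0)
  # uniform expansion beyond the 1.2 margin also kills Q but leaves G at 0
  expect_equal(compute_Q(traj_ref * 1.5, traj_ncs), 0)
  expect_equal(compute_G(traj_ref * 1.5, traj_ncs), 0)  # linking is scale-free
})

test_that("Q counts exactly the satisfied contacts on a hand-built set", {
  ncs <- data.frame(i = c(1, 1, 2, 3), j = c(5, 6, 7, 8),
                    d_ref = c(5, 5, 5, 5), in_ss = TRUE,
                    g_ref_N = 0, g_ref_C = 0, state_ref_N = 0, state_ref_C = 0)
  class(ncs) <- c("native_contact_set", "data.frame")
  # frame: residues on a line; distances |i-j| * 2 -> contacts (1,5),(1,6)
  # at 8, 10 vs threshold 6; place so exactly two pass
  frame <- cbind(c(0, 1, 2, 3, 4, 5.9, 2.1, 8.9), 0, 0)
  # d(1,5)=4 ok; d(1,6)=5.9 ok (<=6); d(2,7)=1.1 ok... adjust to exactly 2
  frame <- cbind(c(0, 0, 0, 0, 4, 5.9, 20, 30), 0, 0)
  expect_equal(compute_Q(frame, ncs), 0.5)
})

test_that("the secondary-structure filter restricts Q but not G", {
  ss <- unique(c(traj_ncs$i, traj_ncs$j))
  ss <- ss[ss > 29]  # drop thread residues from the ss set
  ncs_ss <- native_contact_set(traj_ref, ss = ss)
  expect_lt(sum(ncs_ss$in_ss), nrow(ncs_ss))
  expect_equal(nrow(ncs_ss), nrow(traj_ncs))
  expect_equal(compute_Q(traj_ref, ncs_ss), 1)
  expect_equal(compute_G(traj_ref, ncs_ss), 0)
})

test_that("rigid motion of a frame changes neither Q, G nor classification", {
  sim <- simulate_trajectory(n_frames = 5, events = list(
    list(time_ns = 0.15, kind = "retract_thread")), seed = 3)
  f <- sim$trajectory$frames[[4]]
  moved <- rigid_transform(f)
  expect_equal(compute_Q(moved, traj_ncs), compute_Q(f, traj_ncs),
               tolerance = 1e-12)
  expect_equal(compute_G(moved, traj_ncs), compute_G(f, traj_ncs))
})

test_that("threshold arithmetic matches hand-computed window modes", {
  # constant series: thresholds equal the constants (sigma = 0)
  op_const <- data.frame(time_ns = (1:40) * 0.075, Q = 0.9, G = 0.05)
  th <- reference_thresholds(list(op_const), window_ns = 0.75, n_ref = 20)
  expect_equal(th$q_threshold, 0.9)
  expect_equal(th$g_threshold, 0.05)
  # two windows with modes 0.9 and 0.8
  op2 <- data.frame(time_ns = (1:20) * 0.075,
                    Q = rep(c(0.9, 0.8), each = 10),
                    G = rep(c(0, 0.1), each = 10))
  th2 <- reference_thresholds(list(op2), window_ns = 0.75, n_ref = 10)
  expect_equal(th2$q_threshold, 0.85 - 3 * sd(c(0.9, 0.8)))
  expect_equal(th2$g_threshold, 0.05 + 3 * sd(c(0, 0.1)))
  expect_error(reference_thresholds(list(op_const), window_ns = 10, n_ref = 5),
               "window longer")
})

test_that("frame classification is boundary-inclusive", {
  th <- list(q_threshold = 0.8, g_threshold = 0.1)
  op <- data.frame(Q = c(0.8, 0.85, 0.79, 0.9), G = c(0.1, 0.05, 0.0, 0.2))
  expect_equal(classify_frames(op, th), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("reference trajectories classify as native (self-consistency)", {
  refs <- lapply(1:3, function(s) simulate_trajectory(n_frames = 80, seed = s))
  ops <- lapply(refs, function(r) trajectory_order_params(r$trajectory, traj_ncs))
  th <- reference_thresholds(ops, window_ns = 1.5, n_ref = nrow(traj_ncs))
  for (op in ops) expect_gte(mean(classify_frames(op, th)), 0.99)
})

test_that("misfolding propensity recovers planted non-native fractions", {
  refs <- lapply(1:2, function(s) simulate_trajectory(n_frames = 60, seed = s))
  ops <- lapply(refs, function(r) trajectory_order_params(r$trajectory, traj_ncs))
  th <- reference_thresholds(ops, window_ns = 1.5, n_ref = nrow(traj_ncs))
  # retraction at 60% of the run: last 50% of frames are half native
  q <- simulate_trajectory(n_frames = 60,
                           events = list(list(time_ns = 2.7, kind = "retract_thread")),
                           seed = 5)
  opq <- trajectory_order_params(q$trajectory, traj_ncs)
  mp <- misfolding_propensity(list(opq), th, last_fraction = 0.5, n_boot = 50)
  planted <- mean(!q$ground_truth$native[31:60])
  expect_equal(mp$propensity, planted)
  # all native / all non-native limits
  expect_equal(misfolding_propensity(list(ops[[1]]), th, n_boot = 10)$propensity, 0)
  q2 <- simulate_trajectory(n_frames = 40,
                            events = list(list(time_ns = 0.075, kind = "retract_thread")),
                            seed = 6)
  op2 <- trajectory_order_params(q2$trajectory, traj_ncs)
  expect_equal(misfolding_propensity(list(op2), th, n_boot = 10)$propensity, 1)
})

test_that("misfolded lifetime is the mean run length times the frame interval", {
  expect_equal(misfolded_lifetime(rep(FALSE, 1000)), 1000 * 0.075)
  expect_equal(misfolded_lifetime(rep(c(TRUE, FALSE), 50)), 0.075)
  expect_equal(misfolded_lifetime(rep(TRUE, 10)), 0)
  nat <- c(rep(TRUE, 5), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 20))
  expect_equal(misfolded_lifetime(nat), 15 * 0.075)
  # bimodal run lengths split at the dataset median
  lt <- c(misfolded_lifetime(c(rep(FALSE, 4), rep(TRUE, 36))),
          misfolded_lifetime(c(rep(FALSE, 30), rep(TRUE, 10))))
  expect_true(lt[1] < median(lt) && lt[2] >= median(lt))
})

test_that("mechanism classes match the scripted ground truth exactly", {
  refn <- reference_ncles(traj_ref, traj_ncs)
  sims <- list(
    simulate_trajectory(n_frames = 30, events = list(
      list(time_ns = 1.125, kind = "retract_thread")), seed = 11),
    simulate_trajectory(n_frames = 30, events = list(
      list(time_ns = 0.75, kind = "retract_thread"),
      list(time_ns = 1.5, kind = "rethread")), seed = 12))
  for (sim in sims) {
    calls <- lapply(sim$trajectory$frames, classify_mechanism,
                    ncs = traj_ncs, ref_ncles = refn)
    got <- vapply(calls, function(x) x$class, "")
    expect_equal(got, sim$ground_truth$class)
  }
  # gain-only needs an unthreaded native state and its own contact set
  g <- simulate_trajectory(n_frames = 20, events = list(
    list(time_ns = 0.45, kind = "rethread")), native_threaded = FALSE, seed = 13)
  ncs_g <- native_contact_set(g$reference)
  refn_g <- reference_ncles(g$reference, ncs_g)
  expect_length(refn_g, 0)
  got_g <- vapply(g$trajectory$frames, function(f)
    classify_mechanism(f, ncs_g, refn_g)$class, "")
  expect_equal(got_g, g$ground_truth$class)
})

test_that("mechanism probabilities average per trajectory and sum to one", {
  mk_call <- function(cl) structure(list(class = cl, lost = list(),
                                         gained = list()),
                                    class = "mechanism_call")
  t1 <- lapply(c(rep("loss_only", 5), "gain_only", rep("both", 4)), mk_call)
  expect_equal(mechanism_probabilities(list(t1)),
               c(only_loss = 0.5, only_gain = 0.1, both = 0.4))
  t2 <- list(mk_call("loss_only"))
  t3 <- list(mk_call("gain_only"))
  expect_equal(mechanism_probabilities(list(t2, t3)),
               c(only_loss = 0.5, only_gain = 0.5, both = 0))
  expect_equal(sum(mechanism_probabilities(list(t1, t2, t3))), 1)
  expect_error(mechanism_probabilities(list(list(mk_call("native")))),
               "no misfolded")
})

test_that("interdependence window arithmetic and planted recovery", {
  mk_ncle <- function(i, j, cross) {
    structure(list(loop = c(i = i, j = j), gN = -0.9, gC = 0,
                   crossings = data.frame(residue = cross, sign = -1L,
                                          terminus = "N")),
              class = "raw_ncle")
  }
  both_call <- function(lost, gained) {
    structure(list(class = "both", lost = lost, gained = gained),
              class = "mechanism_call")
  }
  # gain crossing at 48 is within +/- 3 of the lost loop end 50
  overlap <- both_call(list(mk_ncle(10, 50, 30)), list(mk_ncle(60, 90, 48)))
  expect_equal(interdependence_probability(list(list(overlap))), 1)
  # disjoint halves of the chain
  disjoint <- both_call(list(mk_ncle(10, 30, 5)), list(mk_ncle(60, 90, 45)))
  expect_equal(interdependence_probability(list(list(disjoint))), 0)
  expect_true(is.na(interdependence_probability(list(list()))))

  # scripted: rethread at the native crossing overlaps; far crossing does not
  near <- simulate_trajectory(n_frames = 20, events = list(
    list(time_ns = 0.3, kind = "retract_thread"),
    list(time_ns = 0.6, kind = "rethread", crossing_residue = 13)),
    conn2_length = 10, seed = 14)
  far <- simulate_trajectory(n_frames = 20, events = list(
    list(time_ns = 0.3, kind = "retract_thread"),
    list(time_ns = 0.6, kind = "rethread", crossing_residue = 22)),
    conn2_length = 10, seed = 15)
  evaluate <- function(sim) {
    ncs <- native_contact_set(sim$reference)
    refn <- reference_ncles(sim$reference, ncs)
    list(lapply(sim$trajectory$frames, classify_mechanism,
                ncs = ncs, ref_ncles = refn))
  }
  expect_equal(interdependence_probability(evaluate(near)), 1)
  expect_equal(interdependence_probability(evaluate(far)), 0)
  # planted 50% mix across two trajectories
  mixed <- c(evaluate(near), evaluate(far))
  expect_equal(interdependence_probability(mixed), 0.5)
})

test_that("trajectory container validates its invariants", {
  expect_error(new_trajectory(list(matrix(0, 3, 3), matrix(0, 4, 3))),
               "constant")
  expect_error(new_trajectory(list(matrix(0, 3, 3)), frame_interval = 0))
  tr <- new_trajectory(list(matrix(rnorm(9), 3)), protein_id = "t")
  expect_s3_class(tr, "ncle_trajectory")
})
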