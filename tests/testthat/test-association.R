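test_that("Fisher OR point estimates and symmetry", {
  r <- fisher_or(20, 80, 5, 95)
  expect_equal(r$odds_ratio, 4.75)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  r2 <- fisher_or(10, 10, 10, 10)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)

  expect_equal(fisher_or(3, 1, 1, 3)$p_value, 34 / 70, tolerance = 1e-12)
  expect_warning(r3 <- fisher_or(5, 0, 2, 3), "infinite")
  expect_equal(r3$odds_ratio, Inf)
})

test_that("Fisher p equals brute-force hypergeometric enumeration (sampled)", {
  set.seed(3)
  for (k in 1:50) {
    tab <- as.vector(stats::rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
    got <- fisher_or(tab[1], tab[2], tab[3], tab[4], conf_int = FALSE)$p_value
    want <- brute_fisher_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("logistic OR on one binary covariate equals the 2x2 cross-product", {
  set.seed(8)
  d <- data.frame(x_region = rbinom(2000, 1, 0.4))
  d$y_cutsite <- rbinom(2000, 1, ifelse(d$x_region == 1, 0.3, 0.15))
  r <- residue_logistic_or(d, covariates = character())
  a <- sum(d$x_region == 1 & d$y_cutsite == 1)
  b <- sum(d$x_region == 1 & d$y_cutsite == 0)
  c_ <- sum(d$x_region == 0 & d$y_cutsite == 1)
  dd <- sum(d$x_region == 0 & d$y_cutsite == 0)
  expect_equal(r$odds_ratio, (a * dd) / (b * c_), tolerance = 1e-6)
})

test_that("planted region log-odds is recovered and the null covers 1", {
  d0 <- simulate_residue_dataset(20000, beta_region = 0, seed = 21)$data
  r0 <- residue_logistic_or(d0)
  expect_true(r0$ci_low <= 1 && 1 <= r0$ci_high)

  d1 <- simulate_residue_dataset(50000, beta_region = 0.5, seed = 22)$data
  r1 <- residue_logistic_or(d1)
  expect_true(r1$ci_low <= exp(0.5) && exp(0.5) <= r1$ci_high)
})

test_that("residue model input validation and separation diagnostics", {
  d <- data.frame(x_region = rep(1, 10), y_cutsite = rbinom(10, 1, 0.5),
                  aa = "A")
  expect_error(residue_logistic_or(d), "both region classes")
  d2 <- data.frame(x_region = rep(0:1, each = 20),
                   y_cutsite = rep(0:1, each = 20), aa = "A")
  expect_error(residue_logistic_or(d2, covariates = character()), "separation")
})

test_that("protein-level logistic OR recovers a planted effect", {
  set.seed(31)
  n <- 2000
  pr <- data.frame(has_ncle = rbinom(n, 1, 0.5),
                   length = rnorm(n, 300, 60))
  comp <- matrix(abs(rnorm(n * 3, 0.05, 0.01)), n)
  colnames(comp) <- c("frac_A", "frac_L", "frac_K")
  pr <- cbind(pr, comp)
  lin <- -1 + log(3) * pr$has_ncle + 0.001 * (pr$length - 300)
  pr$non_refoldable <- rbinom(n, 1, plogis(lin))
  r <- protein_logistic_or(pr)
  expect_true(r$ci_low <= 3 && 3 <= r$ci_high)

  set.seed(32)
  pr$non_refoldable <- rbinom(n, 1, 0.3)
  r0 <- protein_logistic_or(pr)
  expect_true(r0$ci_low <= 1 && 1 <= r0$ci_high)
})

test_that("propensity matching balances exchangeable groups and errors without overlap", {
  set.seed(41)
  d <- data.frame(x_region = rep(0:1, c(600, 300)), y_cutsite = 0)
  d$sasa <- rnorm(900, 80, 20)
  pm <- propensity_match(d)
  expect_gte(pm$n_pairs, 250)
  expect_lt(abs(pm$smd_after), 0.1)

  d2 <- data.frame(x_region = rep(0:1, each = 50), y_cutsite = 0,
                   sasa = c(runif(50, 0, 10), runif(50, 100, 120)))
  expect_error(propensity_match(d2), "overlap")
})

test_that("matching removes planted burial confounding", {
  d <- simulate_residue_dataset(10000, beta_region = 0,
                                burial_confounding = TRUE, seed = 6)$data
  crude <- residue_logistic_or(d)
  expect_gt(crude$odds_ratio, 1.2)
  pm <- propensity_match(d)
  expect_lt(abs(pm$smd_after), 0.1)
  matched <- residue_logistic_or(pm$matched)
  expect_true(matched$ci_low <= 1 && 1 <= matched$ci_high)
})

test_that("delta OR on identical datasets is 0 with p near 0.5", {
  d <- simulate_residue_dataset(600, beta_region = 0.4, beta0 = -1.2,
                                residues_per_protein = 6L, seed = 51)$data
  r <- delta_or_permutation(d, d, n_perm = 200, seed = 5,
                            covariates = character())
  expect_equal(r$delta_or, 0)
  expect_gt(r$p_one_sided, 0.2)
  expect_lt(r$p_one_sided, 0.8)
  # reproducible for a fixed seed
  r2 <- delta_or_permutation(d, d, n_perm = 200, seed = 5,
                             covariates = character())
  expect_identical(r$null, r2$null)
})

test_that("delta OR detects a planted chaperone rescue", {
  base <- simulate_residue_dataset(2400, beta_region = 0.6, beta0 = -1.2,
                                   residues_per_protein = 12L, seed = 52)$data
  resc <- simulate_residue_dataset(2400, beta_region = 0.2, beta0 = -1.2,
                                   residues_per_protein = 12L, seed = 53)$data
  r <- delta_or_permutation(base, resc, n_perm = 300, seed = 7,
                            covariates = character())
  expect_lt(r$delta_or, 0)
  expect_lt(r$p_one_sided, 0.05)
})

test_that("motif scanning matches the sliding-window oracle", {
  expect_equal(motif_scan("KLLLLLR"), 1L)
  expect_equal(motif_scan("KLLLLLE"), integer())
  expect_equal(motif_scan("KKLLLLLRR"), 2L)
  set.seed(61)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:20) {
    s <- paste(sample(c(aas, "K", "R", "L", "L"), 60, replace = TRUE),
               collapse = "")
    expect_equal(motif_scan(s), brute_motif_positions(s))
  }
})

test_that("motif density is per 100 residues of the full protein length", {
  expect_equal(motif_density("KLLLLLR", 200), 0.5)
  seqs <- c("KLLLLLR", "AKLLLLLRA", "DDDD")  # 2 pools with 1 match each
  expect_equal(motif_density(seqs, 200), 1.0)
  expect_equal(motif_density("DDDD", 200), 0)
  expect_error(motif_density("KLLLLLR", 0), "positive")
})

test_that("group comparison: identity, power, and bootstrap coverage", {
  set.seed(71)
  a <- rnorm(100)
  same <- group_compare(a, a, n_boot = 500, n_perm = 500, seed = 1)
  expect_gt(same$p_perm, 0.9)
  b <- rnorm(100, 3, 1)
  far <- group_compare(a, b, n_boot = 500, n_perm = 1000, seed = 1)
  expect_lt(far$p_perm, 0.005)
  ci <- group_compare(1:100, 1:100, n_boot = 2000, n_perm = 10, seed = 2)$ci_a
  expect_true(ci["low"] <= 50.5 && 50.5 <= ci["high"])
  # degenerate constant identical groups
  expect_equal(group_compare(rep(2, 5), rep(2, 5), 10, 10, 1)$p_perm, 1)
})

test_that("loop-contact enrichment odds ratio arithmetic", {
  ess <- data.frame(aa_i = c(rep("F", 10), rep("L", 90)),
                    aa_j = c(rep("F", 10), rep("V", 90)))
  non <- data.frame(aa_i = c(rep("F", 40), rep("L", 160)),
                    aa_j = c(rep("F", 40), rep("V", 160)))
  r <- loop_contact_enrichment(ess, non, n_perm = 200, seed = 1)
  ff <- r[r$pair == "F-F", ]
  expect_equal(ff$or_value, (40 / 160) / (10 / 90))
  expect_equal(r$p_adjusted, bh_adjust(r$p_perm))
  # proportional counts give OR 1 everywhere
  non2 <- data.frame(aa_i = c(rep("F", 20), rep("L", 180)),
                     aa_j = c(rep("F", 20), rep("V", 180)))
  r2 <- loop_contact_enrichment(ess, non2, n_perm = 100, seed = 1)
  expect_true(all(abs(r2$or_value - 1) < 1e-12))
  # duplicating every contact in both groups leaves the OR unchanged
  r3 <- loop_contact_enrichment(rbind(ess, ess), rbind(non, non),
                                n_perm = 100, seed = 1)
  expect_equal(r3$or_value, r$or_value)
})

test_that("fraction of proteins with selected pairs and its bootstrap CI", {
  pp <- list(P1 = c("F-F", "L-V"), P2 = c("L-V"), P3 = c("F-Y"), P4 = "A-A")
  r <- fraction_with_pairs(pp, c("F-F", "F-Y", "S-Y", "C-H"), n_boot = 200)
  expect_equal(r$fraction, 0.5)
  expect_equal(fraction_with_pairs(pp, character(), n_boot = 10)$fraction, 0)
  expect_error(fraction_with_pairs(list(), "F-F"), "empty")
  # coverage of a planted 30% carrier rate
  set.seed(81)
  hit <- 0
  for (k in 1:100) {
    carriers <- lapply(rbinom(200, 1, 0.3),
                       function(z) if (z) "F-F" else "L-V")
    ci <- fraction_with_pairs(carriers, "F-F", n_boot = 300, seed = k)$ci
    if (ci["low"] <= 0.3 && 0.3 <= ci["high"]) hit <- hit + 1
  }
  expect_gte(hit, 90)
})

test_that("hydrophobic fraction arithmetic and group difference power", {
  expect_equal(hydrophobic_fraction("LLLL", n_boot = 10)$fractions, 1)
  expect_equal(hydrophobic_fraction("LLDD", n_boot = 10)$fractions, 0.5)
  expect_error(hydrophobic_fraction(""), "empty")
  set.seed(91)
  mk <- function(p, n) vapply(seq_len(n), function(k) {
    paste(sample(c("L", "D"), 300, replace = TRUE, prob = c(p, 1 - p)),
          collapse = "")
  }, "")
  fa <- hydrophobic_fraction(mk(0.63, 100), n_boot = 100)$fractions
  fb <- hydrophobic_fraction(mk(0.62, 100), n_boot = 100)$fractions
  r <- group_compare(fa, fb, n_boot = 200, n_perm = 2000, seed = 3)
  expect_lt(r$p_perm, 0.05)
})

test_that("client OR handles balanced and planted tables", {
  pr <- data.frame(essential = rep(c(1, 1, 0, 0), c(30, 10, 30, 10)),
                   client = rep(c(1, 0, 1, 0), c(30, 10, 30, 10)))
  expect_equal(client_or(pr)$odds_ratio, 1)
  set.seed(101)
  ess <- rbinom(400, 1, 0.5)
  cli <- rbinom(400, 1, plogis(-0.5 + log(3) * ess))
  r <- client_or(data.frame(essential = ess, client = cli))
  expect_gt(r$ci_low, 1)
})
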