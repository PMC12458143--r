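new_or_result <- function(odds_ratio, ci_low, ci_high, p_value, method,
                          n_proteins = NA_integer_, n_residues = NA_integer_,
                          beta = NA_real_) {
  structure(list(odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, method = method, n_proteins = n_proteins,
                 n_residues = n_residues, beta = beta),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$method))
  if (!is.na(x$n_proteins)) cat(sprintf("  n_proteins = %d\n", x$n_proteins))
  if (!is.na(x$n_residues)) cat(sprintf("  n_residues = %d\n", x$n_residues))
  invisible(x)
}

#' Fisher exact odds ratio of a 2x2 table
#'
#' The point estimate is the sample cross-product OR (a d)/(b c); the
#' two-sided p-value is the exact conditional (hypergeometric) test and the
#' 95% CI the conditional-likelihood interval, both from
#' [stats::fisher.test()]. For tables with total count above 1000 the CI
#' falls back to the Woolf log-OR interval for speed. A zero in b or c gives
#' an infinite OR, reported with a warning and a one-sided interval.
#'
#' @param a,b,c,d counts: rows are exposure yes/no, columns outcome yes/no.
#'   Alternatively `a` may be a 2x2 matrix.
#' @param conf_int compute the 95% CI (default TRUE; FALSE skips it, useful
#'   in exhaustive sweeps).
#' @return `or_result`.
#' @examples
#' fisher_or(20, 80, 5, 95)
#' @export
fisher_or <- function(a, b = NULL, c = NULL, d = NULL, conf_int = TRUE) {
  if (is.matrix(a)) { tab <- a } else { tab <- matrix(c(a, c, b, d), 2) }
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be non-negative with positive total")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  ft <- stats::fisher.test(tab, conf.int = conf_int)
  or <- (a * d) / (b * c)
  if (!conf_int) {
    return(new_or_result(or, NA_real_, NA_real_, ft$p.value, "fisher",
                         n_proteins = sum(tab)))
  }
  if (b * c == 0 && a * d > 0) {
    warning("empty off-diagonal cell: OR infinite, one-sided CI")
    return(new_or_result(Inf, ft$conf.int[1], Inf, ft$p.value, "fisher",
                         n_proteins = sum(tab)))
  }
  if (sum(tab) > 1000 && all(tab > 0)) {
    se <- sqrt(sum(1 / tab))
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  } else {
    ci <- ft$conf.int
  }
  new_or_result(or, ci[1], ci[2], ft$p.value, "fisher", n_proteins = sum(tab))
}

# Fast logistic fit on a prebuilt model matrix; returns coefficients and, on
# request, their covariance. Used by the OR functions and permutation loops.
logit_fit <- function(X, y, vcov = FALSE) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- fit$fitted.values
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    sep <- TRUE
  } else sep <- FALSE
  out <- list(coef = fit$coefficients, separation = sep)
  if (vcov) {
    w <- p * (1 - p)
    XtWX <- crossprod(X * w, X)
    out$vcov <- tryCatch(solve(XtWX), error = function(e) matrix(NA, ncol(X), ncol(X)))
  }
  out
}

residue_model_matrix <- function(d, covariates = "aa") {
  X <- cbind(`(Intercept)` = 1, x_region = d$x_region)
  if ("aa" %in% covariates) {
    aa <- factor(d$aa, levels = sort(unique(d$aa)))
    if (nlevels(aa) > 1) {
      M <- stats::model.matrix(~aa)[, -1, drop = FALSE]
      X <- cbind(X, M)
    }
  }
  X
}

#' Residue-level logistic odds ratio of cut-sites on NCLE regions
#'
#' Fits the log-odds of a residue carrying a significant cut-site on an
#' intercept, the NCLE-region indicator, and (by default) 19 amino-acid
#' indicators with alanine as the reference level:
#' logit p = b0 + b_region X_region + sum_AA b_AA X_AA.
#' The reported OR is exp(b_region) with a Wald 95% CI and Wald p-value.
#'
#' @param d residue dataset: data.frame with x_region (0/1), y_cutsite (0/1),
#'   and `aa` when amino-acid covariates are requested.
#' @param covariates character vector, subset of "aa" (default) or empty for
#'   a region-only model.
#' @return `or_result` (method "logistic"); `beta` holds b_region.
#' @export
residue_logistic_or <- function(d, covariates = "aa") {
  if (length(unique(d$x_region)) < 2) stop("both region classes required")
  if (length(unique(d$y_cutsite)) < 2) stop("both outcome values required")
  X <- residue_model_matrix(d, covariates)
  fit <- logit_fit(X, d$y_cutsite, vcov = TRUE)
  if (fit$separation) stop("perfect separation: logistic MLE does not exist")
  beta <- unname(fit$coef["x_region"])
  se <- sqrt(fit$vcov[2, 2])
  ci <- exp(beta + c(-1, 1) * 1.96 * se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_or_result(exp(beta), ci[1], ci[2], p, "logistic",
                n_proteins = if ("protein_id" %in% names(d))
                  length(unique(d$protein_id)) else NA_integer_,
                n_residues = nrow(d), beta = unname(beta))
}

#' Protein-level logistic odds ratio of non-refoldability on NCLE presence
#'
#' Logistic fit of the non-refoldable indicator on NCLE presence, protein
#' length, and amino-acid composition fractions (one reference fraction,
#' alanine, dropped to avoid the sum-to-one singularity). OR =
#' exp(coefficient of `has_ncle`), Wald CI and p.
#'
#' @param proteins data.frame with has_ncle (0/1), non_refoldable (0/1),
#'   `length`, and optionally columns `frac_<AA>` of composition fractions.
#' @return `or_result`.
#' @export
protein_logistic_or <- function(proteins) {
  X <- cbind(`(Intercept)` = 1, has_ncle = proteins$has_ncle,
             length = proteins$length)
  fr <- grep("^frac_", names(proteins), value = TRUE)
  fr <- setdiff(fr, "frac_A")
  if (length(fr)) X <- cbind(X, as.matrix(proteins[, fr, drop = FALSE]))
  fit <- logit_fit(X, proteins$non_refoldable, vcov = TRUE)
  if (fit$separation) stop("perfect separation: logistic MLE does not exist")
  beta <- unname(fit$coef["has_ncle"])
  se <- sqrt(fit$vcov[2, 2])
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_or_result(exp(beta), exp(beta - 1.96 * se), exp(beta + 1.96 * se), p,
                "logistic", n_proteins = nrow(proteins), beta = unname(beta))
}

standardized_mean_diff <- function(x1, x0) {
  (mean(x1) - mean(x0)) / sqrt((stats::var(x1) + stats::var(x0)) / 2)
}

#' Propensity-score matching of NCLE and non-NCLE residues on SASA
#'
#' Fits a logistic propensity model P(region | SASA), then greedily 1:1
#' nearest-neighbour matches each NCLE-region residue to an unused non-NCLE
#' residue on the logit propensity scale, within a caliper of 0.2 SD of the
#' logit propensity. Unmatched NCLE residues are dropped. Balance is reported
#' as the standardized mean difference (SMD) of SASA before and after.
#'
#' @param d residue dataset with x_region and sasa.
#' @param caliper caliper width in SDs of the logit propensity (default 0.2).
#' @return list: `matched` (the matched subset of `d`), `smd_before`,
#'   `smd_after`, `n_pairs`, `pairs` (row indices into `d`).
#' @export
propensity_match <- function(d, caliper = 0.2) {
  if (any(is.na(d$sasa))) stop("SASA required for all rows")
  tr <- which(d$x_region == 1); ct <- which(d$x_region == 0)
  if (!length(tr) || !length(ct)) stop("both region classes required")
  if (min(d$sasa[tr]) > max(d$sasa[ct]) || max(d$sasa[tr]) < min(d$sasa[ct])) {
    stop("no overlap in SASA support between regions")
  }
  fit <- logit_fit(cbind(1, d$sasa), d$x_region)
  lp <- cbind(1, d$sasa) %*% fit$coef
  cal <- caliper * stats::sd(lp)
  ord <- tr[order(lp[tr], decreasing = TRUE)]
  avail <- rep(TRUE, length(ct))
  ct_lp <- lp[ct]
  pairs <- matrix(NA_integer_, 0, 2)
  for (t in ord) {
    dd <- abs(ct_lp - lp[t])
    dd[!avail] <- Inf
    k <- which.min(dd)
    if (is.finite(dd[k]) && dd[k] <= cal) {
      avail[k] <- FALSE
      pairs <- rbind(pairs, c(t, ct[k]))
    }
  }
  if (!nrow(pairs)) stop("no matches within caliper")
  matched <- d[as.vector(t(pairs)), , drop = FALSE]
  list(matched = matched,
       smd_before = standardized_mean_diff(d$sasa[tr], d$sasa[ct]),
       smd_after = standardized_mean_diff(d$sasa[pairs[, 1]], d$sasa[pairs[, 2]]),
       n_pairs = nrow(pairs), pairs = pairs)
}

#' Permutation test of the chaperone change in odds ratio
#'
#' Observed statistic: delta OR = OR(chaperone dataset) - OR(base dataset),
#' each from [residue_logistic_or()]. The null distribution permutes the
#' buffer label over proteins (keeping residues of a protein together,
#' preserving within-protein correlation) and recomputes delta OR. The
#' one-sided p-value is the smoothed fraction of null values at or below the
#' observed one (direction: chaperone rescue lowers the OR).
#'
#' @param dataset_base,dataset_chaperone residue datasets with protein_id.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed RNG seed.
#' @param covariates passed to the logistic fits (default "aa").
#' @return list(delta_or, p_one_sided, null = numeric vector of null deltas).
#' @export
delta_or_permutation <- function(dataset_base, dataset_chaperone,
                                 n_perm = 10000, seed = 1, covariates = "aa") {
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  or_of <- function(d) residue_logistic_or(d, covariates)$odds_ratio
  obs <- or_of(dataset_chaperone) - or_of(dataset_base)
  pooled <- rbind(dataset_base, dataset_chaperone)
  X <- residue_model_matrix(pooled, covariates)
  y <- pooled$y_cutsite
  prot <- paste(rep(c("b", "c"), c(nrow(dataset_base), nrow(dataset_chaperone))),
                pooled$protein_id)
  prots <- unique(prot)
  n_base_prot <- length(unique(dataset_base$protein_id))
  prot_idx <- match(prot, prots)
  or_rows <- function(rows) {
    fit <- logit_fit(X[rows, , drop = FALSE], y[rows])
    exp(unname(fit$coef["x_region"]))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    lab <- sample(prots)
    base_set <- prot_idx %in% match(lab[seq_len(n_base_prot)], prots)
    or_rows(which(!base_set)) - or_rows(which(base_set))
  }, 0)
  p <- (sum(null <= obs) + 1) / (n_perm + 1)
  list(delta_or = obs, p_one_sided = p, null = null)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Scan a sequence for a chaperone-binding motif pattern
#'
#' Patterns are words over residue classes, e.g. the expanded Bukau-like
#' DnaK motif "BHHHHHB" with B basic and H hydrophobic. All (overlapping)
#' match start positions are returned. Letters outside the classes never
#' match.
#'
#' @param sequence one-letter amino-acid string.
#' @param motif_pattern class word (default "BHHHHHB").
#' @param classes named list mapping class letters to residue sets; defaults
#'   B = R, K and H = A, V, L, I, M, F, W, Y.
#' @return integer vector of 1-based match start positions.
#' @examples
#' motif_scan("KLLLLLR") # 1
#' @export
motif_scan <- function(sequence, motif_pattern = "BHHHHHB",
                       classes = list(B = c("R", "K"),
                                      H = c("A", "V", "L", "I", "M", "F", "W", "Y"))) {
  if (!nchar(sequence)) return(integer())
  parts <- strsplit(motif_pattern, "")[[1]]
  rx <- vapply(parts, function(ch) {
    if (!is.null(classes[[ch]])) paste0("[", paste(classes[[ch]], collapse = ""), "]")
    else ch
  }, "")
  rx <- paste0("(?=", paste(rx, collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Motif density per 100 residues
#'
#' D = N(pool, motif) / L x 100, where N counts motif matches in the given
#' sequence pool (full sequence, NCLE loops, or threads) and L is the full
#' protein length regardless of pool.
#'
#' @param pool_sequences character vector of pool sequences (e.g. one string
#'   per loop); the count is the sum of per-sequence matches.
#' @param protein_length L, the full canonical length (> 0).
#' @param motif_pattern class word passed to [motif_scan()].
#' @param ... further arguments (e.g. `classes`) passed to [motif_scan()].
#' @return density, motifs per 100 residues.
#' @export
motif_density <- function(pool_sequences, protein_length,
                          motif_pattern = "BHHHHHB", ...) {
  if (protein_length <= 0) stop("protein_length must be positive")
  n <- sum(vapply(pool_sequences,
                  function(s) length(motif_scan(s, motif_pattern, ...)), 0L))
  n / protein_length * 100
}

basic_bootstrap_ci <- function(x, n_boot = 10000, stat = mean, level = 0.95) {
  est <- stat(x)
  reps <- vapply(seq_len(n_boot),
                 function(k) stat(x[sample.int(length(x), replace = TRUE)]), 0)
  q <- stats::quantile(reps, c((1 + level) / 2, (1 - level) / 2), names = FALSE)
  c(low = 2 * est - q[1], high = 2 * est - q[2])
}

#' Compare two groups of values by bootstrap and permutation
#'
#' Reports each group's mean with a basic (reflected) bootstrap 95% CI and a
#' two-sided permutation p-value for the difference in means, with
#' (r + 1)/(n + 1) smoothing. Constant identical groups give p = 1.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param n_boot bootstrap replicates (default 10000).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list(mean_a, mean_b, ci_a, ci_b, diff, p_perm).
#' @export
group_compare <- function(values_a, values_b, n_boot = 10000, n_perm = 10000,
                          seed = 1) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  obs <- mean(values_a) - mean(values_b)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  if (stats::sd(pooled) == 0) {
    p <- 1
  } else {
    null <- vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 0)
    p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  }
  list(mean_a = mean(values_a), mean_b = mean(values_b),
       ci_a = basic_bootstrap_ci(values_a, n_boot),
       ci_b = basic_bootstrap_ci(values_b, n_boot),
       diff = obs, p_perm = p)
}

pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}

#' Enrichment of amino-acid pairs among loop-closing contacts
#'
#' For each unordered residue-type pair (a, b) observed as a loop-closing
#' contact, the odds ratio contrasts its share among non-essential proteins'
#' loop-closing contacts against its share among essential proteins':
#' OR = [N_nE(a,b) / (N_nE - N_nE(a,b))] / [N_E(a,b) / (N_E - N_E(a,b))].
#' P-values come from permuting the essential/non-essential labels over
#' contacts (two-sided on log OR, smoothed), BH-adjusted across pairs.
#'
#' @param essential_contacts,nonessential_contacts data.frames with columns
#'   `aa_i`, `aa_j` (one-letter types of the loop-closing contact).
#' @param n_perm permutations (default 100000).
#' @param seed RNG seed.
#' @return data.frame (pair, n_essential, n_nonessential, or_value, p_perm,
#'   p_adjusted); pairs absent from both sets are skipped.
#' @export
loop_contact_enrichment <- function(essential_contacts, nonessential_contacts,
                                    n_perm = 100000, seed = 1) {
  ek <- pair_key(essential_contacts$aa_i, essential_contacts$aa_j)
  nk <- pair_key(nonessential_contacts$aa_i, nonessential_contacts$aa_j)
  pairs <- sort(unique(c(ek, nk)))
  ne <- length(ek); nn <- length(nk)
  ce <- table(factor(ek, levels = pairs))
  cn <- table(factor(nk, levels = pairs))
  or_from_counts <- function(cnt_n, cnt_e) {
    (cnt_n / (nn - cnt_n)) / (cnt_e / (ne - cnt_e))
  }
  obs_or <- or_from_counts(as.numeric(cn), as.numeric(ce))
  all_keys <- factor(c(ek, nk), levels = pairs)
  key_idx <- as.integer(all_keys)
  npairs <- length(pairs)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  log_obs <- log(obs_or)
  hi <- integer(npairs); lo <- integer(npairs)
  for (t in seq_len(n_perm)) {
    e_set <- sample.int(ne + nn, ne)
    ce_p <- tabulate(key_idx[e_set], nbins = npairs)
    cn_p <- tabulate(key_idx[-e_set], nbins = npairs)
    log_null <- log(or_from_counts(cn_p, ce_p))
    hi <- hi + (is.finite(log_null) & log_null >= log_obs - 1e-12 |
                  !is.finite(log_null) & log_null > 0)
    lo <- lo + (is.finite(log_null) & log_null <= log_obs + 1e-12 |
                  !is.finite(log_null) & log_null < 0)
  }
  p <- pmin(1, 2 * pmin(hi + 1, lo + 1) / (n_perm + 1))
  out <- data.frame(pair = pairs, n_essential = as.integer(ce),
                    n_nonessential = as.integer(cn), or_value = obs_or,
                    p_perm = p, stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_perm)
  rownames(out) <- NULL
  out
}

#' Fraction of proteins carrying selected loop-closing pairs
#'
#' Fraction of proteins with at least one loop-closing contact whose residue
#' pair is in `pair_set`, with a basic bootstrap 95% CI over proteins.
#'
#' @param protein_pairs named list: per protein, a character vector of
#'   unordered pair keys ("F-F" style) or a data.frame with aa_i/aa_j.
#' @param pair_set character vector of pair keys, e.g.
#'   `c("F-F", "F-Y", "S-Y", "C-H")` (keys are alphabetically ordered).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return list(fraction, ci, n).
#' @export
fraction_with_pairs <- function(protein_pairs, pair_set, n_boot = 10000, seed = 1) {
  if (!length(protein_pairs)) stop("empty protein set")
  has <- vapply(protein_pairs, function(p) {
    if (is.data.frame(p)) p <- pair_key(p$aa_i, p$aa_j)
    any(p %in% pair_set)
  }, TRUE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  list(fraction = mean(has),
       ci = basic_bootstrap_ci(as.numeric(has), n_boot),
       n = length(has))
}

#' Hydrophobic residue fraction of protein groups
#'
#' Per-protein fraction of residues in `hydrophobic_set`, summarised as the
#' group mean with a basic bootstrap CI.
#'
#' @param sequences character vector of one-letter sequences.
#' @param hydrophobic_set residue letters counted as hydrophobic; the default
#'   `c("A","V","L","I","M","F","W","Y","C","G","P")` is a configurable
#'   choice, not a universal convention.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return list(fractions, mean, ci).
#' @export
hydrophobic_fraction <- function(sequences,
                                 hydrophobic_set = c("A", "V", "L", "I", "M",
                                                     "F", "W", "Y", "C", "G", "P"),
                                 n_boot = 10000, seed = 1) {
  if (any(!nchar(sequences))) stop("empty sequence")
  fr <- vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% hydrophobic_set)
  }, 0, USE.NAMES = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  list(fractions = fr, mean = mean(fr), ci = basic_bootstrap_ci(fr, n_boot))
}

#' Odds ratio of chaperone clienthood on essentiality
#'
#' Fisher exact OR for the 2x2 table of essential x client status among
#' entangled proteins.
#'
#' @param proteins data.frame with logical/0-1 columns `essential`, `client`.
#' @return `or_result`.
#' @export
client_or <- function(proteins) {
  a <- sum(proteins$essential == 1 & proteins$client == 1)
  b <- sum(proteins$essential == 1 & proteins$client == 0)
  c <- sum(proteins$essential == 0 & proteins$client == 1)
  d <- sum(proteins$essential == 0 & proteins$client == 0)
  fisher_or(a, b, c, d)
}
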