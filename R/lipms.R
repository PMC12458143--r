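#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; thin wrapper over
#' [stats::p.adjust()] kept as the single adjustment point of the pipeline.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

validate_peptides <- function(peptides) {
  need <- c("protein_id", "start", "end", "condition", "replicate", "abundance")
  miss <- setdiff(need, names(peptides))
  if (length(miss)) stop("peptide table missing columns: ", paste(miss, collapse = ", "))
  if (any(peptides$start > peptides$end)) stop("peptide start > end")
  if (any(peptides$abundance < 0)) stop("negative abundances")
  peptides
}

#' Call significant proteinase-K cut-sites
#'
#' For each cut-site and refolding timepoint, abundances of the half-tryptic
#' peptides carrying that site are compared between the treated (refolded)
#' and untreated samples: the fold change is the difference of condition
#' means on the log2 scale, and a Welch t-test on log2 abundances gives the
#' p-value. P-values are BH-adjusted within each timepoint's family. A site
#' is significant when, in at least one timepoint, |log2 fold change| >= 1
#' (a two-fold change, boundary inclusive) and adjusted p < `alpha`.
#'
#' Sites whose untreated abundances are all zero have an undefined fold
#' change and are excluded (flagged in the `excluded` attribute). Zeros
#' amid otherwise-positive values are imputed with half the smallest
#' positive abundance of the protein.
#'
#' @param peptides data.frame with columns protein_id, start, end,
#'   half_tryptic, pk_site, condition ("untreated"/"treated"), timepoint
#'   ("1min"/"5min"/"2h", NA for untreated), replicate, abundance.
#' @param alpha FDR level (default 0.05).
#' @param bh_family "timepoint" (default) adjusts within each timepoint;
#'   "global" adjusts across all tests at once.
#' @return data.frame of per-(site, timepoint) calls: protein_id, residue,
#'   timepoint, log2_fold_change, p_value, p_adjusted, significant (the
#'   pooled site-level flag, repeated on each timepoint row).
#' @export
call_cutsites <- function(peptides, alpha = 0.05,
                          bh_family = c("timepoint", "global")) {
  bh_family <- match.arg(bh_family)
  peptides <- validate_peptides(peptides)
  pk <- peptides[!is.na(peptides$pk_site), , drop = FALSE]
  if (!nrow(pk)) stop("no peptides carry a pk_site")
  # half-minimum imputation of zero abundances, within protein
  for (pid in unique(pk$protein_id)) {
    rows <- pk$protein_id == pid
    pos <- pk$abundance[rows & pk$abundance > 0]
    if (length(pos)) pk$abundance[rows & pk$abundance == 0] <- min(pos) / 2
  }
  site_key <- paste(pk$protein_id, pk$pk_site)
  rows <- list(); excluded <- character()
  for (sk in unique(site_key)) {
    d <- pk[site_key == sk, , drop = FALSE]
    unt <- d$abundance[d$condition == "untreated"]
    if (!length(unt) || all(unt == 0)) { excluded <- c(excluded, sk); next }
    for (tp in unique(d$timepoint[d$condition == "treated"])) {
      tr <- d$abundance[d$condition == "treated" & d$timepoint == tp]
      if (length(tr) < 2 || length(unt) < 2) next
      lt <- log2(tr); lu <- log2(unt)
      lfc <- mean(lt) - mean(lu)
      pv <- if (stats::sd(lt) == 0 && stats::sd(lu) == 0) {
        if (isTRUE(all.equal(mean(lt), mean(lu)))) 1 else 0
      } else stats::t.test(lt, lu)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = d$protein_id[1], residue = d$pk_site[1], timepoint = tp,
        log2_fold_change = lfc, p_value = pv, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable cut-sites (need >= 2 replicates per condition)")
  calls <- do.call(rbind, rows)
  if (bh_family == "timepoint") {
    calls$p_adjusted <- NA_real_
    for (tp in unique(calls$timepoint)) {
      sel <- calls$timepoint == tp
      calls$p_adjusted[sel] <- bh_adjust(calls$p_value[sel])
    }
  } else {
    calls$p_adjusted <- bh_adjust(calls$p_value)
  }
  hit <- abs(calls$log2_fold_change) >= 1 & calls$p_adjusted < alpha
  site <- paste(calls$protein_id, calls$residue)
  sig_sites <- unique(site[hit])
  calls$significant <- site %in% sig_sites
  attr(calls, "excluded") <- excluded
  rownames(calls) <- NULL
  calls
}

#' Summed peptide abundance and sequence coverage of a protein
#'
#' SPA is the sum of untreated-condition peptide ion abundances mapped to the
#' protein; coverage is the fraction of the canonical sequence covered by the
#' union of observed peptide spans.
#'
#' @param peptides peptide table rows for one protein.
#' @param protein_length canonical sequence length (> 0).
#' @return list(spa = , coverage = ).
#' @export
compute_spa_and_coverage <- function(peptides, protein_length) {
  if (protein_length <= 0) stop("protein_length must be positive")
  peptides <- validate_peptides(peptides)
  unt <- peptides[peptides$condition == "untreated", , drop = FALSE]
  spa <- sum(unt$abundance)
  covered <- logical(protein_length)
  for (k in seq_len(nrow(peptides))) {
    lo <- max(1L, peptides$start[k]); hi <- min(protein_length, peptides$end[k])
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  list(spa = spa, coverage = mean(covered))
}

#' Per-protein LiP-MS summary table
#'
#' Joins cut-site calls with SPA/coverage and the refoldability definition:
#' a protein is refoldable iff it has zero significant cut-sites. Proteins
#' absent from the treated data (no calls) are excluded, not classified.
#'
#' @param peptides full peptide table.
#' @param lengths named vector or data.frame (protein_id, length).
#' @param calls output of [call_cutsites()]; computed if `NULL`.
#' @param ... passed to [call_cutsites()].
#' @return data.frame (protein_id, spa, spa_percentile, coverage,
#'   n_significant, refoldable).
#' @export
protein_lip_summary <- function(peptides, lengths, calls = NULL, ...) {
  peptides <- validate_peptides(peptides)
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$protein_id)
  }
  if (is.null(calls)) calls <- call_cutsites(peptides, ...)
  ids <- intersect(unique(peptides$protein_id), unique(calls$protein_id))
  rows <- lapply(ids, function(pid) {
    sc <- compute_spa_and_coverage(peptides[peptides$protein_id == pid, , drop = FALSE],
                                   lengths[[pid]])
    cs <- calls[calls$protein_id == pid, , drop = FALSE]
    nsig <- length(unique(cs$residue[cs$significant]))
    data.frame(protein_id = pid, spa = sc$spa, coverage = sc$coverage,
               n_significant = nsig, refoldable = nsig == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spa_percentile <- spa_percentiles(out$spa)
  rownames(out) <- NULL
  out[, c("protein_id", "spa", "spa_percentile", "coverage",
          "n_significant", "refoldable")]
}

# Percentile ranks in [0, 100); ties share the lower rank so that
# ">= percentile" subsets are stable.
spa_percentiles <- function(spa) {
  n <- length(spa)
  100 * (rank(spa, ties.method = "min") - 1) / n
}

#' Abundance-percentile and coverage filter
#'
#' Retains proteins whose SPA percentile is at least `percentile` and whose
#' sequence coverage is at least `min_coverage` (default 0.5). Sweeping the
#' percentile threshold from 0 upward yields nested decreasing subsets.
#'
#' @param summaries data.frame from [protein_lip_summary()].
#' @param percentile SPA percentile threshold in [0, 100] (default 50, the
#'   reporting threshold).
#' @param min_coverage coverage floor (default 0.5).
#' @return the retained rows of `summaries`.
#' @export
spa_percentile_filter <- function(summaries, percentile = 50, min_coverage = 0.5) {
  keep <- summaries$spa_percentile >= percentile & summaries$coverage >= min_coverage
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refoldability from a summary row
#'
#' A protein refolds to its native ensemble (refoldable) iff it exhibits no
#' significant cut-sites; one or more makes it non-refoldable.
#'
#' @param summary data.frame with `n_significant`.
#' @return logical vector.
#' @export
classify_refoldability <- function(summary) summary$n_significant == 0
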