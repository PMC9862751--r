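# Screening and assay triage arithmetic: docking-score ranking with
# per-cluster diversity picks, radioligand inhibition-percent, threshold
# hit counting, and four-parameter-logistic (4PL) IC50 fitting.

#' Inhibition percentage from binding counts
#'
#' `100 * (total - test) / (total - nonspecific)`: the fraction of
#' *specific* radioligand binding displaced by the test compound.
#'
#' @param total total binding counts (no competitor).
#' @param test counts in the presence of the test compound.
#' @param nonspecific counts with excess cold competitor.
#' @return inhibition, percent (can exceed bounds for noisy counts).
#' @export
inhibition_percent <- function(total, test, nonspecific) {
  if (any(total <= nonspecific))
    stop("total binding must exceed non-specific binding")
  100 * (total - test) / (total - nonspecific)
}

#' Count compounds above an inhibition threshold
#'
#' Strict inequality: "over X%" means `inhibition_pct > threshold_pct`.
#'
#' @param records data frame with an `inhibition_pct` column (NA rows
#'   are ignored).
#' @param threshold_pct percent threshold.
#' @return integer count.
#' @export
count_hits <- function(records, threshold_pct) {
  v <- records$inhibition_pct
  sum(v > threshold_pct, na.rm = TRUE)
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^((log10(IC50) - log10(x)) * hill))`
#' in log-concentration space (Levenberg-Marquardt), with `bottom` and
#' `top` bounded to [-10, 110] percent -- unconstrained fits are
#' unstable on short curves.
#'
#' @param concentrations micromolar, strictly positive, >= 4 distinct.
#' @param responses percent inhibition.
#' @return object of class `fit_4pl`: `bottom`, `top`, `log_ic50`,
#'   `hill`, `ic50` (uM), `residual_norm`, `converged`.
#' @export
fit_4pl <- function(concentrations, responses) {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (any(x <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct concentrations for a 4PL fit")
  if (stats::sd(y) < 1e-8 || diff(range(y)) < 1)
    stop("flat response: IC50 unidentifiable")
  lx <- log10(x)
  start <- list(bottom = max(-10, min(y)), top = min(110, max(y)),
                log_ic50 = lx[which.min(abs(y - (min(y) + max(y)) / 2))],
                hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - lx) * hill)),
      start = start,
      lower = c(bottom = -10, top = -10, log_ic50 = min(lx) - 3,
                hill = 0.1),
      upper = c(bottom = 110, top = 110, log_ic50 = max(lx) + 3,
                hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    resid0 <- sqrt(sum((y - mean(y))^2))
    stop(sprintf("4PL fit did not converge (residual norm %.3g): %s",
                 resid0, conditionMessage(fit)))
  }
  cf <- as.list(stats::coef(fit))
  structure(list(bottom = cf$bottom, top = cf$top,
                 log_ic50 = cf$log_ic50, hill = cf$hill,
                 ic50 = 10^cf$log_ic50,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf("<fit_4pl> IC50 %.4g uM (hill %.2f, range %.1f-%.1f%%, resid %.3g)\n",
              x$ic50, x$hill, x$bottom, x$top, x$residual_norm))
  invisible(x)
}

#' Rank by docking score and pick cluster representatives
#'
#' Keeps the `top_n` best (lowest, i.e. most negative) docking scores,
#' then retains the minimum-score compound of each chemical cluster --
#' the diversity-selection step of a screening funnel.  Chemical
#' clustering itself (e.g. on circular fingerprints) is outside this
#' package; labels are supplied.
#'
#' @param records data frame with `compound_id` and `vina_score`.
#' @param cluster_labels named vector (or data frame column) mapping
#'   compound id to cluster label; every top-`n` compound must be
#'   labelled.
#' @param top_n compounds carried into clustering.
#' @param n_clusters cap on picks; when more clusters are present, the
#'   best-scoring `n_clusters` picks are kept.
#' @return data frame of picked records, score-ascending, with a
#'   `cluster` column.
#' @export
rank_and_pick <- function(records, cluster_labels, top_n = 300,
                          n_clusters = 40) {
  ord <- order(records$vina_score)
  top <- records[ord[seq_len(min(top_n, nrow(records)))], , drop = FALSE]
  lab <- cluster_labels[match(top$compound_id, names(cluster_labels))]
  if (anyNA(lab))
    stop("cluster labels missing for compound(s): ",
         paste(top$compound_id[is.na(lab)], collapse = ", "))
  top$cluster <- lab
  picks <- do.call(rbind, lapply(split(top, top$cluster), function(g) {
    g[which.min(g$vina_score), , drop = FALSE]
  }))
  picks <- picks[order(picks$vina_score), , drop = FALSE]
  if (nrow(picks) > n_clusters)
    picks <- picks[seq_len(n_clusters), , drop = FALSE]
  rownames(picks) <- NULL
  picks
}

#' Packaged reference assay table
#'
#' The 27 assayed virtual-screening hits against the dopamine D3
#' receptor: compound id, docking score (kcal/mol), percent inhibition
#' of specific radioligand binding at 10 uM, and the measured IC50 (uM)
#' where determined.
#'
#' @return data frame with columns `compound_id`, `vina_score`,
#'   `inhibition_pct`, `ic50`.
#' @export
load_assay_reference <- function() {
  utils::read.csv(system.file("extdata", "d3r_assay_table.csv",
                              package = "poseval"),
                  stringsAsFactors = FALSE)
}

#' Packaged reference pose-stability score table
#'
#' Published PoseScore/PersScore/CompScore triples for the candidate
#' poses of eticlopride and five D3R screening hits (up to three poses
#' each), plus the eticlopride crystal-pose control.
#'
#' @return data frame with columns `compound_id`, `pose`, `ifd_score`,
#'   `pose_score`, `pers_score`, `comp_score`.
#' @export
load_bpmd_reference <- function() {
  utils::read.csv(system.file("extdata", "d3r_bpmd_scores.csv",
                              package = "poseval"),
                  stringsAsFactors = FALSE)
}

#' Packaged reference pose-comparison table
#'
#' Pre- vs post-MD comparison of the five D3R hits: binding free
#' energies of the top-scored and representative conformations,
#' ligand displacement RMSD, and strong-interaction counts.
#'
#' @return data frame with columns `ligand`, `dg_top`, `dg_rep`,
#'   `rmsd`, `strong_top`, `strong_rep`.
#' @export
load_comparison_reference <- function() {
  utils::read.csv(system.file("extdata", "d3r_pose_comparison.csv",
                              package = "poseval"),
                  stringsAsFactors = FALSE)
}
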