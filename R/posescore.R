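# Pose-stability scoring from multi-trial trajectory ensembles:
# PoseScore (max trial-averaged ligand RMSD), PersScore (hydrogen-bond
# persistence over the final simulation window), CompScore (linear
# combination), and the <2 A stability call.

#' Binding-site alignment atom selection
#'
#' Receptor backbone atoms (N, CA, C, O) within `radius` Angstrom of any
#' frame-0 ligand atom.  Used to superpose every frame onto frame 0
#' before measuring ligand displacement, so global tumbling does not
#' inflate the score.
#'
#' @param ens a `traj_ensemble` whose template carries roles.
#' @param radius site radius, Angstrom.
#' @return integer atom indices.
#' @export
site_selection <- function(ens, radius = 5) {
  at <- ens$atom_template$atoms
  xyz0 <- ens$trials[[1]][, , 1]
  lig <- which(at$role == "ligand")
  bb <- which(at$role == "receptor" & at$name %in% c("N", "CA", "C", "O"))
  if (!length(bb)) bb <- which(at$role == "receptor" & at$is_heavy)
  if (!length(lig) || !length(bb)) stop("selections must be non-empty")
  d <- .dist_mat(xyz0[bb, , drop = FALSE], xyz0[lig, , drop = FALSE])
  sel <- bb[apply(d, 1, min) <= radius]
  if (length(sel) < 3) sel <- bb  # tiny toy receptors: use all backbone
  sel
}

#' Trial-averaged ligand RMSD curve
#'
#' For every frame of every trial the complex is superposed onto frame 0
#' using the binding-site selection (Kabsch), then the ligand heavy-atom
#' RMSD to its frame-0 position is taken at fixed correspondence.  The
#' curve is the per-timestamp mean over trials -- the quantity whose
#' maximum is the PoseScore.
#'
#' @param ens a `traj_ensemble`.
#' @param ligand_idx ligand heavy-atom indices (default: from roles).
#' @param site_idx alignment atom indices (default: [site_selection()]).
#' @param site_radius radius passed to [site_selection()].
#' @return data frame with columns `time_ps`, `rmsd`.
#' @export
ligand_rmsd_curve <- function(ens, ligand_idx = NULL, site_idx = NULL,
                              site_radius = 5) {
  if (is.null(ligand_idx))
    ligand_idx <- role_idx(ens$atom_template, "ligand", heavy_only = TRUE)
  if (!length(ligand_idx)) stop("empty ligand selection")
  if (is.null(site_idx)) site_idx <- site_selection(ens, site_radius)
  nf <- n_frames(ens)
  per_trial <- vapply(ens$trials, function(tr) {
    ref_site <- tr[site_idx, , 1]
    ref_lig <- tr[ligand_idx, , 1]
    vapply(seq_len(nf), function(k) {
      fr <- tr[, , k]
      sp <- kabsch_superpose(fr[site_idx, , drop = FALSE], ref_site)
      rmsd_fixed(apply_superposition(sp, fr[ligand_idx, , drop = FALSE]),
                 ref_lig)
    }, 0)
  }, numeric(nf))
  data.frame(time_ps = ens$timestamps, rmsd = rowMeans(per_trial))
}

#' PoseScore: maximum of the averaged RMSD curve
#' @param curve data frame from [ligand_rmsd_curve()] (or bare numeric).
#' @return PoseScore in Angstrom.
#' @export
pose_score <- function(curve) {
  v <- if (is.data.frame(curve)) curve$rmsd else curve
  if (!length(v)) stop("empty RMSD curve")
  max(v)
}

#' PersScore: hydrogen-bond persistence
#'
#' The reference hydrogen bonds are those detected on frame 0 (via
#' [detect_hbonds()]).  Over the final `window_frac` of frames in each
#' trial, each reference bond is re-tested with the same geometric
#' criteria; the score is the fraction of (bond x frame) observations
#' still satisfied, averaged over trials.  With no reference bonds the
#' score is 0 by convention.
#'
#' @param ens a `traj_ensemble`.
#' @param reference_hbs optional precomputed frame-0 hydrogen-bond
#'   records; detected when `NULL`.
#' @param window_frac fraction of trailing frames scored, in (0, 1].
#' @param d_ha_max,dha_min,hax_min geometry cutoffs, as [detect_hbonds()].
#' @return persistence in [0, 1].
#' @export
pers_score <- function(ens, reference_hbs = NULL, window_frac = 0.2,
                       d_ha_max = 2.8, dha_min = 120, hax_min = 90) {
  if (window_frac <= 0 || window_frac > 1)
    stop("window_frac must be in (0, 1]")
  f0 <- frame_structure(ens, 1)
  if (is.null(reference_hbs))
    reference_hbs <- detect_hbonds(f0, d_ha_max, dha_min, hax_min)
  hbs <- reference_hbs[reference_hbs$kind == "hb", , drop = FALSE]
  if (!nrow(hbs)) return(0)
  at <- ens$atom_template$atoms
  # acceptor-bonded heavy atoms from the frame-0 topology
  bonds <- bond_list(f0)
  adj <- vector("list", nrow(at))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  triples <- lapply(seq_len(nrow(hbs)), function(r) {
    d_i <- match(hbs$donor_serial[r], at$serial)
    h_i <- match(hbs$h_serial[r], at$serial)
    a_i <- match(hbs$acceptor_serial[r], at$serial)
    list(d = d_i, h = h_i, a = a_i,
         x = adj[[a_i]][at$element[adj[[a_i]]] != "H"])
  })
  nf <- n_frames(ens)
  n_win <- max(1, floor(window_frac * nf))
  window <- (nf - n_win + 1):nf
  trial_scores <- vapply(ens$trials, function(tr) {
    kept <- 0
    for (k in window) {
      xyz <- tr[, , k]
      for (tp in triples) {
        if (.hb_geometry_ok(xyz, tp$d, tp$h, tp$a, tp$x, d_ha_max,
                            dha_min, hax_min)) kept <- kept + 1
      }
    }
    kept / (length(window) * length(triples))
  }, 0)
  mean(trial_scores)
}

#' CompScore: composite stability score
#'
#' `pose_score - weight * pers_score`; lower values indicate a more
#' stable pose.  The default weight of 5 is the value that reproduces
#' the published score tables for this protocol.
#'
#' @param pose_score PoseScore, Angstrom.
#' @param pers_score persistence in [0, 1].
#' @param weight persistence weight.
#' @return CompScore (Angstrom-scaled).
#' @export
comp_score <- function(pose_score, pers_score, weight = 5) {
  if (any(pers_score < 0 | pers_score > 1))
    stop("pers_score must be in [0, 1]")
  pose_score - weight * pers_score
}

#' Stability call from the PoseScore
#'
#' A pose is called stable when its PoseScore is strictly below the
#' threshold (default 2 Angstrom); a score of exactly 2 is unstable.
#'
#' @param result a `bpmd_result`, or a bare PoseScore.
#' @param threshold Angstrom.
#' @return `"stable"` or `"unstable"`.
#' @export
stability_call <- function(result, threshold = 2.0) {
  ps <- if (inherits(result, "bpmd_result")) result$pose_score else result
  if (ps < threshold) "stable" else "unstable"
}

#' Score a pose from its trajectory ensemble
#'
#' Convenience wrapper running [ligand_rmsd_curve()], [pose_score()],
#' [pers_score()] and [comp_score()] in one call.
#'
#' @param ens a `traj_ensemble`.
#' @param window_frac persistence window fraction.
#' @param weight CompScore persistence weight.
#' @param site_radius binding-site alignment radius, Angstrom.
#' @return object of class `bpmd_result`: `pose_score`, `pers_score`,
#'   `comp_score`, `rmsd_curve`, `n_trials`, `stable`.
#' @export
bpmd_score <- function(ens, window_frac = 0.2, weight = 5,
                       site_radius = 5) {
  curve <- ligand_rmsd_curve(ens, site_radius = site_radius)
  ps <- pose_score(curve)
  prs <- pers_score(ens, window_frac = window_frac)
  res <- structure(list(pose_score = ps, pers_score = prs,
                        comp_score = comp_score(ps, prs, weight),
                        rmsd_curve = curve,
                        n_trials = length(ens$trials)),
                   class = "bpmd_result")
  res$stable <- stability_call(res)
  res
}

#' @export
print.bpmd_result <- function(x, ...) {
  cat(sprintf("<bpmd_result> PoseScore %.3f A, PersScore %.3f, CompScore %.3f (%s, %d trials)\n",
              x$pose_score, x$pers_score, x$comp_score, x$stable,
              x$n_trials))
  invisible(x)
}

#' Rank poses by CompScore
#'
#' Ascending CompScore; ties broken by lower PoseScore, then pose id.
#'
#' @param results named list of `bpmd_result`s (names = pose ids).
#' @return data frame with one row per pose, best first.
#' @export
rank_by_compscore <- function(results) {
  if (!length(results)) stop("no results to rank")
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_along(results))
  df <- data.frame(pose_id = ids,
                   pose_score = vapply(results, `[[`, 0, "pose_score"),
                   pers_score = vapply(results, `[[`, 0, "pers_score"),
                   comp_score = vapply(results, `[[`, 0, "comp_score"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$comp_score, df$pose_score, df$pose_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Export a BPMD-style result
#'
#' Writes the scores as JSON and the averaged RMSD curve as CSV
#' (`timestamp_ps, mean_rmsd`).
#'
#' @param result a `bpmd_result`.
#' @param pose_id identifier recorded in the JSON.
#' @param json_path,curve_path output paths (`NULL` to skip either).
#' @return invisibly, the JSON string.
#' @export
write_bpmd_result <- function(result, pose_id, json_path = NULL,
                              curve_path = NULL) {
  js <- jsonlite::toJSON(list(pose_id = pose_id,
                              pose_score = result$pose_score,
                              pers_score = result$pers_score,
                              comp_score = result$comp_score,
                              stable = result$stable == "stable"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(curve_path)) {
    utils::write.csv(data.frame(timestamp_ps = result$rmsd_curve$time_ps,
                                mean_rmsd = result$rmsd_curve$rmsd),
                     curve_path, row.names = FALSE)
  }
  invisible(js)
}
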