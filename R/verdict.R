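# Pose-reliability decision procedure: compare the top-scored candidate
# pose against the post-MD representative conformation and classify the
# outcome as confirmed, refined, or ambiguous.

#' Compare a candidate pose with a post-MD representative conformation
#'
#' The representative complex is aligned onto the candidate complex via
#' the binding-site backbone (receptor backbone within `site_radius`
#' Angstrom of the candidate ligand), then the ligand heavy-atom RMSD is
#' measured at fixed correspondence.  Strong interactions (hydrogen
#' bonds, pi-pi stackings, ionic bridges) are counted on both complexes.
#'
#' @param top_complex `mol` of the candidate (pre-MD) complex.
#' @param rep_complex `mol` of the representative (post-MD) complex;
#'   same atom set.
#' @param ring_defs ring definitions for the pi-pi detector.
#' @param ddg binding free-energy change `dG(before) - dG(after)`
#'   (kcal/mol); computed with [delta_g_bind()] on both complexes when
#'   `NULL` and parameters are present, else left `NA`.
#' @param site_radius alignment site radius, Angstrom.
#' @param gb a [gb_params()] used when `ddg` is computed here.
#' @return object of class `pose_comparison`: `rmsd_pre_post`, `ddg`,
#'   `strong_before`, `strong_after`, `verdict` (unset, see
#'   [classify_pose()]).
#' @export
compare_poses <- function(top_complex, rep_complex, ring_defs = list(),
                          ddg = NULL, site_radius = 5,
                          gb = gb_params()) {
  if (n_atoms(top_complex) != n_atoms(rep_complex) ||
      !identical(top_complex$atoms$serial, rep_complex$atoms$serial))
    stop("complexes must share the same atom set")
  lig <- role_idx(top_complex, "ligand", heavy_only = TRUE)
  if (!length(lig)) stop("no ligand heavy atoms")
  at <- top_complex$atoms
  bb <- which(at$role == "receptor" & at$name %in% c("N", "CA", "C", "O"))
  if (length(bb) < 3) bb <- which(at$role == "receptor" & at$is_heavy)
  xyz_top <- mol_xyz(top_complex)
  d <- .dist_mat(xyz_top[bb, , drop = FALSE],
                 xyz_top[lig, , drop = FALSE])
  site <- bb[apply(d, 1, min) <= site_radius]
  if (length(site) < 3) site <- bb
  xyz_rep <- mol_xyz(rep_complex)
  sp <- kabsch_superpose(xyz_rep[site, , drop = FALSE],
                         xyz_top[site, , drop = FALSE])
  moved_lig <- apply_superposition(sp, xyz_rep[lig, , drop = FALSE])
  rmsd <- rmsd_fixed(moved_lig, xyz_top[lig, , drop = FALSE])
  strong <- function(m) {
    recs <- detect_interactions(m, ring_defs)
    sum(recs$kind %in% c("hb", "pipi", "ionic"))
  }
  if (is.null(ddg)) {
    ddg <- if (!any(is.na(top_complex$atoms$charge))) {
      delta_delta_g(delta_g_bind(top_complex, params = gb)$dg_bind,
                    delta_g_bind(rep_complex, params = gb)$dg_bind)
    } else NA_real_
  }
  structure(list(rmsd_pre_post = rmsd, ddg = ddg,
                 strong_before = strong(top_complex),
                 strong_after = strong(rep_complex),
                 verdict = NA_character_),
            class = "pose_comparison")
}

#' Classify pose reliability
#'
#' Decision rule (thresholds configurable):
#' \itemize{
#'   \item \strong{ambiguous} -- the ligand moved a long way
#'     (`rmsd > rmsd_ambiguous`): the simulation is inconclusive about
#'     which pose is real.
#'   \item \strong{confirmed} -- the ligand barely moved
#'     (`rmsd <= rmsd_confirm`) and the binding free energy did not
#'     improve appreciably (`ddg < ddg_significant`): the candidate pose
#'     survives molecular dynamics essentially unchanged.
#'   \item \strong{refined} -- otherwise: the simulation found a
#'     meaningfully stabilised variant, and the representative pose is
#'     preferred.
#' }
#' Boundary values resolve conservatively: an RMSD exactly at
#' `rmsd_confirm` is still confirm-eligible, and exactly at
#' `rmsd_ambiguous` is not ambiguous.
#'
#' @param cmp a `pose_comparison` (or a list with `rmsd_pre_post`, `ddg`).
#' @param rmsd_confirm Angstrom; at or below, the pose counts as
#'   position-preserved.
#' @param rmsd_ambiguous Angstrom; strictly above, the outcome is
#'   ambiguous.
#' @param ddg_significant kcal/mol; a stabilisation at or above this is
#'   treated as a meaningful energy gain.
#' @return the input with `verdict` set and a `rationale` string.
#' @export
classify_pose <- function(cmp, rmsd_confirm = 1.0, rmsd_ambiguous = 3.0,
                          ddg_significant = 7.5) {
  r <- cmp$rmsd_pre_post; g <- cmp$ddg
  if (r > rmsd_ambiguous) {
    cmp$verdict <- "ambiguous"
    cmp$rationale <- sprintf(
      "ligand moved %.2f A (> %.1f A): simulation inconclusive", r,
      rmsd_ambiguous)
  } else if (r <= rmsd_confirm && (is.na(g) || g < ddg_significant)) {
    cmp$verdict <- "confirmed"
    cmp$rationale <- sprintf(
      "ligand moved only %.2f A and dGbind changed by %.2f kcal/mol: candidate pose preserved",
      r, ifelse(is.na(g), 0, g))
  } else {
    cmp$verdict <- "refined"
    cmp$rationale <- sprintf(
      "ligand moved %.2f A and/or dGbind improved by %.2f kcal/mol: representative pose preferred",
      r, ifelse(is.na(g), 0, g))
  }
  cmp
}

#' @export
print.pose_comparison <- function(x, ...) {
  cat(sprintf("<pose_comparison> RMSD %.2f A, ddG %.2f kcal/mol, strong %d -> %d, verdict: %s\n",
              x$rmsd_pre_post, x$ddg, x$strong_before, x$strong_after,
              if (is.na(x$verdict)) "(unset)" else x$verdict))
  invisible(x)
}

#' End-to-end pose-validation pipeline
#'
#' For each ligand: cluster candidate poses by interaction fingerprint,
#' keep the top-`k` cluster representatives, score each with the
#' metadynamics-style stability scores, rank by CompScore, run the
#' unbiased-trajectory provider for the winner, extract the
#' representative conformation, compare, and classify.  A failing stage
#' aborts that ligand's row with a diagnostic; the pipeline continues.
#'
#' @param ligands named list; each entry a list with elements:
#'   `poses` (list of `pose_record`), `receptor_site` (residue data
#'   frame for [build_sift()]), `bpmd_provider` (`function(pose)` ->
#'   `traj_ensemble` of biased trials), `md_provider` (`function(pose)`
#'   -> `traj_ensemble`, unbiased), and optionally `ring_defs`,
#'   `cluster_selection` / `cluster_cutoff` (forwarded to
#'   [representative_conformation()]).
#' @param k cluster representatives carried into scoring.
#' @param sim_threshold Tanimoto clustering threshold.
#' @param gb a [gb_params()] for the binding free energies.
#' @param ... threshold overrides passed to [classify_pose()].
#' @return data frame with one row per ligand: pose accounting, winning
#'   pose scores, comparison metrics and verdict.
#' @export
run_pipeline <- function(ligands, k = 3, sim_threshold = 0.7,
                         gb = gb_params(), ...) {
  rows <- lapply(names(ligands), function(nm) {
    lg <- ligands[[nm]]
    tryCatch({
      poses <- lapply(lg$poses, function(p) {
        if (is.null(p$fingerprint))
          p$fingerprint <- build_sift(p, lg$receptor_site,
                                      ring_defs = lg$ring_defs %||% list())
        p
      })
      cl <- cluster_poses(poses, sim_threshold)
      top <- select_top_k(cl$representatives, k)
      results <- lapply(top, function(p) bpmd_score(lg$bpmd_provider(p)))
      names(results) <- vapply(top, `[[`, "", "pose_id")
      ranking <- rank_by_compscore(results)
      winner <- top[[match(ranking$pose_id[1],
                           vapply(top, `[[`, "", "pose_id"))]]
      md <- lg$md_provider(winner)
      rep_mol <- representative_conformation(
        md, selection = lg$cluster_selection %||% NULL,
        cutoff = lg$cluster_cutoff %||% 2.0)
      cmp <- compare_poses(winner$structure, rep_mol,
                           ring_defs = lg$ring_defs %||% list(), gb = gb)
      cmp <- classify_pose(cmp, ...)
      best <- results[[ranking$pose_id[1]]]
      data.frame(ligand = nm, n_poses = cl$n_poses,
                 n_clusters = cl$n_clusters,
                 top_pose = ranking$pose_id[1],
                 pose_score = best$pose_score,
                 pers_score = best$pers_score,
                 comp_score = best$comp_score, stable = best$stable,
                 rmsd_pre_post = cmp$rmsd_pre_post, ddg = cmp$ddg,
                 strong_before = cmp$strong_before,
                 strong_after = cmp$strong_after, verdict = cmp$verdict,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(ligand = nm, n_poses = NA_integer_,
                 n_clusters = NA_integer_, top_pose = NA_character_,
                 pose_score = NA_real_, pers_score = NA_real_,
                 comp_score = NA_real_, stable = NA_character_,
                 rmsd_pre_post = NA_real_, ddg = NA_real_,
                 strong_before = NA_integer_, strong_after = NA_integer_,
                 verdict = NA_character_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
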