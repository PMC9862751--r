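# RMSD-matrix clustering of trajectory frames and most-neighbors
# representative-conformation selection.

#' Pairwise superposed RMSD matrix over frames
#'
#' Every frame pair is superposed on the selection (Kabsch) before the
#' RMSD of the selection atoms is taken, so rigid-body motion does not
#' register as conformational distance.
#'
#' @param frames list of N x 3 matrices, or an N x 3 x T array.
#' @param selection atom indices (backbone atoms, conventionally).
#' @return symmetric T x T matrix, Angstrom, zero diagonal.
#' @export
rmsd_matrix <- function(frames, selection) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (length(frames) < 2) stop("need at least 2 frames")
  if (!length(selection)) stop("empty atom selection")
  sel <- lapply(frames, function(f) as.matrix(f)[selection, , drop = FALSE])
  n <- length(sel)
  m <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- kabsch_superpose(sel[[i]], sel[[j]])$rmsd
  }
  m
}

#' Subsample frames at a fixed interval
#'
#' Keeps every `interval`-th frame starting from the first, capped at
#' `max_frames`; original indices are retained.
#'
#' @param frames list or array of frames (or an integer frame count).
#' @param interval extraction interval.
#' @param max_frames cap on retained frames.
#' @return list with `indices` (1-based original positions) and `frames`
#'   (the subset, when frames were supplied).
#' @export
subsample_frames <- function(frames, interval = 10, max_frames = 1000) {
  if (interval < 1) stop("interval must be >= 1")
  n <- if (is.numeric(frames) && length(frames) == 1) frames
  else if (is.array(frames) && length(dim(frames)) == 3) dim(frames)[3]
  else length(frames)
  idx <- seq(1, n, by = interval)
  if (length(idx) > max_frames) idx <- idx[seq_len(max_frames)]
  out <- list(indices = idx)
  if (!(is.numeric(frames) && length(frames) == 1)) {
    out$frames <- if (is.array(frames) && length(dim(frames)) == 3)
      frames[, , idx, drop = FALSE]
    else frames[idx]
  }
  out
}

#' Neighbor-count (leader) clustering of an RMSD matrix
#'
#' Iteratively: the frame with the most neighbors (pairwise distance
#' <= `cutoff`) among the unassigned frames seeds the next cluster and
#' absorbs its neighbors; repeat until all frames are assigned or
#' `max_clusters` is reached, the remainder being labelled 0
#' (singleton overflow).  Ties in neighbor count resolve to the lowest
#' frame index.  Each cluster's representative is its seed -- the member
#' with the most neighbors.
#'
#' @param mat symmetric RMSD matrix.
#' @param cutoff neighbor distance cutoff, Angstrom.
#' @param max_clusters maximum clusters emitted.
#' @return object of class `traj_clusters`: `labels` (per-frame cluster
#'   id, 0 = overflow), `representative_frame` (seed of the largest
#'   cluster), `seeds` (per-cluster seed frames), `neighbor_counts`
#'   (on the full matrix), `cutoff`.
#' @export
neighbor_cluster <- function(mat, cutoff = 2.0, max_clusters = 10) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || any(abs(mat - t(mat)) > 1e-8))
    stop("RMSD matrix must be square and symmetric")
  n <- nrow(mat)
  adj <- mat <= cutoff
  diag(adj) <- FALSE
  full_counts <- rowSums(adj)
  labels <- rep(0L, n)
  seeds <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining) && cl < max_clusters) {
    counts <- rowSums(adj[, remaining, drop = FALSE]) * remaining
    seed <- which(counts == max(counts[remaining]) & remaining)[1]
    cl <- cl + 1L
    members <- c(seed, which(adj[seed, ] & remaining))
    members <- unique(members)
    labels[members] <- cl
    seeds <- c(seeds, seed)
    remaining[members] <- FALSE
  }
  structure(list(labels = labels, representative_frame = seeds[1],
                 seeds = seeds, neighbor_counts = full_counts,
                 cutoff = cutoff),
            class = "traj_clusters")
}

#' @export
print.traj_clusters <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<traj_clusters> %d frames in %d cluster(s) (+%d overflow), cutoff %.2f A; representative frame %d\n",
              length(x$labels), k, sum(x$labels == 0), x$cutoff,
              x$representative_frame))
  invisible(x)
}

#' Representative conformation of a trajectory
#'
#' Pipeline of [subsample_frames()], [rmsd_matrix()] on the selection
#' (receptor backbone by default) and [neighbor_cluster()]; returns the
#' seed frame of the top cluster -- the structure with the largest
#' number of neighbors -- materialised as a `mol`.
#'
#' @param ens a `traj_ensemble` (first trial is used).
#' @param selection atom indices for the RMSD matrix; default receptor
#'   backbone (falling back to all heavy atoms).
#' @param cutoff neighbor cutoff, Angstrom.
#' @param interval,max_frames subsampling parameters.
#' @param max_clusters cluster cap.
#' @return `mol` of the representative frame; its original frame index
#'   is in attribute `"frame"`, the clustering in `"clusters"`.
#' @export
representative_conformation <- function(ens, selection = NULL,
                                        cutoff = 2.0, interval = 10,
                                        max_frames = 1000,
                                        max_clusters = 10) {
  at <- ens$atom_template$atoms
  if (is.null(selection)) {
    selection <- which(at$role == "receptor" &
                         at$name %in% c("N", "CA", "C", "O"))
    if (length(selection) < 3)
      selection <- which(at$is_heavy)
  }
  tr <- ens$trials[[1]]
  sub <- subsample_frames(tr, interval, max_frames)
  if (length(sub$indices) == 1) {
    out <- frame_structure(ens, sub$indices[1])
    attr(out, "frame") <- sub$indices[1]
    return(out)
  }
  m <- rmsd_matrix(sub$frames, selection)
  cl <- neighbor_cluster(m, cutoff, max_clusters)
  frame <- sub$indices[cl$representative_frame]
  out <- frame_structure(ens, frame)
  attr(out, "frame") <- frame
  attr(out, "clusters") <- cl
  out
}
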