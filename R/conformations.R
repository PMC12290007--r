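#' Conformational clustering of adsorbed states
#'
#' Bound-state frames are superposed pairwise by least-squares (Kabsch)
#' rotation and clustered with the GROMOS neighbor-count algorithm at a
#' fixed RMSD cutoff (0.15 nm in the reference protocol, applied to the
#' peptide structure): the structure with the most neighbors within the
#' cutoff seeds a cluster, it and its neighbors are removed, and the
#' procedure repeats until all frames are assigned.
#'
#' @name conformations
NULL

#' Kabsch-superposed RMSD between two coordinate sets
#'
#' Applies the optimal least-squares rotation and translation of `y` onto
#' `x` (proper rotation enforced, determinant +1) and returns the RMSD.
#'
#' @param x,y n x 3 coordinate matrices with matching atom order.
#' @param weights optional per-atom weights (e.g. masses); uniform when
#'   omitted.
#' @return RMSD in the input units.
#' @export
kabsch_rmsd <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("coordinate sets must have equal sizes")
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 atoms for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  xc <- sweep(x, 2, colSums(x * w))
  yc <- sweep(y, 2, colSums(y * w))
  h <- t(yc * w) %*% xc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- xc - yc %*% t(rot)
  sqrt(sum(w * rowSums(diff^2)))
}

#' Extract the bound-state frames of a trajectory
#'
#' @param frames list of [traj_frame] aligned with the profile.
#' @param profile a [binding_profile] computed from the same frames.
#' @return the frames with `bound = TRUE`, timestamps preserved.
#' @export
extract_bound_frames <- function(frames, profile) {
  if (length(frames) != length(profile$bound))
    stop("profile is not aligned with the frames")
  out <- frames[profile$bound]
  if (!length(out)) warning("no bound frames to extract")
  out
}

#' Pairwise Kabsch RMSD matrix over a frame set
#'
#' @param frames list of [traj_frame].
#' @param selection atom indices used for superposition (default: all).
#' @param topology optional [system_topology]; when given and `selection` is
#'   `NULL`, peptide non-hydrogen atoms are used.
#' @param stride keep every stride-th frame before the pairwise computation.
#' @param weights optional per-atom weights.
#' @param unwrap make the peptide whole per frame first (needs `topology`).
#' @return symmetric matrix of RMSDs (nm) with attribute `frame_ids` (the
#'   indices into `frames` retained after striding).
#' @export
rmsd_matrix <- function(frames, selection = NULL, topology = NULL,
                        stride = 1L, weights = NULL, unwrap = FALSE) {
  ids <- seq(1L, length(frames), by = as.integer(stride))
  frames <- frames[ids]
  if (length(frames) < 2L) stop("need at least 2 frames after striding")
  if (is.null(selection)) {
    if (is.null(topology)) stop("give a selection or a topology")
    selection <- which(topology$segment == "peptide" &
                         topology$element != "H")
  }
  if (!length(selection)) stop("empty selection")
  coords <- lapply(frames, function(f) {
    if (unwrap) f <- unwrap_peptide(f, topology)
    f$xyz[selection, , drop = FALSE]
  })
  n <- length(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]], weights)
    }
  }
  attr(m, "frame_ids") <- ids
  m
}

#' GROMOS neighbor-count clustering
#'
#' Iteratively counts, among unassigned frames, the neighbors of each frame
#' within the RMSD cutoff (a frame is its own neighbor); the frame with the
#' most neighbors (ties: lowest frame index) becomes a cluster center and is
#' removed together with its neighbors. Repeats until all frames are
#' assigned; singleton clusters are allowed. Cluster sizes are
#' non-increasing by construction.
#'
#' @param m square symmetric RMSD matrix (nm).
#' @param cutoff RMSD cutoff in nm (neighbors satisfy RMSD <= cutoff).
#' @return list of class `gromos_clusters`: `members` (list of index
#'   vectors into the matrix rows), `centers` (cluster center indices),
#'   `populations` (percent of frames), `cutoff`, `n_frames`.
#' @export
gromos_cluster <- function(m, cutoff) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RMSD matrix must be square")
  if (anyNA(m)) stop("NaN/NA in RMSD matrix")
  stopifnot(cutoff > 0)
  n <- nrow(m)
  adj <- m <= cutoff
  unassigned <- rep(TRUE, n)
  members <- list(); centers <- integer(0)
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- rowSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]          # which.max: lowest index wins
    neigh <- idx[adj[center, idx]]
    members[[length(members) + 1L]] <- neigh
    centers <- c(centers, center)
    unassigned[neigh] <- FALSE
  }
  sizes <- lengths(members)
  structure(list(members = members, centers = centers,
                 populations = 100 * sizes / n,
                 cutoff = cutoff, n_frames = n,
                 frame_ids = attr(m, "frame_ids")),
            class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat(sprintf("<gromos_clusters> %d frames, %d clusters (cutoff %.3f nm)\n",
              x$n_frames, length(x$members), x$cutoff))
  k <- min(5L, length(x$members))
  for (i in seq_len(k))
    cat(sprintf("  cluster %d: %5.1f%% (center frame %d)\n",
                i, x$populations[i], x$centers[i]))
  if (length(x$members) > k) cat("  ...\n")
  invisible(x)
}

#' Summarise clusters above a population floor
#'
#' @param result a [gromos_cluster] result.
#' @param times,ssd,eed per-frame series aligned with the clustered frames
#'   (i.e. of length `result$n_frames`).
#' @param population_floor_percent report clusters above this population
#'   (default 10).
#' @return data.frame with cluster, population_percent, ssd_nm, eed_nm,
#'   representative_time_ps (timestamp of the cluster center).
#' @export
cluster_summary <- function(result, times, ssd, eed,
                            population_floor_percent = 10) {
  stopifnot(length(times) == result$n_frames,
            length(ssd) == result$n_frames,
            length(eed) == result$n_frames)
  keep <- which(result$populations > population_floor_percent)
  out <- data.frame(
    cluster = keep,
    population_percent = result$populations[keep],
    ssd_nm = vapply(keep, function(i) mean(ssd[result$members[[i]]]),
                    numeric(1)),
    eed_nm = vapply(keep, function(i) mean(eed[result$members[[i]]]),
                    numeric(1)),
    representative_time_ps = times[result$centers[keep]])
  rownames(out) <- NULL
  out
}

#' Write cluster assignments as TSV
#'
#' @param result a [gromos_cluster] result.
#' @param times timestamps of the clustered frames.
#' @param path output path.
#' @export
write_cluster_assignments <- function(result, times, path) {
  cl <- integer(result$n_frames)
  for (i in seq_along(result$members)) cl[result$members[[i]]] <- i
  write_tsv_plain(data.frame(frame_id = seq_len(result$n_frames),
                             time_ps = times, cluster_id = cl), path)
}
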