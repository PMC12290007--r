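#' Per-frame adsorption observables and binding profiles
#'
#' The binding coordinate is the surface separation distance (SSD): the
#' periodic z-distance between the peptide center of mass and the plane of
#' the outermost Ti atoms, minimised over the two equivalent slab faces. The
#' conformational coordinate is the end-to-end distance (EED) between the
#' Calpha atoms of the first and last residues. A frame is bound when
#' SSD < 1 nm (strict); the binding fraction is the percentage of bound
#' frames over the analysed window.
#'
#' @name observables
NULL

#' Analysis parameter set
#'
#' @param bound_threshold nm; SSD below which a frame is bound (default 1.0).
#' @param layer_tolerance nm; outer-Ti layer window (default 0.05).
#' @param production_start ps; frames before this time are discarded
#'   (default 0: deposited series are production-only).
#' @param min_dwell_frames runs of bound/unbound shorter than this are merged
#'   into the surrounding state (default 1 = no debouncing).
#' @param strong_binder_percent percent-bound cutoff for the strong-binder
#'   subset (default 50).
#' @param cluster_series_percent percent-bound cutoff for sequences entering
#'   conformational clustering (default 90).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(bound_threshold = 1.0, layer_tolerance = 0.05,
                            production_start = 0, min_dwell_frames = 1L,
                            strong_binder_percent = 50,
                            cluster_series_percent = 90,
                            sd_type = c("population", "sample")) {
  stopifnot(bound_threshold > 0,
            strong_binder_percent > 0, strong_binder_percent <= 100,
            cluster_series_percent > 0, cluster_series_percent <= 100)
  structure(list(bound_threshold = bound_threshold,
                 layer_tolerance = layer_tolerance,
                 production_start = production_start,
                 min_dwell_frames = as.integer(min_dwell_frames),
                 strong_binder_percent = strong_binder_percent,
                 cluster_series_percent = cluster_series_percent,
                 sd_type = match.arg(sd_type)),
            class = "analysis_params")
}

peptide_bonds <- function(topology, frame = NULL, cutoff = 0.2) {
  b <- attr(topology, "bonds")
  pep <- which(topology$segment == "peptide")
  if (!is.null(b)) {
    keep <- b[, 1] %in% pep & b[, 2] %in% pep
    return(b[keep, , drop = FALSE])
  }
  if (is.null(frame))
    stop("no bond list in topology and no frame to infer bonds from")
  d <- pairwise_min_image(frame$xyz[pep, , drop = FALSE],
                          frame$xyz[pep, , drop = FALSE], frame$box)
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  cbind(pep[hit[, 1]], pep[hit[, 2]])
}

#' Make the peptide whole across periodic boundaries
#'
#' Rebuilds the peptide by a breadth-first traversal of its bond graph from
#' its first atom, placing each atom at the minimum-image position relative
#' to its already-placed bonded neighbour. Other segments are untouched.
#'
#' @param frame a [traj_frame].
#' @param topology a [system_topology] (peptide bond list taken from its
#'   `bonds` attribute, or inferred by a 0.2 nm distance cutoff).
#' @return the frame with unwrapped peptide coordinates.
#' @export
unwrap_peptide <- function(frame, topology) {
  pep <- which(topology$segment == "peptide")
  if (!length(pep)) return(frame)
  bonds <- peptide_bonds(topology, frame)
  n <- length(pep)
  local <- match(c(bonds[, 1], bonds[, 2]), pep)
  adj <- split(c(match(bonds[, 2], pep), match(bonds[, 1], pep)),
               c(match(bonds[, 1], pep), match(bonds[, 2], pep)))
  xyz <- frame$xyz
  placed <- logical(n)
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[as.character(i)]] %||% integer(0)) {
      if (placed[j]) next
      d <- xyz[pep[j], ] - xyz[pep[i], ]
      xyz[pep[j], ] <- xyz[pep[i], ] + min_image(d, frame$box)
      placed[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  if (!all(placed))
    stop("peptide bond graph is disconnected; cannot unwrap")
  # verify integrity: every bond must be short after unwrapping
  bl <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                        xyz[bonds[, 2], , drop = FALSE])^2))
  if (any(bl > 0.25))
    stop("broken peptide after unwrapping: bond length ",
         sprintf("%.3f", max(bl)), " nm exceeds 0.25 nm")
  frame$xyz <- xyz
  frame
}

peptide_com <- function(frame, topology) {
  pep <- which(topology$segment == "peptide")
  m <- topology$mass[pep]
  colSums(frame$xyz[pep, , drop = FALSE] * m) / sum(m)
}

#' Surface separation distance of a frame
#'
#' Periodic z-distance from the mass-weighted peptide center of mass to the
#' mean outer-Ti plane, minimised over the two slab faces. The peptide must
#' already be whole ([unwrap_peptide]).
#'
#' @param frame a [traj_frame] with unwrapped peptide.
#' @param classes an [classify_atoms] result.
#' @param topology a [system_topology].
#' @return SSD in nm.
#' @export
compute_ssd <- function(frame, classes, topology) {
  if (!length(classes$TI_TOP) || !length(classes$TI_BOTTOM))
    stop("empty outer Ti layer")
  com_z <- peptide_com(frame, topology)[3]
  lz <- frame$box[3]
  d_top <- periodic_dist1(com_z %% lz, classes$plane_top %% lz, lz)
  d_bot <- periodic_dist1(com_z %% lz, classes$plane_bottom %% lz, lz)
  min(d_top, d_bot)
}

#' End-to-end distance of a frame
#'
#' Euclidean distance between the Calpha atoms of the first and last
#' residues (peptide must be whole).
#'
#' @inheritParams compute_ssd
#' @return EED in nm.
#' @export
compute_eed <- function(frame, classes) {
  ca <- classes$peptide_CA
  if (length(ca) < 2L) stop("need Calpha atoms of first and last residues")
  sqrt(sum((frame$xyz[ca[1], ] - frame$xyz[ca[length(ca)], ])^2))
}

debounce_states <- function(bound, min_dwell) {
  if (min_dwell <= 1L || length(bound) < 2L) return(bound)
  repeat {
    r <- rle(bound)
    short <- which(r$lengths < min_dwell)
    short <- short[short != 1L & short != length(r$lengths)]
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    r$values[k] <- r$values[k - 1L]
    bound <- inverse.rle(r)
  }
  bound
}

state_events <- function(times, bound) {
  if (!length(bound)) return(data.frame(t_start = numeric(0),
                                        t_end = numeric(0),
                                        state = character(0)))
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(t_start = times[starts], t_end = times[ends],
             state = ifelse(r$values, "bound", "unbound"),
             n_frames = r$lengths)
}

#' Binding profile of a trajectory
#'
#' Computes SSD and EED per frame (after unwrapping the peptide), classifies
#' bound/unbound states by the SSD threshold, and derives the binding
#' fraction, bound/unbound EED statistics and the state event list. The
#' surface is taken as rigid: atom classes are resolved on the first frame.
#'
#' @param frames list of [traj_frame].
#' @param topology a [system_topology].
#' @param params an [analysis_params].
#' @return list of class `binding_profile` with elements `times`, `ssd`,
#'   `eed`, `bound`, `percent_bound`, `eed_a`, `std_a`, `eed_d`, `std_d`,
#'   `events`, `n_frames`. EED statistics over an empty state are `NA`.
#' @export
binding_profile <- function(frames, topology, params = analysis_params()) {
  times <- vapply(frames, `[[`, numeric(1), "time")
  keep <- times >= params$production_start
  frames <- frames[keep]; times <- times[keep]
  if (!length(frames)) stop("no frames in the analysis window")
  classes <- classify_atoms(topology, frames[[1]],
                            layer_tolerance = params$layer_tolerance)
  n <- length(frames)
  ssd <- numeric(n); eed <- numeric(n)
  for (i in seq_len(n)) {
    f <- unwrap_peptide(frames[[i]], topology)
    ssd[i] <- compute_ssd(f, classes, topology)
    eed[i] <- compute_eed(f, classes)
  }
  bound <- debounce_states(ssd < params$bound_threshold,
                           params$min_dwell_frames)
  sdf <- if (params$sd_type == "population") sd_pop else stats::sd
  profile <- list(times = times, ssd = ssd, eed = eed, bound = bound,
                  percent_bound = 100 * mean(bound),
                  eed_a = if (any(bound)) mean(eed[bound]) else NA_real_,
                  std_a = if (any(bound)) sdf(eed[bound]) else NA_real_,
                  eed_d = if (any(!bound)) mean(eed[!bound]) else NA_real_,
                  std_d = if (any(!bound)) sdf(eed[!bound]) else NA_real_,
                  events = state_events(times, bound),
                  n_frames = n)
  structure(profile, class = "binding_profile")
}

#' Binding profile from a precomputed SSD/EED series
#'
#' Builds a [binding_profile] directly from per-frame series (e.g. deposited
#' SSD/EED files), without trajectory processing.
#'
#' @param times ps.
#' @param ssd,eed nm per frame.
#' @param params an [analysis_params].
#' @export
profile_from_series <- function(times, ssd, eed,
                                params = analysis_params()) {
  keep <- times >= params$production_start
  times <- times[keep]; ssd <- ssd[keep]; eed <- eed[keep]
  if (!length(times)) stop("no frames in the analysis window")
  bound <- debounce_states(ssd < params$bound_threshold,
                           params$min_dwell_frames)
  sdf <- if (params$sd_type == "population") sd_pop else stats::sd
  structure(list(times = times, ssd = ssd, eed = eed, bound = bound,
                 percent_bound = 100 * mean(bound),
                 eed_a = if (any(bound)) mean(eed[bound]) else NA_real_,
                 std_a = if (any(bound)) sdf(eed[bound]) else NA_real_,
                 eed_d = if (any(!bound)) mean(eed[!bound]) else NA_real_,
                 std_d = if (any(!bound)) sdf(eed[!bound]) else NA_real_,
                 events = state_events(times, bound),
                 n_frames = length(times)),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("<binding_profile> %d frames, %.2f%% bound\n",
              x$n_frames, x$percent_bound))
  cat(sprintf("  EED bound %.3f +/- %.3f nm; unbound %.3f +/- %.3f nm\n",
              x$eed_a, x$std_a, x$eed_d, x$std_d))
  invisible(x)
}

#' Rank peptides by binding fraction
#'
#' @param profiles named list of [binding_profile] (names are sequence
#'   labels).
#' @param digits decimals used in the report columns (default 2); the
#'   underlying profiles are not rounded.
#' @return data.frame with columns label, percent_bound, eed_a, std_a,
#'   eed_d, std_d, sorted by percent_bound descending, ties alphabetical.
#' @export
rank_peptides <- function(profiles, digits = 2) {
  if (!length(profiles)) stop("profiles must be a nonempty named list")
  stopifnot(!is.null(names(profiles)))
  tab <- data.frame(
    label = names(profiles),
    percent_bound = vapply(profiles, `[[`, numeric(1), "percent_bound"),
    eed_a = vapply(profiles, `[[`, numeric(1), "eed_a"),
    std_a = vapply(profiles, `[[`, numeric(1), "std_a"),
    eed_d = vapply(profiles, `[[`, numeric(1), "eed_d"),
    std_d = vapply(profiles, `[[`, numeric(1), "std_d"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$percent_bound, tab$label), ]
  rownames(tab) <- NULL
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  tab
}

#' Read / write per-frame SSD/EED series
#'
#' Three-column TSV: `time_ps`, `ssd_nm`, `eed_nm`.
#'
#' @param profile a [binding_profile].
#' @param path file path.
#' @name series_io
NULL

#' @rdname series_io
#' @export
write_series <- function(profile, path) {
  write_tsv_plain(data.frame(time_ps = profile$times, ssd_nm = profile$ssd,
                             eed_nm = profile$eed), path)
}

#' @rdname series_io
#' @param params an [analysis_params] used to rebuild the profile.
#' @export
read_series <- function(path, params = analysis_params()) {
  df <- read_tsv_plain(path)
  profile_from_series(df$time_ps, df$ssd_nm, df$eed_nm, params)
}
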