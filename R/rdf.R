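#' Radial distribution functions against surface oxygens
#'
#' RDFs between typed peptide atoms (sidechain N of basic residues,
#' N-terminal amine, carboxylate and sidechain oxygens, Calpha of apolar
#' residues) and the two surface oxygen types of the hydroxylated anatase
#' (101) face: bridging lattice oxygens (OB) and hydroxyl oxygens (OF).
#' Normalisation follows the GROMACS convention (whole-box density of the
#' B selection); raw pair counts are retained so alternative normalisations
#' can be applied afterwards. Peak positions, not heights, are the
#' convention-independent observable.
#'
#' @name rdf
NULL

#' Resolve a selection expression to atom indices
#'
#' Grammar (case-insensitive, tokens separated by spaces):
#' \itemize{
#'   \item `"surface OB"`, `"surface OF"`, `"surface TI"`
#'   \item `"NA"`, `"CL"`, `"water O"`
#'   \item `"nterm N"`, `"cterm O"`, `"peptide O"`
#'   \item `"sidechain N pos <i>"`, `"sidechain O pos <i>"` (1-based
#'     residue position; hyphenated `sidechain-N` also accepted)
#'   \item `"CA pos <i>"`, `"CA res <letters>"` (Calpha of positions whose
#'     residue is among the letters, e.g. `"CA res ALP"`)
#' }
#'
#' @param expr selection string.
#' @param topology a [system_topology].
#' @param classes an [classify_atoms] result.
#' @return integer vector of atom indices (possibly empty).
#' @export
resolve_selection <- function(expr, topology, classes) {
  toks <- strsplit(trimws(gsub("-", " ", tolower(expr))), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  fail <- function(pos) stop("unknown token '", toks[pos],
                             "' at position ", pos, " in selection '",
                             expr, "'")
  get_pos <- function(at) {
    if (length(toks) < at || toks[at - 1L] != "pos") fail(min(at, length(toks)))
    p <- suppressWarnings(as.integer(toks[at]))
    if (is.na(p)) fail(at)
    p
  }
  head1 <- toks[1]
  if (head1 == "surface") {
    if (length(toks) != 2L) fail(length(toks))
    return(switch(toks[2], ob = classes$OB, of = classes$OF,
                  ti = classes$TI, fail(2)))
  }
  if (head1 == "na") return(classes$NA.)
  if (head1 == "cl") return(classes$CL)
  if (head1 == "water") {
    if (length(toks) != 2L || toks[2] != "o") fail(2)
    return(classes$water_O)
  }
  if (head1 == "nterm") {
    if (length(toks) != 2L || toks[2] != "n") fail(2)
    return(classes$NTERM_N)
  }
  if (head1 == "cterm") {
    if (length(toks) != 2L || toks[2] != "o") fail(2)
    return(classes$CTERM_O)
  }
  if (head1 == "peptide") {
    if (length(toks) != 2L || toks[2] != "o") fail(2)
    return(classes$peptide_O)
  }
  if (head1 == "sidechain") {
    if (length(toks) < 2L) fail(1)
    set <- switch(toks[2], n = classes$sidechain_N,
                  o = classes$sidechain_O, fail(2))
    if (length(toks) == 2L) return(sort(unlist(set, use.names = FALSE)))
    p <- get_pos(4L)
    if (p < 1L || p > length(set)) stop("residue position ", p,
                                        " out of range in '", expr, "'")
    return(set[[p]])
  }
  if (head1 == "ca") {
    if (length(toks) == 1L)
      return(unname(classes$peptide_CA))
    if (toks[2] == "pos") {
      p <- get_pos(3L)
      if (p < 1L || p > length(classes$peptide_CA))
        stop("residue position ", p, " out of range in '", expr, "'")
      return(unname(classes$peptide_CA[p]))
    }
    if (toks[2] == "res") {
      if (length(toks) != 3L) fail(length(toks))
      want <- PEPTIDE_RESNAMES[split_letters(toupper(toks[3]))]
      if (anyNA(want)) fail(3)
      pos_res <- topology$resname[classes$peptide_CA]
      return(unname(classes$peptide_CA[pos_res %in% want]))
    }
    fail(2)
  }
  fail(1)
}

rdf_result <- function(bin_edges, counts, frames_used, n_a_total, n_b,
                       volume, normalization) {
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  dr <- diff(bin_edges)[1]
  rho_b <- n_b / volume
  denom <- n_a_total * 4 * pi * centers^2 * dr * rho_b
  g <- ifelse(denom > 0 & n_a_total > 0, counts / denom, 0)
  structure(list(r = centers, g = g, bin_edges = bin_edges, counts = counts,
                 frames_used = frames_used,
                 mean_n_a = if (frames_used) n_a_total / frames_used else 0,
                 n_b = n_b, normalization = normalization),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("<rdf_result> %d bins to %.3f nm, %d frames (%s)\n",
              length(x$r), max(x$bin_edges), x$frames_used,
              x$normalization))
  invisible(x)
}

#' Radial distribution function between two selections
#'
#' Minimum-image pair distances are histogrammed over frames and normalised
#' as g(r) = count(r) / (N_A_total 4 pi r^2 dr rho_B) with rho_B the
#' whole-box number density of the B selection (GROMACS convention).
#'
#' @param frames list of [traj_frame].
#' @param sel_a,sel_b atom index vectors (nonempty).
#' @param r_max histogram range, nm (default 1.2; must be below half the
#'   smallest box edge).
#' @param bin_width nm (default 0.002).
#' @return an `rdf_result` with fields `r` (bin centers), `g`, `counts`,
#'   `bin_edges`, `frames_used`, `mean_n_a`, `n_b`, `normalization`.
#' @export
compute_rdf <- function(frames, sel_a, sel_b, r_max = 1.2,
                        bin_width = 0.002) {
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  if (!length(frames)) stop("no frames")
  box <- frames[[1]]$box
  if (r_max >= min(box) / 2)
    stop("r_max must be below half the smallest box edge")
  nbin <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbin + 1L)
  counts <- numeric(nbin)
  for (f in frames) {
    d <- pairwise_min_image(f$xyz[sel_a, , drop = FALSE],
                            f$xyz[sel_b, , drop = FALSE], f$box)
    d <- d[d < nbin * bin_width & d > 0]
    if (length(d))
      counts <- counts + tabulate(pmin(nbin, floor(d / bin_width) + 1L),
                                  nbins = nbin)
  }
  rdf_result(edges, counts, length(frames),
             n_a_total = length(sel_a) * length(frames),
             n_b = length(sel_b), volume = prod(box),
             normalization = "box-density (GROMACS convention)")
}

#' First RDF peak within a distance window
#'
#' Returns the global maximum of g(r) over (0, `window_max`]; the reporting
#' convention for direct surface contacts keeps only maxima below
#' 4 Angstrom.
#'
#' @param rdf an `rdf_result`.
#' @param window_max nm (default 0.4).
#' @return list with `r_peak` (bin center, nm), `g_peak`, and
#'   `outside_window` (TRUE when the full-range global maximum lies beyond
#'   the window).
#' @export
first_peak <- function(rdf, window_max = 0.4) {
  if (window_max > max(rdf$bin_edges)) stop("window_max outside binned range")
  if (all(rdf$g == 0)) stop("all-zero g(r); no peak")
  inwin <- rdf$r <= window_max
  i <- which(inwin)[which.max(rdf$g[inwin])]
  list(r_peak = rdf$r[i], g_peak = rdf$g[i],
       outside_window = max(rdf$g) > rdf$g[i])
}

#' Sodium ions bridging the surface and the peptide
#'
#' Returns the Na+ ions simultaneously within `d_surface` of at least one
#' surface oxygen (OB or OF) and within `d_peptide` of at least one peptide
#' oxygen (backbone carbonyl, carboxylate, or sidechain oxygen) in the given
#' frame: the dual 3 Angstrom bridging criterion.
#'
#' @param frame a [traj_frame].
#' @param classes an [classify_atoms] result.
#' @param d_surface,d_peptide cutoffs in nm (default 0.3 = 3 Angstrom).
#' @return integer vector of Na atom indices (possibly empty).
#' @export
bridging_na_filter <- function(frame, classes, d_surface = 0.3,
                               d_peptide = 0.3) {
  na_idx <- classes$NA.
  if (!length(na_idx)) stop("no Na+ ions in the system")
  surf_o <- c(classes$OB, classes$OF)
  pep_o <- classes$peptide_O
  if (!length(surf_o) || !length(pep_o)) return(integer(0))
  ds <- pairwise_min_image(frame$xyz[na_idx, , drop = FALSE],
                           frame$xyz[surf_o, , drop = FALSE], frame$box)
  dp <- pairwise_min_image(frame$xyz[na_idx, , drop = FALSE],
                           frame$xyz[pep_o, , drop = FALSE], frame$box)
  hit <- apply(ds <= d_surface, 1, any) & apply(dp <= d_peptide, 1, any)
  na_idx[hit]
}

#' Conditional RDF from bridging sodium ions
#'
#' Per frame, the A selection is the output of [bridging_na_filter]; pair
#' distances to `sel_b` are histogrammed. With
#' `normalize = "pooled_count"` (default) the normalisation uses the summed
#' per-frame filtered counts, so frames with no bridging ion contribute zero
#' counts and zero A particles; with `"per_frame"` per-frame g curves are
#' averaged over frames with a nonempty filter.
#'
#' @param frames list of [traj_frame].
#' @param classes an [classify_atoms] result.
#' @param sel_b target atom indices.
#' @param d_surface,d_peptide bridging cutoffs, nm.
#' @param r_max,bin_width as [compute_rdf].
#' @param normalize `"pooled_count"` or `"per_frame"`.
#' @return an `rdf_result`; `mean_n_a` records the mean filtered Na count.
#' @export
conditional_rdf <- function(frames, classes, sel_b, d_surface = 0.3,
                            d_peptide = 0.3, r_max = 1.2, bin_width = 0.002,
                            normalize = c("pooled_count", "per_frame")) {
  normalize <- match.arg(normalize)
  if (!length(sel_b)) stop("empty selection")
  if (!length(frames)) stop("no frames")
  box <- frames[[1]]$box
  if (r_max >= min(box) / 2)
    stop("r_max must be below half the smallest box edge")
  nbin <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbin + 1L)
  counts <- numeric(nbin)
  n_a_total <- 0L
  g_acc <- numeric(nbin); n_nonempty <- 0L
  for (f in frames) {
    sel_a <- bridging_na_filter(f, classes, d_surface, d_peptide)
    if (!length(sel_a)) next
    d <- pairwise_min_image(f$xyz[sel_a, , drop = FALSE],
                            f$xyz[sel_b, , drop = FALSE], f$box)
    d <- d[d < nbin * bin_width & d > 0]
    ci <- if (length(d)) tabulate(pmin(nbin, floor(d / bin_width) + 1L),
                                  nbins = nbin) else numeric(nbin)
    counts <- counts + ci
    n_a_total <- n_a_total + length(sel_a)
    if (normalize == "per_frame") {
      centers <- (edges[-1] + edges[-length(edges)]) / 2
      rho_b <- length(sel_b) / prod(f$box)
      denom <- length(sel_a) * 4 * pi * centers^2 * bin_width * rho_b
      g_acc <- g_acc + ci / denom
      n_nonempty <- n_nonempty + 1L
    }
  }
  res <- rdf_result(edges, counts, length(frames), n_a_total,
                    n_b = length(sel_b), volume = prod(box),
                    normalization = paste0("conditional Na bridge, ",
                                           normalize))
  res$mean_n_a <- n_a_total / length(frames)
  if (normalize == "per_frame")
    res$g <- if (n_nonempty) g_acc / n_nonempty else numeric(nbin)
  res
}

#' Write an RDF as a plain-text curve
#'
#' Two whitespace-separated columns (r_nm, g) below a `#`-comment header
#' recording selections, frame count and normalisation (xvg-style).
#'
#' @param rdf an `rdf_result`.
#' @param path output path.
#' @param label free-text selection description for the header.
#' @export
write_rdf <- function(rdf, path, label = "") {
  hdr <- c(sprintf("# rdf %s", label),
           sprintf("# frames %d  mean_nA %.4f  nB %d", rdf$frames_used,
                   rdf$mean_n_a, rdf$n_b),
           sprintf("# normalization: %s", rdf$normalization))
  body <- sprintf("%10.4f %12.6f", rdf$r, rdf$g)
  writeLines(c(hdr, body), path)
  invisible(path)
}
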