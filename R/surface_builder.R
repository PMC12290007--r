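#' Anatase (101) slab construction and hydroxylation
#'
#' The slab is cut from the anatase lattice (tetragonal, a = b = 0.37845 nm,
#' c = 0.95143 nm, oxygen parameter u = 0.2081) along the (101) plane at the
#' stoichiometric lowest-energy termination, which exposes only 5- and
#' 6-coordinated Ti (and 2-/3-coordinated O) on both equivalent faces. The
#' cell is re-based on the lattice vectors (A - C, B, A), an unimodular
#' transform whose first two vectors span the (101) plane; a fixed
#' termination shift selects the natural cleavage. Hydroxyl groups (OF-HF)
#' are attached at random to 5-coordinated surface Ti at a stated fraction,
#' which sets the effective surface charge density.
#'
#' @name surface_builder
NULL

ANATASE_A <- 0.37845
ANATASE_C <- 0.95143
ANATASE_U <- 0.2081
# termination shift (fraction of the stacking vector); any value in
# [0.25, 0.50] cuts between trilayers, leaving only 5c/6c Ti
ANATASE_TERMINATION_SHIFT <- 0.375
TI_O_BOND <- 0.18
O_H_BOND <- 0.098

anatase_basis <- function() {
  a <- ANATASE_A; cc <- ANATASE_C; u <- ANATASE_U
  ti <- rbind(c(0, 0, 0), c(.5, .5, .5), c(0, .5, .25), c(.5, 0, .75))
  o <- rbind(ti + rep(c(0, 0, u), each = 4), ti - rep(c(0, 0, u), each = 4))
  cell <- diag(c(a, a, cc))
  list(frac = rbind(ti, o), species = c(rep("TI", 4), rep("O", 8)),
       cell = cell)
}

#' Build an anatase (101) slab
#'
#' @param n1 repeats along the long surface vector (|A - C| = 1.0239 nm).
#' @param n2 repeats along the short surface vector (|B| = 0.37845 nm).
#' @param n_layers stacking repeats along the surface normal; each repeat
#'   adds one corrugated TiO2 double-row (0.3517 nm). The reference system
#'   of the study corresponds to `n1 = 5, n2 = 13, n_layers = 9`
#'   (2340 Ti, 4680 O, 4.92 x 5.12 nm lateral, 3.05 nm thick).
#' @param z_offset nm; z of the lowest slab atom (default 0.5, leaving room
#'   below for periodic images).
#' @return list of class `slab_model`: `xyz` (nm, surface frame: z is the
#'   surface normal), `species` (`TI`, `O`, later also `OF`/`HF`), `box_lat`
#'   (2 lateral periodic edges, nm), `thickness`, `n1`, `n2`, `n_layers`,
#'   `hydroxyls` (data.frame, empty until [hydroxylate]), `seed`.
#' @export
build_anatase_slab <- function(n1, n2, n_layers, z_offset = 0.5) {
  stopifnot(n1 >= 1, n2 >= 1, n_layers >= 1)
  b <- anatase_basis()
  m <- rbind(c(1, 0, -1), c(0, 1, 0), c(1, 0, 0))   # L1, L2, L3 in A,B,C
  newcell <- m %*% b$cell
  fnew <- (b$frac %*% b$cell) %*% solve(newcell)
  fnew <- fnew - floor(fnew + 1e-9)
  fnew[, 3] <- fnew[, 3] + ANATASE_TERMINATION_SHIFT
  fnew[, 3] <- fnew[, 3] - floor(fnew[, 3] + 1e-9)

  reps <- as.matrix(expand.grid(i = 0:(n1 - 1), j = 0:(n2 - 1),
                                k = 0:(n_layers - 1)))
  n_at <- nrow(fnew)
  fa <- fnew[rep(seq_len(n_at), nrow(reps)), , drop = FALSE] +
    reps[rep(seq_len(nrow(reps)), each = n_at), ]
  species <- rep(b$species, nrow(reps))

  l1 <- newcell[1, ]; l2 <- newcell[2, ]
  ex <- l1 / sqrt(sum(l1^2)); ey <- l2 / sqrt(sum(l2^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  xyz <- (fa %*% newcell) %*% cbind(ex, ey, ez)
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + z_offset
  # wrap lateral coordinates into the periodic cell
  box_lat <- c(n1 * sqrt(sum(l1^2)), n2 * ANATASE_A)
  for (k in 1:2) xyz[, k] <- xyz[, k] - box_lat[k] * floor(xyz[, k] / box_lat[k])

  structure(list(xyz = xyz, species = species, box_lat = box_lat,
                 thickness = diff(range(xyz[, 3])),
                 n1 = n1, n2 = n2, n_layers = n_layers,
                 hydroxyls = data.frame(face = character(0),
                                        ti = integer(0), o = integer(0),
                                        h = integer(0)),
                 fraction_hydroxylated = 0, seed = NA_integer_),
            class = "slab_model")
}

#' @export
print.slab_model <- function(x, ...) {
  cat(sprintf("<slab_model> %d Ti, %d O lattice, %d OH; %.2f x %.2f nm, %.2f nm thick\n",
              sum(x$species == "TI"), sum(x$species == "O"),
              nrow(x$hydroxyls), x$box_lat[1], x$box_lat[2], x$thickness))
  invisible(x)
}

#' Ti coordination numbers of a slab
#'
#' Counts lattice/hydroxyl oxygens within the bond cutoff of each Ti under
#' lateral periodicity (the normal direction is non-periodic for a slab).
#'
#' @param slab a `slab_model`.
#' @param cutoff Ti-O bond cutoff, nm (default 0.25).
#' @return integer vector, one count per Ti atom (in slab atom order).
#' @export
coordination_numbers <- function(slab, cutoff = 0.25) {
  stopifnot(cutoff > 0)
  ti <- which(slab$species == "TI")
  ox <- which(slab$species %in% c("O", "OF"))
  lx <- slab$box_lat[1]; ly <- slab$box_lat[2]
  out <- integer(length(ti))
  chunk <- 500L
  for (s in seq(1L, length(ti), by = chunk)) {
    idx <- ti[s:min(s + chunk - 1L, length(ti))]
    dx <- min_image(outer(slab$xyz[idx, 1], slab$xyz[ox, 1], "-"), lx)
    dy <- min_image(outer(slab$xyz[idx, 2], slab$xyz[ox, 2], "-"), ly)
    dz <- outer(slab$xyz[idx, 3], slab$xyz[ox, 3], "-")
    out[s:(s + length(idx) - 1L)] <-
      rowSums(dx * dx + dy * dy + dz * dz < cutoff^2)
  }
  out
}

five_coordinated_ti <- function(slab, cutoff = 0.25) {
  ti <- which(slab$species == "TI")
  ti[coordination_numbers(slab, cutoff) == 5L]
}

#' Hydroxylate 5-coordinated surface Ti
#'
#' Selects `round(fraction x N_5c)` five-coordinated Ti sites uniformly at
#' random (without replacement, reproducible from the seed) on the chosen
#' face(s) and attaches an O-H group along the outward surface normal at
#' Ti-O 0.18 nm and O-H 0.098 nm.
#'
#' @param slab a `slab_model`.
#' @param fraction hydroxylated fraction of eligible 5c Ti in \[0, 1\]
#'   (0.30 in the reference system).
#' @param seed integer RNG seed for site selection.
#' @param faces `"both"` (default) or `"top"`.
#' @return the slab with `OF`/`HF` atoms appended and the `hydroxyls` table
#'   filled (face, ti, o, h indices).
#' @export
hydroxylate <- function(slab, fraction, seed = 1L, faces = c("both", "top")) {
  faces <- match.arg(faces)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  ti5 <- five_coordinated_ti(slab)
  zmid <- mean(range(slab$xyz[slab$species == "TI", 3]))
  on_top <- slab$xyz[ti5, 3] > zmid
  eligible <- if (faces == "both") ti5 else ti5[on_top]
  n_oh <- round(fraction * length(eligible))
  sites <- with_local_seed(seed,
                           sort(eligible[sample.int(length(eligible), n_oh)]))

  if (n_oh > 0) {
    up <- slab$xyz[sites, 3] > zmid
    sgn <- ifelse(up, 1, -1)
    o_xyz <- slab$xyz[sites, , drop = FALSE]
    o_xyz[, 3] <- o_xyz[, 3] + sgn * TI_O_BOND
    h_xyz <- o_xyz
    h_xyz[, 3] <- h_xyz[, 3] + sgn * O_H_BOND
    n0 <- nrow(slab$xyz)
    slab$xyz <- rbind(slab$xyz, o_xyz, h_xyz)
    slab$species <- c(slab$species, rep("OF", n_oh), rep("HF", n_oh))
    slab$hydroxyls <- data.frame(face = ifelse(up, "top", "bottom"),
                                 ti = sites,
                                 o = n0 + seq_len(n_oh),
                                 h = n0 + n_oh + seq_len(n_oh))
  }
  slab$fraction_hydroxylated <- fraction
  slab$seed <- seed
  slab
}

#' Surface charge density from hydroxyl coverage
#'
#' @param slab a hydroxylated `slab_model`.
#' @param q_per_OH effective charge per hydroxyl group, e. The reference
#'   system tunes hydroxyl coverage to reproduce the experimental TiO2
#'   surface charge of -0.62 e/nm2 at neutral pH.
#' @return list of class `charge_report`: per-face hydroxyl counts, face
#'   area (nm2), per-face and total charge densities (e/nm2).
#' @export
surface_charge_density <- function(slab, q_per_OH) {
  area <- slab$box_lat[1] * slab$box_lat[2]
  if (area <= 0) stop("zero face area")
  n_top <- sum(slab$hydroxyls$face == "top")
  n_bot <- sum(slab$hydroxyls$face == "bottom")
  structure(list(n_OH_top = n_top, n_OH_bottom = n_bot,
                 area_per_face = area,
                 q_per_OH = q_per_OH,
                 density_top = q_per_OH * n_top / area,
                 density_bottom = q_per_OH * n_bot / area,
                 density_mean = q_per_OH * (n_top + n_bot) / (2 * area)),
            class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf("<charge_report> OH top %d / bottom %d on %.2f nm2 per face\n",
              x$n_OH_top, x$n_OH_bottom, x$area_per_face))
  cat(sprintf("  density top %.3f, bottom %.3f e/nm2\n",
              x$density_top, x$density_bottom))
  invisible(x)
}

#' Convert a slab model to a system topology and frame
#'
#' Atom names follow the surface typing convention: `TI` for titanium, `O`
#' for lattice oxygen, `OF`/`HF` for hydroxyl oxygen/hydrogen; all slab
#' atoms share residue name `TIO`.
#'
#' @param slab a `slab_model`.
#' @param box full orthorhombic box (nm); lateral edges default to the slab
#'   cell, z must be given (slab plus solvent region).
#' @return list with `topology` and `frame`.
#' @export
slab_system <- function(slab, box) {
  stopifnot(length(box) == 3L)
  name <- slab$species
  name[name == "TI"] <- "TI"
  top <- system_topology(name = name, resname = "TIO", resid = 1L)
  list(topology = top, frame = traj_frame(slab$xyz, box))
}

#' Export a slab with a JSON parameter sidecar
#'
#' Writes the slab as GRO (or PDB by extension) plus `<path>.json` echoing
#' builder parameters for reproducibility.
#'
#' @param slab a `slab_model`.
#' @param path output structure path (`.gro` or `.pdb`).
#' @param box full box (nm); defaults to the lateral cell with z =
#'   thickness + 2 nm.
#' @export
write_slab <- function(slab, path, box = NULL) {
  if (is.null(box))
    box <- c(slab$box_lat, max(slab$xyz[, 3]) + 2)
  sys <- slab_system(slab, box)
  if (grepl("\\.pdb$", path, ignore.case = TRUE))
    write_pdb_structure(sys$topology, sys$frame, path)
  else write_gro(sys$topology, sys$frame, path)
  meta <- list(n1 = slab$n1, n2 = slab$n2, n_layers = slab$n_layers,
               fraction_hydroxylated = slab$fraction_hydroxylated,
               seed = slab$seed, box = box,
               lattice = list(a = ANATASE_A, c = ANATASE_C, u = ANATASE_U),
               termination_shift = ANATASE_TERMINATION_SHIFT)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
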