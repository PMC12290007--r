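#' System topologies, structure/trajectory IO, and atom classification
#'
#' A `SystemTopology` is a data.frame of atoms (name, element, residue name,
#' residue index, segment, mass, optional charge) carrying the peptide
#' sequence and, when known, the peptide bond list as attributes. A
#' `TrajectoryFrame` holds a timestamp (ps), orthorhombic box edges (nm) and
#' an N x 3 coordinate matrix (nm). Internal units are nm and ps throughout;
#' PDB Angstroms are converted at the boundary.
#'
#' @name model_io
NULL

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    NA. = 22.990, CL = 35.453, TI = 47.867, S = 32.06)

PEPTIDE_RESNAMES <- c(R = "ARG", K = "LYS", L = "LEU", P = "PRO",
                      D = "ASP", A = "ALA")

SOLVENT_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3")
ION_RESNAMES <- c("NA", "NA+", "SOD", "CL", "CL-", "CLA")
SURFACE_RESNAMES <- c("TIO", "SLB", "SUR", "ANA")

#' Infer the chemical element from an atom name
#'
#' Surface typing conventions are honoured: `TI*` is titanium, `OB`/`OF`/
#' lattice `O*` are oxygen, `HF`/`HW*` hydrogen, `NA`/`SOD` sodium,
#' `CL`/`CLA` chlorine; otherwise the first alphabetic character is used.
#'
#' @param name character vector of atom names.
#' @param resname residue names (used to disambiguate NA ion vs. nitrogen).
#' @return character vector of element symbols.
#' @export
guess_element <- function(name, resname = "") {
  name <- toupper(name)
  resname <- toupper(resname)
  out <- character(length(name))
  first <- sub("^[0-9]*", "", name)
  out <- substr(first, 1, 1)
  out[grepl("^TI", name)] <- "TI"
  is_na <- name %in% c("NA", "NA+", "SOD") &
    resname %in% c("", ION_RESNAMES, "ION")
  out[is_na] <- "NA."
  out[name %in% c("CL", "CL-", "CLA")] <- "CL"
  out
}

infer_segment <- function(resname, element) {
  resname <- toupper(resname)
  seg <- rep("other", length(resname))
  seg[resname %in% PEPTIDE_RESNAMES] <- "peptide"
  seg[resname %in% SOLVENT_RESNAMES] <- "solvent"
  seg[resname %in% ION_RESNAMES | element %in% c("NA.", "CL")] <- "ion"
  seg[resname %in% SURFACE_RESNAMES | element == "TI"] <- "surface"
  # lattice oxygens of the slab share the surface residue name
  seg[seg == "other" & resname %in% SURFACE_RESNAMES] <- "surface"
  seg
}

#' Construct a system topology
#'
#' @param name atom names.
#' @param resname residue names.
#' @param resid residue indices (1-based within each segment).
#' @param segment optional explicit segments (`peptide`, `surface`, `solvent`,
#'   `ion`); inferred from residue names when omitted.
#' @param element optional element symbols; inferred when omitted.
#' @param charge optional charges (e).
#' @param peptide_sequence optional one-letter peptide sequence string.
#' @param bonds optional 2-column integer matrix of bonded atom index pairs
#'   (1-based), covering at least the peptide.
#' @return data.frame of class `system_topology`.
#' @export
system_topology <- function(name, resname, resid, segment = NULL,
                            element = NULL, charge = NA_real_,
                            peptide_sequence = NULL, bonds = NULL) {
  if (is.null(element)) element <- guess_element(name, resname)
  if (is.null(segment)) segment <- infer_segment(resname, element)
  unknown <- !(element %in% names(ELEMENT_MASSES))
  if (any(unknown))
    stop("no mass table entry for element(s): ",
         paste(unique(element[unknown]), collapse = ", "))
  top <- data.frame(name = as.character(name),
                    element = element,
                    resname = toupper(as.character(resname)),
                    resid = as.integer(resid),
                    segment = segment,
                    mass = unname(ELEMENT_MASSES[element]),
                    charge = charge,
                    stringsAsFactors = FALSE)
  class(top) <- c("system_topology", "data.frame")
  attr(top, "peptide_sequence") <- peptide_sequence
  attr(top, "bonds") <- bonds
  top
}

#' @export
print.system_topology <- function(x, ...) {
  cat(sprintf("<system_topology> %d atoms (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$segment)),
                            as.integer(table(x$segment))), collapse = ", ")))
  seqs <- attr(x, "peptide_sequence")
  if (!is.null(seqs)) cat("  peptide:", seqs, "\n")
  invisible(x)
}

#' Construct a trajectory frame
#'
#' @param xyz N x 3 coordinate matrix, nm.
#' @param box length-3 orthorhombic box edges, nm.
#' @param time timestamp, ps.
#' @return object of class `traj_frame`.
#' @export
traj_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  stopifnot(ncol(xyz) == 3L)
  box <- as.numeric(box)
  if (length(box) == 9L) {
    m <- matrix(box, 3, 3)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-9))
      stop("triclinic boxes are not supported; analyses require orthorhombic")
    box <- diag(m)
  }
  if (length(box) != 3L || any(box <= 0))
    stop("box must be 3 positive orthorhombic edge lengths (nm)")
  structure(list(time = time, box = box, xyz = xyz), class = "traj_frame")
}

# ---- GRO ----------------------------------------------------------------

parse_gro_block <- function(lines, offset = 0L) {
  title <- lines[1]
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms))
    stop("malformed GRO atom count at line ", offset + 2L)
  if (length(lines) < natoms + 3L)
    stop("truncated GRO block starting at line ", offset + 1L)
  at <- lines[3:(2 + natoms)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  rest <- substr(at, 21, nchar(at))
  nums <- lapply(strsplit(trimws(rest), "\\s+"), as.numeric)
  bad <- which(vapply(nums, function(v) length(v) < 3 || anyNA(v[1:3]),
                      logical(1)))
  if (length(bad))
    stop("malformed GRO coordinate record at line ", offset + 2L + bad[1])
  xyz <- t(vapply(nums, function(v) v[1:3], numeric(3)))
  boxv <- as.numeric(strsplit(trimws(lines[natoms + 3L]), "\\s+")[[1]])
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("malformed GRO box line at line ", offset + natoms + 3L)
  if (length(boxv) > 3 && any(abs(boxv[4:length(boxv)]) > 1e-9))
    stop("triclinic boxes are not supported; analyses require orthorhombic")
  time <- 0
  tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  list(resid = resid, resname = resname, name = name, xyz = xyz,
       box = boxv[1:3], time = time, nlines = natoms + 3L)
}

#' Read a GRO structure file
#'
#' @param path file path.
#' @return list with elements `topology` ([system_topology]) and `frame`
#'   ([traj_frame]); coordinates in nm as stored.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  blk <- parse_gro_block(lines)
  top <- system_topology(blk$name, blk$resname, blk$resid)
  pep <- which(top$segment == "peptide")
  if (length(pep)) {
    rn <- top$resname[pep][!duplicated(top$resid[pep])]
    letters1 <- names(PEPTIDE_RESNAMES)[match(rn, PEPTIDE_RESNAMES)]
    attr(top, "peptide_sequence") <- paste(letters1, collapse = "")
  }
  list(topology = top, frame = traj_frame(blk$xyz, blk$box, blk$time))
}

#' Write a GRO structure file
#'
#' @param topology a [system_topology].
#' @param frame a [traj_frame].
#' @param path output path.
#' @param title title line; the frame time is appended as `t= <ps>`.
#' @param append append as an additional frame (multi-frame GRO trajectory).
#' @export
write_gro <- function(topology, frame, path, title = "surfpep system",
                      append = FALSE) {
  n <- nrow(topology)
  stopifnot(nrow(frame$xyz) == n)
  atnum <- seq_len(n) %% 100000L
  lines <- c(sprintf("%s t= %.4f", title, frame$time),
             sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topology$resid %% 100000L,
                     substr(topology$resname, 1, 5),
                     substr(topology$name, 1, 5),
                     atnum, frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

# ---- PDB (via bio3d) ----------------------------------------------------

#' Read a PDB structure file
#'
#' Parsed with bio3d; coordinates are converted from Angstrom to nm. The box
#' is taken from the CRYST1 record when present.
#'
#' @param path file path.
#' @return list with `topology` and `frame`, as [read_gro].
#' @export
read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  top <- system_topology(a$elety, a$resid, a$resno)
  xyz <- cbind(a$x, a$y, a$z) / 10
  box <- c(5, 5, 5)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr)) {
    v <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33)))
    if (!anyNA(v) && all(v > 0)) box <- v / 10
  }
  pep <- which(top$segment == "peptide")
  if (length(pep)) {
    rn <- top$resname[pep][!duplicated(top$resid[pep])]
    letters1 <- names(PEPTIDE_RESNAMES)[match(rn, PEPTIDE_RESNAMES)]
    attr(top, "peptide_sequence") <- paste(letters1, collapse = "")
  }
  list(topology = top, frame = traj_frame(xyz, box))
}

#' Write a PDB structure file
#'
#' Coordinates are written in Angstrom with a CRYST1 record from the frame
#' box.
#'
#' @inheritParams write_gro
#' @export
write_pdb_structure <- function(topology, frame, path) {
  n <- nrow(topology)
  lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10),
             sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(n) %% 100000L,
                     substr(topology$name, 1, 4),
                     substr(topology$resname, 1, 3),
                     topology$resid %% 10000L,
                     frame$xyz[, 1] * 10, frame$xyz[, 2] * 10,
                     frame$xyz[, 3] * 10),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Load a structure file
#'
#' @param path file path.
#' @param format `"GRO"` or `"PDB"`; guessed from the extension when omitted.
#' @return list with `topology` and `frame`.
#' @export
load_structure <- function(path, format = c("auto", "GRO", "PDB")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "PDB" else "GRO"
  switch(format, GRO = read_gro(path), PDB = read_pdb_structure(path))
}

#' Load a trajectory
#'
#' Supported formats: multi-frame GRO (concatenated GRO blocks) and DCD (via
#' bio3d; Angstrom converted to nm, box taken from the structure frame since
#' DCD cell records are not relied upon). Frames are returned in time order;
#' a stride and a closed-open time window can be applied.
#'
#' @param path trajectory file.
#' @param topology the matching [system_topology] (atom counts must agree).
#' @param format `"multi-GRO"` or `"DCD"` (guessed from extension).
#' @param stride keep every stride-th frame (default 1).
#' @param t_min,t_max time window in ps, `[t_min, t_max)`.
#' @param box box edges to use for DCD input (nm).
#' @return list of [traj_frame] objects.
#' @export
load_trajectory <- function(path, topology,
                            format = c("auto", "multi-GRO", "DCD"),
                            stride = 1L, t_min = -Inf, t_max = Inf,
                            box = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "DCD"
              else "multi-GRO"
  frames <- if (format == "multi-GRO") {
    lines <- readLines(path)
    out <- list(); off <- 0L
    while (off < length(lines)) {
      remaining <- length(lines) - off
      if (remaining < 3L) {
        warning("trailing partial GRO block ignored (", remaining, " lines)")
        break
      }
      blk <- tryCatch(parse_gro_block(lines[(off + 1L):length(lines)], off),
                      error = function(e) {
                        warning("truncated trajectory: ", conditionMessage(e))
                        NULL
                      })
      if (is.null(blk)) break
      if (nrow(blk$xyz) != nrow(topology))
        stop("frame atom count (", nrow(blk$xyz),
             ") does not match topology (", nrow(topology), ")")
      out[[length(out) + 1L]] <- traj_frame(blk$xyz, blk$box, blk$time)
      off <- off + blk$nlines
    }
    out
  } else {
    dcd <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(dcd) != 3L * nrow(topology))
      stop("frame atom count does not match topology")
    if (is.null(box)) stop("DCD input requires an explicit box (nm)")
    lapply(seq_len(nrow(dcd)), function(i)
      traj_frame(matrix(dcd[i, ], ncol = 3, byrow = TRUE) / 10, box,
                 time = i - 1))
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  frames <- frames[order(times)]
  times <- sort(times)
  frames <- frames[times >= t_min & times < t_max]
  frames[seq(1L, length(frames), by = as.integer(stride))]
}

#' Write a multi-frame GRO trajectory
#'
#' @param topology a [system_topology].
#' @param frames list of [traj_frame].
#' @param path output path.
#' @export
write_trajectory_gro <- function(topology, frames, path) {
  if (file.exists(path)) file.remove(path)
  file.create(path)
  for (f in frames) write_gro(topology, f, path, append = TRUE)
  invisible(path)
}

# ---- atom classification ------------------------------------------------

#' Classify atoms into analysis roles
#'
#' Surface classification is geometric: the outermost Ti layer of each face
#' is all Ti within `layer_tolerance` of the extreme Ti z; hydroxyl oxygens
#' (OF) are surface oxygens within `oh_bond_cutoff` of a surface hydrogen
#' (HF); bridging oxygens (OB) are the remaining surface oxygens exposed on
#' either face (within `exposure_depth` of the outer Ti plane). Peptide roles
#' are read from the residue topology: one Calpha per residue, the backbone N
#' of residue 1 (N-terminal amine), both carboxylate oxygens of the last
#' residue, and sidechain N/O sets by residue identity (ARG: NE/NH1/NH2,
#' LYS: NZ, ASP: OD1/OD2).
#'
#' @param topology a [system_topology].
#' @param frame a [traj_frame].
#' @param layer_tolerance nm; z-window defining the outer Ti layers
#'   (default 0.05).
#' @param oh_bond_cutoff nm; O-H bond cutoff for hydroxyl detection
#'   (default 0.12).
#' @param exposure_depth nm; how far below the outer Ti plane an oxygen may
#'   sit and still count as exposed (default 0.25).
#' @return list of class `atom_classes` holding 1-based index vectors:
#'   `TI`, `TI_TOP`, `TI_BOTTOM`, `OB`, `OF`, `HF`, `peptide`,
#'   `peptide_CA` (named by residue position), `NTERM_N`, `CTERM_O`,
#'   `sidechain_N` (list per residue), `sidechain_O` (list per residue),
#'   `peptide_O` (all peptide oxygens), `NA.`, `CL`, `water_O`.
#' @export
classify_atoms <- function(topology, frame, layer_tolerance = 0.05,
                           oh_bond_cutoff = 0.12, exposure_depth = 0.25) {
  stopifnot(nrow(frame$xyz) == nrow(topology))
  surf <- which(topology$segment == "surface")
  ti <- surf[topology$element[surf] == "TI"]
  if (!length(ti)) stop("no Ti atoms in the surface segment")
  z <- frame$xyz[, 3]
  z_top <- max(z[ti]); z_bot <- min(z[ti])
  ti_top <- ti[z[ti] >= z_top - layer_tolerance]
  ti_bottom <- ti[z[ti] <= z_bot + layer_tolerance]

  surf_o <- surf[topology$element[surf] == "O"]
  surf_h <- surf[topology$element[surf] == "H"]
  of <- integer(0)
  if (length(surf_o) && length(surf_h)) {
    d <- pairwise_min_image(frame$xyz[surf_o, , drop = FALSE],
                            frame$xyz[surf_h, , drop = FALSE], frame$box)
    of <- surf_o[apply(d <= oh_bond_cutoff, 1, any)]
  }
  plane_top <- mean(z[ti_top]); plane_bot <- mean(z[ti_bottom])
  lattice_o <- setdiff(surf_o, of)
  exposed <- lattice_o[z[lattice_o] >= plane_top - exposure_depth |
                         z[lattice_o] <= plane_bot + exposure_depth]
  ob <- exposed

  pep <- which(topology$segment == "peptide")
  ca <- integer(0); nterm <- integer(0); cterm_o <- integer(0)
  schn <- list(); scho <- list(); pep_o <- integer(0)
  if (length(pep)) {
    resids <- sort(unique(topology$resid[pep]))
    if (length(resids) != 6L)
      stop("peptide must have exactly 6 residues, found ", length(resids))
    ca <- vapply(resids, function(r) {
      idx <- pep[topology$resid[pep] == r & topology$name[pep] == "CA"]
      if (length(idx) != 1L)
        stop("residue ", r, " must have exactly one CA atom")
      idx
    }, integer(1))
    names(ca) <- as.character(resids)
    nterm <- pep[topology$resid[pep] == resids[1] & topology$name[pep] == "N"]
    lastr <- resids[length(resids)]
    cterm_o <- pep[topology$resid[pep] == lastr &
                     topology$name[pep] %in% c("O", "OXT", "OC1", "OC2",
                                               "OT1", "OT2")]
    sc_n_names <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
    sc_o_names <- list(ASP = c("OD1", "OD2"))
    for (i in seq_along(resids)) {
      r <- resids[i]
      rn <- topology$resname[pep][match(r, topology$resid[pep])]
      schn[[i]] <- pep[topology$resid[pep] == r &
                         topology$name[pep] %in% (sc_n_names[[rn]] %||%
                                                    character(0))]
      scho[[i]] <- pep[topology$resid[pep] == r &
                         topology$name[pep] %in% (sc_o_names[[rn]] %||%
                                                    character(0))]
    }
    names(schn) <- names(scho) <- as.character(resids)
    pep_o <- pep[topology$element[pep] == "O"]
  }
  ions <- which(topology$segment == "ion")
  na_idx <- ions[topology$element[ions] == "NA."]
  cl_idx <- ions[topology$element[ions] == "CL"]
  wat <- which(topology$segment == "solvent" & topology$element == "O")

  structure(list(TI = ti, TI_TOP = ti_top, TI_BOTTOM = ti_bottom,
                 OB = ob, OF = of, HF = surf_h,
                 plane_top = plane_top, plane_bottom = plane_bot,
                 peptide = pep, peptide_CA = ca, NTERM_N = nterm,
                 CTERM_O = cterm_o, sidechain_N = schn, sidechain_O = scho,
                 peptide_O = pep_o, NA. = na_idx, CL = cl_idx,
                 water_O = wat),
            class = "atom_classes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
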