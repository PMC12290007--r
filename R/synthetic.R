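#' Synthetic adsorption trajectories with planted ground truth
#'
#' Generates a slab + hexapeptide + ion system and a discrete-time two-state
#' (bound/unbound) Markov trajectory in which every analysis observable is
#' known by construction: the per-frame SSD is imposed exactly by
#' translating the peptide center of mass above a randomly chosen face; the
#' conformation is drawn from rigid templates with prescribed end-to-end
#' distances plus isotropic jitter; bound frames carry a planted
#' sidechain-N-to-OF contact at an exact distance; and bridging Na+ ions are
#' planted to satisfy the dual 3 Angstrom criterion (other ions are decoys
#' kept away from both criteria). Output frames are periodically wrapped so
#' the unwrapping stage is always exercised.
#'
#' @name synthetic_data
NULL

# residue sidechain heavy-atom chains (names only; geometry built per
# template); ARG NH1/NH2 and ASP OD1/OD2 branch from the chain end
SIDECHAIN_ATOMS <- list(
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  PRO = c("CB", "CG", "CD"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  ALA = "CB")

#' Specification for a synthetic adsorption system
#'
#' Defaults encode the reference validation benchmark: stationary bound
#' probability 0.8 (transition probabilities 0.08 unbound-to-bound, 0.02
#' bound-to-unbound), bound-state SSD from a truncated normal (mean 0.7 nm,
#' sd 0.1, support (0,1)), unbound SSD uniform on (1 nm, half the solvent
#' height), a compact (EED 0.65 nm) and an extended (EED 1.40 nm) conformer
#' used 70/30 in the bound state (30/70 unbound), a planted sidechain-N to
#' OF contact at 0.28 nm, and a planted bridging Na+ at 0.23 nm from a
#' peptide oxygen.
#'
#' @param sequence peptide sequence (default "RKLPDA").
#' @param n_frames number of frames.
#' @param frame_dt ps between frames.
#' @param p_bind,p_unbind Markov transition probabilities per frame.
#' @param ssd_bound_mean,ssd_bound_sd truncated-normal bound SSD (nm).
#' @param conformer_eeds template end-to-end distances (nm).
#' @param bound_weights,unbound_weights per-state conformer weights.
#' @param jitter_sd isotropic per-atom jitter, nm.
#' @param contact_dist planted sidechain-N to OF distance, nm.
#' @param bridge_dist planted Na to peptide-oxygen distance, nm.
#' @param p_bridge probability a bound frame carries a planted bridging ion.
#' @param n_na,n_cl ion counts.
#' @param slab_n1,slab_n2,slab_layers slab replication.
#' @param hydroxyl_fraction fraction of 5-coordinated Ti hydroxylated.
#' @param solvent_height nm of solvent region above the slab.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(sequence = "RKLPDA", n_frames = 2000L,
                           frame_dt = 100, p_bind = 0.08, p_unbind = 0.02,
                           ssd_bound_mean = 0.7, ssd_bound_sd = 0.1,
                           conformer_eeds = c(compact = 0.65,
                                              extended = 1.40),
                           bound_weights = c(0.7, 0.3),
                           unbound_weights = c(0.3, 0.7),
                           jitter_sd = 0.01, contact_dist = 0.28,
                           bridge_dist = 0.23, p_bridge = 0.9,
                           n_na = 8L, n_cl = 4L,
                           slab_n1 = 3L, slab_n2 = 7L, slab_layers = 3L,
                           hydroxyl_fraction = 0.3, solvent_height = 5.0) {
  stopifnot(p_bind >= 0, p_bind <= 1, p_unbind >= 0, p_unbind <= 1,
            ssd_bound_mean < 1, length(conformer_eeds) >= 1,
            length(bound_weights) == length(conformer_eeds),
            length(unbound_weights) == length(conformer_eeds))
  structure(as.list(environment()), class = "synthetic_spec")
}

arc_ca_positions <- function(n, bond, eed) {
  span <- (n - 1) * bond
  if (eed >= span - 1e-9)
    return(cbind(seq(0, by = bond, length.out = n), 0, 0))
  # planar circular arc: chord between first and last Calpha equals eed
  f <- function(r) 2 * r * sin((n - 1) * asin(bond / (2 * r))) - eed
  r <- stats::uniroot(f, c(bond / 2 + 1e-6, 1e4), tol = 1e-12)$root
  theta <- 2 * asin(bond / (2 * r))
  ang <- (seq_len(n) - 1) * theta
  cbind(r * sin(ang), r * (1 - cos(ang)), 0)
}

#' Build a rigid hexapeptide template
#'
#' Idealised heavy-atom geometry: Calpha atoms on a planar arc whose chord
#' gives the target end-to-end distance (virtual Calpha-Calpha bond 0.38
#' nm); backbone N/C/O near each Calpha; sidechains as straight chains,
#' pointing away from the surface except for the anchor residues (first
#' sidechain-N-bearing and first sidechain-O-bearing residue), which point
#' toward it. Chemically plausible, not force-field-accurate.
#'
#' @param sequence one-letter sequence string.
#' @param eed target end-to-end distance, nm.
#' @return list: `xyz`, `atoms` (name/resname/resid), `bonds`,
#'   `anchor_n`, `anchor_o` (template-local indices), `eed`.
#' @export
build_peptide_template <- function(sequence, eed) {
  letters1 <- split_letters(sequence)
  resnames <- unname(PEPTIDE_RESNAMES[letters1])
  if (anyNA(resnames)) stop("sequence letters must be in {R,K,L,P,D,A}")
  n_res <- length(letters1)
  ca <- arc_ca_positions(n_res, 0.38, eed)
  # chain tangents and in-plane normals
  name <- character(0); resid <- integer(0); rn <- character(0)
  xyz <- NULL; bonds <- NULL
  prev_c <- NA_integer_
  down_n_res <- which(vapply(resnames, function(r)
    any(grepl("^N", SIDECHAIN_ATOMS[[r]])), logical(1)))[1]
  down_o_res <- which(vapply(resnames, function(r)
    any(grepl("^O", SIDECHAIN_ATOMS[[r]])), logical(1)))[1]
  add <- function(nm, pos, parent_local = NA_integer_) {
    xyz <<- rbind(xyz, pos)
    name <<- c(name, nm); resid <<- c(resid, i); rn <<- c(rn, resnames[i])
    k <- nrow(xyz)
    if (!is.na(parent_local)) bonds <<- rbind(bonds, c(parent_local, k))
    k
  }
  for (i in seq_len(n_res)) {
    t_vec <- if (i < n_res) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    s_vec <- c(-t_vec[2], t_vec[1], 0)
    i_ca <- add("CA", ca[i, ])
    i_n <- add("N", ca[i, ] - 0.14 * t_vec + c(0, 0, 0.05), i_ca)
    if (!is.na(prev_c)) bonds <- rbind(bonds, c(prev_c, i_n))
    i_c <- add("C", ca[i, ] + 0.15 * t_vec + c(0, 0, 0.04), i_ca)
    add("O", xyz[i_c, ] + 0.123 * (0.3 * s_vec + c(0, 0, 0.95)), i_c)
    if (i == n_res)
      add("OXT", xyz[i_c, ] + 0.123 * (0.8 * s_vec + c(0, 0, -0.6)), i_c)
    # sidechain: straight chain with branch at the end for ARG/ASP/LEU
    sc <- SIDECHAIN_ATOMS[[resnames[i]]]
    dirz <- if (i %in% c(down_n_res, down_o_res)) -1 else 1
    branch <- intersect(sc, c("NH1", "NH2", "OD1", "OD2", "CD1", "CD2"))
    chain <- setdiff(sc, branch)
    parent <- i_ca
    for (j in seq_along(chain)) {
      pos <- ca[i, ] + c(0.02 * j * s_vec[1], 0.02 * j * s_vec[2],
                         dirz * (0.125 + 0.115 * (j - 1)))
      parent <- add(chain[j], pos, parent)
    }
    for (b in seq_along(branch)) {
      side <- if (b == 1) 1 else -1
      pos <- xyz[parent, ] + c(side * 0.11 * s_vec[1], side * 0.11 * s_vec[2],
                               dirz * 0.05)
      add(branch[b], pos, parent)
    }
    prev_c <- i_c
  }
  rownames(xyz) <- NULL
  anchor_n <- which(name == "NE" & resid == down_n_res)
  if (!length(anchor_n)) anchor_n <- which(name == "NZ" & resid == down_n_res)
  if (!length(anchor_n)) anchor_n <- which(name == "N" & resid == 1L)
  anchor_o <- which(name == "OD1" & resid == down_o_res)
  if (!length(anchor_o)) anchor_o <- which(name == "OXT")
  list(xyz = xyz,
       atoms = data.frame(name = name, resname = rn, resid = resid,
                          stringsAsFactors = FALSE),
       bonds = bonds, anchor_n = anchor_n[1], anchor_o = anchor_o[1],
       eed = sqrt(sum((ca[n_res, ] - ca[1, ])^2)))
}

slab_planes <- function(slab_xyz, species, tol = 0.05) {
  zti <- slab_xyz[species == "TI", 3]
  list(top = mean(zti[zti >= max(zti) - tol]),
       bottom = mean(zti[zti <= min(zti) + tol]))
}

#' Generate the synthetic system topology
#'
#' Builds the hydroxylated slab, appends the peptide (atom roles per residue
#' identity), Na+ and Cl- ions, and records the peptide bond graph.
#' Deterministic given the seed.
#'
#' @param spec a [synthetic_spec].
#' @param seed integer seed (drives hydroxyl site selection).
#' @return list of class `synthetic_system`: `topology`, `slab`,
#'   `templates` (one per conformer), `box`, `planes`, index bookkeeping
#'   and a ground-truth skeleton.
#' @export
generate_synthetic_system <- function(spec, seed = 1L) {
  slab <- build_anatase_slab(spec$slab_n1, spec$slab_n2, spec$slab_layers,
                             z_offset = 0.5)
  slab <- hydroxylate(slab, spec$hydroxyl_fraction, seed = seed)
  box <- c(slab$box_lat, max(slab$xyz[, 3]) + spec$solvent_height)
  if (any(box[1:2] <= 0)) stop("box too small for slab")

  templates <- lapply(spec$conformer_eeds, function(e)
    build_peptide_template(spec$sequence, e))

  t1 <- templates[[1]]
  n_slab <- nrow(slab$xyz)
  n_pep <- nrow(t1$xyz)
  name <- c(slab$species, t1$atoms$name, rep("NA", spec$n_na),
            rep("CL", spec$n_cl))
  resname <- c(rep("TIO", n_slab), t1$atoms$resname,
               rep("NA", spec$n_na), rep("CL", spec$n_cl))
  resid <- c(rep(1L, n_slab), t1$atoms$resid,
             seq_len(spec$n_na + spec$n_cl))
  bonds <- t1$bonds + n_slab
  top <- system_topology(name, resname, resid,
                         peptide_sequence = spec$sequence, bonds = bonds)
  pep_idx <- n_slab + seq_len(n_pep)
  na_idx <- n_slab + n_pep + seq_len(spec$n_na)
  cl_idx <- n_slab + n_pep + spec$n_na + seq_len(spec$n_cl)

  structure(list(topology = top, slab = slab, templates = templates,
                 box = box,
                 planes = slab_planes(slab$xyz, slab$species),
                 n_slab = n_slab, pep_idx = pep_idx, na_idx = na_idx,
                 cl_idx = cl_idx, spec = spec, seed = seed),
            class = "synthetic_system")
}

rot_z <- function(phi) {
  rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
}

# truncated normal on (lo, hi) by rejection
rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

#' Generate a synthetic trajectory with ground truth
#'
#' See [synthetic_data] for the construction. Frames are wrapped into the
#' box on output.
#'
#' @param system a [generate_synthetic_system] result.
#' @param seed integer seed for the trajectory randomness.
#' @return list: `frames` (list of [traj_frame]) and `truth`, a list with
#'   per-frame `bound`, `ssd`, `conformer`, `eed`, `face`,
#'   `contact_planted`, `bridge_na` (topology index or NA), the planted
#'   distances, and `stationary_p`.
#' @export
generate_trajectory <- function(system, seed = 1L) {
  spec <- system$spec
  with_local_seed(seed, {
    n <- spec$n_frames
    p01 <- spec$p_bind; p10 <- spec$p_unbind
    stat_p <- if (p01 + p10 > 0) p01 / (p01 + p10) else 0
    bound <- logical(n)
    bound[1] <- stats::runif(1) < stat_p
    for (i in seq_len(n - 1L))
      bound[i + 1L] <- if (bound[i]) stats::runif(1) >= p10
                       else stats::runif(1) < p01

    slab_xyz <- system$slab$xyz
    box <- system$box
    planes <- system$planes
    z_half <- (box[3] - system$slab$thickness) / 2
    hyd <- system$slab$hydroxyls
    surf_cls <- NULL  # surface oxygen indices (slab-local) per face
    of_local <- split(hyd$o, hyd$face)
    # exposed lattice O per face for bridge targets
    zs <- slab_xyz[, 3]
    is_o <- system$slab$species %in% c("O", "OF")
    surf_o_top <- which(is_o & zs >= planes$top - 0.25)
    surf_o_bot <- which(is_o & zs <= planes$bottom + 0.25)

    pep_idx <- system$pep_idx
    conformer <- integer(n); ssd <- numeric(n); eed <- numeric(n)
    face <- character(n); contact <- logical(n)
    bridge_na <- rep(NA_integer_, n)
    masses <- system$topology$mass[pep_idx]
    frames <- vector("list", n)

    for (i in seq_len(n)) {
      w <- if (bound[i]) spec$bound_weights else spec$unbound_weights
      ci <- sample.int(length(system$templates), 1L, prob = w)
      conformer[i] <- ci
      tpl <- system$templates[[ci]]
      xyz_p <- tpl$xyz + matrix(stats::rnorm(3 * nrow(tpl$xyz), 0,
                                             spec$jitter_sd),
                                ncol = 3)
      xyz_p <- xyz_p %*% t(rot_z(stats::runif(1, 0, 2 * pi)))
      up <- stats::runif(1) < 0.5
      face[i] <- if (up) "top" else "bottom"
      if (!up) {
        # proper rotation by pi about x: points anchors at the bottom face
        xyz_p[, 2] <- -xyz_p[, 2]; xyz_p[, 3] <- -xyz_p[, 3]
      }
      sgn <- if (up) 1 else -1
      plane_z <- if (up) planes$top else planes$bottom
      s_i <- if (bound[i]) rtruncnorm1(spec$ssd_bound_mean,
                                       spec$ssd_bound_sd, 0, 1)
             else stats::runif(1, 1, z_half)
      ssd[i] <- s_i
      com <- colSums(xyz_p * masses) / sum(masses)
      z_com <- plane_z + sgn * s_i
      lat <- stats::runif(2) * box[1:2]

      planted <- FALSE
      ofs <- of_local[[face[i]]]
      if (bound[i] && length(ofs)) {
        a_rel <- xyz_p[tpl$anchor_n, ] - com          # anchor rel. to COM
        z_anchor <- z_com + a_rel[3]
        o_pick <- ofs[sample.int(length(ofs), 1L)]
        gap_z <- z_anchor - slab_xyz[o_pick, 3]
        if (abs(gap_z) < spec$contact_dist - 0.01) {
          lat_off <- sqrt(spec$contact_dist^2 - gap_z^2)
          phi <- stats::runif(1, 0, 2 * pi)
          target <- slab_xyz[o_pick, 1:2] + lat_off * c(cos(phi), sin(phi))
          lat <- target - a_rel[1:2]
          planted <- TRUE
        }
      }
      contact[i] <- planted
      xyz_p <- sweep(xyz_p, 2, com - c(lat, z_com), "-")

      # ions: optionally one planted bridge, rest decoys in bulk solvent
      na_xyz <- matrix(0, spec$n_na, 3)
      first_decoy <- 1L
      if (spec$n_na > 0 && bound[i] && planted &&
          stats::runif(1) < spec$p_bridge) {
        po <- xyz_p[tpl$anchor_o, ]
        so_idx <- if (up) surf_o_top else surf_o_bot
        dvec <- sweep(slab_xyz[so_idx, , drop = FALSE], 2, po)
        for (k in 1:2) dvec[, k] <- min_image(dvec[, k], box[k])
        dd <- sqrt(rowSums(dvec^2))
        j <- which.min(dd)
        if (dd[j] <= 0.5) {
          na_xyz[1, ] <- po + spec$bridge_dist * dvec[j, ] / dd[j]
          bridge_na[i] <- system$na_idx[1]
          first_decoy <- 2L
        }
      }
      if (spec$n_na >= first_decoy) {
        pep_o_xyz <- xyz_p[system$topology$element[pep_idx] == "O", ,
                           drop = FALSE]
        for (k in first_decoy:spec$n_na) {
          repeat {
            cand <- c(stats::runif(2) * box[1:2],
                      planes$top + stats::runif(1, 1.2, z_half - 0.3))
            dmin <- min(pairwise_min_image(matrix(cand, 1), pep_o_xyz, box))
            if (dmin > 0.45) { na_xyz[k, ] <- cand; break }
          }
        }
      }
      cl_xyz <- cbind(stats::runif(spec$n_cl) * box[1],
                      stats::runif(spec$n_cl) * box[2],
                      planes$top + stats::runif(spec$n_cl, 1.2,
                                                z_half - 0.3))
      eed[i] <- sqrt(sum((xyz_p[which(tpl$atoms$name == "CA" &
                                        tpl$atoms$resid == 1L)[1], ] -
                            xyz_p[which(tpl$atoms$name == "CA" &
                                          tpl$atoms$resid ==
                                            max(tpl$atoms$resid))[1], ])^2))
      all_xyz <- rbind(slab_xyz, xyz_p, na_xyz, cl_xyz)
      frames[[i]] <- traj_frame(wrap_coords(all_xyz, box), box,
                                time = (i - 1) * spec$frame_dt)
    }
    truth <- list(bound = bound, ssd = ssd, conformer = conformer,
                  eed = eed, face = face, contact_planted = contact,
                  bridge_na = bridge_na,
                  contact_dist = spec$contact_dist,
                  bridge_dist = spec$bridge_dist,
                  stationary_p = stat_p)
    list(frames = frames, truth = truth)
  })
}

#' Write a synthetic run to disk
#'
#' Emits the structure (GRO), the trajectory (multi-frame GRO) and a JSON
#' ground-truth sidecar.
#'
#' @param system a [generate_synthetic_system] result.
#' @param traj a [generate_trajectory] result.
#' @param prefix output path prefix.
#' @export
write_synthetic_run <- function(system, traj, prefix) {
  write_gro(system$topology, traj$frames[[1]], paste0(prefix, ".gro"))
  write_trajectory_gro(system$topology, traj$frames,
                       paste0(prefix, "_traj.gro"))
  jsonlite::write_json(traj$truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}
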