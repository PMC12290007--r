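#' End-to-end analysis pipeline
#'
#' Composes the analysis stages in the reference order: binding profile
#' (SSD/EED, bound classification) -> conformational clustering of bound
#' frames (only for strong binders) -> RDFs against surface oxygens ->
#' conditional bridging-Na RDF. All tables are written as TSV with a JSON
#' manifest echoing parameters and content hashes; identical inputs and
#' seed reproduce identical outputs.
#'
#' @name pipeline
NULL

#' Run the full pipeline on one system
#'
#' @param frames list of [traj_frame].
#' @param topology a [system_topology].
#' @param out_dir output directory (created).
#' @param params an [analysis_params].
#' @param label sequence label used in file names.
#' @param rdf_selections character vector of selection expressions for RDFs
#'   against `"surface OF"` and `"surface OB"`.
#' @param cluster_cutoff GROMOS RMSD cutoff, nm (default 0.15).
#' @param cluster_max_frames bound frames are strided down to at most this
#'   many before the pairwise RMSD matrix (default 400).
#' @param rdf_r_max,rdf_bin_width RDF histogram settings (r_max is capped
#'   below half the smallest box edge).
#' @param seed echoed into the manifest.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(frames, topology, out_dir,
                         params = analysis_params(), label = "peptide",
                         rdf_selections = c("sidechain N pos 1", "nterm N"),
                         cluster_cutoff = 0.15, cluster_max_frames = 400L,
                         rdf_r_max = 1.2, rdf_bin_width = 0.002,
                         seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "observables"
  manifest <- list(label = label, seed = seed,
                   params = unclass(params),
                   n_frames = length(frames), outputs = list())
  emit <- function(name, path) {
    manifest$outputs[[name]] <<- list(file = basename(path),
                                      md5 = unname(tools::md5sum(path)))
  }
  tryCatch({
    profile <- binding_profile(frames, topology, params)
    p <- file.path(out_dir, paste0(label, "_series.tsv"))
    write_series(profile, p); emit("series", p)
    p <- file.path(out_dir, paste0(label, "_ranking.tsv"))
    write_tsv_plain(rank_peptides(stats::setNames(list(profile), label)), p)
    emit("ranking", p)

    classes <- classify_atoms(topology, frames[[1]],
                              layer_tolerance = params$layer_tolerance)

    stage <- "clustering"
    if (profile$percent_bound > params$strong_binder_percent &&
        sum(profile$bound) >= 2L) {
      bidx <- which(profile$bound)
      stride <- max(1L, ceiling(length(bidx) / cluster_max_frames))
      bframes <- extract_bound_frames(frames, profile)
      m <- rmsd_matrix(bframes, topology = topology, stride = stride,
                       unwrap = TRUE)
      cl <- gromos_cluster(m, cluster_cutoff)
      kept <- bidx[attr(m, "frame_ids")]
      summ <- cluster_summary(cl, profile$times[kept], profile$ssd[kept],
                              profile$eed[kept])
      p <- file.path(out_dir, paste0(label, "_clusters.tsv"))
      write_tsv_plain(summ, p); emit("clusters", p)
      p <- file.path(out_dir, paste0(label, "_cluster_assignments.tsv"))
      write_cluster_assignments(cl, profile$times[kept], p)
      emit("cluster_assignments", p)
      manifest$clustering <- list(stride = stride, cutoff = cluster_cutoff,
                                  n_clustered = cl$n_frames)
    } else {
      manifest$clustering <- list(
        skipped = sprintf("percent_bound %.2f below threshold %.1f",
                          profile$percent_bound,
                          params$strong_binder_percent))
      message("clustering skipped: ", manifest$clustering$skipped)
    }

    stage <- "rdf"
    box <- frames[[1]]$box
    r_max <- min(rdf_r_max, min(box) / 2 - rdf_bin_width)
    bframes_all <- if (any(profile$bound))
      extract_bound_frames(frames, profile) else frames
    for (sel in rdf_selections) {
      sel_a <- resolve_selection(sel, topology, classes)
      if (!length(sel_a)) next
      for (target in c("surface OF", "surface OB")) {
        sel_b <- resolve_selection(target, topology, classes)
        if (!length(sel_b)) next
        r <- compute_rdf(bframes_all, sel_a, sel_b, r_max = r_max,
                         bin_width = rdf_bin_width)
        tag <- gsub("\\s+", "_", paste(label, sel, target))
        p <- file.path(out_dir, paste0(tag, ".rdf"))
        write_rdf(r, p, label = paste(sel, "vs", target))
        emit(paste0("rdf:", sel, ":", target), p)
      }
    }

    stage <- "conditional_rdf"
    if (length(classes$NA.)) {
      sel_b <- c(unlist(classes$sidechain_O, use.names = FALSE),
                 classes$CTERM_O)
      if (length(sel_b)) {
        r <- conditional_rdf(bframes_all, classes, sel_b, r_max = r_max,
                             bin_width = rdf_bin_width)
        p <- file.path(out_dir, paste0(label, "_na_bridge.rdf"))
        write_rdf(r, p, label = "bridging Na vs peptide O")
        emit("conditional_rdf", p)
      }
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest_path <- file.path(out_dir, paste0(label, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(manifest)
}

#' Rank a batch of peptides and derive motif statistics
#'
#' Reproduces the binding-ranking table and the strong-binder motif counts
#' from per-peptide SSD/EED series (either [binding_profile] objects or a
#' directory of `<label>_series.tsv` / `<label>.tsv` files, enabling direct
#' ingestion of deposited per-frame series).
#'
#' @param x named list of [binding_profile] objects, or a directory path.
#' @param params an [analysis_params].
#' @param threshold_percent strong-binder cutoff (default
#'   `params$strong_binder_percent`).
#' @return list: `ranking` (data.frame), `strong` ([sequence_library]),
#'   `n_strong`, `motifs` (list of motif tables: pairs ordered/agnostic,
#'   interior pairs, terminal pairs, triplets, positional pairs/triplets),
#'   `skipped` (labels whose series failed to load).
#' @export
batch_rank <- function(x, params = analysis_params(),
                       threshold_percent = NULL) {
  threshold_percent <- threshold_percent %||% params$strong_binder_percent
  skipped <- character(0)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- list.files(x, pattern = "\\.tsv$", full.names = TRUE)
    labels <- sub("_series$", "", sub("\\.tsv$", "", basename(files)))
    profiles <- list()
    for (i in seq_along(files)) {
      pr <- tryCatch(read_series(files[i], params), error = function(e) NULL)
      if (is.null(pr)) {
        warning("skipping unreadable series: ", files[i])
        skipped <- c(skipped, labels[i])
      } else profiles[[labels[i]]] <- pr
    }
  } else profiles <- x
  if (!length(profiles)) stop("no per-peptide series available")

  ranking <- rank_peptides(profiles)
  fractions <- stats::setNames(
    vapply(profiles, `[[`, numeric(1), "percent_bound"), names(profiles))
  strong <- select_by_rank(names(profiles), fractions, threshold_percent)
  motifs <- list(
    pairs_ordered = motif_pair_counts(strong, "ordered", "all"),
    pairs_total = motif_pair_counts(strong, "order_agnostic", "all"),
    pairs_interior = motif_pair_counts(strong, "ordered", "interior_2_5"),
    pairs_nterm = motif_pair_counts(strong, "ordered", "nterm_1_2"),
    pairs_cterm = motif_pair_counts(strong, "ordered", "cterm_5_6"),
    triplets = motif_triplet_counts(strong, "all"),
    positional_pairs = positional_motif_counts(strong, 2L),
    positional_triplets = positional_motif_counts(strong, 3L))
  list(ranking = ranking, strong = strong, n_strong = length(strong),
       motifs = motifs, skipped = skipped)
}
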