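#' Sequence permutation libraries and motif statistics
#'
#' The titanium-binding hexapeptide RKLPDA (min TBP-1) defines a residue
#' multiset \{R, K, L, P, D, A\}. The sequence-space tools enumerate all
#' orderings of such a multiset, collapse reverse pairs to a single
#' representative (a sequence and its reversal share the same residue
#' composition class), select strong binders by binding fraction, and count
#' adjacent pair/triplet motifs over a library, optionally position-resolved.
#'
#' @name sequence_space
NULL

PEPTIDE_ALPHABET <- c("R", "K", "L", "P", "D", "A")

#' Construct a sequence library
#'
#' A light container for a set of equal-purpose peptide labels together with
#' the deduplication policy that produced it.
#'
#' @param sequences character vector of sequence labels (no duplicates).
#' @param dedup_policy one of `"none"`, `"lexicographic_first"`, `"keep_list"`.
#' @param provenance free-form list recording generation parameters.
#' @return an object of class `sequence_library`.
#' @export
sequence_library <- function(sequences, dedup_policy = "none",
                             provenance = list()) {
  sequences <- as.character(sequences)
  if (anyDuplicated(sequences))
    stop("sequence library contains duplicate entries")
  structure(list(sequences = sequences, dedup_policy = dedup_policy,
                 provenance = provenance),
            class = "sequence_library")
}

#' @export
print.sequence_library <- function(x, ...) {
  cat(sprintf("<sequence_library> %d sequences (dedup: %s)\n",
              length(x$sequences), x$dedup_policy))
  show <- utils::head(x$sequences, 6L)
  cat(" ", paste(show, collapse = " "),
      if (length(x$sequences) > 6L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.sequence_library <- function(x) length(x$sequences)

as_sequences <- function(x) {
  if (inherits(x, "sequence_library")) x$sequences else as.character(x)
}

split_letters <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Enumerate all distinct orderings of a residue multiset
#'
#' Generates every distinct permutation of the given letters exactly once, in
#' lexicographic order. For the six distinct residues of RKLPDA this yields
#' the full 720-member permutation library.
#'
#' @param residues either a single string (e.g. `"RKLPDA"`) or a character
#'   vector of one-letter residue codes; repeats allowed (multiset).
#' @param alphabet allowed letters; defaults to the RKLPDA residue alphabet.
#' @return a [sequence_library] with all distinct orderings.
#' @examples
#' length(enumerate_permutations("RKLPDA"))  # 720
#' enumerate_permutations("AAB", alphabet = c("A", "B"))$sequences
#' @export
enumerate_permutations <- function(residues, alphabet = PEPTIDE_ALPHABET) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- split_letters(residues)
  residues <- as.character(residues)
  if (length(residues) == 0L) stop("residue multiset must be nonempty")
  bad <- setdiff(unique(residues), alphabet)
  if (length(bad))
    stop("residues outside the declared alphabet: ", paste(bad, collapse = ", "))

  # multiset permutations in lexicographic order via counts recursion
  letters_u <- sort(unique(residues))
  counts <- vapply(letters_u, function(l) sum(residues == l), integer(1))
  n <- length(residues)
  out <- character(0)
  recurse <- function(prefix, counts) {
    if (nchar(prefix) == n) return(prefix)
    unlist(lapply(seq_along(letters_u), function(i) {
      if (counts[i] == 0L) return(character(0))
      counts2 <- counts
      counts2[i] <- counts2[i] - 1L
      recurse(paste0(prefix, letters_u[i]), counts2)
    }))
  }
  out <- recurse("", counts)
  sequence_library(out, dedup_policy = "none",
                   provenance = list(op = "enumerate_permutations",
                                     residues = paste(residues, collapse = "")))
}

reverse_label <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Collapse reverse-sequence pairs to one representative
#'
#' A peptide read N-to-C and its reversal contain the same residues in
#' opposite order; for library construction the two are treated as one
#' composition class and a single member is retained. Palindromic sequences
#' are retained once. For the 720 orderings of six distinct residues the
#' result has 360 members.
#'
#' @param library a [sequence_library] or character vector (deduplicated).
#' @param policy `"lexicographic_first"` keeps the lexicographically smaller
#'   member of each pair; `"keep_list"` keeps the member present in
#'   `keep_list`; `"none"` returns the input unchanged.
#' @param keep_list for `policy = "keep_list"`: character vector containing
#'   exactly one member of every reverse pair.
#' @return a deduplicated [sequence_library].
#' @examples
#' lib <- enumerate_permutations("RKLPDA")
#' length(canonicalize_reverse_pairs(lib))  # 360
#' @export
canonicalize_reverse_pairs <- function(library,
                                       policy = c("lexicographic_first",
                                                  "keep_list", "none"),
                                       keep_list = NULL) {
  policy <- match.arg(policy)
  seqs <- as_sequences(library)
  if (anyDuplicated(seqs)) stop("library must be deduplicated")
  if (policy == "none")
    return(sequence_library(seqs, dedup_policy = "none"))

  revs <- reverse_label(seqs)
  if (policy == "lexicographic_first") {
    # keep the smaller of each pair; an entry whose reverse is absent from
    # the library is unpaired and kept as-is
    keep <- seqs[seqs <= revs | !(revs %in% seqs)]
  } else {
    if (is.null(keep_list)) stop("keep_list required for policy 'keep_list'")
    pair_key <- pmin(seqs, revs)
    offending <- character(0)
    keep <- character(0)
    for (key in unique(pair_key)) {
      members <- unique(seqs[pair_key == key])
      chosen <- intersect(keep_list, members)
      if (length(chosen) != 1L) offending <- c(offending, key)
      else keep <- c(keep, chosen)
    }
    if (length(offending))
      stop("keep_list must contain exactly one member of every reverse pair; ",
           "offending pairs: ", paste(offending, collapse = ", "))
    keep <- seqs[seqs %in% keep]
  }
  sequence_library(keep, dedup_policy = policy,
                   provenance = list(op = "canonicalize_reverse_pairs",
                                     n_input = length(seqs)))
}

#' Select sequences whose binding fraction exceeds a threshold
#'
#' Keeps sequences bound to the surface for strictly more than
#' `threshold_percent` of the trajectory, ordered by descending binding
#' fraction with lexicographic tie-break.
#'
#' @param library a [sequence_library] or character vector.
#' @param binding_fractions named numeric vector, label -> percent in
#'   \[0, 100\].
#' @param threshold_percent strong-binder cutoff (default 50, the
#'   more-than-half-the-time criterion).
#' @return a [sequence_library] of the selected sequences.
#' @export
select_by_rank <- function(library, binding_fractions,
                           threshold_percent = 50) {
  seqs <- as_sequences(library)
  missing <- setdiff(seqs, names(binding_fractions))
  if (length(missing))
    stop("missing binding fraction for: ", paste(missing, collapse = ", "))
  frac <- binding_fractions[seqs]
  if (any(frac < 0 | frac > 100))
    stop("binding fractions must lie in [0, 100]")
  keep <- seqs[frac > threshold_percent]
  keep <- keep[order(-binding_fractions[keep], keep)]
  sequence_library(keep, dedup_policy = "none",
                   provenance = list(op = "select_by_rank",
                                     threshold = threshold_percent))
}

motif_scope_starts <- function(scope, k, L) {
  all_starts <- seq_len(L - k + 1L)
  switch(scope,
         all = all_starts,
         interior_2_5 = all_starts[all_starts >= 2L & (all_starts + k - 1L) <= 5L],
         nterm_1_2 = 1L,
         cterm_5_6 = L - k + 1L,
         stop("unknown position scope: ", scope))
}

check_equal_length <- function(seqs, k) {
  L <- unique(nchar(seqs))
  if (length(L) > 1L) stop("sequences must all have equal length")
  if (length(L) == 0L) return(0L)
  if (L < k) stop("motif length k exceeds sequence length")
  L
}

window_tally <- function(seqs, k, starts, keep_position = FALSE,
                         order_agnostic = FALSE) {
  if (length(seqs) == 0L || length(starts) == 0L)
    return(data.frame(motif = character(0), position = integer(0),
                      count = integer(0)))
  windows <- unlist(lapply(starts, function(p)
    substr(seqs, p, p + k - 1L)), use.names = FALSE)
  positions <- rep(starts, each = length(seqs))
  if (order_agnostic) {
    windows <- vapply(strsplit(windows, "", fixed = TRUE),
                      function(ch) paste(sort(ch), collapse = ""), character(1))
  }
  key <- if (keep_position) paste(windows, positions, sep = "@") else windows
  tab <- table(key)
  if (keep_position) {
    parts <- strsplit(names(tab), "@", fixed = TRUE)
    data.frame(motif = vapply(parts, `[`, character(1), 1L),
               position = as.integer(vapply(parts, `[`, character(1), 2L)),
               count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(motif = names(tab), position = NA_integer_,
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
}

finish_motif_table <- function(df, mode, scope) {
  df$mode <- rep_len(mode, nrow(df))
  df$scope <- rep_len(scope, nrow(df))
  df <- df[order(-df$count, df$motif), c("motif", "position", "mode",
                                         "scope", "count")]
  rownames(df) <- NULL
  df
}

#' Count adjacent residue-pair motifs
#'
#' Tallies length-2 windows over a library. `mode = "ordered"` counts XY as
#' written; `mode = "order_agnostic"` merges XY and YX under the
#' alphabetically sorted key. `position_scope` restricts which window start
#' positions contribute: `"all"` (starts 1..L-1), `"interior_2_5"` (windows
#' fully inside positions 2..5), `"nterm_1_2"` (start 1 only),
#' `"cterm_5_6"` (last start only).
#'
#' @param seqs a [sequence_library] or character vector of equal-length
#'   sequences.
#' @param mode `"ordered"` or `"order_agnostic"`.
#' @param position_scope window-start restriction, see Details.
#' @return data.frame with columns motif, position (NA here), mode, scope,
#'   count, ordered by decreasing count.
#' @export
motif_pair_counts <- function(seqs, mode = c("ordered", "order_agnostic"),
                              position_scope = c("all", "interior_2_5",
                                                 "nterm_1_2", "cterm_5_6")) {
  mode <- match.arg(mode)
  position_scope <- match.arg(position_scope)
  seqs <- as_sequences(seqs)
  L <- check_equal_length(seqs, 2L)
  starts <- if (L) motif_scope_starts(position_scope, 2L, L) else integer(0)
  df <- window_tally(seqs, 2L, starts,
                     order_agnostic = (mode == "order_agnostic"))
  finish_motif_table(df, mode, position_scope)
}

#' Count adjacent residue-triplet motifs
#'
#' As [motif_pair_counts] with window length 3 (ordered only; starts 1..L-2
#' for scope `"all"`).
#'
#' @inheritParams motif_pair_counts
#' @export
motif_triplet_counts <- function(seqs, position_scope = c("all",
                                                          "interior_2_5",
                                                          "nterm_1_2",
                                                          "cterm_5_6")) {
  position_scope <- match.arg(position_scope)
  seqs <- as_sequences(seqs)
  L <- check_equal_length(seqs, 3L)
  starts <- if (L) motif_scope_starts(position_scope, 3L, L) else integer(0)
  df <- window_tally(seqs, 3L, starts)
  finish_motif_table(df, "ordered", position_scope)
}

#' Count motifs jointly with their start position
#'
#' Tallies (motif, start position) pairs; positions are 1-based.
#'
#' @param seqs a [sequence_library] or character vector of equal-length
#'   sequences.
#' @param k motif length, 2 or 3.
#' @return data.frame with columns motif, position, mode, scope, count.
#' @export
positional_motif_counts <- function(seqs, k = 2L) {
  stopifnot(k %in% c(2L, 3L))
  seqs <- as_sequences(seqs)
  L <- check_equal_length(seqs, k)
  starts <- if (L) seq_len(L - k + 1L) else integer(0)
  df <- window_tally(seqs, k, starts, keep_position = TRUE)
  finish_motif_table(df, "ordered", "positional")
}

#' Read / write sequence lists and motif tables
#'
#' Sequence lists are plain text, one label per line; labelled binding
#' fractions are TSV with columns `label`, `percent_bound`. Motif tables are
#' TSV with columns motif, position, mode, scope, count.
#'
#' @param x object to write.
#' @param path file path.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
write_sequence_list <- function(x, path) {
  writeLines(as_sequences(x), path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_sequence_list <- function(path) {
  sequence_library(readLines(path))
}

#' @rdname sequence_io
#' @export
write_motif_table <- function(x, path) {
  x$position <- ifelse(is.na(x$position), "-", as.character(x$position))
  write_tsv_plain(x, path)
}
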