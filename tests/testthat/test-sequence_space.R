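test_that("permutation enumeration is exhaustive, distinct and ordered", {
  lib <- enumerate_permutations("RKLPDA")
  expect_s3_class(lib, "sequence_library")
  expect_length(lib, 720L)
  expect_false(anyDuplicated(lib$sequences) > 0)
  expect_identical(lib$sequences, sort(lib$sequences))
  expect_true(all(nchar(lib$sequences) == 6L))

  expect_identical(enumerate_permutations("A", alphabet = "A")$sequences, "A")

  # multiset case against a brute-force set of orderings
  oracle <- unique(apply(
    expand.grid(1:3, 1:3, 1:3)[apply(expand.grid(1:3, 1:3, 1:3), 1,
                                     function(p) length(unique(p)) == 3), ],
    1, function(p) paste(c("A", "A", "B")[as.integer(p)], collapse = "")))
  got <- enumerate_permutations("AAB", alphabet = c("A", "B"))$sequences
  expect_setequal(got, oracle)
  expect_length(got, 3L)

  expect_error(enumerate_permutations(character(0)), "nonempty")
  expect_error(enumerate_permutations("RKLPDZ"), "alphabet")
})

test_that("reverse-pair canonicalization keeps one member per pair", {
  lib <- enumerate_permutations("RKLPDA")
  can <- canonicalize_reverse_pairs(lib)
  expect_length(can, 360L)
  revs <- vapply(strsplit(can$sequences, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  expect_length(intersect(can$sequences, revs), 0L)

  # idempotence
  again <- canonicalize_reverse_pairs(can)
  expect_identical(sort(again$sequences), sort(can$sequences))

  expect_identical(
    canonicalize_reverse_pairs(c("AB", "BA"))$sequences, "AB")
  abc <- enumerate_permutations("ABC", alphabet = c("A", "B", "C"))
  expect_length(canonicalize_reverse_pairs(abc), 3L)

  # n!/2 for distinct letters, for several n
  for (n in 3:5) {
    l <- enumerate_permutations(paste(LETTERS[1:n], collapse = ""),
                                alphabet = LETTERS[1:n])
    expect_length(canonicalize_reverse_pairs(l), factorial(n) / 2)
  }
})

test_that("keep_list canonicalization honours and validates the list", {
  lib <- enumerate_permutations("ABC", alphabet = c("A", "B", "C"))
  keep <- c("CBA", "BAC", "ACB")   # one per reverse pair, not all smallest
  got <- canonicalize_reverse_pairs(lib, policy = "keep_list",
                                    keep_list = keep)
  expect_setequal(got$sequences, keep)
  expect_error(
    canonicalize_reverse_pairs(lib, policy = "keep_list",
                               keep_list = c("ABC", "CBA", "BAC", "ACB")),
    "exactly one member")
  expect_error(
    canonicalize_reverse_pairs(lib, policy = "keep_list",
                               keep_list = c("BAC", "ACB")),
    "exactly one member")
})

test_that("rank selection uses a strict threshold and deterministic order", {
  seqs <- c("AAAAAA", "BBBBBB", "CCCCCC", "DDDDDD", "EEEEEE")
  frac <- setNames(c(10, 40, 50, 51, 90), seqs)
  got <- select_by_rank(seqs, frac, 50)
  expect_identical(got$sequences, c("EEEEEE", "DDDDDD"))  # strict: 50 excluded

  expect_length(select_by_rank(seqs, frac, 100), 0L)
  expect_error(select_by_rank(c(seqs, "FFFFFF"), frac), "FFFFFF")

  # ties broken lexicographically
  frac2 <- setNames(c(80, 80, 10, 10, 10), seqs)
  expect_identical(select_by_rank(seqs, frac2, 50)$sequences,
                   c("AAAAAA", "BBBBBB"))
})

test_that("pair motif counts match windows, modes and scopes", {
  t1 <- motif_pair_counts("RKLPDA", "ordered", "all")
  expect_setequal(t1$motif, c("RK", "KL", "LP", "PD", "DA"))
  expect_true(all(t1$count == 1L))

  t2 <- motif_pair_counts(c("RKLPDA", "ADPLKR"), "order_agnostic", "all")
  expect_equal(t2$count[t2$motif == "KR"], 2L)

  t3 <- motif_pair_counts("RPKLDA", "ordered", "nterm_1_2")
  expect_identical(t3$motif, "RP")
  expect_identical(t3$count, 1L)

  t4 <- motif_pair_counts("RPKLDA", "ordered", "cterm_5_6")
  expect_identical(t4$motif, "DA")

  t5 <- motif_pair_counts("RKLPDA", "ordered", "interior_2_5")
  expect_setequal(t5$motif, c("KL", "LP", "PD"))

  expect_error(motif_pair_counts(c("AB", "ABC")), "equal length")
})

test_that("triplet and positional counts agree with the brute-force scan", {
  t1 <- motif_triplet_counts("RKLPDA")
  expect_setequal(t1$motif, c("RKL", "KLP", "LPD", "PDA"))
  t2 <- motif_triplet_counts(c("RKLPDA", "RKLPDA"))
  expect_true(all(t2$count == 2L))

  p1 <- positional_motif_counts("RKLPDA", 2L)
  expect_equal(nrow(p1), 5L)
  expect_equal(p1$position[p1$motif == "DA"], 5L)
  expect_equal(nrow(positional_motif_counts(character(0), 2L)), 0L)

  set.seed(42)
  seqs <- replicate(20, paste(sample(c("R", "K", "L", "P", "D", "A")),
                              collapse = ""))
  for (scope_starts in list(list("all", 1:5), list("interior_2_5", 2:4))) {
    got <- motif_pair_counts(seqs, "ordered", scope_starts[[1]])
    want <- motif_oracle(seqs, 2L, scope_starts[[2]])
    expect_identical(setNames(as.integer(got$count), got$motif)[names(want)],
                     unlist(want))
  }
  got <- motif_triplet_counts(seqs, "all")
  want <- motif_oracle(seqs, 3L, 1:4)
  expect_identical(setNames(as.integer(got$count), got$motif)[names(want)],
                   unlist(want))
  got <- positional_motif_counts(seqs, 3L)
  want <- motif_oracle(seqs, 3L, 1:4, positional = TRUE)
  keys <- paste0(got$motif, "@", got$position)
  expect_identical(setNames(as.integer(got$count), keys)[names(want)],
                   unlist(want))

  # order-agnostic oracle agreement
  got <- motif_pair_counts(seqs, "order_agnostic", "all")
  want <- motif_oracle(seqs, 2L, 1:5, order_agnostic = TRUE)
  expect_identical(setNames(as.integer(got$count), got$motif)[names(want)],
                   unlist(want))
})

test_that("ordered pair counts sum to windows-per-sequence times sequences", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    seqs <- replicate(n, paste(sample(c("R", "K", "L", "P", "D", "A"), 6,
                                      replace = TRUE), collapse = ""))
    expect_equal(sum(motif_pair_counts(seqs, "ordered", "all")$count), 5L * n)
    expect_equal(sum(motif_triplet_counts(seqs, "all")$count), 4L * n)
    expect_equal(sum(motif_pair_counts(seqs, "order_agnostic", "all")$count),
                 5L * n)
  }
})

test_that("sequence lists and motif tables round-trip through disk", {
  lib <- sequence_library(c("RKLPDA", "AKPLDR"))
  f <- tempfile(fileext = ".txt")
  write_sequence_list(lib, f)
  expect_identical(read_sequence_list(f)$sequences, lib$sequences)
  tab <- motif_pair_counts("RKLPDA", "ordered", "all")
  f2 <- tempfile(fileext = ".tsv")
  write_motif_table(tab, f2)
  back <- read.table(f2, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$count, tab$count)
  expect_true(all(back$position == "-"))
})
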