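# internal helpers shared across modules

# minimum-image displacement along one orthorhombic box edge
min_image <- function(d, L) d - L * round(d / L)

# periodic distance between two scalar coordinates along an edge
periodic_dist1 <- function(z1, z2, L) {
  d <- abs(z1 - z2)
  pmin(d, L - d)
}

# pairwise minimum-image distances between two coordinate matrices (n x 3)
# under an orthorhombic box; returns an nA x nB matrix
pairwise_min_image <- function(xa, xb, box) {
  dx <- min_image(outer(xa[, 1], xb[, 1], "-"), box[1])
  dy <- min_image(outer(xa[, 2], xb[, 2], "-"), box[2])
  dz <- min_image(outer(xa[, 3], xb[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# wrap coordinates into [0, L) per box edge
wrap_coords <- function(xyz, box) {
  for (k in 1:3) xyz[, k] <- xyz[, k] - box[k] * floor(xyz[, k] / box[k])
  xyz
}

# run code with a locally seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# population standard deviation (divide by N)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
}
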