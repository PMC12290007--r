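# Independent oracles and small fixture builders used across the suite.

# Horn's quaternion method for least-squares superposition RMSD: an
# implementation independent of the SVD-based kabsch_rmsd.
quaternion_rmsd <- function(x, y) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- t(yc) %*% xc
  nmat <- matrix(0, 4, 4)
  nmat[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  nmat[1, 2] <- nmat[2, 1] <- s[2, 3] - s[3, 2]
  nmat[1, 3] <- nmat[3, 1] <- s[3, 1] - s[1, 3]
  nmat[1, 4] <- nmat[4, 1] <- s[1, 2] - s[2, 1]
  nmat[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  nmat[2, 3] <- nmat[3, 2] <- s[1, 2] + s[2, 1]
  nmat[2, 4] <- nmat[4, 2] <- s[1, 3] + s[3, 1]
  nmat[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  nmat[3, 4] <- nmat[4, 3] <- s[2, 3] + s[3, 2]
  nmat[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lam <- max(eigen(nmat, symmetric = TRUE, only.values = TRUE)$values)
  e0 <- sum(xc^2) + sum(yc^2)
  sqrt(max(0, (e0 - 2 * lam)) / n)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# plain double-loop GROMOS clustering, written directly from the verbal
# procedure; no shared code with gromos_cluster
gromos_oracle <- function(m, cutoff) {
  unassigned <- seq_len(nrow(m))
  clusters <- list()
  while (length(unassigned) > 0) {
    counts <- vapply(unassigned,
                     function(i) sum(m[i, unassigned] <= cutoff),
                     numeric(1))
    center <- unassigned[which.max(counts)]   # first max = lowest index
    mem <- unassigned[m[center, unassigned] <= cutoff]
    clusters[[length(clusters) + 1L]] <- mem
    unassigned <- setdiff(unassigned, mem)
  }
  clusters
}

# brute-force window scan for motif counts
motif_oracle <- function(seqs, k, starts, order_agnostic = FALSE,
                         positional = FALSE) {
  env <- new.env()
  for (s in seqs) {
    for (p in starts) {
      w <- substr(s, p, p + k - 1)
      if (order_agnostic)
        w <- paste(sort(strsplit(w, "")[[1]]), collapse = "")
      key <- if (positional) paste0(w, "@", p) else w
      env[[key]] <- (env[[key]] %||% 0L) + 1L
    }
  }
  out <- sort(unlist(as.list(env)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_symmetric_rmsd_matrix <- function(n, scale = 0.3) {
  m <- matrix(runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# minimal two-layer Ti slab system with a template peptide placed at a
# chosen COM height; small enough for arithmetic checks
toy_ssd_system <- function(com_z, plane_top = 3.05, plane_bot = 0,
                           box = c(5, 5, 10.7)) {
  ti_xy <- as.matrix(expand.grid(x = c(1, 2, 3), y = c(1, 2, 3)))
  ti <- rbind(cbind(ti_xy, plane_top), cbind(ti_xy, plane_bot))
  tpl <- build_peptide_template("RKLPDA", 0.65)
  top <- system_topology(
    name = c(rep("TI", nrow(ti)), tpl$atoms$name),
    resname = c(rep("TIO", nrow(ti)), tpl$atoms$resname),
    resid = c(rep(1L, nrow(ti)), tpl$atoms$resid),
    peptide_sequence = "RKLPDA",
    bonds = tpl$bonds + nrow(ti))
  pep <- tpl$xyz
  m <- top$mass[top$segment == "peptide"]
  com <- colSums(pep * m) / sum(m)
  pep <- sweep(pep, 2, com - c(2.5, 2.5, com_z), "-")
  frame <- traj_frame(rbind(ti, pep), box, time = 0)
  list(topology = top, frame = frame,
       classes = classify_atoms(top, frame))
}

# small shared benchmark run (computed once per test session)
benchmark_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_validation_benchmark(seed = 101L,
                                         spec = synthetic_spec(n_frames = 2000L))
    cache
  }
})
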