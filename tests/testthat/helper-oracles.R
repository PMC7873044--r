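# Independent reference implementations and small fixture builders used
# across the test files. These deliberately avoid the package's own code
# paths (loops instead of vectorized distance math, quaternion eigenvalue
# method instead of SVD, manual scan instead of rle).

# all-pairs brute-force contact detection
oracle_contacts <- function(frame, topology, cutoff = 8,
                            min_separation = 5) {
  res <- topology$residues
  n <- nrow(frame)
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      eligible <- res$chain_id[i] != res$chain_id[j] ||
        abs(res$local_index[i] - res$local_index[j]) >= min_separation
      if (eligible && d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

# manual scan run-length encoding of a logical series into
# (start, length, censored) rows
oracle_events <- function(s) {
  s <- as.logical(s)
  rows <- NULL
  start <- NA_integer_
  for (f in seq_along(s)) {
    if (s[f] && is.na(start)) start <- f
    ended <- !is.na(start) && (!s[f] || f == length(s))
    if (ended) {
      end <- if (s[f]) f else f - 1L
      rows <- rbind(rows, c(start, end - start + 1L,
                            as.integer(start == 1L || end == length(s))))
      start <- NA_integer_
    }
  }
  if (is.null(rows))
    return(data.frame(start_frame = integer(), length_frames = integer(),
                      censored = logical()))
  data.frame(start_frame = rows[, 1], length_frames = rows[, 2],
             censored = rows[, 3] == 1L)
}

# quaternion eigenvalue method (Horn) for the minimal superposition RMSD
oracle_kabsch_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4,
    byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(a^2) + sum(b^2) - 2 * lambda, 0) / nrow(mobile))
}

# random proper rotation + translation applied to an n x 3 matrix
random_rigid_motion <- function(coords) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t(q %*% t(coords)) + matrix(rnorm(3, sd = 20), nrow(coords), 3,
                              byrow = TRUE)
}

# minimal topologies/trajectories -------------------------------------------

two_bead_topology <- function() {
  cg_topology(data.frame(index = 1:2, chain_id = c("A", "B"),
                         local_index = c(1L, 1L), name = "GLY",
                         region = c("BAR", "C_TERM")))
}

# single-chain topology of n GLY residues, all one region
chain_topology <- function(n, region = "PDZ", chains = 1L) {
  per <- n %/% chains
  cg_topology(data.frame(index = seq_len(per * chains),
                         chain_id = rep(LETTERS[seq_len(chains)],
                                        each = per),
                         local_index = rep(seq_len(per), chains),
                         name = "GLY", region = region))
}

# a 2-bead trajectory whose contact state encodes a given logical series
traj_from_series <- function(s, interval = 10000L, label = "t") {
  nf <- length(s)
  coords <- array(0, dim = c(nf, 2, 3))
  coords[, 2, 1] <- ifelse(as.logical(s), 5, 20)
  cg_trajectory(coords, interval, label)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "cgcontact", mustWork = TRUE)
}
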