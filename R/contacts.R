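## Residue-residue contact analysis: detection, probabilities, maps,
## events/lifetimes, top-pair ranking and interaction-type classification.
##
## A contact is defined on the C-alpha trace: two residues are in contact in
## a frame when their C-alpha distance is at most the cutoff (default 8
## Angstrom, boundary inclusive) and, within one chain, they are at least
## `min_sequence_separation` residues apart (default 5). Pairs on different
## chains are always eligible: for inter-protomer or inter-domain pairs a
## concatenated-index gap is meaningless, so the separation rule is read as
## an intra-chain exclusion of trivial sequence neighbours.

#' Contact criterion
#'
#' @param cutoff Distance cutoff in Angstrom; a pair at exactly the cutoff
#'   is in contact ("8 Angstrom or less").
#' @param min_sequence_separation Minimum |local index difference| for
#'   same-chain pairs (`|i - j| >=` this value). Inter-chain pairs are
#'   always eligible.
#' @return Object of class `cg_contact_criterion`.
#' @export
contact_criterion <- function(cutoff = 8.0, min_sequence_separation = 5L) {
  stopifnot(cutoff > 0, min_sequence_separation >= 0)
  structure(list(cutoff = as.numeric(cutoff),
                 min_sequence_separation =
                   as.integer(min_sequence_separation)),
            class = "cg_contact_criterion")
}

#' Which residue pairs are eligible under the contact criterion?
#'
#' @param topology A `cg_topology`.
#' @param i,j Equal-length vectors of concatenated indices.
#' @param criterion A [contact_criterion()].
#' @return Logical vector.
#' @export
pair_eligible <- function(topology, i, j, criterion = contact_criterion()) {
  i <- .check_index(topology, i); j <- .check_index(topology, j)
  res <- topology$residues
  same_chain <- res$chain_id[i] == res$chain_id[j]
  sep <- abs(res$local_index[i] - res$local_index[j])
  (i != j) & (!same_chain | sep >= criterion$min_sequence_separation)
}

#' Detect contacts in a single frame
#'
#' @param frame `n_residues x 3` coordinate matrix (or a one-frame slice of
#'   a trajectory via [frame_coords()]).
#' @param topology Matching `cg_topology`.
#' @param criterion A [contact_criterion()].
#' @return Two-column integer matrix of contacting pairs `(i, j)`, `i < j`,
#'   ordered lexicographically.
#' @export
detect_contacts <- function(frame, topology,
                            criterion = contact_criterion()) {
  stopifnot(is.matrix(frame), ncol(frame) == 3)
  n <- n_residues(topology)
  if (nrow(frame) != n)
    stop("frame has ", nrow(frame), " residues, topology ", n)
  dm <- as.matrix(dist(frame))
  hit <- which(upper.tri(dm) & dm <= criterion$cutoff, arr.ind = TRUE)
  if (!nrow(hit))
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  keep <- pair_eligible(topology, hit[, 1], hit[, 2], criterion)
  out <- hit[keep, , drop = FALSE]
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  storage.mode(out) <- "integer"
  out
}

## distance series for a set of pairs over pooled frames, chunked so the
## intermediate (frames x pairs x 3) arrays stay small
.pair_dist_series <- function(coords, pairs, chunk_pairs = 2000L) {
  nf <- dim(coords)[1]
  m <- nrow(pairs)
  out <- matrix(NA_real_, nf, m)
  for (s in seq(1L, m, by = chunk_pairs)) {
    e <- min(s + chunk_pairs - 1L, m)
    pi <- pairs[s:e, 1]; pj <- pairs[s:e, 2]
    d2 <- (coords[, pi, 1, drop = FALSE] - coords[, pj, 1, drop = FALSE])^2 +
      (coords[, pi, 2, drop = FALSE] - coords[, pj, 2, drop = FALSE])^2 +
      (coords[, pi, 3, drop = FALSE] - coords[, pj, 3, drop = FALSE])^2
    out[, s:e] <- sqrt(matrix(d2, nf))
  }
  out
}

.as_pair_matrix <- function(pair) {
  if (is.matrix(pair)) {
    stopifnot(ncol(pair) == 2)
    p <- pair
  } else if (is.data.frame(pair)) {
    p <- cbind(pair[[1]], pair[[2]])
  } else {
    stopifnot(length(pair) == 2)
    p <- matrix(pair, 1, 2)
  }
  storage.mode(p) <- "integer"
  p
}

#' Per-frame contact indicator series for residue pair(s)
#'
#' @param x A `cg_pool`, `cg_ensemble` or `cg_trajectory`.
#' @param pair Length-2 vector, or an `m x 2` matrix of pairs.
#' @param topology Matching `cg_topology`.
#' @param criterion A [contact_criterion()].
#' @return Logical matrix `(pooled frames) x m` (a vector if one pair was
#'   given as a length-2 vector). Pairs ineligible under the criterion are
#'   an error.
#' @export
contact_series <- function(x, pair, topology,
                           criterion = contact_criterion()) {
  pool <- pool_frames(x)
  p <- .as_pair_matrix(pair)
  ok <- pair_eligible(topology, p[, 1], p[, 2], criterion)
  if (!all(ok))
    stop("pair(s) ineligible under the contact criterion: ",
         paste(sprintf("(%d,%d)", p[!ok, 1], p[!ok, 2]), collapse = " "))
  d <- .pair_dist_series(pool$coords, p)
  res <- d <= criterion$cutoff
  if (!is.matrix(pair) && !is.data.frame(pair)) res[, 1] else res
}

#' Contact probability of a residue pair over pooled frames
#'
#' 100 x (frames in contact) / (total pooled frames); every frame of every
#' trajectory counts with equal weight, so trajectories weight by length.
#'
#' @inheritParams contact_series
#' @return Numeric percentage in `[0, 100]` (vectorized over pair rows).
#' @export
contact_probability <- function(x, pair, topology,
                                criterion = contact_criterion()) {
  s <- contact_series(x, pair, topology, criterion)
  if (is.matrix(s)) 100 * colMeans(s) else 100 * mean(s)
}

#' Contact probability map between two residue groups
#'
#' Entry `(a, b)` is the pooled-frame contact probability (in %) of the
#' pair; cells excluded by the sequence-separation rule (and the diagonal)
#' are `NA`. The map over `(B, A)` is the transpose of the map over
#' `(A, B)`.
#'
#' @param x A `cg_pool`, `cg_ensemble` or `cg_trajectory`.
#' @param group_a,group_b Integer vectors of concatenated residue indices
#'   (non-empty; typically two regions via [region_indices()]).
#' @param topology Matching `cg_topology`.
#' @param criterion A [contact_criterion()].
#' @return Object of class `cg_contact_map`: list with `map` (matrix %,
#'   dimnames = residue indices), `row_indices`, `col_indices`,
#'   `n_frames`, `criterion`.
#' @export
contact_map <- function(x, group_a, group_b, topology,
                        criterion = contact_criterion()) {
  group_a <- .check_index(topology, group_a)
  group_b <- .check_index(topology, group_b)
  if (!length(group_a) || !length(group_b))
    stop("residue groups must be non-empty")
  pool <- pool_frames(x)
  grid <- expand.grid(a = group_a, b = group_b)
  elig <- pair_eligible(topology, grid$a, grid$b, criterion)
  prob <- rep(NA_real_, nrow(grid))
  if (any(elig)) {
    d <- .pair_dist_series(pool$coords,
                           .as_pair_matrix(grid[elig, c("a", "b")]))
    prob[elig] <- 100 * colMeans(d <= criterion$cutoff)
  }
  map <- matrix(prob, length(group_a), length(group_b),
                dimnames = list(group_a, group_b))
  structure(list(map = map, row_indices = group_a, col_indices = group_b,
                 n_frames = n_frames(pool), criterion = criterion),
            class = "cg_contact_map")
}

#' @export
print.cg_contact_map <- function(x, ...) {
  cat("cg_contact_map: ", length(x$row_indices), " x ",
      length(x$col_indices), " residues over ", x$n_frames, " frames; ",
      sum(!is.na(x$map)), " eligible pairs, max ",
      round(max(x$map, na.rm = TRUE), 2), "%\n", sep = "")
  invisible(x)
}

#' Log-percentage display transform of a contact map
#'
#' `log10(max(probability_pct, floor_pct))`; the floor makes
#' zero-probability cells representable on a log colour scale (the
#' conventional display transform for contact maps over many frames).
#'
#' @param map A `cg_contact_map` (or bare matrix of percentages).
#' @param floor_pct Positive floor in percent (default 0.01).
#' @return Matrix of log10 percentages; `NA` cells stay `NA`.
#' @export
log_percentage <- function(map, floor_pct = 0.01) {
  stopifnot(floor_pct > 0)
  m <- if (inherits(map, "cg_contact_map")) map$map else map
  log10(pmax(m, floor_pct))
}

#' Contact events (maximal runs of consecutive in-contact frames)
#'
#' Events are computed per trajectory and never span a trajectory boundary.
#' An event touching the first or last frame of its trajectory is flagged
#' `censored`: its true duration is only partially observed.
#'
#' @param x A `cg_ensemble` or `cg_trajectory`.
#' @param pair Length-2 integer vector (concatenated indices).
#' @param topology Matching `cg_topology`.
#' @param criterion A [contact_criterion()].
#' @return Data frame with columns `trajectory`, `start_frame`,
#'   `length_frames`, `censored`; attribute `pair`.
#' @export
contact_events <- function(x, pair, topology,
                           criterion = contact_criterion()) {
  if (inherits(x, "cg_trajectory")) x <- cg_ensemble(list(x))
  stopifnot(inherits(x, "cg_ensemble"))
  out <- lapply(x$trajectories, function(tr) {
    s <- contact_series(tr, pair, topology, criterion)
    ev <- .runs_from_series(s)
    if (nrow(ev)) ev$trajectory <- tr$label
    ev
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(trajectory = character(), start_frame = integer(),
                      length_frames = integer(), censored = logical())
  out <- out[, c("trajectory", "start_frame", "length_frames", "censored")]
  rownames(out) <- NULL
  attr(out, "pair") <- as.integer(pair)
  out
}

## run-length encoding of a logical series into events
.runs_from_series <- function(s) {
  r <- rle(as.logical(s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = starts[keep],
             length_frames = r$lengths[keep],
             censored = starts[keep] == 1L | ends[keep] == length(s))
}

#' Lifetime statistics of contact events
#'
#' Event duration = `length_frames * snapshot_interval_steps / unit_steps`;
#' by convention lifetimes are reported in units of 100,000 simulation
#' steps. Censored (boundary-touching) events are included by default:
#' excluding them would bias against long-lived contacts; the `censored`
#' flag on the events lets callers re-filter. The standard deviation is the
#' population SD (divide by n) since the reported "mean +/- sd" values are
#' descriptive; set `sd_type = "sample"` for the n-1 version.
#'
#' @param events Event data frame from [contact_events()].
#' @param snapshot_interval_steps Simulation steps between frames.
#' @param unit_steps Steps per lifetime unit (default 100000).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `mean`, `sd`, `n_events`.
#' @export
lifetime_stats <- function(events, snapshot_interval_steps,
                           unit_steps = 100000, sd_type = c("population",
                                                            "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(unit_steps > 0)
  if (!nrow(events))
    stop("no contact events: lifetime statistics undefined")
  dur <- events$length_frames * snapshot_interval_steps / unit_steps
  n <- length(dur)
  m <- mean(dur)
  s <- if (n == 1L) 0 else {
    v <- sum((dur - m)^2) / if (sd_type == "population") n else n - 1L
    sqrt(v)
  }
  list(mean = m, sd = s, n_events = n)
}

#' Per-pair contact statistics over an ensemble
#'
#' For each requested pair: pooled contact probability, event count, and
#' lifetime mean/SD in units of `unit_steps` simulation steps, plus residue
#' names and interaction class.
#'
#' @param x A `cg_ensemble` or `cg_trajectory`.
#' @param pairs `m x 2` matrix/data frame of concatenated index pairs.
#' @param topology Matching `cg_topology`.
#' @param criterion A [contact_criterion()].
#' @param unit_steps Lifetime unit in simulation steps (default 100000).
#' @return Data frame with columns `i`, `name_i`, `j`, `name_j`,
#'   `probability_pct`, `lifetime_mean`, `lifetime_sd`, `n_events`,
#'   `class`.
#' @export
contact_pair_stats <- function(x, pairs, topology,
                               criterion = contact_criterion(),
                               unit_steps = 100000) {
  if (inherits(x, "cg_trajectory")) x <- cg_ensemble(list(x))
  stopifnot(inherits(x, "cg_ensemble"))
  p <- .as_pair_matrix(pairs)
  m <- nrow(p)
  total_frames <- n_frames(x)
  in_contact <- numeric(m)
  nev <- integer(m)
  sum_d <- numeric(m); sum_d2 <- numeric(m)
  for (tr in x$trajectories) {
    s <- contact_series(tr, p, topology, criterion)
    if (!is.matrix(s)) s <- matrix(s, ncol = m)
    in_contact <- in_contact + colSums(s)
    fac <- tr$snapshot_interval_steps / unit_steps
    for (k in seq_len(m)) {
      ev <- .runs_from_series(s[, k])
      if (nrow(ev)) {
        d <- ev$length_frames * fac
        nev[k] <- nev[k] + nrow(ev)
        sum_d[k] <- sum_d[k] + sum(d)
        sum_d2[k] <- sum_d2[k] + sum(d^2)
      }
    }
  }
  lt_mean <- ifelse(nev > 0, sum_d / pmax(nev, 1), NA_real_)
  lt_sd <- ifelse(nev > 0,
                  sqrt(pmax(sum_d2 / pmax(nev, 1) - lt_mean^2, 0)),
                  NA_real_)
  data.frame(
    i = p[, 1], name_i = residue_name(topology, p[, 1]),
    j = p[, 2], name_j = residue_name(topology, p[, 2]),
    probability_pct = 100 * in_contact / total_frames,
    lifetime_mean = lt_mean, lifetime_sd = lt_sd, n_events = nev,
    class = vapply(seq_len(m), function(k)
      suppressWarnings(classify_interaction(p[k, ], topology)), ""),
    stringsAsFactors = FALSE)
}

#' Top-ranked contact pairs between two regions
#'
#' Enumerates all criterion-eligible pairs with one residue in `region_a`
#' and the other in `region_b` (either orientation), computes pooled
#' probabilities and lifetimes, and returns the top `n` pairs sorted by
#' probability (descending), breaking ties by lifetime mean (descending),
#' then by `(i, j)` ascending. Pairs never in contact are dropped; fewer
#' than `n` qualifying pairs simply gives a shorter table.
#'
#' @param x A `cg_ensemble` or `cg_trajectory`.
#' @param topology Matching `cg_topology`.
#' @param region_a,region_b Region labels, or integer index vectors.
#' @param n Number of pairs to return (default 10).
#' @param criterion A [contact_criterion()].
#' @param unit_steps Lifetime unit in simulation steps.
#' @return Data frame as in [contact_pair_stats()], ranked.
#' @export
top_pairs <- function(x, topology, region_a, region_b, n = 10L,
                      criterion = contact_criterion(),
                      unit_steps = 100000) {
  stopifnot(n >= 1)
  ia <- if (is.character(region_a)) region_indices(topology, region_a)
        else .check_index(topology, region_a)
  ib <- if (is.character(region_b)) region_indices(topology, region_b)
        else .check_index(topology, region_b)
  if (!length(ia) || !length(ib)) stop("empty residue region")
  grid <- expand.grid(i = ia, j = ib)
  ## canonical i < j and dedupe (regions may overlap)
  sw <- grid$i > grid$j
  tmp <- grid$i[sw]; grid$i[sw] <- grid$j[sw]; grid$j[sw] <- tmp
  grid <- unique(grid[grid$i != grid$j, ])
  grid <- grid[pair_eligible(topology, grid$i, grid$j, criterion), ]
  if (!nrow(grid)) return(.empty_stats())
  stats <- contact_pair_stats(x, grid, topology, criterion, unit_steps)
  stats <- stats[stats$probability_pct > 0, ]
  if (!nrow(stats)) return(.empty_stats())
  ord <- order(-stats$probability_pct, -stats$lifetime_mean,
               stats$i, stats$j)
  out <- head(stats[ord, ], n)
  rownames(out) <- NULL
  out
}

.empty_stats <- function() {
  data.frame(i = integer(), name_i = character(), j = integer(),
             name_j = character(), probability_pct = numeric(),
             lifetime_mean = numeric(), lifetime_sd = numeric(),
             n_events = integer(), class = character(),
             stringsAsFactors = FALSE)
}

#' Classify the interaction type of a residue pair
#'
#' Residue-type-based classification using the topology's hydropathy table:
#' `ELECTROSTATIC` if one residue is positive and the other negative,
#' `HYDROPHOBIC` if both are hydrophobic, `POLAR` if both are polar,
#' otherwise `MIXED`. An `UNK` residue gives `UNKNOWN` with a warning.
#'
#' @param pair Length-2 vector of concatenated indices.
#' @param topology A `cg_topology`.
#' @return One of `"HYDROPHOBIC"`, `"ELECTROSTATIC"`, `"POLAR"`, `"MIXED"`,
#'   `"UNKNOWN"`.
#' @export
#' @examples
#' # a lysine-aspartate pair classifies as ELECTROSTATIC
classify_interaction <- function(pair, topology) {
  stopifnot(length(pair) == 2)
  cls <- residue_class(topology, pair)
  if (any(cls == "UNKNOWN")) {
    warning("pair (", pair[1], ",", pair[2],
            ") involves an UNK residue; classification UNKNOWN")
    return("UNKNOWN")
  }
  if (all(c("POSITIVE", "NEGATIVE") %in% cls)) return("ELECTROSTATIC")
  if (all(cls == "HYDROPHOBIC")) return("HYDROPHOBIC")
  if (all(cls == "POLAR")) return("POLAR")
  "MIXED"
}

## ---- TSV export ----------------------------------------------------------

#' Export a contact map or top-pairs table as TSV
#'
#' @param x A `cg_contact_map` or a stats data frame.
#' @param path Output file.
#' @param provenance Optional comment line (written with a leading `#`).
#' @param log_floor If non-`NULL`, export [log_percentage()] values with
#'   this floor instead of raw percentages.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(x, path, provenance = NULL, log_floor = NULL) {
  stopifnot(inherits(x, "cg_contact_map"))
  m <- if (is.null(log_floor)) x$map else log_percentage(x, log_floor)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("residue", colnames(m)), collapse = "\t"), con)
  for (r in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[r],
                       formatC(m[r, ], format = "g", digits = 6)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
write_pair_table <- function(x, path, provenance = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(format(x, digits = 6, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
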