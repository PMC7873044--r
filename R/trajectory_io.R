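## Trajectory containers and I/O. Coordinates are C-alpha positions in
## Angstrom throughout; a trajectory stores an (n_frames x n_residues x 3)
## array plus the simulation-step interval between recorded snapshots.

#' Construct a coarse-grained trajectory
#'
#' @param coords Numeric array of dimension `(n_frames, n_residues, 3)`, or a
#'   single `n_residues x 3` matrix for a one-frame trajectory. Angstrom.
#' @param snapshot_interval_steps Simulation steps between consecutive
#'   frames (default 10000, the conventional coarse-grained MD output
#'   interval).
#' @param label Trajectory identifier used in pooled analyses and event
#'   tables.
#' @return Object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, snapshot_interval_steps = 10000L,
                          label = "traj") {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  storage.mode(coords) <- "double"
  if (dim(coords)[1] < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  snapshot_interval_steps <- as.integer(snapshot_interval_steps)
  if (is.na(snapshot_interval_steps) || snapshot_interval_steps < 1L)
    stop("snapshot_interval_steps must be a positive integer")
  structure(list(coords = coords,
                 snapshot_interval_steps = snapshot_interval_steps,
                 label = as.character(label)),
            class = "cg_trajectory")
}

#' @export
n_residues.cg_trajectory <- function(x) dim(x$coords)[2]

#' Number of frames in a trajectory, ensemble or pooled frame stream
#' @param x A `cg_trajectory`, `cg_ensemble` or `cg_pool`.
#' @return Integer frame count (summed over members for ensembles).
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.cg_trajectory <- function(x) dim(x$coords)[1]

#' Extract one frame as an `n_residues x 3` coordinate matrix
#' @param trajectory A `cg_trajectory`.
#' @param i Frame number (1-based).
#' @return Numeric matrix.
#' @export
frame_coords <- function(trajectory, i = 1L) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(trajectory)) stop("frame index out of range")
  matrix(trajectory$coords[i, , ], ncol = 3L)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory '", x$label, "': ", n_frames(x), " frames x ",
      n_residues(x), " residues, snapshot interval ",
      x$snapshot_interval_steps, " steps\n", sep = "")
  invisible(x)
}

#' Bundle trajectories into an ensemble
#'
#' Member trajectories must share one topology (identical residue counts);
#' trajectory boundaries are preserved so that contact events never span two
#' trajectories.
#'
#' @param ... `cg_trajectory` objects, or a single list of them.
#' @return Object of class `cg_ensemble`.
#' @export
cg_ensemble <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && !inherits(trajs[[1]], "cg_trajectory"))
    trajs <- trajs[[1]]
  if (!length(trajs)) stop("ensemble must contain at least one trajectory")
  ok <- vapply(trajs, inherits, TRUE, what = "cg_trajectory")
  if (!all(ok)) stop("all members must be cg_trajectory objects")
  nres <- vapply(trajs, n_residues, 1L)
  if (length(unique(nres)) != 1L)
    stop("member trajectories have differing residue counts: ",
         paste(unique(nres), collapse = ", "))
  labs <- vapply(trajs, function(t) t$label, "")
  if (anyDuplicated(labs)) {
    labs <- make.unique(labs, sep = "_")
    for (k in seq_along(trajs)) trajs[[k]]$label <- labs[k]
  }
  structure(list(trajectories = trajs), class = "cg_ensemble")
}

#' @export
n_frames.cg_ensemble <- function(x)
  sum(vapply(x$trajectories, n_frames, 1L))

#' @export
n_residues.cg_ensemble <- function(x) n_residues(x$trajectories[[1]])

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("cg_ensemble:", length(x$trajectories), "trajectories,",
      n_frames(x), "frames total,", n_residues(x), "residues\n")
  invisible(x)
}

## ---- pooled frame stream -------------------------------------------------

#' Pool frames of an ensemble into one tagged frame stream
#'
#' Contact probabilities are computed over the combined trajectories with
#' equal weight per frame; each pooled frame keeps its source trajectory tag
#' so that event detection never crosses a trajectory boundary. Frame order
#' within each trajectory is preserved.
#'
#' @param x A `cg_ensemble`, or a single `cg_trajectory`.
#' @return Object of class `cg_pool`: list with `coords` (array
#'   `(total_frames, n_residues, 3)`), `trajectory` (character tag per
#'   frame), and `frame` (1-based frame number within its trajectory).
#' @export
pool_frames <- function(x) {
  if (inherits(x, "cg_pool")) return(x)
  if (inherits(x, "cg_trajectory")) x <- cg_ensemble(list(x))
  stopifnot(inherits(x, "cg_ensemble"))
  nf <- vapply(x$trajectories, n_frames, 1L)
  nres <- n_residues(x)
  total <- sum(nf)
  coords <- array(NA_real_, dim = c(total, nres, 3L))
  at <- 0L
  for (t in x$trajectories) {
    coords[at + seq_len(n_frames(t)), , ] <- t$coords
    at <- at + n_frames(t)
  }
  structure(list(
    coords = coords,
    trajectory = rep(vapply(x$trajectories, function(t) t$label, ""), nf),
    frame = unlist(lapply(nf, seq_len), use.names = FALSE)
  ), class = "cg_pool")
}

#' @export
n_frames.cg_pool <- function(x) dim(x$coords)[1]

#' @export
n_residues.cg_pool <- function(x) dim(x$coords)[2]

## ---- multi-model PDB -----------------------------------------------------

#' Read a multi-model PDB trajectory (C-alpha records)
#'
#' Reads MODEL/ENDMDL-delimited C-alpha coordinates via [bio3d::read.pdb()]
#' and validates them against the topology: every model must contain exactly
#' one CA atom per topology residue. Chains are matched by order of
#' appearance (coarse-grained PDB chain ids are unreliable); frames are
#' returned in MODEL-number order even if the file stores them out of order.
#'
#' @param path PDB file path.
#' @param topology A `cg_topology` the file must match.
#' @param snapshot_interval_steps Steps between models (not stored in PDB).
#' @param label Trajectory label (default: file base name).
#' @return A [cg_trajectory].
#' @export
read_multimodel_pdb <- function(path, topology,
                                snapshot_interval_steps = 10000L,
                                label = NULL) {
  stopifnot(inherits(topology, "cg_topology"))
  if (!file.exists(path)) stop("no such file: ", path)
  nres <- n_residues(topology)

  ## pre-scan for MODEL numbers and per-model CA counts so that format
  ## errors can name the offending model/residue
  lines <- readLines(path, warn = FALSE)
  model_at <- grep("^MODEL", lines)
  model_no <- if (length(model_at)) {
    as.integer(sub("^MODEL\\s+(\\d+).*", "\\1", lines[model_at]))
  } else 1L
  is_ca <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA "
  if (length(model_at)) {
    grp <- findInterval(which(is_ca), model_at)
    counts <- tabulate(grp, nbins = length(model_at))
  } else {
    counts <- sum(is_ca)
  }
  bad <- which(counts != nres)
  if (length(bad))
    stop("model ", model_no[bad[1]], " has ", counts[bad[1]],
         " CA atoms but topology expects ", nres,
         if (counts[bad[1]] < nres)
           paste0(" (first missing residue: concatenated index ",
                  counts[bad[1]] + 1L, ")") else "")

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  if (ncol(xyz) != 3L * nres)
    stop("CA count mismatch: file has ", ncol(xyz) / 3, ", topology ", nres)
  ord <- order(model_no)
  xyz <- xyz[ord, , drop = FALSE]

  ## validate residue names where the file provides them
  fnames <- pdb$atom$resid[sel$atom]
  tnames <- topology$residues$name
  known <- tnames != "UNK" & fnames %in% c(.aa3, "UNK")
  if (any(known & fnames != tnames)) {
    k <- which(known & fnames != tnames)[1]
    warning("residue name mismatch at concatenated index ", k, ": file ",
            fnames[k], ", topology ", tnames[k])
  }

  nfr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nfr, nres, 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3L * nres, by = 3L)]
  cg_trajectory(coords, snapshot_interval_steps,
                label = label %||% sub("\\.pdb$", "", basename(path)))
}

#' Write a trajectory as a multi-model PDB (CA atoms)
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology Matching `cg_topology` (supplies chain ids, residue names
#'   and local numbering).
#' @param path Output file path.
#' @return `path`, invisibly. Coordinates are written at PDB fixed precision
#'   (0.001 Angstrom).
#' @export
write_multimodel_pdb <- function(trajectory, topology, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"),
            inherits(topology, "cg_topology"))
  nres <- n_residues(topology)
  if (n_residues(trajectory) != nres)
    stop("trajectory has ", n_residues(trajectory),
         " residues, topology ", nres)
  nfr <- n_frames(trajectory)
  xyz <- matrix(NA_real_, nfr, 3L * nres)
  for (d in 1:3) xyz[, seq(d, 3L * nres, by = 3L)] <- trajectory$coords[, , d]
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topology$residues$local_index,
                   resid = topology$residues$name,
                   chain = substr(topology$residues$chain_id, 1, 1),
                   elety = rep("CA", nres))
  invisible(path)
}

## ---- tabular trajectory --------------------------------------------------

#' Read/write trajectories in the tabular coordinate format
#'
#' A TSV with one metadata comment line then the columns `frame`,
#' `residue_index`, `x`, `y`, `z`:
#'
#' ```
#' # snapshot_interval_steps=10000
#' frame  residue_index  x  y  z
#' 1      1              0  0  0
#' ```
#'
#' The writer emits full double precision (`%.17g`), so a write/read round
#' trip is bit-identical. A missing metadata line falls back to the default
#' interval of 10000 steps with a warning.
#'
#' @param path File path.
#' @param label Trajectory label (default: file base name).
#' @return A [cg_trajectory].
#' @export
read_coordinate_table <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  interval <- NA_integer_
  if (grepl("^#", first)) {
    m <- regmatches(first,
                    regexec("snapshot_interval_steps\\s*=\\s*(\\d+)", first))[[1]]
    if (length(m) == 2L) interval <- as.integer(m[2])
  }
  if (is.na(interval)) {
    warning("no snapshot_interval_steps metadata line in ", path,
            "; defaulting to 10000 steps")
    interval <- 10000L
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("integer", "integer", "numeric",
                                   "numeric", "numeric"))
  req <- c("frame", "residue_index", "x", "y", "z")
  if (!identical(names(tab), req))
    stop("expected columns ", paste(req, collapse = ", "))
  frames <- sort(unique(tab$frame))
  counts <- table(tab$frame)
  if (length(unique(as.integer(counts))) != 1L)
    stop("ragged frames: residue counts differ across frames (",
         paste(range(counts), collapse = "-"), ")")
  nres <- as.integer(counts[1])
  tab <- tab[order(tab$frame, tab$residue_index), ]
  if (!all(tab$residue_index == rep(seq_len(nres), length(frames))))
    stop("residue_index must run 1..", nres, " within every frame")
  coords <- array(NA_real_, dim = c(length(frames), nres, 3L))
  coords[, , 1] <- matrix(tab$x, length(frames), nres, byrow = TRUE)
  coords[, , 2] <- matrix(tab$y, length(frames), nres, byrow = TRUE)
  coords[, , 3] <- matrix(tab$z, length(frames), nres, byrow = TRUE)
  cg_trajectory(coords, interval,
                label = label %||% sub("\\.(tsv|txt)$", "", basename(path)))
}

#' @rdname read_coordinate_table
#' @param trajectory A `cg_trajectory` to write.
#' @export
write_coordinate_table <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  nfr <- n_frames(trajectory); nres <- n_residues(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# snapshot_interval_steps=%d",
                     trajectory$snapshot_interval_steps), con)
  writeLines("frame\tresidue_index\tx\ty\tz", con)
  fr <- rep(seq_len(nfr), each = nres)
  ri <- rep(seq_len(nres), times = nfr)
  x <- as.vector(t(matrix(trajectory$coords[, , 1], nfr, nres)))
  y <- as.vector(t(matrix(trajectory$coords[, , 2], nfr, nres)))
  z <- as.vector(t(matrix(trajectory$coords[, , 3], nfr, nres)))
  writeLines(sprintf("%d\t%d\t%.17g\t%.17g\t%.17g", fr, ri, x, y, z), con)
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
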