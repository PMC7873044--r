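## Superposition-based geometry analyses: Kabsch least-squares alignment,
## RMSD series, radius of gyration, anchor-residue distance series and
## frequency distributions.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `R %*% mobile + t` and `reference` over the fit selection, using
#' the SVD of the cross-covariance matrix with the determinant sign
#' correction that excludes reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices (same `n`).
#' @param fit_selection Integer vector of rows used for the fit (default:
#'   all). At least 3 non-collinear points are required.
#' @return Object of class `cg_superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom, over the fit
#'   selection).
#' @export
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(30), 10, 3)
#' sup <- kabsch_superpose(a, a)
#' sup$rmsd   # 0
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  sel <- fit_selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3) stop("fit selection must contain at least 3 points")
  m <- mobile[sel, , drop = FALSE]
  r <- reference[sel, , drop = FALSE]
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2, mc); r0 <- sweep(r, 2, rc)
  h <- crossprod(m0, r0)                       # 3x3 cross-covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) fit selection: superposition ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- rc - as.numeric(rot %*% mc)
  fitted <- t(rot %*% t(m)) + matrix(trans, nrow(m), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "cg_superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix.
#' @param sup A `cg_superposition`.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sup) {
  t(sup$rotation %*% t(coords)) +
    matrix(sup$translation, nrow(coords), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#' @param a,b `n x 3` matrices.
#' @param selection Optional row selection.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL) {
  sel <- selection %||% seq_len(nrow(a))
  sqrt(mean(rowSums((a[sel, , drop = FALSE] - b[sel, , drop = FALSE])^2)))
}

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed onto the reference over `fit_selection` and the
#' RMSD reported over `calc_selection`. Defaults follow the convention for
#' tethered-domain systems: the reference is the initial structure, the fit
#' uses the restrained (rigid-core) regions of the topology so that
#' flexible-part motion is signal rather than fit noise, and the RMSD is
#' computed over all residues.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology Optional `cg_topology` (supplies the restrained-region
#'   default for `fit_selection`).
#' @param reference Reference `n x 3` matrix (default: first frame).
#' @param fit_selection,calc_selection Integer residue selections.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(trajectory, topology = NULL, reference = NULL,
                        fit_selection = NULL, calc_selection = NULL) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  reference <- reference %||% frame_coords(trajectory, 1L)
  if (is.null(fit_selection) && !is.null(topology) &&
      length(topology$restrained_regions)) {
    fit_selection <- region_indices(topology,
                                    topology$restrained_regions)
  }
  fit_selection <- fit_selection %||% seq_len(n_residues(trajectory))
  calc_selection <- calc_selection %||% seq_len(n_residues(trajectory))
  if (!length(fit_selection) || !length(calc_selection))
    stop("empty residue selection")
  vapply(seq_len(n_frames(trajectory)), function(f) {
    fr <- frame_coords(trajectory, f)
    sup <- kabsch_superpose(fr, reference, fit_selection)
    rmsd(apply_superposition(fr, sup), reference, calc_selection)
  }, 1.0)
}

#' Radius of gyration of a frame
#'
#' Root-mean-square distance of the selected C-alpha sites from their
#' centroid, with uniform bead masses.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param selection Optional integer selection (default: all).
#' @return Rg in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)) # 2
radius_of_gyration <- function(frame, selection = NULL) {
  stopifnot(is.matrix(frame), ncol(frame) == 3)
  sel <- selection %||% seq_len(nrow(frame))
  if (!length(sel)) stop("empty residue selection")
  x <- frame[sel, , drop = FALSE]
  c0 <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, c0)^2)))
}

#' @rdname radius_of_gyration
#' @param trajectory A `cg_trajectory`.
#' @return `rg_series()`: one Rg per frame.
#' @export
rg_series <- function(trajectory, selection = NULL) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  vapply(seq_len(n_frames(trajectory)), function(f)
    radius_of_gyration(frame_coords(trajectory, f), selection), 1.0)
}

#' Per-frame distance between two anchor residues
#'
#' The conventional way to summarize mobile-domain position is the
#' C-alpha-C-alpha distance between an anchor residue on the mobile domain
#' and an anchor on the reference body (domain-to-rod-tip, domain-to-rod
#' centre, domain-to-domain). A centroid mode is provided as an option: it
#' uses the centroid of each anchor's whole region instead of the single
#' C-alpha.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology Matching `cg_topology`.
#' @param anchors Length-2 integer vector of concatenated indices.
#' @param mode `"ca"` (default) or `"region_centroid"` (centroid of each
#'   anchor's region, split by chain).
#' @return Numeric vector of per-frame distances (Angstrom).
#' @export
anchor_distance_series <- function(trajectory, topology, anchors,
                                   mode = c("ca", "region_centroid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajectory, "cg_trajectory"), length(anchors) == 2)
  anchors <- .check_index(topology, anchors)
  if (mode == "ca") {
    d <- trajectory$coords[, anchors[1], ] - trajectory$coords[, anchors[2], ]
    if (is.null(dim(d))) d <- matrix(d, 1)
    return(sqrt(rowSums(d^2)))
  }
  res <- topology$residues
  sel <- lapply(anchors, function(a)
    which(res$region == res$region[a] & res$chain_id == res$chain_id[a]))
  vapply(seq_len(n_frames(trajectory)), function(f) {
    fr <- frame_coords(trajectory, f)
    sqrt(sum((colMeans(fr[sel[[1]], , drop = FALSE]) -
                colMeans(fr[sel[[2]], , drop = FALSE]))^2))
  }, 1.0)
}

#' Anchor pairs declared by a topology
#'
#' If the topology has a special set named `anchors`, returns the
#' conventional pairing: first anchor against each of the others.
#'
#' @param topology A `cg_topology`.
#' @return `m x 2` integer matrix of anchor pairs.
#' @export
default_anchor_pairs <- function(topology) {
  a <- topology$special_sets$anchors
  if (is.null(a) || length(a) < 2)
    stop("topology declares no usable 'anchors' special set")
  cbind(a[1], a[-1])
}

#' Frequency distribution of a per-frame scalar series
#'
#' Frequency is the proportion of frames per bin (bin counts / total), so
#' frequencies sum to 1. The sample median and range are reported
#' alongside.
#'
#' @param values Numeric vector (at least one value).
#' @param bins Number of equal-width bins over the observed range (default
#'   50), or an explicit vector of strictly increasing bin edges.
#' @return Object of class `cg_distribution`: list with `values`, `breaks`,
#'   `frequency`, `median`, `range`.
#' @export
make_distribution <- function(values, bins = 50L) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector")
  if (length(bins) == 1L) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = as.integer(bins) + 1L)
  } else {
    breaks <- as.numeric(bins)
    if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(values = values, breaks = h$breaks,
                 frequency = h$counts / length(values),
                 median = median(values), range = range(values)),
            class = "cg_distribution")
}

#' @export
print.cg_distribution <- function(x, ...) {
  cat("cg_distribution: n =", length(x$values),
      " median =", signif(x$median, 4),
      " range = [", signif(x$range[1], 4), ",", signif(x$range[2], 4),
      "]\n")
  invisible(x)
}

#' Export a distribution (or raw series) as TSV
#'
#' @param x A `cg_distribution` or numeric vector.
#' @param path Output file.
#' @param provenance Optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(x, path, provenance = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  if (inherits(x, "cg_distribution")) {
    nb <- length(x$frequency)
    writeLines("bin_left\tbin_right\tfrequency", con)
    writeLines(sprintf("%.10g\t%.10g\t%.10g", x$breaks[seq_len(nb)],
                       x$breaks[-1], x$frequency), con)
  } else {
    writeLines("value", con)
    writeLines(sprintf("%.10g", as.numeric(x)), con)
  }
  invisible(path)
}
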