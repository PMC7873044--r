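## Mobile-unit position clustering in the reference-body frame: where does
## the tethered domain (or tail) sit relative to the rigid reference body,
## and what fraction of frames does each preferred position hold?

#' Mobile-unit positions in the reference-body frame
#'
#' Every frame is superposed onto a reference structure using the C-alpha
#' sites of `ref_region`, and the position of each copy of `mobile_region`
#' (split by chain, so symmetric copies such as the two tethered domains of
#' a dimer are separate observation streams) is recorded in that common
#' frame. Position = centroid of the copy's C-alpha sites by default, or a
#' single anchor residue per copy.
#'
#' @param x A `cg_ensemble` or `cg_trajectory`.
#' @param topology Matching `cg_topology`.
#' @param mobile_region Region label(s) of the mobile unit (e.g. `"PDZ"`,
#'   `"C_TERM"`).
#' @param ref_region Region label(s) of the rigid reference body (default
#'   `"BAR"`); needs at least 3 non-collinear residues.
#' @param reference Reference `n x 3` coordinates (default: first frame of
#'   the first trajectory).
#' @param mode `"centroid"` (default) or `"anchor"`.
#' @param anchor For `mode = "anchor"`: one concatenated index per copy.
#' @return Object of class `cg_positions`: data frame with columns
#'   `trajectory`, `frame`, `copy`, `x`, `y`, `z`; attributes `reference`
#'   and `ref_selection`.
#' @export
mobile_positions <- function(x, topology, mobile_region,
                             ref_region = "BAR", reference = NULL,
                             mode = c("centroid", "anchor"),
                             anchor = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "cg_trajectory")) x <- cg_ensemble(list(x))
  stopifnot(inherits(x, "cg_ensemble"), inherits(topology, "cg_topology"))
  ref_sel <- region_indices(topology, ref_region)
  if (length(ref_sel) < 3)
    stop("reference region needs at least 3 residues")
  mob <- region_indices(topology, mobile_region)
  if (!length(mob)) stop("mobile region is empty")
  copies <- split(mob, topology$residues$chain_id[mob])
  if (mode == "anchor") {
    anchor <- .check_index(topology, anchor)
    if (length(anchor) != length(copies))
      stop("need one anchor per copy (", length(copies), ")")
    copies <- as.list(anchor)
    names(copies) <- topology$residues$chain_id[anchor]
  }
  reference <- reference %||% frame_coords(x$trajectories[[1]], 1L)

  rows <- vector("list", length(x$trajectories))
  for (t in seq_along(x$trajectories)) {
    tr <- x$trajectories[[t]]
    nf <- n_frames(tr)
    pos <- array(NA_real_, dim = c(nf, length(copies), 3))
    for (f in seq_len(nf)) {
      fr <- frame_coords(tr, f)
      sup <- kabsch_superpose(fr, reference, ref_sel)
      frt <- apply_superposition(fr, sup)
      for (k in seq_along(copies))
        pos[f, k, ] <- colMeans(frt[copies[[k]], , drop = FALSE])
    }
    rows[[t]] <- data.frame(
      trajectory = tr$label,
      frame = rep(seq_len(nf), times = length(copies)),
      copy = rep(names(copies), each = nf),
      x = as.vector(pos[, , 1]), y = as.vector(pos[, , 2]),
      z = as.vector(pos[, , 3]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "ref_selection") <- ref_sel
  class(out) <- c("cg_positions", "data.frame")
  out
}

#' Cluster mobile-unit positions
#'
#' Partitional (k-means) clustering of the observations of a
#' [mobile_positions()] set, with seeded deterministic initialization.
#' Every observation is assigned to exactly one cluster, so occupancy
#' fractions are a partition of 100%. Clusters are reported in descending
#' occupancy order.
#'
#' @param positions A `cg_positions` data frame (or any data frame with
#'   `x`, `y`, `z` columns).
#' @param k Number of clusters (default 5, the conventional count for
#'   mobile-domain position analysis).
#' @param seed Integer seed controlling initialization.
#' @param nstart Random restarts of k-means (default 10).
#' @return Object of class `cg_clusters`: list with `centroids` (`k x 3`),
#'   `assignments` (per observation, relabelled so cluster 1 is largest),
#'   `fractions` (% of observations per cluster, sums to 100),
#'   `observations` (the input positions), `algorithm`, `k`, `seed`.
#' @export
cluster_positions <- function(positions, k = 5L, seed = 1L, nstart = 10L) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  n <- nrow(xyz)
  k <- as.integer(k)
  if (k < 1L || k > n)
    stop("k must be between 1 and the number of observations (", n, ")")
  set.seed(as.integer(seed))
  km <- if (k == n) {
    list(cluster = seq_len(n), centers = xyz)
  } else {
    ## Lloyd iterations: same minimizer family as the default algorithm but
    ## free of Quick-TRANSfer convergence warnings on diffuse clouds
    kmeans(xyz, centers = k, nstart = as.integer(nstart), iter.max = 500L,
           algorithm = "Lloyd")
  }
  size <- tabulate(km$cluster, nbins = k)
  ord <- order(-size, seq_len(k))            # stable relabel, largest first
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[km$cluster]
  centroids <- unname(as.matrix(km$centers))[ord, , drop = FALSE]
  colnames(centroids) <- c("x", "y", "z")
  structure(list(centroids = centroids, assignments = assignments,
                 fractions = 100 * size[ord] / n,
                 observations = positions, algorithm = "kmeans",
                 k = k, seed = as.integer(seed)),
            class = "cg_clusters")
}

#' @export
print.cg_clusters <- function(x, ...) {
  cat("cg_clusters: k =", x$k, "(", x$algorithm, ", seed", x$seed, ")\n")
  for (c2 in seq_len(x$k))
    cat(sprintf("  cluster %d: %5.1f%%  centroid (%.1f, %.1f, %.1f)\n",
                c2, x$fractions[c2], x$centroids[c2, 1],
                x$centroids[c2, 2], x$centroids[c2, 3]))
  invisible(x)
}

#' Proximity of cluster centroids to a special residue set
#'
#' For each cluster centroid, the minimum distance to any C-alpha of the
#' named special set in the reference structure; clusters closer than
#' `threshold` are flagged as covering that set (default threshold: the 8
#' Angstrom contact cutoff plus 4 Angstrom of slack, since a centroid sits
#' roughly a domain radius away from its surface residues).
#'
#' @param clusters A [cluster_positions()] result.
#' @param topology Matching `cg_topology`.
#' @param set_name Name of the special set (e.g. `"basic_patch"`).
#' @param reference Reference coordinates (default: the `reference`
#'   attribute of the clustered positions).
#' @param threshold Covering distance threshold in Angstrom (default 12).
#' @return Data frame: `cluster`, `fraction_pct`, `centroid_x/y/z`,
#'   `min_dist`, `covering`.
#' @export
occupancy_report <- function(clusters, topology, set_name,
                             reference = NULL, threshold = 12) {
  stopifnot(inherits(clusters, "cg_clusters"))
  set <- topology$special_sets[[set_name]]
  if (is.null(set)) stop("no special set named '", set_name, "'")
  reference <- reference %||% attr(clusters$observations, "reference")
  if (is.null(reference))
    stop("no reference structure available; pass `reference`")
  ref_pts <- reference[set, , drop = FALSE]
  dmin <- vapply(seq_len(clusters$k), function(c2)
    min(.cdist(clusters$centroids[c2, , drop = FALSE], ref_pts)), 1.0)
  data.frame(cluster = seq_len(clusters$k),
             fraction_pct = clusters$fractions,
             centroid_x = clusters$centroids[, 1],
             centroid_y = clusters$centroids[, 2],
             centroid_z = clusters$centroids[, 3],
             min_dist = dmin,
             covering = dmin <= threshold)
}

#' Export cluster report / assignments as TSV
#'
#' @param clusters A `cg_clusters`.
#' @param path Output file.
#' @param provenance Optional `#` comment line.
#' @param report Optional [occupancy_report()] output to use as the report
#'   table; otherwise fractions and centroids only.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path, provenance = NULL,
                                 report = NULL) {
  tab <- report %||% data.frame(
    cluster = seq_len(clusters$k), fraction_pct = clusters$fractions,
    centroid_x = clusters$centroids[, 1],
    centroid_y = clusters$centroids[, 2],
    centroid_z = clusters$centroids[, 3])
  write_pair_table(tab, path, provenance)
}

#' @rdname write_cluster_report
#' @export
write_cluster_assignments <- function(clusters, path, provenance = NULL) {
  obs <- clusters$observations
  tab <- data.frame(trajectory = obs$trajectory, frame = obs$frame,
                    copy = obs$copy, cluster = clusters$assignments)
  write_pair_table(tab, path, provenance)
}
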