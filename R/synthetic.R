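## Synthetic tethered-domain trajectory generator.
##
## The generator emulates the architecture of a dimeric scaffolding protein
## at bead resolution: a rigid curved rod (surrogate for a dimeric BAR
## domain) with compact rigid bodies (PDZ surrogates) tethered to it by
## flexible linkers, and/or flexible tails (C-terminus surrogates). Sticky
## square-well pairs plant contact propensities with known ground truth;
## optional screened-Coulomb charges plant electrostatic contacts.
## Sampling is Metropolis Monte Carlo at unit kT, which targets exactly the
## equilibrium ensemble the contact/position analyses consume; frame
## "time" is MC pseudo-time and is used only to exercise the lifetime
## estimator, not to mimic physical kinetics.

#' Parameters of the synthetic tethered-domain model
#'
#' @param ref_body List `list(n_beads, radius_of_curvature)` describing the
#'   rigid curved reference rod (bead spacing = `bond_length`). Default: 40
#'   beads on an arc of radius 60 Angstrom.
#' @param mobile_bodies Integer vector: bead count of each rigid compact
#'   mobile body (tethered domain surrogate). May be empty.
#' @param linkers Integer vector, same length as `mobile_bodies`: flexible
#'   linker length (beads) tethering each mobile body to the rod.
#' @param tails Integer vector: lengths of flexible tails attached directly
#'   to the rod. May be empty.
#' @param bond_length Virtual bond length in Angstrom (default 3.8, the
#'   C-alpha spacing).
#' @param bead_radius Hard-sphere bead radius in Angstrom (default 2.0);
#'   nonbonded beads of different rigid units may not come closer than
#'   `2 * bead_radius`. Set to 0 to disable excluded volume.
#' @param bond_k Harmonic bond stiffness in kT/Angstrom^2 (default 100; the
#'   thermal bond-length standard deviation is `1/sqrt(2 * bond_k)`).
#' @param sticky_pairs Data frame with columns `i`, `j` (concatenated bead
#'   indices, see [bead_layout()]), `eps` (square-well depth in kT, >= 0)
#'   and `width` (well width in Angstrom, default 8).
#' @param charges Data frame with columns `index`, `q` (integer charges), or
#'   `NULL`. Interacts via screened Coulomb `bjerrum * qi * qj *
#'   exp(-r/debye) / r` (kT).
#' @param bjerrum Bjerrum length in Angstrom (default 7, aqueous solvent).
#' @param debye Debye screening length in Angstrom (default 10).
#' @param temperature_factor Dimensionless temperature; energies are divided
#'   by it in the Metropolis test (default 1).
#' @param n_steps Monte Carlo steps per trajectory.
#' @param record_interval Steps between recorded frames.
#' @param n_equil Equilibration steps discarded before recording.
#' @param seed Root random seed; per-trajectory streams are derived from it
#'   deterministically.
#' @param attach_sites Optional integer vector of rod bead indices where
#'   the chains attach, in unit order (mobile bodies first, then tails).
#'   Default alternates between the two rod ends.
#' @param step_disp,step_trans,step_rot,step_pivot Move amplitudes: Gaussian
#'   single-bead displacement (Angstrom), rigid-body translation (Angstrom),
#'   rigid-body rotation (radians), pivot rotation (radians).
#' @return Object of class `cg_synthetic_params`.
#' @seealso [build_system()], [run_mc()], [load_preset()]
#' @export
synthetic_params <- function(ref_body = list(n_beads = 40,
                                             radius_of_curvature = 60),
                             mobile_bodies = integer(),
                             linkers = integer(),
                             tails = integer(),
                             bond_length = 3.8,
                             bead_radius = 2.0,
                             bond_k = 100,
                             sticky_pairs = NULL,
                             charges = NULL,
                             bjerrum = 7.0,
                             debye = 10.0,
                             temperature_factor = 1.0,
                             n_steps = 600000L,
                             record_interval = 300L,
                             n_equil = 30000L,
                             seed = 1L,
                             attach_sites = NULL,
                             step_disp = 0.8,
                             step_trans = 1.2,
                             step_rot = 0.35,
                             step_pivot = 0.8) {
  mobile_bodies <- as.integer(mobile_bodies)
  linkers <- as.integer(linkers)
  tails <- as.integer(tails)
  if (length(mobile_bodies) != length(linkers))
    stop("linkers must give one length per mobile body")
  stopifnot(ref_body$n_beads >= 1, bond_length > 0, bead_radius >= 0,
            bond_k > 0, temperature_factor > 0,
            n_steps >= 1, record_interval >= 1, n_equil >= 0)
  if (length(mobile_bodies) && any(mobile_bodies < 1 | linkers < 1))
    stop("mobile body and linker lengths must be positive")
  if (length(tails) && any(tails < 1)) stop("tail lengths must be positive")
  p <- structure(list(
    ref_body = list(n_beads = as.integer(ref_body$n_beads),
                    radius_of_curvature =
                      as.numeric(ref_body$radius_of_curvature %||% 60)),
    mobile_bodies = mobile_bodies, linkers = linkers, tails = tails,
    bond_length = bond_length, bead_radius = bead_radius, bond_k = bond_k,
    sticky_pairs = sticky_pairs, charges = charges,
    bjerrum = bjerrum, debye = debye,
    temperature_factor = temperature_factor,
    n_steps = as.integer(n_steps),
    record_interval = as.integer(record_interval),
    n_equil = as.integer(n_equil), seed = as.integer(seed),
    attach_sites = if (!is.null(attach_sites)) as.integer(attach_sites),
    step_disp = step_disp, step_trans = step_trans,
    step_rot = step_rot, step_pivot = step_pivot
  ), class = "cg_synthetic_params")
  lay <- bead_layout(p)
  if (!is.null(sticky_pairs)) {
    sp <- as.data.frame(sticky_pairs)
    if (!all(c("i", "j", "eps") %in% names(sp)))
      stop("sticky_pairs needs columns i, j, eps")
    if (is.null(sp$width)) sp$width <- 8.0
    if (any(sp$eps < 0)) stop("sticky well depths must be >= 0")
    if (any(sp$i < 1 | sp$i > lay$n_beads | sp$j < 1 | sp$j > lay$n_beads))
      stop("sticky pair indices reference nonexistent beads (1..",
           lay$n_beads, ")")
    p$sticky_pairs <- data.frame(i = as.integer(sp$i), j = as.integer(sp$j),
                                 eps = as.numeric(sp$eps),
                                 width = as.numeric(sp$width))
  }
  if (!is.null(charges)) {
    ch <- as.data.frame(charges)
    if (!all(c("index", "q") %in% names(ch)))
      stop("charges needs columns index, q")
    if (any(ch$index < 1 | ch$index > lay$n_beads))
      stop("charge indices reference nonexistent beads")
    p$charges <- data.frame(index = as.integer(ch$index),
                            q = as.numeric(ch$q))
  }
  p
}

#' Concatenated bead indexing of a synthetic system
#'
#' Beads are numbered rod first, then for each mobile body its linker
#' followed by its body beads, then each tail — matching the chain
#' declaration order of the generated topology.
#'
#' @param params A `cg_synthetic_params`.
#' @return List with `rod`, `linker` (list per body), `body` (list per
#'   body), `tail` (list per tail) index vectors and `n_beads`.
#' @export
bead_layout <- function(params) {
  B <- params$ref_body$n_beads
  at <- B
  linker <- body <- vector("list", length(params$mobile_bodies))
  for (k in seq_along(params$mobile_bodies)) {
    linker[[k]] <- at + seq_len(params$linkers[k]); at <- at + params$linkers[k]
    body[[k]] <- at + seq_len(params$mobile_bodies[k])
    at <- at + params$mobile_bodies[k]
  }
  tail <- vector("list", length(params$tails))
  for (k in seq_along(params$tails)) {
    tail[[k]] <- at + seq_len(params$tails[k]); at <- at + params$tails[k]
  }
  list(rod = seq_len(B), linker = linker, body = body, tail = tail,
       n_beads = at)
}

## compact rigid cluster: lattice points (spacing >= hard-core diameter)
## nearest the origin, restricted to the half-space beyond the attachment
## direction d so the body never folds back onto its linker; bead 1 is the
## attachment bead (minimal projection along d), returned at the origin
.body_geometry <- function(m, spacing, d) {
  g <- 3L
  pts <- as.matrix(expand.grid(x = -g:g, y = -g:g, z = -g:g)) * spacing
  proj <- as.numeric(pts %*% d)
  keep <- proj >= -1e-9
  pts <- pts[keep, , drop = FALSE]
  proj <- proj[keep]
  ord <- order(rowSums(pts^2))[seq_len(m)]
  pts <- pts[ord, , drop = FALSE]
  proj <- proj[ord]
  first <- which.min(proj)
  pts <- pts[c(first, setdiff(seq_len(m), first)), , drop = FALSE]
  sweep(pts, 2, pts[1, ])
}

.rod_geometry <- function(B, Rc, b) {
  if (B == 1L) return(matrix(0, 1, 3))
  dth <- 2 * asin(b / (2 * Rc))      # chord spacing = bond length exactly
  th <- (seq_len(B) - (B + 1) / 2) * dth
  cbind(Rc * sin(th), Rc * (cos(th) - 1), 0)
}

#' Build the initial frame and topology of a synthetic system
#'
#' Places the rigid rod on a circular arc in the xy-plane, then grows each
#' linker/tail outward from its rod attachment site as a straight chain at
#' bond-length spacing, with the rigid mobile body (a compact lattice
#' cluster) beyond the linker. Placement is retried with rotated growth
#' directions (bounded attempts) if hard-sphere overlaps occur.
#'
#' Topology regions: rod beads are labelled `BAR`, mobile bodies `PDZ`,
#' linkers `LINKER`, tails `C_TERM`. The rod is chain `A`; each tethered
#' unit gets its own chain, so symmetric copies are distinguished by chain.
#' Special sets `anchors` (rod end beads) and `sticky` (all sticky-pair
#' members) are declared. Charged beads are named LYS/ASP by charge sign,
#' all others GLY.
#'
#' @param params A [synthetic_params()] object.
#' @return Object of class `cg_system`: list with `topology`, `coords`
#'   (initial frame), `bonds`, `kind`, `unit`, `bodies`, `segments`,
#'   `params`.
#' @export
build_system <- function(params) {
  stopifnot(inherits(params, "cg_synthetic_params"))
  lay <- bead_layout(params)
  b <- params$bond_length
  hc <- 2 * params$bead_radius
  n <- lay$n_beads
  B <- params$ref_body$n_beads

  rod <- .rod_geometry(B, params$ref_body$radius_of_curvature, b)
  n_units <- length(params$mobile_bodies) + length(params$tails)
  attach <- params$attach_sites
  if (is.null(attach)) {
    ends <- integer(0)
    lo <- 1L; hi <- B
    for (k in seq_len(max(n_units, 0))) {
      if (k %% 2L == 1L) { ends <- c(ends, lo); lo <- lo + 1L }
      else { ends <- c(ends, hi); hi <- hi - 1L }
    }
    attach <- ends
  }
  if (n_units > 0 && length(attach) < n_units)
    stop("need ", n_units, " attachment sites, got ", length(attach))
  if (n_units > 0 && any(attach < 1L | attach > B))
    stop("attachment sites must be rod bead indices 1..", B)

  rod_centroid <- colMeans(rod)
  out_dir <- function(site, attempt) {
    d <- rod[site, ] - rod_centroid
    if (sum(d^2) < 1e-9) d <- c(0, 0, 1)
    d <- d / sqrt(sum(d^2))
    if (attempt > 0) {           # deterministic jitter for retries
      ang <- attempt * (2 * pi / 8)
      axis <- c(0, 0, 1)
      d <- d * cos(ang) + .cross(axis, d) * sin(ang) +
        axis * sum(axis * d) * (1 - cos(ang))
      d <- d / sqrt(sum(d^2))
    }
    d
  }

  coords <- matrix(NA_real_, n, 3)
  coords[lay$rod, ] <- rod
  bonds <- data.frame(i = integer(), j = integer())
  if (B > 1)
    bonds <- data.frame(i = lay$rod[-B], j = lay$rod[-1])
  unit <- integer(n); unit[lay$rod] <- 1L
  kind <- integer(n)                       # rod fixed = 0
  bodies <- list(); segments <- list(); seg_npivot <- integer()

  place_chain <- function(site, idx, body_idx = NULL) {
    ## returns coords rows for idx (and body) grown along dir; NULL if clash
    for (attempt in 0:7) {
      d <- out_dir(site, attempt)
      pos <- matrix(NA_real_, length(idx) + length(body_idx), 3)
      for (k in seq_along(idx))
        pos[k, ] <- rod[site, ] + k * b * d
      if (length(body_idx)) {
        geo <- .body_geometry(length(body_idx), max(hc, b) + 0.2, d)
        anchor_pt <- rod[site, ] + (length(idx) + 1) * b * d
        pos[length(idx) + seq_along(body_idx), ] <-
          sweep(geo, 2, anchor_pt, "+")
      }
      ## clash check against already-placed beads
      placed <- which(!is.na(coords[, 1]))
      ok <- TRUE
      if (hc > 0 && length(placed)) {
        dm <- .cdist(pos, coords[placed, , drop = FALSE])
        ## ignore the bonded attachment contact (chain bead 1 vs rod site)
        dm[1, match(site, placed)] <- Inf
        if (min(dm) < hc) ok <- FALSE
      }
      if (ok) return(pos)
    }
    NULL
  }

  u <- 1L
  chain_ids <- LETTERS[-1]
  chains <- list(list(id = "A", region = rep("BAR", B), name = rep("GLY", B)))
  ci <- 1L
  for (k in seq_along(params$mobile_bodies)) {
    site <- attach[u]
    idx <- lay$linker[[k]]; bidx <- lay$body[[k]]
    pos <- place_chain(site, idx, bidx)
    if (is.null(pos))
      stop("infeasible packing: could not place mobile body ", k,
           " without hard-sphere overlap")
    coords[c(idx, bidx), ] <- pos
    bonds <- rbind(bonds,
                   data.frame(i = c(site, idx), j = c(idx, bidx[1])[
                     seq_len(length(idx) + 1)]))
    unit[bidx] <- 1L + k
    kind[idx] <- 1L; kind[bidx] <- 2L
    bodies[[length(bodies) + 1L]] <- bidx
    segments[[length(segments) + 1L]] <- c(site, idx, bidx)
    seg_npivot <- c(seg_npivot, 1L + length(idx))
    ci <- ci + 1L
    chains[[ci]] <- list(
      id = chain_ids[ci - 1L],
      region = c(rep("LINKER", length(idx)), rep("PDZ", length(bidx))),
      name = rep("GLY", length(idx) + length(bidx)))
    u <- u + 1L
  }
  for (k in seq_along(params$tails)) {
    site <- attach[u]
    idx <- lay$tail[[k]]
    pos <- place_chain(site, idx)
    if (is.null(pos))
      stop("infeasible packing: could not place tail ", k,
           " without hard-sphere overlap")
    coords[idx, ] <- pos
    bonds <- rbind(bonds, data.frame(i = c(site, idx[-length(idx)]),
                                     j = idx))
    kind[idx] <- 1L
    segments[[length(segments) + 1L]] <- c(site, idx)
    seg_npivot <- c(seg_npivot, length(idx))
    ci <- ci + 1L
    chains[[ci]] <- list(
      id = chain_ids[ci - 1L],
      region = rep("C_TERM", length(idx)),
      name = rep("GLY", length(idx)))
    u <- u + 1L
  }

  ## residue names: charged beads LYS/ASP, sticky partners kept GLY
  name <- unlist(lapply(chains, `[[`, "name"))
  if (!is.null(params$charges)) {
    name[params$charges$index[params$charges$q > 0]] <- "LYS"
    name[params$charges$index[params$charges$q < 0]] <- "ASP"
  }
  residues <- data.frame(
    index = seq_len(n),
    chain_id = rep(vapply(chains, `[[`, "", "id"),
                   vapply(chains, function(c2) length(c2$region), 1L)),
    local_index = unlist(lapply(chains,
                                function(c2) seq_along(c2$region))),
    name = name,
    region = unlist(lapply(chains, `[[`, "region")),
    stringsAsFactors = FALSE)
  special <- list(anchors = c(1L, B))
  if (!is.null(params$sticky_pairs)) {
    members <- sort(unique(c(params$sticky_pairs$i, params$sticky_pairs$j)))
    special$sticky <- members
    special$sticky_ref <- members[unit[members] == 1L]
    special$sticky_partner <- members[unit[members] != 1L]
  }
  if (!is.null(params$charges))
    special$charged <- sort(unique(params$charges$index))
  topology <- cg_topology(residues, special_sets = special,
                          restrained_regions = c("BAR", "PDZ"))

  sys <- structure(list(topology = topology, coords = coords,
                        bonds = bonds, kind = kind, unit = unit,
                        bodies = bodies, segments = segments,
                        seg_npivot = seg_npivot, params = params),
                   class = "cg_system")
  .check_overlaps(sys)
  sys
}

#' @keywords internal
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
.cdist <- function(a, b) {
  ## cross-distance matrix between two coordinate matrices
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## nonbonded, different-unit pairs must respect the hard core
.check_overlaps <- function(sys) {
  hc <- 2 * sys$params$bead_radius
  if (hc <= 0) return(invisible(TRUE))
  n <- nrow(sys$coords)
  dm <- .cdist(sys$coords, sys$coords)
  excl <- diag(n) > 0
  excl[cbind(sys$bonds$i, sys$bonds$j)] <- TRUE
  excl[cbind(sys$bonds$j, sys$bonds$i)] <- TRUE
  same_unit <- outer(sys$unit, sys$unit, "==") & sys$unit > 0
  viol <- dm < hc & !excl & !same_unit
  if (any(viol))
    stop("hard-sphere overlap in built system (min nonbonded distance ",
         round(min(dm[!excl & !same_unit]), 3), " < ", hc, ")")
  invisible(TRUE)
}

#' Minimum nonbonded bead-bead distance of a frame
#'
#' Distance over pairs that are neither bonded nor members of the same rigid
#' unit — the pairs the hard-sphere term applies to.
#'
#' @param sys A `cg_system`.
#' @param coords Optional `n x 3` frame (default: the system's initial
#'   frame).
#' @return Numeric scalar (Angstrom).
#' @export
min_nonbonded_distance <- function(sys, coords = sys$coords) {
  n <- nrow(coords)
  dm <- .cdist(coords, coords)
  excl <- diag(n) > 0
  excl[cbind(sys$bonds$i, sys$bonds$j)] <- TRUE
  excl[cbind(sys$bonds$j, sys$bonds$i)] <- TRUE
  same_unit <- outer(sys$unit, sys$unit, "==") & sys$unit > 0
  min(dm[!excl & !same_unit])
}

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$coords), "beads;",
      length(x$bodies), "mobile bodies;",
      length(x$segments), "flexible segments;",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Run a Metropolis Monte Carlo trajectory of a synthetic system
#'
#' Samples the Boltzmann ensemble of the bead model with single-bead
#' displacements, pivot rotations of chain subtrees, and rigid-body moves of
#' mobile bodies. Identical `(system, seed)` give bit-identical
#' trajectories. The recorded trajectory's `snapshot_interval_steps` is the
#' recording interval, so lifetime statistics come out in MC-step units.
#'
#' @param system A [build_system()] result.
#' @param seed Integer seed (default: `params$seed`).
#' @param label Trajectory label.
#' @param n_steps,record_interval,n_equil Optional overrides of the
#'   parameter values.
#' @return A [cg_trajectory] with attribute `acceptance_rate`.
#' @export
run_mc <- function(system, seed = system$params$seed, label = NULL,
                   n_steps = NULL, record_interval = NULL, n_equil = NULL) {
  stopifnot(inherits(system, "cg_system"))
  p <- system$params
  n_steps <- as.integer(n_steps %||% p$n_steps)
  record_interval <- as.integer(record_interval %||% p$record_interval)
  n_equil <- as.integer(n_equil %||% p$n_equil)
  sp <- p$sticky_pairs
  has_sticky <- !is.null(sp) && nrow(sp) > 0
  ch <- numeric(nrow(system$coords))
  if (!is.null(p$charges)) ch[p$charges$index] <- p$charges$q
  bonds <- as.matrix(system$bonds)
  set.seed(as.integer(seed))
  res <- mc_run_cpp(
    coords0 = system$coords,
    kind = as.integer(system$kind), unit = as.integer(system$unit),
    bonds = matrix(as.integer(bonds), ncol = 2),
    bond_b0 = rep(p$bond_length, nrow(bonds)),
    bond_k = rep(p$bond_k, nrow(bonds)),
    sticky = if (has_sticky) matrix(as.integer(c(sp$i, sp$j)), ncol = 2)
             else matrix(integer(), ncol = 2),
    sticky_eps = if (has_sticky) sp$eps else numeric(),
    sticky_w = if (has_sticky) sp$width else numeric(),
    charge = ch, bjerrum = p$bjerrum, debye = p$debye,
    hard_core = 2 * p$bead_radius, confine_radius = -1,
    bodies = lapply(system$bodies, as.integer),
    segments = lapply(system$segments, as.integer),
    seg_npivot = as.integer(system$seg_npivot),
    n_steps = n_steps, record_interval = record_interval,
    n_equil = n_equil, temp = p$temperature_factor,
    step_disp = p$step_disp, step_trans = p$step_trans,
    step_rot = p$step_rot, step_pivot = p$step_pivot)
  tr <- cg_trajectory(res$frames, snapshot_interval_steps = record_interval,
                      label = label %||% sprintf("mc_seed%d", seed))
  attr(tr, "acceptance_rate") <- res$accepted / res$attempted
  tr
}

#' Simulate an ensemble of independent trajectories
#'
#' Per-trajectory seeds are derived deterministically from the root seed and
#' the trajectory index, so the ensemble is reproducible and members are
#' independent streams.
#'
#' @param params A [synthetic_params()] object.
#' @param n_traj Number of trajectories.
#' @param seed Root seed (default `params$seed`).
#' @param system Optional pre-built [build_system()] result.
#' @return A [cg_ensemble].
#' @export
simulate_ensemble <- function(params, n_traj = 4L, seed = params$seed,
                              system = NULL) {
  system <- system %||% build_system(params)
  trajs <- lapply(seq_len(n_traj), function(t) {
    run_mc(system, seed = .derive_seed(seed, t),
           label = sprintf("traj%02d", t))
  })
  cg_ensemble(trajs)
}

#' @keywords internal
.derive_seed <- function(root, index) {
  as.integer((as.numeric(root) + 7919 * as.numeric(index)) %% 2147483629)
}

#' Calibrate ground-truth contact probabilities of the planted sticky pairs
#'
#' Runs an independent, longer reference simulation (seed stream disjoint
#' from [run_mc()]'s by a fixed offset) and measures each sticky pair's
#' contact probability under the standard contact criterion, with a binomial
#' standard error. If `eps_grid` is given, the calibration is repeated with
#' every sticky well depth set to each grid value and a monotonicity check
#' is applied: estimated probability must be non-decreasing in the well
#' depth within noise (3 combined standard errors), otherwise a calibration
#' warning is raised.
#'
#' @param params A [synthetic_params()] object with at least one sticky
#'   pair.
#' @param eps_grid Optional numeric vector of well depths (kT).
#' @param n_steps_factor Reference run length multiplier (default 2).
#' @param criterion Contact criterion (default: [contact_criterion()]).
#' @return Data frame of class `cg_ground_truth`: columns `i`, `j`, `eps`,
#'   `probability_pct`, `se_pct`, `n_frames`.
#' @export
calibrate_ground_truth <- function(params, eps_grid = NULL,
                                   n_steps_factor = 2,
                                   criterion = contact_criterion()) {
  stopifnot(inherits(params, "cg_synthetic_params"))
  if (is.null(params$sticky_pairs) || !nrow(params$sticky_pairs))
    stop("params declare no sticky pairs to calibrate")
  one <- function(p) {
    sys <- build_system(p)
    tr <- run_mc(sys, seed = .derive_seed(p$seed, 104729L),
                 n_steps = as.integer(p$n_steps * n_steps_factor),
                 label = "calibration")
    pool <- pool_frames(tr)
    out <- p$sticky_pairs
    out$probability_pct <- vapply(seq_len(nrow(out)), function(r) {
      contact_probability(pool, c(out$i[r], out$j[r]),
                          topology = sys$topology, criterion = criterion)
    }, 1.0)
    out$se_pct <- 100 * sqrt(pmax(out$probability_pct / 100 *
                                    (1 - out$probability_pct / 100), 1e-12) /
                               n_frames(tr))
    out$n_frames <- n_frames(tr)
    out
  }
  if (is.null(eps_grid)) {
    res <- one(params)
  } else {
    res <- do.call(rbind, lapply(eps_grid, function(e) {
      p <- params
      p$sticky_pairs$eps <- e
      one(p)
    }))
    ## monotonicity across the grid, per pair
    for (r in seq_len(nrow(params$sticky_pairs))) {
      sub <- res[res$i == params$sticky_pairs$i[r] &
                   res$j == params$sticky_pairs$j[r], ]
      sub <- sub[order(sub$eps), ]
      if (nrow(sub) > 1) {
        dp <- diff(sub$probability_pct)
        tol <- 3 * sqrt(sub$se_pct[-1]^2 + sub$se_pct[-nrow(sub)]^2)
        if (any(dp < -tol))
          warning("calibration non-monotone in well depth for pair (",
                  sub$i[1], ",", sub$j[1], ") beyond noise tolerance")
      }
    }
  }
  class(res) <- c("cg_ground_truth", "data.frame")
  res
}

## ---- closed-form reference systems ---------------------------------------

#' Two-state square-well occupancy: closed form and Monte Carlo estimate
#'
#' A single particle moves in a hard spherical box of radius
#' `confine_radius` around a fixed partner, with a hard core of diameter
#' `core_diameter` and a square well of depth `eps` for separations up to
#' `well_width`. The Boltzmann well occupancy is
#' `exp(eps) * V_in / (exp(eps) * V_in + V_out)` with shell volumes
#' `V_in = (4/3) pi (w^3 - c^3)` and `V_out = (4/3) pi (R^3 - w^3)`.
#' `run_two_state_sphere()` estimates the same occupancy by Metropolis
#' sampling with the package's MC engine; the pair is a detailed-balance
#' smoke test.
#'
#' @param eps Well depth in kT.
#' @param well_width,confine_radius,core_diameter Geometry in Angstrom.
#' @return `two_state_occupancy()`: the exact occupancy probability.
#' @export
two_state_occupancy <- function(eps, well_width = 6, confine_radius = 12,
                                core_diameter = 4) {
  v_in <- well_width^3 - core_diameter^3
  v_out <- confine_radius^3 - well_width^3
  exp(eps) * v_in / (exp(eps) * v_in + v_out)
}

#' @rdname two_state_occupancy
#' @param n_steps,record_interval,n_equil,step_disp,seed Sampling controls.
#' @return `run_two_state_sphere()`: list with `occupancy` (estimated),
#'   `se`, `n_frames`, `expected` (closed form) and the per-frame
#'   separations `r`.
#' @export
run_two_state_sphere <- function(eps, well_width = 6, confine_radius = 12,
                                 core_diameter = 4, n_steps = 1000000L,
                                 record_interval = 200L, n_equil = 10000L,
                                 step_disp = 1.5, seed = 1L) {
  coords <- matrix(c(0, 0, 0,  (core_diameter + well_width) / 2, 0, 0),
                   2, 3, byrow = TRUE)
  set.seed(as.integer(seed))
  res <- mc_run_cpp(
    coords0 = coords, kind = c(0L, 1L), unit = c(1L, 0L),
    bonds = matrix(integer(), ncol = 2), bond_b0 = numeric(),
    bond_k = numeric(),
    sticky = matrix(c(1L, 2L), 1, 2), sticky_eps = eps,
    sticky_w = well_width,
    charge = c(0, 0), bjerrum = 0, debye = 1,
    hard_core = core_diameter, confine_radius = confine_radius,
    bodies = list(), segments = list(), seg_npivot = integer(),
    n_steps = as.integer(n_steps),
    record_interval = as.integer(record_interval),
    n_equil = as.integer(n_equil), temp = 1,
    step_disp = step_disp, step_trans = 0, step_rot = 0, step_pivot = 0)
  fr <- res$frames
  r <- sqrt((fr[, 2, 1] - fr[, 1, 1])^2 + (fr[, 2, 2] - fr[, 1, 2])^2 +
              (fr[, 2, 3] - fr[, 1, 3])^2)
  occ <- mean(r <= well_width)
  nfr <- length(r)
  list(occupancy = occ, se = sqrt(max(occ * (1 - occ), 1e-12) / nfr),
       n_frames = nfr,
       expected = two_state_occupancy(eps, well_width, confine_radius,
                                      core_diameter),
       r = r)
}

#' Sample the freely-jointed-chain end-to-end distance
#'
#' Direct reference sampler: sums `n_bonds` independent uniformly oriented
#' bond vectors of fixed length. Used as the theory oracle for the
#' flexible-chain statistics of the MC generator.
#'
#' @param n_bonds Number of bonds.
#' @param bond_length Bond length in Angstrom.
#' @param n Number of samples.
#' @return Numeric vector of `n` end-to-end distances.
#' @export
sample_fjc_end_to_end <- function(n_bonds, bond_length = 3.8, n = 10000L) {
  g <- matrix(stats::rnorm(3L * n_bonds * n), ncol = 3L)
  g <- g / sqrt(rowSums(g^2)) * bond_length
  grp <- rep(seq_len(n), each = n_bonds)
  x <- rowsum(g[, 1], grp); y <- rowsum(g[, 2], grp); z <- rowsum(g[, 3], grp)
  sqrt(x^2 + y^2 + z^2)[, 1]
}

## ---- presets -------------------------------------------------------------

#' Shipped synthetic-model presets
#'
#' Three parameter presets mirror the architectures analysed in tethered
#' multi-domain systems:
#' * `system1_like` — curved rod plus two mobile compact bodies on flexible
#'   linkers (BAR dimer with two tethered PDZ surrogates), with planted
#'   sticky contacts on the rod;
#' * `system2_like` — curved rod plus two flexible charged tails (BAR dimer
#'   with C-terminus surrogates), with a basic patch on the rod and acidic
#'   tail tips interacting by screened Coulomb;
#' * `two_state_toy` — minimal rod + short tail with one sticky pair, used
#'   for ground-truth calibration checks.
#'
#' @param name Preset name.
#' @return `load_preset()`: a [synthetic_params()] object.
#' @export
load_preset <- function(name = preset_names()) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "cgcontact", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sticky_pairs))
    cfg$sticky_pairs <- do.call(rbind.data.frame, cfg$sticky_pairs)
  if (!is.null(cfg$charges))
    cfg$charges <- do.call(rbind.data.frame, cfg$charges)
  do.call(synthetic_params, cfg)
}

#' @rdname load_preset
#' @export
preset_names <- function() c("system1_like", "system2_like", "two_state_toy")
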