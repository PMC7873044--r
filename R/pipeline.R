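## End-to-end pipeline: configuration -> simulate/load -> analyses -> TSV
## report bundle with provenance. Deterministic given the config seeds:
## reruns with the same config hash reproduce byte-identical outputs.

#' Run the full contact-dynamics analysis pipeline
#'
#' Drives the package end to end from a single configuration: obtain an
#' ensemble (synthetic preset/params, or trajectory files plus a topology
#' config), then run the enabled analyses and write TSV outputs plus a
#' JSON provenance record into the output directory. Every output carries
#' a leading comment naming the config hash that produced it; reruns with
#' identical config and seed give byte-identical files.
#'
#' Config keys (YAML file or list): `synthetic` (with `preset` or
#' `params`, and `n_traj`) or `topology` + `trajectories`; `analyses`
#' (subset of `"contacts"`, `"map"`, `"rmsd_rg"`, `"distances"`,
#' `"clusters"`); `contact` (`cutoff`, `min_sequence_separation`, `top_n`,
#' `region_a`, `region_b`); `map` (`group_a`, `group_b`, `log_floor`);
#' `clusters` (`mobile_region`, `ref_region`, `k`); `bins`; `seed`;
#' `output_dir`.
#'
#' @param config Path to a YAML config, or an equivalent list.
#' @param out_dir Output directory (overrides `config$output_dir`).
#' @param seed Root seed (overrides `config$seed`).
#' @return Invisibly, a list with the analysis objects and `files`, the
#'   written paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  analyses <- unlist(cfg$analyses)
  known <- c("contacts", "map", "rmsd_rg", "distances", "clusters")
  if (is.null(analyses) || !length(analyses))
    stop("configuration error: no analyses enabled")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analysis toggle(s): ",
                        paste(bad, collapse = ", "))
  out_dir <- out_dir %||% cfg$output_dir %||% "cgcontact_out"
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg$seed <- seed
  hash <- .config_hash(cfg)
  prov_line <- sprintf("cgcontact %s config_hash=%s",
                       as.character(packageVersion("cgcontact")), hash)
  files <- character()
  result <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    on.exit(message(sprintf("[cgcontact] stage %-10s %6.1f s", name,
                            proc.time()[["elapsed"]] - t0)))
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- input stage ----
  inp <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      params <- if (!is.null(cfg$synthetic$preset))
        load_preset(cfg$synthetic$preset)
      else do.call(synthetic_params, cfg$synthetic$params)
      params$seed <- seed
      sys <- build_system(params)
      ens <- simulate_ensemble(params, n_traj =
                                 as.integer(cfg$synthetic$n_traj %||% 2L),
                               seed = seed, system = sys)
      list(topology = sys$topology, ensemble = ens,
           reference = sys$coords)
    } else {
      if (is.null(cfg$topology) || is.null(cfg$trajectories))
        stop("need either 'synthetic' or 'topology' + 'trajectories'")
      top <- load_topology(cfg$topology)
      trajs <- lapply(cfg$trajectories, function(p) {
        if (!file.exists(p)) stop("trajectory file not found: ", p)
        if (grepl("\\.pdb$", p, ignore.case = TRUE))
          read_multimodel_pdb(p, top)
        else read_coordinate_table(p)
      })
      ens <- cg_ensemble(trajs)
      list(topology = top, ensemble = ens,
           reference = frame_coords(ens$trajectories[[1]], 1L))
    }
  })
  top <- inp$topology; ens <- inp$ensemble
  crit <- contact_criterion(
    cutoff = cfg$contact$cutoff %||% 8.0,
    min_sequence_separation = cfg$contact$min_sequence_separation %||% 5L)
  bins <- as.integer(cfg$bins %||% 50L)
  emit <- function(fname) {
    path <- file.path(out_dir, fname)
    files[[length(files) + 1L]] <<- path
    path
  }

  regions_present <- unique(top$residues$region)
  pick_region <- function(wanted, fallback)
    if (wanted %in% regions_present) wanted else fallback

  if ("contacts" %in% analyses) {
    result$top_pairs <- stage("contacts", {
      ra <- cfg$contact$region_a %||% pick_region("PDZ", "C_TERM")
      rb <- cfg$contact$region_b %||% "BAR"
      tp <- top_pairs(ens, top, ra, rb,
                      n = as.integer(cfg$contact$top_n %||% 10L),
                      criterion = crit)
      write_pair_table(tp, emit("top_pairs.tsv"), prov_line)
      tp
    })
  }
  if ("map" %in% analyses) {
    result$contact_map <- stage("map", {
      ga <- cfg$map$group_a %||% pick_region("PDZ", "C_TERM")
      gb <- cfg$map$group_b %||% "BAR"
      cm <- contact_map(ens, region_indices(top, ga),
                        region_indices(top, gb), top, crit)
      write_contact_map(cm, emit("contact_map.tsv"), prov_line,
                        log_floor = cfg$map$log_floor %||% 0.01)
      cm
    })
  }
  if ("rmsd_rg" %in% analyses) {
    result$rmsd <- stage("rmsd_rg", {
      rms <- unlist(lapply(ens$trajectories, rmsd_series, topology = top,
                           reference = inp$reference))
      rg <- unlist(lapply(ens$trajectories, rg_series))
      write_distribution(rms, emit("rmsd_series.tsv"), prov_line)
      write_distribution(make_distribution(rms, bins),
                         emit("rmsd_hist.tsv"), prov_line)
      write_distribution(rg, emit("rg_series.tsv"), prov_line)
      write_distribution(make_distribution(rg, bins),
                         emit("rg_hist.tsv"), prov_line)
      list(rmsd = rms, rg = rg)
    })
  }
  if ("distances" %in% analyses) {
    result$distances <- stage("distances", {
      pairs <- default_anchor_pairs(top)
      lapply(seq_len(nrow(pairs)), function(r) {
        v <- unlist(lapply(ens$trajectories, anchor_distance_series,
                           topology = top, anchors = pairs[r, ]))
        write_distribution(make_distribution(v, bins),
                           emit(sprintf("distance_%d_%d.tsv",
                                        pairs[r, 1], pairs[r, 2])),
                           prov_line)
        v
      })
    })
  }
  if ("clusters" %in% analyses) {
    result$clusters <- stage("clusters", {
      mreg <- cfg$clusters$mobile_region %||% pick_region("PDZ", "C_TERM")
      rreg <- cfg$clusters$ref_region %||% "BAR"
      pos <- mobile_positions(ens, top, mreg, rreg,
                              reference = inp$reference)
      k <- min(as.integer(cfg$clusters$k %||% 5L), nrow(pos))
      cl <- cluster_positions(pos, k = k, seed = seed)
      write_cluster_report(cl, emit("clusters.tsv"), prov_line)
      write_cluster_assignments(cl, emit("cluster_assignments.tsv"),
                                prov_line)
      cl
    })
  }

  prov <- list(
    package = "cgcontact",
    version = as.character(packageVersion("cgcontact")),
    config_hash = hash, seed = seed, config = cfg,
    n_trajectories = length(ens$trajectories),
    n_frames = n_frames(ens), n_residues = n_residues(ens),
    outputs = basename(unlist(files)))
  ppath <- file.path(out_dir, "provenance.json")
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), ppath)
  files[[length(files) + 1L]] <- ppath
  result$files <- unlist(files)
  result$topology <- top
  result$ensemble <- ens
  invisible(result)
}

## md5 of the canonical YAML serialization of the config
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
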