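## Residue-level topology: chains, regions, special residue sets, and the
## concatenated 1-based indexing convention used by every analysis function.
## Concatenation follows chain declaration order, so a residue index larger
## than the first protomer's length identifies the partner protomer (the
## convention used by single-running-index contact tables for dimers).

#' @keywords internal
.region_labels <- c("N_TERM", "PDZ", "LINKER", "LINKER_HELIX", "BAR",
                    "C_TERM", "OTHER")

#' @keywords internal
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Default residue hydropathy/charge classification table
#'
#' Maps each standard 3-letter amino-acid code to one of the classes
#' `HYDROPHOBIC`, `POSITIVE`, `NEGATIVE`, `POLAR`. The grouping is the
#' conventional coarse one used when labelling residue-pair interactions as
#' hydrophobic (both apolar), electrostatic (opposite charges) or polar:
#' Tyr, Cys, Gly and Pro are counted as hydrophobic, Lys/Arg/His as positive
#' and Asp/Glu as negative. Individual assignments can be overridden in the
#' topology config (`hydropathy_override`).
#'
#' @return Named character vector: names are 3-letter codes, values class
#'   labels.
#' @export
#' @examples
#' default_hydropathy()[["LYS"]]
default_hydropathy <- function() {
  tab <- c(
    ALA = "HYDROPHOBIC", VAL = "HYDROPHOBIC", LEU = "HYDROPHOBIC",
    ILE = "HYDROPHOBIC", MET = "HYDROPHOBIC", PHE = "HYDROPHOBIC",
    TRP = "HYDROPHOBIC", PRO = "HYDROPHOBIC", GLY = "HYDROPHOBIC",
    CYS = "HYDROPHOBIC", TYR = "HYDROPHOBIC",
    LYS = "POSITIVE", ARG = "POSITIVE", HIS = "POSITIVE",
    ASP = "NEGATIVE", GLU = "NEGATIVE",
    SER = "POLAR", THR = "POLAR", ASN = "POLAR", GLN = "POLAR"
  )
  tab[order(names(tab))]
}

#' Construct a residue topology
#'
#' Low-level constructor; most users will call [load_topology()] on a YAML
#' config instead.
#'
#' @param residues Data frame with columns `index` (concatenated 1-based),
#'   `chain_id`, `local_index` (1-based within chain), `name` (3-letter code
#'   or `"UNK"`), `region` (one of `N_TERM`, `PDZ`, `LINKER`,
#'   `LINKER_HELIX`, `BAR`, `C_TERM`, `OTHER`).
#' @param special_sets Named list of integer vectors of concatenated indices
#'   (e.g. the basic membrane-binding patch, distance anchors).
#' @param restrained_regions Character vector of region labels treated as
#'   rigid cores (used as default superposition selections).
#' @param hydropathy Named character vector mapping 3-letter codes to
#'   interaction classes; defaults to [default_hydropathy()].
#' @return Object of class `cg_topology`.
#' @export
cg_topology <- function(residues, special_sets = list(),
                        restrained_regions = character(),
                        hydropathy = default_hydropathy()) {
  stopifnot(is.data.frame(residues))
  req <- c("index", "chain_id", "local_index", "name", "region")
  if (!all(req %in% names(residues)))
    stop("residues must have columns: ", paste(req, collapse = ", "))
  residues <- residues[order(residues$index), req, drop = FALSE]
  rownames(residues) <- NULL
  n <- nrow(residues)
  if (n < 1L) stop("topology must contain at least one residue")
  if (!identical(as.integer(residues$index), seq_len(n)))
    stop("concatenated indices must be unique and contiguous from 1 to ", n)
  residues$index <- as.integer(residues$index)
  residues$local_index <- as.integer(residues$local_index)
  residues$chain_id <- as.character(residues$chain_id)
  residues$name <- as.character(residues$name)
  residues$region <- as.character(residues$region)
  bad <- !(residues$region %in% .region_labels)
  if (any(bad))
    stop("unknown region label(s): ",
         paste(unique(residues$region[bad]), collapse = ", "))
  bad <- !(residues$name %in% c(.aa3, "UNK"))
  if (any(bad))
    stop("invalid residue name(s): ",
         paste(unique(residues$name[bad]), collapse = ", "))
  ## local contiguity per chain, chains contiguous in declaration order
  for (ch in unique(residues$chain_id)) {
    li <- residues$local_index[residues$chain_id == ch]
    if (!identical(as.integer(li), seq_along(li)))
      stop("local indices of chain ", ch, " are not contiguous from 1")
  }
  special_sets <- lapply(special_sets, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) && (min(s) < 1L || max(s) > n))
      stop("special-set index outside any chain (valid range 1..", n, ")")
    s
  })
  hydropathy <- hydropathy[order(names(hydropathy))]
  structure(list(residues = residues,
                 special_sets = special_sets,
                 restrained_regions = as.character(restrained_regions),
                 hydropathy = hydropathy),
            class = "cg_topology")
}

#' Number of residues in a topology, trajectory or related object
#' @param x A `cg_topology`, `cg_trajectory`, `cg_ensemble` or coordinate
#'   matrix.
#' @return Integer residue count.
#' @export
n_residues <- function(x) UseMethod("n_residues")

#' @export
n_residues.cg_topology <- function(x) nrow(x$residues)

#' @export
print.cg_topology <- function(x, ...) {
  ch <- table(x$residues$chain_id)[unique(x$residues$chain_id)]
  cat("cg_topology: ", nrow(x$residues), " residues, ",
      length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]\n", sep = "")
  reg <- table(factor(x$residues$region, levels = .region_labels))
  reg <- reg[reg > 0]
  cat("  regions: ",
      paste(sprintf("%s(%d)", names(reg), as.integer(reg)), collapse = " "),
      "\n", sep = "")
  if (length(x$special_sets))
    cat("  special sets: ",
        paste(sprintf("%s(%d)", names(x$special_sets),
                      lengths(x$special_sets)), collapse = " "),
        "\n", sep = "")
  if (length(x$restrained_regions))
    cat("  restrained regions:",
        paste(x$restrained_regions, collapse = ", "), "\n")
  invisible(x)
}

## ---- config loading ------------------------------------------------------

.expand_chain_names <- function(chain) {
  if (!is.null(chain$residues)) {
    r <- chain$residues
    if (is.character(r) && length(r) == 1L && !(r %in% .aa3)) {
      ## 1-letter string
      one <- strsplit(r, "")[[1]]
      three <- suppressWarnings(bio3d::aa123(one))
      if (any(is.na(three) | !(three %in% .aa3)))
        three[is.na(three) | !(three %in% .aa3)] <- "UNK"
      three
    } else {
      as.character(unlist(r))
    }
  } else if (!is.null(chain$length)) {
    rep("GLY", as.integer(chain$length))
  } else {
    stop("chain '", chain$id, "' declares neither length nor residues")
  }
}

#' Load a residue topology from a YAML config
#'
#' The config declares chains (in concatenation order), inclusive local-index
#' region ranges, named special residue sets and optional hydropathy
#' overrides:
#'
#' ```yaml
#' chains:
#'   - {id: A, length: 360}            # or residues: "MFADL..." / [MET, PHE, ...]
#' regions:                            # applies to every chain unless chain: given
#'   - {label: PDZ, start: 22, end: 105}
#' special_sets:
#'   basic_patch: {local: [251, 252]}  # replicated on every chain
#'   anchors: {concatenated: [60, 390]}
#'   mixed: [{chain: A, local: 60}]
#' restrained_regions: [PDZ, BAR]
#' hydropathy_override: {GLY: POLAR}
#' ```
#'
#' Residues not covered by any region range get region `OTHER`, so region
#' labels always partition the residue list. Overlapping ranges on one chain
#' are a configuration error.
#'
#' @param config Path to a YAML file, or an already-parsed config list.
#' @return A [cg_topology] object.
#' @seealso [write_topology()] for the inverse operation.
#' @export
load_topology <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$chains) || !length(cfg$chains))
    stop("config must declare at least one chain")

  chains <- cfg$chains
  ids <- vapply(chains, function(ch) as.character(ch$id), "")
  if (anyDuplicated(ids)) stop("duplicate chain ids in config")
  names_by_chain <- lapply(chains, .expand_chain_names)
  lens <- lengths(names_by_chain)

  residues <- data.frame(
    index = seq_len(sum(lens)),
    chain_id = rep(ids, lens),
    local_index = unlist(lapply(lens, seq_len), use.names = FALSE),
    name = unlist(names_by_chain, use.names = FALSE),
    region = "OTHER",
    stringsAsFactors = FALSE
  )
  bad <- !(residues$name %in% c(.aa3, "UNK"))
  if (any(bad)) residues$name[bad] <- "UNK"

  ## regions: inclusive local ranges, per chain or for all chains
  for (rg in cfg$regions) {
    lab <- as.character(rg$label)
    if (!(lab %in% .region_labels))
      stop("unknown region label '", lab, "'")
    start <- as.integer(rg$start); end <- as.integer(rg$end)
    if (is.na(start) || is.na(end) || start > end)
      stop("bad region range for ", lab, ": ", rg$start, "-", rg$end)
    target <- if (is.null(rg$chain)) ids else as.character(rg$chain)
    for (ch in target) {
      if (!(ch %in% ids)) stop("region ", lab, " names unknown chain ", ch)
      len <- lens[[match(ch, ids)]]
      if (end > len)
        stop("region ", lab, " range ", start, "-", end,
             " exceeds chain ", ch, " length ", len)
      sel <- residues$chain_id == ch &
        residues$local_index >= start & residues$local_index <= end
      clash <- sel & residues$region != "OTHER"
      if (any(clash)) {
        prev <- unique(residues$region[clash])
        stop("overlapping region ranges on chain ", ch, ": ", lab, " ",
             start, "-", end, " overlaps ", paste(prev, collapse = "/"))
      }
      residues$region[sel] <- lab
    }
  }

  ## special sets: local (replicated per chain), concatenated, or explicit
  offsets <- setNames(cumsum(c(0L, lens[-length(lens)])), ids)
  special <- list()
  for (nm in names(cfg$special_sets)) {
    s <- cfg$special_sets[[nm]]
    idx <- if (is.list(s) && !is.null(s$local)) {
      loc <- as.integer(unlist(s$local))
      unlist(lapply(ids, function(ch) {
        len <- lens[[match(ch, ids)]]
        if (any(loc < 1L | loc > len))
          stop("special set '", nm, "' has index outside chain ", ch)
        offsets[[ch]] + loc
      }))
    } else if (is.list(s) && !is.null(s$concatenated)) {
      as.integer(unlist(s$concatenated))
    } else if (is.list(s) && is.null(names(s))) {
      vapply(s, function(e) {
        ch <- as.character(e$chain)
        if (!(ch %in% ids))
          stop("special set '", nm, "' names unknown chain ", ch)
        loc <- as.integer(e$local)
        len <- lens[[match(ch, ids)]]
        if (loc < 1L || loc > len)
          stop("special set '", nm, "' has index outside chain ", ch)
        offsets[[ch]] + loc
      }, integer(1))
    } else {
      as.integer(unlist(s))
    }
    if (length(idx) && (min(idx) < 1L || max(idx) > sum(lens)))
      stop("special set '", nm, "' has index outside any chain")
    special[[nm]] <- idx
  }

  hyd <- default_hydropathy()
  if (!is.null(cfg$hydropathy_override)) {
    ov <- cfg$hydropathy_override
    cls <- c("HYDROPHOBIC", "POSITIVE", "NEGATIVE", "POLAR")
    for (code in names(ov)) {
      if (!(ov[[code]] %in% cls))
        stop("hydropathy_override: unknown class '", ov[[code]], "'")
      hyd[[code]] <- as.character(ov[[code]])
    }
  }

  cg_topology(residues, special_sets = special,
              restrained_regions = as.character(
                unlist(cfg$restrained_regions)),
              hydropathy = hyd)
}

#' Serialize a topology back to a YAML config
#'
#' Writes a canonical config that [load_topology()] reads back to an
#' identical `cg_topology` (round-trip property).
#'
#' @param topology A `cg_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  res <- topology$residues
  ids <- unique(res$chain_id)
  chains <- lapply(ids, function(ch) {
    list(id = ch, residues = as.list(res$name[res$chain_id == ch]))
  })
  regions <- list()
  for (ch in ids) {
    sub <- res[res$chain_id == ch, ]
    r <- rle(sub$region)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "OTHER") next
      regions[[length(regions) + 1L]] <-
        list(label = r$values[k], start = starts[k], end = ends[k],
             chain = ch)
    }
  }
  special <- lapply(topology$special_sets,
                    function(s) list(concatenated = as.list(as.integer(s))))
  cfg <- list(chains = chains, regions = regions,
              special_sets = special,
              restrained_regions = as.list(topology$restrained_regions),
              hydropathy_override = as.list(topology$hydropathy))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## ---- index arithmetic ----------------------------------------------------

.check_index <- function(topology, index) {
  index <- as.integer(index)
  n <- nrow(topology$residues)
  if (any(is.na(index)) || any(index < 1L) || any(index > n))
    stop("residue index out of range 1..", n)
  index
}

#' Region label of a residue
#'
#' @param topology A `cg_topology`.
#' @param index Concatenated residue index (vectorized).
#' @return Character vector of region labels.
#' @export
#' @examples
#' top <- load_topology(list(chains = list(list(id = "A", length = 10)),
#'                           regions = list(list(label = "PDZ", start = 1, end = 10))))
#' region_of(top, 3)
region_of <- function(topology, index) {
  index <- .check_index(topology, index)
  topology$residues$region[index]
}

#' Split a concatenated residue index into (chain, local index)
#'
#' Inverse of the concatenation convention: for two protomers of length 360
#' the concatenated index 608 resolves to residue 248 of the second chain.
#'
#' @inheritParams region_of
#' @return Data frame with columns `index`, `chain_id`, `local_index`.
#' @seealso [concat_index()] for the inverse.
#' @export
split_dimer_index <- function(topology, index) {
  index <- .check_index(topology, index)
  data.frame(index = index,
             chain_id = topology$residues$chain_id[index],
             local_index = topology$residues$local_index[index],
             stringsAsFactors = FALSE)
}

#' Concatenated index of a (chain, local index) pair
#'
#' @param topology A `cg_topology`.
#' @param chain_id Chain label.
#' @param local_index 1-based index within the chain.
#' @return Integer concatenated index.
#' @export
concat_index <- function(topology, chain_id, local_index) {
  res <- topology$residues
  hit <- which(res$chain_id == as.character(chain_id) &
                 res$local_index == as.integer(local_index))
  if (length(hit) != 1L)
    stop("no residue ", local_index, " in chain ", chain_id)
  res$index[hit]
}

#' Residue name(s) by concatenated index
#' @inheritParams region_of
#' @return Character vector of 3-letter codes.
#' @export
residue_name <- function(topology, index) {
  index <- .check_index(topology, index)
  topology$residues$name[index]
}

#' Concatenated indices of residues belonging to given regions or chains
#'
#' @param topology A `cg_topology`.
#' @param region Character vector of region labels, or `NULL` for all.
#' @param chain Character vector of chain ids, or `NULL` for all.
#' @return Integer vector of concatenated indices.
#' @export
region_indices <- function(topology, region = NULL, chain = NULL) {
  res <- topology$residues
  keep <- rep(TRUE, nrow(res))
  if (!is.null(region)) keep <- keep & res$region %in% region
  if (!is.null(chain)) keep <- keep & res$chain_id %in% chain
  res$index[keep]
}

#' Hydropathy class of residues
#' @inheritParams region_of
#' @return Character vector with values `HYDROPHOBIC`, `POSITIVE`,
#'   `NEGATIVE`, `POLAR`, or `UNKNOWN` for `UNK` residues.
#' @export
residue_class <- function(topology, index) {
  nm <- residue_name(topology, index)
  cls <- unname(topology$hydropathy[nm])
  cls[is.na(cls)] <- "UNKNOWN"
  cls
}
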