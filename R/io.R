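#' Write peptide observations to CSV
#'
#' One row per centroid-mass observation with peptide metadata joined on,
#' in the dialect read back by [read_peptide_observations()]: columns
#' \code{peptide_id, sequence, start, end, charge, state, time_min,
#' replicate, centroid_mass, control}. Rows are sorted (peptide, state,
#' control, time, replicate) so output is deterministic.
#'
#' @param peptides peptide pool data.frame.
#' @param observations observation data.frame from [simulate_uptake()].
#' @param path output CSV path.
#' @export
write_peptide_observations <- function(peptides, observations, path) {
  idx <- match(observations$peptide_id, peptides$peptide_id)
  if (anyNA(idx)) stop("observations reference unknown peptide_id(s)")
  tab <- data.frame(
    peptide_id = observations$peptide_id,
    sequence = peptides$sequence[idx],
    start = peptides$start[idx],
    end = peptides$end[idx],
    charge = peptides$charge[idx],
    state = observations$state,
    time_min = observations$time_min,
    replicate = observations$replicate,
    centroid_mass = observations$centroid_mass,
    control = observations$control,
    stringsAsFactors = FALSE
  )
  ord <- order(tab$peptide_id, tab$state, tab$control, tab$time_min,
               tab$replicate)
  utils::write.csv(tab[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peptide observations (or source-data percent-deuteration tables)
#'
#' Reads the observation CSV dialect written by
#' [write_peptide_observations()] and validates it: 1-based inclusive
#' coordinates consistent with the stated sequence, known control tokens,
#' and no duplicate (peptide, state, time, replicate) deuterated rows.
#'
#' A table carrying a \code{dp} column instead of \code{centroid_mass}
#' (the layout of deposited percent-deuteration source tables) is ingested
#' in source-data mode: DP values are taken as given and returned as an
#' uptake table; controls are skipped.
#'
#' @param path CSV path.
#' @return list with \code{peptides} (unique peptide table),
#'   \code{observations} (mass observations, or NULL in source-data mode)
#'   and \code{uptake} (uptake records in source-data mode, else NULL).
#' @export
read_peptide_observations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("peptide_id", "sequence", "start", "end", "charge", "state",
                 "time_min")
  missing_cols <- setdiff(base_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(tab$end < tab$start)
  if (length(bad) > 0) {
    stop("end < start at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(tab$start < 1)
  if (length(bad) > 0) {
    stop("start < 1 at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(nchar(tab$sequence) != tab$end - tab$start + 1L)
  if (length(bad) > 0) {
    stop("sequence length does not match coordinates at row(s): ",
         paste(bad, collapse = ", "))
  }
  peptides <- unique(tab[, c("peptide_id", "sequence", "start", "end",
                             "charge")])
  if (anyDuplicated(peptides$peptide_id)) {
    stop("peptide_id with inconsistent metadata across rows")
  }
  rownames(peptides) <- NULL

  if ("dp" %in% names(tab) && !("centroid_mass" %in% names(tab))) {
    # source-data mode: percent deuteration given directly
    uptake <- data.frame(
      peptide_id = tab$peptide_id, state = tab$state,
      time_min = tab$time_min, dp_mean = tab$dp,
      dp_sd = if ("dp_sd" %in% names(tab)) tab$dp_sd else NA_real_,
      n_replicates = if ("n_replicates" %in% names(tab)) tab$n_replicates
                     else 1L,
      stringsAsFactors = FALSE)
    return(list(peptides = peptides, observations = NULL, uptake = uptake))
  }

  need <- c("replicate", "centroid_mass", "control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  known <- c("none", "nondeuterated", "fully_deuterated")
  bad <- which(!tab$control %in% known)
  if (length(bad) > 0) {
    stop("unknown control token at row(s): ", paste(bad, collapse = ", "))
  }
  deut <- tab[tab$control == "none", ]
  key <- paste(deut$peptide_id, deut$state, deut$time_min, deut$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (peptide, state, time, replicate) observation(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  observations <- tab[, c("peptide_id", "state", "time_min", "replicate",
                          "centroid_mass", "control")]
  rownames(observations) <- NULL
  list(peptides = peptides, observations = observations, uptake = NULL)
}

#' Write/read uptake, difference and residue tables
#'
#' Plain deterministic CSV writers (stable row order) and their readers for
#' the pipeline's tabular outputs.
#'
#' @param x table to write.
#' @param path CSV path.
#' @name table-io
#' @export
write_uptake_table <- function(x, path) {
  ord <- order(x$peptide_id, x$state, x$time_min)
  utils::write.csv(x[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
read_uptake_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname table-io
#' @export
write_difference_table <- function(x, path) {
  ord <- order(x$peptide_id, x$time_min)
  utils::write.csv(x[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
write_residue_table <- function(x, path) {
  ord <- order(x$state, x$residue)
  utils::write.csv(x[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read simulation ground truth as JSON
#'
#' @param truth an \code{hdx_truth}.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(sequence = truth$sequence,
              exchangeable = truth$exchangeable,
              k_int = as.list(truth$k_int),
              protection = lapply(truth$states, function(s)
                unname(truth$protection[s, ])),
              states = truth$states,
              back_exchange = truth$back_exchange,
              seed = truth$seed)
  names(obj$protection) <- truth$states
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prot <- do.call(rbind, obj$protection)
  rownames(prot) <- obj$states
  structure(list(sequence = obj$sequence,
                 exchangeable = as.integer(obj$exchangeable),
                 k_int = stats::setNames(unlist(obj$k_int),
                                         names(obj$k_int)),
                 protection = prot,
                 back_exchange = obj$back_exchange,
                 states = obj$states,
                 seed = as.integer(obj$seed)),
            class = "hdx_truth")
}

#' Binned deuteration matrix underlying the uptake heat map
#'
#' Rows are (state, time point) pairs ordered by state then time; columns
#' are peptides ordered along the sequence (by start, then end). Entries
#' are percent-deuteration bins: 10 equal bins over 0-100\% (values are
#' clipped to that range first; bin 1 = 0-10\%, bin 10 = 90-100\%).
#'
#' @param uptake uptake table from [build_uptake_table()].
#' @param peptides peptide pool data.frame.
#' @param bins number of equal bins over 0-100\%.
#' @return integer matrix of bin indices (NA where a peptide/time is
#'   unmeasured), with a \code{dp} attribute holding the unbinned matrix.
#' @export
uptake_heatmap_matrix <- function(uptake, peptides, bins = 10L) {
  if (nrow(uptake) == 0L) stop("empty uptake table")
  pep_order <- peptides$peptide_id[order(peptides$start, peptides$end)]
  pep_order <- pep_order[pep_order %in% uptake$peptide_id]
  states <- sort(unique(uptake$state))
  rows <- do.call(rbind, lapply(states, function(s) {
    data.frame(state = s,
               time_min = sort(unique(uptake$time_min[uptake$state == s])))
  }))
  m <- matrix(NA_real_, nrow = nrow(rows), ncol = length(pep_order),
              dimnames = list(paste(rows$state, rows$time_min, sep = "@"),
                              pep_order))
  for (i in seq_len(nrow(uptake))) {
    r <- which(rows$state == uptake$state[i] &
               rows$time_min == uptake$time_min[i])
    cidx <- match(uptake$peptide_id[i], pep_order)
    m[r, cidx] <- uptake$dp_mean[i]
  }
  clipped <- pmin(pmax(m, 0), 100)
  binned <- pmin(floor(clipped / (100 / bins)) + 1L, bins)
  mode(binned) <- "integer"
  attr(binned, "dp") <- m
  attr(binned, "row_info") <- rows
  binned
}

#' Render an uptake heat map
#'
#' Horizontal bars per time point per state, peptides laid along the
#' sequence axis, colored by 10-bin percent deuteration with an embedded
#' color key. The plotted quantity is exactly the matrix from
#' [uptake_heatmap_matrix()].
#'
#' @param uptake uptake table.
#' @param peptides peptide pool data.frame.
#' @param path output PNG path.
#' @param bins color bins over 0-100\% deuteration.
#' @return invisibly, the binned matrix.
#' @export
render_heatmap <- function(uptake, peptides, path, bins = 10L) {
  m <- uptake_heatmap_matrix(uptake, peptides, bins)
  pal <- grDevices::hcl.colors(bins, "YlOrRd", rev = TRUE)
  grDevices::png(path, width = 900, height = 60 + 22 * nrow(m), res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 8, 2, 6))  # device-local; discarded with dev.off
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(1, bins), axes = FALSE,
                  xlab = "peptides (sequence order)", ylab = "")
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.6)
  graphics::axis(1)
  # embedded color key
  usr <- graphics::par("usr")
  kx <- usr[2] + 0.01 * (usr[2] - usr[1])
  graphics::legend("topright", inset = c(-0.12, 0),
                   legend = sprintf("%d-%d%%", (seq_len(bins) - 1) *
                                      (100 %/% bins),
                                    seq_len(bins) * (100 %/% bins)),
                   fill = pal, cex = 0.5, xpd = TRUE, title = "DP")
  invisible(m)
}

#' Color a structure by per-residue deuteration difference
#'
#' Writes a per-residue scalar into the B-factor column of a PDB file:
#' values are clipped to [-threshold, +threshold] and mapped affinely to
#' [0, 100] (so 0 difference maps to 50, +threshold to 100). Residues
#' without data get the sentinel -1. A viewer command script reproducing a
#' magenta-white-green ramp over the mapped range is written alongside
#' (\code{<pdb_out>.pml}).
#'
#' @param values numeric vector of per-residue values, named by residue
#'   index in the profile's numbering (e.g. \code{delta_d} from
#'   [classify_difference()]).
#' @param pdb_in input PDB path.
#' @param pdb_out output PDB path.
#' @param chain chain identifier to color.
#' @param offset declared numbering offset: PDB residue number = profile
#'   residue + offset.
#' @param threshold saturation threshold in percent deuteration.
#' @return invisibly, a list with \code{n_matched}, \code{pdb_out},
#'   \code{script}.
#' @export
write_structure_coloring <- function(values, pdb_in, pdb_out, chain,
                                     offset = 0L, threshold = 25) {
  pdb <- bio3d::read.pdb(pdb_in)
  sel <- pdb$atom$chain == chain
  if (!any(sel)) stop("chain not found: ", chain)
  prof_res <- as.integer(names(values))
  pdb_res <- pdb$atom$resno
  target <- prof_res + as.integer(offset)
  b <- rep(-1, nrow(pdb$atom))
  clipped <- pmax(pmin(values, threshold), -threshold)
  mapped <- (clipped + threshold) / (2 * threshold) * 100
  idx <- match(pdb_res, target)
  hit <- sel & !is.na(idx) & !is.na(mapped[idx])
  if (!any(hit)) stop("no residues matched between profile and PDB chain")
  b[hit] <- mapped[idx[hit]]
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = pdb_out)
  script <- paste0(pdb_out, ".pml")
  writeLines(c(
    sprintf("load %s, colored", pdb_out),
    "hide everything, colored",
    "show cartoon, colored",
    "color grey80, colored and b < 0",
    # magenta (protected) - white - green (deprotected) over b in [0, 100]
    "spectrum b, magenta_white_green, colored and b > -0.5, 0, 100"
  ), script)
  invisible(list(n_matched = length(unique(pdb_res[hit])),
                 pdb_out = pdb_out, script = script))
}

#' Read a project configuration
#'
#' YAML (or JSON) configuration naming the subjects (sequences/lengths),
#' state labels, time grids, control conventions, thresholds and the seed.
#' Minimal validation: thresholds positive, states non-empty.
#'
#' @param path YAML or JSON file.
#' @return named list of class \code{hdx_config}.
#' @export
read_project_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(cfg$threshold) && cfg$threshold <= 0) {
    stop("config threshold must be positive")
  }
  structure(cfg, class = c("hdx_config", "list"))
}
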