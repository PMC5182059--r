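#' Neutral centroid mass of an isotopic envelope
#'
#' Intensity-weighted mean m/z of the envelope, deconvoluted to a neutral
#' mass: \eqn{(\sum m/z \cdot I / \sum I) z - z \cdot 1.00728}.
#'
#' @param envelope two-column matrix or data.frame of (mz, intensity).
#' @param charge positive integer charge state.
#' @return neutral mass in Da.
#' @examples
#' centroid_mass(cbind(c(500, 501, 502), c(1, 2, 1)), charge = 2)
#' @export
centroid_mass <- function(envelope, charge) {
  envelope <- as.matrix(envelope)
  if (nrow(envelope) < 1L) stop("empty envelope")
  if (any(envelope[, 2] < 0)) stop("negative intensities")
  total <- sum(envelope[, 2])
  if (total <= 0) stop("all-zero intensities")
  if (charge < 1 || charge != round(charge)) stop("charge must be a positive integer")
  wmz <- sum(envelope[, 1] * envelope[, 2]) / total
  wmz * charge - charge * .MASS_PROTON
}

#' Percent deuteration of a peptide
#'
#' Normalizes a deuterated centroid mass between the non-deuterated (0%)
#' and fully deuterated (100%) controls:
#' \eqn{DP = (m_t - m_0) / (m_{100} - m_0) \cdot 100}. Because back
#' exchange scales \eqn{m_t - m_0} and \eqn{m_{100} - m_0} by the same
#' factor, DP is back-exchange-corrected by construction. Values outside
#' [0, 100] (measurement noise) are returned as-is.
#'
#' @param mt deuterated centroid mass, Da.
#' @param m0 non-deuterated control mass, Da.
#' @param m100 fully deuterated control mass, Da.
#' @return percent deuteration.
#' @export
percent_deuteration <- function(mt, m0, m100) {
  if (any(m100 == m0)) {
    stop("m100 equals m0: zero exchange window, peptide unusable")
  }
  (mt - m0) / (m100 - m0) * 100
}

#' Build a per-peptide percent-deuteration table
#'
#' Converts centroid-mass observations into percent-deuteration time
#' courses. Per (peptide, state), the ND and FD control replicates are
#' averaged to give that peptide's 0% and 100% anchors; DP is then computed
#' per deuterated replicate and summarized as mean and sample SD (n-1)
#' across replicates. Peptides lacking either control in a state are
#' excluded and listed in the \code{exclusions} attribute. A singleton
#' replicate yields \code{dp_sd = NA}, never 0.
#'
#' @param observations data.frame as produced by [simulate_uptake()] or
#'   [read_peptide_observations()]: columns \code{peptide_id},
#'   \code{state}, \code{time_min}, \code{replicate}, \code{centroid_mass},
#'   \code{control}.
#' @return data.frame of records \code{peptide_id}, \code{state},
#'   \code{time_min}, \code{dp_mean}, \code{dp_sd}, \code{n_replicates},
#'   with attribute \code{exclusions} (data.frame of excluded
#'   peptide/state pairs and reasons).
#' @export
build_uptake_table <- function(observations) {
  obs <- observations
  needed <- c("peptide_id", "state", "time_min", "replicate",
              "centroid_mass", "control")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  keys <- unique(obs[, c("peptide_id", "state")])
  out <- vector("list", nrow(keys))
  excl <- list()
  for (i in seq_len(nrow(keys))) {
    pid <- keys$peptide_id[i]; st <- keys$state[i]
    sub <- obs[obs$peptide_id == pid & obs$state == st, ]
    nd <- sub$centroid_mass[sub$control == "nondeuterated"]
    fd <- sub$centroid_mass[sub$control == "fully_deuterated"]
    if (length(nd) == 0L || length(fd) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        peptide_id = pid, state = st,
        reason = if (length(nd) == 0L) "missing nondeuterated control"
                 else "missing fully_deuterated control",
        stringsAsFactors = FALSE)
      next
    }
    m0 <- mean(nd); m100 <- mean(fd)
    if (m100 == m0) {
      excl[[length(excl) + 1L]] <- data.frame(
        peptide_id = pid, state = st, reason = "zero exchange window",
        stringsAsFactors = FALSE)
      next
    }
    deut <- sub[sub$control == "none", ]
    times <- sort(unique(deut$time_min))
    recs <- lapply(times, function(t) {
      dp <- percent_deuteration(
        deut$centroid_mass[deut$time_min == t], m0, m100)
      data.frame(peptide_id = pid, state = st, time_min = t,
                 dp_mean = mean(dp),
                 dp_sd = if (length(dp) > 1L) stats::sd(dp) else NA_real_,
                 n_replicates = length(dp), stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(peptide_id = character(), state = character(),
                      time_min = numeric(), dp_mean = numeric(),
                      dp_sd = numeric(), n_replicates = integer())
  }
  rownames(res) <- NULL
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(peptide_id = character(), state = character(),
               reason = character())
  res
}

#' Per-peptide difference in deuteration between two states
#'
#' Computes \code{delta_dp = dp_mean(B) - dp_mean(A)} on the shared
#' (peptide, time) keys, with \code{combined_sd = sqrt(sd_A^2 + sd_B^2)}.
#' Keys present in only one state are dropped and recorded in the
#' \code{dropped} attribute; no interpolation is attempted.
#'
#' @param uptake_a,uptake_b uptake tables from [build_uptake_table()],
#'   each restricted to (or filtered internally to) a single state.
#' @param state_a,state_b optional state labels selecting rows when a
#'   table holds several states.
#' @return data.frame \code{peptide_id}, \code{time_min}, \code{delta_dp},
#'   \code{combined_sd}.
#' @export
state_difference <- function(uptake_a, uptake_b, state_a = NULL,
                             state_b = NULL) {
  if (!is.null(state_a)) uptake_a <- uptake_a[uptake_a$state == state_a, ]
  if (!is.null(state_b)) uptake_b <- uptake_b[uptake_b$state == state_b, ]
  ka <- paste(uptake_a$peptide_id, uptake_a$time_min, sep = "\r")
  kb <- paste(uptake_b$peptide_id, uptake_b$time_min, sep = "\r")
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("no shared (peptide, time) keys between states")
  ia <- match(shared, ka); ib <- match(shared, kb)
  res <- data.frame(
    peptide_id = uptake_a$peptide_id[ia],
    time_min = uptake_a$time_min[ia],
    delta_dp = uptake_b$dp_mean[ib] - uptake_a$dp_mean[ia],
    combined_sd = sqrt(uptake_a$dp_sd[ia]^2 + uptake_b$dp_sd[ib]^2),
    stringsAsFactors = FALSE
  )
  dropped <- c(setdiff(ka, kb), setdiff(kb, ka))
  attr(res, "dropped") <- dropped
  rownames(res) <- NULL
  res
}
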