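#' Capped length weight of a peptide
#'
#' Weight used when projecting peptide deuteration onto residues: the
#' lesser of 1/L (L = peptide length in residues) and 0.2, so short
#' peptides (L <= 5) all carry the same maximal weight while long peptides
#' are down-weighted in proportion to the positional ambiguity of their
#' signal.
#'
#' @param length peptide length in residues (>= 1).
#' @param cap maximum weight (default 0.2).
#' @return numeric weight(s).
#' @export
peptide_weight <- function(length, cap = 0.2) {
  if (any(length < 1)) stop("peptide length must be positive")
  pmin(1 / length, cap)
}

#' Project peptide deuteration onto residues
#'
#' Assigns each residue \eqn{i} a percent-deuteration value
#' \deqn{D_i = \sum_j w_j \langle DP_j \rangle / \sum_j w_j}
#' over the peptides \eqn{j} whose residue range contains \eqn{i}, where
#' \eqn{\langle DP_j \rangle} is the mean of \code{dp_mean} over the first
#' \code{time_window} time points present for that state and
#' \eqn{w_j = \min(1/L_j, 0.2)} (see [peptide_weight()]). Early time
#' points carry the structural contrast before exchange saturates, hence
#' the default window of the two earliest times. Residues covered by no
#' peptide get \code{d_i = NA}.
#'
#' @param uptake uptake table from [build_uptake_table()].
#' @param peptides peptide pool data.frame (needs \code{peptide_id},
#'   \code{start}, \code{end}).
#' @param protein_length number of residues of the parent protein.
#' @param time_window number of earliest time points averaged per state.
#' @param state optional state label to restrict \code{uptake}.
#' @return data.frame \code{residue}, \code{state}, \code{d_i},
#'   \code{n_peptides}, plus a \code{contributors} attribute (list of
#'   contributing peptide_ids per residue, one list per state).
#' @export
residue_deuteration <- function(uptake, peptides, protein_length,
                                time_window = 2L, state = NULL) {
  if (time_window < 1L) stop("empty time window")
  if (!is.null(state)) uptake <- uptake[uptake$state %in% state, ]
  unknown <- setdiff(unique(uptake$peptide_id), peptides$peptide_id)
  if (length(unknown) > 0) {
    stop("uptake references unknown peptide_id(s): ",
         paste(unknown, collapse = ", "))
  }
  states <- unique(uptake$state)
  out <- vector("list", length(states))
  contribs <- list()
  for (si in seq_along(states)) {
    st <- states[si]
    u <- uptake[uptake$state == st, ]
    times <- sort(unique(u$time_min))
    win <- times[seq_len(min(time_window, length(times)))]
    u <- u[u$time_min %in% win, ]
    # window-mean DP per peptide
    wm <- tapply(u$dp_mean, u$peptide_id, mean)
    idx <- match(names(wm), peptides$peptide_id)
    pstart <- peptides$start[idx]; pend <- peptides$end[idx]
    w <- peptide_weight(pend - pstart + 1)
    d_i <- rep(NA_real_, protein_length)
    n_pep <- integer(protein_length)
    clist <- vector("list", protein_length)
    num <- numeric(protein_length); den <- numeric(protein_length)
    for (j in seq_along(wm)) {
      rng <- pstart[j]:pend[j]
      num[rng] <- num[rng] + w[j] * wm[j]
      den[rng] <- den[rng] + w[j]
      n_pep[rng] <- n_pep[rng] + 1L
      for (r in rng) clist[[r]] <- c(clist[[r]], names(wm)[j])
    }
    covered <- den > 0
    d_i[covered] <- num[covered] / den[covered]
    out[[si]] <- data.frame(residue = seq_len(protein_length), state = st,
                            d_i = d_i, n_peptides = n_pep,
                            stringsAsFactors = FALSE)
    contribs[[st]] <- clist
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "contributors") <- contribs
  res
}

#' Classify per-residue deuteration differences
#'
#' From residue profiles of two states, computes
#' \code{delta_d = d_i(B) - d_i(A)} and classifies each residue:
#' \emph{deprotected} if the increase is at least \code{threshold} percent,
#' \emph{protected} if the decrease is at least \code{threshold}, else
#' \emph{intermediate}. A color scalar \code{delta_d / threshold} clipped
#' to [-1, 1] supports continuous two-hue ramps saturating at the
#' thresholds. Residues missing in either state stay missing, never zero.
#'
#' @param profile_a,profile_b residue profiles from
#'   [residue_deuteration()] on the same residue index set (state A is the
#'   reference).
#' @param threshold classification threshold in percent deuteration
#'   (default 25).
#' @return data.frame \code{residue}, \code{delta_d}, \code{class} in
#'   \{deprotected, protected, intermediate, NA\}, \code{scalar}.
#' @export
classify_difference <- function(profile_a, profile_b, threshold = 25) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (nrow(profile_a) != nrow(profile_b) ||
      any(profile_a$residue != profile_b$residue)) {
    stop("profiles are not on the same residue index set")
  }
  delta <- profile_b$d_i - profile_a$d_i
  cls <- rep(NA_character_, length(delta))
  ok <- !is.na(delta)
  cls[ok & delta >= threshold] <- "deprotected"
  cls[ok & delta <= -threshold] <- "protected"
  cls[ok & abs(delta) < threshold] <- "intermediate"
  scalar <- pmax(pmin(delta / threshold, 1), -1)
  data.frame(residue = profile_a$residue, delta_d = delta, class = cls,
             scalar = scalar, stringsAsFactors = FALSE)
}

#' Peptide coverage statistics
#'
#' Per-residue peptide overlap counts, percent of residues covered by at
#' least one peptide, the mean overlap and the maximum overlap. The mean
#' is denominated, by default, over covered residues only
#' (\code{denominator = "covered"}); \code{"all"} divides by the full
#' protein length instead.
#'
#' @param peptides peptide pool data.frame with \code{start}, \code{end}.
#' @param protein_length number of residues (>= 1).
#' @param denominator \code{"covered"} or \code{"all"}.
#' @return list with \code{percent_covered}, \code{mean_overlap},
#'   \code{max_overlap} and the per-residue \code{counts} vector.
#' @export
coverage_statistics <- function(peptides, protein_length,
                                denominator = c("covered", "all")) {
  denominator <- match.arg(denominator)
  if (protein_length < 1) stop("'protein_length' must be >= 1")
  if (nrow(peptides) > 0 && any(peptides$end > protein_length)) {
    stop("peptide exceeds protein_length")
  }
  counts <- integer(protein_length)
  for (j in seq_len(nrow(peptides))) {
    rng <- peptides$start[j]:peptides$end[j]
    counts[rng] <- counts[rng] + 1L
  }
  covered <- counts > 0
  mean_overlap <- if (!any(covered)) 0 else {
    if (denominator == "covered") mean(counts[covered])
    else sum(counts) / protein_length
  }
  list(percent_covered = 100 * sum(covered) / protein_length,
       mean_overlap = mean_overlap,
       max_overlap = if (length(counts)) max(counts) else 0L,
       counts = counts)
}
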