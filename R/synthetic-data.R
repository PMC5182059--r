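#' Synthetic HDX-MS ground truth
#'
#' Constructs a ground-truth object for simulating peptide-level deuterium
#' uptake: per-residue intrinsic exchange rates, per-state protection
#' factors and a global back-exchange fraction. Exchange follows the
#' Linderstrom-Lang EX2 picture, in which the observed rate at residue
#' \eqn{i} in state \eqn{s} is \eqn{k_{int}(i)/P(s,i)} with protection
#' factor \eqn{P \ge 1}.
#'
#' The exchangeable-amide set excludes residue 1 of the protein (no
#' backbone amide) and all prolines (no amide hydrogen). Intrinsic rates
#' and protection factors are drawn log-uniformly, which spans orders of
#' magnitude the way real amide chemistry does without modelling
#' sequence-dependent rate rules.
#'
#' @param sequence one-letter amino-acid string, length >= 4.
#' @param n_states number of conformational states to simulate.
#' @param pf_range length-2 numeric, protection-factor range (lo >= 1).
#' @param k_int_range length-2 numeric, intrinsic-rate range in 1/min.
#' @param back_exchange fraction of incorporated deuterium lost before
#'   measurement, in [0, 1).
#' @param seed integer seed; identical seeds give identical truth objects.
#' @return an object of class \code{hdx_truth}: list with \code{sequence},
#'   \code{exchangeable} (residue indices), \code{k_int} (named by residue,
#'   1/min), \code{protection} (n_states x n_residues matrix, NA at
#'   non-exchangeable positions), \code{back_exchange}, \code{states},
#'   \code{seed}.
#' @seealso [simulate_uptake()], [make_peptide_pool()]
#' @export
make_truth <- function(sequence, n_states = 2, pf_range = c(1, 1000),
                       k_int_range = c(0.05, 10), back_exchange = 0.3,
                       seed = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 4L) {
    stop("'sequence' must be a single amino-acid string of length >= 4")
  }
  if (length(pf_range) != 2L || pf_range[1] < 1 || pf_range[2] < pf_range[1]) {
    stop("'pf_range' must be (lo, hi) with lo >= 1")
  }
  if (length(k_int_range) != 2L || k_int_range[1] <= 0 ||
      k_int_range[2] < k_int_range[1]) {
    stop("'k_int_range' must be positive (lo, hi)")
  }
  if (back_exchange < 0 || back_exchange >= 1) {
    stop("'back_exchange' must be in [0, 1)")
  }
  n <- nchar(sequence)
  aa <- strsplit(toupper(sequence), "")[[1]]
  exch <- setdiff(which(aa != "P"), 1L)
  if (length(exch) == 0L) stop("no exchangeable amides in sequence")

  runif_log <- function(m, lo, hi) {
    if (lo == hi) rep(lo, m) else exp(stats::runif(m, log(lo), log(hi)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k_int <- stats::setNames(
    runif_log(length(exch), k_int_range[1], k_int_range[2]), exch
  )
  protection <- matrix(NA_real_, nrow = n_states, ncol = n,
                       dimnames = list(paste0("state", seq_len(n_states)),
                                       NULL))
  for (s in seq_len(n_states)) {
    protection[s, exch] <- runif_log(length(exch), pf_range[1], pf_range[2])
  }
  structure(
    list(sequence = toupper(sequence), exchangeable = exch, k_int = k_int,
         protection = protection, back_exchange = back_exchange,
         states = rownames(protection), seed = as.integer(seed)),
    class = "hdx_truth"
  )
}

#' @export
print.hdx_truth <- function(x, ...) {
  cat("Synthetic HDX ground truth\n")
  cat(sprintf("  protein length : %d residues\n", nchar(x$sequence)))
  cat(sprintf("  exchangeable   : %d amides\n", length(x$exchangeable)))
  cat(sprintf("  states         : %s\n", paste(x$states, collapse = ", ")))
  cat(sprintf("  k_int range    : %.3g - %.3g /min\n",
              min(x$k_int), max(x$k_int)))
  cat(sprintf("  back exchange  : %.2f\n", x$back_exchange))
  invisible(x)
}

# save/restore the global RNG state so simulators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Exchangeable amides scored for a peptide
#'
#' Residue indices within \code{[start, end]} that carry a scored amide:
#' excludes residue 1 of the protein, prolines, and the first
#' \code{nterm_skip} residues of the peptide (whose amide deuterium is lost
#' to rapid back exchange).
#'
#' @param sequence parent-protein sequence.
#' @param start,end 1-based inclusive residue coordinates.
#' @param nterm_skip number of peptide N-terminal residues carrying no
#'   scored amide (1 or 2).
#' @return integer vector of residue indices.
#' @export
peptide_exchangeable <- function(sequence, start, end, nterm_skip = 1L) {
  stopifnot(nterm_skip %in% c(1L, 2L))
  aa <- strsplit(toupper(sequence), "")[[1]]
  idx <- seq.int(start, end)
  idx <- idx[idx > 1L & aa[idx] != "P"]
  setdiff(idx, seq.int(start, length.out = nterm_skip))
}

#' Generate a random pepsin-like peptide pool
#'
#' Emulates a pepsin digest in two passes: a tiling pass lays randomly
#' sized fragments end to end so that every accessible residue is covered
#' (real digests recover essentially the whole sequence), then random
#' additional fragments are drawn until the realized mean
#' peptide-per-residue overlap (over covered residues) reaches
#' \code{target_redundancy}. Fragment lengths are uniform on
#' \code{length_range}; typical digests show redundancies of 1.5-3
#' peptides per residue.
#'
#' @param sequence parent-protein amino-acid string.
#' @param length_range length-2 integer, min/max peptide length (min >= 4).
#' @param target_redundancy target mean number of peptides overlapping a
#'   covered residue; the realized mean is within 20\% of this.
#' @param seed integer seed.
#' @param exclude optional list of \code{c(start, end)} residue ranges that
#'   no peptide may overlap (emulates regions unrecovered from digestion).
#' @param nterm_skip passed to [peptide_exchangeable()].
#' @return a data.frame of peptides: \code{peptide_id}, \code{sequence},
#'   \code{start}, \code{end}, \code{charge}, \code{n_exchangeable}.
#' @export
make_peptide_pool <- function(sequence, length_range = c(4L, 20L),
                              target_redundancy = 2.5, seed = 1L,
                              exclude = NULL, nterm_skip = 1L) {
  n <- nchar(sequence)
  lmin <- as.integer(length_range[1]); lmax <- as.integer(length_range[2])
  if (lmin < 4L || lmax < lmin) stop("'length_range' must satisfy max >= min >= 4")
  if (lmax > n) stop("maximum peptide length exceeds protein length")
  if (target_redundancy < 1) {
    stop("target_redundancy below 1 is unattainable: any peptide covers its own residues once")
  }
  blocked <- rep(FALSE, n)
  if (!is.null(exclude)) {
    for (rg in exclude) blocked[seq.int(rg[1], rg[2])] <- TRUE
  }
  # accessible segments long enough to host a fragment
  rl <- rle(!blocked)
  seg_end <- cumsum(rl$lengths)
  seg_start <- seg_end - rl$lengths + 1L
  keep <- rl$values & rl$lengths >= lmin
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  if (length(seg_start) == 0L) stop("no accessible segment can host a peptide")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rand_len <- function() sample.int(lmax - lmin + 1L, 1L) + lmin - 1L
  starts <- integer(0); ends <- integer(0)
  overlap <- numeric(n)
  add <- function(s, e) {
    starts <<- c(starts, s); ends <<- c(ends, e)
    overlap[s:e] <<- overlap[s:e] + 1
  }
  # tiling pass: cover every accessible segment end to end
  for (g in seq_along(seg_start)) {
    pos <- seg_start[g]
    while (pos <= seg_end[g]) {
      len <- min(rand_len(), seg_end[g] - pos + 1L)
      if (len < lmin) {  # short tail: back the fragment up to fit
        add(seg_end[g] - lmin + 1L, seg_end[g])
        break
      }
      add(pos, pos + len - 1L)
      pos <- pos + len
    }
  }
  mean_cov <- function() {
    cov <- overlap[overlap > 0]
    if (length(cov) == 0) 0 else mean(cov)
  }
  # fill pass: random extra fragments up to the redundancy target
  seg_w <- seg_end - seg_start + 1L
  max_iter <- 200L * ceiling(target_redundancy * n / lmin)
  it <- 0L
  while (mean_cov() < target_redundancy && it < max_iter) {
    it <- it + 1L
    g <- sample.int(length(seg_start), 1L, prob = seg_w)
    len <- min(rand_len(), seg_w[g])
    s <- seg_start[g] + sample.int(seg_w[g] - len + 1L, 1L) - 1L
    e <- s + len - 1L
    if (any(starts == s & ends == e)) next  # reject exact duplicates
    add(s, e)
  }
  if (length(starts) == 0L || abs(mean_cov() - target_redundancy) >
      0.2 * target_redundancy) {
    stop(sprintf(
      "could not realize target redundancy %.2f (achieved %.2f)",
      target_redundancy, mean_cov()))
  }
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  aa <- toupper(sequence)
  data.frame(
    peptide_id = sprintf("pep%03d", seq_along(starts)),
    sequence = substring(aa, starts, ends),
    start = starts, end = ends,
    charge = 1L + (ends - starts) %/% 8L,
    n_exchangeable = vapply(
      seq_along(starts),
      function(i) length(peptide_exchangeable(aa, starts[i], ends[i],
                                              nterm_skip)),
      integer(1)),
    stringsAsFactors = FALSE
  )
}

#' True deuteron uptake of a peptide
#'
#' Noise-free expected number of deuterons incorporated by peptide
#' residues, before back exchange: per exchangeable amide \eqn{i},
#' \eqn{1 - \exp(-k_{int}(i) t / P(s,i))}.
#'
#' @param truth an \code{hdx_truth}.
#' @param start,end peptide coordinates (1-based inclusive).
#' @param state state label present in \code{truth$states}.
#' @param time exposure time(s) in minutes.
#' @param nterm_skip see [peptide_exchangeable()].
#' @return numeric vector of deuteron counts, one per time.
#' @export
true_uptake <- function(truth, start, end, state, time, nterm_skip = 1L) {
  if (end > nchar(truth$sequence)) {
    stop("peptide references residues outside the truth sequence")
  }
  idx <- peptide_exchangeable(truth$sequence, start, end, nterm_skip)
  if (length(idx) == 0L) return(rep(0, length(time)))
  k <- truth$k_int[as.character(idx)]
  p <- truth$protection[state, idx]
  vapply(time, function(t) sum(1 - exp(-k * t / p)), numeric(1))
}

#' Simulate centroid-mass observations for a peptide pool
#'
#' Forward-simulates deuterium uptake under the EX2 first-order model and
#' reports per-replicate centroid masses with Gaussian measurement noise,
#' plus non-deuterated (ND) and fully-deuterated (FD) control observations
#' per peptide and state. A global back-exchange fraction \code{b} scales
#' the retained deuterium: reported mass gain is
#' \eqn{(1-b) D \cdot \Delta m_D} with \eqn{\Delta m_D = 1.00628} Da; the FD
#' control carries \eqn{(1-b) n_{exch} \Delta m_D}, so the downstream
#' percent-deuteration normalization divides back exchange out.
#'
#' @param truth an \code{hdx_truth}.
#' @param peptides data.frame from [make_peptide_pool()].
#' @param times exposure times in minutes (default mirrors a typical
#'   30 s - 5 hr series).
#' @param replicates technical replicates per observation.
#' @param noise_sd Gaussian mass noise, Da.
#' @param seed integer seed.
#' @param nterm_skip see [peptide_exchangeable()].
#' @return data.frame of observations: \code{peptide_id}, \code{state},
#'   \code{time_min} (NA for controls), \code{replicate},
#'   \code{centroid_mass}, \code{control} in
#'   \{none, nondeuterated, fully_deuterated\}.
#' @export
simulate_uptake <- function(truth, peptides,
                            times = c(0.5, 1, 3, 5, 10, 30, 60, 300),
                            replicates = 3L, noise_sd = 0.05, seed = 1L,
                            nterm_skip = 1L) {
  stopifnot(inherits(truth, "hdx_truth"))
  if (any(times <= 0)) stop("'times' must be positive")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  if (any(peptides$end > nchar(truth$sequence))) {
    stop("peptide references residues outside the truth sequence")
  }
  b <- truth$back_exchange
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rows <- vector("list", nrow(peptides) * length(truth$states))
  ri <- 0L
  for (j in seq_len(nrow(peptides))) {
    pep <- peptides[j, ]
    m0 <- peptide_mass(pep$sequence)
    n_exch <- length(peptide_exchangeable(truth$sequence, pep$start,
                                          pep$end, nterm_skip))
    for (state in truth$states) {
      d_true <- true_uptake(truth, pep$start, pep$end, state, times,
                            nterm_skip)
      tgrid <- rep(times, each = replicates)
      dvec <- rep(d_true, each = replicates)
      mass <- m0 + (1 - b) * dvec * .MASS_D_INCREMENT +
        stats::rnorm(length(dvec), 0, noise_sd)
      nd <- m0 + stats::rnorm(replicates, 0, noise_sd)
      fd <- m0 + (1 - b) * n_exch * .MASS_D_INCREMENT +
        stats::rnorm(replicates, 0, noise_sd)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        peptide_id = pep$peptide_id,
        state = state,
        time_min = c(tgrid, rep(NA_real_, 2L * replicates)),
        replicate = c(rep(seq_len(replicates), times = length(times)),
                      seq_len(replicates), seq_len(replicates)),
        centroid_mass = c(mass, nd, fd),
        control = c(rep("none", length(mass)),
                    rep("nondeuterated", replicates),
                    rep("fully_deuterated", replicates)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Simulate a single-exponential fluorescence rise
#'
#' Forward model for a GTPgammaS-uptake assay read out by tryptophan
#' fluorescence: \eqn{F(t) = baseline + \Delta F_{max}(1 - e^{-kt})} plus
#' Gaussian noise.
#'
#' @param k first-order rate constant, 1/min (> 0).
#' @param dFmax fluorescence amplitude, AU (> 0).
#' @param baseline baseline fluorescence, AU.
#' @param times sampling times in minutes.
#' @param noise_sd Gaussian noise, AU.
#' @param seed integer seed.
#' @return data.frame with \code{time_min}, \code{intensity}.
#' @export
simulate_fluorescence <- function(k, dFmax, baseline = 0,
                                  times = seq(0, 10, by = 1 / 6),
                                  noise_sd = 0, seed = 1L) {
  if (k <= 0) stop("'k' must be positive")
  if (dFmax <= 0) stop("'dFmax' must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- baseline + dFmax * (1 - exp(-k * times)) +
    stats::rnorm(length(times), 0, noise_sd)
  data.frame(time_min = times, intensity = f)
}

#' Simulate a two-state DSF melting trace
#'
#' The F350/F330 fluorescence ratio follows a two-state sigmoid
#' \eqn{low + (high - low) / (1 + e^{-(T - T_m)/w})} plus Gaussian noise on
#' the ratio. F330 and F350 channels consistent with the ratio are emitted
#' (F330 held at a constant reference intensity).
#'
#' @param tm melting temperature, degrees C; must lie inside \code{temps}.
#' @param width transition width \eqn{w}, degrees C (> 0).
#' @param baselines length-2 numeric, (low, high) ratio plateaus.
#' @param temps temperature grid, degrees C.
#' @param noise_sd Gaussian noise on the ratio.
#' @param seed integer seed.
#' @param f330_level constant F330 channel intensity, AU.
#' @return data.frame with \code{temperature_C}, \code{f330}, \code{f350}.
#' @export
simulate_dsf <- function(tm, width = 1.5, baselines = c(0.8, 1.1),
                         temps = seq(20, 75, by = 0.12), noise_sd = 0,
                         seed = 1L, f330_level = 1000) {
  if (width <= 0) stop("'width' must be positive")
  if (tm < min(temps) || tm > max(temps)) {
    stop("'tm' must lie inside the sampled temperature range")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ratio <- baselines[1] + (baselines[2] - baselines[1]) /
    (1 + exp(-(temps - tm) / width)) +
    stats::rnorm(length(temps), 0, noise_sd)
  data.frame(temperature_C = temps, f330 = rep(f330_level, length(temps)),
             f350 = f330_level * ratio)
}
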