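test_that("ground truth is deterministic in the seed and respects ranges", {
  s <- random_protein(40, 3)
  t1 <- make_truth(s, n_states = 2, pf_range = c(1, 500),
                   k_int_range = c(0.1, 10), seed = 42)
  t2 <- make_truth(s, n_states = 2, pf_range = c(1, 500),
                   k_int_range = c(0.1, 10), seed = 42)
  expect_identical(t1, t2)
  t3 <- make_truth(s, n_states = 2, pf_range = c(1, 500),
                   k_int_range = c(0.1, 10), seed = 43)
  expect_false(identical(t1$k_int, t3$k_int))

  expect_true(all(t1$protection[, t1$exchangeable] >= 1))
  expect_true(all(t1$k_int >= 0.1 & t1$k_int <= 10))

  # degenerate range: free exchange everywhere
  tf <- make_truth(s, pf_range = c(1, 1), seed = 1)
  expect_true(all(tf$protection[, tf$exchangeable] == 1))

  expect_error(make_truth("MG", seed = 1), "length >= 4")
  expect_error(make_truth(s, pf_range = c(0.5, 2)), "lo >= 1")
})

test_that("the exchangeable-amide set excludes residue 1 and prolines", {
  tr <- make_truth("MGAPL", pf_range = c(1, 1), seed = 1)
  expect_identical(tr$exchangeable, c(2L, 3L, 5L))
  expect_length(tr$k_int, 3L)

  # per-peptide scoring also drops the peptide's own N-terminal residue
  expect_identical(peptide_exchangeable("MGAPL", 1, 5), c(2L, 3L, 5L))
  expect_identical(peptide_exchangeable("MGAPL", 2, 5), c(3L, 5L))
  expect_identical(peptide_exchangeable("MGAPL", 2, 5, nterm_skip = 2L), 5L)
})

test_that("peptide pools hit the redundancy target and obey constraints", {
  seq20 <- random_protein(20, 5)
  one <- make_peptide_pool(seq20, length_range = c(20, 20),
                           target_redundancy = 1, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(1L, 20L))

  seq354 <- random_protein(354, 6)
  pool <- make_peptide_pool(seq354, target_redundancy = 2.5, seed = 7)
  cs <- coverage_statistics(pool, 354)
  expect_gte(cs$mean_overlap, 2.0)
  expect_lte(cs$mean_overlap, 3.0)
  expect_true(all(pool$end - pool$start + 1 >= 4))
  expect_true(all(pool$start >= 1 & pool$end <= 354))
  expect_true(all(nchar(pool$sequence) == pool$end - pool$start + 1))
  expect_true(all(pool$n_exchangeable <= pool$end - pool$start))

  expect_error(make_peptide_pool(seq20, target_redundancy = 0.5),
               "unattainable")
})

test_that("excluded regions stay uncovered", {
  s <- random_protein(100, 8)
  pool <- make_peptide_pool(s, target_redundancy = 2, seed = 3,
                            exclude = list(c(40, 55)))
  cs <- coverage_statistics(pool, 100)
  expect_true(all(cs$counts[40:55] == 0))
})

test_that("simulated uptake follows the EX2 forward model", {
  # 3 exchangeable amides with k/P = ln 2 per min: D(1 min) = 1.5 deuterons
  tr <- uniform_truth("GAAA", k_eff = log(2))
  obs <- simulate_uptake(tr, data.frame(peptide_id = "p1", sequence = "GAAA",
                                        start = 1L, end = 4L, charge = 1L,
                                        n_exchangeable = 3L),
                         times = 1, replicates = 1, noise_sd = 0, seed = 1)
  m0 <- peptide_mass("GAAA")
  mt <- obs$centroid_mass[obs$control == "none"]
  expect_equal(mt - m0, 1.5 * 1.00628, tolerance = 1e-9)

  # vanishing exposure: centroid mass returns to m0
  obs0 <- simulate_uptake(tr, data.frame(peptide_id = "p1",
                                         sequence = "GAAA", start = 1L,
                                         end = 4L, charge = 1L,
                                         n_exchangeable = 3L),
                          times = 1e-12, replicates = 1, noise_sd = 0,
                          seed = 1)
  expect_equal(obs0$centroid_mass[obs0$control == "none"], m0,
               tolerance = 1e-9)

  # infinite protection: no deuterium at any finite time
  tri <- uniform_truth("GAAA", k_eff = 1)
  tri$protection[1, ] <- Inf
  expect_equal(true_uptake(tri, 1, 4, "state1", c(1, 100, 1e6)),
               c(0, 0, 0))
})

test_that("FD controls carry (1-b) * n_exchangeable deuterons at noise 0", {
  for (b in c(0, 0.3)) {
    tr <- uniform_truth("GAAAKLM", k_eff = 1, b = b)
    pool <- data.frame(peptide_id = "p1", sequence = "GAAAKLM", start = 1L,
                       end = 7L, charge = 1L, n_exchangeable = 6L)
    obs <- simulate_uptake(tr, pool, times = 1, replicates = 1,
                           noise_sd = 0, seed = 1)
    fd <- obs$centroid_mass[obs$control == "fully_deuterated"]
    m0 <- obs$centroid_mass[obs$control == "nondeuterated"]
    expect_equal((fd - m0) / 1.00628, (1 - b) * 6, tolerance = 1e-9)
  }
})

test_that("noise-free uptake is monotone in time and in protection", {
  tr <- make_truth(random_protein(50, 9), n_states = 2,
                   pf_range = c(1, 100), k_int_range = c(0.05, 10),
                   seed = 21)
  pool <- make_peptide_pool(tr$sequence, target_redundancy = 2, seed = 21)
  times <- c(0.5, 1, 3, 5, 10, 30, 60, 300)
  for (j in seq_len(nrow(pool))) {
    for (st in tr$states) {
      d <- true_uptake(tr, pool$start[j], pool$end[j], st, times)
      expect_true(all(diff(d) >= -1e-12))
    }
  }
  # doubling all protection factors never increases uptake
  tr2 <- tr
  tr2$protection <- tr$protection * 2
  for (j in seq_len(nrow(pool))) {
    d1 <- true_uptake(tr, pool$start[j], pool$end[j], "state1", times)
    d2 <- true_uptake(tr2, pool$start[j], pool$end[j], "state1", times)
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("simulators are byte-identical under identical seeds", {
  tr <- make_truth(random_protein(30, 2), seed = 5)
  pool <- make_peptide_pool(tr$sequence, target_redundancy = 1.5, seed = 5)
  o1 <- simulate_uptake(tr, pool, times = c(1, 10), noise_sd = 0.05,
                        seed = 9)
  o2 <- simulate_uptake(tr, pool, times = c(1, 10), noise_sd = 0.05,
                        seed = 9)
  expect_identical(o1, o2)
  expect_identical(simulate_fluorescence(1, 10, noise_sd = 1, seed = 4),
                   simulate_fluorescence(1, 10, noise_sd = 1, seed = 4))
  expect_identical(simulate_dsf(47, noise_sd = 0.01, seed = 4),
                   simulate_dsf(47, noise_sd = 0.01, seed = 4))
})

test_that("fluorescence forward model has the right anchors", {
  tr <- simulate_fluorescence(k = 1.92, dFmax = 100, baseline = 5,
                              times = c(0, log(2) / 1.92, 50), noise_sd = 0)
  expect_equal(tr$intensity[1], 5)
  expect_equal(tr$intensity[2] - 5, 50, tolerance = 1e-9)  # one half-life
  expect_equal(tr$intensity[3] - 5, 100, tolerance = 1e-6) # plateau
  expect_error(simulate_fluorescence(k = -1, dFmax = 1), "positive")
})

test_that("DSF forward model is a two-state sigmoid in the ratio", {
  temps <- seq(20, 74, by = 0.5)  # grid contains 47 exactly
  tr <- simulate_dsf(tm = 47, width = 1.5, baselines = c(0.8, 1.1),
                     temps = temps, noise_sd = 0)
  ratio <- tr$f350 / tr$f330
  expect_equal(ratio[temps == 47], mean(c(0.8, 1.1)), tolerance = 1e-12)
  expect_true(all(diff(ratio) > 0))
  # numeric derivative of the noise-free curve peaks at tm (one grid step)
  d <- diff(ratio) / diff(temps)
  expect_lt(abs(temps[which.max(d)] + 0.25 - 47), 0.5 + 1e-9)
  expect_error(simulate_dsf(tm = 10, temps = temps), "inside")
})
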