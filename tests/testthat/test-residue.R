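test_that("peptide weights are capped at 0.2", {
  expect_equal(peptide_weight(4), 0.2)   # 1/4 exceeds the cap
  expect_equal(peptide_weight(5), 0.2)   # boundary: 1/5 equals the cap
  expect_equal(peptide_weight(10), 0.1)
  expect_equal(peptide_weight(c(2, 20)), c(0.2, 0.05))
  expect_error(peptide_weight(0), "positive")
})

make_uptake <- function(...) {
  # rows: list(peptide_id, time, dp)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(peptide_id = r[[1]], state = "s1",
               time_min = as.numeric(r[[2]]), dp_mean = as.numeric(r[[3]]),
               dp_sd = 0, n_replicates = 3, stringsAsFactors = FALSE)
  }))
}

test_that("residue projection is the capped length-weighted window mean", {
  # two contributors of lengths 5 and 10 with window-mean DPs 40 and 60:
  # D_i = (0.2*40 + 0.1*60) / 0.3
  peps <- data.frame(peptide_id = c("a", "b"),
                     start = c(6L, 3L), end = c(10L, 12L),
                     stringsAsFactors = FALSE)
  u <- make_uptake(list("a", 0.5, 35), list("a", 1, 45),
                   list("b", 0.5, 55), list("b", 1, 65),
                   list("a", 300, 99), list("b", 300, 99))  # outside window
  prof <- residue_deuteration(u, peps, protein_length = 15)
  shared <- 6:10
  expect_equal(prof$d_i[shared],
               rep((0.2 * 40 + 0.1 * 60) / 0.3, length(shared)),
               tolerance = 1e-12)
  expect_equal(prof$d_i[shared][1], 46.667, tolerance = 1e-4)
  expect_true(all(prof$n_peptides[shared] == 2))

  # residues covered by a single peptide inherit its window mean
  expect_equal(prof$d_i[3:5], rep(60, 3))
  # uncovered residues are missing, with zero contributors
  expect_true(all(is.na(prof$d_i[13:15])))
  expect_true(all(prof$n_peptides[13:15] == 0))

  expect_error(residue_deuteration(u, peps[1, ], 15), "unknown peptide_id")
  expect_error(residue_deuteration(u, peps, 15, time_window = 0),
               "empty time window")
})

test_that("D_i is a convex combination of contributor window means", {
  tr <- make_truth(random_protein(80, 6), n_states = 1, pf_range = c(1, 100),
                   seed = 31)
  pool <- make_peptide_pool(tr$sequence, target_redundancy = 3, seed = 31)
  obs <- simulate_uptake(tr, pool, times = c(0.5, 1, 5), replicates = 3,
                         noise_sd = 0.05, seed = 31)
  u <- build_uptake_table(obs)
  prof <- residue_deuteration(u, pool, protein_length = 80)
  contribs <- attr(prof, "contributors")[["state1"]]
  # recompute window means per peptide
  win <- sort(unique(u$time_min))[1:2]
  uw <- u[u$time_min %in% win, ]
  wm <- tapply(uw$dp_mean, uw$peptide_id, mean)
  for (i in seq_len(80)) {
    ids <- contribs[[i]]
    if (is.null(ids)) next
    expect_gte(prof$d_i[i], min(wm[ids]) - 1e-9)
    expect_lte(prof$d_i[i], max(wm[ids]) + 1e-9)
  }
})

test_that("in the cap regime projection reduces to the unweighted mean", {
  peps <- data.frame(peptide_id = c("a", "b", "c"),
                     start = c(1L, 3L, 4L), end = c(5L, 6L, 8L),
                     stringsAsFactors = FALSE)
  u <- make_uptake(list("a", 1, 20), list("b", 1, 50), list("c", 1, 80))
  prof <- residue_deuteration(u, peps, protein_length = 8, time_window = 1)
  expect_equal(prof$d_i[4], mean(c(20, 50, 80)), tolerance = 1e-12)
  expect_equal(prof$d_i[3], mean(c(20, 50)), tolerance = 1e-12)
})

test_that("difference classification applies the 25-point threshold", {
  prof_a <- data.frame(residue = 1:6, state = "A",
                       d_i = c(10, 10, 10, 10, NA, 10), n_peptides = 1)
  prof_b <- data.frame(residue = 1:6, state = "B",
                       d_i = c(40, 10, -20, 22.5, 50, NA), n_peptides = 1)
  cls <- classify_difference(prof_a, prof_b)
  expect_equal(cls$class,
               c("deprotected", "intermediate", "protected", "intermediate",
                 NA, NA))
  expect_equal(cls$scalar, c(1, 0, -1, 0.5, NA, NA))
  # -12.5 maps to -0.5 on the linear colour scale
  cls2 <- classify_difference(prof_a[1, , drop = FALSE],
                              transform(prof_a[1, , drop = FALSE],
                                        d_i = d_i - 12.5))
  expect_equal(cls2$scalar, -0.5)
  expect_error(classify_difference(prof_a, prof_b[1:3, ]), "residue index")
})

test_that("coverage statistics count interval overlaps per residue", {
  peps <- data.frame(start = c(1L, 6L), end = c(10L, 15L))
  cs <- coverage_statistics(peps, 20)
  expect_equal(cs$percent_covered, 75)
  expect_equal(cs$mean_overlap, (5 * 1 + 5 * 2 + 5 * 1) / 15)
  expect_equal(cs$max_overlap, 2L)
  # denominating over the whole protein instead
  cs_all <- coverage_statistics(peps, 20, denominator = "all")
  expect_equal(cs_all$mean_overlap, 20 / 20)

  cs0 <- coverage_statistics(peps[0, ], 20)
  expect_equal(cs0$percent_covered, 0)
  expect_equal(cs0$mean_overlap, 0)
  expect_equal(cs0$max_overlap, 0L)

  cs1 <- coverage_statistics(data.frame(start = 1L, end = 20L), 20)
  expect_equal(unlist(cs1[1:3], use.names = FALSE), c(100, 1, 1))

  expect_error(coverage_statistics(data.frame(start = 1L, end = 25L), 20),
               "exceeds")
})

test_that("deprotection classification recovers a protected block", {
  tr <- block_truth(n = 120, block = 55:69, factor = 10, seed = 11)
  pool <- make_peptide_pool(tr$sequence, target_redundancy = 3, seed = 11)
  obs <- simulate_uptake(tr, pool, replicates = 3, noise_sd = 0.05,
                         seed = 11)
  u <- build_uptake_table(obs)
  prof1 <- residue_deuteration(u, pool, 120, state = "state1")
  prof2 <- residue_deuteration(u, pool, 120, state = "state2")
  cls <- classify_difference(prof1, prof2)  # state2 - state1: deprotection

  dep <- which(!is.na(cls$class) & cls$class == "deprotected")
  covered <- which(prof1$n_peptides > 0)
  # interior of the block: residues covered by at least one peptide fully
  # inside the block
  inside <- vapply(55:69, function(r) {
    any(pool$start >= 55 & pool$end <= 69 & pool$start <= r & pool$end >= r)
  }, logical(1))
  interior <- (55:69)[inside]
  expect_true(all(interior %in% dep))
  # nothing 10+ positions outside the block is classified
  far <- setdiff(seq_len(120), 45:79)
  expect_length(intersect(dep, far), 0)
})
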