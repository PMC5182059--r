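# shared in-code fixtures for the suite

# a controlled truth object: every exchangeable amide gets the same
# effective rate k_eff (k_int = k_eff, protection = 1 in every state)
uniform_truth <- function(sequence, k_eff, n_states = 1L, b = 0,
                          seed = 1L) {
  tr <- make_truth(sequence, n_states = n_states, pf_range = c(1, 1),
                   k_int_range = c(k_eff, k_eff), back_exchange = b,
                   seed = seed)
  tr
}

# two-state truth with one contiguous block extra-protected in state1
block_truth <- function(n = 120L, block = 55:69, factor = 10,
                        k_int_range = c(1, 5), pf_range = c(1, 2),
                        b = 0.3, seed = 11L) {
  tr <- make_truth(random_protein(n, seed), n_states = 2,
                   pf_range = pf_range, k_int_range = k_int_range,
                   back_exchange = b, seed = seed)
  # states identical except the block, protected `factor`-fold in state1
  tr$protection["state2", ] <- tr$protection["state1", ]
  idx <- intersect(block, tr$exchangeable)
  tr$protection["state1", idx] <- tr$protection["state1", idx] * factor
  tr
}

# expected noise-free DP (percent) for a peptide under a truth object
truth_dp <- function(truth, start, end, state, time) {
  idx <- peptide_exchangeable(truth$sequence, start, end)
  d <- true_uptake(truth, start, end, state, time)
  100 * d / length(idx)
}

# minimal text PDB with one CA atom per residue, chain A, resno 1..n
toy_pdb <- function(path, n = 10L, chain = "A") {
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, chain, i, i * 1.0, 0, 0, 1.00, 0.00)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
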