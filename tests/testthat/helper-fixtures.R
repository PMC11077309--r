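# Shared fixtures built in code.

# A minimal dihedral-record table: `n_per` records per codon for one
# family/stratum, angles from a common wrapped-normal basin unless a
# per-codon psi shift is supplied.
make_stratum_records <- function(codons, n_per, aa, ss = "SHEET",
                                 mean_phi = -120, mean_psi = 135,
                                 sd = 20, psi_shift = NULL, seed = 1) {
  set.seed(seed)
  n_per <- rep(n_per, length.out = length(codons))
  do.call(rbind, lapply(seq_along(codons), function(i) {
    shift <- if (is.null(psi_shift)) 0 else psi_shift[i]
    data.frame(
      gene_id = "g1",
      position = 0L,
      aa = aa,
      codon = codons[i],
      ss = ss,
      phi_deg = wrap_degrees(rnorm(n_per[i], mean_phi, sd)),
      psi_deg = wrap_degrees(rnorm(n_per[i], mean_psi, sd) + shift))
  }))
}

# Random valid coding sequences for round-trip tests.
random_codon_seqs <- function(n_genes, code, min_len = 5, max_len = 60,
                              seed = 1) {
  set.seed(seed)
  sense <- names(code$family_of)
  out <- lapply(seq_len(n_genes), function(i) {
    sample(sense, sample(min_len:max_len, 1), replace = TRUE)
  })
  names(out) <- paste0("gene_", seq_len(n_genes))
  coding_sequences(out, code)
}

# Analytic bivariate wrapped-normal density (independent axes) on a grid,
# degrees; replicas +/- 2 turns.
wrapped_normal_grid <- function(centers, mean_phi, mean_psi, sd_phi, sd_psi) {
  wn <- function(x, m, s) {
    d <- 0
    for (r in -2:2) d <- d + dnorm(x + 360 * r, m, s)
    d
  }
  outer(wn(centers, mean_phi, sd_phi), wn(centers, mean_psi, sd_psi))
}
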