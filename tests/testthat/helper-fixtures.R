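# Small, fast configurations used across tests.

tiny_config <- function(...) {
  args <- list(...)
  base <- list(n_strains = 12, n_replicates = 4, n_snps = 60,
               n_recombinants = 50, n_sup_tag_snps = 4, n_copy_tag_snps = 4,
               seed = 101L)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  do.call(sim_config, base)
}

noiseless_config <- function(...) {
  tiny_config(noise_illumina = 0, noise_blot = 0, noise_qpcr = 0,
              missing_rate = 0, ...)
}

# Build a recombinant genotype matrix from known crossovers: donor segment
# left of the crossover when orientation is TRUE, right otherwise.
make_recombinants <- function(crossovers, orientation, marker_pos) {
  t(vapply(seq_along(crossovers), function(i) {
    left <- marker_pos < crossovers[i]
    ifelse(left == orientation[i], "donor", "recipient")
  }, character(length(marker_pos))))
}
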