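# Small fixture builders shared across test files.

# a handful of synthetic introns with a motif planted at a known offset
planted_introns <- function(n = 50, len = 90, motif = "TTTATGCT",
                            offset = 10, seed_base = 1000) {
  lapply(seq_len(n), function(i)
    generate_intron(len, seed = seed_base + i,
                    planted_motifs = list(list(motif = motif,
                                               anchor = "5ss",
                                               offset = offset))))
}

# uniform-background PPM of the given length (log-odds identically zero)
uniform_motif <- function(L = 6, id = "unif") {
  motif(id, matrix(0.25, L, 4))
}

# a tiny simulated plate with the given efficiencies
tiny_plate <- function(eff, n_replicates = 4, seed = 1, ...) {
  strains <- data.frame(id = sprintf("S%02d", seq_along(eff)),
                        true_efficiency = eff)
  simulate_plate_timeseries(strains,
                            plate_design(n_replicates = n_replicates,
                                         n_control_wells = 2,
                                         seed = seed, ...))
}
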