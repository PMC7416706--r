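# Fixtures built in code: tiny record tables and repertoires with known
# structure used across the suite.

# record table from compact arguments; aa translated when omitted
recs <- function(nt, count, v = "TRBV1", j = "TRBJ1-1", aa = NULL) {
  n <- length(nt)
  clonotype_records(nt, aa, rep_len(v, n), rep_len(j, n), count)
}

# repertoire with exact clone frequencies: counts scaled to integers
rep_from_counts <- function(counts, sample_id = "fx", key_mode = "nt+vj",
                            v = "TRBV1", j = "TRBJ1-1") {
  base <- c("AAA", "CCC", "GGG", "TTT", "ACG", "CGT", "GTA", "TAC",
            "AGC", "GCA", "CAT", "ATG")
  stopifnot(length(counts) <= length(base)^2)
  nt <- as.vector(outer(base, base, paste0))[seq_along(counts)]
  build_repertoire(recs(nt, counts, v = v, j = j), key_mode, sample_id)
}

# six nucleotide variants mapping onto four amino-acid clonotypes
# (hand enumeration: CTT/CTC/CTA -> L, GGT/GGC -> G, ATG -> M, TGG -> W)
aa_partition_fixture <- function() {
  recs(nt = c("CTT", "CTC", "CTA", "GGT", "GGC", "ATG", "TGG"),
       count = c(5, 3, 2, 4, 6, 9, 1))
}

# small repertoire pair sharing three clones at perfectly log-linear
# frequency pairs (0.1, 0.2), (0.01, 0.02), (0.001, 0.002)
loglinear_pair <- function() {
  shared_nt <- c("AAACCC", "GGGTTT", "ACGACG")
  a <- build_repertoire(
    recs(c(shared_nt, "TTTTTT"), c(100, 10, 1, 889)), "nt+vj", "A")
  b <- build_repertoire(
    recs(c(shared_nt, "CCCCCC"), c(200, 20, 2, 778)), "nt+vj", "B")
  list(a = a, b = b)
}

sim_rep <- function(seed, n_clones = 100L, depth = 5000L, ...) {
  simulate_repertoire(
    simulation_params(n_clones = n_clones, depth = depth, seed = seed, ...),
    sample_id = paste0("sim", seed))
}
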