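# In-code fixtures shared across test files.

# tiny 3-array, T0 + 1 endpoint count matrix
tiny_counts <- function(t0 = c(100, 200, 300), ep = c(100, 400, 300),
                        ids = c("a1", "a2", "a3")) {
  m <- cbind(T0 = t0, EP = ep)
  rownames(m) <- ids
  gi_counts(m, t0 = "T0")
}

# annotation for a toy library: singles for each gene plus pair arrays
toy_annotation <- function() {
  gi_annotation(data.frame(
    array_id = c("sA1", "sA2", "sB1", "sB2", "pAB1", "pAB2", "sE1", "sN1", "sE2", "sN2"),
    gene1 = c("GA", "GA", "GB", "GB", "GA", "GA", "GE1", "GN1", "GE2", "GN2"),
    gene2 = c(NA, NA, NA, NA, "GB", "GB", NA, NA, NA, NA),
    control_class = c(rep("none", 6), "essential_ctrl", "nonessential_ctrl",
                      "essential_ctrl", "nonessential_ctrl"),
    stringsAsFactors = FALSE))
}

# small but full simulated study used by several end-to-end tests
small_sim <- function(seed = 11L, ...) {
  simulate_screens(sim_config(n_genes = 300L, n_pairs = 150L,
                              n_screens = 3L, seed = seed, ...))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
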