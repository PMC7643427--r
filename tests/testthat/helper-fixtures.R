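# shared fixtures, all built in code

ballistic_track <- function(n = 4L, v = 1, dt = 1) {
  track("ballistic", cbind(v * dt * (seq_len(n) - 1), 0), dt = dt)
}

random_walk_track <- function(n = 50L, dt = 0.02, sd = 0.05, dim = 2L,
                              seed = 1L, id = "rw") {
  set.seed(seed)
  track(id, apply(matrix(rnorm(n * dim, sd = sd), n, dim), 2L, cumsum),
        dt = dt)
}

# independent brute-force MSD: double loop over all (t, t + k) pairs
brute_msd <- function(pos, k) {
  n <- nrow(pos)
  sq <- vapply(seq_len(n - k), function(t)
    sum((pos[t + k, ] - pos[t, ])^2), numeric(1))
  c(msd = mean(sq), var_sq = mean((sq - mean(sq))^2), n = length(sq))
}

# one chromosome, arms of `arm_bins` bins each side of the centromere
toy_layout <- function(arm_bins = 100L, binsize = 1e4, chrom = "chrI") {
  len <- 2 * arm_bins * binsize
  genome_layout(data.frame(chrom = chrom, length = len,
                           centromere = len / 2), binsize = binsize)
}

write_triplets <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

uniform_matrix <- function(layout, value = 5) {
  contact_matrix(layout, matrix(value, layout$n_bins, layout$n_bins))
}
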