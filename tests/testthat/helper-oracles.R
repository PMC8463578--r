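# Independent oracles, kept deliberately naive.

# Explicit set-based NCS: sum the exponential kernel over all strictly
# previous firing times of a single binary train.
ncs_oracle <- function(train, gamma, t) {
  prev <- which(train[seq_len(t - 1)] == 1)
  if (length(prev) == 0) return(0)
  sum(exp(-gamma * (t - prev)))
}

# Brute-force SAM from the definition (per-neuron set sums, channel sum).
sam_oracle <- function(raster, gamma) {
  d <- dim(raster)
  maps <- array(0, c(d[1], d[3], d[4]))
  for (t in seq_len(d[1])) {
    for (k in seq_len(d[2])) {
      for (i in seq_len(d[3])) {
        for (j in seq_len(d[4])) {
          if (raster[t, k, i, j] == 1) {
            maps[t, i, j] <- maps[t, i, j] + ncs_oracle(raster[, k, i, j], gamma, t)
          }
        }
      }
    }
  }
  maps
}

# Scalar LIF trace oracle: literal recurrence, returning potentials and spikes.
lif_trace_oracle <- function(drives, leak, theta) {
  u <- 0; o <- 0
  us <- ss <- numeric(length(drives))
  for (t in seq_along(drives)) {
    u <- leak * u + drives[t] - (if (is.finite(theta)) theta * o else 0)
    o <- as.numeric(u > theta)
    us[t] <- u; ss[t] <- o
  }
  list(potential = us, spikes = ss)
}
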