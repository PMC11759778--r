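# shared helpers: tiny builders and independent oracles

make_instance <- function(id, group, score, moduli) {
  recording_instance(id, group, score, moduli)
}

# uniformly sampled rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# brute-force oracle: minimal SSE over all contiguous partitions of sorted x
# into k non-empty blocks (optimal 1-D clusters are contiguous in sorted order)
enum_contiguous_sse <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  sse_block <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(sse_block(xs))
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    s <- sum(vapply(seq_len(k), function(u)
      sse_block(xs[(b[u] + 1):b[u + 1]]), numeric(1)))
    if (s < best) best <- s
  }
  best
}

# a small synthetic recording wrapped with annotations, for io/preprocess tests
tiny_recording <- function(n = 64, fs = 31.25, id = "tiny") {
  t <- (seq_len(n) - 1) / fs
  triaxial_recording(id, data.frame(t = t, x = sin(t), y = cos(t),
                                    z = rep(0.5, n)), sampling_rate = fs)
}

noise_free_config <- function(seed = 1L, n_per_severity = c("0" = 1, "3" = 1)) {
  simulation_config(n_per_severity = n_per_severity,
                    n_rest_intervals = 2, rest_duration = 4,
                    nonrest_duration = 3, noise_sd = 0, seed = seed)
}
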