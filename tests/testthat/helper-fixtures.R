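# Shared fixture builders; everything is generated in code at test time.

# Gaussian blobs with known labels, for clustering recovery checks.
make_blobs <- function(n_per, centers, sd = 1, seed = 42) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                   sd = sd),
             nrow = n_per)
    })
  })
  list(x = do.call(rbind, parts),
       labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Minimal event table with explicit marker columns.
make_events <- function(values, markers = colnames(values), meta = NULL) {
  df <- tibble::as_tibble(values)
  if (!is.null(meta)) df <- dplyr::bind_cols(meta, df)
  attr(df, "markers") <- markers
  attr(df, "scale_state") <- "raw"
  df
}

# Adjusted Rand index via the independent mclust implementation.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Closed-form 33-day IV for the noise-free exponential killing generator:
# sum over rounds r and frame times t of 100 * (1 - exp((g - k_r) * t)).
analytic_iv33 <- function(growth, kill, decay, rounds = 11,
                          frames = 11, dt = 7, et_mult = 1) {
  total <- 0
  for (r in seq_len(rounds)) {
    k_r <- kill * et_mult * decay^(r - 1)
    t <- (seq_len(frames) - 1) * dt
    total <- total + sum(100 * (1 - exp((growth - k_r) * t)))
  }
  total
}
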