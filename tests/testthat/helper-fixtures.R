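# small deterministic fixtures built in code

ramp_volume <- function(shape = c(4, 4, 4)) {
  # voxel (i,j,k) holds 100*i + 10*j + k so positions are identifiable
  a <- array(0, dim = shape)
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3]))
        a[i, j, k] <- 100 * i + 10 * j + k
  as_volume(a)
}

random_volume <- function(shape = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  as_volume(array(stats::runif(prod(shape)), dim = shape))
}

small_phantom_cohort <- function(n_per_class = 4, shape = c(16, 16, 16),
                                 effect = 0.5, noise = 0.05, seed = 11) {
  spec <- phantom_spec(shape = shape, effect_size = effect, noise_sd = noise,
                       seed = seed)
  cohort <- generate_cohort(spec, n_per_class)
  cohort_map(cohort, function(v) normalize_volume(v, c(-1, 1)))
}

# direct single-window SSIM formula with plain (unweighted) moments
ssim_single_window <- function(x, y, data_range) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# O(n^2) concordant-pair AUC with half credit for ties
auc_pair_count <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
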