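# Independent per-pixel oracles for the vectorized region equations and
# transfer functions, plus small random-input generators.

random_hu_grid <- function(nr = 32, nc = 32) {
  matrix(runif(nr * nc, -1000, 1500), nr, nc)
}

random_mask <- function(nr = 32, nc = 32, p = 0.4) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# double-loop versions of the four region equations
loop_suspect_hemorrhage <- function(P, H_l, K, cap = 110) {
  out <- P * 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    f <- if (P[i, j] <= cap) P[i, j] else 0
    out[i, j] <- abs(K[i, j] - H_l[i, j]) * f
  }
  out
}

loop_csf <- function(P, M, Hp, cap = 15) {
  out <- P * 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    f <- if (P[i, j] <= cap) P[i, j] else 0
    out[i, j] <- abs(M[i, j] - Hp[i, j]) * f
  }
  out
}

loop_wm <- function(P, M, Hp, a = 15, b) {
  out <- P * 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    f <- if (P[i, j] >= a && P[i, j] <= b / 2) P[i, j] else 0
    out[i, j] <- abs(M[i, j] - Hp[i, j]) * f
  }
  out
}

loop_gm <- function(P, M, Hp, b) {
  out <- P * 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    f <- if (P[i, j] > b / 2 && P[i, j] <= b) P[i, j] else 0
    out[i, j] <- abs(M[i, j] - Hp[i, j]) * f
  }
  out
}

loop_transform <- function(P, s, method, p = transfer_params()) {
  out <- matrix(0L, nrow(P), ncol(P))
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    out[i, j] <- as.integer(if (method == "traditional")
      traditional_transform(P[i, j], s)
    else min(max(floor(sigmoid_transform(P[i, j], s, p) + 0.5), 0), 255))
  out
}

# a phantom with a calcified nodule, for ablation tests
calc_phantom_spec <- function(seed = 1) {
  phantom_spec(
    calcifications = list(list(center = c(50, 75), radius = 4, hu = 120)),
    seed = seed)
}
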