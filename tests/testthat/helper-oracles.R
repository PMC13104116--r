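# Independent brute-force oracles, written directly from the definitions
# and kept free of any package code paths.

# Pearson correlation as an explicit double sum
pearson_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx <- dx + (x[i] - xb)^2
    dy <- dy + (y[i] - yb)^2
  }
  num / sqrt(dx * dy)
}

# full pairwise connectivity matrix via the double-sum oracle
connectivity_oracle <- function(traces) {
  n <- nrow(traces)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) w[i, j] <- pearson_oracle(traces[i, ], traces[j, ])
  }
  w
}

# modularity as a literal double loop over ordered node pairs
modularity_oracle <- function(A, membership, gamma = 1) {
  n <- nrow(A)
  k <- rowSums(A)
  two_m <- sum(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + A[i, j] - gamma * k[i] * k[j] / two_m
  }
  q / two_m
}

# random symmetric nonnegative weight matrix with zero diagonal
random_graph <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

as_network <- function(A) {
  structure(list(w = A, nodes = paste0("V", seq_len(nrow(A))),
                 level = "neuron"), class = "functional_network")
}

# tiny session for fast tests
tiny_params <- function(n_neurons = 30, ...) {
  session_params(n_neurons = n_neurons, n_sets = 1, reps_per_set = 2, ...)
}
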