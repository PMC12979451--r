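# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths: the rich-club
# oracle walks every node pair explicitly, and the random-graph builder
# fills the matrix entry by entry.

# brute-force rich-club coefficient: re-derive survivors and count the
# subgraph's edges pair by pair
phi_oracle <- function(adj, k, rule = "ge") {
  n <- nrow(adj)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && adj[i, j] != 0) deg[i] <- deg[i] + 1
    }
  }
  survivors <- which(if (rule == "ge") deg >= k else deg > k)
  s <- length(survivors)
  if (s < 2) return(NA_real_)
  e <- 0
  for (a in seq_len(s - 1)) {
    for (b in (a + 1):s) {
      if (adj[survivors[a], survivors[b]] != 0) e <- e + 1
    }
  }
  e / (s * (s - 1) / 2)
}

# Erdős–Rényi graph as a labeled adjacency matrix
rand_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
      }
    }
    dimnames(adj) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    adj
  })
}

# symmetric integer weight matrix with zero diagonal
rand_weighted <- function(n, p, max_w, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) adj[i, j] <- adj[j, i] <- sample.int(max_w, 1)
      }
    }
    dimnames(adj) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    adj
  })
}

# named small graphs
complete_graph <- function(n) {
  adj <- matrix(1, n, n) - diag(n)
  dimnames(adj) <- list(LETTERS[1:n], LETTERS[1:n])
  adj
}

path_graph <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  dimnames(adj) <- list(LETTERS[1:n], LETTERS[1:n])
  adj
}

star_graph <- function(n) {
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  dimnames(adj) <- list(LETTERS[1:n], LETTERS[1:n])
  adj
}

# samples with exactly the requested mean and sd (affine-rescaled z-scores),
# the raw-data oracle for the summary-statistic reconstructions
exact_sample <- function(n, mean, sd, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    x <- (x - base::mean(x)) / stats::sd(x)
    mean + sd * x
  })
}
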