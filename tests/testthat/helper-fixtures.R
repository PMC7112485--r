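# Shared fixtures and independent oracles for the test suite.

# Small multiplex with the standard awareness-layer parameters.
small_multiplex <- function(n = 300, m = 8, seed = 101) {
  lay <- activity_layer(n, gamma = 3, xi = 1e-3, eta = 10, m = m,
                        seed = derive_seed(seed, 1))
  net <- suppressMessages(
    generate_scale_free(n, seed = derive_seed(seed, 2)))
  multiplex(lay, net)
}

# Static layer from an explicit edge list (1-based pairs).
static_from_edges <- function(n, edges) {
  adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
  f <- tempfile()
  on.exit(unlink(f))
  lo <- pmin(edges[, 1], edges[, 2]) - 1L
  hi <- pmax(edges[, 1], edges[, 2]) - 1L
  writeLines(paste(lo, hi), f)
  read_edge_list(f, n_nodes = n)
}

# Snapshot with a fixed edge set (bypasses the generator).
snapshot_from_edges <- function(n, edges, t = 0L) {
  structure(list(n_nodes = as.integer(n), time_index = as.integer(t),
                 edges = matrix(as.integer(edges), ncol = 2),
                 degrees = tabulate(as.integer(edges), nbins = n)),
            class = "temporal_snapshot")
}

# Literal per-node transcription of the three-state MMCA update equations;
# the independent oracle for mmca_step.
naive_mmca_step <- function(state, snapshot, static, params) {
  n <- length(state$p_us)
  B <- as.matrix(static$adjacency)
  A <- matrix(0, n, n)
  if (nrow(snapshot$edges) > 0) {
    for (e in seq_len(nrow(snapshot$edges))) {
      i <- snapshot$edges[e, 1]; j <- snapshot$edges[e, 2]
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  pA <- state$p_as + state$p_ai
  us <- as_ <- ai <- numeric(n)
  for (i in seq_len(n)) {
    if (params$awareness_model == "sis") {
      r <- 1
      for (j in seq_len(n)) r <- r * (1 - A[j, i] * pA[j] * params$lambda_aware)
    } else {
      ki <- sum(A[, i])
      r <- if (ki == 0) 1 else {
        ratio <- sum(A[, i] * pA) / ki
        aware <- if (params$strict_threshold) ratio >= params$alpha
                 else ratio > params$alpha
        as.numeric(!aware)
      }
    }
    qa <- 1; qu <- 1
    for (j in seq_len(n)) {
      qa <- qa * (1 - B[j, i] * state$p_ai[j] * params$beta_a)
      qu <- qu * (1 - B[j, i] * state$p_ai[j] * params$beta_u)
    }
    d <- params$delta; mu <- params$mu
    us[i] <- state$p_ai[i] * d * mu + state$p_us[i] * r * qu +
      state$p_as[i] * d * qu
    as_[i] <- state$p_ai[i] * mu * (1 - d) + state$p_us[i] * (1 - r) * qa +
      state$p_as[i] * (1 - d) * qa
    ai[i] <- state$p_ai[i] * (1 - mu) +
      state$p_us[i] * ((1 - r) * (1 - qa) + r * (1 - qu)) +
      state$p_as[i] * (d * (1 - qu) + (1 - d) * (1 - qa))
  }
  list(p_us = us, p_as = as_, p_ai = ai)
}

# Plain single-layer discrete-time SIS MMCA on a static adjacency;
# oracle for the lambda = 0, delta = 1 reduction.
single_layer_sis_mmca <- function(static, p0, beta, mu, steps) {
  p <- p0
  for (t in seq_len(steps)) {
    q <- not_infected_probs(static, p, beta)
    p <- (1 - p) * (1 - q) + p * (1 - mu)
  }
  p
}

random_state <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(3 * n), ncol = 3)
  m <- m / rowSums(m)
  state_probs(m[, 1], m[, 2], m[, 3])
}
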