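#' Sample activity potentials from a truncated power law
#'
#' Draws i.i.d. activity potentials x from the density F(x) = C x^(-gamma)
#' truncated to the interval `[xi, 1]`, by inverse-CDF sampling. These
#' potentials parameterize the activity-driven awareness layer: node i fires
#' with per-step probability a_i = eta * x_i.
#'
#' @param n number of draws (one per node).
#' @param gamma power-law exponent, must be > 1. Default 3.
#' @param xi lower truncation bound, in (0, 1). Default 1e-3.
#' @param seed optional integer seed; same seed gives identical output.
#' @return numeric vector of length `n` with values in `[xi, 1]`.
#' @examples
#' x <- sample_activity_potentials(10, gamma = 3, xi = 1e-3, seed = 1)
#' range(x)
#' @export
sample_activity_potentials <- function(n, gamma = 3, xi = 1e-3, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1)
    stop("`gamma` must be a single number > 1")
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0 || xi >= 1)
    stop("`xi` must lie strictly between 0 and 1")
  draw <- function() {
    u <- stats::runif(n)
    g1 <- 1 - gamma # < 0
    # CDF(x) = (x^g1 - xi^g1) / (1 - xi^g1); invert
    (xi^g1 + u * (1 - xi^g1))^(1 / g1)
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  pmin(pmax(x, xi), 1) # guard rounding at the boundaries
}

# Closed-form moments of the truncated power law (used as test oracles and
# by awareness_boundary when distribution-level moments are requested).
truncated_powerlaw_moment <- function(order, gamma, xi) {
  stopifnot(order >= 0, gamma > 1, xi > 0, xi < 1)
  norm <- function(p) { # integral of x^p over [xi, 1]
    if (abs(p + 1) < 1e-12) log(1 / xi) else (1 - xi^(p + 1)) / (p + 1)
  }
  norm(order - gamma) / norm(-gamma)
}

#' Construct an activity-driven awareness layer
#'
#' Bundles the node activity potentials and the generative parameters of the
#' activity-driven temporal network: at each time step node i activates with
#' probability `min(eta * x_i, 1)` and, if active, wires `m` ephemeral
#' undirected links to distinct, uniformly chosen partners. All links are
#' deleted before the next step (memoryless snapshots).
#'
#' @param n_nodes number of nodes N.
#' @param gamma activity power-law exponent (default 3).
#' @param xi lower bound of the activity potential (default 1e-3).
#' @param eta rescaling factor: a_i = eta * x_i (default 10).
#' @param m links created per activation (default 8); must be < `n_nodes`.
#' @param seed integer seed used to draw the potentials.
#' @param potentials optional explicit potential vector (overrides sampling);
#'   values must lie in `[xi, 1]`.
#' @return an object of class `activity_layer` with fields `n_nodes`,
#'   `potentials`, `activities` (= eta * potentials), `act_prob`
#'   (activities clamped to 1, the per-step activation probability), `m`,
#'   `gamma`, `xi`, `eta`.
#' @examples
#' lay <- activity_layer(100, seed = 1)
#' mean(lay$act_prob)
#' @export
activity_layer <- function(n_nodes, gamma = 3, xi = 1e-3, eta = 10, m = 8,
                           seed = NULL, potentials = NULL) {
  if (!is.numeric(n_nodes) || n_nodes < 2) stop("`n_nodes` must be >= 2")
  if (m >= n_nodes) stop("`m` must be smaller than `n_nodes`")
  if (m < 1 || m != floor(m)) stop("`m` must be a positive integer")
  if (eta <= 0) stop("`eta` must be positive")
  if (is.null(potentials)) {
    potentials <- sample_activity_potentials(n_nodes, gamma, xi, seed)
  } else {
    if (length(potentials) != n_nodes) stop("`potentials` has wrong length")
    if (any(potentials < xi - 1e-12) || any(potentials > 1 + 1e-12))
      stop("`potentials` must lie in [xi, 1]")
  }
  a <- eta * potentials
  structure(list(n_nodes = as.integer(n_nodes), potentials = potentials,
                 activities = a, act_prob = pmin(a, 1), m = as.integer(m),
                 gamma = gamma, xi = xi, eta = eta),
            class = "activity_layer")
}

#' @export
print.activity_layer <- function(x, ...) {
  cat(sprintf(
    "activity_layer: N=%d, m=%d, gamma=%g, xi=%g, eta=%g, <a>=%.4g\n",
    x$n_nodes, x$m, x$gamma, x$xi, x$eta, mean(x$activities)))
  invisible(x)
}

new_snapshot <- function(n_nodes, edges, time_index = 0L) {
  edges <- matrix(as.integer(edges), ncol = 2)
  deg <- tabulate(edges, nbins = n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), time_index = as.integer(time_index),
                 edges = edges, degrees = deg),
            class = "temporal_snapshot")
}

#' Generate one snapshot of the activity-driven awareness layer
#'
#' Each node activates independently with probability `min(eta * x_i, 1)`;
#' every active node links to `m` distinct partners chosen uniformly among
#' the other N-1 nodes. Duplicate unordered pairs (two activations creating
#' the same contact) collapse into a single undirected edge. Snapshots carry
#' no memory of previous steps.
#'
#' @param layer an [activity_layer()].
#' @param seed optional integer seed for this snapshot; if `NULL`, draws from
#'   the current RNG stream (the usual mode inside iterations).
#' @param time_index time stamp stored on the snapshot.
#' @return an object of class `temporal_snapshot`: fields `n_nodes`,
#'   `time_index`, `edges` (e x 2 integer matrix, 1-based node ids, each
#'   unordered pair once), `degrees` (per-node contact count).
#' @examples
#' lay <- activity_layer(50, seed = 1)
#' sn <- generate_snapshot(lay, seed = 2)
#' nrow(sn$edges)
#' @export
generate_snapshot <- function(layer, seed = NULL, time_index = 0L) {
  stopifnot(inherits(layer, "activity_layer"))
  gen <- function() {
    n <- layer$n_nodes
    m <- layer$m
    active <- which(stats::runif(n) < layer$act_prob)
    if (length(active) == 0L)
      return(new_snapshot(n, integer(0), time_index))
    # each active node picks m distinct partners among the other n-1 nodes
    partners <- vapply(active, function(i) {
      p <- sample.int(n - 1L, m)
      p + (p >= i) # shift to skip i itself
    }, integer(m))
    u <- rep(active, each = m)
    v <- as.integer(partners)
    lo <- pmin(u, v); hi <- pmax(u, v)
    keep <- !duplicated(lo * (n + 1) + hi)
    new_snapshot(n, cbind(lo[keep], hi[keep]), time_index)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.temporal_snapshot <- function(x, ...) {
  cat(sprintf("temporal_snapshot: N=%d, t=%d, %d edges\n",
              x$n_nodes, x$time_index, nrow(x$edges)))
  invisible(x)
}

#' Aggregate activity-driven snapshots into a static graph
#'
#' Union of the edge sets of `window` consecutive snapshots, used as the
#' static-awareness-layer comparator in model comparisons.
#'
#' @param layer an [activity_layer()].
#' @param window number of snapshots to union (default 20).
#' @param seed integer seed.
#' @return a `temporal_snapshot` holding the aggregated edge set.
#' @export
aggregate_snapshots <- function(layer, window = 20L, seed = NULL) {
  stopifnot(inherits(layer, "activity_layer"), window >= 1)
  gen <- function() {
    acc <- matrix(integer(0), ncol = 2)
    for (w in seq_len(window)) {
      sn <- generate_snapshot(layer)
      acc <- rbind(acc, sn$edges)
    }
    keep <- !duplicated(acc[, 1] * (layer$n_nodes + 1) + acc[, 2])
    new_snapshot(layer$n_nodes, acc[keep, , drop = FALSE])
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

new_static_layer <- function(adjacency) {
  adjacency <- methods::as(methods::as(adjacency, "generalMatrix"), "CsparseMatrix")
  structure(list(n_nodes = nrow(adjacency), adjacency = adjacency,
                 degree_sequence = as.integer(Matrix::rowSums(adjacency))),
            class = "static_layer")
}

#' Generate the static scale-free contagion layer
#'
#' Samples a degree sequence from P(k) proportional to k^(-exponent) on
#' `[min_degree, floor(sqrt(n))]` (structural cutoff) and wires it with the
#' configuration model; self-loops and multi-edges are removed afterwards, so
#' realized degrees can fall slightly below their sampled values. An odd stub
#' total is repaired by decrementing one stub of a maximum-degree node (a
#' message notes the repair).
#'
#' @param n number of nodes (>= 10).
#' @param exponent degree-distribution exponent (default 3).
#' @param min_degree minimum sampled degree (default 2).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `static_layer`: `n_nodes`, `adjacency`
#'   (symmetric binary sparse Matrix with zero diagonal), `degree_sequence`.
#' @examples
#' net <- generate_scale_free(200, seed = 1)
#' summary(net$degree_sequence)
#' @export
generate_scale_free <- function(n, exponent = 3, min_degree = 2, seed = NULL) {
  if (n < 10) stop("`n` must be >= 10")
  if (min_degree < 1) stop("`min_degree` must be >= 1")
  gen <- function() {
    k_cut <- max(min_degree, floor(sqrt(n)))
    ks <- min_degree:k_cut
    deg <- sample(ks, n, replace = TRUE, prob = ks^(-exponent))
    if (sum(deg) %% 2 == 1) {
      i <- which.max(deg)
      deg[i] <- deg[i] - 1L
      message("odd stub total: decremented one stub of node ", i)
    }
    g <- igraph::sample_degseq(deg, method = "configuration")
    g <- igraph::simplify(g)
    out <- new_static_layer(igraph::as_adjacency_matrix(g, sparse = TRUE))
    short <- sum(out$degree_sequence < min_degree)
    if (short > 0)
      message(short, " node(s) below min_degree after self-loop/multi-edge ",
              "removal")
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.static_layer <- function(x, ...) {
  cat(sprintf("static_layer: N=%d, %d edges, <k>=%.2f, k_max=%d\n",
              x$n_nodes, sum(x$degree_sequence) / 2,
              mean(x$degree_sequence), max(x$degree_sequence)))
  invisible(x)
}

#' Read a static layer from an edge-list file
#'
#' Lines of whitespace-separated `u v` pairs with 0-based node ids. Duplicate
#' (undirected) edges collapse into one with a warning; self-loops are
#' rejected.
#'
#' @param path file path.
#' @param n_nodes optional node count; defaults to `max(id) + 1`.
#' @return a `static_layer`.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    if (is.null(n_nodes))
      stop("empty edge list: `n_nodes` must be given explicitly")
    return(new_static_layer(Matrix::sparseMatrix(i = integer(0),
                                                 j = integer(0), x = numeric(0),
                                                 dims = c(n_nodes, n_nodes))))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  u <- integer(length(toks)); v <- integer(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != 2L || anyNA(suppressWarnings(as.integer(tk))) ||
        any(as.numeric(tk) != floor(as.numeric(tk))))
      stop(sprintf("line %d: expected two integer node ids, got '%s'",
                   i, paste(tk, collapse = " ")))
    u[i] <- as.integer(tk[1]); v[i] <- as.integer(tk[2])
  }
  if (any(u < 0) || any(v < 0))
    stop(sprintf("line %d: negative node id", which(u < 0 | v < 0)[1]))
  if (any(u == v))
    stop(sprintf("line %d: self-loop not allowed", which(u == v)[1]))
  n <- if (is.null(n_nodes)) max(u, v) + 1L else as.integer(n_nodes)
  if (max(u, v) + 1L > n)
    stop(sprintf("line %d: node id out of range (n_nodes = %d)",
                 which(pmax(u, v) + 1L > n)[1], n))
  lo <- pmin(u, v) + 1L; hi <- pmax(u, v) + 1L
  dup <- duplicated(lo * (n + 1) + hi)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge line(s) collapsed")
    lo <- lo[!dup]; hi <- hi[!dup]
  }
  adj <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                              dims = c(n, n))
  new_static_layer(adj)
}

static_layer_edges <- function(static) {
  tri <- Matrix::triu(static$adjacency)
  sm <- methods::as(tri, "TsparseMatrix")
  cbind(sm@i + 1L, sm@j + 1L)
}

#' Write a static layer or snapshot as an edge list
#'
#' One `u v` pair per line, 0-based ids, each undirected edge once
#' (smaller id first, rows sorted).
#'
#' @param x a `static_layer` or `temporal_snapshot`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  e <- if (inherits(x, "static_layer")) static_layer_edges(x)
       else if (inherits(x, "temporal_snapshot")) x$edges
       else stop("`x` must be a static_layer or temporal_snapshot")
  if (nrow(e) > 0) {
    lo <- pmin(e[, 1], e[, 2]) - 1L; hi <- pmax(e[, 1], e[, 2]) - 1L
    o <- order(lo, hi)
    writeLines(paste(lo[o], hi[o]), path)
  } else writeLines(character(0), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_snapshot <- function(x, path) write_edge_list(x, path)
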