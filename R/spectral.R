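#' Stationary awareness probabilities in the epidemic-free state
#'
#' Runs the awareness dynamics alone (infection terms switched off, the
#' linearization limit p^AI -> 0) on the time-varying layer and returns the
#' per-node awareness probability p^A time-averaged over the stationarity
#' window. This vector parameterizes the H matrix of the spectral threshold.
#'
#' Awareness is seeded like the MC runs: a fraction `rho_a0` of randomly
#' chosen nodes starts fully aware (p^A = 1), the rest unaware.
#'
#' @param layer awareness `activity_layer`.
#' @param params `model_params` (only the awareness fields are used).
#' @param t0,window stationarity protocol (defaults 901, 100).
#' @param rho_a0 initially aware fraction (default 0.2).
#' @param seed integer seed (snapshot sequence and seeding pattern).
#' @param contact_mode `"snapshot"` (default) or `"annealed"`.
#' @return numeric vector p^A of length N (time-averaged), with the full
#'   trace of the mean awareness density as attribute `"rho_a_trace"`.
#' @export
stationary_awareness <- function(layer, params, t0 = 901L, window = 100L,
                                 rho_a0 = 0.2, seed = 1L,
                                 contact_mode = c("snapshot", "annealed")) {
  contact_mode <- match.arg(contact_mode)
  stopifnot(inherits(layer, "activity_layer"), inherits(params, "model_params"),
            t0 >= 1, window >= 1)
  n <- layer$n_nodes
  p_a <- numeric(n)
  p_a[sample_seed_nodes(n, rho_a0, derive_seed(seed, 0L))] <- 1
  total <- t0 + window - 1L
  acc <- numeric(n)
  trace <- numeric(total)
  d <- params$delta
  pmat <- if (contact_mode == "annealed") annealed_contact_matrix(layer)
  run <- function() {
    for (t in seq_len(total)) {
      r <- if (contact_mode == "snapshot")
        stay_unaware(generate_snapshot(layer, time_index = t), p_a, params)
      else stay_unaware_annealed(pmat, p_a, params)
      p_a <<- (1 - p_a) * (1 - r) + p_a * (1 - d)
      trace[t] <<- mean(p_a)
      if (t >= t0) acc <<- acc + p_a
    }
  }
  with_seed(derive_seed(seed, 1L), run())
  structure(acc / window, rho_a_trace = trace)
}

#' Build the awareness-modulated adjacency matrix H
#'
#' `h_ij = (1 - p_i^A) * b_ji`: row i of the contagion adjacency scaled by
#' node i's probability of being unaware. The epidemic threshold of the
#' linearized MMCA is mu / Lambda_max(H).
#'
#' @param static contagion `static_layer`.
#' @param p_aware stationary awareness vector p^A in `[0, 1]^N`.
#' @return a sparse Matrix H of the same dimension as the adjacency.
#' @export
build_h_matrix <- function(static, p_aware) {
  stopifnot(inherits(static, "static_layer"))
  if (length(p_aware) != static$n_nodes)
    stop("`p_aware` length must equal the number of nodes")
  if (any(p_aware < -1e-12 | p_aware > 1 + 1e-12))
    stop("`p_aware` must lie in [0, 1]")
  # b is symmetric, so (1 - p_i) b_ji = (1 - p_i) b_ij: scale rows
  Matrix::Diagonal(x = 1 - p_aware) %*% static$adjacency
}

# Largest eigenvalue of H = D B with D = diag(1 - pA) >= 0 and B symmetric
# non-negative. H is similar to the symmetric S = sqrt(D) B sqrt(D), whose
# spectrum is real; power iteration with Rayleigh quotients on S, dense
# symmetric eigendecomposition as fallback / for small n.
largest_eigenvalue_h <- function(static, p_aware, tol = 1e-12,
                                 max_iter = 20000L) {
  w <- sqrt(pmax(0, pmin(1, 1 - p_aware)))
  if (all(w == 0)) return(0)
  B <- static$adjacency
  n <- static$n_nodes
  # shift by +1 so the Perron root strictly dominates in magnitude even for
  # bipartite graphs (where lambda_min = -lambda_max)
  shift <- 1
  mv <- function(v) w * as.numeric(B %*% (w * v)) + shift * v
  v <- w * (static$degree_sequence + 1)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  v <- v / nv
  lam <- 0
  for (it in seq_len(max_iter)) {
    u <- mv(v)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-300) return(0)
    lam_new <- sum(v * u) # Rayleigh quotient of the shifted operator
    v <- u / nu
    if (it > 5 && abs(lam_new - lam) <= tol * max(1, abs(lam_new))) {
      return(max(0, lam_new - shift))
    }
    lam <- lam_new
  }
  if (n <= 3000) {
    S <- Matrix::Diagonal(x = w) %*% B %*% Matrix::Diagonal(x = w)
    ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
    return(max(ev))
  }
  warning("power iteration did not reach tolerance; returning last estimate")
  lam
}

#' Spectral epidemic threshold from the H matrix
#'
#' The linearized MMCA has a non-trivial solution iff mu / beta^U is an
#' eigenvalue of H, giving the threshold `beta_c = mu / Lambda_max(H)`.
#'
#' @param static contagion `static_layer`.
#' @param p_aware stationary epidemic-free awareness vector (default all
#'   zero, reducing H to the plain adjacency B).
#' @param mu recovery probability.
#' @return an object of class `threshold_result`: `beta_c` (`Inf` when
#'   Lambda_max = 0), `lambda_max`, `p_aware_stationary`, `h_dim`.
#' @examples
#' net <- generate_scale_free(100, seed = 1)
#' epidemic_threshold(net, mu = 0.2)
#' @export
epidemic_threshold <- function(static, p_aware = NULL, mu = 0.2) {
  stopifnot(inherits(static, "static_layer"), mu >= 0, mu <= 1)
  if (is.null(p_aware)) p_aware <- numeric(static$n_nodes)
  if (length(p_aware) != static$n_nodes)
    stop("`p_aware` length must equal the number of nodes")
  lam <- largest_eigenvalue_h(static, p_aware)
  structure(list(beta_c = if (lam > 0) mu / lam else Inf,
                 lambda_max = lam,
                 p_aware_stationary = p_aware,
                 mu = mu,
                 h_dim = c(static$n_nodes, static$n_nodes)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result: beta_c=%.6g (mu=%g, Lambda_max=%.6g, N=%d)\n",
              x$beta_c, x$mu, x$lambda_max, x$h_dim[1]))
  invisible(x)
}

#' Awareness-survival boundary of the single-layer activity-driven SIS
#'
#' Critical awareness rate below which awareness cannot survive on the
#' time-varying layer alone: `lambda_c = delta / (m (<a> + s))` where
#' `s = sqrt(<a^2>)` for the default `"sqrt"` variant (the canonical
#' activity-driven threshold) or `s = <a^2>` for the `"literal"` variant.
#' Moments are taken over the realized activity vector a_i = eta x_i.
#'
#' @param layer awareness `activity_layer`.
#' @param delta forgetting probability.
#' @param variant `"sqrt"` (default) or `"literal"`.
#' @param clamp use the clamped per-step activation probabilities
#'   `min(a_i, 1)` for the moments (default `TRUE`, matching what the
#'   generator actually uses).
#' @return the critical value lambda_c (0 when delta = 0).
#' @export
awareness_boundary <- function(layer, delta, variant = c("sqrt", "literal"),
                               clamp = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(layer, "activity_layer"), delta >= 0, delta <= 1)
  a <- if (clamp) layer$act_prob else layer$activities
  m1 <- mean(a); m2 <- mean(a^2)
  s <- if (variant == "sqrt") sqrt(m2) else m2
  delta / (layer$m * (m1 + s))
}

#' Metacritical point of the coupled dynamics
#'
#' Returns the pair `(lambda_c, beta_c_upper)` bounding the region of the
#' (lambda, beta) plane where awareness dynamics starts shifting the epidemic
#' threshold: `lambda_c` is the awareness-survival boundary of the
#' time-varying layer and `beta_c_upper = mu / Lambda_max(B)` is the
#' awareness-free epidemic threshold of the contagion layer.
#'
#' @param layer awareness `activity_layer`.
#' @param static contagion `static_layer`.
#' @param delta forgetting probability.
#' @param mu recovery probability.
#' @param variant passed to [awareness_boundary()].
#' @return named numeric vector `c(lambda_c = ..., beta_c = ...)`.
#' @export
metacritical_point <- function(layer, static, delta, mu,
                               variant = c("sqrt", "literal")) {
  variant <- match.arg(variant)
  c(lambda_c = awareness_boundary(layer, delta, variant),
    beta_c = epidemic_threshold(static, mu = mu)$beta_c)
}

#' MMCA epidemic threshold as a function of an awareness parameter
#'
#' For each value of the awareness parameter (`lambda` for SIS awareness,
#' `alpha` for the threshold model), computes the stationary epidemic-free
#' awareness, builds H, and returns the spectral threshold
#' `beta_c = mu / Lambda_max(H)`.
#'
#' @param layer awareness `activity_layer`.
#' @param static contagion `static_layer`.
#' @param params baseline `model_params` (mu, delta, awareness model).
#' @param over which parameter the grid varies: `"alpha"` or `"lambda"`.
#' @param grid ascending vector of parameter values.
#' @param t0,window,rho_a0,seed stationary-awareness protocol, see
#'   [stationary_awareness()].
#' @return data.frame with columns `param`, `beta_c`, `lambda_max`, `rho_a`
#'   (mean stationary awareness).
#' @export
threshold_curve <- function(layer, static, params, over = c("alpha", "lambda"),
                            grid, t0 = 901L, window = 100L, rho_a0 = 0.2,
                            seed = 1L) {
  over <- match.arg(over)
  stopifnot(!is.unsorted(grid))
  out <- data.frame(param = grid, beta_c = NA_real_, lambda_max = NA_real_,
                    rho_a = NA_real_)
  for (i in seq_along(grid)) {
    p <- params
    if (over == "alpha") p$alpha <- grid[i] else p$lambda_aware <- grid[i]
    pa <- stationary_awareness(layer, p, t0 = t0, window = window,
                               rho_a0 = rho_a0,
                               seed = derive_seed(seed, 10L + i))
    th <- epidemic_threshold(static, as.numeric(pa), mu = params$mu)
    out$beta_c[i] <- th$beta_c
    out$lambda_max[i] <- th$lambda_max
    out$rho_a[i] <- mean(pa)
  }
  out
}

#' Locate the largest jump of a threshold curve
#'
#' Returns the midpoint of the grid interval with the largest forward
#' difference of `values` — used to locate the abrupt (two-stage) transition
#' of beta_c(alpha).
#'
#' @param grid ascending parameter grid.
#' @param values curve values (same length).
#' @return list with `midpoint`, `jump` (absolute forward difference) and
#'   `interval` (the two grid points).
#' @export
locate_jump <- function(grid, values) {
  stopifnot(length(grid) == length(values), length(grid) >= 2,
            !is.unsorted(grid))
  dif <- abs(diff(values))
  i <- which.max(dif)
  list(midpoint = (grid[i] + grid[i + 1]) / 2, jump = dif[i],
       interval = c(grid[i], grid[i + 1]))
}
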