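#' Model parameters of the coupled awareness-epidemic dynamics
#'
#' All rates are per-step probabilities in `[0, 1]`.
#'
#' @param lambda_aware lambda: probability that an unaware node becomes aware
#'   through one aware contact on the awareness layer (SIS awareness only).
#' @param delta delta: probability that an aware node forgets (aware -> unaware).
#' @param beta_u beta^U: infection probability per infected contact for an
#'   unaware susceptible node.
#' @param beta_a beta^A: infection probability for an aware susceptible node;
#'   default 0 (complete immunity of aware nodes). Must satisfy
#'   `beta_a <= beta_u`.
#' @param mu mu: recovery probability of an infected node.
#' @param alpha alpha: local awareness threshold (threshold model only): an
#'   unaware node becomes aware when the fraction of aware contacts in the
#'   current snapshot reaches alpha.
#' @param awareness_model `"sis"` or `"threshold"`.
#' @param strict_threshold if `TRUE` (default), a contact ratio exactly equal
#'   to alpha makes the node aware (Heaviside H with H(0) = 0); if `FALSE`
#'   the ratio must strictly exceed alpha.
#' @return an object of class `model_params`.
#' @examples
#' model_params(lambda_aware = 0.8, delta = 0.2, beta_u = 0.1, mu = 0.2)
#' @export
model_params <- function(lambda_aware = 0.2, delta = 0.8, beta_u = 0.1,
                         beta_a = 0, mu = 0.2, alpha = 0.5,
                         awareness_model = c("sis", "threshold"),
                         strict_threshold = TRUE) {
  awareness_model <- match.arg(awareness_model)
  rates <- c(lambda_aware = lambda_aware, delta = delta, beta_u = beta_u,
             beta_a = beta_a, mu = mu, alpha = alpha)
  bad <- names(rates)[!is.finite(rates) | rates < 0 | rates > 1]
  if (length(bad))
    stop("parameter(s) out of [0, 1]: ", paste(bad, collapse = ", "))
  if (beta_a > beta_u)
    stop("`beta_a` must not exceed `beta_u` (awareness reduces infectivity)")
  structure(list(lambda_aware = lambda_aware, delta = delta, beta_u = beta_u,
                 beta_a = beta_a, mu = mu, alpha = alpha,
                 awareness_model = awareness_model,
                 strict_threshold = isTRUE(strict_threshold)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params [%s awareness]: lambda=%g delta=%g beta_u=%g beta_a=%g mu=%g%s\n",
    x$awareness_model, x$lambda_aware, x$delta, x$beta_u, x$beta_a, x$mu,
    if (x$awareness_model == "threshold") sprintf(" alpha=%g", x$alpha) else ""))
  invisible(x)
}

#' Monte Carlo / stationarity protocol
#'
#' @param rho0 initial infected fraction (default 0.2); the corresponding
#'   nodes start aware-infected, all others unaware-susceptible.
#' @param t0 burn-in: first step included in the time average (default 901).
#' @param window averaging window T (default 100); the stationary density is
#'   the mean over steps `t0 ... t0 + window - 1`.
#' @param n_runs number of independent replicates averaged (default 100).
#' @param seed master seed for the protocol.
#' @return an object of class `mc_protocol`.
#' @export
mc_protocol <- function(rho0 = 0.2, t0 = 901L, window = 100L, n_runs = 100L,
                        seed = 1L) {
  if (rho0 <= 0 || rho0 >= 1) stop("`rho0` must lie strictly in (0, 1)")
  if (t0 < 1 || window < 1 || n_runs < 1) stop("t0, window, n_runs must be >= 1")
  structure(list(rho0 = rho0, t0 = as.integer(t0), window = as.integer(window),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "mc_protocol")
}

#' Per-node state probabilities of the MMCA
#'
#' Holds the probability triplet (p^US, p^AS, p^AI) for every node; each
#' triplet sums to one.
#'
#' @param p_us,p_as,p_ai numeric vectors of equal length with entries in
#'   `[0, 1]` and per-node sums equal to 1 (tolerance 1e-9).
#' @return an object of class `state_probs`.
#' @export
state_probs <- function(p_us, p_as, p_ai) {
  n <- length(p_us)
  if (length(p_as) != n || length(p_ai) != n)
    stop("probability vectors must have equal length")
  if (any(p_us < -1e-12 | p_as < -1e-12 | p_ai < -1e-12) ||
      any(p_us > 1 + 1e-12 | p_as > 1 + 1e-12 | p_ai > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]")
  s <- p_us + p_as + p_ai
  if (max(abs(s - 1)) > 1e-9)
    stop("per-node probabilities must sum to 1 (max drift ",
         format(max(abs(s - 1))), ")")
  structure(list(p_us = p_us / s, p_as = p_as / s, p_ai = p_ai / s),
            class = "state_probs")
}

#' Initial MMCA state / MC seeding pattern
#'
#' Seeds `ceiling(rho0 * n)` randomly chosen nodes as aware-infected
#' (p^AI = 1); all remaining nodes start unaware-susceptible. Mirrors the MC
#' initialization so the two methods are comparable.
#'
#' @param n number of nodes.
#' @param rho0 initial infected fraction.
#' @param seed integer seed choosing the infected set.
#' @return a `state_probs` object.
#' @export
initial_state_probs <- function(n, rho0 = 0.2, seed = NULL) {
  idx <- sample_seed_nodes(n, rho0, seed)
  p_ai <- numeric(n); p_ai[idx] <- 1
  state_probs(p_us = 1 - p_ai, p_as = numeric(n), p_ai = p_ai)
}

sample_seed_nodes <- function(n, rho0, seed = NULL) {
  k <- min(n, max(1L, ceiling(rho0 * n)))
  if (is.null(seed)) sample.int(n, k) else with_seed(seed, sample.int(n, k))
}

#' @export
print.state_probs <- function(x, ...) {
  cat(sprintf("state_probs: N=%d, rho_I=%.4f, rho_A=%.4f\n",
              length(x$p_us), mean(x$p_ai), mean(x$p_as + x$p_ai)))
  invisible(x)
}
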