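#' Probability of staying unaware (SIS awareness)
#'
#' For each node i, `r_i = prod over snapshot contacts j of
#' (1 - p_j^A * lambda)`: the probability that none of i's current awareness
#' contacts transmits awareness this step. Nodes without contacts get r = 1.
#'
#' @param snapshot a `temporal_snapshot` of the awareness layer.
#' @param p_aware per-node awareness probabilities p^A in `[0, 1]`.
#' @param lambda_aware awareness transmission probability lambda.
#' @return numeric vector r of length N.
#' @export
stay_unaware_sis <- function(snapshot, p_aware, lambda_aware) {
  stopifnot(inherits(snapshot, "temporal_snapshot"),
            length(p_aware) == snapshot$n_nodes,
            lambda_aware >= 0, lambda_aware <= 1)
  n <- snapshot$n_nodes
  r <- rep(1, n)
  e <- snapshot$edges
  if (nrow(e) == 0L || lambda_aware == 0) return(r)
  idx <- c(e[, 1], e[, 2])
  nb <- c(e[, 2], e[, 1])
  lg <- log1p(-lambda_aware * p_aware[nb]) # -Inf when lambda * p == 1 -> r = 0
  s <- rowsum(lg, idx)
  r[as.integer(rownames(s))] <- exp(s[, 1])
  r
}

#' Probability of staying unaware (local threshold awareness)
#'
#' Heaviside rule: node i becomes aware (r_i = 0) when the mean awareness of
#' its current snapshot contacts, `sum_j p_j^A / k_i(t)`, reaches the local
#' threshold alpha; otherwise r_i = 1. A contact ratio exactly equal to alpha
#' triggers awareness when `strict = TRUE` (H(0) = 0), the default. Nodes
#' without contacts (k_i(t) = 0) stay unaware.
#'
#' @inheritParams stay_unaware_sis
#' @param alpha local awareness threshold in `[0, 1]`.
#' @param strict boundary convention, see Description.
#' @return numeric vector r with entries in `{0, 1}`.
#' @export
stay_unaware_threshold <- function(snapshot, p_aware, alpha, strict = TRUE) {
  stopifnot(inherits(snapshot, "temporal_snapshot"),
            length(p_aware) == snapshot$n_nodes,
            alpha >= 0, alpha <= 1)
  n <- snapshot$n_nodes
  r <- rep(1, n)
  e <- snapshot$edges
  if (nrow(e) == 0L) return(r)
  idx <- c(e[, 1], e[, 2])
  nb <- c(e[, 2], e[, 1])
  s <- rowsum(p_aware[nb], idx)
  nodes <- as.integer(rownames(s))
  ratio <- s[, 1] / snapshot$degrees[nodes]
  aware <- if (strict) ratio >= alpha else ratio > alpha
  r[nodes] <- as.numeric(!aware)
  r
}

# dispatch on the awareness model in params
stay_unaware <- function(snapshot, p_aware, params) {
  if (params$awareness_model == "sis")
    stay_unaware_sis(snapshot, p_aware, params$lambda_aware)
  else
    stay_unaware_threshold(snapshot, p_aware, params$alpha,
                           params$strict_threshold)
}

#' Probability of not being infected through the contagion layer
#'
#' `q_i = prod over static neighbors j of (1 - p_j^AI * beta)`. Called once
#' with beta^U (unaware) and once with beta^A (aware).
#'
#' @param static a `static_layer`.
#' @param p_ai per-node infection probabilities p^AI.
#' @param beta per-contact infection probability.
#' @return numeric vector q of length N.
#' @export
not_infected_probs <- function(static, p_ai, beta) {
  stopifnot(inherits(static, "static_layer"),
            length(p_ai) == static$n_nodes, beta >= 0, beta <= 1)
  if (beta == 0 || all(p_ai == 0)) return(rep(1, static$n_nodes))
  lg <- log1p(-beta * p_ai)
  exp(as.numeric(static$adjacency %*% lg))
}

#' One synchronous MMCA step of the coupled dynamics
#'
#' Applies the three-state update (probability tree with parallel updating)
#' simultaneously from the time-t state:
#' \deqn{p^{US}_{t+1} = p^{AI} \delta\mu + p^{US} r q^U + p^{AS} \delta q^U}
#' \deqn{p^{AS}_{t+1} = p^{AI} \mu(1-\delta) + p^{US}(1-r) q^A + p^{AS}(1-\delta) q^A}
#' \deqn{p^{AI}_{t+1} = p^{AI}(1-\mu) + p^{US}[(1-r)(1-q^A) + r(1-q^U)] +
#'        p^{AS}[\delta(1-q^U) + (1-\delta)(1-q^A)]}
#' A node that becomes aware within the step is already exposed at beta^A in
#' the same step (and an aware node that forgets at beta^U), per the
#' cross-terms above.
#'
#' @param state a `state_probs` object (time-t probabilities).
#' @param snapshot awareness-layer `temporal_snapshot` for this step.
#' @param static contagion `static_layer`.
#' @param params `model_params`.
#' @return the time-(t+1) `state_probs`.
#' @export
mmca_step <- function(state, snapshot, static, params) {
  stopifnot(inherits(state, "state_probs"), inherits(params, "model_params"))
  p_us <- state$p_us; p_as <- state$p_as; p_ai <- state$p_ai
  p_aware <- p_as + p_ai
  r <- stay_unaware(snapshot, p_aware, params)
  q_u <- not_infected_probs(static, p_ai, params$beta_u)
  q_a <- not_infected_probs(static, p_ai, params$beta_a)
  d <- params$delta; mu <- params$mu
  us_new <- p_ai * d * mu + p_us * r * q_u + p_as * d * q_u
  as_new <- p_ai * mu * (1 - d) + p_us * (1 - r) * q_a + p_as * (1 - d) * q_a
  ai_new <- p_ai * (1 - mu) +
    p_us * ((1 - r) * (1 - q_a) + r * (1 - q_u)) +
    p_as * (d * (1 - q_u) + (1 - d) * (1 - q_a))
  s <- us_new + as_new + ai_new
  drift <- max(abs(s - 1))
  if (drift > 1e-9)
    stop("internal error: MMCA normalization drift ", format(drift))
  structure(list(p_us = us_new / s, p_as = as_new / s, p_ai = ai_new / s),
            class = "state_probs")
}

# Expected (annealed) contact-probability matrix of the activity-driven layer:
# P_ij = probability that the unordered pair {i, j} is connected in a snapshot.
annealed_contact_matrix <- function(layer) {
  n <- layer$n_nodes
  if (n > 4000)
    stop("annealed contact matrix is dense; refusing n_nodes > 4000")
  p <- layer$act_prob * layer$m / (n - 1)
  pm <- outer(p, p, function(a, b) a + b - a * b)
  diag(pm) <- 0
  pm
}

# Annealed analogues of the stay-unaware probabilities (optional mode):
# expectations taken over the snapshot ensemble instead of one realization.
stay_unaware_annealed <- function(pmat, p_aware, params) {
  if (params$awareness_model == "sis") {
    if (params$lambda_aware == 0) return(rep(1, nrow(pmat)))
    exp(rowSums(log1p(-params$lambda_aware * pmat *
                        rep(p_aware, each = nrow(pmat)))))
  } else {
    k <- rowSums(pmat)
    ratio <- as.numeric(pmat %*% p_aware) / ifelse(k > 0, k, 1)
    aware <- if (params$strict_threshold) ratio >= params$alpha
             else ratio > params$alpha
    as.numeric(!(aware & k > 0))
  }
}

#' Iterate the MMCA to its stochastic stationary state
#'
#' Runs `t0 + window - 1` synchronous MMCA steps, drawing a fresh
#' activity-driven snapshot at every step (the awareness layer is deleted and
#' regenerated each time step). Because the layer is time-varying, the
#' stationary state is a stochastic steady state; it is summarized by the
#' time average over steps `t0 ... t0 + window - 1`.
#'
#' @param initial a `state_probs` starting state, e.g.
#'   [initial_state_probs()].
#' @param layer awareness `activity_layer`.
#' @param static contagion `static_layer`.
#' @param params `model_params`.
#' @param t0 burn-in (default 901).
#' @param window averaging window T (default 100).
#' @param seed integer seed governing the snapshot sequence.
#' @param contact_mode `"snapshot"` (default): one realized snapshot per
#'   step; `"annealed"`: expected contact matrix instead of realizations.
#' @return a list with `state_mean` (per-node probabilities averaged over the
#'   window, `state_probs`), `state_final`, `rho_i_trace` and `rho_a_trace`
#'   (length `t0 + window - 1`), `rho_i` and `rho_a` (window means).
#' @export
iterate_to_stationarity <- function(initial, layer, static, params,
                                    t0 = 901L, window = 100L, seed = 1L,
                                    contact_mode = c("snapshot", "annealed")) {
  contact_mode <- match.arg(contact_mode)
  stopifnot(t0 >= 1, window >= 1)
  n <- layer$n_nodes
  total <- t0 + window - 1L
  rho_i <- numeric(total); rho_a <- numeric(total)
  acc_us <- numeric(n); acc_as <- numeric(n); acc_ai <- numeric(n)
  state <- initial
  pmat <- if (contact_mode == "annealed") annealed_contact_matrix(layer)
  run <- function() {
    for (t in seq_len(total)) {
      if (contact_mode == "snapshot") {
        sn <- generate_snapshot(layer, time_index = t)
        state <<- mmca_step(state, sn, static, params)
      } else {
        state <<- mmca_step_annealed(state, pmat, static, params)
      }
      rho_i[t] <<- mean(state$p_ai)
      rho_a[t] <<- mean(state$p_as + state$p_ai)
      if (t >= t0) {
        acc_us <<- acc_us + state$p_us
        acc_as <<- acc_as + state$p_as
        acc_ai <<- acc_ai + state$p_ai
      }
    }
  }
  with_seed(seed, run())
  list(state_mean = state_probs(acc_us / window, acc_as / window,
                                acc_ai / window),
       state_final = state,
       rho_i_trace = rho_i, rho_a_trace = rho_a,
       rho_i = mean(rho_i[t0:total]), rho_a = mean(rho_a[t0:total]))
}

# annealed-mode step: same tree, expected contacts for the awareness layer
mmca_step_annealed <- function(state, pmat, static, params) {
  p_us <- state$p_us; p_as <- state$p_as; p_ai <- state$p_ai
  r <- stay_unaware_annealed(pmat, p_as + p_ai, params)
  q_u <- not_infected_probs(static, p_ai, params$beta_u)
  q_a <- not_infected_probs(static, p_ai, params$beta_a)
  d <- params$delta; mu <- params$mu
  us_new <- p_ai * d * mu + p_us * r * q_u + p_as * d * q_u
  as_new <- p_ai * mu * (1 - d) + p_us * (1 - r) * q_a + p_as * (1 - d) * q_a
  ai_new <- p_ai * (1 - mu) +
    p_us * ((1 - r) * (1 - q_a) + r * (1 - q_u)) +
    p_as * (d * (1 - q_u) + (1 - d) * (1 - q_a))
  s <- us_new + as_new + ai_new
  structure(list(p_us = us_new / s, p_as = as_new / s, p_ai = ai_new / s),
            class = "state_probs")
}

#' Stationary infected density curve of the MMCA over an infection-rate grid
#'
#' Convenience scan used for threshold location: for each beta in
#' `beta_grid`, iterates the MMCA to stationarity and records the
#' time-averaged infected density rho^I.
#'
#' @inheritParams iterate_to_stationarity
#' @param beta_grid ascending vector of beta^U values.
#' @param protocol an [mc_protocol()] (rho0, t0, window and seed are used).
#' @param stop_after_crossing if not `NULL`, stop scanning once rho^I exceeds
#'   this level (remaining grid values are returned as `NA`); speeds up
#'   threshold location.
#' @return data.frame with columns `beta` and `rho_i`.
#' @export
mmca_rho_curve <- function(layer, static, params, beta_grid,
                           protocol = mc_protocol(),
                           stop_after_crossing = NULL) {
  stopifnot(!is.unsorted(beta_grid))
  rho <- rep(NA_real_, length(beta_grid))
  init <- initial_state_probs(layer$n_nodes, protocol$rho0,
                              seed = derive_seed(protocol$seed, 100L))
  for (b in seq_along(beta_grid)) {
    p <- params
    p$beta_u <- beta_grid[b]
    if (p$beta_a > p$beta_u) p$beta_a <- p$beta_u
    res <- iterate_to_stationarity(init, layer, static, p,
                                   t0 = protocol$t0, window = protocol$window,
                                   seed = derive_seed(protocol$seed, 200L + b))
    rho[b] <- res$rho_i
    if (!is.null(stop_after_crossing) && rho[b] > stop_after_crossing) break
  }
  data.frame(beta = beta_grid, rho_i = rho)
}
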