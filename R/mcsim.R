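# Node states are encoded as integers: 0 = US (unaware susceptible),
# 1 = AS (aware susceptible), 2 = AI (aware infected). Infection always
# implies awareness, so "unaware infected" cannot be represented.

#' Construct a Monte Carlo population
#'
#' @param states integer vector with entries 0 (US), 1 (AS), 2 (AI).
#' @param time_index current time step.
#' @return an object of class `mc_population`.
#' @export
mc_population <- function(states, time_index = 0L) {
  states <- as.integer(states)
  if (any(states < 0L | states > 2L)) stop("states must be 0 (US), 1 (AS) or 2 (AI)")
  structure(list(states = states, time_index = as.integer(time_index)),
            class = "mc_population")
}

#' @export
print.mc_population <- function(x, ...) {
  tab <- tabulate(x$states + 1L, nbins = 3L)
  cat(sprintf("mc_population: N=%d t=%d | US=%d AS=%d AI=%d\n",
              length(x$states), x$time_index, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Seed an initial population
#'
#' `ceiling(rho0 * n)` randomly chosen nodes start aware-infected, all other
#' nodes unaware-susceptible.
#'
#' @param n number of nodes.
#' @param rho0 initial infected fraction.
#' @param seed integer seed.
#' @return an `mc_population`.
#' @export
initial_population <- function(n, rho0 = 0.2, seed = NULL) {
  st <- integer(n)
  st[sample_seed_nodes(n, rho0, seed)] <- 2L
  mc_population(st)
}

#' One synchronous Monte Carlo step of the coupled dynamics
#'
#' Parallel update from the time-t configuration, mirroring the probability
#' tree of the MMCA:
#' * AI nodes recover with probability mu; a recovered node forgets with
#'   probability delta (-> US) else stays aware (-> AS). Nodes recovering
#'   this step are not re-exposed within the step.
#' * US nodes first resolve awareness from their snapshot contacts (SIS: each
#'   aware contact transmits independently with probability lambda;
#'   threshold model: deterministic rule on the realized fraction of aware
#'   contacts), then face infection from infected static-layer neighbors at
#'   rate beta^A if now aware, beta^U otherwise.
#' * AS nodes forget with probability delta and are then exposed at beta^U
#'   this same step, otherwise remain aware and are exposed at beta^A.
#' * Any infection forces the AI state (infection implies awareness).
#'
#' @param pop `mc_population` at time t.
#' @param snapshot awareness-layer `temporal_snapshot` for this step.
#' @param static contagion `static_layer`.
#' @param params `model_params`.
#' @return the `mc_population` at time t+1.
#' @export
mc_step <- function(pop, snapshot, static, params) {
  stopifnot(inherits(pop, "mc_population"), inherits(params, "model_params"))
  st <- pop$states
  n <- length(st)
  aware <- st >= 1L
  infected <- st == 2L

  # --- awareness resolution for susceptible nodes (from time-t states) ---
  aware_now <- aware # post-awareness, pre-infection awareness indicator
  e <- snapshot$edges
  if (nrow(e) > 0L && any(!aware)) {
    idx <- c(e[, 1], e[, 2]); nb <- c(e[, 2], e[, 1])
    cnt <- rowsum(as.numeric(aware[nb]), idx)
    nodes <- as.integer(rownames(cnt))
    if (params$awareness_model == "sis") {
      p_aw <- 1 - (1 - params$lambda_aware)^cnt[, 1]
      hit <- stats::runif(length(nodes)) < p_aw
    } else {
      ratio <- cnt[, 1] / snapshot$degrees[nodes]
      hit <- if (params$strict_threshold) ratio >= params$alpha
             else ratio > params$alpha
    }
    gained <- nodes[hit & !aware[nodes]]
    aware_now[gained] <- TRUE
  }
  # AS nodes forgetting (resolved before infection exposure, per the tree)
  as_idx <- which(st == 1L)
  forgot <- logical(n)
  if (length(as_idx)) {
    f <- stats::runif(length(as_idx)) < params$delta
    forgot[as_idx[f]] <- TRUE
    aware_now[as_idx[f]] <- FALSE
  }

  # --- infection of susceptible nodes from time-t infected neighbors ---
  new_st <- st
  sus <- st != 2L
  if (any(infected) && any(sus)) {
    n_inf <- as.numeric(static$adjacency %*% as.numeric(infected))
    beta_i <- ifelse(aware_now, params$beta_a, params$beta_u)
    p_inf <- 1 - (1 - beta_i)^n_inf
    got <- sus & (stats::runif(n) < p_inf)
    new_st[got] <- 2L
  } else got <- logical(n)

  # susceptible nodes not infected keep their post-awareness status
  keep <- sus & !got
  new_st[keep] <- ifelse(aware_now[keep], 1L, 0L)

  # --- recovery of time-t infected nodes ---
  ai_idx <- which(infected)
  if (length(ai_idx)) {
    rec <- stats::runif(length(ai_idx)) < params$mu
    rec_idx <- ai_idx[rec]
    if (length(rec_idx)) {
      fg <- stats::runif(length(rec_idx)) < params$delta
      new_st[rec_idx] <- ifelse(fg, 0L, 1L)
    }
  }
  mc_population(new_st, pop$time_index + 1L)
}

#' Bundle the two layers of the multiplex
#'
#' @param awareness an `activity_layer` (time-varying awareness layer) or a
#'   fixed `temporal_snapshot` (static awareness layer), or `NULL` for no
#'   awareness layer (single-layer epidemic).
#' @param static contagion `static_layer`.
#' @return an object of class `multiplex`.
#' @export
multiplex <- function(awareness, static) {
  stopifnot(inherits(static, "static_layer"))
  if (!is.null(awareness) &&
      !inherits(awareness, c("activity_layer", "temporal_snapshot")))
    stop("`awareness` must be an activity_layer, temporal_snapshot or NULL")
  if (!is.null(awareness) && awareness$n_nodes != static$n_nodes)
    stop("layers must have the same number of nodes")
  structure(list(awareness = awareness, static = static,
                 n_nodes = static$n_nodes), class = "multiplex")
}

empty_snapshot <- function(n) new_snapshot(n, integer(0))

#' Run replicated Monte Carlo simulations of the coupled dynamics
#'
#' Each replicate seeds `ceiling(rho0 * N)` infected (aware) nodes, then
#' iterates [mc_step()] with parallel updating, regenerating the awareness
#' snapshot at every step when the awareness layer is time-varying (a fixed
#' snapshot is reused as-is). Densities are time-averaged over steps
#' `t0 ... t0 + window - 1` and averaged over replicates.
#'
#' @param mplex a [multiplex()].
#' @param params `model_params`.
#' @param protocol an [mc_protocol()].
#' @param stop_when_extinct if `TRUE`, a replicate stops early once no node
#'   is infected; remaining trace entries are zero-filled (the infected
#'   density is exactly 0 from then on; awareness bookkeeping is also
#'   truncated). Intended for threshold scans where only rho^I matters.
#' @param keep_traces keep the full per-step traces (default `TRUE`); switch
#'   off in large scans to save memory.
#' @return list with `rho_i_mean`, `rho_a_mean` (replicate means of the
#'   time-averaged densities), `rho_i_runs`, `rho_a_runs` (per-replicate
#'   values) and `traces`, a data.frame (run, t, rho_i, rho_a).
#' @export
run_simulation <- function(mplex, params, protocol = mc_protocol(),
                           stop_when_extinct = FALSE, keep_traces = TRUE) {
  stopifnot(inherits(mplex, "multiplex"), inherits(protocol, "mc_protocol"))
  n <- mplex$n_nodes
  total <- protocol$t0 + protocol$window - 1L
  tv <- inherits(mplex$awareness, "activity_layer")
  fixed_sn <- if (!tv && !is.null(mplex$awareness)) mplex$awareness
              else if (is.null(mplex$awareness)) empty_snapshot(n)
  rho_i_runs <- numeric(protocol$n_runs)
  rho_a_runs <- numeric(protocol$n_runs)
  traces <- if (keep_traces) vector("list", protocol$n_runs)
  for (run in seq_len(protocol$n_runs)) {
    rseed <- derive_seed(protocol$seed, 1000L + run)
    tr_i <- numeric(total); tr_a <- numeric(total)
    run_one <- function() {
      pop <- initial_population(n, protocol$rho0)
      for (t in seq_len(total)) {
        sn <- if (tv) generate_snapshot(mplex$awareness, time_index = t)
              else fixed_sn
        pop <- mc_step(pop, sn, mplex$static, params)
        tr_i[t] <<- mean(pop$states == 2L)
        tr_a[t] <<- mean(pop$states >= 1L)
        if (stop_when_extinct && tr_i[t] == 0) break
      }
    }
    with_seed(rseed, run_one())
    idx <- protocol$t0:total
    rho_i_runs[run] <- mean(tr_i[idx])
    rho_a_runs[run] <- mean(tr_a[idx])
    if (keep_traces)
      traces[[run]] <- data.frame(run = run, t = seq_len(total),
                                  rho_i = tr_i, rho_a = tr_a)
  }
  list(rho_i_mean = mean(rho_i_runs), rho_a_mean = mean(rho_a_runs),
       rho_i_runs = rho_i_runs, rho_a_runs = rho_a_runs,
       traces = if (keep_traces) do.call(rbind, traces))
}

#' Locate the epidemic threshold on a density curve
#'
#' First-crossing operationalization: the smallest grid beta whose
#' time-averaged infected density exceeds the detection level `epsilon`.
#'
#' @param beta_grid ascending beta values.
#' @param rho_curve stationary rho^I at each beta (`NA` entries, e.g. from a
#'   truncated scan, are treated as not yet computed and ignored after the
#'   first crossing).
#' @param epsilon detection level (default 0.005).
#' @return list with `beta_c` (NA if the curve never exceeds epsilon),
#'   `uncertainty` (half the local grid spacing) and `index`.
#' @export
estimate_mc_threshold <- function(beta_grid, rho_curve, epsilon = 0.005) {
  stopifnot(length(beta_grid) == length(rho_curve), !is.unsorted(beta_grid))
  idx <- which(!is.na(rho_curve) & rho_curve > epsilon)
  if (length(idx) == 0L)
    return(list(beta_c = NA_real_, uncertainty = NA_real_, index = NA_integer_))
  i <- idx[1]
  half <- if (i > 1) (beta_grid[i] - beta_grid[i - 1]) / 2
          else if (length(beta_grid) > 1) (beta_grid[2] - beta_grid[1]) / 2
          else NA_real_
  list(beta_c = beta_grid[i], uncertainty = half, index = i)
}

#' Monte Carlo infected-density curve over an infection-rate grid
#'
#' For each beta in `beta_grid` runs `protocol$n_runs` replicates and records
#' the replicate-averaged stationary infected density. Scanning can stop
#' early once the detection level is crossed (remaining entries `NA`).
#'
#' @inheritParams run_simulation
#' @param beta_grid ascending vector of beta^U values.
#' @param stop_after_crossing detection level at which to stop scanning, or
#'   `NULL` to compute the full curve.
#' @return data.frame with columns `beta`, `rho_i`, `rho_a`.
#' @export
mc_rho_curve <- function(mplex, params, beta_grid, protocol = mc_protocol(),
                         stop_after_crossing = NULL) {
  stopifnot(!is.unsorted(beta_grid))
  rho_i <- rep(NA_real_, length(beta_grid))
  rho_a <- rep(NA_real_, length(beta_grid))
  for (b in seq_along(beta_grid)) {
    p <- params
    p$beta_u <- beta_grid[b]
    if (p$beta_a > p$beta_u) p$beta_a <- p$beta_u
    prot <- protocol
    prot$seed <- derive_seed(protocol$seed, 5000L + b)
    res <- run_simulation(mplex, p, prot,
                          stop_when_extinct = !is.null(stop_after_crossing),
                          keep_traces = FALSE)
    rho_i[b] <- res$rho_i_mean
    rho_a[b] <- res$rho_a_mean
    if (!is.null(stop_after_crossing) && rho_i[b] > stop_after_crossing) break
  }
  data.frame(beta = beta_grid, rho_i = rho_i, rho_a = rho_a)
}
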