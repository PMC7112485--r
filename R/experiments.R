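#' Monte Carlo phase diagram with MMCA threshold overlay
#'
#' Computes the time-averaged infected density rho^I over a 2-D grid of the
#' infection probability beta (x axis) and an awareness parameter (lambda for
#' SIS awareness, alpha for the threshold model; y axis), plus the MMCA
#' spectral threshold beta_c for every y value.
#'
#' @param mplex a [multiplex()] with a time-varying awareness layer.
#' @param params baseline `model_params` (fixes mu, delta and the awareness
#'   model).
#' @param beta_grid,y_grid ascending grids within `[0, 1]`.
#' @param protocol [mc_protocol()]; `n_runs` replicates per grid cell.
#' @param t0_aware,window_aware protocol of the epidemic-free awareness runs
#'   that feed the MMCA threshold curve (defaults follow `protocol`).
#' @return an object of class `phase_diagram`: `beta_grid`, `y_grid`,
#'   `y_param`, `rho_grid` (length(y) x length(beta) matrix),
#'   `mmca_threshold_curve` (data.frame from [threshold_curve()]), `meta`
#'   (params, protocol, N).
#' @export
phase_diagram <- function(mplex, params, beta_grid, y_grid,
                          protocol = mc_protocol(),
                          t0_aware = protocol$t0,
                          window_aware = protocol$window) {
  stopifnot(inherits(mplex, "multiplex"),
            inherits(mplex$awareness, "activity_layer"))
  y_param <- if (params$awareness_model == "sis") "lambda" else "alpha"
  rho <- matrix(NA_real_, length(y_grid), length(beta_grid),
                dimnames = list(format(y_grid), format(beta_grid)))
  for (yi in seq_along(y_grid)) {
    p <- params
    if (y_param == "lambda") p$lambda_aware <- y_grid[yi] else p$alpha <- y_grid[yi]
    prot <- protocol
    prot$seed <- derive_seed(protocol$seed, 20000L + yi)
    curve <- mc_rho_curve(mplex, p, beta_grid, prot)
    rho[yi, ] <- curve$rho_i
  }
  thr <- threshold_curve(mplex$awareness, mplex$static, params,
                         over = if (y_param == "lambda") "lambda" else "alpha",
                         grid = y_grid, t0 = t0_aware, window = window_aware,
                         seed = derive_seed(protocol$seed, 21000L))
  structure(list(beta_grid = beta_grid, y_grid = y_grid, y_param = y_param,
                 rho_grid = rho, mmca_threshold_curve = thr,
                 meta = list(params = params, protocol = protocol,
                             n_nodes = mplex$n_nodes)),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram: %d x %d grid (beta x %s), N=%d, %d runs/cell\n",
              length(x$beta_grid), length(x$y_grid), x$y_param,
              x$meta$n_nodes, x$meta$protocol$n_runs))
  invisible(x)
}

#' Compare epidemic spreading across network scenarios
#'
#' MC infected-density curves rho^I(beta) for three conditions sharing the
#' same contagion layer: (i) single-layer SIS (no awareness), (ii) the
#' time-varying multiplex, (iii) a static multiplex whose awareness layer is
#' a time-aggregate of the activity-driven process.
#'
#' @param mplex time-varying [multiplex()].
#' @param params `model_params`.
#' @param beta_grid ascending beta values.
#' @param protocol [mc_protocol()].
#' @param static_mode `"aggregate"` (default): the static awareness layer is
#'   the union of `aggregate_window` snapshots; `"single"`: one realized
#'   snapshot held fixed.
#' @param aggregate_window snapshots unioned in `"aggregate"` mode
#'   (default 20).
#' @return data.frame with columns `scenario` (`single`, `time_varying`,
#'   `static_multiplex`), `beta`, `rho_i`, `rho_a`.
#' @export
compare_models <- function(mplex, params, beta_grid,
                           protocol = mc_protocol(),
                           static_mode = c("aggregate", "single"),
                           aggregate_window = 20L) {
  static_mode <- match.arg(static_mode)
  stopifnot(inherits(mplex$awareness, "activity_layer"))
  frozen <- if (static_mode == "aggregate")
    aggregate_snapshots(mplex$awareness, aggregate_window,
                        seed = derive_seed(protocol$seed, 30000L))
  else generate_snapshot(mplex$awareness,
                         seed = derive_seed(protocol$seed, 30000L))
  # single layer: awareness machinery inert (lambda = 0, immediate forgetting)
  p_single <- params
  p_single$lambda_aware <- 0; p_single$delta <- 1
  p_single$awareness_model <- "sis"
  scen <- list(
    single = list(mp = multiplex(NULL, mplex$static), p = p_single),
    time_varying = list(mp = mplex, p = params),
    static_multiplex = list(mp = multiplex(frozen, mplex$static), p = params))
  out <- lapply(names(scen), function(nm) {
    prot <- protocol
    prot$seed <- derive_seed(protocol$seed, 31000L + match(nm, names(scen)))
    cv <- mc_rho_curve(scen[[nm]]$mp, scen[[nm]]$p, beta_grid, prot)
    cbind(scenario = nm, cv)
  })
  do.call(rbind, out)
}

#' Fluctuation-ratio analysis over the activity-driven link parameter m
#'
#' For each m, rebuilds the awareness layer (same activity potentials, m
#' links per activation), measures the stationary final epidemic size
#' f(m) = rho^I by MC simulation at fixed parameters, and reports the
#' fluctuation ratio relative to the baseline `FR(m) = (f(m) - f(m0)) / f(m0)`
#' with m0 = 4.
#'
#' @param mplex time-varying [multiplex()] (its awareness potentials and
#'   static layer are reused for every m).
#' @param params `model_params` (beta_u is the fixed infection probability).
#' @param m_values integer vector of m settings; must contain the baseline.
#' @param baseline_m baseline m (default 4).
#' @param protocol [mc_protocol()].
#' @return an object of class `fluctuation_report`: data.frame `results`
#'   (m, final_size, fr) plus `baseline_m`. FR is `NA` with a message when
#'   the baseline final size is 0.
#' @export
fluctuation_ratio <- function(mplex, params, m_values = c(4, 7, 10, 20),
                              baseline_m = 4, protocol = mc_protocol()) {
  stopifnot(inherits(mplex$awareness, "activity_layer"))
  if (!baseline_m %in% m_values)
    stop("`m_values` must include the baseline m = ", baseline_m)
  lay0 <- mplex$awareness
  f <- vapply(seq_along(m_values), function(i) {
    lay <- activity_layer(lay0$n_nodes, gamma = lay0$gamma, xi = lay0$xi,
                          eta = lay0$eta, m = m_values[i],
                          potentials = lay0$potentials)
    prot <- protocol
    prot$seed <- derive_seed(protocol$seed, 40000L + i)
    run_simulation(multiplex(lay, mplex$static), params, prot,
                   keep_traces = FALSE)$rho_i_mean
  }, numeric(1))
  f0 <- f[match(baseline_m, m_values)]
  fr <- if (f0 > 0) (f - f0) / f0 else {
    message("baseline final size f(", baseline_m, ") = 0: FR undefined")
    rep(NA_real_, length(f))
  }
  structure(list(results = data.frame(m = m_values, final_size = f, fr = fr),
                 baseline_m = baseline_m),
            class = "fluctuation_report")
}

#' @export
print.fluctuation_report <- function(x, ...) {
  cat("fluctuation_report (baseline m =", x$baseline_m, ")\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Threshold-difference map over the (mu, delta) plane
#'
#' For every (mu, delta) cell, the MMCA spectral epidemic threshold at the
#' awareness-favoring parameter setting minus the threshold at the
#' unfavoring setting (SIS awareness: lambda = high minus lambda = low;
#' threshold model: alpha = low minus alpha = high, since small alpha favors
#' awareness). The stationary awareness depends only on (delta, awareness
#' parameter), so it is computed once per delta and the mu dependence
#' `beta_c = mu / Lambda_max` is applied analytically.
#'
#' @param mplex time-varying [multiplex()].
#' @param params baseline `model_params` (fixes the awareness model).
#' @param mu_grid,delta_grid grids within `[0, 1]`.
#' @param favoring,unfavoring the two awareness-parameter values compared
#'   (defaults: lambda 0.8 vs 0.2 for SIS; alpha 0.2 vs 0.8 for the
#'   threshold model).
#' @param t0,window,seed stationary-awareness protocol.
#' @return matrix (length(mu_grid) x length(delta_grid)) of threshold
#'   differences, with `mu_grid`/`delta_grid` as dimnames.
#' @export
threshold_difference_map <- function(mplex, params, mu_grid, delta_grid,
                                     favoring = NULL, unfavoring = NULL,
                                     t0 = 901L, window = 100L, seed = 1L) {
  stopifnot(inherits(mplex$awareness, "activity_layer"))
  sis <- params$awareness_model == "sis"
  if (is.null(favoring)) favoring <- if (sis) 0.8 else 0.2
  if (is.null(unfavoring)) unfavoring <- if (sis) 0.2 else 0.8
  lam_fav <- numeric(length(delta_grid))
  lam_unf <- numeric(length(delta_grid))
  for (di in seq_along(delta_grid)) {
    for (which in c("fav", "unf")) {
      p <- params
      p$delta <- delta_grid[di]
      val <- if (which == "fav") favoring else unfavoring
      if (sis) p$lambda_aware <- val else p$alpha <- val
      pa <- stationary_awareness(mplex$awareness, p, t0 = t0, window = window,
                                 seed = derive_seed(seed, 50000L + di))
      lam <- largest_eigenvalue_h(mplex$static, as.numeric(pa))
      if (which == "fav") lam_fav[di] <- lam else lam_unf[di] <- lam
    }
  }
  out <- outer(mu_grid, seq_along(delta_grid), function(mu, di) {
    bc_fav <- ifelse(lam_fav[di] > 0, mu / lam_fav[di], Inf)
    bc_unf <- ifelse(lam_unf[di] > 0, mu / lam_unf[di], Inf)
    bc_fav - bc_unf
  })
  dimnames(out) <- list(mu = format(mu_grid), delta = format(delta_grid))
  out
}

#' Heatmap of a phase diagram (requires ggplot2)
#'
#' @param x a `phase_diagram`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_phase_diagram <- function(x, ...) {
  stopifnot(inherits(x, "phase_diagram"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- expand.grid(y = x$y_grid, beta = x$beta_grid)
  df$rho_i <- as.vector(x$rho_grid)
  thr <- x$mmca_threshold_curve
  ggplot2::ggplot(df, ggplot2::aes(x = beta, y = y, fill = rho_i)) +
    ggplot2::geom_tile() +
    ggplot2::geom_path(
      data = data.frame(beta = thr$beta_c, y = thr$param),
      ggplot2::aes(x = beta, y = y), inherit.aes = FALSE,
      linetype = "dashed", colour = "green") +
    ggplot2::labs(x = "infection probability beta",
                  y = if (x$y_param == "lambda") "awareness probability lambda"
                      else "local threshold alpha",
                  fill = expression(rho^I))
}
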