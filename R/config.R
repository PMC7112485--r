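#' Default run configuration
#'
#' Nested list of the standard study conditions: N = 5000 nodes, awareness
#' layer with gamma = 3, xi = 1e-3, eta = 10, m = 8, scale-free contagion
#' layer with minimum degree 2, SIS awareness with lambda = 0.2, delta = 0.8,
#' beta^A = 0, mu = 0.2, and the MC protocol rho0 = 0.2, t0 = 901, T = 100,
#' 100 replicates.
#'
#' @return a `run_config` object (nested named list).
#' @export
default_config <- function() {
  structure(list(
    network = list(n_nodes = 5000L, gamma = 3, xi = 1e-3, eta = 10, m = 8L,
                   sf_min_degree = 2L, sf_exponent = 3),
    dynamics = list(lambda_aware = 0.2, delta = 0.8, beta_u = 0.1, beta_a = 0,
                    mu = 0.2, alpha = 0.5, awareness_model = "sis"),
    protocol = list(rho0 = 0.2, t0 = 901L, window = 100L, n_runs = 100L),
    master_seed = 1L), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Missing keys are filled from [default_config()]; rate parameters are
#' validated to lie in `[0, 1]`. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `run_config` object.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file must contain a YAML mapping")
    for (section in names(user)) {
      if (section == "master_seed") { cfg$master_seed <- user[[section]]; next }
      if (!section %in% names(cfg))
        stop("unknown config section: ", section)
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]]))
          stop("unknown config key: ", section, ".", key)
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
  }
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  d <- cfg$dynamics
  rates <- c(lambda_aware = d$lambda_aware, delta = d$delta, beta_u = d$beta_u,
             beta_a = d$beta_a, mu = d$mu, alpha = d$alpha)
  bad <- names(rates)[!is.finite(rates) | rates < 0 | rates > 1]
  if (length(bad))
    stop("config value out of [0, 1] for: ",
         paste0("dynamics.", bad, collapse = ", "))
  if (!d$awareness_model %in% c("sis", "threshold"))
    stop("dynamics.awareness_model must be 'sis' or 'threshold'")
  nw <- cfg$network
  if (nw$n_nodes < 10) stop("network.n_nodes must be >= 10")
  if (nw$xi <= 0 || nw$xi >= 1) stop("network.xi must lie in (0, 1)")
  if (nw$gamma <= 1) stop("network.gamma must be > 1")
  if (nw$m < 1 || nw$m >= nw$n_nodes) stop("network.m out of range")
  pr <- cfg$protocol
  if (pr$rho0 <= 0 || pr$rho0 >= 1) stop("protocol.rho0 must lie in (0, 1)")
  if (pr$t0 < 1 || pr$window < 1 || pr$n_runs < 1)
    stop("protocol.t0, window and n_runs must be >= 1")
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build the model objects described by a configuration
#'
#' @param cfg a `run_config`.
#' @param seed optional override of `cfg$master_seed`.
#' @return list with `layer` (activity layer), `static` (contagion layer),
#'   `mplex`, `params`, `protocol`.
#' @export
build_from_config <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  master <- if (is.null(seed)) cfg$master_seed else seed
  nw <- cfg$network; d <- cfg$dynamics; pr <- cfg$protocol
  layer <- activity_layer(nw$n_nodes, gamma = nw$gamma, xi = nw$xi,
                          eta = nw$eta, m = nw$m,
                          seed = derive_seed(master, 1L))
  static <- generate_scale_free(nw$n_nodes, exponent = nw$sf_exponent,
                                min_degree = nw$sf_min_degree,
                                seed = derive_seed(master, 2L))
  params <- model_params(lambda_aware = d$lambda_aware, delta = d$delta,
                         beta_u = d$beta_u, beta_a = d$beta_a, mu = d$mu,
                         alpha = d$alpha, awareness_model = d$awareness_model)
  protocol <- mc_protocol(rho0 = pr$rho0, t0 = pr$t0, window = pr$window,
                          n_runs = pr$n_runs, seed = derive_seed(master, 3L))
  list(layer = layer, static = static, mplex = multiplex(layer, static),
       params = params, protocol = protocol, master_seed = master)
}
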