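test_that("stay-unaware probabilities follow the contact products", {
  sn <- snapshot_from_edges(4, rbind(c(1, 2)))
  # isolated nodes keep r = 1; a single certainly-aware neighbor gives 1 - lambda
  r <- stay_unaware_sis(sn, c(0, 1, 0, 0), 0.3)
  expect_equal(r, c(0.7, 1, 1, 1))
  # two neighbors at p^A = 0.5, lambda = 0.4: (1 - 0.2)^2
  sn2 <- snapshot_from_edges(3, rbind(c(1, 2), c(1, 3)))
  expect_equal(stay_unaware_sis(sn2, c(0, 0.5, 0.5), 0.4)[1], 0.64)
  expect_equal(stay_unaware_sis(sn2, c(0, 0, 0), 0.9), rep(1, 3))
})

test_that("threshold awareness rule implements the Heaviside ratio", {
  # degree-4 node (node 1) with 2 certainly-aware contacts, alpha = 0.5:
  # ratio 0.5 -> aware (H(0) = 0)
  sn <- snapshot_from_edges(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  pa2 <- c(0, 1, 1, 0, 0)
  expect_equal(stay_unaware_threshold(sn, pa2, 0.5)[1], 0)
  # one aware contact of four: ratio 0.25 < 0.5 -> stays unaware
  pa1 <- c(0, 1, 0, 0, 0)
  expect_equal(stay_unaware_threshold(sn, pa1, 0.5)[1], 1)
  # non-strict boundary: ratio == alpha no longer triggers
  expect_equal(stay_unaware_threshold(sn, pa2, 0.5, strict = FALSE)[1], 1)
  # isolated node never gains awareness through contacts
  sn_iso <- snapshot_from_edges(3, rbind(c(1, 2)))
  expect_equal(stay_unaware_threshold(sn_iso, c(1, 1, 1), 0.1)[3], 1)
})

test_that("contagion-layer escape probabilities multiply per neighbor", {
  net <- static_from_edges(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(not_infected_probs(net, c(0, 0, 0), 0.7), rep(1, 3))
  expect_equal(not_infected_probs(net, c(0.4, 0.2, 0.9), 0), rep(1, 3))
  # single neighbor with p^AI = 0.5 at beta = 0.4 -> 0.8
  q <- not_infected_probs(net, c(0, 0.5, 0), 0.4)
  expect_equal(q[1], 0.8)
  expect_equal(q[2], 1)
  expect_equal(q[3], 0.8)
})

test_that("one MMCA step conserves probability and matches limiting cases", {
  mp <- small_multiplex(n = 80, seed = 3)
  sn <- generate_snapshot(mp$awareness, seed = 4)
  # all transitions off: identity dynamics
  p0 <- model_params(lambda_aware = 0, delta = 0, beta_u = 0, beta_a = 0,
                     mu = 0)
  st <- random_state(80, seed = 5)
  out <- mmca_step(st, sn, mp$static, p0)
  expect_equal(out$p_ai, st$p_ai, tolerance = 1e-14)
  expect_equal(out$p_us, st$p_us, tolerance = 1e-14)
  # everyone infected, certain recovery and forgetting: p^US = delta * mu = 1
  p1 <- model_params(lambda_aware = 0.3, delta = 1, beta_u = 0.5, mu = 1)
  st1 <- state_probs(numeric(80), numeric(80), rep(1, 80))
  out1 <- mmca_step(st1, sn, mp$static, p1)
  expect_equal(out1$p_us, rep(1, 80), tolerance = 1e-14)
  # conservation at machine precision for random states
  for (s in 1:5) {
    st <- random_state(80, seed = 50 + s)
    out <- mmca_step(st, sn, mp$static,
                     model_params(0.6, 0.3, 0.4, 0.1, 0.5))
    expect_lt(max(abs(out$p_us + out$p_as + out$p_ai - 1)), 1e-12)
  }
})

test_that("mmca_step agrees with a literal per-node transcription", {
  mp <- small_multiplex(n = 40, seed = 7)
  sn <- generate_snapshot(mp$awareness, seed = 8)
  for (model in c("sis", "threshold")) {
    p <- model_params(lambda_aware = 0.7, delta = 0.3, beta_u = 0.5,
                      beta_a = 0.1, mu = 0.4, alpha = 0.3,
                      awareness_model = model)
    for (s in 1:3) {
      st <- random_state(40, seed = 70 + s)
      fast <- mmca_step(st, sn, mp$static, p)
      slow <- naive_mmca_step(st, sn, mp$static, p)
      expect_lt(max(abs(fast$p_us - slow$p_us)), 1e-12)
      expect_lt(max(abs(fast$p_as - slow$p_as)), 1e-12)
      expect_lt(max(abs(fast$p_ai - slow$p_ai)), 1e-12)
    }
  }
})

test_that("mmca_step is equivariant under node relabeling", {
  mp <- small_multiplex(n = 60, seed = 9)
  sn <- generate_snapshot(mp$awareness, seed = 10)
  p <- model_params(0.6, 0.3, 0.4, 0, 0.5, alpha = 0.4)
  st <- random_state(60, seed = 11)
  perm <- with_seed(12, sample.int(60))
  out <- mmca_step(st, sn, mp$static, p)
  # permute state and both layers consistently, then step
  sn_p <- snapshot_from_edges(60, cbind(perm[sn$edges[, 1]],
                                        perm[sn$edges[, 2]]))
  adj_p <- mp$static$adjacency[order(perm), order(perm)]
  e <- which(as.matrix(Matrix::triu(adj_p)) > 0, arr.ind = TRUE)
  net_p <- static_from_edges(60, e)
  st_p <- state_probs(st$p_us[order(perm)], st$p_as[order(perm)],
                      st$p_ai[order(perm)])
  out_p <- mmca_step(st_p, sn_p, net_p, p)
  expect_equal(out_p$p_ai, out$p_ai[order(perm)], tolerance = 1e-12)
})

test_that("with no epidemic coupling the chain reduces to single-layer SIS", {
  mp <- small_multiplex(n = 150, seed = 13)
  # lambda = 0 and delta = 1: awareness never transmitted, instantly forgotten
  p <- model_params(lambda_aware = 0, delta = 1, beta_u = 0.12, mu = 0.3)
  init <- initial_state_probs(150, 0.2, seed = 14)
  res <- iterate_to_stationarity(init, mp$awareness, mp$static, p,
                                 t0 = 120, window = 1, seed = 15)
  oracle <- single_layer_sis_mmca(mp$static, init$p_ai, 0.12, 0.3, 120)
  expect_lt(max(abs(res$state_final$p_ai - oracle)), 1e-10)
})

test_that("epidemic stays off below coupling and awareness settles alone", {
  mp <- small_multiplex(n = 120, seed = 16)
  p <- model_params(lambda_aware = 0.9, delta = 0.1, beta_u = 0, beta_a = 0,
                    mu = 0.4)
  init <- initial_state_probs(120, 0.2, seed = 17)
  res <- iterate_to_stationarity(init, mp$awareness, mp$static, p,
                                 t0 = 201, window = 50, seed = 18)
  expect_equal(res$rho_i, 0, tolerance = 1e-12)
  expect_gt(res$rho_a, 0.3) # awareness self-sustains at these rates
})

test_that("stationary infected density is suppressed monotonically by lambda", {
  mp <- small_multiplex(n = 400, seed = 19)
  rho <- vapply(c(0, 0.45, 0.9), function(lam) {
    p <- model_params(lambda_aware = lam, delta = 0.2, beta_u = 0.15,
                      mu = 0.2)
    init <- initial_state_probs(400, 0.2, seed = 20)
    iterate_to_stationarity(init, mp$awareness, mp$static, p,
                            t0 = 301, window = 100, seed = 21)$rho_i
  }, numeric(1))
  expect_lt(rho[2], rho[1] + 0.02)
  expect_lt(rho[3], rho[2] + 0.02)
  expect_gt(rho[1], 0.1) # above threshold so the comparison is informative
})

test_that("stationary density is reproducible across master seeds", {
  mp <- small_multiplex(n = 1000, seed = 22)
  p <- model_params(lambda_aware = 0.2, delta = 0.8, beta_u = 0.2, mu = 0.2)
  rho <- vapply(c(31, 57), function(s) {
    init <- initial_state_probs(1000, 0.2, seed = derive_seed(s, 1))
    iterate_to_stationarity(init, mp$awareness, mp$static, p,
                            t0 = 401, window = 100,
                            seed = derive_seed(s, 2))$rho_i
  }, numeric(1))
  expect_lt(abs(rho[1] - rho[2]), 0.01)
})

test_that("annealed contact mode approximates the snapshot ensemble", {
  mp <- small_multiplex(n = 300, seed = 23)
  p <- model_params(lambda_aware = 0.8, delta = 0.2, beta_u = 0.2, mu = 0.2)
  init <- initial_state_probs(300, 0.2, seed = 24)
  snap <- iterate_to_stationarity(init, mp$awareness, mp$static, p,
                                  t0 = 301, window = 100, seed = 25)
  ann <- iterate_to_stationarity(init, mp$awareness, mp$static, p,
                                 t0 = 151, window = 50, seed = 26,
                                 contact_mode = "annealed")
  expect_lt(abs(snap$rho_i - ann$rho_i), 0.05)
})

test_that("state_probs validates its inputs", {
  expect_error(state_probs(c(0.5, 0.5), c(0.5), c(0, 0)), "length")
  expect_error(state_probs(0.9, 0.3, 0.3), "sum to 1")
  expect_error(state_probs(-0.2, 0.6, 0.6), "0, 1")
  expect_error(model_params(lambda_aware = 1.5), "out of")
  expect_error(model_params(beta_u = 0.1, beta_a = 0.5), "beta_a")
})
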