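test_that("DoG lateral weight matches its closed form and is symmetric in distance", {
  p <- lateral_profile(w_e = 2, w_i = 140, sigma_l = 3.2, beta = 15)
  expect_equal(dog_weight(0, p), 2 / (2 * pi * 3.2^2) - 140 / (2 * pi * 48^2),
               tolerance = 1e-12)
  expect_lt(abs(dog_weight(0, p) - 0.0214140), 1e-7)  # printed-precision value
  expect_equal(dog_weight(3.7, p), dog_weight(3.7, p))
  p0 <- lateral_profile(w_e = 2, w_i = 0, sigma_l = 3.2, beta = 15)
  expect_gt(dog_weight(40, p0), 0)
  expect_lt(dog_weight(40, p0), 1e-10)
  expect_error(lateral_profile(w_e = -1), class = "salnet_config_error")
})

test_that("feedforward weights are the separable 5x5 tap products", {
  expect_equal(feedforward_weight(0, 0), 1.13^2)
  expect_equal(feedforward_weight(1, -2), 0.71 * 0.14)
  expect_equal(feedforward_weight(3, 0), 0)
  expect_equal(feedforward_weight(-1, 0), feedforward_weight(1, 0))
})

test_that("input scaling applies the per-modality gains", {
  fs <- tiny_features()
  cfg <- tiny_config()
  I <- compute_input(fs, cfg)
  expect_equal(I[, , 1], 30 * fs$lum)
  expect_equal(I[, , 3], 15 * fs$col_green)
  expect_equal(I[, , 8], 20 * fs$ori_90)
  expect_true(all(I[, , 10:13] == 0))

  zero <- feature_set(lapply(fs, function(m) m * 0))
  expect_true(all(compute_input(zero, cfg) == 0))

  # Brecht-Saiki: raw red channel scaled by 30
  bs <- feature_set(list(v_red = matrix(1, 9, 12), v_green = matrix(0, 9, 12),
                         ori_0 = matrix(0, 9, 12), ori_90 = matrix(0, 9, 12)),
                    variant = "brecht_saiki")
  Ib <- compute_input(bs, tiny_config(variant = "brecht_saiki"))
  expect_equal(Ib[1, 1, 1], 30)
  expect_error(compute_input(bs, cfg), class = "salnet_config_error")
})

test_that("lateral signal: zero activity, single-source, and oracle equivalence", {
  p <- lateral_profile(2, 140, 3.2, 15)
  z1 <- matrix(1, 9, 12)
  expect_true(all(lateral_signal(matrix(0, 9, 12), z1, p) == 0))

  # one active cell: every target receives 0.5 * w(d)
  A <- matrix(0, 9, 12); A[4, 7] <- 1
  S <- lateral_signal(A, z1, p)
  d <- sqrt(outer((1:9 - 4)^2, (1:12 - 7)^2, `+`))
  expect_equal(S, 0.5 * dog_weight(d, p), tolerance = 1e-12)

  withr::with_seed(21, {
    A <- matrix(runif(9 * 12), 9)
    z <- matrix(runif(9 * 12, 0.3, 1), 9)
    oracle <- lateral_direct(A, z, p)
    expect_lt(max(abs(lateral_signal(A, z, p, method = "separable") - oracle)), 1e-9)
    expect_lt(max(abs(lateral_signal(A, z, p, method = "explicit") - oracle)), 1e-9)
  })
})

test_that("masked lateral signal equals the masked double-loop sum", {
  p <- lateral_profile(2, 140, 3.2, 15)
  withr::with_seed(22, {
    A <- matrix(runif(6 * 8), 6)
    z <- matrix(runif(6 * 8, 0.3, 1), 6)
    keep <- matrix(runif(48 * 48) >= 0.6, 48)
    expect_lt(max(abs(lateral_signal(A, z, p, mask = keep) -
                        lateral_direct(A, z, p, keep = keep))), 1e-9)
  })
})

test_that("feedforward signal matches the explicit kernel sum and the routing table", {
  cfg <- tiny_config()
  withr::with_seed(23, {
    A <- array(runif(9 * 12 * 13), c(9, 12, 13))
    zf <- array(runif(9 * 12 * 13, 0.3, 1), c(9, 12, 13))
    state <- list(A = A, z_f = zf)
    S13 <- feedforward_signal(state, cfg, 13)
    oracle <- feedforward_direct(A[, , 10], zf[, , 10]) +
      feedforward_direct(A[, , 11], zf[, , 11]) +
      feedforward_direct(A[, , 12], zf[, , 12])
    expect_lt(max(abs(S13 - oracle)), 1e-9)

    # single source cell: centre 0.5*1.13^2, horizontal neighbour 0.5*0.71*1.13
    A0 <- array(0, c(9, 12, 13)); A0[5, 6, 10] <- 1
    z1 <- array(1, c(9, 12, 13))
    S <- feedforward_signal(list(A = A0, z_f = z1), cfg, 13)
    expect_equal(S[5, 6], 0.5 * 1.2769, tolerance = 1e-12)
    expect_equal(S[5, 7], 0.5 * 0.71 * 1.13, tolerance = 1e-12)

    # all-zero sources give zero
    expect_true(all(feedforward_signal(list(A = A0 * 0, z_f = z1), cfg, 11) == 0))
    # feature maps return their external input
    I <- compute_input(tiny_features(), cfg)
    expect_equal(feedforward_signal(state, cfg, 4, inputs = I), I[, , 4])
    expect_error(feedforward_signal(state, cfg, 14), class = "salnet_config_error")
  })
  expect_equal(cfg$sources[["13"]], 10:12)
})

test_that("activity and resource updates obey their closed-form limits", {
  # A = 0, b = 0, no drive: fixed point
  expect_equal(activity_update(0, 0, b = 0), 0)
  # A relaxes to b with no drive: 400 Euler steps at tau = 0.03
  A <- 0
  for (t in 1:400) A <- activity_update(A, 0, b = 1)
  expect_equal(A, 1, tolerance = 1e-3)
  # clamped activity: z -> 1 / (1 + u_se * tau_rec * A)
  z <- 1
  for (t in 1:4000) z <- resource_update(z, 10, u_se = 0.5, tau_rec = 0.1)
  expect_equal(z, 1 / 1.5, tolerance = 1e-3)
})

test_that("zero stimulus with b = 0 is a global fixed point; simulations are deterministic", {
  fs0 <- feature_set(lapply(tiny_features(), function(m) m * 0))
  cfg <- tiny_config(steps = 50)
  sim <- simulate_saliency(fs0, cfg)
  expect_true(all(sim$activity == 0))
  expect_true(all(sim$saliency == 0))

  fs <- tiny_features()
  s1 <- simulate_saliency(fs, tiny_config(steps = 120))
  s2 <- simulate_saliency(fs, tiny_config(steps = 120))
  expect_identical(s1$saliency, s2$saliency)
  expect_identical(s1$activity, s2$activity)
})

test_that("activity stays nonnegative and resources stay in (0,1] during driven runs", {
  sim <- simulate_saliency(tiny_features(), tiny_config(steps = 400, baseline = 1),
                           check_every = 1L)
  expect_gte(sim$diagnostics$min_activity, 0)
  expect_gt(sim$diagnostics$z_range[1], 0)
  expect_lte(sim$diagnostics$z_range[2], 1)
})

test_that("with baseline drive and no stimulus, feature maps relax to b and all maps inherit the stimulus symmetry", {
  fs0 <- feature_set(lapply(tiny_features(24, 16), function(m) m * 0))
  cfg <- tiny_config(w = 24, h = 16, baseline = 1, steps = 400)
  sim <- simulate_saliency(fs0, cfg)
  # feature maps: net lateral drive is inhibition-dominated and rectified
  # away, so activity relaxes to the baseline exactly as in the scalar limit
  for (m in 1:9)
    expect_lt(max(abs(sim$activity[, , m] - 1)), 1e-3)
  # upper maps are shaped by border truncation of the wide inhibitory
  # Gaussian, but must retain the stimulus's mirror symmetries exactly
  for (m in seq_len(cfg$n_maps)) {
    M <- sim$activity[, , m]
    expect_lt(max(abs(M - M[, ncol(M):1])), 1e-9)
    expect_lt(max(abs(M - M[nrow(M):1, ])), 1e-9)
  }
})

test_that("recorded trajectories match the returned final state", {
  fs <- tiny_features()
  sim <- simulate_saliency(fs, tiny_config(steps = 60), record = c(1L, 13L))
  expect_named(sim$trajectory, c("map1", "map13"))
  expect_equal(sim$trajectory$map13[, , 60], unclass(sim$saliency)[,],
               ignore_attr = TRUE)
  expect_equal(dim(sim$trajectory$map1), c(9, 12, 60))
})

test_that("ablation: identity at 0, pure feedforward at 1, binomial keep counts", {
  fs <- tiny_features()
  cfg <- tiny_config(steps = 100)
  base <- simulate_saliency(fs, cfg)
  cfg0 <- ablate_connections(cfg, 0, seed = 1)
  expect_identical(simulate_saliency(fs, cfg0)$saliency, base$saliency)

  cfg1 <- ablate_connections(cfg, 1, seed = 1)
  nolat <- cfg
  nolat$lateral <- rep(list(NULL), cfg$n_maps)
  expect_equal(simulate_saliency(fs, cfg1)$saliency,
               simulate_saliency(fs, nolat)$saliency, tolerance = 1e-12)

  cfg6 <- ablate_connections(cfg, 0.6, seed = 7)
  masks <- salnet:::build_ablation_masks(cfg6)
  n <- 9 * 12
  for (m in c(1, 7, 13)) {
    kept <- Matrix::nnzero(masks[[m]])
    mu <- 0.4 * n^2
    sdev <- sqrt(n^2 * 0.4 * 0.6)
    expect_lt(abs(kept - mu), 3 * sdev)
  }
  # masks differ across maps (per_map scope) and runs are reproducible
  expect_false(identical(masks[[1]], masks[[2]]))
  s1 <- simulate_saliency(fs, cfg6)
  s2 <- simulate_saliency(fs, cfg6)
  expect_identical(s1$saliency, s2$saliency)
})

test_that("Brecht-Saiki configuration has 7 maps, shared profiles, and no saliency-layer lateral connections", {
  cfg <- brecht_saiki_config()
  expect_equal(cfg$n_maps, 7L)
  expect_equal(cfg$saliency_map, 7L)
  expect_null(cfg$lateral[[7]])
  for (m in 1:6) {
    expect_equal(cfg$lateral[[m]]$w_e, 5)
    expect_equal(cfg$lateral[[m]]$w_i, 250)
    expect_equal(cfg$lateral[[m]]$sigma_l, 3.2)
    expect_equal(cfg$lateral[[m]]$beta, 15)
  }
  expect_equal(cfg$sources[["7"]], 5:6)

  # lateral signal contributes nothing on the saliency map: a run with a
  # modified saliency-layer profile must differ, while NULL equals NULL
  fs <- feature_set(list(v_red = matrix(runif(9 * 12), 9),
                         v_green = matrix(runif(9 * 12), 9),
                         ori_0 = matrix(runif(9 * 12), 9),
                         ori_90 = matrix(runif(9 * 12), 9)),
                    variant = "brecht_saiki")
  cfg_t <- brecht_saiki_config(grid_width = 12, grid_height = 9, steps = 100)
  simA <- simulate_saliency(fs, cfg_t)
  cfg_l <- cfg_t
  cfg_l$lateral[[7]] <- lateral_profile(5, 250, 3.2, 15)
  simB <- simulate_saliency(fs, cfg_l)
  expect_false(isTRUE(all.equal(simA$saliency, simB$saliency)))
})

test_that("simulation aborts with a divergence error instead of silently clamping", {
  fs <- tiny_features()
  # absurd gain drives activity and resources out of range within the run
  cfg <- tiny_config(steps = 400, c_lum = 1e7, c_col = 1e7, c_ori = 1e7)
  expect_error(simulate_saliency(fs, cfg, check_every = 1L),
               class = "salnet_divergence_error")
})
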