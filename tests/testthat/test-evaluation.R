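test_that("NSS matches hand computation with population SD", {
  sal <- matrix(c(0, 0, 0, 4), 2, 2)
  # mean 1, population SD sqrt(3); fixating the 4-cell gives (4-1)/sqrt(3)
  expect_equal(nss(sal, tibble::tibble(col = 1L, row = 1L)), sqrt(3),
               tolerance = 1e-12)
  # fixating a cell at the map mean gives 0
  sal2 <- matrix(c(0, 1, 2, 1), 2, 2)
  expect_equal(nss(sal2, tibble::tibble(col = 0L, row = 1L)), 0)
  # symmetric pair of z-scores averages to 0
  expect_equal(nss(sal2, tibble::tibble(col = c(0L, 1L), row = c(0L, 0L))), 0)
})

test_that("NSS is affine-invariant, rejects constant maps and empty fixations", {
  withr::with_seed(31, {
    sal <- matrix(runif(54 * 96), 54)
    cells <- tibble::tibble(col = sample(0:95, 30, TRUE),
                            row = sample(0:53, 30, TRUE))
    a <- nss(sal, cells)
    expect_equal(nss(3.7 * sal + 11, cells), a, tolerance = 1e-9)
    expect_error(nss(matrix(1, 4, 4), tibble::tibble(col = 1L, row = 1L)),
                 class = "salnet_undefined_nss")
    expect_error(nss(sal, cells[0, ]), class = "salnet_precondition_error")
    expect_error(nss(sal, tibble::tibble(col = 96L, row = 0L)),
                 class = "salnet_precondition_error")
  })
})

test_that("fixation sampling is categorical on the normalized map", {
  # all mass on one cell
  sal <- matrix(0, 5, 5); sal[3, 4] <- 2
  fx <- sample_fixations(sal, 10, seed = 1)
  expect_true(all(fx$col == 3L & fx$row == 2L))
  # determinism
  sal2 <- matrix(runif(25), 5)
  expect_identical(sample_fixations(sal2, 50, seed = 9),
                   sample_fixations(sal2, 50, seed = 9))
  expect_error(sample_fixations(matrix(0, 3, 3), 5, seed = 1),
               class = "salnet_normalize_error")
})

test_that("uniform map sampling passes a chi-square goodness-of-fit check", {
  sal <- matrix(1, 9, 12)
  fx <- sample_fixations(sal, 1e4, seed = 42)
  counts <- table(factor(fx$col * 9 + fx$row, levels = 0:(108 - 1)))
  gof <- suppressWarnings(stats::chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("sampled frequencies converge to the normalized map in total variation", {
  withr::with_seed(33, {
    sal <- matrix(runif(9 * 12), 9)
    p <- as.vector(sal) / sum(sal)
    fx <- sample_fixations(sal, 1e5, seed = 7)
    idx <- fx$col * 9 + fx$row
    phat <- tabulate(idx + 1L, nbins = 108) / 1e5
    expect_lt(sum(abs(phat - p)) / 2, 0.05)
  })
})

test_that("mean NSS over stimuli aggregates, excludes, and is ~0 under uniform fixations", {
  withr::with_seed(34, {
    sals <- list(matrix(runif(54 * 96), 54), matrix(runif(54 * 96), 54))
    cells <- lapply(1:2, function(i)
      tibble::tibble(col = sample(0:95, 10, TRUE), row = sample(0:53, 10, TRUE)))
    one <- mean_nss_over_stimuli(list(NULL), cells[1], network_config(),
                                 saliency_maps = sals[1])
    expect_equal(one$mean_nss, nss(sals[[1]], cells[[1]]))
    both <- mean_nss_over_stimuli(list(NULL, NULL), cells, network_config(),
                                  saliency_maps = sals)
    expect_equal(both$mean_nss,
                 (nss(sals[[1]], cells[[1]]) + nss(sals[[2]], cells[[2]])) / 2)

    # a constant map is excluded with a warning
    expect_warning(
      mix <- mean_nss_over_stimuli(list(NULL, NULL),
                                   cells, network_config(),
                                   saliency_maps = list(sals[[1]],
                                                        matrix(1, 54, 96))),
      class = "salnet_nss_excluded")
    expect_equal(mix$n_excluded, 1L)
    expect_equal(mix$mean_nss, nss(sals[[1]], cells[[1]]))

    # 1e4 uniform-random fixations on one map: mean z-score ~ 0
    ucells <- tibble::tibble(col = sample(0:95, 1e4, TRUE),
                             row = sample(0:53, 1e4, TRUE))
    expect_lt(abs(nss(sals[[1]], ucells)), 0.05)
  })
})

test_that("NSS under the map's own fixation distribution is nonnegative", {
  withr::with_seed(35, {
    for (s in 1:3) {
      sal <- matrix(runif(9 * 12)^2, 9)
      fx <- sample_fixations(sal, 2000, seed = s)
      expect_gte(nss(sal, fx), 0)
    }
  })
})

test_that("parameter grid search returns the curve and a deterministic argmax", {
  withr::with_seed(36, {
    sal <- matrix(runif(54 * 96), 54)
    cells <- list(tibble::tibble(col = sample(0:95, 10, TRUE),
                                 row = sample(0:53, 10, TRUE)))
    # degenerate one-value grid
    rec <- estimate_parameter(list(NULL), cells, grid = 200, network_config(),
                              saliency_maps = list(`200` = list(sal)))
    expect_equal(rec$estimate, 200)
    expect_equal(nrow(rec$curve), 1L)

    # identical maps for every grid value: flat curve, tie broken to smallest
    maps <- list(`100` = list(sal), `200` = list(sal), `300` = list(sal))
    rec2 <- estimate_parameter(list(NULL), cells, grid = c(300, 100, 200),
                               network_config(), saliency_maps = maps)
    expect_equal(rec2$estimate, 100)
    expect_equal(length(unique(rec2$curve$mean_nss)), 1L)
  })
})

test_that("uniform-random fixations give a flat near-zero recovery curve", {
  withr::with_seed(37, {
    sals <- lapply(1:4, function(i) matrix(runif(54 * 96), 54))
    maps <- list(`120` = sals, `280` = lapply(sals, function(m) m^2))
    cells <- lapply(1:4, function(i)
      tibble::tibble(col = sample(0:95, 500, TRUE), row = sample(0:53, 500, TRUE)))
    rec <- estimate_parameter(as.list(rep(list(NULL), 4)), cells,
                              grid = c(120, 280), network_config(),
                              saliency_maps = maps)
    expect_true(all(abs(rec$curve$mean_nss) < 0.1))
  })
})

test_that("region means recover single-cell trajectories and uniform maps", {
  arr <- array(runif(9 * 12 * 5), c(9, 12, 5))
  m1 <- matrix(FALSE, 9, 12); m1[4, 7] <- TRUE
  tr <- region_mean_activity(arr, m1)
  expect_equal(tr$mean_activity, arr[4, 7, ])
  arr2 <- array(rep(3, 9 * 12 * 2), c(9, 12, 2))
  many <- matrix(c(TRUE, FALSE), 9, 12)
  expect_true(all(region_mean_activity(arr2, many)$mean_activity == 3))
  expect_error(region_mean_activity(arr, matrix(FALSE, 9, 12)),
               class = "salnet_precondition_error")
})

test_that("grid-cell centres round-trip through the pixel mapping", {
  cells <- tibble::tibble(col = c(0L, 95L, 48L), row = c(0L, 53L, 27L))
  fx <- cells_to_fixations(cells, 1920, 1080)
  back <- map_fixations_to_grid(fx)
  expect_equal(back$col, cells$col)
  expect_equal(back$row, cells$row)
})
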