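# Shared fixtures and independent oracles. Expensive simulations are cached
# in an environment so acceptance blocks can share them within one test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

fig_bar_stimulus <- function() cached("fig_bar_stimulus",
                                      generate_bar_stimulus(default_bar_layout()))

fig_bar_features <- function() cached("fig_bar_features",
                                      extract_features(build_pyramid(fig_bar_stimulus()$image)))

fig_bar_sim <- function(w_i = 140, sigma_l = 3.2, baseline = 0, ...) {
  key <- paste0("fig_sim_", w_i, "_", sigma_l, "_", baseline)
  cached(key, simulate_saliency(fig_bar_features(),
                                network_config(w_i = w_i, sigma_l = sigma_l,
                                               baseline = baseline, ...)))
}

# small feature set / config for fast network tests
tiny_config <- function(w = 12L, h = 9L, ...) {
  network_config(grid_width = w, grid_height = h, ...)
}

tiny_features <- function(w = 12L, h = 9L, seed = 1) {
  withr::with_seed(seed, {
    mk <- function() matrix(runif(h * w), h, w)
    feature_set(list(lum = mk(), col_red = mk(), col_green = mk(),
                     col_blue = mk(), col_yellow = mk(), ori_0 = mk(),
                     ori_45 = mk(), ori_90 = mk(), ori_135 = mk()))
  })
}

# --- independent oracles ----------------------------------------------------

# direct double-loop convolution, Eq-style sum with zero padding
conv2_direct <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  hh <- (nrow(k) - 1L) %/% 2L; hw <- (ncol(k) - 1L) %/% 2L
  out <- matrix(0i, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0i
    for (u in 1:h) for (v in 1:w) {
      dr <- r - u; dc <- c - v
      if (abs(dr) <= hh && abs(dc) <= hw)
        acc <- acc + k[dr + hh + 1L, dc + hw + 1L] * x[u, v]
    }
    out[r, c] <- acc
  }
  out
}

# explicit lateral sum over all ordered pairs, optionally masked
lateral_direct <- function(A, z, profile, u_se = 0.5, keep = NULL) {
  h <- nrow(A); w <- ncol(A)
  out <- matrix(0, h, w)
  idx <- function(r, c) (c - 1L) * h + r
  for (ri in 1:h) for (ci in 1:w) {
    acc <- 0
    for (rj in 1:h) for (cj in 1:w) {
      if (!is.null(keep) && !keep[idx(ri, ci), idx(rj, cj)]) next
      d <- sqrt((ci - cj)^2 + (ri - rj)^2)
      acc <- acc + dog_weight(d, profile) * z[rj, cj] * A[rj, cj]
    }
    out[ri, ci] <- u_se * acc
  }
  out
}

# explicit feedforward sum with the 5 x 5 separable kernel
feedforward_direct <- function(A, z, u_se = 0.5) {
  h <- nrow(A); w <- ncol(A)
  out <- matrix(0, h, w)
  for (ri in 1:h) for (ci in 1:w) {
    acc <- 0
    for (rj in max(1, ri - 2):min(h, ri + 2))
      for (cj in max(1, ci - 2):min(w, ci + 2))
        acc <- acc + feedforward_weight(ci - cj, ri - rj) * z[rj, cj] * A[rj, cj]
    out[ri, ci] <- u_se * acc
  }
  out
}

write_temp_png <- function(arr) {
  path <- tempfile(fileext = ".png")
  png::writePNG(arr, path)
  path
}
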