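# The layered mean-field network: feature maps -> conspicuity maps -> saliency
# map. Every population is one cell of a height x width grid; activity follows
# a first-order rate equation driven by rectified lateral plus feedforward
# input, and every synapse class carries a depressing resource variable.
#
# Numerics: forward Euler with dt = 1 ms on per-second derivatives (the 0.001
# update factor); synchronous updates (all new values computed from the
# previous step's state); sums truncated at the grid border (zero padding); all
# accumulation in double precision.

ff_taps <- c(1.13, 0.71, 0.14)  # feedforward tap at offsets |d| = 0, 1, 2

#' Lateral difference-of-Gaussians profile
#'
#' Parameters of the lateral connectivity within one map: a narrow excitatory
#' Gaussian of amplitude `w_e` and SD `sigma_l` (grid cells) minus a broad
#' inhibitory Gaussian of amplitude `w_i` and SD `beta * sigma_l`.
#'
#' @param w_e excitatory amplitude (> 0).
#' @param w_i inhibitory amplitude (>= 0).
#' @param sigma_l excitatory Gaussian SD in grid cells (> 0).
#' @param beta inhibitory-to-excitatory SD ratio (> 1).
#' @return A `lateral_profile` list.
#' @export
lateral_profile <- function(w_e = 2, w_i = 140, sigma_l = 3.2, beta = 15) {
  if (w_e <= 0 || w_i < 0 || sigma_l <= 0 || beta <= 1)
    abort("need w_e > 0, w_i >= 0, sigma_l > 0, beta > 1.",
          class = "salnet_config_error")
  structure(list(w_e = w_e, w_i = w_i, sigma_l = sigma_l, beta = beta),
            class = "lateral_profile")
}

#' Lateral connection weight at a given distance
#'
#' Difference-of-Gaussians weight
#' `w_e/(2 pi sigma_l^2) exp(-d^2/(2 sigma_l^2)) -
#'  w_i/(2 pi (beta sigma_l)^2) exp(-d^2/(2 (beta sigma_l)^2))`
#' as a function of the Euclidean distance between two populations. Depends on
#' the distance only, hence symmetric in the pair.
#'
#' @param d distance(s) in grid cells, >= 0.
#' @param profile a [lateral_profile()].
#' @return Numeric weight(s).
#' @export
dog_weight <- function(d, profile = lateral_profile()) {
  s1 <- profile$sigma_l
  s2 <- profile$beta * profile$sigma_l
  profile$w_e / (2 * pi * s1^2) * exp(-d^2 / (2 * s1^2)) -
    profile$w_i / (2 * pi * s2^2) * exp(-d^2 / (2 * s2^2))
}

#' Feedforward connection weight for a cell offset
#'
#' Separable profile `w(dx, dy) = w1(dx) * w1(dy)` with taps 1.13 at offset 0,
#' 0.71 at +-1, 0.14 at +-2 and 0 beyond, so each population excites a 5 x 5
#' neighbourhood of the map above.
#'
#' @param dx,dy integer cell offsets (vectorized).
#' @return Numeric weight(s).
#' @export
feedforward_weight <- function(dx, dy) {
  tap <- function(d) ifelse(abs(d) <= 2, ff_taps[abs(d) + 1], 0)
  tap(dx) * tap(dy)
}

variant_maps <- function(variant) {
  if (variant == "proposed") {
    list(n_maps = 13L, n_features = 9L,
         sources = list(`10` = 1L, `11` = 2:5, `12` = 6:9, `13` = 10:12),
         saliency_map = 13L)
  } else {
    list(n_maps = 7L, n_features = 4L,
         sources = list(`5` = 1:2, `6` = 3:4, `7` = 5:6),
         saliency_map = 7L)
  }
}

#' Network configuration
#'
#' Collects every scalar and wiring choice of the simulator. Defaults are the
#' proposed model's values: input gains `c_lum = 30`, `c_col = 15`,
#' `c_ori = 20`; membrane time constant `tau = 0.03` s; synaptic utilization
#' `u_se_l = u_se_f = 0.5`; resource recovery `tau_rec_l = 0.1` s,
#' `tau_rec_f = 0.05` s; a single lateral profile (`w_e = 2`, `w_i`,
#' `sigma_l`, `beta = 15`) shared by all maps including the saliency map; 400
#' integration steps of 1 ms.
#'
#' @param variant `"proposed"` (13 maps: 9 feature, 3 conspicuity, 1 saliency)
#'   or `"brecht_saiki"` (7 maps; see [brecht_saiki_config()]).
#' @param grid_width,grid_height map size in cells.
#' @param c_lum,c_col,c_ori input gains of the proposed variant.
#' @param c_col_bs,c_ori_bs input gains of the Brecht-Saiki variant.
#' @param tau activity time constant, seconds.
#' @param baseline baseline activity `b` added to every population's drive.
#' @param u_se_l,u_se_f utilization of synaptic efficacy, lateral/feedforward.
#' @param tau_rec_l,tau_rec_f resource recovery time constants, seconds.
#' @param w_e,w_i,sigma_l,beta shared lateral profile (used when `lateral` is
#'   not given).
#' @param lateral optional list of length `n_maps`: a [lateral_profile()] per
#'   map or `NULL` for maps without lateral connections.
#' @param ablation `NULL`, or the result of [ablate_connections()]: a list
#'   `list(fraction, seed, scope)` removing a random fraction of lateral
#'   connections.
#' @param steps number of 1-ms Euler steps (readout time).
#' @return A `network_config` list with derived fields `n_maps`,
#'   `n_features`, `sources` (feedforward routing) and `saliency_map`.
#' @export
network_config <- function(variant = c("proposed", "brecht_saiki"),
                           grid_width = 96L, grid_height = 54L,
                           c_lum = 30, c_col = 15, c_ori = 20,
                           c_col_bs = 30, c_ori_bs = 30,
                           tau = 0.03, baseline = 0,
                           u_se_l = 0.5, u_se_f = 0.5,
                           tau_rec_l = 0.1, tau_rec_f = 0.05,
                           w_e = 2, w_i = 140, sigma_l = 3.2, beta = 15,
                           lateral = NULL, ablation = NULL, steps = 400L) {
  variant <- match.arg(variant)
  if (tau <= 0 || tau_rec_l <= 0 || tau_rec_f <= 0)
    abort("time constants must be positive.", class = "salnet_config_error")
  if (any(c(c_lum, c_col, c_ori, c_col_bs, c_ori_bs) <= 0))
    abort("input gains must be positive.", class = "salnet_config_error")
  vm <- variant_maps(variant)
  if (is.null(lateral)) {
    prof <- lateral_profile(w_e, w_i, sigma_l, beta)
    lateral <- rep(list(prof), vm$n_maps)
    if (variant == "brecht_saiki") lateral[vm$saliency_map] <- list(NULL)
  }
  if (length(lateral) != vm$n_maps)
    abort(sprintf("`lateral` must have one entry per map (%d).", vm$n_maps),
          class = "salnet_config_error")
  if (!is.null(ablation)) {
    if (is.null(ablation$fraction) || ablation$fraction < 0 || ablation$fraction > 1)
      abort("ablation fraction must lie in [0, 1].", class = "salnet_config_error")
    ablation$scope <- match.arg(ablation$scope %||% "per_map",
                                c("per_map", "global"))
  }
  structure(list(variant = variant,
                 grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 c_lum = c_lum, c_col = c_col, c_ori = c_ori,
                 c_col_bs = c_col_bs, c_ori_bs = c_ori_bs,
                 tau = tau, baseline = baseline,
                 u_se_l = u_se_l, u_se_f = u_se_f,
                 tau_rec_l = tau_rec_l, tau_rec_f = tau_rec_f,
                 lateral = lateral, ablation = ablation,
                 steps = as.integer(steps),
                 n_maps = vm$n_maps, n_features = vm$n_features,
                 sources = vm$sources, saliency_map = vm$saliency_map),
            class = "network_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> variant '%s', %d maps of %d x %d cells, %d steps\n",
              x$variant, x$n_maps, x$grid_width, x$grid_height, x$steps))
  if (!is.null(x$ablation))
    cat(sprintf("  lateral ablation: fraction %.2f, seed %d, scope %s\n",
                x$ablation$fraction, x$ablation$seed, x$ablation$scope))
  invisible(x)
}

#' Brecht-Saiki comparison configuration
#'
#' The reduced 7-map variant used as a baseline: four feature maps (raw red,
#' raw green, 0- and 90-degree Gabor magnitude at 96 x 54 only), two
#' conspicuity maps (colour, orientation) and a saliency map. Input gains are
#' 30 for both colour and orientation; feature and conspicuity maps share the
#' lateral profile `w_e = 5.0`, `w_i = 250`, `sigma_l = 3.2`, `beta = 15`;
#' the saliency map has no lateral connections.
#'
#' @param ... overrides passed to [network_config()].
#' @return A `network_config` with `variant = "brecht_saiki"`.
#' @export
brecht_saiki_config <- function(...) {
  network_config(variant = "brecht_saiki",
                 w_e = 5, w_i = 250, sigma_l = 3.2, beta = 15, ...)
}

#' Request random ablation of lateral connections
#'
#' Marks a configuration so that, at simulation time, each ordered lateral
#' pair (i, j) is independently removed with probability `fraction` (weights
#' set to 0). Masks are drawn once from the seeded generator and held fixed
#' for the whole run; `scope = "per_map"` draws an independent mask per map,
#' `"global"` shares one mask across maps. `fraction = 0` is the identity.
#'
#' @param cfg a [network_config()].
#' @param fraction fraction of lateral connections removed, in `[0, 1]`.
#' @param seed integer seed for the mask draw.
#' @param scope `"per_map"` (default) or `"global"`.
#' @return The configuration with its `ablation` field set.
#' @export
ablate_connections <- function(cfg, fraction, seed, scope = "per_map") {
  stopifnot(inherits(cfg, "network_config"))
  if (fraction < 0 || fraction > 1)
    abort("ablation fraction must lie in [0, 1].", class = "salnet_config_error")
  if (fraction == 0) cfg$ablation <- NULL
  else cfg$ablation <- list(fraction = fraction, seed = as.integer(seed),
                            scope = match.arg(scope, c("per_map", "global")))
  cfg
}

#' Scale features into network input
#'
#' Multiplies each feature map by its gain to form the external input of the
#' corresponding feature-layer map; conspicuity and saliency maps receive no
#' external input. Proposed variant: luminance x `c_lum`, the four colour
#' channels x `c_col`, the four orientation channels x `c_ori`. Brecht-Saiki
#' variant: raw red/green x `c_col_bs`, Gabor magnitudes x `c_ori_bs`.
#'
#' @param fs a [feature_set()] matching the configuration's variant and grid.
#' @param cfg a [network_config()].
#' @return Numeric array `grid_height x grid_width x n_maps`.
#' @export
compute_input <- function(fs, cfg) {
  stopifnot(inherits(fs, "feature_set"), inherits(cfg, "network_config"))
  if (!identical(attr(fs, "variant"), cfg$variant))
    abort(sprintf("feature set is for variant '%s' but config is '%s'.",
                  attr(fs, "variant"), cfg$variant),
          class = "salnet_config_error")
  d <- dim(fs[[1]])
  if (d[1] != cfg$grid_height || d[2] != cfg$grid_width)
    abort(sprintf("feature maps are %d x %d but the config grid is %d x %d.",
                  d[2], d[1], cfg$grid_width, cfg$grid_height),
          class = "salnet_config_error")
  gains <- if (cfg$variant == "proposed")
    c(cfg$c_lum, rep(cfg$c_col, 4), rep(cfg$c_ori, 4))
  else c(cfg$c_col_bs, cfg$c_col_bs, cfg$c_ori_bs, cfg$c_ori_bs)
  I <- array(0, c(cfg$grid_height, cfg$grid_width, cfg$n_maps))
  for (m in seq_len(cfg$n_features)) I[, , m] <- gains[m] * fs[[m]]
  I
}

# ---- connectivity operators ------------------------------------------------

gauss_op <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  exp(-d^2 / (2 * sigma^2))
}

# Separable factorization of the DoG: each Gaussian term factorizes over the
# two axes, so truncated-at-border lateral sums are two small dense matrix
# products per term.
lateral_ops <- function(profile, h, w) {
  s1 <- profile$sigma_l
  s2 <- profile$beta * profile$sigma_l
  list(KyE = profile$w_e / (2 * pi * s1^2) * gauss_op(h, s1),
       KxE = gauss_op(w, s1),
       KyI = profile$w_i / (2 * pi * s2^2) * gauss_op(h, s2),
       KxI = gauss_op(w, s2))
}

band_op <- function(n) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  matrix(ifelse(abs(d) <= 2, ff_taps[abs(d) + 1], 0), n, n)
}

# Explicit dense lateral weight matrix over cell pairs; cell index runs down
# columns first (R's column-major vec of an h x w matrix).
lateral_weight_matrix <- function(profile, h, w) {
  ix <- rep(seq_len(w), each = h)   # x = column
  iy <- rep(seq_len(h), times = w)  # y = row
  d2 <- outer(ix, ix, `-`)^2 + outer(iy, iy, `-`)^2
  s1 <- profile$sigma_l
  s2 <- profile$beta * profile$sigma_l
  profile$w_e / (2 * pi * s1^2) * exp(-d2 / (2 * s1^2)) -
    profile$w_i / (2 * pi * s2^2) * exp(-d2 / (2 * s2^2))
}

# Sparse masked weight matrices per map, drawn from one seeded stream.
# Entry (i, j) is the weight of the connection from source j to target i;
# removed pairs become structural zeros.
build_ablation_masks <- function(cfg) {
  ab <- cfg$ablation
  n <- cfg$grid_height * cfg$grid_width
  profs <- cfg$lateral
  dense <- list()
  key_of <- function(p) paste(p$w_e, p$w_i, p$sigma_l, p$beta)
  for (p in profs) if (!is.null(p)) {
    k <- key_of(p)
    if (is.null(dense[[k]]))
      dense[[k]] <- lateral_weight_matrix(p, cfg$grid_height, cfg$grid_width)
  }
  withr::with_seed(ab$seed, {
    shared_keep <- if (ab$scope == "global") runif(n * n) >= ab$fraction else NULL
    lapply(seq_len(cfg$n_maps), function(m) {
      p <- profs[[m]]
      if (is.null(p)) return(NULL)
      keep <- if (ab$scope == "global") shared_keep
              else runif(n * n) >= ab$fraction
      Wm <- dense[[key_of(p)]]
      Wm[!keep] <- 0
      Matrix::Matrix(Wm, sparse = TRUE)
    })
  })
}

#' Lateral signal of one map
#'
#' Depressing-synapse lateral drive
#' `S_L(i) = u_se * sum_j w_L(d_ij) z_j A_j`, summed over every population j
#' of the same map (including j = i), with weights from [dog_weight()] and
#' sums truncated at the grid border. The default separable computation
#' exploits the translation invariance of the Gaussian terms; the explicit
#' path multiplies by the full weight matrix and supports an ablation mask.
#' Both paths agree to double-precision rounding.
#'
#' @param A activity matrix of the map (`grid_height x grid_width`).
#' @param z lateral synaptic resources, same shape.
#' @param profile a [lateral_profile()].
#' @param u_se utilization of synaptic efficacy.
#' @param mask optional masked weight representation: either a logical
#'   `n x n` matrix (TRUE = connection kept, cell index column-major) or a
#'   precomputed sparse masked weight matrix.
#' @param method `"separable"` (default when unmasked) or `"explicit"`.
#' @return Signal matrix of the map's shape.
#' @export
lateral_signal <- function(A, z, profile, u_se = 0.5, mask = NULL,
                           method = c("auto", "separable", "explicit")) {
  method <- match.arg(method)
  h <- nrow(A); w <- ncol(A)
  P <- z * A
  if (!is.null(mask) || method == "explicit") {
    Wm <- if (inherits(mask, "Matrix")) mask
    else {
      W <- lateral_weight_matrix(profile, h, w)
      if (!is.null(mask)) W[!mask] <- 0
      W
    }
    return(matrix(as.numeric(Wm %*% as.vector(P)), h, w) * u_se)
  }
  op <- lateral_ops(profile, h, w)
  u_se * (op$KyE %*% P %*% op$KxE - op$KyI %*% P %*% op$KxI)
}


#' Feedforward signal received by one map
#'
#' Feature-layer maps receive their scaled external input; each conspicuity
#' map sums the depressing-synapse signals
#' `S_FPre(p, i) = u_se_f * sum_k w_F(i - k) z_p,k A_p,k` over its source
#' feature maps; the saliency map sums over the conspicuity maps. The 5 x 5
#' feedforward kernel is zero-padded at the border.
#'
#' @param state list with `A` and `z_f`: arrays
#'   `grid_height x grid_width x n_maps`.
#' @param cfg a [network_config()].
#' @param m target map index.
#' @param inputs external input array from [compute_input()] (needed for
#'   feature-layer maps).
#' @return Signal matrix for map `m`.
#' @export
feedforward_signal <- function(state, cfg, m, inputs = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (m < 1 || m > cfg$n_maps)
    abort(sprintf("map index %d outside 1..%d.", m, cfg$n_maps),
          class = "salnet_config_error")
  src <- cfg$sources[[as.character(m)]]
  if (is.null(src)) {
    if (is.null(inputs))
      abort("feature-layer maps need `inputs`.", class = "salnet_config_error")
    return(inputs[, , m])
  }
  Fy <- band_op(cfg$grid_height); Fx <- band_op(cfg$grid_width)
  out <- matrix(0, cfg$grid_height, cfg$grid_width)
  for (p in src) {
    Q <- state$z_f[, , p] * state$A[, , p]
    out <- out + cfg$u_se_f * (Fy %*% Q %*% Fx)
  }
  out
}

#' One synchronous Euler step of the activity equation
#'
#' `A <- A + 0.001 * (-A + b + 0.5 * rectify(signal)) / tau`, the 1-ms update
#' of the per-second rate derivative.
#'
#' @param A activity (any shape).
#' @param signal summed lateral + feedforward drive, same shape.
#' @param b baseline activity.
#' @param tau time constant in seconds.
#' @return Updated activity.
#' @export
activity_update <- function(A, signal, b, tau = 0.03) {
  A + 0.001 * (-A + b + 0.5 * rectify(signal)) / tau
}

#' One synchronous Euler step of the synaptic-resource equation
#'
#' `z <- z + 0.001 * (-u_se * A * z + (1 - z) / tau_rec)`: resources are
#' consumed in proportion to presynaptic activity and recover towards 1. With
#' activity clamped at `A`, the fixed point is `1 / (1 + u_se * tau_rec * A)`.
#'
#' @param z resources in `(0, 1]` (any shape).
#' @param A presynaptic activity, same shape.
#' @param u_se utilization of synaptic efficacy.
#' @param tau_rec recovery time constant in seconds.
#' @return Updated resources.
#' @export
resource_update <- function(z, A, u_se, tau_rec) {
  z + 0.001 * (-u_se * A * z + (1 - z) / tau_rec)
}

#' Simulate the network on a feature set
#'
#' Initializes all activities at 0 and all synaptic resources at 1, holds the
#' feature-derived input constant, and integrates the coupled activity and
#' resource equations for `cfg$steps` 1-ms Euler steps with synchronous
#' updates. Returns the saliency map (the top map's activity at the readout
#' time) plus diagnostics; optionally records the full activity trajectory of
#' selected maps. Deterministic given the configuration (including the
#' ablation seed). Non-finite values or resources leaving `(0, 1]` abort with
#' a divergence error naming the map and time.
#'
#' @param fs a [feature_set()] matching the configuration.
#' @param cfg a [network_config()].
#' @param record integer map indices whose per-step activity should be kept
#'   (`grid_height x grid_width x steps` arrays; memory scales accordingly).
#' @param check_every how often (in steps) to run finiteness/range checks.
#' @return A `salnet_sim` list: `saliency` (class `saliency_map`: matrix with
#'   attribute `t`), `activity` (final `h x w x n_maps` array), `trajectory`
#'   (named list of recorded arrays), `config`, and `diagnostics`
#'   (`min_activity`, `z_range`).
#' @export
simulate_saliency <- function(fs, cfg, record = NULL, check_every = 25L) {
  stopifnot(inherits(cfg, "network_config"))
  I <- compute_input(fs, cfg)
  h <- cfg$grid_height; w <- cfg$grid_width; nm <- cfg$n_maps
  A <- array(0, c(h, w, nm))
  zL <- array(1, c(h, w, nm))
  zF <- array(1, c(h, w, nm))

  # group maps by lateral profile; ablated maps use their sparse masked matrix
  frac <- if (is.null(cfg$ablation)) 0 else cfg$ablation$fraction
  ablate_all <- frac >= 1
  masks <- if (frac > 0 && !ablate_all) build_ablation_masks(cfg) else NULL
  prof_key <- vapply(cfg$lateral, function(p)
    if (is.null(p)) "" else paste(p$w_e, p$w_i, p$sigma_l, p$beta), character(1))
  groups <- list()   # separable groups: list(maps, op)
  masked <- integer(0)
  for (k in unique(prof_key[prof_key != ""])) {
    maps_k <- which(prof_key == k)
    if (frac == 0) {
      groups[[length(groups) + 1L]] <-
        list(maps = maps_k, op = lateral_ops(cfg$lateral[[maps_k[1]]], h, w))
    } else masked <- c(masked, maps_k)
  }

  Fy <- band_op(h); Fx <- band_op(w)
  presyn <- sort(unique(unlist(cfg$sources)))
  src_of <- cfg$sources
  traj <- if (length(record))
    stats::setNames(lapply(record, function(m) array(0, c(h, w, cfg$steps))),
                    paste0("map", record)) else NULL

  dt_tau <- 0.001 / cfg$tau
  b <- cfg$baseline
  uL <- cfg$u_se_l; uF <- cfg$u_se_f
  lat_maps <- integer(0)
  lat_op <- vector("list", nm)
  for (gr in groups) for (m in gr$maps) {
    lat_maps <- c(lat_maps, m)
    lat_op[[m]] <- gr$op
  }
  min_A <- 0; z_lo <- 1; z_hi <- 1
  for (t in seq_len(cfg$steps)) {
    S <- I + 0  # total drive, starting from the external input
    for (m in lat_maps) {
      P <- zL[, , m] * A[, , m]
      op <- lat_op[[m]]
      S[, , m] <- S[, , m] +
        uL * (op$KyE %*% P %*% op$KxE - op$KyI %*% P %*% op$KxI)
    }
    if (length(masked) && !ablate_all) for (m in masked)
      S[, , m] <- S[, , m] + uL *
        matrix(as.numeric(masks[[m]] %*% as.vector(zL[, , m] * A[, , m])), h, w)
    if (length(presyn)) {
      SFPre <- vector("list", nm)
      for (p in presyn)
        SFPre[[p]] <- uF * (Fy %*% (zF[, , p] * A[, , p]) %*% Fx)
      for (ms in names(src_of)) {
        m <- as.integer(ms)
        for (p in src_of[[ms]]) S[, , m] <- S[, , m] + SFPre[[p]]
      }
    }

    gS <- rectify(S)
    A_new <- A + dt_tau * (-A + b + 0.5 * gS)
    zL <- resource_update(zL, A, cfg$u_se_l, cfg$tau_rec_l)
    zF <- resource_update(zF, A, cfg$u_se_f, cfg$tau_rec_f)
    A <- A_new
    if (length(record)) for (i in seq_along(record))
      traj[[i]][, , t] <- A[, , record[i]]

    if (t %% check_every == 0L || t == cfg$steps) {
      if (anyNA(A) || !all(is.finite(A)))
        abort(sprintf("numerical divergence: non-finite activity at t = %d ms (map %d)",
                      t, which(apply(!is.finite(A), 3, any))[1]),
              class = "salnet_divergence_error")
      zr <- range(zL, zF)
      if (zr[1] <= 0 || zr[2] > 1 + 1e-12)
        abort(sprintf("numerical divergence: synaptic resources left (0, 1] at t = %d ms",
                      t), class = "salnet_divergence_error")
      min_A <- min(min_A, min(A))
      z_lo <- min(z_lo, zr[1]); z_hi <- max(z_hi, zr[2])
    }
  }

  sal <- A[, , cfg$saliency_map]
  attr(sal, "t") <- cfg$steps
  class(sal) <- c("saliency_map", "matrix", "array")
  structure(list(saliency = sal, activity = A, trajectory = traj, config = cfg,
                 diagnostics = list(min_activity = min_A,
                                    z_range = c(z_lo, z_hi))),
            class = "salnet_sim")
}

#' @export
print.salnet_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<salnet_sim> variant '%s', %d x %d grid, readout t = %d ms\n",
              cfg$variant, cfg$grid_width, cfg$grid_height,
              attr(x$saliency, "t")))
  cat(sprintf("  saliency range [%.4g, %.4g]; min activity %.3g; z in [%.4f, %.4f]\n",
              min(x$saliency), max(x$saliency), x$diagnostics$min_activity,
              x$diagnostics$z_range[1], x$diagnostics$z_range[2]))
  invisible(x)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d cells at t = %s ms, range [%.4g, %.4g]\n",
              ncol(x), nrow(x), attr(x, "t"), min(x), max(x)))
  invisible(x)
}

#' Export a saliency map to CSV (and optionally PNG)
#'
#' Writes the activity matrix as a plain CSV matrix; if `png_path` is given,
#' also writes a min-max scaled 8-bit grayscale PNG plus a text sidecar
#' recording the scaling and readout time (the CSV carries full precision).
#'
#' @param sal a `saliency_map`.
#' @param csv_path output CSV path.
#' @param png_path optional output PNG path.
#' @return `csv_path`, invisibly.
#' @export
write_saliency_map <- function(sal, csv_path, png_path = NULL) {
  utils::write.table(unclass(sal)[,], csv_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(png_path)) {
    rng <- range(sal)
    scl <- if (diff(rng) > 0) (sal - rng[1]) / diff(rng) else sal * 0
    png::writePNG(matrix(scl, nrow(sal), ncol(sal)), png_path)
    writeLines(sprintf("min=%.10g max=%.10g t=%s", rng[1], rng[2],
                       attr(sal, "t")),
               paste0(png_path, ".scale.txt"))
  }
  invisible(csv_path)
}
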