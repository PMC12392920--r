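# Evaluation: Normalized Scanpath Saliency against fixation data,
# saliency-driven fixation simulation, and grid-search parameter recovery.

cells_to_index <- function(sal, cells) {
  h <- nrow(sal); w <- ncol(sal)
  if (!all(c("col", "row") %in% names(cells)))
    abort("`cells` must have columns `col` and `row` (0-based).",
          class = "salnet_precondition_error")
  if (nrow(cells) == 0)
    abort("at least one fixation cell is required.",
          class = "salnet_precondition_error")
  if (any(cells$col < 0 | cells$col >= w | cells$row < 0 | cells$row >= h))
    abort("fixation cells outside the grid.", class = "salnet_precondition_error")
  cbind(cells$row + 1L, cells$col + 1L)
}

#' Normalized Scanpath Saliency
#'
#' Z-scores the saliency map with its own mean and population (divide-by-N)
#' standard deviation over all cells, then averages the z-scored values at
#' the fixation cells (duplicates counted). Positive values mean fixations
#' fell on above-average saliency; the score is invariant under positive
#' affine rescaling of the map.
#'
#' @param sal saliency map matrix (non-constant).
#' @param cells tibble of fixated grid cells with 0-based columns `col`,
#'   `row` (e.g. from [map_fixations_to_grid()] or [sample_fixations()]).
#' @return A single NSS value.
#' @export
nss <- function(sal, cells) {
  idx <- cells_to_index(sal, cells)
  mu <- mean(sal)
  sdev <- sqrt(mean((sal - mu)^2))
  if (sdev == 0)
    abort("NSS is undefined for a constant saliency map.",
          class = "salnet_undefined_nss")
  mean((sal[idx] - mu) / sdev)
}

#' Sample fixations from a saliency map
#'
#' Normalizes the map to sum to 1 and draws `n` independent fixation cells
#' (with replacement) from the resulting categorical distribution over cells.
#'
#' @param sal saliency map matrix with positive sum.
#' @param n number of fixations.
#' @param seed integer seed; the draw is a deterministic function of it.
#' @return Tibble of 0-based `col`, `row` cells, in draw order.
#' @export
sample_fixations <- function(sal, n = 20, seed) {
  p <- as.vector(sal)
  if (any(p < 0) || sum(p) <= 0)
    abort("cannot normalize saliency map: needs nonnegative values and a positive sum.",
          class = "salnet_normalize_error")
  h <- nrow(sal)
  k <- withr::with_seed(seed,
                        sample.int(length(p), n, replace = TRUE, prob = p))
  tibble(col = as.integer((k - 1L) %/% h), row = as.integer((k - 1L) %% h))
}

#' Convert grid cells to pixel coordinates of cell centres
#'
#' Inverse companion of [map_fixations_to_grid()]: reports each cell's centre
#' in stimulus pixel coordinates, for exporting simulated fixations.
#'
#' @param cells tibble with 0-based `col`, `row`.
#' @param stimulus_width,stimulus_height stimulus size in pixels.
#' @param grid_width,grid_height grid size in cells.
#' @return A `fixation_set` with pixel `x`, `y`.
#' @export
cells_to_fixations <- function(cells, stimulus_width, stimulus_height,
                               grid_width = 96, grid_height = 54) {
  fixation_set(tibble(x = (cells$col + 0.5) * stimulus_width / grid_width,
                      y = (cells$row + 0.5) * stimulus_height / grid_height),
               stimulus_width, stimulus_height)
}

as_feature_set <- function(x, cfg) {
  if (!inherits(x, "feature_set")) {
    if (inherits(x, "bar_stimulus")) x <- x$image
    if (!inherits(x, "rgb_image"))
      abort("stimuli must be feature_set, rgb_image or bar_stimulus objects.",
            class = "salnet_config_error")
    x <- extract_features(build_pyramid(x), cfg$variant)
  }
  d <- dim(x[[1]])
  if (d[1] != cfg$grid_height || d[2] != cfg$grid_width)
    x <- resize_feature_set(x, cfg$grid_width, cfg$grid_height)
  x
}

#' Mean NSS over a stimulus set
#'
#' Simulates the network for every stimulus at the given configuration, scores
#' each steady-state saliency map against that stimulus's fixation cells, and
#' averages the per-stimulus NSS (unweighted). Stimuli whose NSS is undefined
#' (constant map) or that have no fixations are excluded from the aggregate
#' and counted in a warning.
#'
#' @param stimuli list of stimuli ([feature_set()], [rgb_image] or
#'   `bar_stimulus` objects).
#' @param fixations list (same length) of fixated grid-cell tibbles
#'   (`col`/`row`, 0-based).
#' @param cfg a [network_config()].
#' @param saliency_maps optional list of precomputed saliency maps (bypasses
#'   simulation; used by grid searches to reuse maps).
#' @return An `nss_result`: list with `scores` (per-stimulus tibble), the
#'   aggregate `mean_nss`, and `n_used`/`n_excluded`.
#' @export
mean_nss_over_stimuli <- function(stimuli, fixations, cfg,
                                  saliency_maps = NULL) {
  stopifnot(length(stimuli) == length(fixations))
  n <- length(stimuli)
  vals <- rep(NA_real_, n)
  nfix <- integer(n)
  for (i in seq_len(n)) {
    sal <- if (!is.null(saliency_maps)) saliency_maps[[i]]
           else simulate_saliency(as_feature_set(stimuli[[i]], cfg),
                                  cfg)$saliency
    cells <- fixations[[i]]
    nfix[i] <- NROW(cells)
    if (nfix[i] == 0) next
    vals[i] <- tryCatch(nss(sal, cells),
                        salnet_undefined_nss = function(e) NA_real_)
  }
  excluded <- is.na(vals)
  if (all(excluded))
    abort("NSS undefined for every stimulus; nothing to aggregate.",
          class = "salnet_aggregation_error")
  if (any(excluded))
    warn(sprintf("excluded %d stimulus/stimuli with undefined NSS or no fixations",
                 sum(excluded)), class = "salnet_nss_excluded")
  scores <- tibble(stimulus = seq_len(n), nss = vals, n_fixations = nfix,
                   excluded = excluded)
  structure(list(scores = scores, mean_nss = mean(vals[!excluded]),
                 n_used = sum(!excluded), n_excluded = sum(excluded)),
            class = "nss_result")
}

#' @export
print.nss_result <- function(x, ...) {
  cat(sprintf("<nss_result> mean NSS %.4f over %d stimuli (%d excluded)\n",
              x$mean_nss, x$n_used, x$n_excluded))
  invisible(x)
}

#' Grid-search estimation of the inhibitory weight
#'
#' For each candidate `w_i`, computes the mean NSS of the saliency maps
#' simulated at that value against the given fixation sets, and returns the
#' NSS-vs-`w_i` curve together with its argmax (ties broken toward the
#' smaller `w_i`). The best-corresponding value estimates the lateral
#' inhibition strength that generated the fixations.
#'
#' @param stimuli list of stimuli (as in [mean_nss_over_stimuli()]).
#' @param fixations list of fixated grid-cell tibbles, one per stimulus.
#' @param grid candidate `w_i` values.
#' @param cfg base [network_config()] (its `w_i` is replaced per grid value;
#'   all other parameters, e.g. `sigma_l`, stay fixed).
#' @param saliency_maps optional precomputed maps: list indexed by
#'   `as.character(w_i)`, each a list of maps per stimulus.
#' @param true_value the generating `w_i`, when known (recorded for
#'   reporting).
#' @return A `recovery_result`: list with `curve` (tibble `w_i`,
#'   `mean_nss`, `n_used`), `estimate`, and `true_value`.
#' @export
estimate_parameter <- function(stimuli, fixations, grid, cfg,
                               saliency_maps = NULL, true_value = NA_real_) {
  if (length(grid) == 0)
    abort("`grid` must be nonempty.", class = "salnet_precondition_error")
  grid <- sort(grid)
  rows <- purrr::map(grid, function(w) {
    cfg_w <- cfg
    cfg_w$lateral <- lapply(cfg_w$lateral, function(p) {
      if (is.null(p)) return(NULL)
      p$w_i <- w
      p
    })
    res <- mean_nss_over_stimuli(stimuli, fixations, cfg_w,
                                 saliency_maps = saliency_maps[[as.character(w)]])
    tibble(w_i = w, mean_nss = res$mean_nss, n_used = res$n_used)
  })
  curve <- dplyr::bind_rows(rows)
  est <- curve$w_i[which.max(curve$mean_nss)]  # first max = smallest w_i on ties
  structure(list(curve = curve, estimate = est, true_value = true_value),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> estimate w_i = %g%s\n", x$estimate,
              if (is.na(x$true_value)) "" else sprintf(" (true %g)", x$true_value)))
  print(x$curve)
  invisible(x)
}

#' Simulate saliency maps for a stimulus set over a grid of w_i values
#'
#' Helper for recovery experiments: runs the model once per (stimulus, `w_i`)
#' pair and returns the maps indexed as [estimate_parameter()] expects.
#'
#' @param stimuli list of stimuli.
#' @param grid `w_i` values.
#' @param cfg base configuration.
#' @return List indexed by `as.character(w_i)` of per-stimulus saliency maps.
#' @export
simulate_map_grid <- function(stimuli, grid, cfg) {
  fsets <- lapply(stimuli, as_feature_set, cfg = cfg)
  out <- list()
  for (w in grid) {
    cfg_w <- cfg
    cfg_w$lateral <- lapply(cfg_w$lateral, function(p) {
      if (is.null(p)) return(NULL)
      p$w_i <- w
      p
    })
    out[[as.character(w)]] <- lapply(fsets, function(fs)
      simulate_saliency(fs, cfg_w)$saliency)
  }
  out
}

#' Parameter-recovery experiment on synthetic bar stimuli
#'
#' Full simulation-based recovery check: generates `n_stimuli` random pop-out
#' bar stimuli, simulates saliency maps for every grid value, samples
#' `n_fixations` fixations per stimulus from the maps at each generating
#' `w_i`, and estimates `w_i` by grid search, repeated for several sampling
#' replicates. Saliency maps are deterministic, so they are computed once and
#' shared across replicates; replicate seeds only redraw the fixations.
#'
#' @param gen_values generating `w_i` values.
#' @param grid candidate `w_i` grid (should contain the generating values).
#' @param n_stimuli number of random bar stimuli.
#' @param n_fixations fixations sampled per stimulus.
#' @param seeds integer vector of replicate seeds.
#' @param cfg base configuration (defaults to the recovery setting
#'   `sigma_l = 6.4`).
#' @param stimulus_seed seed offset for the stimulus layouts.
#' @return A `recovery_experiment`: list with `estimates` (tibble
#'   `gen_w_i`, `seed`, `estimate`, `hit`), `curves` (tibble with per-replicate
#'   NSS curves) and the settings.
#' @export
run_recovery <- function(gen_values = c(120, 280),
                         grid = c(120, 160, 200, 240, 280),
                         n_stimuli = 20, n_fixations = 20, seeds = 1:5,
                         cfg = network_config(sigma_l = 6.4),
                         stimulus_seed = 1000) {
  stimuli <- lapply(seq_len(n_stimuli), function(i)
    generate_bar_stimulus(random_bar_layout(stimulus_seed + i)))
  grid_all <- sort(unique(c(grid, gen_values)))
  maps <- simulate_map_grid(stimuli, grid_all, cfg)
  est_rows <- list()
  curve_rows <- list()
  for (g in gen_values) {
    gen_maps <- maps[[as.character(g)]]
    for (s in seeds) {
      fix <- lapply(seq_along(gen_maps), function(i)
        sample_fixations(gen_maps[[i]], n_fixations,
                         seed = s * 10000 + i))
      rec <- estimate_parameter(stimuli, fix, grid, cfg,
                                saliency_maps = maps, true_value = g)
      est_rows[[length(est_rows) + 1L]] <-
        tibble(gen_w_i = g, seed = s, estimate = rec$estimate,
               hit = rec$estimate == g)
      curve_rows[[length(curve_rows) + 1L]] <-
        dplyr::mutate(rec$curve, gen_w_i = g, seed = s)
    }
  }
  structure(list(estimates = dplyr::bind_rows(est_rows),
                 curves = dplyr::bind_rows(curve_rows),
                 gen_values = gen_values, grid = grid,
                 n_stimuli = n_stimuli, n_fixations = n_fixations,
                 seeds = seeds),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("<recovery_experiment> %d stimuli x %d fixations, %d replicates\n",
              x$n_stimuli, x$n_fixations, length(x$seeds)))
  print(dplyr::summarise(dplyr::group_by(x$estimates, .data$gen_w_i),
                         hits = sum(.data$hit), n = dplyr::n()))
  invisible(x)
}

#' Mean activity of a region over time
#'
#' Averages the recorded activity of one map over the cells of a region mask,
#' per time step. Requires the map's trajectory to have been recorded
#' (`record =` in [simulate_saliency()]).
#'
#' @param sim a `salnet_sim` with a recorded trajectory, or a raw
#'   `h x w x steps` activity array.
#' @param mask logical `h x w` region mask (nonempty), or a named list of
#'   masks.
#' @param map map index (defaults to the saliency map).
#' @return Tibble with columns `t` (ms), `region`, `mean_activity`.
#' @export
region_mean_activity <- function(sim, mask, map = NULL) {
  arr <- if (is.array(sim) && length(dim(sim)) == 3L) sim
  else {
    map <- map %||% sim$config$saliency_map
    tr <- sim$trajectory[[paste0("map", map)]]
    if (is.null(tr))
      abort(sprintf("map %d's trajectory was not recorded; pass record = %d to simulate_saliency().",
                    map, map), class = "salnet_precondition_error")
    tr
  }
  masks <- if (is.list(mask)) mask else list(region = mask)
  if (is.null(names(masks))) names(masks) <- paste0("region_", seq_along(masks))
  steps <- dim(arr)[3]
  purrr::map2_dfr(masks, names(masks), function(m, nm) {
    if (!any(m)) abort("region mask is empty.", class = "salnet_precondition_error")
    flat <- matrix(arr, prod(dim(arr)[1:2]), steps)
    tibble(t = seq_len(steps), region = nm,
           mean_activity = colMeans(flat[as.vector(m), , drop = FALSE]))
  })
}

#' Region saliency summary for a bar stimulus
#'
#' Summarizes a saliency map over the regions of a pop-out bar stimulus: the
#' target bar, each distractor bar, and the background, at the model grid
#' resolution.
#'
#' @param sal saliency map matrix.
#' @param stim the `bar_stimulus` the map was computed from.
#' @param threshold area-coverage threshold for [grid_region_masks()].
#' @return Tibble with columns `region` (`"target"`, `"distractor_<i>"`,
#'   `"background"`), `n_cells`, `mean_saliency`.
#' @export
region_saliency <- function(sal, stim, threshold = 0.5) {
  gm <- grid_region_masks(stim, grid_width = ncol(sal), grid_height = nrow(sal),
                          threshold = threshold)
  regions <- list()
  di <- 0
  for (b in seq_along(gm$bars)) {
    nm <- if (!is.na(gm$target) && b == gm$target) "target"
          else { di <- di + 1; paste0("distractor_", di) }
    regions[[nm]] <- gm$bars[[b]]
  }
  regions[["background"]] <- gm$background
  purrr::map2_dfr(regions, names(regions), function(m, nm)
    tibble(region = nm, n_cells = sum(m),
           mean_saliency = if (any(m)) mean(sal[m]) else NA_real_))
}

#' Salient-to-non-salient contrast of a saliency map
#'
#' Ratio of the mean saliency over the target-bar region to the mean over the
#' union of all distractor-bar regions; the scalar used to compare
#' perturbation conditions.
#'
#' @inheritParams region_saliency
#' @return A single ratio.
#' @export
salience_contrast <- function(sal, stim, threshold = 0.5) {
  rs <- region_saliency(sal, stim, threshold)
  tgt <- rs$mean_saliency[rs$region == "target"]
  dis <- dplyr::filter(rs, grepl("^distractor", .data$region))
  mean_dis <- sum(dis$mean_saliency * dis$n_cells) / sum(dis$n_cells)
  tgt / mean_dis
}
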