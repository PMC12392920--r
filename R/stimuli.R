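# Stimulus handling: image I/O, the three-level resolution pyramid, synthetic
# bar-array stimuli, and fixation files.
#
# Conventions used throughout the package:
#   * images are numeric arrays dim = c(height, width, 3), values in [0, 1],
#     row 1 at the top of the picture;
#   * pixel and grid coordinates are 0-based, x = column, y = row, origin at
#     the top-left corner, each pixel covering the half-open box
#     [x, x + 1) x [y, y + 1).

PYRAMID_LEVELS <- list(x384 = c(w = 384L, h = 216L),
                       x192 = c(w = 192L, h = 108L),
                       x96  = c(w = 96L,  h = 54L))

#' Construct an RGB image object
#'
#' Wraps a `height x width x 3` numeric array of channel intensities in
#' `[0, 1]`. All image-producing functions in the package return this class.
#'
#' @param x numeric array with `dim = c(height, width, 3)`, values in `[0, 1]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    abort("`x` must be a height x width x 3 array.", class = "salnet_format_error")
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    abort("image values must lie in [0, 1].", class = "salnet_format_error")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    abort("image must have at least one pixel.", class = "salnet_format_error")
  structure(x, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels (width x height), range [%.3f, %.3f]\n",
              d[2], d[1], min(x), max(x)))
  invisible(x)
}

#' Load an image file as a normalized RGB array
#'
#' Reads a PNG, JPEG or TIFF raster and returns channel values normalized to
#' `[0, 1]` (8-bit values are divided by 255, 16-bit by 65535, as done by the
#' format readers). Grayscale images are replicated onto three channels; an
#' alpha channel, if present, is dropped.
#'
#' @param path path to the image file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    abort(paste0("cannot read image: file not found: ", path),
          class = "salnet_io_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      abort(paste0("unsupported image format '", ext, "' for ", path,
                   " (supported: png, jpeg, tiff)"),
            class = "salnet_format_error")
    ),
    error = function(e) {
      if (inherits(e, "salnet_format_error")) stop(e)
      abort(paste0("failed to decode image ", path, ": ", conditionMessage(e)),
            class = "salnet_io_error")
    }
  )
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  nc <- dim(arr)[3]
  if (nc == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  else if (nc >= 3L) arr <- arr[, , 1:3, drop = FALSE]
  else abort(paste0("image ", path, " has ", nc, " channels; expected 1, 3 or 4"),
             class = "salnet_format_error")
  rgb_image(pmin(pmax(arr, 0), 1))
}

# 1-D area-resampling operator: rows are output pixels, columns input pixels,
# entry (i, j) = fraction of output pixel i's footprint covered by input pixel
# j. Rows sum to 1, so constant signals are preserved exactly.
area_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov / scale
    }
  }
  W
}

#' Area-average resampling of a matrix
#'
#' Resamples a matrix to a target size by exact area averaging (block average
#' when the ratio is an integer). Preserves constant inputs exactly and the
#' mean value of the input.
#'
#' @param mat numeric matrix.
#' @param out_h,out_w target number of rows / columns.
#' @return A numeric `out_h x out_w` matrix.
#' @export
resize_area <- function(mat, out_h, out_w) {
  area_weights(nrow(mat), out_h) %*% mat %*% t(area_weights(ncol(mat), out_w))
}

resize_area_rgb <- function(img, out_h, out_w) {
  out <- array(0, c(out_h, out_w, 3L))
  for (k in 1:3) out[, , k] <- resize_area(img[, , k], out_h, out_w)
  out
}

#' Build the three-level resolution pyramid
#'
#' Downsizes an image to the three working resolutions used by the model:
#' 384 x 216, 192 x 108 and 96 x 54 (width x height). Downsizing is
#' area-average resampling; the two coarser levels are obtained by exact 2 x 2
#' block averaging of the level above, so the levels nest consistently.
#'
#' @param img an [rgb_image] (any input size).
#' @return A `resolution_pyramid`: named list of [rgb_image]s
#'   `x384`, `x192`, `x96`.
#' @export
build_pyramid <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  l384 <- resize_area_rgb(img, 216L, 384L)
  l192 <- resize_area_rgb(l384, 108L, 192L)
  l96  <- resize_area_rgb(l192, 54L, 96L)
  structure(list(x384 = rgb_image(pmin(pmax(l384, 0), 1)),
                 x192 = rgb_image(pmin(pmax(l192, 0), 1)),
                 x96  = rgb_image(pmin(pmax(l96, 0), 1))),
            class = "resolution_pyramid")
}

#' @export
print.resolution_pyramid <- function(x, ...) {
  cat("<resolution_pyramid> levels: 384x216, 192x108, 96x54\n")
  invisible(x)
}

col_to_rgb01 <- function(col) as.numeric(grDevices::col2rgb(col)) / 255

#' Describe a bar-array stimulus layout
#'
#' Builds a layout tibble for [generate_bar_stimulus()], one row per bar.
#' Angles are in degrees with 0 = horizontal (bar axis along x) and
#' 90 = vertical; `target` marks the odd-one-out bar used by region-contrast
#' summaries.
#'
#' @param cx,cy bar centre, pixels (0-based image coordinates).
#' @param length,width bar extent along / across its axis, pixels.
#' @param angle bar axis angle in degrees (0 horizontal, 90 vertical).
#' @param color any R colour specification.
#' @param target logical, is this the designated salient bar?
#' @return A tibble with class `bar_layout`.
#' @export
bar_layout <- function(cx, cy, length, width, angle, color, target = FALSE) {
  out <- tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                length = as.numeric(length), width = as.numeric(width),
                angle = as.numeric(angle), color = as.character(color),
                target = as.logical(target))
  class(out) <- c("bar_layout", class(out))
  out
}

#' Default pop-out bar layout
#'
#' A 5 x 2 grid of bars on a black 1920 x 1080 background: one vertical red
#' bar (the target) among nine horizontal blue bars, the classic colour +
#' orientation pop-out display. Bars are 180 x 36 px and centred in their grid
#' cells.
#'
#' @param stim_width,stim_height stimulus size in pixels.
#' @param n_cols,n_rows grid of bar positions.
#' @param bar_length,bar_width bar geometry in pixels.
#' @param target_index which grid cell (1-based, column-major) holds the
#'   target bar.
#' @param target_color,distractor_color bar colours.
#' @return A `bar_layout` tibble of `n_cols * n_rows` bars.
#' @export
default_bar_layout <- function(stim_width = 1920, stim_height = 1080,
                               n_cols = 5, n_rows = 2,
                               bar_length = 180, bar_width = 36,
                               target_index = 2,
                               target_color = "red",
                               distractor_color = "blue") {
  cw <- stim_width / n_cols
  ch <- stim_height / n_rows
  idx <- seq_len(n_cols * n_rows)
  col <- (idx - 1) %/% n_rows
  row <- (idx - 1) %% n_rows
  is_target <- idx == target_index
  bar_layout(cx = (col + 0.5) * cw,
             cy = (row + 0.5) * ch,
             length = bar_length, width = bar_width,
             angle = ifelse(is_target, 90, 0),
             color = ifelse(is_target, target_color, distractor_color),
             target = is_target)
}

#' Random pop-out bar layout
#'
#' Draws a random variant of the pop-out display: the target bar occupies a
#' random grid cell, the target/distractor colour pair is drawn from a palette
#' of saturated colours, the target is vertical among horizontal distractors
#' (or the reverse), and bar centres are jittered within their cells. Used to
#' build stimulus sets for parameter-recovery experiments.
#'
#' @param seed integer seed; the layout is a deterministic function of it.
#' @inheritParams default_bar_layout
#' @param jitter maximum centre jitter in pixels (uniform in each axis).
#' @param palette candidate bar colours; target and distractor colours are
#'   distinct draws.
#' @return A `bar_layout` tibble.
#' @export
random_bar_layout <- function(seed, stim_width = 1920, stim_height = 1080,
                              n_cols = 5, n_rows = 2,
                              bar_length = 180, bar_width = 36,
                              jitter = 40,
                              palette = c("red", "green", "blue", "yellow")) {
  withr::with_seed(seed, {
    cols <- sample(palette, 2)
    target_index <- sample.int(n_cols * n_rows, 1)
    flip <- runif(1) < 0.5  # vertical target among horizontal bars, or reverse
    lay <- default_bar_layout(stim_width, stim_height, n_cols, n_rows,
                              bar_length, bar_width, target_index,
                              target_color = cols[1], distractor_color = cols[2])
    if (flip) lay$angle <- 90 - lay$angle
    n <- nrow(lay)
    lay$cx <- lay$cx + runif(n, -jitter, jitter)
    lay$cy <- lay$cy + runif(n, -jitter, jitter)
    lay
  })
}

rasterize_bar <- function(bar, width, height) {
  # pixel centres in 0-based coordinates
  th <- bar$angle * pi / 180
  u <- c(cos(th), sin(th))   # along the bar axis (y down; sign irrelevant)
  v <- c(-sin(th), cos(th))  # across
  hx <- abs(u[1]) * bar$length / 2 + abs(v[1]) * bar$width / 2
  hy <- abs(u[2]) * bar$length / 2 + abs(v[2]) * bar$width / 2
  x0 <- max(0L, floor(bar$cx - hx)); x1 <- min(width - 1L, ceiling(bar$cx + hx))
  y0 <- max(0L, floor(bar$cy - hy)); y1 <- min(height - 1L, ceiling(bar$cy + hy))
  m <- matrix(FALSE, height, width)
  if (x1 < x0 || y1 < y0) return(m)
  xs <- (x0:x1) + 0.5 - bar$cx
  ys <- (y0:y1) + 0.5 - bar$cy
  du <- outer(ys * u[2], xs * u[1], `+`)  # projection onto bar axis
  dv <- outer(ys * v[2], xs * v[1], `+`)
  inside <- abs(du) <= bar$length / 2 & abs(dv) <= bar$width / 2
  m[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- inside
  m
}

#' Render a bar-array stimulus
#'
#' Rasterizes a [bar_layout] onto a uniform background. Bars must not overlap
#' and must fit inside the image. The per-bar region masks are returned
#' alongside the image; they are pairwise disjoint by construction (overlap is
#' an error).
#'
#' @param layout a `bar_layout` tibble (possibly empty: uniform background).
#' @param width,height stimulus size in pixels.
#' @param background background colour.
#' @return A `bar_stimulus`: list with elements `image` ([rgb_image]), `masks`
#'   (list of logical `height x width` matrices, one per bar) and `layout`.
#' @export
generate_bar_stimulus <- function(layout, width = 1920, height = 1080,
                                  background = "black") {
  stopifnot(is.data.frame(layout))
  bg <- col_to_rgb01(background)
  img <- array(rep(bg, each = height * width), c(height, width, 3L))
  masks <- vector("list", nrow(layout))
  covered <- matrix(FALSE, height, width)
  for (b in seq_len(nrow(layout))) {
    bar <- layout[b, ]
    m <- rasterize_bar(bar, width, height)
    if (any(m & covered))
      abort(sprintf("bars overlap (bar %d intersects an earlier bar)", b),
            class = "salnet_layout_error")
    covered <- covered | m
    rgbv <- col_to_rgb01(bar$color)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[m] <- rgbv[k]
      img[, , k] <- ch
    }
    masks[[b]] <- m
  }
  structure(list(image = rgb_image(img), masks = masks, layout = layout),
            class = "bar_stimulus")
}

#' @export
print.bar_stimulus <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<bar_stimulus> %d bars on %d x %d px background\n",
              length(x$masks), d[2], d[1]))
  invisible(x)
}

#' Project stimulus-resolution region masks onto the model grid
#'
#' Converts the pixel-resolution bar masks of a [generate_bar_stimulus()]
#' result to the network grid: a grid cell belongs to a bar region when at
#' least `threshold` of its area is covered by the bar. The background region
#' is the set of cells with zero bar coverage.
#'
#' @param stim a `bar_stimulus`.
#' @param grid_width,grid_height model grid size.
#' @param threshold minimum covered-area fraction for membership.
#' @return List with `bars` (list of logical `grid_height x grid_width`
#'   matrices), `background` (logical matrix) and `target` (index of the
#'   target bar, or `NA`).
#' @export
grid_region_masks <- function(stim, grid_width = 96, grid_height = 54,
                              threshold = 0.5) {
  stopifnot(inherits(stim, "bar_stimulus"))
  bars <- lapply(stim$masks, function(m) {
    resize_area(m * 1, grid_height, grid_width) >= threshold
  })
  any_cov <- Reduce(`+`, c(list(matrix(0, grid_height, grid_width)),
                           lapply(stim$masks, function(m)
                             resize_area(m * 1, grid_height, grid_width))))
  tgt <- which(stim$layout$target)
  list(bars = bars,
       background = any_cov == 0,
       target = if (length(tgt)) tgt[1] else NA_integer_)
}

#' Read fixation points from CSV
#'
#' Reads the package's fixation CSV dialect: a header `x,y` with an optional
#' third `observer` column, one point per row, 0-based pixel coordinates.
#' Points outside the stimulus bounds are dropped with a warning reporting the
#' count; row order is preserved.
#'
#' @param path CSV file path.
#' @param stimulus_width,stimulus_height stimulus size in pixels.
#' @return A `fixation_set`: tibble with columns `x`, `y` (and `observer` if
#'   present) and attributes `stimulus_width`, `stimulus_height`.
#' @export
read_fixations <- function(path, stimulus_width, stimulus_height) {
  if (!file.exists(path))
    abort(paste0("fixation file not found: ", path), class = "salnet_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prb <- readr::problems(df)
  if (nrow(prb) > 0)
    abort(sprintf("malformed fixation file %s: first problem at line %d (%s)",
                  path, prb$row[1] + 1L, prb$expected[1]),
          class = "salnet_parse_error")
  if (!all(c("x", "y") %in% names(df)))
    abort(paste0("fixation file ", path, " must have columns x,y[,observer]"),
          class = "salnet_parse_error")
  if (nrow(df) > 0 && (!is.numeric(df$x) || !is.numeric(df$y)))
    abort(paste0("fixation coordinates in ", path, " must be numeric"),
          class = "salnet_parse_error")
  fixation_set(df, stimulus_width, stimulus_height)
}

#' Construct a fixation set
#'
#' @param points data frame with numeric columns `x`, `y` (0-based pixels) and
#'   optionally `observer`; out-of-bounds points are dropped with a warning.
#' @param stimulus_width,stimulus_height stimulus size in pixels.
#' @return A `fixation_set` tibble.
#' @export
fixation_set <- function(points, stimulus_width, stimulus_height) {
  df <- as_tibble(points)
  keep <- intersect(c("x", "y", "observer"), names(df))
  df <- df[, keep, drop = FALSE]
  if (nrow(df) > 0) {
    ok <- df$x >= 0 & df$x < stimulus_width & df$y >= 0 & df$y < stimulus_height
    if (any(!ok)) {
      warn(sprintf("dropped %d fixation(s) outside the %d x %d stimulus bounds",
                   sum(!ok), stimulus_width, stimulus_height),
           class = "salnet_fixations_dropped")
      df <- df[ok, , drop = FALSE]
    }
  }
  structure(df,
            stimulus_width = stimulus_width, stimulus_height = stimulus_height,
            class = c("fixation_set", class(as_tibble(df))))
}

#' Write fixation points to CSV
#'
#' @param fx a `fixation_set` (or data frame with `x`, `y`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fx, path) {
  readr::write_csv(as_tibble(as.data.frame(fx)), path, progress = FALSE)
  invisible(path)
}

#' Map pixel fixations onto the model grid
#'
#' Maps fixation pixel coordinates onto grid cells by floor scaling:
#' `cell = floor(coordinate * grid_size / stimulus_size)`, clamped to the
#' valid range. Duplicates are preserved. Both pixels and cells are 0-based.
#'
#' @param fx a `fixation_set`, or a data frame with `x`, `y` plus explicit
#'   `stimulus_width`/`stimulus_height` arguments.
#' @param grid_width,grid_height grid size in cells.
#' @param stimulus_width,stimulus_height override the stimulus size recorded
#'   in `fx` (required when `fx` is a plain data frame).
#' @return A tibble with 0-based integer columns `col`, `row`.
#' @export
map_fixations_to_grid <- function(fx, grid_width = 96, grid_height = 54,
                                  stimulus_width = attr(fx, "stimulus_width"),
                                  stimulus_height = attr(fx, "stimulus_height")) {
  if (is.null(stimulus_width) || is.null(stimulus_height))
    abort("stimulus dimensions are required to map fixations onto the grid.")
  col <- pmin(pmax(floor(fx$x * grid_width / stimulus_width), 0), grid_width - 1)
  row <- pmin(pmax(floor(fx$y * grid_height / stimulus_height), 0), grid_height - 1)
  tibble(col = as.integer(col), row = as.integer(row))
}
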