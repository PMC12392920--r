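# Feature extraction: the nine 96 x 54 feature images that drive the network.
#
# Orientation convention: the Gabor kernel's carrier oscillates along the
# rotated x axis (angle theta, measured in screen coordinates with y pointing
# down), while its Gaussian envelope is elongated along the rotated y axis
# (aspect ratio gamma < 1). A filter with carrier angle theta therefore
# responds most strongly to bars whose axis is perpendicular to theta: the
# theta = 0 channel prefers vertical bars, theta = 90 prefers horizontal bars.
# This pairing is pinned down by a generated-bar test.

#' Half-wave rectification
#'
#' The linear gain function used throughout the model: identity on positive
#' values, zero otherwise.
#'
#' @param x numeric vector/matrix/array (finite).
#' @return `pmax(x, 0)` with the same shape.
#' @export
rectify <- function(x) pmax(x, 0)

#' Luminance (intensity) feature
#'
#' Per-pixel mean of the three channels, `(V_red + V_green + V_blue) / 3`.
#' This is also the intensity image fed to the Gabor filters.
#'
#' @param img an [rgb_image] at any resolution.
#' @return A numeric matrix of the image's size.
#' @export
luminance_feature <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Colour-opponency features
#'
#' Red-green and blue-yellow opponent responses, rectified and normalized by
#' luminance: red `g(V_r - V_g)/F_lum`, green `g(V_g - V_r)/F_lum`, blue
#' `g(V_b - V_yellow)/F_lum`, yellow `g(V_yellow - V_b)/F_lum`, with
#' `V_yellow = min(V_r, V_g)`. Where the luminance is exactly zero the output
#' is defined as 0: black pixels carry no chromatic signal (this guard is a
#' definition, not an error).
#'
#' @param img an [rgb_image] (normally the 96 x 54 pyramid level).
#' @return Named list of four nonnegative matrices: `red`, `green`, `blue`,
#'   `yellow`.
#' @export
color_features <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  lum <- (r + g + b) / 3
  yel <- pmin(r, g)
  safe_div <- function(num) {
    out <- num
    nz <- lum > 0
    out[nz] <- num[nz] / lum[nz]
    out[!nz] <- 0
    out
  }
  list(red    = safe_div(rectify(r - g)),
       green  = safe_div(rectify(g - r)),
       blue   = safe_div(rectify(b - yel)),
       yellow = safe_div(rectify(yel - b)))
}

#' Complex Gabor kernel
#'
#' Evaluates the complex Gabor function
#' `G(x, y) = exp(-(x_t^2 + (gamma y_t)^2) / (2 sigma^2)) * exp(i omega0 x_t)`
#' with `x_t = x cos(theta) + y sin(theta)`,
#' `y_t = -x sin(theta) + y cos(theta)`, on an integer grid
#' `-half_width .. half_width` (y increases downward, matching image rows).
#'
#' @param theta carrier orientation in degrees.
#' @param gamma spatial aspect ratio of the Gaussian envelope.
#' @param sigma envelope standard deviation, pixels.
#' @param omega0 carrier spatial frequency, radians per pixel.
#' @param half_width kernel support half-width in pixels; the default 12
#'   (`>= 3 * sigma / gamma`) truncates the envelope below 2e-8.
#' @return A complex `(2 half_width + 1)^2` matrix; rows index y, columns x.
#' @export
gabor_kernel <- function(theta, gamma = 0.5, sigma = 2, omega0 = 2,
                         half_width = 12) {
  th <- theta * pi / 180
  off <- -half_width:half_width
  x <- matrix(off, 2 * half_width + 1, 2 * half_width + 1, byrow = TRUE)
  y <- matrix(off, 2 * half_width + 1, 2 * half_width + 1)
  xt <- x * cos(th) + y * sin(th)
  yt <- -x * sin(th) + y * cos(th)
  exp(-(xt^2 + (gamma * yt)^2) / (2 * sigma^2)) * exp(1i * omega0 * xt)
}

#' Bank of four oriented Gabor kernels
#'
#' @inheritParams gabor_kernel
#' @param orientations carrier angles in degrees.
#' @return A `gabor_bank`: list with `kernels` (named complex matrices) and
#'   the parameters.
#' @export
gabor_bank <- function(orientations = c(0, 45, 90, 135), gamma = 0.5,
                       sigma = 2, omega0 = 2, half_width = 12) {
  kernels <- lapply(orientations, gabor_kernel, gamma = gamma, sigma = sigma,
                    omega0 = omega0, half_width = half_width)
  names(kernels) <- as.character(orientations)
  structure(list(kernels = kernels, orientations = orientations, gamma = gamma,
                 sigma = sigma, omega0 = omega0, half_width = half_width),
            class = "gabor_bank")
}

#' Same-size 2-D convolution
#'
#' Convolution `O(x, y) = sum_{u,v} K(x - u, y - v) X(u, v)` with zero padding
#' outside the image and output of the image's size (the kernel is indexed on
#' `-h..h`). Computed via FFT; equal to the direct double-loop sum to within
#' floating-point rounding.
#'
#' @param x numeric or complex matrix.
#' @param k odd-sized (2h+1 x 2h+1) numeric or complex kernel matrix.
#' @return Matrix of `dim(x)`; complex if `x` or `k` is complex.
#' @export
conv2_same <- function(x, k) {
  hr <- nrow(x); wc <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ph <- hr + kh - 1L; pw <- wc + kw - 1L
  px <- matrix(0i, ph, pw); px[1:hr, 1:wc] <- x
  pk <- matrix(0i, ph, pw); pk[1:kh, 1:kw] <- k
  full <- fft(fft(px) * fft(pk), inverse = TRUE) / (ph * pw)
  hy <- (kh - 1L) %/% 2L; hx <- (kw - 1L) %/% 2L
  out <- full[(hy + 1):(hy + hr), (hx + 1):(hx + wc)]
  if (!is.complex(x) && !is.complex(k)) Re(out) else out
}

block_mean <- function(mat, f) {
  h <- nrow(mat) %/% f; w <- ncol(mat) %/% f
  # average f x f blocks: fold rows then columns
  m1 <- matrix(colMeans(matrix(mat, f, h * ncol(mat))), h, ncol(mat))
  t(matrix(colMeans(matrix(t(m1), f, w * h)), w, h))
}

#' Multi-scale Gabor orientation features
#'
#' For each carrier orientation, convolves the intensity image of every
#' pyramid level with the complex Gabor kernel, takes the response magnitude,
#' block-averages the 192 x 108 and 384 x 216 responses down to 96 x 54
#' (2 x 2 and 4 x 4 blocks), and averages the three maps. Taking the
#' magnitude before downsizing preserves fine-scale structure that phase
#' cancellation would otherwise remove.
#'
#' @param pyr a [build_pyramid()] result.
#' @param bank a [gabor_bank()].
#' @return Named list of four nonnegative 54 x 96 matrices (carrier angles).
#' @export
orientation_features <- function(pyr, bank = gabor_bank()) {
  stopifnot(inherits(pyr, "resolution_pyramid"))
  vints <- lapply(pyr, luminance_feature)
  out <- lapply(bank$kernels, function(k) {
    o96  <- Mod(conv2_same(vints$x96, k))
    o192 <- block_mean(Mod(conv2_same(vints$x192, k)), 2L)
    o384 <- block_mean(Mod(conv2_same(vints$x384, k)), 4L)
    (o96 + o192 + o384) / 3
  })
  names(out) <- names(bank$kernels)
  out
}

#' Extract the model's feature set from a pyramid
#'
#' Assembles the nine feature images of the proposed model (luminance, four
#' colour-opponency channels, four orientation channels), or the four inputs
#' of the Brecht-Saiki variant (raw red and green channels plus 0 and 90
#' degree Gabor magnitudes computed at 96 x 54 only).
#'
#' @param pyr a [build_pyramid()] result.
#' @param variant `"proposed"` (nine features) or `"brecht_saiki"` (four).
#' @param bank Gabor bank used for the orientation channels.
#' @return A `feature_set`: named list of nonnegative 54 x 96 matrices with a
#'   `variant` attribute. Proposed-variant names: `lum`, `col_red`,
#'   `col_green`, `col_blue`, `col_yellow`, `ori_0`, `ori_45`, `ori_90`,
#'   `ori_135`. Variant names: `v_red`, `v_green`, `ori_0`, `ori_90`.
#' @export
extract_features <- function(pyr, variant = c("proposed", "brecht_saiki"),
                             bank = gabor_bank()) {
  variant <- match.arg(variant)
  stopifnot(inherits(pyr, "resolution_pyramid"))
  img96 <- pyr$x96
  if (variant == "proposed") {
    cols <- color_features(img96)
    oris <- orientation_features(pyr, bank)
    feature_set(list(lum = luminance_feature(img96),
                     col_red = cols$red, col_green = cols$green,
                     col_blue = cols$blue, col_yellow = cols$yellow,
                     ori_0 = oris[["0"]], ori_45 = oris[["45"]],
                     ori_90 = oris[["90"]], ori_135 = oris[["135"]]),
                variant = "proposed")
  } else {
    vint <- luminance_feature(img96)
    feature_set(list(v_red = img96[, , 1], v_green = img96[, , 2],
                     ori_0 = Mod(conv2_same(vint, bank$kernels[["0"]])),
                     ori_90 = Mod(conv2_same(vint, bank$kernels[["90"]]))),
                variant = "brecht_saiki")
  }
}

#' Construct a feature set from matrices
#'
#' Validates and labels a named list of equally sized nonnegative matrices.
#' Mostly useful for building small synthetic inputs.
#'
#' @param maps named list of numeric matrices, all of one size, values >= 0.
#' @param variant which model variant the names follow.
#' @return A `feature_set`.
#' @export
feature_set <- function(maps, variant = c("proposed", "brecht_saiki")) {
  variant <- match.arg(variant)
  need <- if (variant == "proposed")
    c("lum", "col_red", "col_green", "col_blue", "col_yellow",
      "ori_0", "ori_45", "ori_90", "ori_135")
  else c("v_red", "v_green", "ori_0", "ori_90")
  if (!setequal(names(maps), need))
    abort(paste0("feature set for variant '", variant, "' needs maps: ",
                 paste(need, collapse = ", ")), class = "salnet_config_error")
  maps <- maps[need]
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1)
    abort("all feature maps must share one size.", class = "salnet_config_error")
  if (any(vapply(maps, function(m) anyNA(m) || min(m) < 0, logical(1))))
    abort("feature maps must be finite and nonnegative.",
          class = "salnet_config_error")
  structure(maps, variant = variant, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<feature_set> variant '%s': %d maps of %d x %d cells\n",
              attr(x, "variant"), length(x), d[2], d[1]))
  invisible(x)
}

#' Resample a feature set to another grid size
#'
#' Area-averages every feature map to the target grid, preserving
#' nonnegativity and mean level. Used for reduced-resolution simulations
#' (with lateral length scales rescaled accordingly by the caller).
#'
#' @param fs a `feature_set`.
#' @param grid_width,grid_height target grid size.
#' @return A `feature_set` at the new size.
#' @export
resize_feature_set <- function(fs, grid_width, grid_height) {
  out <- lapply(fs, function(m) pmax(resize_area(m, grid_height, grid_width), 0))
  feature_set(out, attr(fs, "variant"))
}

#' Export a feature set as CSV matrices
#'
#' Writes one `<name>.csv` per feature map (plain matrix, no header) into a
#' directory, for debugging and fixtures.
#'
#' @param fs a `feature_set`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_feature_set <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fs))
    utils::write.table(fs[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
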