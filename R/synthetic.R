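# Synthetic cohort generator: causal-AR textured patches embedded in smooth
# background images, with the study layout (5 groups, 49 rats, 5 slices per
# rat, 2 ROIs per slice -> 245 ROIs) as the default conditions.

#' Group texture parameters
#'
#' Parameters of the causal 2D autoregressive texture process used to
#' synthesize group-specific patches:
#' `x(i,j) = a1 x(i,j-1) + a2 x(i-1,j-1) + a3 x(i-1,j) + a4 x(i-1,j+1) + eps`.
#' Stability requires `|a1|+|a2|+|a3|+|a4| < 1`.
#'
#' @param mean Mean intensity added after texture generation.
#' @param noise_sd Innovation standard deviation (> 0).
#' @param a Length-4 numeric: coefficients for the left, upper-left, upper
#'   and upper-right causal neighbors.
#' @return List of class `group_texture_params`.
#' @export
group_texture_params <- function(mean = 100, noise_sd = 1,
                                 a = c(0.1, 0, 0.1, 0)) {
  a <- as.numeric(a)
  if (length(a) != 4L) stop("a must have length 4")
  if (sum(abs(a)) >= 1) stop("unstable AR coefficients: sum(|a|) must be < 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(mean = mean, noise_sd = noise_sd, a = a),
            class = "group_texture_params")
}

#' Generate one textured patch
#'
#' Runs the causal AR recursion over an enlarged grid (20 extra rows above
#' and 20 extra columns on each side, cropped afterwards so edge
#' initialization does not contaminate the output) and adds the mean
#' intensity last.
#'
#' @param params A [group_texture_params()].
#' @param height,width Output patch size in pixels.
#' @param seed Integer seed; same seed, same patch.
#' @return An [image2d()].
#' @export
generate_patch <- function(params, height, width, seed) {
  stopifnot(inherits(params, "group_texture_params"))
  a <- params$a
  hh <- height + 20L
  ww <- width + 40L
  set.seed(seed)
  eps <- matrix(stats::rnorm(hh * ww, 0, params$noise_sd), hh, ww)
  x <- matrix(0, hh, ww)
  x[1, ] <- eps[1, ]
  for (i in 2:hh) {
    up <- x[i - 1, ]
    drive <- eps[i, ] +
      a[2] * c(0, up[-ww]) +      # upper-left
      a[3] * up +                 # upper
      a[4] * c(up[-1], 0)         # upper-right
    x[i, ] <- stats::filter(drive, a[1], method = "recursive")
  }
  out <- x[21:(20 + height), 21:(20 + width), drop = FALSE] + params$mean
  image2d(out, generator = "causal-ar", seed = seed)
}

#' Cohort configuration
#'
#' Defines the synthetic study layout. The defaults reproduce the standard
#' conditions used throughout this package: five groups (control and four
#' post-stress time points) with 10/10/10/9/10 rats and 5 slices per rat,
#' one pooled ROI row per slice — 50/50/50/45/50 = 245 ROIs in total —
#' each ROI an 8 x 9 rectangle inside a 64 x 64 image. Setting
#' `rois_per_slice = 2` instead emits independent left/right rectangles.
#'
#' @param groups Character vector of group names.
#' @param rats_per_group Integer vector, one entry per group.
#' @param params Named list of [group_texture_params()], one per group;
#'   default gives every group the same mild texture (a null cohort).
#' @param slices_per_rat,rois_per_slice,roi_width,roi_height,image_size
#'   Layout parameters.
#' @param seed Master seed; the whole cohort is a pure function of the
#'   config.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("control", "SPS1d", "SPS4d", "SPS7d", "SPS14d"),
                          rats_per_group = c(10L, 10L, 10L, 9L, 10L),
                          params = NULL,
                          slices_per_rat = 5L, rois_per_slice = 1L,
                          roi_width = 8L, roi_height = 9L,
                          image_size = 64L, seed = 1L) {
  if (length(rats_per_group) != length(groups))
    stop("rats_per_group must match groups")
  if (is.null(params))
    params <- stats::setNames(replicate(length(groups), group_texture_params(),
                                        simplify = FALSE), groups)
  if (!all(groups %in% names(params)))
    stop("params must contain an entry for every group")
  if (!rois_per_slice %in% c(1L, 2L))
    stop("rois_per_slice must be 1 (pooled, centered) or 2 (left/right)")
  structure(
    list(groups = groups, rats_per_group = as.integer(rats_per_group),
         params = params, slices_per_rat = as.integer(slices_per_rat),
         rois_per_slice = as.integer(rois_per_slice),
         roi_width = as.integer(roi_width), roi_height = as.integer(roi_height),
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Preset cohort configurations
#'
#' `"null"`: all five groups share identical texture parameters (no true
#' group signal). `"effect"`: groups differ in the horizontal AR
#' coefficient `a1` (-0.5, -0.2, 0.1, 0.4, 0.7; adjacent gap 0.3) at equal
#' mean and noise, a strong pure-texture group effect.
#'
#' @param preset `"null"` or `"effect"`.
#' @param seed Master seed.
#' @return A [cohort_config()].
#' @export
cohort_preset <- function(preset = c("null", "effect"), seed = 1L) {
  preset <- match.arg(preset)
  groups <- c("control", "SPS1d", "SPS4d", "SPS7d", "SPS14d")
  params <- if (preset == "null") {
    stats::setNames(replicate(5, group_texture_params(a = c(0.1, 0, 0.1, 0)),
                              simplify = FALSE), groups)
  } else {
    a1 <- c(-0.5, -0.2, 0.1, 0.4, 0.7)
    stats::setNames(lapply(a1, function(v)
      group_texture_params(a = c(v, 0, 0.1, 0))), groups)
  }
  cohort_config(groups = groups, params = params, seed = seed)
}

# smooth low-frequency background field: bilinear upsampling of coarse noise
.background_field <- function(size, seed, base = 60, amplitude = 20) {
  set.seed(seed)
  coarse_n <- 8L
  coarse <- matrix(stats::rnorm(coarse_n^2), coarse_n, coarse_n)
  src <- seq(1, size, length.out = coarse_n)
  dst <- seq_len(size)
  rows <- t(apply(coarse, 1, function(v) stats::approx(src, v, dst)$y))
  full <- apply(rows, 2, function(v) stats::approx(src, v, dst)$y)
  base + amplitude * full
}

#' Generate a full synthetic cohort
#'
#' Produces per-rat, per-slice images (smooth background with two textured
#' rectangles embedded at the left/right ROI positions) plus the ROI table
#' with group labels. Per-ROI seeds are drawn deterministically from the
#' master seed, so regeneration from the same config is bit-identical.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `images` (named list keyed
#'   `"<rat_id>_<slice_id>"`), `roi_table`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sz <- config$image_size
  w <- config$roi_width; h <- config$roi_height
  if (w > sz || h > sz) stop("ROI larger than image")
  pooled <- config$rois_per_slice == 1L
  x_left <- round(sz * 0.18)
  x_right <- sz - x_left - w
  x_center <- round((sz - w) / 2)
  y0 <- round((sz - h) / 2)
  set.seed(config$seed)
  n_img <- sum(config$rats_per_group) * config$slices_per_rat
  seed_pool <- sample.int(.Machine$integer.max - 1L, n_img * 3L)
  images <- list()
  rows <- list()
  k <- 0L
  for (gi in seq_along(config$groups)) {
    gname <- config$groups[gi]
    par <- config$params[[gname]]
    for (rat in seq_len(config$rats_per_group[gi])) {
      rat_id <- sprintf("%s_r%02d", gname, rat)
      for (sl in seq_len(config$slices_per_rat)) {
        k <- k + 1L
        bg <- .background_field(sz, seed_pool[3L * k - 2L])
        x0s <- if (pooled) x_center else c(x_left, x_right)
        sides <- if (pooled) "pooled" else c("left", "right")
        patch_seeds <- seed_pool[c(3L * k - 1L, 3L * k)][seq_along(x0s)]
        for (ri in seq_along(x0s)) {
          patch <- generate_patch(par, h, w, patch_seeds[ri])
          bg[(y0 + 1):(y0 + h), (x0s[ri] + 1):(x0s[ri] + w)] <- patch$pixels
        }
        slice_id <- sl - 1L
        images[[paste(rat_id, slice_id, sep = "_")]] <-
          image2d(bg, rat_id = rat_id, slice_id = slice_id)
        rows[[length(rows) + 1L]] <- data.frame(
          rat_id = rat_id, slice_id = slice_id,
          side = sides, group = gname,
          x0 = x0s, y0 = y0, width = w, height = h,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(images = images, roi_table = do.call(rbind, rows), config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d images, %d ROIs, groups %s>\n",
              length(x$images), nrow(x$roi_table),
              paste(x$config$groups, collapse = "/")))
  invisible(x)
}
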