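#' Geometric-transformation augmentation plan
#'
#' The augmentation stage uses only label-preserving geometric transforms:
#' random rotations about the image centre and horizontal/vertical flips.
#' Photometric operations (zoom, shear, brightness) are deliberately
#' excluded — they can alter the staining and size cues that define WBC
#' subtypes.
#'
#' @param rounds number of random rotations per source image (default 15).
#' @param angle_domain rotation angles are drawn uniformly from this
#'   interval (degrees, within `[0, 360)`).
#' @param include_flips also emit one horizontal and one vertical flip of
#'   the source (de-duplicated; they are added once, not per round).
#' @param seed integer seed for the angle stream.
#' @return a `gt_plan` list.
#' @export
gt_plan <- function(rounds = 15L, angle_domain = c(0, 360),
                    include_flips = TRUE, seed = 1L) {
  if (rounds < 1) abort("rounds must be >= 1")
  if (angle_domain[1] < 0 || angle_domain[2] > 360 ||
      diff(angle_domain) <= 0)
    abort("angle_domain must be an increasing interval within [0, 360]")
  structure(list(rounds = as.integer(rounds),
                 angle_domain = as.numeric(angle_domain),
                 include_flips = isTRUE(include_flips),
                 seed = as.integer(seed)),
            class = "gt_plan")
}

#' Rotate an image about its centre
#'
#' Exact multiples of 90 degrees are dispatched to lossless index
#' permutations; other angles use bilinear interpolation with the border
#' filled by the median of the four image corners (a plausible background
#' estimate for single-cell crops). The label is preserved.
#'
#' @param img a [image_sample()] or `H x W x C` array (square).
#' @param angle rotation angle in degrees, counter-clockwise; taken
#'   modulo 360.
#' @return the rotated image, same shape and metadata.
#' @examples
#' img <- image_sample(array(runif(12 * 12 * 3), c(12, 12, 3)))
#' r <- rotate_image(img, 90)
#' all.equal(unclass(rotate_image(r, -90)), unclass(img))
#' @export
rotate_image <- function(img, angle) {
  px <- unclass(img)
  d <- dim(px)
  if (d[1] != d[2]) abort("rotation requires a square image")
  angle <- angle %% 360
  out <- if (angle %% 90 == 0) {
    k <- (angle %/% 90) %% 4
    r <- px
    if (k >= 1) for (q in seq_len(k)) {
      # one lossless 90-degree CCW turn: transpose then reverse rows
      r <- aperm(r, c(2, 1, 3))[d[1]:1, , , drop = FALSE]
    }
    r
  } else {
    fill <- vapply(seq_len(d[3]), function(ch)
      median(c(px[1, 1, ch], px[1, d[2], ch], px[d[1], 1, ch],
               px[d[1], d[2], ch])), numeric(1))
    .rotate_bilinear(px, angle, fill)
  }
  if (inherits(img, "wbc_image")) rewrap_image(out, img) else out
}

#' Flip an image along an axis
#'
#' @param img a [image_sample()] or `H x W x C` array.
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"`
#'   (mirror top-bottom).
#' @return the mirrored image, metadata preserved.
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  px <- unclass(img)
  d <- dim(px)
  out <- if (axis == "horizontal") px[, d[2]:1, , drop = FALSE]
         else px[d[1]:1, , , drop = FALSE]
  if (inherits(img, "wbc_image")) rewrap_image(out, img) else out
}

#' Apply a geometric-transformation plan to one image
#'
#' Produces `rounds` rotated copies (angles drawn uniformly from the
#' plan's angle domain) plus, if `include_flips`, one horizontal and one
#' vertical flip of the original — `rounds + 2` images in total. Every
#' output carries the input's label.
#'
#' @param img a labelled [image_sample()].
#' @param plan a [gt_plan()].
#' @param seed optional override of the plan's seed.
#' @return list of [image_sample()] objects.
#' @examples
#' img <- image_sample(array(runif(16 * 16 * 3), c(16, 16, 3)), "myeloblast")
#' length(gt_augment(img, gt_plan(rounds = 15)))  # 17
#' @export
gt_augment <- function(img, plan = gt_plan(), seed = NULL) {
  seed <- seed %||% plan$seed
  angles <- with_seed(seed, runif(plan$rounds, plan$angle_domain[1],
                                  plan$angle_domain[2]))
  out <- lapply(angles, function(a) rotate_image(img, a))
  if (plan$include_flips) {
    out <- c(out, list(flip_image(img, "horizontal"),
                       flip_image(img, "vertical")))
  }
  src <- image_source_id(img) %||% "img"
  for (i in seq_along(out))
    attr(out[[i]], "source_id") <- sprintf("%s_gt%02d", src, i)
  out
}

# Draw one random geometric transform of `img` (rotation, plus optional
# random flips) using the current RNG stream. Shared by the synthesis and
# balancing code paths.
random_gt_transform <- function(img, plan) {
  angle <- runif(1, plan$angle_domain[1], plan$angle_domain[2])
  out <- rotate_image(img, angle)
  if (plan$include_flips) {
    if (runif(1) < 0.5) out <- flip_image(out, "horizontal")
    if (runif(1) < 0.5) out <- flip_image(out, "vertical")
  }
  out
}
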