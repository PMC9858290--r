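#' Describe the morphology of one synthetic WBC class
#'
#' The synthetic generator draws one stained cell per image: an
#' anti-aliased ellipse of cytoplasm on a pale smear background, with a
#' nucleus composed of one or more lobes (overlaid ellipses) and optional
#' granular texture. The knobs mirror the morphological cues a
#' hematologist uses — cell size, nucleus-to-cytoplasm ratio, nuclear
#' lobulation, stain colour, and azurophilic granularity — so that the
#' synthetic classes are separable for the same reasons real subtypes are.
#'
#' @param label class label (must belong to the taxonomy).
#' @param cell_radius_range length-2 numeric, cell semi-major axis as a
#'   fraction of the image width; the upper end must keep the cell fully
#'   in frame (< 0.5 after centre jitter).
#' @param nucleus_ratio_range length-2 numeric in (0, 1], target
#'   nucleus-to-cell area ratio interval.
#' @param nucleus_lobes integer >= 1, number of nuclear lobes.
#' @param nucleus_color,cytoplasm_color RGB means in `[0, 1]`.
#' @param color_sd per-image RGB standard deviation around the means.
#' @param granularity standard deviation of per-pixel cytoplasmic noise
#'   (0 = smooth cytoplasm).
#' @return a `cell_class_spec` list.
#' @export
cell_class_spec <- function(label, cell_radius_range, nucleus_ratio_range,
                            nucleus_lobes = 1L,
                            nucleus_color = c(0.4, 0.25, 0.55),
                            cytoplasm_color = c(0.7, 0.65, 0.8),
                            color_sd = 0.03, granularity = 0) {
  stopifnot(length(cell_radius_range) == 2, length(nucleus_ratio_range) == 2)
  if (nucleus_ratio_range[1] <= 0 || nucleus_ratio_range[2] > 1)
    abort("nucleus_ratio_range must lie in (0, 1]")
  if (cell_radius_range[2] >= 0.48)
    abort(paste0("cell_radius_range for '", label,
                 "' cannot fit in the frame (upper end must be < 0.48)"))
  if (cell_radius_range[1] <= 0 || diff(cell_radius_range) < 0)
    abort("cell_radius_range must be increasing and positive")
  if (nucleus_lobes < 1) abort("nucleus_lobes must be >= 1")
  if (any(nucleus_color < 0 | nucleus_color > 1) ||
      any(cytoplasm_color < 0 | cytoplasm_color > 1))
    abort("colors must lie in [0, 1]")
  if (granularity < 0) abort("granularity must be >= 0")
  structure(
    list(label = label,
         cell_radius_range = as.numeric(cell_radius_range),
         nucleus_ratio_range = as.numeric(nucleus_ratio_range),
         nucleus_lobes = as.integer(nucleus_lobes),
         nucleus_color = as.numeric(nucleus_color),
         cytoplasm_color = as.numeric(cytoplasm_color),
         color_sd = as.numeric(color_sd),
         granularity = as.numeric(granularity)),
    class = "cell_class_spec"
  )
}

#' Default morphology specs for the 15-class taxonomy
#'
#' Encodes the qualitative cues that distinguish the subtypes: blasts are
#' large with high nuclear ratios and agranular cytoplasm; promyelocytes
#' carry heavy granulation (bilobed ones with two nuclear lobes);
#' erythroblasts are small with a dark round nucleus; atypical lymphocytes
#' have abundant pale cytoplasm like monocytes but a rounder, darker
#' nucleus; granulocytes show lobulated nuclei and stain-specific
#' cytoplasm colours.
#'
#' @return named list of [cell_class_spec()] objects, one per taxonomy
#'   label.
#' @export
default_cell_specs <- function() {
  sp <- list(
    erythroblast = cell_class_spec(
      "erythroblast", c(0.18, 0.24), c(0.45, 0.55),
      nucleus_color = c(0.20, 0.10, 0.35), cytoplasm_color = c(0.80, 0.55, 0.60)),
    lymphocyte_atypical = cell_class_spec(
      "lymphocyte_atypical", c(0.30, 0.36), c(0.35, 0.45),
      nucleus_color = c(0.40, 0.25, 0.50), cytoplasm_color = c(0.70, 0.75, 0.90)),
    metamyelocyte = cell_class_spec(
      "metamyelocyte", c(0.26, 0.32), c(0.50, 0.60),
      nucleus_color = c(0.40, 0.25, 0.55), cytoplasm_color = c(0.80, 0.70, 0.75),
      granularity = 0.03),
    monoblast = cell_class_spec(
      "monoblast", c(0.34, 0.40), c(0.60, 0.70),
      nucleus_color = c(0.45, 0.30, 0.55), cytoplasm_color = c(0.65, 0.60, 0.80),
      granularity = 0.01),
    myeloblast = cell_class_spec(
      "myeloblast", c(0.32, 0.38), c(0.75, 0.85),
      nucleus_color = c(0.35, 0.20, 0.50), cytoplasm_color = c(0.60, 0.65, 0.85)),
    myelocyte = cell_class_spec(
      "myelocyte", c(0.24, 0.30), c(0.55, 0.65),
      nucleus_color = c(0.45, 0.30, 0.60), cytoplasm_color = c(0.75, 0.65, 0.70),
      granularity = 0.05),
    promyelocyte = cell_class_spec(
      "promyelocyte", c(0.30, 0.36), c(0.60, 0.70),
      nucleus_color = c(0.40, 0.22, 0.50), cytoplasm_color = c(0.70, 0.60, 0.75),
      granularity = 0.09),
    promyelocyte_bilobed = cell_class_spec(
      "promyelocyte_bilobed", c(0.30, 0.36), c(0.22, 0.32), nucleus_lobes = 2L,
      nucleus_color = c(0.40, 0.22, 0.50), cytoplasm_color = c(0.70, 0.60, 0.75),
      granularity = 0.09),
    basophil = cell_class_spec(
      "basophil", c(0.24, 0.30), c(0.40, 0.50),
      nucleus_color = c(0.30, 0.20, 0.45), cytoplasm_color = c(0.50, 0.40, 0.70),
      granularity = 0.12),
    eosinophil = cell_class_spec(
      "eosinophil", c(0.26, 0.32), c(0.22, 0.32), nucleus_lobes = 2L,
      nucleus_color = c(0.35, 0.25, 0.50), cytoplasm_color = c(0.90, 0.50, 0.40),
      granularity = 0.08),
    lymphocyte_typical = cell_class_spec(
      "lymphocyte_typical", c(0.16, 0.22), c(0.80, 0.90),
      nucleus_color = c(0.30, 0.15, 0.45), cytoplasm_color = c(0.55, 0.60, 0.85)),
    monocyte = cell_class_spec(
      "monocyte", c(0.34, 0.40), c(0.45, 0.55),
      nucleus_color = c(0.50, 0.35, 0.60), cytoplasm_color = c(0.68, 0.68, 0.78),
      granularity = 0.02),
    neutrophil_band = cell_class_spec(
      "neutrophil_band", c(0.26, 0.32), c(0.35, 0.45), nucleus_lobes = 2L,
      nucleus_color = c(0.40, 0.30, 0.55), cytoplasm_color = c(0.85, 0.78, 0.72),
      granularity = 0.04),
    neutrophil_segmented = cell_class_spec(
      "neutrophil_segmented", c(0.26, 0.32), c(0.35, 0.45), nucleus_lobes = 3L,
      nucleus_color = c(0.40, 0.30, 0.55), cytoplasm_color = c(0.85, 0.75, 0.70),
      granularity = 0.04),
    smudge = cell_class_spec(
      "smudge", c(0.22, 0.30), c(0.88, 0.98),
      nucleus_color = c(0.55, 0.40, 0.65), cytoplasm_color = c(0.60, 0.45, 0.70),
      color_sd = 0.05, granularity = 0.06)
  )
  sp[order(names(sp))]
}

#' Configuration for synthetic dataset generation
#'
#' @param specs named list of [cell_class_spec()] (default: all 15 classes).
#' @param images_per_class images generated per class (>= 1).
#' @param image_size square edge in pixels (default 224, matching the
#'   canonical input size).
#' @param seed root seed; per-image seeds are derived from it.
#' @param background_color RGB of the smear background.
#' @return a `generator_config` list.
#' @export
generator_config <- function(specs = default_cell_specs(),
                             images_per_class = 20L, image_size = 224L,
                             seed = 1L,
                             background_color = c(0.85, 0.82, 0.88)) {
  if (images_per_class < 1) abort("images_per_class must be >= 1")
  if (image_size < 16) abort("image_size must be at least 16 pixels")
  structure(
    list(specs = specs, images_per_class = as.integer(images_per_class),
         image_size = as.integer(image_size), seed = as.integer(seed),
         background_color = as.numeric(background_color)),
    class = "generator_config"
  )
}

# Anti-aliased coverage of an ellipse over the pixel grid: ~1 inside,
# ~0 outside, a one-pixel linear ramp across the boundary.
ellipse_alpha <- function(xg, yg, cx, cy, a, b, theta) {
  dx <- xg - cx
  dy <- yg - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  r <- sqrt(u^2 + v^2)
  pmin(pmax((1 - r) * min(a, b) + 0.5, 0), 1)
}

#' Generate one synthetic single-cell image
#'
#' Draws a single elliptical cell on the background, with
#' `spec$nucleus_lobes` nuclear lobes whose combined area is iteratively
#' rescaled so that the realized nucleus-to-cell area ratio falls within
#' the spec's target range (tolerance 0.05). Deterministic per seed.
#'
#' @param spec a [cell_class_spec()].
#' @param seed integer seed for this image.
#' @param image_size square edge in pixels.
#' @param background_color RGB background.
#' @return a labelled [image_sample()]; the realized nucleus-to-cell area
#'   ratio is attached as attribute `nucleus_ratio`, and the binary
#'   nucleus mask (mid-threshold) as attribute `nucleus_mask`.
#' @export
generate_cell_image <- function(spec, seed = 1L, image_size = 224L,
                                background_color = c(0.85, 0.82, 0.88)) {
  S <- as.integer(image_size)
  with_seed(seed, {
    xg <- matrix(rep(seq_len(S), each = S), S, S)   # column index
    yg <- matrix(rep(seq_len(S), times = S), S, S)  # row index

    a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2]) * S
    ecc <- runif(1, 0.78, 1)
    b <- a * ecc
    theta <- runif(1, 0, pi)
    margin <- S / 2 - a - 1
    cx <- S / 2 + runif(1, -1, 1) * max(margin, 0) * 0.5
    cy <- S / 2 + runif(1, -1, 1) * max(margin, 0) * 0.5

    cell <- ellipse_alpha(xg, yg, cx, cy, a, b, theta)
    cell_area <- sum(cell)

    # nucleus: nucleus_lobes ellipses; scale lobe size until the realized
    # area ratio lands inside the target range
    target <- runif(1, spec$nucleus_ratio_range[1], spec$nucleus_ratio_range[2])
    n_lobes <- spec$nucleus_lobes
    lobe_ecc <- runif(n_lobes, 0.85, 1)
    lobe_theta <- runif(n_lobes, 0, pi)
    base_angle <- runif(1, 0, 2 * pi)
    r_l <- sqrt(target * cell_area / (pi * n_lobes))
    for (iter in 1:4) {
      if (n_lobes == 1) {
        lx <- cx + runif(1, -1, 1) * 0.1 * a
        ly <- cy + runif(1, -1, 1) * 0.1 * b
        if (iter > 1) { lx <- lx0; ly <- ly0 } else { lx0 <- lx; ly0 <- ly }
      } else {
        ang <- base_angle + 2 * pi * (seq_len(n_lobes) - 1) / n_lobes
        # lobe centres > 2 lobe-radii apart (distinct lobes) but clamped so
        # lobes stay inside the cell body
        d <- min(1.25 * r_l, max(0.88 * min(a, b) - r_l, 1.06 * r_l))
        lx <- cx + d * cos(ang)
        ly <- cy + d * sin(ang)
      }
      nuc <- matrix(0, S, S)
      for (l in seq_len(n_lobes))
        nuc <- pmax(nuc, ellipse_alpha(xg, yg, lx[l], ly[l],
                                       r_l, r_l * lobe_ecc[l], lobe_theta[l]))
      nuc <- pmin(nuc, cell)
      realized <- sum(nuc) / cell_area
      if (abs(realized - target) <= 0.02) break
      r_l <- r_l * sqrt(target / max(realized, 1e-6))
    }

    nuc_col <- pmin(pmax(rnorm(3, spec$nucleus_color, spec$color_sd), 0), 1)
    cyt_col <- pmin(pmax(rnorm(3, spec$cytoplasm_color, spec$color_sd), 0), 1)

    px <- array(0, c(S, S, 3))
    cyto <- cell * (1 - nuc)
    bg <- 1 - cell
    grain <- if (spec$granularity > 0)
      matrix(rnorm(S * S, 0, spec$granularity), S, S) else 0
    for (ch in 1:3) {
      layer <- bg * background_color[ch] +
        cyto * (cyt_col[ch] + if (is.matrix(grain)) grain else 0) +
        nuc * nuc_col[ch]
      px[, , ch] <- pmin(pmax(layer, 0), 1)
    }

    img <- image_sample(px, label = spec$label,
                        source_id = paste0(spec$label, "_seed", seed))
    attr(img, "nucleus_ratio") <- realized
    attr(img, "nucleus_mask") <- nuc >= 0.5
    img
  })
}

#' Generate a synthetic labelled dataset on disk
#'
#' Writes `images_per_class` PNG files per class under `out_dir` (one
#' subdirectory per class) plus a `manifest.csv`, and returns the
#' manifest. Byte-identical across runs with the same config.
#'
#' @param cfg a [generator_config()].
#' @param out_dir writable output directory (created if absent).
#' @return manifest tibble (columns `path`, `label`, `split`).
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  records <- list()
  idx <- 0L
  for (lab in names(cfg$specs)) {
    cls_dir <- file.path(out_dir, lab)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(cfg$images_per_class)) {
      idx <- idx + 1L
      img <- generate_cell_image(cfg$specs[[lab]],
                                 seed = derive_seed(cfg$seed, idx),
                                 image_size = cfg$image_size,
                                 background_color = cfg$background_color)
      f <- file.path(cls_dir, sprintf("%s_%04d.png", lab, i))
      write_image(img, f)
      records[[idx]] <- tibble(path = f, label = lab, split = "unassigned")
    }
  }
  m <- dplyr::bind_rows(records)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}

#' Generate a list of synthetic images in memory
#'
#' Convenience wrapper used for training experiments that do not need the
#' images on disk.
#'
#' @inheritParams generate_cell_image
#' @param n number of images.
#' @return list of labelled [image_sample()] objects.
#' @export
generate_class_images <- function(spec, n, image_size = 224L, seed = 1L,
                                  background_color = c(0.85, 0.82, 0.88)) {
  lapply(seq_len(n), function(i)
    generate_cell_image(spec, seed = derive_seed(seed, i),
                        image_size = image_size,
                        background_color = background_color))
}

# 4-connected component count of a logical mask (used to verify nuclear
# lobe construction).
count_components <- function(mask) {
  n <- 0L
  lab <- matrix(0L, nrow(mask), ncol(mask))
  H <- nrow(mask); W <- ncol(mask)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    n <- n + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- n
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        qi <- p[1] + d[1]; qj <- p[2] + d[2]
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- n
          queue <- rbind(queue, c(qi, qj))
        }
      }
    }
  }
  n
}
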