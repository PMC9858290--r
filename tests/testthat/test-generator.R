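specs <- default_cell_specs()

test_that("realized nucleus-to-cell ratio stays within the spec range", {
  for (lab in c("myeloblast", "erythroblast", "promyelocyte_bilobed",
                "neutrophil_segmented", "smudge")) {
    sp <- specs[[lab]]
    for (i in 1:5) {
      img <- generate_cell_image(sp, seed = i, image_size = 56)
      r <- attr(img, "nucleus_ratio")
      expect_gte(r, sp$nucleus_ratio_range[1] - 0.05)
      expect_lte(r, sp$nucleus_ratio_range[2] + 0.05)
    }
  }
})

test_that("bilobed specs produce a two-lobed nucleus", {
  for (i in 1:8) {
    img <- generate_cell_image(specs$promyelocyte_bilobed, seed = i,
                               image_size = 56)
    expect_equal(leukotype:::count_components(attr(img, "nucleus_mask")), 2)
  }
  img1 <- generate_cell_image(specs$myeloblast, seed = 1, image_size = 56)
  expect_equal(leukotype:::count_components(attr(img1, "nucleus_mask")), 1)
})

test_that("noise-free spec yields an (almost) three-colour image", {
  sp <- cell_class_spec("myeloblast", c(0.30, 0.34), c(0.6, 0.7),
                        color_sd = 0, granularity = 0)
  img <- generate_cell_image(sp, seed = 3, image_size = 64)
  vals <- round(as.vector(unclass(img)), 6)
  tab <- sort(table(vals), decreasing = TRUE)
  # three flat colour populations dominate; the remainder is the one-pixel
  # anti-aliasing ramp along the cell and nucleus boundaries
  expect_gte(sum(tab[1:9]) / length(vals), 0.90)  # 3 colours x 3 channels
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cell_image(specs$monocyte, seed = 11, image_size = 48)
  b <- generate_cell_image(specs$monocyte, seed = 11, image_size = 48)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(
    unclass(generate_cell_image(specs$monocyte, seed = 12, image_size = 48)),
    unclass(a)))
})

test_that("all pixels are in [0,1] and labels are attached", {
  for (lab in names(specs)) {
    img <- generate_cell_image(specs[[lab]], seed = 2, image_size = 40)
    expect_gte(min(img), 0)
    expect_lte(max(img), 1)
    expect_equal(image_label(img), lab)
  }
})

test_that("generate_dataset writes the promised records deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- generator_config(images_per_class = 2, image_size = 32, seed = 9)
  m1 <- generate_dataset(cfg, dir1)
  expect_equal(nrow(m1), 30)  # 15 classes x 2
  expect_equal(unname(table(m1$label)[names(cfg$specs)]),
               rep(2L, 15), ignore_attr = TRUE)
  expect_true(all(file.exists(m1$path)))
  m2 <- generate_dataset(cfg, dir2)
  expect_identical(basename(m1$path), basename(m2$path))
  expect_identical(readBin(m1$path[1], "raw", 1e5),
                   readBin(m2$path[1], "raw", 1e5))
})

test_that("classes are separable: inter-class histogram distance exceeds intra", {
  hist_of <- function(img) {
    c(hist(img[, , 1], breaks = seq(0, 1, 0.1), plot = FALSE)$density,
      hist(img[, , 2], breaks = seq(0, 1, 0.1), plot = FALSE)$density,
      hist(img[, , 3], breaks = seq(0, 1, 0.1), plot = FALSE)$density)
  }
  hists <- lapply(names(specs), function(lab)
    lapply(1:10, function(i)
      hist_of(generate_cell_image(specs[[lab]], seed = i, image_size = 40))))
  intra <- c()
  inter <- c()
  for (a in seq_along(hists)) {
    for (i in 1:9) for (j in (i + 1):10)
      intra <- c(intra, mean(abs(hists[[a]][[i]] - hists[[a]][[j]])))
    for (b in seq_along(hists)) if (b > a)
      inter <- c(inter, mean(abs(hists[[a]][[1]] - hists[[b]][[1]])))
  }
  expect_gt(mean(inter), mean(intra))
})

test_that("impossible morphology configs error", {
  expect_error(cell_class_spec("smudge", c(0.3, 0.5), c(0.5, 0.6)),
               "cannot fit")
  expect_error(cell_class_spec("smudge", c(0.2, 0.3), c(0, 0.6)),
               "\\(0, 1\\]")
})
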