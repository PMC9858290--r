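#' Augmentation balancing plan
#'
#' Describes how the minority (atypical) classes are brought up to a
#' common per-class count before classifier training: either plain
#' geometric transforms (`"gt"`) or autoencoder reconstructions of
#' geometrically transformed sources (`"gt-dcae"`). Only training-split
#' images are used as sources, so no test information leaks into the
#' synthetic pool.
#'
#' @param target_per_class target image count per atypical class
#'   (default 10000, the full-scale protocol; desk-scale experiments use
#'   much smaller targets).
#' @param method `"gt-dcae"` or `"gt"`.
#' @param classes classes to balance (default: the 8 atypical classes).
#' @return a `balance_plan` list.
#' @export
balance_plan <- function(target_per_class = 10000L,
                         method = c("gt-dcae", "gt"),
                         classes = atypical_classes()) {
  method <- match.arg(method)
  if (target_per_class < 1) abort("target_per_class must be >= 1")
  structure(list(target_per_class = as.integer(target_per_class),
                 method = method, classes = classes),
            class = "balance_plan")
}

#' Balance a dataset by synthesizing minority-class images
#'
#' For each planned class, generates enough synthetic images to reach the
#' target count, writes them under `out_dir/<class>/` and returns the
#' augmented manifest with a `synthetic` flag. With `method = "gt-dcae"`
#' a trained per-class autoencoder must be supplied for every planned
#' class; with `method = "gt"` sources are geometrically transformed
#' without reconstruction.
#'
#' @param manifest manifest tibble with assigned splits.
#' @param plan a [balance_plan()].
#' @param models named list of trained `dcae` models (one per planned
#'   class; required for `"gt-dcae"`).
#' @param out_dir directory for synthetic images.
#' @param seed integer seed.
#' @param image_size square edge synthetic images are written at
#'   (sources are resized to it).
#' @param gt a [gt_plan()] describing the transform distribution.
#' @return augmented manifest tibble (`path`, `label`, `split`,
#'   `synthetic`); synthetic records always carry `split = "train"`.
#' @export
balance_dataset <- function(manifest, plan, models = NULL, out_dir,
                            seed = 1L, image_size = 224L, gt = gt_plan()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$synthetic <- FALSE
  extra <- list()
  for (ci in seq_along(plan$classes)) {
    cls <- plan$classes[ci]
    src_rows <- manifest[manifest$label == cls & manifest$split == "train" &
                           !manifest$synthetic, ]
    n_have <- sum(manifest$label == cls & !manifest$synthetic)
    n_need <- plan$target_per_class - n_have
    if (n_need <= 0) next
    if (nrow(src_rows) == 0)
      abort(paste0("no training sources for class ", cls))
    pool <- lapply(seq_len(nrow(src_rows)), function(i)
      read_image(src_rows$path[i], label = cls, resize = image_size))
    cls_seed <- derive_seed(seed, ci)
    if (plan$method == "gt-dcae") {
      if (is.null(models[[cls]]) || !inherits(models[[cls]], "dcae"))
        abort(paste0("gt-dcae balancing needs a trained dcae model for ",
                     cls))
      synth <- synthesize(models[[cls]], pool, n_need, plan = gt,
                          seed = cls_seed)
    } else {
      # plain GT balancing draws from the finite pool of rounds+2 geometric
      # variants per source; past that the variants repeat, so unlike the
      # autoencoder route the method cannot add diversity beyond
      # n_sources * (rounds + 2) images
      synth <- with_seed(cls_seed, {
        variants <- unlist(lapply(seq_along(pool), function(i)
          gt_augment(pool[[i]], gt, seed = derive_seed(cls_seed, i))),
          recursive = FALSE)
        idx <- if (n_need <= length(variants)) sample.int(length(variants), n_need)
               else sample.int(length(variants), n_need, replace = TRUE)
        variants[idx]
      })
    }
    cls_dir <- file.path(out_dir, cls)
    dir.create(cls_dir, showWarnings = FALSE)
    paths <- character(length(synth))
    for (i in seq_along(synth)) {
      paths[i] <- file.path(cls_dir, sprintf("%s_synth_%05d.png", cls, i))
      write_image(synth[[i]], paths[i])
    }
    extra[[cls]] <- tibble(path = paths, label = cls, split = "train",
                           synthetic = TRUE)
  }
  dplyr::bind_rows(c(list(manifest), extra))
}

#' Two-stage classification of single cells
#'
#' Implements the two-stage decision rule: encode the image, apply the
#' typical-vs-atypical gate, and only when the gate calls the cell
#' atypical (probability >= `threshold`) run the eight-way subtype model.
#' Typical calls therefore carry no subtype probabilities.
#'
#' @param images a labelled or unlabelled [image_sample()], a list of
#'   them, or a manifest tibble (images are read and resized to the
#'   autoencoder's input size).
#' @param dcae trained `dcae` used as the feature encoder.
#' @param stage1 trained `stage1_model`.
#' @param stage2 trained `stage2_model`.
#' @param threshold gate threshold on the atypical probability
#'   (default 0.5; 1.0 forces everything typical).
#' @param batch_size inference chunk size.
#' @return tibble with one row per image: `source_id`, `truth` (label or
#'   `NA`), `stage1_probability`, `final_label`, and one `pi_<class>`
#'   column per atypical subtype (`NA` for typical calls).
#' @export
classify_cells <- function(images, dcae, stage1, stage2, threshold = 0.5,
                           batch_size = 32L) {
  if (is.data.frame(images)) {
    images <- lapply(seq_len(nrow(images)), function(i)
      read_image(images$path[i], label = images$label[i],
                 resize = dcae$spec$input_size))
  }
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  ids <- vapply(seq_len(n), function(i)
    image_source_id(images[[i]]) %||% sprintf("img%05d", i), character(1))
  truth <- vapply(images, function(im) image_label(im) %||% NA_character_,
                  character(1))
  z <- encode(dcae, stack_images(images), batch_size)
  p1 <- predict_typicality(stage1, z, batch_size)
  classes <- atypical_classes()
  pi_mat <- matrix(NA_real_, n, 8, dimnames = list(NULL, classes))
  final <- rep("typical", n)
  atyp <- which(p1 >= threshold)
  if (length(atyp) > 0) {
    pa <- predict_subtype(stage2, z[, , , atyp, drop = FALSE], batch_size)
    pi_mat[atyp, ] <- pa
    final[atyp] <- argmax_class(pa)
  }
  out <- tibble(source_id = ids, truth = truth, stage1_probability = p1,
                final_label = final)
  pi_df <- as_tibble(pi_mat)
  names(pi_df) <- paste0("pi_", classes)
  dplyr::bind_cols(out, pi_df)
}

#' Experiment configuration
#'
#' A single structured description of an end-to-end run on synthetic
#' data: generation, split, augmentation, autoencoder and classifier
#' training, and evaluation. Defaults are desk-scale (56-pixel images);
#' the full-scale protocol uses `image_size = 224`, per-class targets of
#' 10000, and 100/200 classifier epochs.
#'
#' @param image_size square image edge (multiple of 8).
#' @param images_per_class synthetic images generated per class.
#' @param test_fraction held-out fraction per class.
#' @param balance_target per-class count after augmentation.
#' @param method augmentation method, `"gt-dcae"` or `"gt"`.
#' @param dcae_epochs,stage1_epochs,stage2_epochs training epochs.
#' @param dcae_lr,stage_lr learning rates for this problem size.
#' @param gt_rounds rotations per source in the GT stage.
#' @param threshold stage I gate threshold.
#' @param ablation if `TRUE`, also run the 2x2 grid
#'   {latent vs raw-pixel features} x {gt vs gt-dcae augmentation}.
#' @param seed root seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(image_size = 56L, images_per_class = 20L,
                              test_fraction = 0.2, balance_target = NULL,
                              method = "gt-dcae", dcae_epochs = 5L,
                              stage1_epochs = 5L, stage2_epochs = 8L,
                              dcae_lr = 0.02, stage_lr = 0.01,
                              gt_rounds = 15L, threshold = 0.5,
                              ablation = FALSE, seed = 1L) {
  structure(list(
    image_size = as.integer(image_size),
    images_per_class = as.integer(images_per_class),
    test_fraction = test_fraction,
    balance_target = as.integer(balance_target %||%
                                  round(1.5 * images_per_class)),
    method = method, dcae_epochs = as.integer(dcae_epochs),
    stage1_epochs = as.integer(stage1_epochs),
    stage2_epochs = as.integer(stage2_epochs),
    dcae_lr = dcae_lr, stage_lr = stage_lr,
    gt_rounds = as.integer(gt_rounds), threshold = threshold,
    ablation = isTRUE(ablation), seed = as.integer(seed)),
    class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file whose keys mirror the `experiment_config()`
#'   arguments.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

# internal: split a list of per-class images into train/test indices
split_indices <- function(n, test_fraction, seed) {
  n_test <- round(test_fraction * n)
  test <- with_seed(seed, sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Run an end-to-end synthetic experiment
#'
#' Generates the synthetic dataset, trains one augmentation autoencoder
#' per atypical subtype plus a shared feature encoder, balances the
#' atypical classes with the configured method, trains the two stage
#' classifiers on latent representations, and evaluates on the held-out
#' split. Optionally repeats stage II over the 2x2
#' feature-by-augmentation ablation grid. All randomness derives from
#' `config$seed`, so reports are reproducible.
#'
#' @param config an [experiment_config()].
#' @param out_dir if non-`NULL`, reports (JSON), per-sample predictions
#'   (CSV) and loss/ROC figures (PNG) are written there.
#' @return list with `stage1_report`, `stage2_report`, `two_stage`
#'   predictions tibble, `dcae_history`, per-arm `ablation` reports (when
#'   requested) and the `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  specs <- default_cell_specs()
  S <- config$image_size
  seed <- config$seed
  gt <- gt_plan(rounds = config$gt_rounds, seed = derive_seed(seed, 11L))

  # --- generate and split -------------------------------------------------
  data <- list()
  for (ci in seq_along(specs)) {
    lab <- names(specs)[ci]
    imgs <- generate_class_images(specs[[lab]], config$images_per_class,
                                  image_size = S,
                                  seed = derive_seed(seed, 100L + ci))
    idx <- split_indices(length(imgs), config$test_fraction,
                         derive_seed(seed, 200L + ci))
    data[[lab]] <- list(train = imgs[idx$train], test = imgs[idx$test])
  }
  atyp <- atypical_classes()

  # --- per-subtype augmentation autoencoders ------------------------------
  aug_cfg <- training_config(epochs = config$dcae_epochs, batch_size = 32L,
                             learning_rate = config$dcae_lr, momentum = 0.8,
                             seed = derive_seed(seed, 31L))
  aug_models <- list()
  for (cls in atyp) {
    m <- build_dcae(dcae_spec(input_size = S),
                    seed = derive_seed(seed, 300L + match(cls, atyp)))
    aug_models[[cls]] <- train_dcae(m, data[[cls]]$train, aug_cfg)
  }

  # --- shared feature encoder --------------------------------------------
  all_train <- unlist(lapply(data, `[[`, "train"), recursive = FALSE)
  feat <- build_dcae(dcae_spec(input_size = S), seed = derive_seed(seed, 41L))
  feat <- train_dcae(feat, all_train, aug_cfg)

  # --- balanced training pools -------------------------------------------
  make_pool <- function(method) {
    pool <- data
    for (cls in atyp) {
      n_have <- length(pool[[cls]]$train) + length(pool[[cls]]$test)
      n_need <- config$balance_target - n_have
      if (n_need <= 0) next
      cls_seed <- derive_seed(seed, 500L + match(cls, atyp) +
                                1000L * (method == "gt"))
      synth <- if (method == "gt-dcae")
        synthesize(aug_models[[cls]], pool[[cls]]$train, n_need, plan = gt,
                   seed = cls_seed)
      else with_seed(cls_seed, {
        variants <- unlist(lapply(seq_along(pool[[cls]]$train), function(i)
          gt_augment(pool[[cls]]$train[[i]], gt,
                     seed = derive_seed(cls_seed, i))), recursive = FALSE)
        variants[sample.int(length(variants), n_need,
                            replace = n_need > length(variants))]
      })
      pool[[cls]]$train <- c(pool[[cls]]$train, synth)
    }
    pool
  }
  pool <- make_pool(config$method)

  encode_set <- function(imgs) encode(feat, stack_images(imgs))
  thumb_set <- function(imgs) {
    g <- S %/% 8L
    stack_images(lapply(imgs, function(im) resize_image(im, g)))
  }

  train_imgs <- unlist(lapply(pool, `[[`, "train"), recursive = FALSE)
  train_labs <- vapply(train_imgs, image_label, character(1))
  test_imgs <- unlist(lapply(data, `[[`, "test"), recursive = FALSE)
  test_labs <- vapply(test_imgs, image_label, character(1))

  z_train <- encode_set(train_imgs)
  z_test <- encode_set(test_imgs)
  grid <- dim(z_train)[1:3]

  # --- stage I -----------------------------------------------------------
  s1 <- build_stage1(stage1_spec(input_grid = grid),
                     seed = derive_seed(seed, 51L))
  s1 <- train_stage1(s1, z_train, train_labs,
                     training_config(epochs = config$stage1_epochs,
                                     learning_rate = config$stage_lr,
                                     momentum = 0.8,
                                     seed = derive_seed(seed, 52L)))
  p1_test <- predict_typicality(s1, z_test)
  truth_atyp <- class_group(test_labs) == "atypical"
  s1_pred <- ifelse(p1_test >= config$threshold, "atypical", "typical")
  s1_report <- evaluation_report(ifelse(truth_atyp, "atypical", "typical"),
                                 s1_pred,
                                 class_order = c("atypical", "typical"))
  s1_auc <- roc_auc(truth_atyp, p1_test)

  # --- stage II ----------------------------------------------------------
  fit_stage2 <- function(ztr, labs_tr, zte, labs_te, seed_off = 0L) {
    m <- build_stage2(stage2_spec(input_grid = dim(ztr)[1:3]),
                      seed = derive_seed(seed, 61L + seed_off))
    m <- train_stage2(m, ztr, labs_tr,
                      training_config(epochs = config$stage2_epochs,
                                      learning_rate = config$stage_lr,
                                      momentum = 0.8,
                                      seed = derive_seed(seed, 62L + seed_off)))
    probs <- predict_subtype(m, zte)
    list(model = m,
         report = evaluation_report(labs_te, argmax_class(probs), probs,
                                    class_order = atypical_classes()),
         probs = probs)
  }
  at_tr <- train_labs %in% atyp
  at_te <- test_labs %in% atyp
  s2 <- fit_stage2(z_train[, , , at_tr, drop = FALSE], train_labs[at_tr],
                   z_test[, , , at_te, drop = FALSE], test_labs[at_te])

  # --- two-stage dispatch on the test set --------------------------------
  two_stage <- classify_cells(test_imgs, feat, s1, s2$model,
                              threshold = config$threshold)

  out <- list(config = config, stage1_report = s1_report, stage1_auc = s1_auc,
              stage2_report = s2$report, two_stage = two_stage,
              dcae_history = feat$history,
              stage1_model = s1, stage2_model = s2$model,
              feature_dcae = feat, augmentation_models = aug_models)

  # --- ablation grid ------------------------------------------------------
  if (config$ablation) {
    arms <- list()
    for (method in c("gt-dcae", "gt")) {
      arm_pool <- if (method == config$method) pool else make_pool(method)
      arm_imgs <- unlist(lapply(arm_pool[atyp], `[[`, "train"),
                         recursive = FALSE)
      arm_labs <- vapply(arm_imgs, image_label, character(1))
      for (features in c("latent", "raw")) {
        enc_fun <- if (features == "latent") encode_set else thumb_set
        ztr <- enc_fun(arm_imgs)
        zte <- enc_fun(test_imgs[at_te])
        key <- paste(features, method, sep = "_")
        arms[[key]] <- fit_stage2(ztr, arm_labs, zte, test_labs[at_te],
                                  seed_off = 10L * length(arms))$report
      }
    }
    out$ablation <- arms
  }

  if (!is.null(out_dir)) write_experiment_outputs(out, out_dir)
  out
}

# write reports (JSON), predictions (CSV) and figures (PNG)
write_experiment_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(out$stage1_report, file.path(out_dir, "stage1_report.json"))
  write_report_json(out$stage2_report, file.path(out_dir, "stage2_report.json"))
  write.csv(out$two_stage, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(seed = out$config$seed,
                            stage1_auc = out$stage1_auc),
                       file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(out$dcae_history) && nrow(out$dcae_history) > 0) {
    p <- ggplot2::ggplot(out$dcae_history,
                         ggplot2::aes(x = .data$epoch, y = .data$loss)) +
      ggplot2::geom_line() + ggplot2::theme_minimal() +
      ggplot2::labs(x = "epoch", y = "MSE", title = "Autoencoder loss")
    ggplot2::ggsave(file.path(out_dir, "dcae_loss.png"), p,
                    width = 5, height = 4, dpi = 120)
  }
  probs <- as.matrix(out$two_stage[, paste0("pi_", atypical_classes())])
  colnames(probs) <- atypical_classes()
  keep <- stats::complete.cases(probs) &
    out$two_stage$truth %in% atypical_classes()
  if (sum(keep) > 2 && length(unique(out$two_stage$truth[keep])) >= 2) {
    p <- plot_roc_curves(out$two_stage$truth[keep], probs[keep, , drop = FALSE])
    ggplot2::ggsave(file.path(out_dir, "stage2_roc.png"), p,
                    width = 6, height = 4, dpi = 120)
  }
  if (!is.null(out$ablation)) {
    for (key in names(out$ablation))
      write_report_json(out$ablation[[key]],
                        file.path(out_dir, paste0("ablation_", key, ".json")))
  }
  invisible(out_dir)
}
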