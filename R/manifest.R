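#' Load and validate an image manifest
#'
#' A manifest is the tabular index of a single-cell image collection: one
#' row per image with its path, class label and (optionally) a train/test
#' split assignment. On disk it is a UTF-8 CSV with header
#' `path,label[,split]`; in R it is a tibble with columns `path`, `label`,
#' `split` (`"train"`, `"test"` or `"unassigned"`).
#'
#' @param path path to the manifest CSV.
#' @param root directory against which relative image paths are resolved;
#'   defaults to the manifest's directory.
#' @param taxonomy taxonomy tibble used to validate labels
#'   (see [wbc_taxonomy()]).
#' @param check_files if `TRUE` (default), error when referenced image
#'   files are missing.
#' @return a tibble with columns `path` (absolute), `label`, `split`.
#' @export
load_manifest <- function(path, root = dirname(path),
                          taxonomy = wbc_taxonomy(), check_files = TRUE) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    abort("manifest must have a header with columns path,label[,split]")
  if (!"split" %in% names(df)) df$split <- "unassigned"
  df$split[is.na(df$split) | df$split == ""] <- "unassigned"
  m <- tibble(path = df$path, label = df$label, split = df$split)
  validate_manifest(m, root = root, taxonomy = taxonomy,
                    check_files = check_files)
}

validate_manifest <- function(m, root = NULL, taxonomy = wbc_taxonomy(),
                              check_files = FALSE) {
  bad_split <- setdiff(unique(m$split), c("train", "test", "unassigned"))
  if (length(bad_split) > 0)
    abort(paste0("invalid split value(s): ", paste(bad_split, collapse = ", ")))
  bad_lab <- which(!m$label %in% taxonomy$label)
  if (length(bad_lab) > 0)
    abort(paste0(
      "unknown label(s) in manifest row(s) ",
      paste(head(bad_lab, 5), collapse = ", "), ": ",
      paste(unique(m$label[bad_lab]), collapse = ", ")
    ))
  if (!is.null(root)) {
    rel <- !grepl("^(/|[A-Za-z]:)", m$path)
    m$path[rel] <- file.path(root, m$path[rel])
  }
  dup <- duplicated(m$path)
  if (any(dup))
    abort(paste0("duplicate path(s) in manifest: ",
                 paste(unique(m$path[dup]), collapse = ", ")))
  if (check_files) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing) > 0)
      abort(paste0("missing image file(s): ",
                   paste(head(missing, 10), collapse = ", ")))
  }
  m
}

#' @rdname load_manifest
#' @param m a manifest tibble.
#' @export
write_manifest <- function(m, path) {
  write.csv(m[, c("path", "label", "split")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Stratified train/test split of a manifest
#'
#' Assigns every record to `train` or `test`, stratified by class so that
#' each class's test count is within one sample of
#' `round(test_fraction * n_class)`. Stratification protects rare subtypes
#' (some atypical classes have very low prevalence in blood smears) from
#' vanishing out of either split. Deterministic for a fixed seed.
#'
#' @param m a manifest tibble (columns `path`, `label`, `split`).
#' @param test_fraction fraction of each class assigned to the test split,
#'   in (0, 1). Default 0.2 (an 80/20 split).
#' @param seed integer seed.
#' @return the manifest with its `split` column filled in.
#' @examples
#' m <- tibble::tibble(
#'   path = sprintf("img%03d.png", 1:100),
#'   label = "myeloblast", split = "unassigned"
#' )
#' s <- stratified_split(m, 0.2, seed = 1)
#' table(s$split)
#' @export
stratified_split <- function(m, test_fraction = 0.2, seed = 1L) {
  if (nrow(m) == 0) abort("cannot split an empty manifest")
  if (!(test_fraction > 0 && test_fraction < 1))
    abort("test_fraction must lie strictly between 0 and 1")
  split <- rep("train", nrow(m))
  with_seed(seed, {
    for (lab in unique(m$label)) {
      idx <- which(m$label == lab)
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0)
        split[sample(idx, n_test)] <- "test"
    }
  })
  m$split <- split
  m
}
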