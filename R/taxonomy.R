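#' The white-blood-cell class taxonomy
#'
#' Single-cell peripheral-blood-smear images are labelled with one of 15
#' WBC classes. Eight of them are "atypical" — immature precursors and
#' reactive forms that matter for acute myeloid leukemia work-ups — and the
#' remaining seven are mature ("typical") leukocytes plus smudge cells.
#' The atypical set is fixed; the typical set is configurable because
#' laboratories differ in which mature classes they report.
#'
#' The order of the atypical labels returned by [atypical_classes()] is the
#' canonical class order used everywhere in the package (probability
#' vectors, confusion matrices, ROC panels): alphabetical by label.
#'
#' @param typical character vector of typical class names (default: the
#'   seven mature classes below).
#' @return `wbc_taxonomy()` returns a tibble with columns `label` and
#'   `group` (`"typical"` or `"atypical"`), 15 rows by default.
#' @examples
#' wbc_taxonomy()
#' atypical_classes()
#' @export
wbc_taxonomy <- function(typical = typical_classes()) {
  typical <- as.character(typical)
  if (anyDuplicated(typical) > 0) abort("typical class names must be unique")
  if (any(typical %in% atypical_classes()))
    abort("typical classes may not overlap the atypical set")
  tibble(
    label = c(atypical_classes(), sort(typical)),
    group = c(rep("atypical", 8L), rep("typical", length(typical)))
  )
}

#' @rdname wbc_taxonomy
#' @export
atypical_classes <- function() {
  c("erythroblast", "lymphocyte_atypical", "metamyelocyte", "monoblast",
    "myeloblast", "myelocyte", "promyelocyte", "promyelocyte_bilobed")
}

#' @rdname wbc_taxonomy
#' @export
typical_classes <- function() {
  c("basophil", "eosinophil", "lymphocyte_typical", "monocyte",
    "neutrophil_band", "neutrophil_segmented", "smudge")
}

#' Map class labels to their typical/atypical group
#'
#' @param labels character vector of class labels.
#' @param taxonomy a taxonomy tibble from [wbc_taxonomy()].
#' @return character vector of `"typical"` / `"atypical"`.
#' @examples
#' class_group(c("myeloblast", "monocyte"))
#' @export
class_group <- function(labels, taxonomy = wbc_taxonomy()) {
  idx <- match(labels, taxonomy$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  taxonomy$group[idx]
}

check_labels <- function(labels, allowed, context = "manifest") {
  bad <- setdiff(unique(labels), allowed)
  if (length(bad) > 0)
    abort(paste0(
      "unknown class label(s) in ", context, ": ", paste(bad, collapse = ", ")
    ))
  invisible(labels)
}
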