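#' Cross-classify manual against predicted labels
#'
#' Builds the confusion matrix between expert (manual) labels — rows —
#' and device-predicted labels — columns — over a fixed label vocabulary
#' (typically the abundant taxa plus the `Varia` unknown-pollen sink and
#' the `NoPollen`/`Spores` classes). Objects without a manual label, or
#' with a label outside the vocabulary, are excluded and tallied, never
#' silently dropped.
#'
#' @param objects Tibble of labelled objects with `manual` and
#'   `predicted` columns (see [generate_labeled_objects()] or
#'   [read_pomo_object_table()]).
#' @param vocabulary Character vector of labels defining rows/columns.
#'
#' @return A `confusion_matrix`: an integer matrix with `manual` rows and
#'   `predicted` columns, plus attributes `n_missing_manual` and
#'   `excluded_labels` (a named count of out-of-vocabulary labels).
#' @export
build_confusion_matrix <- function(objects, vocabulary) {
  assert(all(c("manual", "predicted") %in% names(objects)),
         "`objects` must have `manual` and `predicted` columns")
  assert(length(vocabulary) > 0 && !anyDuplicated(vocabulary),
         "`vocabulary` must be a non-empty set of unique labels")
  no_manual <- is.na(objects$manual)
  if (any(no_manual)) {
    warn(sprintf("%d object(s) lack a manual label and were excluded",
                 sum(no_manual)))
  }
  kept <- objects[!no_manual, ]
  outside <- !(kept$manual %in% vocabulary) |
    !(kept$predicted %in% vocabulary)
  bad_labels <- c(kept$manual[outside], kept$predicted[outside])
  excluded <- table(bad_labels[!(bad_labels %in% vocabulary)])
  kept <- kept[!outside, ]
  counts <- table(
    manual = factor(kept$manual, levels = vocabulary),
    predicted = factor(kept$predicted, levels = vocabulary)
  )
  m <- matrix(as.integer(counts), nrow = length(vocabulary),
              dimnames = list(manual = vocabulary, predicted = vocabulary))
  structure(m, class = c("confusion_matrix", "matrix"),
            n_missing_manual = sum(no_manual),
            excluded_labels = excluded)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d objects over %d labels\n",
              sum(x), nrow(x)))
  print(unclass(x))
  if (attr(x, "n_missing_manual") > 0) {
    cat(sprintf("  (%d objects without manual label excluded)\n",
                attr(x, "n_missing_manual")))
  }
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), n = "n") %>%
    dplyr::mutate(n = as.integer(.data$n))
}

#' One-vs-rest binary counts for one label
#'
#' Collapses the multi-class confusion matrix to the standard binary
#' quadruple for a single class: TP are objects of that class predicted
#' as it, FN those predicted as anything else (including `Varia`), FP
#' objects of other classes predicted as it, and TN the remainder.
#'
#' @param cm A [build_confusion_matrix()] result.
#' @param label A label in the matrix vocabulary.
#' @return A one-row tibble: `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
binary_decompose <- function(cm, label) {
  assert(inherits(cm, "confusion_matrix"), "`cm` must be a confusion_matrix")
  assert(label %in% rownames(cm),
         sprintf("label '%s' is not in the matrix vocabulary", label))
  m <- unclass(cm)
  tp <- m[label, label]
  fn <- sum(m[label, ]) - tp
  fp <- sum(m[, label]) - tp
  tn <- sum(m) - tp - fn - fp
  tibble::tibble(label = label, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-class sensitivity, PPV and accuracy
#'
#' For every label computes one-vs-rest sensitivity `TP/(TP+FN)` (the
#' share of true members the device labels correctly), positive
#' predictive value `TP/(TP+FP)` (the share of the device's calls that
#' are correct) and the column-conditioned `predicted_class_accuracy`
#' (identical to PPV for a square matrix; reported separately because
#' published per-class "accuracy" figures are usually
#' column-conditioned). A ratio with zero denominator is `NA`, never
#' coerced to 0 or 1. Overall accuracies live in
#' [glance.confusion_matrix()].
#'
#' @inheritParams binary_decompose
#' @return A tibble with one row per label: `label`, `support` (manual
#'   objects of the class), `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `ppv`, `predicted_class_accuracy`.
#' @export
performance_scores <- function(cm) {
  assert(inherits(cm, "confusion_matrix"), "`cm` must be a confusion_matrix")
  assert(sum(cm) > 0, "confusion matrix is empty (all-zero)")
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  purrr::map_dfr(rownames(cm), function(lab) binary_decompose(cm, lab)) %>%
    dplyr::mutate(
      support = .data$tp + .data$fn,
      sensitivity = ratio(.data$tp, .data$tp + .data$fn),
      ppv = ratio(.data$tp, .data$tp + .data$fp),
      predicted_class_accuracy = ratio(.data$tp, .data$tp + .data$fp)
    ) %>%
    dplyr::select("label", "support", "tp", "fp", "fn", "tn",
                  "sensitivity", "ppv", "predicted_class_accuracy")
}

#' Overall accuracy summaries of a confusion matrix
#'
#' @param x A [build_confusion_matrix()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_objects`, `micro_accuracy` (trace over
#'   total — every object weighted equally), `macro_accuracy` (unweighted
#'   mean over classes of the column-conditioned per-class accuracy,
#'   undefined classes dropped), `macro_sensitivity` and `macro_ppv`.
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  assert(sum(x) > 0, "confusion matrix is empty (all-zero)")
  scores <- performance_scores(x)
  m <- unclass(x)
  tibble::tibble(
    n_objects = sum(m),
    micro_accuracy = sum(diag(m)) / sum(m),
    macro_accuracy = mean(scores$predicted_class_accuracy, na.rm = TRUE),
    macro_sensitivity = mean(scores$sensitivity, na.rm = TRUE),
    macro_ppv = mean(scores$ppv, na.rm = TRUE)
  )
}

#' Manual composition of device-flagged non-pollen objects
#'
#' Restricted to objects the device labelled `NoPollen` or `Spores`,
#' reports what they manually turned out to be, with all pollen taxa
#' aggregated into a single `Pollen` bucket. Proportions sum to 1 within
#' each predicted class. This quantifies how much genuine pollen (or how
#' many spores) the device discards as non-pollen.
#'
#' @param objects Tibble of labelled objects with `manual` and
#'   `predicted`.
#' @param nonpollen_labels Predicted classes to audit (default
#'   `c("NoPollen", "Spores")`).
#' @param pollen_taxa Character vector of labels to fold into `Pollen`;
#'   by default every manual label other than the non-pollen classes and
#'   `Varia`.
#' @return A tibble: `predicted`, `manual_group`, `n`, `proportion`.
#' @export
particle_breakdown <- function(objects,
                               nonpollen_labels = c("NoPollen", "Spores"),
                               pollen_taxa = NULL) {
  assert(all(c("manual", "predicted") %in% names(objects)),
         "`objects` must have `manual` and `predicted` columns")
  sel <- objects %>%
    dplyr::filter(.data$predicted %in% nonpollen_labels,
                  !is.na(.data$manual))
  assert(nrow(sel) > 0,
         "no objects with a non-pollen predicted label to break down")
  pollen_taxa <- pollen_taxa %||%
    setdiff(unique(sel$manual), c(nonpollen_labels, "Varia"))
  sel %>%
    dplyr::mutate(manual_group = dplyr::case_when(
      .data$manual %in% nonpollen_labels ~ .data$manual,
      .data$manual %in% pollen_taxa ~ "Pollen",
      TRUE ~ "Other"
    )) %>%
    dplyr::count(.data$predicted, .data$manual_group, name = "n") %>%
    dplyr::group_by(.data$predicted) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
}

#' Heatmap of a confusion matrix
#'
#' @param object A [build_confusion_matrix()] result.
#' @param normalize Normalise counts by row (`"manual"`, default), by
#'   column (`"predicted"`), or not at all (`"none"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object,
                                      normalize = c("manual", "predicted",
                                                    "none"),
                                      ...) {
  normalize <- match.arg(normalize)
  df <- tidy(object)
  df <- switch(normalize,
    manual = df %>% dplyr::group_by(.data$manual) %>%
      dplyr::mutate(value = .data$n / max(1L, sum(.data$n))) %>%
      dplyr::ungroup(),
    predicted = df %>% dplyr::group_by(.data$predicted) %>%
      dplyr::mutate(value = .data$n / max(1L, sum(.data$n))) %>%
      dplyr::ungroup(),
    none = dplyr::mutate(df, value = .data$n)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$manual,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 name = normalize) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted (automatic)", y = "target (manual)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
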