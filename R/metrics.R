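#' Voxel-wise confusion counts
#'
#' Tallies true/false positive/negative voxels between a predicted and a
#' ground-truth binary mask or volume of identical shape. Counts always sum
#' to the number of voxels compared.
#'
#' @param pred,truth logical (or 0/1) arrays of identical shape.
#' @return A `confusion_counts` object (named list `tp`, `tn`, `fp`, `fn`).
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth shapes differ")
  p <- as.logical(pred); t <- as.logical(truth)
  confusion_counts(tp = sum(p & t), tn = sum(!p & !t),
                   fp = sum(p & !t), fn = sum(!p & t))
}

#' Construct confusion counts directly
#'
#' Counts may be non-integer so that published percentage tables can be
#' re-checked as-is.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %g  TN %g  FP %g  FN %g\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Tidy a confusion_counts object
#'
#' @param x a `confusion_counts` object.
#' @param ... unused.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`, `ac`, `ji`.
#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
                 ac = accuracy(x),
                 ji = if (x$tp + x$fp + x$fn > 0) jaccard(x) else NA_real_)
}

#' Segmentation accuracy
#'
#' `AC = (TP + TN) / (TP + FN + TN + FP)`: the fraction of voxels whose
#' class was predicted correctly. Note that in a large field the many true
#' negatives inflate AC; the Jaccard index is the stricter measure.
#'
#' @param c a [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$fn + c$tn + c$fp
  if (total <= 0) stop("accuracy undefined: zero voxels compared")
  (c$tp + c$tn) / total
}

#' Jaccard similarity index
#'
#' `JI = TP / (TP + FP + FN)`: intersection over union of prediction and
#' truth. True negatives play no part, so JI is unaffected by how much
#' empty field surrounds the object.
#'
#' @param c a [confusion_counts()] object.
#' @param empty_union what to do when `tp + fp + fn == 0` (both masks
#'   empty): `"error"` (default) or `"one"` to declare perfect agreement.
#' @return Fraction in `[0, 1]`.
#' @export
jaccard <- function(c, empty_union = c("error", "one")) {
  denom <- c$tp + c$fp + c$fn
  if (denom <= 0) {
    if (match.arg(empty_union) == "one") return(1)
    stop("Jaccard undefined: empty union (tp + fp + fn == 0)")
  }
  c$tp / denom
}

scenario_mask <- function(labels, scenario, codes) {
  switch(scenario,
    cell_excl_nucleus = labels == codes[["cell_cytoplasm"]],
    cell_incl_nucleus = labels == codes[["cell_cytoplasm"]] |
                        labels == codes[["nucleus"]],
    nucleus_only = labels == codes[["nucleus"]],
    stop("unknown scenario: ", scenario))
}

#' Evaluate the three standard scenarios
#'
#' Scores prediction against truth under three binarizations of the class
#' map: (a) the cell excluding its nucleus, (b) the cell including the
#' nucleus, and (c) the nucleus only. By construction the scenario-(b) mask
#' is the voxel-wise union of (a) and (c).
#'
#' @param pred,truth [label_volume()] objects of identical shape sharing
#'   the class-code map.
#' @return A `scenario_report` tibble: `scenario`, `tp`, `tn`, `fp`, `fn`,
#'   `ac`, `ji`.
#' @export
evaluate_scenarios <- function(pred, truth) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("pred and truth shapes differ")
  codes <- c(background = 0L, cell_cytoplasm = 1L, nucleus = 2L, neighbour = 3L)
  for (nm in c("pred", "truth")) {
    v <- get(nm)
    bad <- setdiff(unique(as.vector(v$labels)), unname(codes))
    if (length(bad)) stop("unknown class codes in ", nm, ": ",
                          paste(bad, collapse = ", "))
  }
  scenarios <- c("cell_excl_nucleus", "cell_incl_nucleus", "nucleus_only")
  rep <- purrr::map_dfr(scenarios, function(s) {
    cc <- confusion(scenario_mask(pred$labels, s, codes),
                    scenario_mask(truth$labels, s, codes))
    tibble::tibble(scenario = s, tp = cc$tp, tn = cc$tn, fp = cc$fp,
                   fn = cc$fn, ac = accuracy(cc),
                   ji = jaccard(cc, empty_union = "one"))
  })
  class(rep) <- c("scenario_report", class(rep))
  rep
}

#' Plot a scenario report
#'
#' Bar chart of Accuracy and Jaccard per evaluation scenario.
#'
#' @param object a `scenario_report` from [evaluate_scenarios()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scenario_report
#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::select("scenario", "ac", "ji") |>
    tidyr_pivot()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL,
                  title = "Segmentation quality by scenario") +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble::tibble(scenario = df$scenario, metric = "AC", value = df$ac),
    tibble::tibble(scenario = df$scenario, metric = "JI", value = df$ji))
}
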