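#' Seven-by-seven frame confusion matrix
#'
#' Tallies (true, predicted) frame label pairs into the 49 categories indexed
#' by true (rows) and predicted (columns) reading frame; all 49 cells are
#' present, zeros included, so the grand total equals the number of evaluated
#' fragments.
#'
#' @param true Character vector of true labels, or a `frame_evaluation`
#'   object (in which case `predicted` is taken from it).
#' @param predicted Character vector of predicted labels.
#' @param species_id Identifier stored on the matrix (`"pooled"` by default).
#' @return A 7x7 integer matrix of class `frame_confusion`.
#' @export
frame_confusion <- function(true, predicted = NULL, species_id = "pooled") {
  if (inherits(true, "frame_evaluation")) {
    predicted <- true$pairs$predicted
    true <- true$pairs$true
  }
  .assert_label(true); .assert_label(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted labels differ in length")
  lv <- frame_labels()
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(m), 7L, 7L, dimnames = list(true = lv,
                                                     predicted = lv))
  structure(m, class = c("frame_confusion", class(m)),
            species_id = species_id)
}

#' @export
print.frame_confusion <- function(x, ...) {
  cat(sprintf("<frame_confusion> species=%s, N=%d (rows true, cols predicted)\n",
              attr(x, "species_id"), sum(x)))
  print(unclass(x)[, ])
  invisible(x)
}

#' Summarize a confusion matrix into the five error classes
#'
#' TP: true coding, predicted in the same frame (diagonal over the six coding
#' labels).  TN: true NC predicted NC.  FP: true NC predicted coding.
#' FN: true coding predicted NC.  WF: true coding, predicted coding in a
#' different frame — a nonoverlapping error class of its own.
#' `N_tot = TP + TN + FP + FN + WF`.
#'
#' @param object A `frame_confusion` matrix.
#' @param ... Unused.
#' @return A list of class `frame_summary` with elements `TP`, `TN`, `FP`,
#'   `FN`, `WF`, `N_tot`, `species_id`.
#' @export
summary.frame_confusion <- function(object, ...) {
  m <- unclass(object)
  cod <- 1:6
  TP <- sum(diag(m)[cod])
  TN <- m["NC", "NC"]
  FP <- sum(m["NC", cod])
  FN <- sum(m[cod, "NC"])
  WF <- sum(m[cod, cod]) - TP
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, WF = WF,
                 N_tot = sum(m), species_id = attr(object, "species_id")),
            class = "frame_summary")
}

#' @export
print.frame_summary <- function(x, ...) {
  cat(sprintf("<frame_summary> TP=%d TN=%d FP=%d FN=%d WF=%d N_tot=%d\n",
              x$TP, x$TN, x$FP, x$FN, x$WF, x$N_tot))
  invisible(x)
}

.ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Performance metrics with an explicit wrong-frame class
#'
#' Sensitivity `Sn = TP / (TP + FN + WF)`, specificity `Sp = TN / (TN + FP)`,
#' positive predictive value `PPV = TP / (TP + FP + WF)` and overall accuracy
#' `(TP + TN) / N_tot` — the incidence-weighted combination
#' `Sn * P/N_tot + Sp * F/N_tot` of sensitivity and specificity.  Wrong-frame
#' calls (WF) enter the denominators of Sn and PPV as errors.  Ratios with a
#' zero denominator are reported as `NA`, never coerced to 0 or 1.
#'
#' @param x A `frame_summary`, `frame_confusion` or `frame_evaluation`.
#' @return A list of class `frame_metrics` with elements `sensitivity`,
#'   `specificity`, `ppv`, `overall_accuracy`, `summary`, `species_id`.
#' @export
frame_metrics <- function(x) {
  s <- if (inherits(x, "frame_summary")) x
       else if (inherits(x, "frame_confusion")) summary(x)
       else if (inherits(x, "frame_evaluation")) summary(frame_confusion(x))
       else stop("x must be a frame_summary, frame_confusion or frame_evaluation")
  structure(list(
    sensitivity = .ratio_or_na(s$TP, s$TP + s$FN + s$WF),
    specificity = .ratio_or_na(s$TN, s$TN + s$FP),
    ppv = .ratio_or_na(s$TP, s$TP + s$FP + s$WF),
    overall_accuracy = .ratio_or_na(s$TP + s$TN, s$N_tot),
    summary = s, species_id = s$species_id),
    class = "frame_metrics")
}

#' @export
print.frame_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("<frame_metrics> %s: Sn=%s Sp=%s PPV=%s accuracy=%s (N=%d)\n",
              x$species_id, fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$ppv), fmt(x$overall_accuracy), x$summary$N_tot))
  invisible(x)
}

#' Per-species confusion matrices and metrics
#'
#' @param evaluation A `frame_evaluation`.
#' @return Named list of `frame_metrics`, one per species.
#' @export
metrics_by_species <- function(evaluation) {
  stopifnot(inherits(evaluation, "frame_evaluation"))
  sp <- split(evaluation$pairs, evaluation$pairs$species_id)
  lapply(sp, function(p)
    frame_metrics(frame_confusion(p$true, p$predicted,
                                  species_id = p$species_id[1L])))
}

#' Equal-weight average of per-species metrics
#'
#' The unweighted arithmetic mean of each metric across species, regardless
#' of per-species fragment counts.  A species is excluded from a metric's
#' mean (with a warning) only where that metric is undefined for it; the
#' number of contributing species per metric is attached as attribute
#' `"n_species"`.
#'
#' @param reports List of `frame_metrics` (e.g. from [metrics_by_species()]).
#' @return A `frame_metrics` with `species_id = "averaged"`; its `summary`
#'   holds the summed counts (for reference only — the metrics are means, not
#'   ratios of the summed counts).
#' @export
species_average <- function(reports) {
  if (!length(reports)) stop("species_average requires at least one species")
  stopifnot(all(vapply(reports, inherits, logical(1L), "frame_metrics")))
  fields <- c("sensitivity", "specificity", "ppv", "overall_accuracy")
  vals <- sapply(reports, function(r) unlist(r[fields]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(fields))
  rownames(vals) <- fields
  n_def <- rowSums(!is.na(vals))
  if (any(n_def < length(reports)))
    warning("some species excluded from averaging where a metric is undefined",
            call. = FALSE)
  means <- rowMeans(vals, na.rm = TRUE)
  means[n_def == 0L] <- NA_real_
  tot <- Reduce(function(a, b) Map(`+`, a, b),
                lapply(reports, function(r)
                  r$summary[c("TP", "TN", "FP", "FN", "WF", "N_tot")]))
  s <- structure(c(tot, list(species_id = "averaged")),
                 class = "frame_summary")
  out <- structure(list(sensitivity = means[["sensitivity"]],
                        specificity = means[["specificity"]],
                        ppv = means[["ppv"]],
                        overall_accuracy = means[["overall_accuracy"]],
                        summary = s, species_id = "averaged"),
                   class = "frame_metrics")
  attr(out, "n_species") <- n_def
  out
}

#' Score-threshold ROC curve
#'
#' For each threshold, predictions scoring below it are discarded (their
#' fragments fall back to predicted `NC`) and the center-selection / frame /
#' metric pipeline is re-applied.  Because center selection always picks the
#' highest-scoring covering prediction, thresholding is equivalent to masking
#' each fragment's selected prediction once its score drops below the
#' threshold, which is how the sweep is computed.  The default grid is every
#' distinct observed score plus `-Inf`; the `-Inf` point reproduces the
#' unthresholded (default operating point) metrics and is the rightmost point
#' of the curve.
#'
#' @param evaluation A `frame_evaluation` whose predictions all carry scores.
#' @param thresholds Numeric score cutoffs; default: all distinct observed
#'   scores plus `-Inf`.
#' @return data.frame of class `frame_roc`: `threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `overall_accuracy`, and the five counts.
#' @export
roc_curve <- function(evaluation, thresholds = NULL) {
  stopifnot(inherits(evaluation, "frame_evaluation"))
  preds <- evaluation$predictions
  if (nrow(preds) && anyNA(preds$score))
    stop("ROC thresholds requested but some predictions carry no score")
  if (is.null(thresholds))
    thresholds <- c(-Inf, sort(unique(preds$score)))
  p <- evaluation$pairs
  rows <- lapply(sort(thresholds), function(thr) {
    lab <- ifelse(!is.na(p$score) & p$score >= thr, p$predicted, "NC")
    m <- frame_metrics(frame_confusion(p$true, lab))
    data.frame(threshold = thr, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv,
               overall_accuracy = m$overall_accuracy,
               TP = m$summary$TP, TN = m$summary$TN, FP = m$summary$FP,
               FN = m$summary$FN, WF = m$summary$WF, N_tot = m$summary$N_tot)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frame_roc", "data.frame")
  out
}

#' @export
plot.frame_roc <- function(x, ...) {
  plot(x$specificity, x$sensitivity, type = "b", pch = 16,
       xlab = "Specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  invisible(x)
}

#' TSV writers for confusion matrices, metrics tables and ROC curves
#'
#' @param x Object to write (`frame_confusion`; a list of `frame_metrics` or
#'   a single one; a `frame_roc`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_confusion <- function(x, path) {
  stopifnot(inherits(x, "frame_confusion"))
  df <- as.data.frame(unclass(x)[, ])
  df <- cbind(true = rownames(df), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
write_metrics <- function(x, path) {
  if (inherits(x, "frame_metrics")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(m)
    data.frame(species_id = m$species_id, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv,
               overall_accuracy = m$overall_accuracy, TP = m$summary$TP,
               TN = m$summary$TN, FP = m$summary$FP, FN = m$summary$FN,
               WF = m$summary$WF, N_tot = m$summary$N_tot)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
write_roc <- function(x, path) {
  stopifnot(inherits(x, "frame_roc"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
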