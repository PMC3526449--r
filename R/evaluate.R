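#' Evaluate predictions against ground-truth frame labels
#'
#' The full center-based evaluation: for every fragment, the prediction
#' covering the center is selected ([select_center_prediction()]), its
#' read-coordinate frame computed ([predicted_frame_at_center()]) and, when
#' `adjust_indels = TRUE`, corrected for the cumulative simulated indels
#' before the center ([adjust_predicted_frame()]); fragments with no covering
#' prediction are predicted `NC`.
#'
#' @param fragments List of `errored_fragment`s (may be `NULL` if `truth` is
#'   given).
#' @param genome The `annotated_genome` (may be `NULL` if `truth` is given).
#' @param predictions A [prediction_table()].
#' @param truth Optional precomputed [truth_labels()] table.
#' @param adjust_indels Apply the cumulative indel correction (default).
#'   Disabling it reproduces the artefactual decay of apparent accuracy with
#'   fragment length on indel-containing data.
#' @param use_reported_indels Honor caller-reported indels in the frame
#'   computation.
#' @param score_threshold Optional score cutoff: predictions scoring below it
#'   are discarded before center selection.
#' @return An object of class `frame_evaluation` with element `pairs`
#'   (data.frame: `fragment_id`, `species_id`, `true`, `predicted`,
#'   `raw_predicted`, `score`).
#' @export
evaluate_frames <- function(fragments = NULL, genome = NULL, predictions,
                            truth = NULL, adjust_indels = TRUE,
                            use_reported_indels = TRUE,
                            score_threshold = NULL) {
  if (is.null(truth)) {
    if (is.null(fragments) || is.null(genome))
      stop("either `truth` or both `fragments` and `genome` are required")
    truth <- truth_labels(fragments, genome)
  }
  predictions <- as.data.frame(predictions)
  if (!is.null(score_threshold)) {
    if (nrow(predictions) && anyNA(predictions$score))
      stop("score threshold requested but some predictions carry no score")
    predictions <- predictions[predictions$score >= score_threshold, ,
                               drop = FALSE]
  }
  idx <- if (nrow(predictions))
    split(seq_len(nrow(predictions)), predictions$fragment_id) else list()
  ps <- predictions$start; pe <- predictions$end
  pstr <- predictions$strand; psc <- predictions$score
  pind <- predictions$indels
  n <- nrow(truth)
  pred_lab <- raw_lab <- rep("NC", n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- idx[[truth$fragment_id[i]]]
    if (is.null(j)) next
    c0 <- truth$center_read_pos[i]
    if (any(pe[j] > truth$read_length[i]))
      stop("prediction extends past the read end: ", truth$fragment_id[i])
    k <- .select_center_idx(ps[j], pe[j], psc[j], c0)
    if (k == 0L) next
    jj <- j[k]
    raw_lab[i] <- .frame_at_center(ps[jj], pe[jj], pstr[jj], pind[jj], c0,
                                   use_reported_indels)
    score[i] <- psc[jj]
  }
  pred_lab <- if (adjust_indels)
    adjust_predicted_frame(raw_lab, cbind(ins = truth$ins_before,
                                          del = truth$del_before))
  else raw_lab
  pairs <- data.frame(fragment_id = truth$fragment_id,
                      species_id = truth$species_id,
                      true = truth$label, predicted = pred_lab,
                      raw_predicted = raw_lab, score = score,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, truth = truth, predictions = predictions,
                 adjust_indels = adjust_indels,
                 use_reported_indels = use_reported_indels),
            class = "frame_evaluation")
}

#' @export
print.frame_evaluation <- function(x, ...) {
  cat(sprintf("<frame_evaluation> %d fragments (%d species), indel correction %s\n",
              nrow(x$pairs), length(unique(x$pairs$species_id)),
              if (x$adjust_indels) "on" else "off"))
  print(frame_metrics(x))
  invisible(x)
}

#' @export
summary.frame_evaluation <- function(object, ...) {
  m <- frame_confusion(object)
  print(m)
  frame_metrics(m)
}
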