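#' Per-position predicted coding fraction
#'
#' For each position `n` (1-based, matching the usual reporting convention;
#' internally positions stay 0-based), the fraction of the reads at least `n`
#' bases long whose `n`th base is contained within at least one predicted
#' gene.  Overlapping predictions on a read are unioned, so no position is
#' counted twice, and predictions on either strand count as coding coverage.
#' The accompanying read-length histogram is attached.
#'
#' @param reads A list of `errored_fragment`s, or a named integer vector of
#'   read lengths (names = fragment ids).
#' @param predictions A [prediction_table()] referencing those reads.
#' @param max_n Largest position to profile; defaults to the longest read.
#' @return data.frame of class `coding_profile`: `n`, `eligible_reads`,
#'   `covered_reads`, `coding_fraction` (`NA` where no read is that long),
#'   with the length histogram as attribute `"length_histogram"`.
#' @export
coding_fraction_profile <- function(reads, predictions, max_n = NULL) {
  if (is.list(reads)) {
    lens <- vapply(reads, function(f) nchar(f$sequence), integer(1L))
    names(lens) <- vapply(reads, `[[`, character(1L), "id")
  } else {
    lens <- as.integer(reads)
    names(lens) <- names(reads)
  }
  if (!length(lens)) stop("no reads supplied")
  if (is.null(max_n)) max_n <- max(lens)
  max_n <- as.integer(max_n)
  if (max_n <= 0L) stop("max_n must be positive")
  predictions <- as.data.frame(predictions)
  if (nrow(predictions) && !all(predictions$fragment_id %in% names(lens)))
    stop("predictions reference unknown reads")

  # eligible[n] = #reads with length >= n; reads longer than max_n are
  # clamped into bin max_n, which is exactly ">= n" for every n <= max_n
  eligible <- rev(cumsum(rev(tabulate(pmin(lens, max_n), nbins = max_n))))
  hist_tab <- tabulate(lens, nbins = max(lens))

  covered <- integer(max_n)
  if (nrow(predictions)) {
    for (pp in split(predictions, predictions$fragment_id)) {
      L <- min(lens[[pp$fragment_id[1L]]], max_n)
      ir <- IRanges::reduce(IRanges::IRanges(pmax(pp$start + 1L, 1L),
                                             pmin(pp$end, L)))
      ir <- ir[IRanges::start(ir) <= IRanges::end(ir)]
      for (k in seq_along(ir)) {
        i0 <- IRanges::start(ir)[k]; i1 <- IRanges::end(ir)[k]
        covered[i0:i1] <- covered[i0:i1] + 1L
      }
    }
  }
  out <- data.frame(n = seq_len(max_n), eligible_reads = eligible,
                    covered_reads = covered,
                    coding_fraction = ifelse(eligible > 0L,
                                             covered / pmax(eligible, 1L),
                                             NA_real_))
  class(out) <- c("coding_profile", "data.frame")
  attr(out, "length_histogram") <- data.frame(read_length = seq_along(hist_tab),
                                              count = hist_tab)
  out
}

#' @export
plot.coding_profile <- function(x, ...) {
  plot(x$n, x$coding_fraction, type = "l", lwd = 2, col = "steelblue",
       ylim = c(0, 1), xlab = "Position in read (n)",
       ylab = "Predicted coding fraction", ...)
  h <- attr(x, "length_histogram")
  if (!is.null(h) && max(h$count) > 0)
    graphics::lines(h$read_length, h$count / max(h$count), col = "black")
  invisible(x)
}

#' Write a coding profile (and its length histogram) to TSV
#'
#' @param x A `coding_profile`.
#' @param path Output path for the profile; the histogram is written next to
#'   it with suffix `.hist.tsv` unless `hist_path` is given.
#' @param hist_path Optional explicit histogram path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(x, path, hist_path = NULL) {
  stopifnot(inherits(x, "coding_profile"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (is.null(hist_path)) hist_path <- sub("(\\.tsv)?$", ".hist.tsv", path)
  write.table(attr(x, "length_histogram"), hist_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
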