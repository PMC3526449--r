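#' Construct a prediction table
#'
#' Predictions are plain data.frames, one row per predicted gene interval on
#' a read: `fragment_id`, `start`/`end` (0-based half-open read coordinates),
#' `strand` (`+`/`-` in read orientation), `score` (`NA` for callers that
#' emit none), `caller`, and `indels` — a caller-reported indel list as a
#' `pos:kind` comma string (`kind` `i`/`d`), `"."` if none.
#'
#' @param fragment_id,start,end,strand,score,caller,indels Column vectors
#'   (recycled to a common length).
#' @return data.frame of class `c("prediction_table", "data.frame")`.
#' @export
prediction_table <- function(fragment_id = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             score = NA_real_, caller = NA_character_,
                             indels = ".") {
  n <- length(fragment_id)
  df <- data.frame(fragment_id = as.character(fragment_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   score = as.numeric(rep_len(score, n)),
                   caller = as.character(rep_len(caller, n)),
                   indels = as.character(rep_len(indels, n)),
                   stringsAsFactors = FALSE)
  if (n && (any(df$start < 0L) || any(df$start >= df$end)))
    stop("predictions must satisfy 0 <= start < end")
  if (n && !all(df$strand %in% c("+", "-")))
    stop("prediction strand must be '+' or '-'")
  class(df) <- c("prediction_table", "data.frame")
  df
}

.rbind_predictions <- function(lst) {
  lst <- lst[vapply(lst, NROW, integer(1L)) > 0L]
  if (!length(lst)) return(prediction_table())
  out <- do.call(rbind, lapply(lst, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

# choose a coordinate in [lo, hi] congruent to target mod 3, nearest to pref;
# the window is chosen by callers so that anchoring never changes whether the
# prediction covers the fragment center
.anchor_mod3 <- function(pref, target, lo, hi) {
  a <- pref + ((target - pref) %% 3L)
  if (a > hi) a <- a - 3L
  if (a < lo) a <- a + 3L
  if (a < lo || a > hi) NA_integer_ else a
}

# frame-anchor windows that preserve center coverage
.fwd_anchor_window <- function(a0, b0, c0) {
  if (a0 <= c0 && c0 < b0) c(0L, c0)            # must keep covering
  else if (a0 > c0) c(c0 + 1L, b0 - 1L)         # right of center: stay right
  else c(0L, b0 - 1L)                           # left of center: a < b0 <= c0
}
.rev_anchor_window <- function(a0, b0, c0, rl) {
  if (a0 <= c0 && c0 < b0) c(max(c0 + 1L, a0 + 1L), rl)
  else if (b0 <= c0) c(a0 + 1L, c0)             # left of center: stay left
  else c(a0 + 1L, rl)                           # right of center: a0 > c0
}

#' Perfect-knowledge oracle caller
#'
#' For each annotated gene overlapping a fragment's template interval, emits
#' one prediction whose read coordinates are the gene's footprint mapped
#' through the error log.  The frame is encoded in the anchor coordinate
#' (start for forward, end for reverse predictions, mod 3) and is the gene's
#' frame referenced to the beginning of the read — the naive template frame,
#' before any indel drift — which is exactly what
#' [adjust_predicted_frame()] corrects to the annotated frame at the center.
#' All scores are 1.0.
#'
#' @param fragment An `errored_fragment` or a list of them.
#' @param genome The `annotated_genome` the fragment(s) came from.
#' @return A [prediction_table()].
#' @export
oracle_caller <- function(fragment, genome) {
  if (is.list(fragment) && !inherits(fragment, "errored_fragment"))
    return(.rbind_predictions(lapply(fragment, oracle_caller, genome = genome)))
  f <- fragment
  if (f$genome_id != genome$id)
    stop("fragment provenance does not match genome")
  g <- genome$genes
  hits <- which(g$start < f$template_end & g$end > f$template_start)
  if (!length(hits)) return(prediction_table())
  rl <- nchar(f$sequence)
  if (rl < 5L)
    stop("reads shorter than 5 bases cannot carry a frame anchor")
  maps <- .fragment_maps(f)
  c0 <- center_index(rl)
  ts <- f$template_start; te <- f$template_end
  t_naive <- if (f$template_strand == "+") ts + c0 else te - 1L - c0
  starts <- ends <- integer(0)
  sides <- character(0)
  for (i in hits) {
    gene <- g[i, , drop = FALSE]
    gs <- max(gene$start, ts); ge <- min(gene$end, te)
    if (f$template_strand == "+") { u0 <- gs - ts; u1 <- ge - ts }
    else { u0 <- te - ge; u1 <- te - gs }
    rp <- maps$tpl2read[(u0 + 1L):u1]
    rp <- rp[!is.na(rp)]
    if (!length(rp)) next                  # footprint entirely deleted
    a0 <- min(rp)
    # the footprint extends through any inserted bases that follow the gene's
    # last template-derived base, mirroring the left-fill convention used for
    # truth labeling of inserted centers: coverage then coincides exactly
    # with "center maps into this gene"
    after <- if (u1 < maps$tl) maps$tpl2read[(u1 + 1L):maps$tl]
             else integer(0)
    after <- after[!is.na(after)]
    b0 <- if (length(after)) min(after) else rl
    phase_e <- .gene_phase(gene, t_naive)
    side <- if (gene$strand == f$template_strand) "+" else "-"
    if (side == "+") {
      w <- .fwd_anchor_window(a0, b0, c0)
      a <- .anchor_mod3(a0, (c0 - phase_e) %% 3L, w[1L], w[2L])
      if (is.na(a)) next
      b <- b0
    } else {
      w <- .rev_anchor_window(a0, b0, c0, rl)
      b <- .anchor_mod3(b0, (c0 + 1L + phase_e) %% 3L, w[1L], w[2L])
      if (is.na(b)) next
      a <- a0
    }
    starts <- c(starts, a); ends <- c(ends, b); sides <- c(sides, side)
  }
  if (!length(starts)) return(prediction_table())
  prediction_table(f$id, starts, ends, sides, score = 1.0, caller = "oracle")
}

#' Parameterised noisy mock caller
#'
#' Starts from the oracle output and degrades it: each true prediction is
#' dropped with `miss_prob`; surviving predictions have their frame shifted
#' by +1 or +2 with `wrongframe_prob`; on fragments with no overlapping gene
#' a spurious center-covering prediction is emitted with
#' `fp_noncoding_prob`.  Scores are drawn so true predictions
#' (uniform on \[0.55, 1\]) stochastically dominate spurious ones (uniform on
#' \[0, 0.45\]), which makes the output usable for ROC threshold sweeps.
#'
#' @param fragment An `errored_fragment` or a list of them.
#' @param genome The `annotated_genome` the fragment(s) came from.
#' With `truncate_at_errors = TRUE` each surviving prediction is cut short at
#' the first injected error after its start, emulating callers that lose the
#' gene downstream of an error-induced frameshift or spurious stop; combined
#' with a ramped error model this produces the characteristic decline of the
#' predicted coding fraction toward the read end.
#'
#' @param miss_prob,wrongframe_prob,fp_noncoding_prob Probabilities in
#'   \[0, 1\].
#' @param truncate_at_errors Truncate predictions at the first injected error
#'   after their start (predictions whose start lies at or after the first
#'   error are dropped).
#' @param seed Integer seed (one generator per call).
#' @return A [prediction_table()].
#' @export
noisy_caller <- function(fragment, genome, miss_prob = 0.2,
                         wrongframe_prob = 0.1, fp_noncoding_prob = 0.3,
                         truncate_at_errors = FALSE, seed = 1L) {
  probs <- c(miss_prob, wrongframe_prob, fp_noncoding_prob)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  set.seed(.derive_seed(seed, 47L))
  frags <- if (is.list(fragment) && !inherits(fragment, "errored_fragment"))
    fragment else list(fragment)
  rows <- lapply(frags, function(f) {
    base <- oracle_caller(f, genome)
    rl <- nchar(f$sequence)
    c0 <- center_index(rl)
    if (nrow(base)) {
      keep <- runif(nrow(base)) >= miss_prob
      base <- base[keep, , drop = FALSE]
      if (!nrow(base)) return(NULL)
      base$score <- runif(nrow(base), 0.55, 1)
      base$caller <- "noisy"
      wrong <- runif(nrow(base)) < wrongframe_prob
      for (k in which(wrong)) {
        shift <- sample(1:2, 1L)
        if (base$strand[k] == "+") {
          w <- .fwd_anchor_window(base$start[k], base$end[k], c0)
          a <- .anchor_mod3(base$start[k], (base$start[k] + shift) %% 3L,
                            w[1L], w[2L])
          if (!is.na(a)) base$start[k] <- a
        } else {
          w <- .rev_anchor_window(base$start[k], base$end[k], c0, rl)
          b <- .anchor_mod3(base$end[k], (base$end[k] + shift) %% 3L,
                            w[1L], w[2L])
          if (!is.na(b)) base$end[k] <- b
        }
      }
      if (truncate_at_errors && nrow(f$errors)) {
        for (k in seq_len(nrow(base))) {
          after <- f$errors$read_pos[f$errors$read_pos > base$start[k]]
          if (length(after))
            base$end[k] <- min(base$end[k], min(after))
        }
      }
      return(base)
    }
    if (runif(1L) < fp_noncoding_prob) {
      a <- max(0L, c0 - sample(0:15, 1L))
      b <- min(rl, c0 + 1L + sample(0:15, 1L))
      return(prediction_table(f$id, a, b, sample(c("+", "-"), 1L),
                              score = runif(1L, 0, 0.45), caller = "noisy"))
    }
    NULL
  })
  .rbind_predictions(rows)
}
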