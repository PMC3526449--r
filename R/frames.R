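#' Center index of a read
#'
#' The single position at which truth and prediction are compared.  For even
#' lengths the convention is the left-of-middle base: `floor(length / 2)`,
#' 0-based.
#'
#' @param read_length Read length in bases.
#' @return 0-based center position.
#' @export
center_index <- function(read_length) {
  if (any(read_length <= 0L)) stop("read_length must be positive")
  as.integer(read_length %/% 2L)
}

#' Map a read position to its template position
#'
#' Walks the fragment's error log: insertions before (or at) the queried
#' position pull the template coordinate back, deletions push it forward.
#' If the queried position is itself an inserted base the mapping is flagged
#' as a gap and the nearest template-derived base to its left is used
#' (falling back to the right, then 0, for degenerate leading insertions).
#'
#' The returned tally counts insertions with `read_pos <=` the query and
#' deletions up to the last template-derived base at or before the query;
#' with this boundary `ins - del` equals `read_pos - template_offset`
#' exactly, which is the shift [adjust_predicted_frame()] must undo.
#'
#' @param fragment An `errored_fragment`.
#' @param read_pos 0-based position in the final read.
#' @return List with `template_pos` (0-based genome coordinate), `gap`
#'   (logical: query fell on an inserted base), `t_offset` (oriented-template
#'   offset) and `tally` = c(ins, del).
#' @export
map_read_to_template <- function(fragment, read_pos) {
  if (!nrow(fragment$errors)) {         # error-free fast path
    rl <- nchar(fragment$sequence)
    if (read_pos < 0L || read_pos >= rl) stop("read_pos out of range")
    tpos <- if (fragment$template_strand == "+")
      fragment$template_start + read_pos
    else fragment$template_end - 1L - read_pos
    return(list(template_pos = as.integer(tpos), gap = FALSE,
                t_offset = as.integer(read_pos),
                tally = c(ins = 0L, del = 0L)))
  }
  maps <- .fragment_maps(fragment)
  if (read_pos < 0L || read_pos >= maps$rl)
    stop("read_pos out of range")
  u <- maps$read2tpl[read_pos + 1L]
  gap <- is.na(u)
  p_eff <- read_pos
  if (gap) {
    left <- which(!is.na(maps$read2tpl[seq_len(read_pos + 1L)]))
    if (length(left)) {
      p_eff <- left[length(left)] - 1L
      u <- maps$read2tpl[p_eff + 1L]
    } else {
      right <- which(!is.na(maps$read2tpl))
      u <- if (length(right)) maps$read2tpl[right[1L]] else 0L
      p_eff <- -1L
    }
  }
  e <- fragment$errors
  ins <- sum(e$kind == "insertion" & e$read_pos <= read_pos)
  del <- if (p_eff >= 0L)
    sum(e$kind == "deletion" & e$read_pos <= p_eff)
  else max(0L, ins - (read_pos - u))
  tpos <- if (fragment$template_strand == "+")
    fragment$template_start + u
  else fragment$template_end - 1L - u
  list(template_pos = as.integer(tpos), gap = gap,
       t_offset = as.integer(u),
       tally = c(ins = as.integer(ins), del = as.integer(del)))
}

# first annotated gene containing template position t: ascending start, then
# '+' before '-' (genes are stored in that order)
.first_gene_at <- function(genome, t) {
  g <- genome$genes
  hit <- which(g$start <= t & t < g$end)
  if (!length(hit)) return(NULL)
  g[hit[1L], , drop = FALSE]
}

# template-space phase of position t within a gene row
.gene_phase <- function(gene, t) {
  if (gene$strand == "+") (t - gene$start) %% 3L
  else (gene$end - 1L - t) %% 3L
}

#' Annotated reading frame at a fragment's center
#'
#' Maps the fragment's center base to the template (indel-aware), finds the
#' first annotated gene containing that position (ascending start, `+` strand
#' first on ties), computes the gene's codon phase there, and expresses the
#' result relative to the read orientation: a gene on the same strand as the
#' read yields F1--F3, on the opposite strand R1--R3; `NC` if no gene
#' contains the center.
#'
#' @param fragment An `errored_fragment`.
#' @param genome The `annotated_genome` it was sampled from.
#' @return A single frame label (see [frame_labels()]).
#' @export
annotate_center_label <- function(fragment, genome) {
  if (fragment$genome_id != genome$id)
    stop("fragment provenance does not match genome")
  c0 <- center_index(nchar(fragment$sequence))
  m <- map_read_to_template(fragment, c0)
  gene <- .first_gene_at(genome, m$template_pos)
  if (is.null(gene)) return("NC")
  phase <- .gene_phase(gene, m$template_pos)
  side <- if (gene$strand == fragment$template_strand) "F" else "R"
  .frame_label(side, phase)
}

#' Ground-truth labels for a set of fragments
#'
#' One row per fragment: the annotated center label plus the center mapping
#' and indel tally needed to correct predicted frames.
#'
#' @param fragments List of `errored_fragment`s.
#' @param genome The `annotated_genome` they were sampled from.
#' @return data.frame with columns `fragment_id`, `species_id`, `label`,
#'   `center_read_pos`, `center_template_pos`, `ins_before`, `del_before`,
#'   `read_length`.
#' @export
truth_labels <- function(fragments, genome) {
  n <- length(fragments)
  fid <- sp <- lab <- character(n)
  c0v <- tpos <- insv <- delv <- rlv <- integer(n)
  gstart <- genome$genes$start
  gend <- genome$genes$end
  gstrand <- genome$genes$strand
  for (i in seq_len(n)) {
    f <- fragments[[i]]
    if (f$genome_id != genome$id)
      stop("fragment provenance does not match genome")
    rl <- nchar(f$sequence)
    c0 <- center_index(rl)
    m <- map_read_to_template(f, c0)
    hit <- which(gstart <= m$template_pos & m$template_pos < gend)
    lab[i] <- if (!length(hit)) "NC" else {
      k <- hit[1L]
      side <- if (gstrand[k] == f$template_strand) "F" else "R"
      phase <- if (gstrand[k] == "+") (m$template_pos - gstart[k]) %% 3L
               else (gend[k] - 1L - m$template_pos) %% 3L
      .frame_label(side, phase)
    }
    fid[i] <- f$id; sp[i] <- f$species_id
    c0v[i] <- c0; tpos[i] <- m$template_pos
    insv[i] <- m$tally[["ins"]]; delv[i] <- m$tally[["del"]]
    rlv[i] <- rl
  }
  data.frame(fragment_id = fid, species_id = sp, label = lab,
             center_read_pos = c0v, center_template_pos = tpos,
             ins_before = insv, del_before = delv, read_length = rlv,
             stringsAsFactors = FALSE)
}

#' Adjust a predicted frame for cumulative indels
#'
#' A caller reports frames referenced to the beginning of the read; every
#' simulated insertion before the fragment center shifts the read-space frame
#' forward by one and every deletion back by one.  With
#' `s = ins_before - del_before`, forward labels become `(phase - s) mod 3`
#' and reverse labels `(phase + s) mod 3`; `NC` is frame-free and unchanged.
#' The sign convention is pinned by the oracle-closure test.
#'
#' @param pred A frame label (possibly vector).
#' @param tally Numeric vector/list with elements `ins` and `del`, or a
#'   2-column matrix/data.frame aligned with `pred`.
#' @return Adjusted frame label(s).
#' @export
adjust_predicted_frame <- function(pred, tally) {
  .assert_label(pred)
  if (is.data.frame(tally) || is.matrix(tally)) {
    ins <- as.integer(tally[, "ins"]); del <- as.integer(tally[, "del"])
  } else {
    ins <- as.integer(tally[["ins"]]); del <- as.integer(tally[["del"]])
  }
  s <- rep_len(ins - del, length(pred))
  out <- pred
  fwd <- .label_side(pred) == "F"
  rev <- .label_side(pred) == "R"
  if (any(fwd))
    out[fwd] <- .frame_label("F", (.label_phase(pred[fwd]) - s[fwd]) %% 3L)
  if (any(rev))
    out[rev] <- .frame_label("R", (.label_phase(pred[rev]) + s[rev]) %% 3L)
  out
}

#' Write a truth table TSV
#'
#' @param truth data.frame from [truth_labels()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_labels <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_labels
#' @export
read_truth_labels <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
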