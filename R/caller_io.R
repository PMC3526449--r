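#' Parse gene-caller output into a normalized prediction table
#'
#' Adapters normalize tool-specific coordinates (1-based inclusive on disk)
#' to the package's 0-based half-open read coordinates and carry scores
#' through only for tools that emit a confidence score (MetaGeneMark and
#' Orphelia do not; their `score` is `NA`).  Malformed records are skipped
#' with a warning; the number skipped is attached as attribute `"skipped"`.
#'
#' Dialects:
#' \describe{
#'   \item{generic_tsv}{The package's bit-specified interchange format:
#'     `fragment_id  start  end  strand  score  caller  indels`, tab
#'     separated, 0-based half-open, `.` for absent score/indels, optional
#'     `#`-prefixed header.}
#'   \item{fgs}{FragGeneScan `.out`: `>read` header lines followed by
#'     `start  end  strand  frame  score` records, optionally with
#'     `I:pos,...` / `D:pos,...` reported-indel fields.}
#'   \item{mga}{MetaGeneAnnotator: three `#` header lines per read (the
#'     first bearing the read name) followed by
#'     `gene_id start end strand frame state score ...` records.}
#'   \item{mgm_gff}{MetaGeneMark GFF: CDS features, seqid = fragment id;
#'     scores dropped.}
#'   \item{orphelia}{Orphelia: `>read` headers followed by
#'     `id start end strand ...` records; scores dropped.}
#'   \item{prodigal_gff}{Prodigal GFF3: CDS features with scores.}
#' }
#'
#' @param stream Character vector of lines, or a path to a file.
#' @param dialect One of `"generic_tsv"`, `"fgs"`, `"mga"`, `"mgm_gff"`,
#'   `"orphelia"`, `"prodigal_gff"`.
#' @return A [prediction_table()].
#' @export
parse_predictions <- function(stream,
                              dialect = c("generic_tsv", "fgs", "mga",
                                          "mgm_gff", "orphelia",
                                          "prodigal_gff")) {
  dialect <- match.arg(dialect)
  lines <- if (length(stream) == 1L && !grepl("[\n\t]", stream) &&
               file.exists(stream)) readLines(stream) else stream
  lines <- lines[nzchar(trimws(lines))]
  parser <- switch(dialect,
                   generic_tsv = .parse_generic_tsv,
                   fgs = .parse_fgs,
                   mga = .parse_mga,
                   mgm_gff = function(l) .parse_gff(l, keep_score = FALSE,
                                                    caller = "mgm"),
                   orphelia = .parse_orphelia,
                   prodigal_gff = function(l) .parse_gff(l, keep_score = TRUE,
                                                         caller = "prodigal"))
  parser(lines)
}

.skip_warn <- function(n, dialect) {
  if (n > 0L)
    warning(sprintf("%d malformed %s record(s) skipped", n, dialect),
            call. = FALSE)
}

.finish_parse <- function(rows, skipped, dialect) {
  out <- .rbind_predictions(rows)
  .skip_warn(skipped, dialect)
  attr(out, "skipped") <- skipped
  out
}

.parse_generic_tsv <- function(lines) {
  lines <- lines[!startsWith(lines, "#")]
  skipped <- 0L
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L]))) ||
        !(f[4L] %in% c("+", "-")) ||
        as.integer(f[2L]) < 0L || as.integer(f[2L]) >= as.integer(f[3L])) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    score <- if (length(f) >= 5L && f[5L] != ".")
      suppressWarnings(as.numeric(f[5L])) else NA_real_
    prediction_table(f[1L], as.integer(f[2L]), as.integer(f[3L]), f[4L],
                     score = score,
                     caller = if (length(f) >= 6L) f[6L] else "generic",
                     indels = if (length(f) >= 7L && nzchar(f[7L])) f[7L]
                              else ".")
  })
  .finish_parse(rows, skipped, "generic_tsv")
}

.parse_fgs <- function(lines) {
  frag <- NA_character_
  skipped <- 0L
  rows <- list()
  for (l in lines) {
    if (startsWith(l, ">")) {
      frag <- sub("\\s.*$", "", substring(l, 2L))
      next
    }
    f <- strsplit(trimws(l), "[\t ]+")[[1L]]
    s <- suppressWarnings(as.integer(f[1L]))
    e <- suppressWarnings(as.integer(f[2L]))
    if (is.na(frag) || length(f) < 4L || is.na(s) || is.na(e) ||
        !(f[3L] %in% c("+", "-")) || s < 1L || s > e) {
      skipped <- skipped + 1L
      next
    }
    score <- if (length(f) >= 5L)
      suppressWarnings(as.numeric(f[5L])) else NA_real_
    ind <- character(0)
    for (tok in f[-(1:5)]) {
      if (startsWith(tok, "I:") && nchar(tok) > 2L)
        ind <- c(ind, sprintf("%d:i", as.integer(
          strsplit(substring(tok, 3L), ",")[[1L]]) - 1L))
      if (startsWith(tok, "D:") && nchar(tok) > 2L)
        ind <- c(ind, sprintf("%d:d", as.integer(
          strsplit(substring(tok, 3L), ",")[[1L]]) - 1L))
    }
    rows[[length(rows) + 1L]] <-
      prediction_table(frag, s - 1L, e, f[3L], score = score, caller = "fgs",
                       indels = if (length(ind)) paste(ind, collapse = ",")
                                else ".")
  }
  .finish_parse(rows, skipped, "fgs")
}

.parse_mga <- function(lines) {
  frag <- NA_character_
  hdr_seen <- 0L
  skipped <- 0L
  rows <- list()
  for (l in lines) {
    if (startsWith(l, "#")) {
      body <- trimws(substring(l, 2L))
      if (startsWith(body, "gc") || startsWith(body, "self")) {
        hdr_seen <- hdr_seen + 1L
      } else {
        frag <- sub("\\s.*$", "", body)
        hdr_seen <- 1L
      }
      next
    }
    f <- strsplit(trimws(l), "[\t ]+")[[1L]]
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(frag) || length(f) < 4L || is.na(s) || is.na(e) ||
        !(f[4L] %in% c("+", "-")) || s < 1L || s > e) {
      skipped <- skipped + 1L
      next
    }
    score <- if (length(f) >= 7L)
      suppressWarnings(as.numeric(f[7L])) else NA_real_
    rows[[length(rows) + 1L]] <-
      prediction_table(frag, s - 1L, e, f[4L], score = score, caller = "mga")
  }
  .finish_parse(rows, skipped, "mga")
}

.parse_gff <- function(lines, keep_score, caller) {
  lines <- lines[!startsWith(lines, "#")]
  skipped <- 0L
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) { skipped <<- skipped + 1L; return(NULL) }
    if (!(tolower(f[3L]) %in% c("cds", "gene"))) return(NULL)
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || !(f[7L] %in% c("+", "-")) || s < 1L ||
        s > e) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    score <- if (keep_score && f[6L] != ".")
      suppressWarnings(as.numeric(f[6L])) else NA_real_
    prediction_table(f[1L], s - 1L, e, f[7L], score = score, caller = caller)
  })
  .finish_parse(rows, skipped, paste0(caller, "_gff"))
}

.parse_orphelia <- function(lines) {
  frag <- NA_character_
  skipped <- 0L
  rows <- list()
  for (l in lines) {
    if (startsWith(l, ">")) {
      frag <- sub("\\s.*$", "", substring(l, 2L))
      next
    }
    f <- strsplit(trimws(l), "[\t ]+")[[1L]]
    if (is.na(frag) || length(f) < 4L) { skipped <- skipped + 1L; next }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    strand <- f[which(f %in% c("+", "-"))[1L]]
    if (is.na(s) || is.na(e) || is.na(strand) || s < 1L || s > e) {
      skipped <- skipped + 1L
      next
    }
    # Orphelia emits no confidence score; any probability column is dropped
    rows[[length(rows) + 1L]] <-
      prediction_table(frag, s - 1L, e, strand, score = NA_real_,
                       caller = "orphelia")
  }
  .finish_parse(rows, skipped, "orphelia")
}

#' Write / read predictions in the generic TSV interchange format
#'
#' @param preds A [prediction_table()].
#' @param path TSV path.
#' @return Invisibly `path` (writer); a [prediction_table()] (reader).
#' @export
write_predictions <- function(preds, path) {
  df <- as.data.frame(preds)
  df$score <- ifelse(is.na(df$score), ".", format(df$score, digits = 15L,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  df$indels[is.na(df$indels) | df$indels == ""] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fragment_id\tstart\tend\tstrand\tscore\tcaller\tindels", con)
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s", df$fragment_id,
                       df$start, df$end, df$strand, df$score, df$caller,
                       df$indels), con)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) parse_predictions(path, "generic_tsv")

#' Select the prediction covering the fragment center
#'
#' Filters predictions to those whose half-open interval contains the center
#' position; ties are broken by highest score, then longest interval, then
#' smallest start.  Returns `NULL` when no prediction covers the center (the
#' fragment is then predicted noncoding).
#'
#' @param preds A [prediction_table()] for a single fragment.
#' @param center 0-based center position.
#' @return One-row prediction table, or `NULL`.
#' @export
select_center_prediction <- function(preds, center) {
  if (is.null(preds) || !nrow(preds)) return(NULL)
  if (length(unique(preds$fragment_id)) > 1L)
    stop("predictions from multiple fragments passed to center selection")
  k <- .select_center_idx(preds$start, preds$end, preds$score, center)
  if (k == 0L) return(NULL)
  preds[k, , drop = FALSE]
}

# index of the winning center-covering prediction, 0 if none
.select_center_idx <- function(start, end, score, center) {
  cov <- which(start <= center & center < end)
  if (!length(cov)) return(0L)
  sc <- score[cov]
  sc[is.na(sc)] <- -Inf
  cov[order(-sc, -(end[cov] - start[cov]), start[cov])[1L]]
}

# parse "pos:kind" comma list -> data.frame(read_pos, kind)
.parse_indel_string <- function(s) {
  if (is.null(s) || is.na(s) || s == "." || !nzchar(s))
    return(data.frame(read_pos = integer(0), kind = character(0)))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(read_pos = as.integer(vapply(parts, `[`, character(1L), 1L)),
             kind = vapply(parts, `[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}

#' Read-coordinate frame of a prediction at the center
#'
#' `NULL` (no covering prediction) maps to `NC`.  For a forward prediction
#' the phase is `(center - start + r) mod 3`, where `r` is the net shift from
#' caller-reported indels between the prediction start and the center
#' (insertions count -1, deletions +1); for a reverse prediction the phase is
#' `(end - 1 - center + r') mod 3` with `r'` the analogous shift between the
#' center and `end - 1`.
#'
#' @param pred One-row prediction table, or `NULL`.
#' @param center 0-based center position.
#' @param read_length Read length (consistency check for reverse frames).
#' @param use_reported_indels If `FALSE`, caller-reported indels are ignored
#'   in the frame computation.
#' @return A frame label.
#' @export
predicted_frame_at_center <- function(pred, center, read_length = NULL,
                                      use_reported_indels = TRUE) {
  if (is.null(pred) || !nrow(pred)) return("NC")
  if (pred$start > center || center >= pred$end)
    stop("center lies outside the prediction interval")
  if (!is.null(read_length) && pred$end > read_length)
    stop("prediction extends past the read end")
  .frame_at_center(pred$start, pred$end, pred$strand, pred$indels, center,
                   use_reported_indels)
}

.frame_at_center <- function(start, end, strand, indels, center,
                             use_reported_indels) {
  r <- 0L
  has_ind <- use_reported_indels && !is.null(indels) && !is.na(indels) &&
    indels != "." && nzchar(indels)
  if (has_ind) {
    ind <- .parse_indel_string(indels)
    sel <- if (strand == "+") ind$read_pos >= start & ind$read_pos <= center
           else ind$read_pos > center & ind$read_pos <= end - 1L
    r <- sum(ind$kind[sel] == "d") - sum(ind$kind[sel] == "i")
  }
  if (strand == "+") .frame_label("F", (center - start + r) %% 3L)
  else .frame_label("R", (end - 1L - center + r) %% 3L)
}
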