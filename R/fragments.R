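#' Sequencing error model
#'
#' Per-base substitution and deletion probabilities, a per-gap insertion
#' probability, and an optional positional profile.  With
#' `position_profile = "linear_ramp"` each rate at read position p (0-based)
#' is multiplied by a factor interpolated linearly from `ramp_start` at the
#' first base to `ramp_end` at the last, emulating the rising error rates of
#' pyrosequencing reads.
#'
#' @param sub_rate,ins_rate,del_rate Per-base (per-gap for insertions)
#'   probabilities in \[0, 1).
#' @param position_profile `"uniform"` or `"linear_ramp"`.
#' @param ramp_start,ramp_end Non-negative multipliers applied at the read
#'   start/end under `"linear_ramp"`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                        position_profile = c("uniform", "linear_ramp"),
                        ramp_start = 1, ramp_end = 1) {
  position_profile <- match.arg(position_profile)
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("error rates must lie in [0, 1)")
  if (ramp_start < 0 || ramp_end < 0)
    stop("ramp multipliers must be >= 0")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, position_profile = position_profile,
                 ramp_start = ramp_start, ramp_end = ramp_end),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> sub=%g ins=%g del=%g profile=%s",
              x$sub_rate, x$ins_rate, x$del_rate, x$position_profile))
  if (x$position_profile == "linear_ramp")
    cat(sprintf(" [%g -> %g]", x$ramp_start, x$ramp_end))
  cat("\n")
  invisible(x)
}

#' Named error-model presets
#'
#' The benchmark's standard error conditions: total indel rates of 0, 0.2\%,
#' 0.5\% and 2.8\% (split equally between insertions and deletions), and
#' substitution rates of 0, 1.5e-5, 1.5e-4, 1.5e-3 and 1.5\%.
#'
#' @param name One of `"indel_0"`, `"indel_02"`, `"indel_05"`, `"indel_28"`,
#'   `"sub_0"`, `"sub_15e5"`, `"sub_15e4"`, `"sub_15e3"`, `"sub_15"`.
#' @return An `error_model`.
#' @export
error_preset <- function(name) {
  presets <- list(
    indel_0  = c(0, 0),
    indel_02 = c(0, 0.002),
    indel_05 = c(0, 0.005),
    indel_28 = c(0, 0.028),
    sub_0    = c(0, 0),
    sub_15e5 = c(1.5e-5, 0),
    sub_15e4 = c(1.5e-4, 0),
    sub_15e3 = c(1.5e-3, 0),
    sub_15   = c(0.015, 0))
  if (!name %in% names(presets)) stop("unknown error preset: ", name)
  p <- presets[[name]]
  m <- error_model(sub_rate = p[1L], ins_rate = p[2L] / 2, del_rate = p[2L] / 2)
  attr(m, "preset") <- name
  m
}

.empty_errors <- function() {
  data.frame(read_pos = integer(0), kind = character(0),
             template_base = character(0), read_base = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a fragment
#'
#' A fragment records its provenance on the template genome (0-based
#' half-open interval and reading orientation), its final (post-error) read
#' sequence, and an ordered log of injected error events.  Error event
#' `read_pos` values are positions in the final read; a deletion is logged at
#' the position of the next emitted read base.
#'
#' @param id Fragment identifier.
#' @param genome_id,species_id Provenance identifiers.
#' @param template_start,template_end 0-based half-open template interval.
#' @param template_strand `"+"` or `"-"`: orientation in which the fragment
#'   was read off the template.
#' @param sequence Final read sequence.
#' @param errors data.frame with columns `read_pos`, `kind`
#'   (`substitution`/`insertion`/`deletion`), `template_base`, `read_base`.
#' @return An object of class `errored_fragment`.
#' @export
errored_fragment <- function(id, genome_id, species_id, template_start,
                             template_end, template_strand, sequence,
                             errors = .empty_errors()) {
  stopifnot(template_start >= 0L, template_end > template_start,
            template_strand %in% c("+", "-"))
  errors <- as.data.frame(errors)
  n_ins <- sum(errors$kind == "insertion")
  n_del <- sum(errors$kind == "deletion")
  expect_len <- (template_end - template_start) + n_ins - n_del
  if (nchar(sequence) != expect_len)
    stop(sprintf("fragment %s: sequence length %d != template span %d + ins %d - del %d",
                 id, nchar(sequence), template_end - template_start, n_ins, n_del))
  if (nrow(errors) > 1L && is.unsorted(errors$read_pos))
    stop("error log must be ordered by ascending read_pos")
  structure(list(id = as.character(id), genome_id = as.character(genome_id),
                 species_id = as.character(species_id),
                 template_start = as.integer(template_start),
                 template_end = as.integer(template_end),
                 template_strand = template_strand,
                 sequence = sequence, errors = errors),
            class = "errored_fragment")
}

#' @export
print.errored_fragment <- function(x, ...) {
  cat(sprintf("<errored_fragment> %s: %s[%d,%d) strand %s, %d bp, %d error(s)\n",
              x$id, x$genome_id, x$template_start, x$template_end,
              x$template_strand, nchar(x$sequence), nrow(x$errors)))
  invisible(x)
}

# oriented template substring (read orientation, pre-error)
.oriented_template <- function(fragment, genome) {
  s <- substr(genome$sequence, fragment$template_start + 1L,
              fragment$template_end)
  if (fragment$template_strand == "-") s <- .revcomp(s) else s
}

#' Sample error-free shotgun fragments from a genome
#'
#' Start positions are uniform over the valid range and the reading
#' orientation is chosen uniformly; the returned fragments carry empty error
#' logs and sequences equal to the (reverse-complemented, for `-`) template
#' substring.
#'
#' @param genome An `annotated_genome`.
#' @param n Number of fragments.
#' @param length Fragment length in bases: a scalar, or a vector of length
#'   `n` giving per-fragment lengths.
#' @param seed Integer seed.
#' @param id_prefix Prefix for fragment identifiers.
#' @return List of `errored_fragment` objects.
#' @export
sample_fragments <- function(genome, n, length, seed = 1L,
                             id_prefix = genome$id) {
  if (n <= 0L) stop("n must be positive")
  L <- nchar(genome$sequence)
  if (L < 1L) stop("empty genome")
  len <- as.integer(rep_len(length, n))
  if (any(len < 1L) || any(len > L))
    stop("fragment lengths must lie in [1, genome length]")
  set.seed(.derive_seed(seed, 23L))
  starts <- vapply(L - len + 1L,
                   function(k) if (k == 1L) 0L else sample.int(k, 1L) - 1L,
                   integer(1L))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome$sequence, starts + 1L, starts + len)
  neg <- strands == "-"
  if (any(neg)) seqs[neg] <- .revcomp(seqs[neg])
  lapply(seq_len(n), function(i)
    errored_fragment(sprintf("%s_frag%06d", id_prefix, i),
                     genome$id, genome$species_id,
                     starts[i], starts[i] + len[i], strands[i], seqs[i]))
}

# per-position rate multipliers for a template of length tl (positions) and
# tl + 1 gaps; gap g (before base g+1) takes the multiplier of the following
# base, the final gap that of the last base
.profile_mult <- function(model, tl) {
  if (model$position_profile == "uniform") {
    list(base = rep(1, tl), gap = rep(1, tl + 1L))
  } else {
    m <- if (tl == 1L) model$ramp_start else
      seq(model$ramp_start, model$ramp_end, length.out = tl)
    list(base = m, gap = c(m, m[tl]))
  }
}

#' Inject sequencing errors into a fragment
#'
#' Per oriented-template base, a deletion and (if not deleted) a substitution
#' are drawn independently; insertions are drawn once per inter-base gap
#' (including the gaps before the first and after the last base).  The
#' returned error log is complete, ordered by final-read position, and
#' replaying it against the template substring reconstructs the read exactly
#' (see [replay_errors()]).
#'
#' @param fragment An error-free `errored_fragment` (or a list of them).
#' @param model An `error_model`.
#' @param seed Integer seed; one generator seeds the whole call.
#' @return The fragment(s) with post-error `sequence` and a filled error log.
#' @export
inject_errors <- function(fragment, model, seed = 1L) {
  if (is.list(fragment) && !inherits(fragment, "errored_fragment")) {
    set.seed(.derive_seed(seed, 31L))
    return(lapply(fragment, .inject_one, model = model))
  }
  set.seed(.derive_seed(seed, 31L))
  .inject_one(fragment, model)
}

.inject_one <- function(fragment, model) {
  if (nrow(fragment$errors))
    stop("inject_errors requires a fragment with an empty error log")
  tl <- fragment$template_end - fragment$template_start
  mult <- .profile_mult(model, tl)
  del_p <- model$del_rate * mult$base
  sub_p <- model$sub_rate * mult$base
  ins_p <- model$ins_rate * mult$gap
  if (any(del_p + sub_p >= 1) || any(ins_p >= 1))
    stop("scaled error rates reach 1 at some position")

  bases <- strsplit(fragment$sequence, "", fixed = TRUE)[[1L]]
  del <- runif(tl) < del_p
  sub <- !del & (runif(tl) < sub_p)
  ins <- runif(tl + 1L) < ins_p

  read_base <- bases
  if (any(sub)) {
    # substitute with a uniformly chosen different base
    read_base[sub] <- vapply(bases[sub],
                             function(b) sample(setdiff(.BASES, b), 1L),
                             character(1L), USE.NAMES = FALSE)
  }
  ins_base <- if (any(ins)) sample(.BASES, sum(ins), replace = TRUE)
              else character(0)

  # emitted elements: insertions at gap g (sort key 2g + 1) and kept bases i
  # (sort key 2i); deletions emit nothing
  keep <- !del
  keys <- c(2L * which(keep), 2L * (which(ins) - 1L) + 1L)
  chars <- c(read_base[keep], ins_base)
  o <- order(keys)
  new_seq <- paste(chars[o], collapse = "")
  emitted_keys <- keys[o]

  ev <- list()
  if (any(ins)) {
    g <- which(ins) - 1L
    ev[[1L]] <- data.frame(
      read_pos = match(2L * g + 1L, emitted_keys) - 1L,
      kind = "insertion", template_base = "",
      read_base = ins_base, key = 2L * g + 1L)
  }
  if (any(del)) {
    i <- which(del)
    ev[[2L]] <- data.frame(
      read_pos = findInterval(2L * i, emitted_keys),  # emitted before key
      kind = "deletion", template_base = bases[i], read_base = "",
      key = 2L * i)
  }
  if (any(sub)) {
    i <- which(sub)
    ev[[3L]] <- data.frame(
      read_pos = match(2L * i, emitted_keys) - 1L,
      kind = "substitution", template_base = bases[i],
      read_base = read_base[i], key = 2L * i)
  }
  errors <- if (length(ev)) do.call(rbind, ev) else .empty_errors()
  if (nrow(errors)) {
    errors <- errors[order(errors$read_pos, errors$key), , drop = FALSE]
    errors$key <- NULL
    rownames(errors) <- NULL
  }
  errored_fragment(fragment$id, fragment$genome_id, fragment$species_id,
                   fragment$template_start, fragment$template_end,
                   fragment$template_strand, new_seq, errors)
}

#' Replay an error log against a template substring
#'
#' Reconstructs a read sequence by applying an ordered error log to the
#' oriented (read-direction) template substring.  Used to verify that every
#' fragment's log is complete and consistent.
#'
#' @param template Oriented template substring (character scalar).
#' @param errors Error log data.frame (see [errored_fragment()]).
#' @return The reconstructed read sequence.
#' @export
replay_errors <- function(template, errors) {
  bases <- strsplit(template, "", fixed = TRUE)[[1L]]
  if (!nrow(errors)) return(template)
  pri <- match(errors$kind, c("insertion", "deletion", "substitution"))
  errors <- errors[order(errors$read_pos, pri), , drop = FALSE]
  out <- character(0)
  ti <- 1L
  for (k in seq_len(nrow(errors))) {
    p <- errors$read_pos[k]
    while (length(out) < p) {           # copy untouched template bases
      out <- c(out, bases[ti]); ti <- ti + 1L
    }
    kind <- errors$kind[k]
    if (kind == "insertion") {
      out <- c(out, errors$read_base[k])
    } else if (kind == "deletion") {
      if (bases[ti] != errors$template_base[k])
        stop("replay mismatch: deletion template base disagrees")
      ti <- ti + 1L
    } else {
      if (bases[ti] != errors$template_base[k])
        stop("replay mismatch: substitution template base disagrees")
      out <- c(out, errors$read_base[k]); ti <- ti + 1L
    }
  }
  if (ti <= length(bases)) out <- c(out, bases[ti:length(bases)])
  paste(out, collapse = "")
}

# read<->oriented-template-offset maps derived from the error log.
# read2tpl[p + 1] = oriented template offset of read base p (NA if inserted);
# tpl2read[u + 1] = read position of template offset u (NA if deleted).
.fragment_maps <- function(fragment) {
  rl <- nchar(fragment$sequence)
  tl <- fragment$template_end - fragment$template_start
  e <- fragment$errors
  if (!nrow(e)) {
    idx <- seq_len(rl) - 1L
    return(list(read2tpl = idx, tpl2read = idx, rl = rl, tl = tl))
  }
  ins_pos <- e$read_pos[e$kind == "insertion"]
  del_pos <- e$read_pos[e$kind == "deletion"]
  ins_tab <- tabulate(ins_pos + 1L, nbins = rl + 1L)
  del_tab <- tabulate(del_pos + 1L, nbins = rl + 1L)
  p <- seq_len(rl) - 1L
  cum_ins_excl <- c(0L, cumsum(ins_tab))[p + 1L]   # insertions with read_pos < p
  cum_del_incl <- cumsum(del_tab)[p + 1L]          # deletions with read_pos <= p
  read2tpl <- p - cum_ins_excl + cum_del_incl
  if (length(ins_pos)) read2tpl[ins_pos + 1L] <- NA_integer_
  tpl2read <- rep(NA_integer_, tl)
  ok <- !is.na(read2tpl)
  tpl2read[read2tpl[ok] + 1L] <- p[ok]
  list(read2tpl = read2tpl, tpl2read = tpl2read, rl = rl, tl = tl)
}

#' Write fragments to FASTA with a ground-truth header dialect
#'
#' Header format (version 1):
#' `>fragID genome=<id> species=<id> tstart=<int> tend=<int> strand=<+|->
#' errors=<pos:kind:base,...>` with `kind` one of `s`/`i`/`d`, `base` the
#' read base for substitutions/insertions and the template base for
#' deletions, and `errors=.` when the log is empty.  Coordinates are 0-based
#' half-open.
#'
#' @param fragments List of `errored_fragment`s.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  hdr <- vapply(fragments, function(f) {
    e <- f$errors
    es <- if (!nrow(e)) "." else paste(sprintf(
      "%d:%s:%s", e$read_pos, substr(e$kind, 1L, 1L),
      ifelse(e$kind == "deletion", e$template_base, e$read_base)),
      collapse = ",")
    sprintf("%s genome=%s species=%s tstart=%d tend=%d strand=%s errors=%s",
            f$id, f$genome_id, f$species_id, f$template_start,
            f$template_end, f$template_strand, es)
  }, character(1L))
  s <- Biostrings::DNAStringSet(vapply(fragments, `[[`, character(1L),
                                       "sequence"))
  names(s) <- hdr
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read fragments from a ground-truth FASTA
#'
#' Inverse of [write_fragments()].  Substitution template bases are not
#' stored in the header; they are restored as empty strings (the sidecar
#' error-log TSV, [write_error_log()], preserves both bases).
#'
#' @param path FASTA path written by [write_fragments()].
#' @return List of `errored_fragment`s.
#' @export
read_fragments <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(s), function(i) {
    h <- names(s)[i]
    id <- sub("\\s.*$", "", h)
    field <- function(k) sub(sprintf(".*%s=([^ ]+).*", k), "\\1", h)
    es <- field("errors")
    errors <- .empty_errors()
    if (es != ".") {
      parts <- strsplit(strsplit(es, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
      kind <- c(s = "substitution", i = "insertion",
                d = "deletion")[vapply(parts, `[`, character(1L), 2L)]
      base <- vapply(parts, `[`, character(1L), 3L)
      errors <- data.frame(
        read_pos = as.integer(vapply(parts, `[`, character(1L), 1L)),
        kind = unname(kind),
        template_base = ifelse(kind == "deletion", base, ""),
        read_base = ifelse(kind == "deletion", "", base),
        stringsAsFactors = FALSE)
    }
    errored_fragment(id, field("genome"), field("species"),
                     as.integer(field("tstart")), as.integer(field("tend")),
                     field("strand"), as.character(s[[i]]), errors)
  })
}

#' Write / read the sidecar error-log TSV
#'
#' Columns: `fragment_id`, `read_pos`, `kind`, `template_base`, `read_base`.
#'
#' @param fragments List of `errored_fragment`s.
#' @param path TSV path.
#' @return Invisibly `path` (writer); a data.frame (reader).
#' @export
write_error_log <- function(fragments, path) {
  rows <- lapply(fragments, function(f) {
    if (!nrow(f$errors)) return(NULL)
    cbind(fragment_id = f$id, f$errors)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- cbind(fragment_id = character(0), .empty_errors())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_log
#' @export
read_error_log <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = NULL,
             colClasses = c("character", "integer", "character",
                            "character", "character"))
}
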