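#' Benchmark run configuration
#'
#' Declares an end-to-end run: the genome source, the fragment-length by
#' error-model grid, the prediction source, and the seed.  The configuration
#' is validated up front and serialized verbatim into the output manifest.
#'
#' @param genome An `annotated_genome`, or a list describing one: either
#'   `list(type = "synthetic", length =, coding_fraction =, mean_gene_len =)`
#'   or `list(type = "files", fasta =, gff3 =)`.
#' @param lengths Fragment lengths in bases (the classic grid is 75, 100,
#'   150, 200, 300, 400, 600, 1000).
#' @param n_per_length Fragments sampled per length per error model.
#' @param errors Character vector of [error_preset()] names, or a (list of)
#'   [error_model()].
#' @param caller Prediction source: `list(type = "oracle")`,
#'   `list(type = "noisy", miss_prob =, wrongframe_prob =,
#'   fp_noncoding_prob =)`, or `list(type = "file", path =, dialect =)`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param adjust_indels Apply the cumulative indel correction.
#' @param roc Also compute an ROC sweep per grid cell (requires scores).
#' @param profile Also compute a coding-fraction profile per grid cell.
#' @param out_dir Optional output directory for the report bundle.
#' @return A validated list of class `benchmark_config`.
#' @export
benchmark_config <- function(genome, lengths = c(75L, 100L, 150L, 200L,
                                                 300L, 400L, 600L, 1000L),
                             n_per_length = 1000L,
                             errors = "indel_0",
                             caller = list(type = "oracle"),
                             seed = 1L, adjust_indels = TRUE, roc = FALSE,
                             profile = FALSE, out_dir = NULL) {
  if (!inherits(genome, "annotated_genome")) {
    stopifnot(is.list(genome), !is.null(genome$type))
    if (genome$type == "synthetic") {
      stopifnot(!is.null(genome$length))
    } else if (genome$type == "files") {
      stopifnot(!is.null(genome$fasta), !is.null(genome$gff3))
    } else stop("genome$type must be 'synthetic' or 'files'")
  }
  stopifnot(length(lengths) >= 1L, all(lengths >= 5L), n_per_length >= 1L)
  if (is.character(errors)) {
    errors <- lapply(errors, error_preset)
  } else if (inherits(errors, "error_model")) {
    errors <- list(errors)
  }
  stopifnot(all(vapply(errors, inherits, logical(1L), "error_model")))
  if (is.null(names(errors)) || any(!nzchar(names(errors))))
    names(errors) <- vapply(seq_along(errors), function(i) {
      p <- attr(errors[[i]], "preset")
      if (is.null(p)) sprintf("model%d", i) else p
    }, character(1L))
  stopifnot(is.list(caller),
            caller$type %in% c("oracle", "noisy", "file"))
  if (caller$type == "file")
    stopifnot(!is.null(caller$path), !is.null(caller$dialect))
  structure(list(genome = genome, lengths = as.integer(lengths),
                 n_per_length = as.integer(n_per_length), errors = errors,
                 caller = caller, seed = as.integer(seed),
                 adjust_indels = isTRUE(adjust_indels), roc = isTRUE(roc),
                 profile = isTRUE(profile), out_dir = out_dir),
            class = "benchmark_config")
}

.resolve_genome <- function(config) {
  g <- config$genome
  if (inherits(g, "annotated_genome")) return(g)
  if (g$type == "synthetic") {
    generate_genome(length = g$length,
                    coding_fraction = if (is.null(g$coding_fraction)) 0.87
                                      else g$coding_fraction,
                    mean_gene_len = if (is.null(g$mean_gene_len)) 900L
                                    else g$mean_gene_len,
                    seed = .derive_seed(config$seed, 1L))
  } else {
    read_genome(g$fasta, g$gff3)
  }
}

.call_predictions <- function(config, fragments, genome, cell_seed) {
  cl <- config$caller
  switch(cl$type,
         oracle = oracle_caller(fragments, genome),
         noisy = noisy_caller(fragments, genome,
                              miss_prob = cl$miss_prob %||% 0.2,
                              wrongframe_prob = cl$wrongframe_prob %||% 0.1,
                              fp_noncoding_prob = cl$fp_noncoding_prob %||% 0.3,
                              seed = cell_seed),
         file = {
           if (!file.exists(cl$path))
             stop("prediction file not found: ", cl$path)
           parse_predictions(cl$path, cl$dialect)
         })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full benchmark pipeline
#'
#' Simulate (or load) -> predict -> label -> evaluate -> summarize, for every
#' cell of the fragment-length by error-model grid, deterministically given
#' the config seed.  The accuracy-versus-length table has one row per
#' length x error model x caller.  When `out_dir` is set, the bundle is
#' written as TSV/FASTA/JSON: the results table, per-cell confusion matrices,
#' optional ROC and profile tables, and a manifest with per-stage record
#' counts (any stage failure aborts the run with a stage-tagged error).
#'
#' @param config A [benchmark_config()].
#' @return Invisibly, a list of class `benchmark_result`: `results`
#'   (data.frame), `confusions`, `evaluations`, `rocs`, `profiles`,
#'   `genome`, `manifest`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  genome <- stage("genome", .resolve_genome(config))
  caller_name <- config$caller$type
  rows <- list(); confusions <- list(); evaluations <- list()
  rocs <- list(); profiles <- list()
  counts <- list()
  warn_n <- 0L
  for (ei in seq_along(config$errors)) {
    emodel <- config$errors[[ei]]
    ename <- names(config$errors)[ei]
    for (li in seq_along(config$lengths)) {
      len <- config$lengths[li]
      cell <- sprintf("%s_L%d", ename, len)
      cell_seed <- .derive_seed(config$seed, ei, li)
      frags <- stage("simulate", {
        f <- sample_fragments(genome, config$n_per_length, len,
                              seed = cell_seed,
                              id_prefix = sprintf("%s_%s", genome$id, cell))
        inject_errors(f, emodel, seed = .derive_seed(cell_seed, 2L))
      })
      preds <- stage("call",
                     .call_predictions(config, frags, genome, cell_seed))
      ev <- stage("evaluate", withCallingHandlers(
        evaluate_frames(frags, genome, preds,
                        adjust_indels = config$adjust_indels),
        warning = function(w) { warn_n <<- warn_n + 1L
                                invokeRestart("muffleWarning") }))
      if (nrow(ev$pairs) != length(frags))
        stop(sprintf("[stage evaluate] %s: %d fragments in, %d rows out",
                     cell, length(frags), nrow(ev$pairs)))
      m <- frame_metrics(ev)
      rows[[cell]] <- data.frame(
        length = len, error_model = ename, caller = caller_name,
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, overall_accuracy = m$overall_accuracy,
        TP = m$summary$TP, TN = m$summary$TN, FP = m$summary$FP,
        FN = m$summary$FN, WF = m$summary$WF, N_tot = m$summary$N_tot)
      confusions[[cell]] <- frame_confusion(ev)
      evaluations[[cell]] <- ev
      counts[[cell]] <- c(fragments = length(frags),
                          predictions = nrow(preds),
                          evaluated = nrow(ev$pairs))
      if (config$roc)
        rocs[[cell]] <- stage("roc", roc_curve(ev))
      if (config$profile)
        profiles[[cell]] <- stage("profile",
                                  coding_fraction_profile(frags, preds))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("framebench")),
    seed = config$seed,
    genome = list(id = genome$id, length = nchar(genome$sequence),
                  genes = nrow(genome$genes),
                  coding_fraction = coding_fraction(genome),
                  source = genome$source),
    lengths = config$lengths,
    error_models = names(config$errors),
    caller = caller_name,
    adjust_indels = config$adjust_indels,
    record_counts = counts,
    warnings = warn_n)
  out <- structure(list(results = results, confusions = confusions,
                        evaluations = evaluations, rocs = rocs,
                        profiles = profiles, genome = genome,
                        manifest = manifest),
                   class = "benchmark_result")
  if (!is.null(config$out_dir)) .write_bundle(out, config)
  invisible(out)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d grid cell(s), caller=%s, genome=%s\n",
              nrow(x$results), x$manifest$caller, x$genome$id))
  print(x$results[, c("length", "error_model", "caller", "sensitivity",
                      "specificity", "ppv", "overall_accuracy")],
        row.names = FALSE)
  invisible(x)
}

.write_bundle <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(config$out_dir, ...)
  write.table(result$results, pth("results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (cell in names(result$confusions))
    write_confusion(result$confusions[[cell]],
                    pth(sprintf("confusion_%s.tsv", cell)))
  for (cell in names(result$rocs))
    write_roc(result$rocs[[cell]], pth(sprintf("roc_%s.tsv", cell)))
  for (cell in names(result$profiles))
    write_profile(result$profiles[[cell]],
                  pth(sprintf("profile_%s.tsv", cell)))
  write_genome(result$genome, pth("genome.fasta"), pth("genome.gff3"))
  jsonlite::write_json(result$manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
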