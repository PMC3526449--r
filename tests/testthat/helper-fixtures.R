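# shared fixtures, built in code; cached so expensive genomes are made once
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fix_genome <- function() cached("genome30k", generate_genome(
  30000, coding_fraction = 0.87, seed = 7))

fix_small_genome <- function() cached("genome10k", generate_genome(
  10000, coding_fraction = 0.87, mean_gene_len = 300L, seed = 11))

# genome that is one single forward gene: every fragment center is coding
all_coding_genome <- function() cached("allcoding", annotated_genome(
  "allcoding", paste(rep("ACGTGA", 2000), collapse = ""),
  data.frame(start = 0L, end = 12000L, strand = "+"),
  species_id = "coding_sp"))

# genome with no annotated genes at all
all_noncoding_genome <- function() cached("allnoncoding", annotated_genome(
  "allnoncoding", paste(rep(c("A", "C", "G", "T"), 3000), collapse = ""),
  data.frame(start = integer(0), end = integer(0), strand = character(0)),
  species_id = "noncoding_sp"))

# hand-built fragment with a fully specified error log; the sequence is
# synthesised by replaying the log so the constructor's invariants hold
manual_fragment <- function(genome, template_start, template_end,
                            strand = "+", errors = NULL,
                            id = "manual1") {
  tmpl <- substr(genome$sequence, template_start + 1L, template_end)
  if (strand == "-")
    tmpl <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tmpl)))
  if (is.null(errors))
    errors <- data.frame(read_pos = integer(0), kind = character(0),
                         template_base = character(0),
                         read_base = character(0))
  seq <- replay_errors(tmpl, errors)
  errored_fragment(id, genome$id, genome$species_id, template_start,
                   template_end, strand, seq, errors)
}

# uniform-random prediction table over a set of read lengths
random_predictions <- function(lens, n) {
  ids <- sample(names(lens), n, replace = TRUE)
  rows <- lapply(ids, function(id) {
    L <- lens[[id]]
    a <- sample.int(L, 1L) - 1L
    b <- a + sample.int(L - a, 1L)
    prediction_table(id, a, b, sample(c("+", "-"), 1L),
                     score = stats::runif(1L))
  })
  do.call(rbind, rows)
}
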