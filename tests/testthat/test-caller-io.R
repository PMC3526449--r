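test_that("generic_tsv lines parse to 0-based half-open predictions", {
  p <- parse_predictions("frag1\t10\t99\t+\t0.87", "generic_tsv")
  expect_equal(nrow(p), 1L)
  expect_identical(p$start, 10L)
  expect_identical(p$end, 99L)
  expect_identical(p$strand, "+")
  expect_equal(p$score, 0.87)
  expect_identical(parse_predictions(character(0), "generic_tsv"),
                   parse_predictions("#fragment_id\tstart", "generic_tsv"))
  expect_error(parse_predictions("frag1\t1\t9\t+", "nope"))
})

test_that("generic_tsv writing and re-parsing is lossless", {
  preds <- prediction_table(
    fragment_id = c("a", "a", "b", "c"),
    start = c(0L, 12L, 3L, 7L), end = c(30L, 60L, 9L, 100L),
    strand = c("+", "-", "+", "-"),
    score = c(0.5, NA, 1.25, 0),
    caller = c("x", "x", "y", "y"),
    indels = c(".", "4:i,10:d", ".", "2:d"))
  path <- tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  attr(back, "skipped") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(preds))
})

test_that("GFF-style dialects convert 1-based inclusive coordinates", {
  line <- "frag9\tMGM\tCDS\t11\t99\t12.5\t-\t0\tgene_id=1"
  p <- parse_predictions(line, "mgm_gff")
  expect_identical(p$start, 10L)
  expect_identical(p$end, 99L)
  expect_true(is.na(p$score))     # MetaGeneMark emits no confidence score
  p2 <- parse_predictions(line, "prodigal_gff")
  expect_equal(p2$score, 12.5)
  expect_identical(p2$caller, "prodigal")
})

test_that("FragGeneScan records carry scores and reported indels", {
  lines <- c(">readA", "11\t220\t+\t1\t1.37\tI:45,101\tD:160",
             ">readB", "5\t94\t-\t2\t0.88")
  p <- parse_predictions(lines, "fgs")
  expect_equal(nrow(p), 2L)
  expect_identical(p$fragment_id, c("readA", "readB"))
  expect_identical(p$start, c(10L, 4L))
  expect_equal(p$score, c(1.37, 0.88))
  expect_identical(p$indels[1L], "44:i,100:i,159:d")
  expect_identical(p$indels[2L], ".")
})

test_that("MGA and Orphelia records parse; Orphelia scores are dropped", {
  mga <- c("# readX", "# gc = 0.61, rbs = -", "# self: -",
           "gene_1\t3\t302\t+\t0\t11\t42.7\tb\t-\t-\t-\t-")
  p <- parse_predictions(mga, "mga")
  expect_identical(p$fragment_id, "readX")
  expect_identical(p$start, 2L)
  expect_identical(p$end, 302L)
  expect_equal(p$score, 42.7)
  orph <- c(">readY", "orf1\t21\t180\t+\t2\t0.93")
  p2 <- parse_predictions(orph, "orphelia")
  expect_identical(p2$start, 20L)
  expect_true(is.na(p2$score))
})

test_that("malformed records are skipped with a warning and counted", {
  lines <- c("frag1\t10\t99\t+\t0.5", "frag2\tnot\ta\trecord",
             "frag3\t50\t20\t+\t0.1")
  expect_warning(p <- parse_predictions(lines, "generic_tsv"),
                 "2 malformed")
  expect_equal(nrow(p), 1L)
  expect_identical(attr(p, "skipped"), 2L)
})

test_that("center selection applies the coverage and tie-break rules", {
  expect_null(select_center_prediction(prediction_table(), 10L))
  # half-open exclusion at the right edge
  p <- prediction_table("f", 0L, 50L, "+")
  expect_null(select_center_prediction(p, 50L))
  expect_equal(select_center_prediction(p, 49L)$start, 0L)
  # highest score wins
  p <- prediction_table(rep("f", 2), c(0L, 5L), c(60L, 70L), c("+", "+"),
                        score = c(0.4, 0.9))
  expect_equal(select_center_prediction(p, 30L)$score, 0.9)
  # then longest, then smallest start
  p <- prediction_table(rep("f", 3), c(10L, 0L, 5L), c(40L, 60L, 65L),
                        rep("+", 3), score = 0.5)
  sel <- select_center_prediction(p, 30L)
  expect_identical(sel$start, 0L)
  expect_identical(sel$end, 60L)
  expect_error(select_center_prediction(
    prediction_table(c("f", "g"), c(0L, 0L), c(9L, 9L), c("+", "+")), 5L),
    "multiple fragments")
})

test_that("center selection is none exactly when no interval covers the center", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample.int(6L, 1L)
    start <- sample(0:80, n, replace = TRUE)
    end <- start + sample.int(40L, n, replace = TRUE)
    p <- prediction_table(rep("f", n), start, end,
                          sample(c("+", "-"), n, replace = TRUE),
                          score = runif(n))
    center <- sample(0:100, 1L)
    sel <- select_center_prediction(p, center)
    covered <- any(start <= center & center < end)
    expect_identical(is.null(sel), !covered)
    if (covered)
      expect_true(sel$start <= center && center < sel$end)
  }
})

test_that("frames at the center follow the modulo conventions and reported indels", {
  p <- prediction_table("f", 10L, 99L, "+")
  expect_identical(predicted_frame_at_center(p, 37L), "F1")
  expect_identical(predicted_frame_at_center(NULL, 37L), "NC")
  # a reported insertion between start and center shifts the phase by -1
  pi <- prediction_table("f", 10L, 99L, "+", indels = "20:i")
  expect_identical(predicted_frame_at_center(pi, 37L), "F3")
  pd <- prediction_table("f", 10L, 99L, "+", indels = "20:d")
  expect_identical(predicted_frame_at_center(pd, 37L), "F2")
  expect_identical(predicted_frame_at_center(pi, 37L,
                                             use_reported_indels = FALSE),
                   "F1")
  # reverse prediction counts indels between center and end - 1
  pr <- prediction_table("f", 10L, 99L, "-", indels = "50:i")
  expect_identical(predicted_frame_at_center(pr, 37L),
                   adjust_predicted_frame(
                     predicted_frame_at_center(
                       prediction_table("f", 10L, 99L, "-"), 37L),
                     c(ins = 2L, del = 0L)))
  expect_error(predicted_frame_at_center(p, 5L), "outside")
})

test_that("the frame is invariant to trimming the non-center end by codons", {
  for (strand in c("+", "-")) {
    p0 <- prediction_table("f", 12L, 96L, strand)
    f0 <- predicted_frame_at_center(p0, 40L)
    for (k in 1:5) {
      p <- if (strand == "+")
        prediction_table("f", 12L, 96L - 3L * k, strand)
      else prediction_table("f", 12L + 3L * k, 96L, strand)
      expect_identical(predicted_frame_at_center(p, 40L), f0)
    }
  }
})
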