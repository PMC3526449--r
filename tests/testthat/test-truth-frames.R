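test_that("the center index follows the floor(L/2) convention", {
  expect_identical(center_index(75), 37L)
  expect_identical(center_index(1), 0L)
  expect_identical(center_index(1000), 500L)
  expect_error(center_index(0), "positive")
})

test_that("read-to-template mapping shifts by the hand-replayed indel tally", {
  g <- fix_small_genome()
  # error-free: identity mapping
  f <- manual_fragment(g, 100L, 120L)
  m <- map_read_to_template(f, 10L)
  expect_identical(m$template_pos, 110L)
  expect_identical(m$tally, c(ins = 0L, del = 0L))
  # one insertion at read_pos 3 pulls the template coordinate back by one
  f <- manual_fragment(g, 100L, 120L, errors = data.frame(
    read_pos = 3L, kind = "insertion", template_base = "", read_base = "A"))
  m <- map_read_to_template(f, 10L)
  expect_identical(m$template_pos, 109L)
  expect_identical(m$tally, c(ins = 1L, del = 0L))
  # one deletion at read_pos 3 pushes it forward by one
  del_base <- substr(g$sequence, 104L, 104L)   # template pos 103, 0-based
  f <- manual_fragment(g, 100L, 120L, errors = data.frame(
    read_pos = 3L, kind = "deletion", template_base = del_base,
    read_base = ""))
  m <- map_read_to_template(f, 10L)
  expect_identical(m$template_pos, 111L)
  expect_identical(m$tally, c(ins = 0L, del = 1L))
  # querying an inserted base flags a gap and uses the base to its left
  f <- manual_fragment(g, 100L, 120L, errors = data.frame(
    read_pos = 10L, kind = "insertion", template_base = "", read_base = "C"))
  m <- map_read_to_template(f, 10L)
  expect_true(m$gap)
  expect_identical(m$template_pos, 109L)
  expect_error(map_read_to_template(f, 21L), "out of range")
})

test_that("center labels follow gene phase and read orientation", {
  seq <- paste(rep("ACGT", 100), collapse = "")      # 400 bp
  g <- annotated_genome("toy", seq,
                        data.frame(start = 100L, end = 199L, strand = "+"))
  # center of a 75 bp read is position 37; template_start 63 puts it at 100
  f <- manual_fragment(g, 63L, 138L, "+")
  expect_identical(annotate_center_label(f, g), "F1")
  f <- manual_fragment(g, 67L, 142L, "+")            # center -> t = 104
  expect_identical(annotate_center_label(f, g), "F2")
  # the same '+' gene seen from a '-' oriented read is a reverse label
  f <- manual_fragment(g, 63L, 138L, "-")            # center -> t = 100
  expect_identical(substr(annotate_center_label(f, g), 1, 1), "R")
  # intergenic center
  f <- manual_fragment(g, 0L, 75L, "+")
  expect_identical(annotate_center_label(f, g), "NC")
  # provenance check
  g2 <- annotated_genome("other", seq, g$genes)
  expect_error(annotate_center_label(f, g2), "provenance")
})

test_that("reverse-strand genes anchor phase at their rightmost template base", {
  seq <- paste(rep("ACGT", 100), collapse = "")
  g <- annotated_genome("toy", seq,
                        data.frame(start = 100L, end = 199L, strand = "-"))
  f <- manual_fragment(g, 161L, 236L, "+")           # center -> t = 198 = end-1
  expect_identical(annotate_center_label(f, g), "R1")
  f <- manual_fragment(g, 160L, 235L, "+")           # center -> t = 197
  expect_identical(annotate_center_label(f, g), "R2")
})

test_that("frame adjustment follows the cumulative indel shift and is periodic", {
  expect_identical(adjust_predicted_frame("F2", c(ins = 0L, del = 0L)), "F2")
  expect_identical(adjust_predicted_frame("F2", c(ins = 1L, del = 0L)), "F1")
  expect_identical(adjust_predicted_frame("F1", c(ins = 0L, del = 1L)), "F2")
  expect_identical(adjust_predicted_frame("R1", c(ins = 1L, del = 0L)), "R2")
  expect_identical(adjust_predicted_frame("NC", c(ins = 5L, del = 2L)), "NC")
  # shift periodicity: tallies differing by 3 in either component agree
  for (lab in frame_labels())
    for (a in 0:2) for (b in 0:2) {
      expect_identical(adjust_predicted_frame(lab, c(ins = a, del = b)),
                       adjust_predicted_frame(lab, c(ins = a + 3L, del = b)))
      expect_identical(adjust_predicted_frame(lab, c(ins = a, del = b)),
                       adjust_predicted_frame(lab, c(ins = a, del = b + 3L)))
    }
  expect_error(adjust_predicted_frame("F4", c(ins = 0L, del = 0L)),
               "invalid")
})

test_that("labels stay within the seven-label alphabet on randomized data", {
  g <- fix_small_genome()
  fr <- inject_errors(sample_fragments(g, 150, 90, seed = 21),
                      error_preset("indel_28"), seed = 22)
  tt <- truth_labels(fr, g)
  expect_true(all(tt$label %in% frame_labels()))
  adj <- adjust_predicted_frame(tt$label,
                                cbind(ins = tt$ins_before,
                                      del = tt$del_before))
  expect_true(all(adj %in% frame_labels()))
})

test_that("on error-free fragments adjustment is the identity and the oracle's raw frame equals the truth", {
  g <- fix_small_genome()
  fr <- sample_fragments(g, 200, 120, seed = 23)
  ev <- evaluate_frames(fr, g, oracle_caller(fr, g))
  expect_identical(ev$pairs$raw_predicted, ev$pairs$predicted)
  expect_identical(ev$pairs$predicted, ev$pairs$true)
})

test_that("oracle predictions match annotated labels exactly even at heavy indel rates", {
  g <- fix_small_genome()
  fr <- inject_errors(sample_fragments(g, 400, 315, seed = 24),
                      error_preset("indel_28"), seed = 25)
  ev <- evaluate_frames(fr, g, oracle_caller(fr, g))
  expect_identical(ev$pairs$predicted, ev$pairs$true)
  m <- frame_metrics(ev)
  expect_equal(m$overall_accuracy, 1.0)
})

test_that("skipping the indel correction degrades oracle accuracy on indel data", {
  g <- fix_small_genome()
  fr <- inject_errors(sample_fragments(g, 400, 315, seed = 26),
                      error_preset("indel_28"), seed = 27)
  pr <- oracle_caller(fr, g)
  acc_naive <- frame_metrics(evaluate_frames(fr, g, pr,
                                             adjust_indels = FALSE))$overall_accuracy
  acc_corr <- frame_metrics(evaluate_frames(fr, g, pr))$overall_accuracy
  expect_equal(acc_corr, 1.0)
  expect_lt(acc_naive, 0.9)
})

test_that("truth tables round-trip through TSV", {
  g <- fix_small_genome()
  fr <- inject_errors(sample_fragments(g, 30, 100, seed = 28),
                      error_preset("indel_05"), seed = 29)
  tt <- truth_labels(fr, g)
  path <- tempfile(fileext = ".tsv")
  write_truth_labels(tt, path)
  tt2 <- read_truth_labels(path)
  expect_equal(tt2, tt)
})
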