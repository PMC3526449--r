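test_that("the confusion matrix tallies pairs into all 49 cells", {
  m <- frame_confusion(character(0), character(0))
  expect_identical(dim(m), c(7L, 7L))
  expect_identical(length(m), 49L)
  expect_true(all(m == 0L))
  m <- frame_confusion(c("F1", "F1", "NC"), c("F1", "F2", "NC"))
  expect_identical(m["F1", "F1"], 1L)
  expect_identical(m["F1", "F2"], 1L)
  expect_identical(m["NC", "NC"], 1L)
  expect_identical(sum(m), 3L)
  expect_error(frame_confusion(c("F1"), c("F1", "F2")), "length")
  expect_error(frame_confusion("F9", "F1"), "invalid")
})

test_that("matrix summaries map cells to TP/TN/FP/FN/WF as defined", {
  lv <- setdiff(frame_labels(), "NC")
  m <- frame_confusion(lv, lv)          # identity diagonal over coding labels
  s <- summary(m)
  expect_identical(c(s$FP, s$FN, s$WF), c(0L, 0L, 0L))
  expect_identical(s$TP, 6L)
  s <- summary(frame_confusion("F1", "F2"))
  expect_identical(s$WF, 1L)
  expect_identical(s$TP + s$TN + s$FP + s$FN, 0L)
  s <- summary(frame_confusion("NC", "F3"))
  expect_identical(s$FP, 1L)
  s <- summary(frame_confusion("R2", "NC"))
  expect_identical(s$FN, 1L)
})

test_that("metric formulas reproduce the hand-computed example", {
  s <- structure(list(TP = 6L, TN = 2L, FP = 1L, FN = 1L, WF = 2L,
                      N_tot = 12L, species_id = "hand"),
                 class = "frame_summary")
  m <- frame_metrics(s)
  expect_equal(m$sensitivity, 6 / 9, tolerance = 1e-12)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$ppv, 6 / 9, tolerance = 1e-12)
  expect_equal(m$overall_accuracy, 8 / 12, tolerance = 1e-12)
})

test_that("degenerate summaries give NA metrics, never coerced values", {
  all_correct <- frame_metrics(frame_confusion(frame_labels(),
                                               frame_labels()))
  expect_equal(all_correct$sensitivity, 1)
  expect_equal(all_correct$specificity, 1)
  expect_equal(all_correct$ppv, 1)
  expect_equal(all_correct$overall_accuracy, 1)
  only_nc <- frame_metrics(frame_confusion("NC", "NC"))
  expect_true(is.na(only_nc$sensitivity))
  expect_equal(only_nc$specificity, 1)
})

test_that("counts are conserved and accuracy decomposes by class incidence", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample.int(200L, 1L)
    tr <- sample(frame_labels(), n, replace = TRUE)
    pr <- sample(frame_labels(), n, replace = TRUE)
    cm <- frame_confusion(tr, pr)
    s <- summary(cm)
    expect_identical(s$TP + s$TN + s$FP + s$FN + s$WF, s$N_tot)
    expect_identical(s$N_tot, n)
    m <- frame_metrics(s)
    P <- s$TP + s$FN + s$WF
    F_ <- s$TN + s$FP
    if (P > 0 && F_ > 0)
      expect_equal(m$overall_accuracy,
                   m$sensitivity * P / s$N_tot + m$specificity * F_ / s$N_tot,
                   tolerance = 1e-12)
  }
})

test_that("turning a correct coding call into a wrong-frame call hurts Sn, PPV and accuracy but not Sp", {
  tr <- c(rep("F1", 10), rep("NC", 5))
  pr <- c(rep("F1", 10), rep("NC", 4), "F2")
  before <- frame_metrics(frame_confusion(tr, pr))
  pr2 <- pr
  pr2[1] <- "F3"                        # one TP becomes WF
  after <- frame_metrics(frame_confusion(tr, pr2))
  expect_lt(after$sensitivity, before$sensitivity)
  expect_lt(after$ppv, before$ppv)
  expect_lt(after$overall_accuracy, before$overall_accuracy)
  expect_equal(after$specificity, before$specificity)
})

test_that("species averaging is equal-weight and ignores fragment counts", {
  mk <- function(tr, pr, id) frame_metrics(frame_confusion(tr, pr, id))
  a <- mk(c(rep("F1", 80), rep("NC", 20)),
          c(rep("F1", 64), rep("F2", 16), rep("NC", 20)), "a")   # Sn 0.8
  b <- mk(c(rep("F1", 6000), rep("NC", 4000)),
          c(rep("F1", 3600), rep("NC", 2400 + 4000)), "b")       # Sn 0.6
  avg <- species_average(list(a, b))
  expect_equal(avg$sensitivity, 0.7, tolerance = 1e-12)
  expect_identical(species_average(list(a))$sensitivity, a$sensitivity)
  expect_error(species_average(list()), "at least one")
})

test_that("duplicating every fragment of one species leaves the average unchanged", {
  g <- fix_small_genome()
  fr_a <- sample_fragments(g, 120, 90, seed = 31)
  g2 <- annotated_genome("sp2", g$sequence, g$genes, species_id = "sp2")
  fr_b <- sample_fragments(g2, 80, 90, seed = 32)
  ev_a <- evaluate_frames(fr_a, g, noisy_caller(fr_a, g, seed = 33))
  ev_b <- evaluate_frames(fr_b, g2, noisy_caller(fr_b, g2, seed = 34))
  rep_a <- frame_metrics(frame_confusion(ev_a$pairs$true, ev_a$pairs$predicted, "a"))
  rep_b <- frame_metrics(frame_confusion(ev_b$pairs$true, ev_b$pairs$predicted, "b"))
  rep_b_dup <- frame_metrics(frame_confusion(rep(ev_b$pairs$true, 2),
                                             rep(ev_b$pairs$predicted, 2), "b"))
  avg1 <- species_average(list(rep_a, rep_b))
  avg2 <- species_average(list(rep_a, rep_b_dup))
  for (f in c("sensitivity", "specificity", "ppv", "overall_accuracy"))
    expect_identical(avg1[[f]], avg2[[f]])
})

test_that("species with undefined metrics are excluded from the mean with a warning", {
  defined <- frame_metrics(frame_confusion(c("F1", "NC"), c("F1", "NC"), "a"))
  no_pos <- frame_metrics(frame_confusion("NC", "NC", "b"))   # Sn undefined
  expect_warning(avg <- species_average(list(defined, no_pos)), "excluded")
  expect_equal(avg$sensitivity, 1)         # only the defined species counts
  expect_equal(avg$specificity, 1)
  expect_identical(attr(avg, "n_species")[["sensitivity"]], 1)
  expect_identical(attr(avg, "n_species")[["specificity"]], 2)
})

test_that("ROC sweeps are monotone and anchored at the default operating point", {
  gc <- all_coding_genome()
  gn <- all_noncoding_genome()
  fc <- sample_fragments(gc, 400, 120, seed = 41)
  fn <- sample_fragments(gn, 400, 120, seed = 42)
  preds <- rbind(noisy_caller(fc, gc, 0.2, 0.05, 0, seed = 43),
                 noisy_caller(fn, gn, 0, 0, 0.4, seed = 44))
  truth <- rbind(truth_labels(fc, gc), truth_labels(fn, gn))
  ev <- evaluate_frames(predictions = preds, truth = truth)
  roc <- roc_curve(ev)
  expect_s3_class(roc, "frame_roc")
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  def <- frame_metrics(ev)
  expect_equal(roc$sensitivity[1L], def$sensitivity)
  expect_equal(roc$specificity[1L], def$specificity)
  # a threshold below every score reproduces the default; above every score
  # everything is predicted noncoding
  ends <- roc_curve(ev, thresholds = c(0, 2))
  expect_equal(ends$sensitivity[1L], def$sensitivity)
  expect_equal(ends$sensitivity[2L], 0)
  expect_equal(ends$specificity[2L], 1)
  # conservation holds along the sweep
  expect_true(all(roc$TP + roc$TN + roc$FP + roc$FN + roc$WF == roc$N_tot))
})

test_that("ROC refuses score-less predictions", {
  g <- all_coding_genome()
  fr <- sample_fragments(g, 10, 90, seed = 45)
  p <- oracle_caller(fr, g)
  p$score <- NA_real_
  ev <- evaluate_frames(fr, g, p)
  expect_error(roc_curve(ev), "no score")
  expect_error(evaluate_frames(fr, g, p, score_threshold = 0.5), "no score")
})

test_that("metric tables and confusion matrices write to TSV", {
  m <- frame_confusion(c("F1", "NC"), c("F1", "F2"))
  path <- tempfile(fileext = ".tsv")
  write_confusion(m, path)
  back <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(dim(back), c(7L, 8L))
  expect_identical(sum(as.matrix(back[, -1])), 2L)
  path2 <- tempfile(fileext = ".tsv")
  write_metrics(frame_metrics(m), path2)
  df <- read.table(path2, sep = "\t", header = TRUE)
  expect_identical(df$N_tot, 2L)
})
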