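# The eight similarity metrics against printed-formula examples and
# brute-force oracles, and the t-distribution CI reporting.

test_that("overlap metrics reproduce the printed-formula examples", {
  d <- c(4L, 4L, 2L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:4] <- TRUE; b[3:6] <- TRUE      # |A| = 4, |B| = 4, |A n B| = 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  a2 <- array(FALSE, d); b2 <- array(FALSE, d)
  a2[1:4] <- TRUE; b2[3:10] <- TRUE   # |A|=4, |B|=8, |AnB|=2
  expect_equal(precision(a2, b2), 0.5)
  expect_equal(recall(a2, b2), 0.25)
  a3 <- array(FALSE, d); b3 <- array(FALSE, d)
  a3[1:3] <- TRUE; b3[1] <- TRUE      # |A|=3, |B|=1
  expect_equal(volumetric_similarity(a3, b3), 0.5)
  # identity and empty-mask conventions
  expect_equal(dsc(a, a), 1)
  e <- array(FALSE, d)
  expect_equal(dsc(e, e), 1)
  expect_equal(dsc(a, e), 0)
  expect_equal(volumetric_similarity(e, e), 1)
  expect_equal(precision(e, b), 0)
  expect_equal(recall(a, e), 0)
})

test_that("hausdorff reproduces the worked 3-point example", {
  d <- c(8L, 8L, 4L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1, 1, 1] <- TRUE
  b[4, 1, 1] <- TRUE                  # distance 3 along x
  b[1, 5, 1] <- TRUE                  # distance 4 along y
  # directed A->B: min(3,4) = 3; directed B->A: max(3,4) = 4 -> HD = 4
  expect_equal(hausdorff(a, b, c(1, 1, 1)), 4)
  expect_equal(hausdorff(a, a, c(1, 1, 1)), 0)
  expect_equal(hausdorff(a, a, c(1, 1, 1), percentile = 95), 0)
  expect_error(hausdorff(a, array(FALSE, d)), "reference mask")
  expect_error(hausdorff(array(FALSE, d), b), "test mask")
})

test_that("assd handles the two-plane fixture and identity", {
  d <- c(6L, 6L, 6L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[, , 2] <- TRUE; b[, , 4] <- TRUE  # parallel planes 2 voxels apart
  expect_equal(assd(a, b, c(1, 1, 1)), 2)
  expect_equal(assd(a, a, c(1, 1, 1)), 0)
})

test_that("all metrics match brute-force oracles on random pairs", {
  set.seed(50)
  for (rep in 1:10) {
    a <- random_mask(c(12L, 12L, 12L), 0.25)
    b <- random_mask(c(12L, 12L, 12L), 0.25)
    sp <- runif(3, 0.5, 1.5)
    o <- brute_overlap(a, b)
    expect_equal(dsc(a, b), o$dsc, tolerance = 1e-12)
    expect_equal(jaccard(a, b), o$jaccard, tolerance = 1e-12)
    expect_equal(precision(a, b), o$precision, tolerance = 1e-12)
    expect_equal(recall(a, b), o$recall, tolerance = 1e-12)
    expect_equal(volumetric_similarity(a, b), o$vs, tolerance = 1e-12)
    bd <- brute_surface_dists(a, b, sp)
    expect_equal(hausdorff(a, b, sp), max(max(bd$dab), max(bd$dba)),
                 tolerance = 1e-9)
    expect_equal(hausdorff(a, b, sp, 95),
                 max(stats::quantile(bd$dab, 0.95, names = FALSE),
                     stats::quantile(bd$dba, 0.95, names = FALSE)),
                 tolerance = 1e-9)
    expect_equal(assd(a, b, sp), mean(c(bd$dab, bd$dba)),
                 tolerance = 1e-9)
    # algebraic identity J = DSC / (2 - DSC)
    expect_equal(jaccard(a, b), dsc(a, b) / (2 - dsc(a, b)),
                 tolerance = 1e-12)
    expect_gte(dsc(a, b), jaccard(a, b))
    expect_equal(volumetric_similarity(a, b), volumetric_similarity(b, a))
  }
})

test_that("distances scale with spacing, overlaps do not", {
  set.seed(51)
  a <- random_mask(c(10L, 10L, 10L), 0.3)
  b <- random_mask(c(10L, 10L, 10L), 0.3)
  s1 <- c(0.6, 0.6, 0.6); s2 <- 2 * s1
  expect_equal(hausdorff(a, b, s2), 2 * hausdorff(a, b, s1))
  expect_equal(hausdorff(a, b, s2, 95), 2 * hausdorff(a, b, s1, 95))
  expect_equal(assd(a, b, s2), 2 * assd(a, b, s1))
  expect_equal(dsc(a, b), dsc(a, b))
  # precision = recall = DSC when |A| == |B|
  bb <- a
  bb[1, 1, 1] <- !bb[1, 1, 1]; bb[10, 10, 10] <- !bb[10, 10, 10]
  if (sum(bb) == sum(a)) {
    expect_equal(precision(a, bb), dsc(a, bb))
    expect_equal(recall(a, bb), dsc(a, bb))
  }
})

test_that("evaluate_subject produces per-group rows with conventions", {
  ph <- generate_phantom(tiny_spec(seed = 52))
  gt <- ph$gt
  rows <- evaluate_subject(gt, gt)
  expect_setequal(unique(rows$group), report_groups())
  overlap <- rows$metric %in% c("dsc", "jaccard", "precision", "recall",
                                "vs")
  expect_true(all(rows$value[overlap] == 1))
  expect_true(all(rows$value[rows$metric %in% c("hd", "hd95", "assd")] == 0))
  # a prediction missing OTL entirely: DSC 0 and distances flagged
  pred <- gt
  pred$data[pred$data == 9L] <- 0L
  rows2 <- evaluate_subject(pred, gt)
  otl <- rows2[rows2$group == "OTL", ]
  expect_equal(otl$value[otl$metric == "dsc"], 0)
  expect_true(all(is.na(otl$value[otl$metric %in% c("hd", "hd95", "assd")])))
  expect_match(otl$note[1], "empty")
  # whole-pathway DSC equals dsc() of the binarized unions
  r <- perturb_reader(gt, reader_perturbation(seed = 3))
  rows3 <- evaluate_subject(r, gt)
  expect_equal(rows3$value[rows3$group == "whole_aVP" &
                             rows3$metric == "dsc"],
               dsc(aggregate_labels(r, "whole_aVP"),
                   aggregate_labels(gt, "whole_aVP")))
  expect_error(evaluate_subject(gt, avp_labelmap(array(0L, c(2, 2, 2)))),
               "shape")
})

test_that("summarize_metric matches an independent t-interval", {
  v <- c(0.8, 0.82, 0.84, 0.86, 0.88)
  s <- summarize_metric(v)
  tt <- stats::t.test(v)               # independent implementation
  expect_equal(s$mean, mean(v), tolerance = 1e-12)
  expect_equal(s$ci_low, tt$conf.int[1], tolerance = 1e-9)
  expect_equal(s$ci_high, tt$conf.int[2], tolerance = 1e-9)
  expect_equal(s$sd, sd(v), tolerance = 1e-12)
  expect_identical(s$n, 5L)
  # constant values collapse the CI onto the mean
  s0 <- summarize_metric(rep(0.7, 4))
  expect_equal(s0$ci_low, 0.7)
  expect_equal(s0$ci_high, 0.7)
  expect_equal(s0$sd, 0)
  # n = 1: mean only, CI flagged undefined
  expect_warning(s1 <- summarize_metric(0.5), "undefined")
  expect_true(is.na(s1$ci_low))
  expect_error(summarize_metric(numeric(0)), "no values")
  # CI width shrinks monotonically with n at fixed SD
  set.seed(55)
  widths <- vapply(c(5, 10, 20, 40), function(n) {
    x <- scale(stats::rnorm(n))[, 1] * 0.05 + 0.8  # exact mean/sd
    s <- summarize_metric(x)
    s$ci_high - s$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("cohort reports use the standard layout and columns", {
  ph1 <- generate_phantom(tiny_spec(seed = 53))
  ph2 <- generate_phantom(tiny_spec(seed = 54))
  preds <- list(a = perturb_reader(ph1$gt, reader_perturbation(seed = 1)),
                b = perturb_reader(ph2$gt, reader_perturbation(seed = 2)))
  gts <- list(a = ph1$gt, b = ph2$gt)
  tmp <- withr::local_tempdir()
  res <- evaluate_cohort(preds, gts,
                         out_prefix = file.path(tmp, "report"))
  expect_identical(names(res$summary),
                   c("structure", "metric", "mean", "ci_low", "ci_high",
                     "sd", "n"))
  csv <- utils::read.csv(file.path(tmp, "report_summary.csv"))
  expect_identical(names(csv),
                   c("structure", "metric", "mean", "ci_low", "ci_high",
                     "sd", "n"))
  subj <- utils::read.csv(file.path(tmp, "report_subjects.csv"))
  expect_setequal(unique(subj$subject_id), c("a", "b"))
  wd <- res$summary[res$summary$structure == "whole_aVP" &
                      res$summary$metric == "dsc", ]
  expect_true(wd$ci_low <= wd$mean && wd$mean <= wd$ci_high)
  expect_identical(wd$n, 2L)
})
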