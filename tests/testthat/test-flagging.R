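fake_rbc <- function(n, mean_d, cv, seed = 1) {
  set.seed(seed)
  data.frame(label = "rbc", cx = runif(n, 0, 900), cy = runif(n, 0, 900),
             diameter_um = rnorm(n, mean_d, mean_d * cv))
}

test_that("morphology flags respond to the size distribution", {
  small <- rbc_morphology_flags(fake_rbc(300, 5.9, 0.10))
  expect_true(small$microcytosis)
  expect_false(small$macrocytosis)
  big <- rbc_morphology_flags(fake_rbc(300, 9.0, 0.10))
  expect_true(big$macrocytosis)
  wide <- rbc_morphology_flags(fake_rbc(300, 7.4, 0.25))
  expect_true(wide$anisocytosis)
  normal <- rbc_morphology_flags(fake_rbc(300, 7.4, 0.10))
  expect_false(normal$microcytosis || normal$macrocytosis ||
                 normal$anisocytosis)
})

test_that("too few red cells gives NA flags with a reason", {
  fl <- rbc_morphology_flags(fake_rbc(50, 5.5, 0.1))
  expect_true(is.na(fl$microcytosis))
  expect_match(fl$reason, "50")
})

test_that("platelet clump flag requires a cluster of minimum size", {
  g <- chamber_geometry(2)
  one <- data.frame(label = "plt", cx = 100, cy = 100, diameter_um = 2.5)
  expect_false(platelet_clump_flag(one, g)$plt_clumps)
  expect_false(platelet_clump_flag(one[0, ], g)$plt_clumps)
  # a tight triplet (within 1.5 diameters) plus scattered singles
  clustered <- data.frame(label = "plt",
                          cx = c(100, 104, 102, 500, 900, 1300) ,
                          cy = c(100, 100, 104, 500, 900, 1300),
                          diameter_um = 2.5)
  expect_true(platelet_clump_flag(clustered, g)$plt_clumps)
  spread <- data.frame(label = "plt", cx = seq(50, 1950, by = 100),
                       cy = seq(50, 1950, by = 100), diameter_um = 2.5)
  expect_false(platelet_clump_flag(spread, g)$plt_clumps)
})

test_that("scattered platelets at default density rarely alarm", {
  p <- std_panel()  # no clump flag
  g <- small_geom2(0.25)
  alarms <- 0
  for (s in 1:8) {
    det <- detect_cells(render_chamber(p, 2, g, seed = 400 + s))
    if (platelet_clump_flag(det, g)$plt_clumps) alarms <- alarms + 1
  }
  expect_equal(alarms, 0)
})

test_that("immature flag counts credible immature detections", {
  none <- data.frame(label = c("neu", "lym"), diameter_um = c(12, 9))
  expect_false(immature_cell_flag(none)$immature_cells)
  one <- rbind(none, data.frame(label = "imm", diameter_um = 15))
  expect_true(immature_cell_flag(one)$immature_cells)
  fragment <- rbind(none, data.frame(label = "imm", diameter_um = 7))
  expect_false(immature_cell_flag(fragment)$immature_cells)
})

test_that("confusion metrics reproduce their defining identities", {
  cm <- confusion_metrics(tp = 17, fp = 0, tn = 433, fn = 0)
  expect_equal(cm$accuracy, 100)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
  expect_equal(cm$kappa, 1)
  expect_equal(cm$balanced_accuracy, 100)

  set.seed(9)
  for (i in 1:20) {
    cts <- rpois(4, c(20, 5, 60, 4)) + 1
    cm <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    n <- sum(cts)
    po <- (cts[1] + cts[3]) / n
    pe <- ((cts[1] + cts[2]) * (cts[1] + cts[4]) +
             (cts[4] + cts[3]) * (cts[2] + cts[3])) / n^2
    expect_equal(cm$kappa, (po - pe) / (1 - pe))
    expect_equal(cm$balanced_accuracy,
                 (cm$sensitivity + cm$specificity) / 2)
    expect_equal(cm$accuracy, 100 * po)
  }
})

test_that("degenerate margins give NA, never a silent 100%", {
  cm <- confusion_metrics(tp = 0, fp = 0, tn = 50, fn = 0)
  expect_true(is.na(cm$sensitivity))
  expect_true(is.na(cm$balanced_accuracy))
  expect_equal(cm$specificity, 100)
})

test_that("kappa is 1 exactly when the off-diagonals vanish and both classes occur", {
  expect_equal(confusion_metrics(10, 0, 30, 0)$kappa, 1)
  expect_lt(confusion_metrics(10, 1, 30, 0)$kappa, 1)
  expect_true(is.na(confusion_metrics(0, 0, 30, 0)$kappa) ||
                confusion_metrics(0, 0, 30, 0)$kappa < 1)
})

test_that("flag concordance builds one matrix per family", {
  pred <- data.frame(microcytosis = c(TRUE, FALSE, TRUE, FALSE),
                     plt_clumps = c(FALSE, FALSE, TRUE, TRUE))
  truth <- data.frame(microcytosis = c(TRUE, FALSE, FALSE, FALSE),
                      plt_clumps = c(FALSE, FALSE, TRUE, FALSE))
  cc <- flag_concordance(pred, truth)
  expect_named(cc, c("microcytosis", "plt_clumps"))
  expect_equal(cc$microcytosis$tp, 1)
  expect_equal(cc$microcytosis$fp, 1)
  expect_error(flag_concordance(pred[1:2, ], truth), "equal length")
})
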