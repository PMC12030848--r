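test_that("confusion tallies are exact and order-invariant", {
  cm <- confusion_counts(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  yt <- c(1, 1, 2, 3, 3, 3); yp <- c(1, 2, 2, 3, 1, 3)
  cm1 <- confusion_counts(yt, yp, 3)
  perm <- c(4, 2, 6, 1, 3, 5)
  cm2 <- confusion_counts(yt[perm], yp[perm], 3)
  expect_identical(unclass(cm1), unclass(cm2))
  expect_equal(sum(cm1), 6)
  expect_true(all(diag(unclass(confusion_counts(yt, yt, 3))) == c(2, 1, 3)))
  expect_error(confusion_counts(c(1, 4), c(1, 1), 3), "outside")
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(matrix(c(50, 0, 0, 50), 2)), 100)
  expect_equal(overall_accuracy(matrix(c(8, 3, 2, 7), 2)), 75)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("average accuracy supports both conventions", {
  d <- diag(c(5, 9, 2))
  expect_equal(average_accuracy(d, "mean_recall"), 100)
  expect_equal(average_accuracy(d, "literal_onevsrest"), 100)

  cm <- matrix(c(5, 0, 1,   1, 4, 0,   0, 2, 7), 3, 3)  # by column
  expect_equal(average_accuracy(cm, "mean_recall"),
               100 * mean(c(5 / 6, 4 / 6, 7 / 8)), tolerance = 1e-12)
  expect_equal(average_accuracy(cm, "literal_onevsrest"),
               100 * mean(c(18 / 20, 17 / 20, 17 / 20)), tolerance = 1e-12)

  bad <- matrix(c(3, 0, 1, 0), 2)
  bad[2, ] <- 0
  expect_error(average_accuracy(bad, "mean_recall"), "class")
})

test_that("the two AA modes coincide exactly on balanced two-class matrices", {
  # for 2 classes the one-vs-rest accuracies of both classes are the OA,
  # so literal AA = OA, while mean recall differs unless classes balance
  set.seed(1)
  for (i in 1:20) {
    cm <- matrix(rpois(4, 10) + 1, 2, 2)
    lit <- average_accuracy(cm, "literal_onevsrest")
    expect_equal(lit, overall_accuracy(cm), tolerance = 1e-12)
    if (sum(cm[1, ]) == sum(cm[2, ])) {
      expect_equal(lit, average_accuracy(cm, "mean_recall"), tolerance = 1e-12)
    }
  }
})

test_that("kappa matches hand arithmetic and degenerate contracts", {
  expect_equal(kappa_coefficient(diag(c(10, 20, 5))), 1)
  expect_equal(kappa_coefficient(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_equal(kappa_coefficient(matrix(c(8, 3, 2, 7), 2)), 0.5,
               tolerance = 1e-12)
  expect_error(kappa_coefficient(matrix(c(4, 0, 0, 0), 2)), "undefined")

  # kappa = 1 iff no off-diagonal mass
  set.seed(2)
  for (i in 1:10) {
    cm <- matrix(rpois(9, 5) + 1, 3, 3)
    expect_lt(kappa_coefficient(cm), 1)
    # invariant under identical row/column permutation
    pr <- sample(3)
    expect_equal(kappa_coefficient(cm[pr, pr]), kappa_coefficient(cm),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with an independent reference on random matrices", {
  skip_if_not_installed("e1071")
  set.seed(3)
  for (i in 1:100) {
    m <- sample(2:6, 1)
    cm <- matrix(rpois(m * m, 6) + 1L, m, m)
    ref <- metrics_ref(cm)
    expect_equal(overall_accuracy(cm), ref$oa, tolerance = 1e-10)
    expect_equal(average_accuracy(cm, "mean_recall"), ref$aa,
                 tolerance = 1e-10)
    expect_equal(kappa_coefficient(cm), ref$kappa, tolerance = 1e-10)
    ca <- e1071::classAgreement(cm)
    expect_equal(overall_accuracy(cm) / 100, ca$diag, tolerance = 1e-10)
    expect_equal(kappa_coefficient(cm), ca$kappa, tolerance = 1e-10)
  }
})

test_that("a majority-class predictor scores the majority fraction", {
  y <- rep(c(1L, 2L, 3L), times = c(60, 30, 10))
  cm <- confusion_counts(y, rep(1L, 100), 3)
  expect_equal(overall_accuracy(cm), 60)
})

test_that("evaluation reports are internally consistent and serialisable", {
  s <- make_toy_samples(seed = 4, n_per_class = 25)
  s <- split_samples(s, 0.6, seed = 5)
  fit <- fit_network(s, small_config(), train_config(max_epochs = 5, seed = 6))
  rep <- evaluate_network(fit, s)
  cm <- rep$confusion
  expect_equal(rep$oa, overall_accuracy(cm))
  expect_equal(rep$aa, average_accuracy(cm))
  expect_equal(rep$kappa, kappa_coefficient(cm))
  expect_equal(sum(cm), sum(s$split == "test"))
  g <- glance(rep)
  expect_named(g, c("oa", "aa", "aa_mode", "kappa", "n"))

  p1 <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rep, p1, "csv")
  back <- utils::read.csv(p1)
  expect_equal(back$accuracy[back$class == "OA"], rep$oa)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep, p2, "json")
  j <- jsonlite::read_json(p2, simplifyVector = TRUE)
  expect_equal(j$kappa, rep$kappa, tolerance = 1e-12)
})
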