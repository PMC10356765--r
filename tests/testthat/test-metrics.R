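# Evaluation statistics against brute-force oracles.

test_that("mre matches its definition and the elementwise oracle", {
  gt1 <- landmarkSet(list(AC = c(0, 0, 0)))
  pr0 <- landmarkSet(list(AC = c(0, 0, 0)), provenance = "predicted")
  expect_equal(mre(pr0, gt1)$mean, 0)
  pr1 <- landmarkSet(list(AC = c(0, 0, 1)), provenance = "predicted")
  pr3 <- landmarkSet(list(AC = c(0, 0, 3)), provenance = "predicted")
  expect_equal(mre(list(pr1, pr3), list(gt1, gt1))$mean, 2)

  set.seed(21)
  gt <- replicate(20, randomLandmarkSet(), simplify = FALSE)
  pred <- lapply(gt, function(g)
    landmarkSet(landmarkCoords(g) + matrix(rnorm(15, 0, 0.8), 5, 3),
                provenance = "predicted"))
  got <- mre(pred, gt)
  expect_lt(abs(mean(oracle_mre(pred, gt)) - mean(got$errors)), 1e-9)
})

test_that("mre counts missing predictions instead of failing", {
  gt <- landmarkSet(list(AC = c(0, 0, 0), SF = c(0, 0, 7)))
  pr <- landmarkSet(list(AC = c(0, 0, 1)), provenance = "predicted")
  m <- mre(pr, gt)
  expect_equal(m$nMissing, 1L)
  expect_equal(m$mean, 1)
  expect_error(mre(landmarkSet(list(MH = c(0, 0, 0))),
                   landmarkSet(list(AC = c(0, 0, 0)))),
               class = "sinusplan_no_pairs")
})

test_that("sdr uses inclusive thresholds with the standard ladder", {
  gt <- replicate(2, landmarkSet(list(AC = c(0, 0, 0))), simplify = FALSE)
  pr <- list(landmarkSet(list(AC = c(0, 0, 1.5)), provenance = "predicted"),
             landmarkSet(list(AC = c(0, 0, 2.5)), provenance = "predicted"))
  s <- sdr(pr, gt)
  expect_identical(names(s), c("2.0mm", "2.5mm", "3.0mm", "3.5mm"))
  expect_equal(as.numeric(s), c(50, 100, 100, 100))
  ## error exactly at the threshold counts as detected
  pr2 <- list(landmarkSet(list(AC = c(0, 0, 2.0)), provenance = "predicted"))
  expect_equal(as.numeric(sdr(pr2, gt[1])[1]), 100)
  ## SDR is non-decreasing in its threshold
  set.seed(9)
  gtr <- replicate(15, randomLandmarkSet(), simplify = FALSE)
  prr <- lapply(gtr, function(g)
    landmarkSet(landmarkCoords(g) + matrix(rnorm(15, 0, 1.5), 5, 3),
                provenance = "predicted"))
  sr <- sdr(prr, gtr, thresholds = seq(0.5, 4, by = 0.5))
  expect_true(all(diff(unname(sr)) >= 0))
})

test_that("mre is invariant to rigid joint translation of both sets", {
  set.seed(2)
  gt <- replicate(5, randomLandmarkSet(), simplify = FALSE)
  pr <- lapply(gt, function(g)
    landmarkSet(landmarkCoords(g) + matrix(rnorm(15, 0, 1), 5, 3),
                provenance = "predicted"))
  shift <- function(ls) landmarkSet(landmarkCoords(ls) + 5, provenance = "predicted")
  expect_equal(mre(lapply(pr, shift), lapply(gt, shift))$mean,
               mre(pr, gt)$mean, tolerance = 1e-12)
})

test_that("class metrics reproduce the printed formulas and the loop oracle", {
  ## TP=9 FN=1 TN=40 FP=3 for class A in a 53-case matrix
  cm <- matrix(0L, 5, 5, dimnames = list(sinusplan:::SURGICAL_CLASSES,
                                         sinusplan:::SURGICAL_CLASSES))
  cm["A", "A"] <- 9; cm["A", "B"] <- 1
  cm["B", "A"] <- 3; cm["B", "B"] <- 40
  met <- classMetrics(cm)
  expect_equal(met$perClass$sensitivity[1], 0.9)
  expect_equal(met$perClass$specificity[1], 40 / 43)
  expect_equal(met$perClass$accuracy[1], 49 / 53)

  diagCm <- diag(c(3L, 4L, 5L, 6L, 7L))
  metD <- classMetrics(diagCm)
  expect_true(all(metD$perClass$accuracy == 1))
  expect_true(all(metD$perClass$sensitivity == 1))
  expect_true(all(metD$perClass$specificity == 1))

  set.seed(33)
  for (r in 1:20) {
    m <- matrix(rpois(25, 4), 5, 5)
    got <- classMetrics(m)$perClass
    want <- oracle_class_metrics(m)
    expect_lt(max(abs(cbind(got$accuracy, got$sensitivity, got$specificity) -
                      want), na.rm = TRUE), 1e-12)
    ## one-vs-rest counts always partition the total
    expect_true(all(got$TP + got$TN + got$FP + got$FN == sum(m)))
  }
})

test_that("confusionMatrix uses the fixed class order with rows as truth", {
  cm <- confusionMatrix(c("A", "B'", "C"), c("A", "C'", "C"))
  expect_identical(rownames(cm), c("A", "B", "B'", "C", "C'"))
  expect_equal(cm["B'", "C'"], 1L)
  expect_equal(sum(cm), 3L)
  expect_error(confusionMatrix("A", "Z"), class = "sinusplan_bad_class")
})

test_that("rocAUC matches the O(n^2) concordance oracle with half-tie credit", {
  ## perfect separation and pure ties
  lab <- rep(c("A", "B"), each = 10)
  sc <- cbind(A = c(rep(0.9, 10), rep(0.1, 10)), B = runif(20))
  expect_equal(unname(rocAUC(sc, lab)$perClass["A"]), 1.0)
  scTie <- cbind(A = rep(0.5, 20), B = rep(0.5, 20))
  expect_equal(unname(rocAUC(scTie, lab)$perClass["A"]), 0.5)

  set.seed(44)
  for (r in 1:50) {
    n <- sample(8:25, 1)
    lab <- sample(sinusplan:::SURGICAL_CLASSES, n, replace = TRUE)
    sc <- matrix(round(runif(n * 5), 2), n, 5,
                 dimnames = list(NULL, sinusplan:::SURGICAL_CLASSES))
    got <- rocAUC(sc, lab)
    for (cl in colnames(sc)) {
      want <- oracle_auc(sc[, cl], lab == cl)
      if (is.na(want)) expect_true(cl %in% got$undefined)
      else expect_lt(abs(got$perClass[cl] - want), 1e-9)
    }
  }
})

test_that("majority vote returns strict majorities and flags ties", {
  expect_identical(as.character(majorityVote(c("B", "B", "C"))), "B")
  expect_identical(as.character(majorityVote(c("A", "A", "A"))), "A")
  out <- majorityVote(list(c("A", "B", "C"), c("A", "A", "B")))
  expect_true(is.na(out[1]))
  expect_identical(attr(out, "adjudicate"), 1L)
  expect_identical(unname(out[2]), "A")
  expect_error(majorityVote(list("A")), class = "sinusplan_bad_votes")
})

test_that("fleiss kappa matches the pairwise-agreement oracle and conventions", {
  ## unanimity
  tab <- ratingTable(matrix(rep(c("A", "B", "C"), each = 3), 3, 3, byrow = TRUE))
  k1 <- fleissKappa(tab)
  expect_equal(unname(k1@overall["kappa"]), 1.0)

  set.seed(55)
  for (r in 1:20) {
    N <- sample(10:40, 1); m <- sample(2:5, 1)
    votes <- matrix(sample(c("A", "B", "B'", "C", "C'"), N * m, replace = TRUE), N, m)
    tab <- ratingTable(votes)
    if (any(colSums(tab) == N * m)) next
    got <- fleissKappa(tab)
    expect_lt(abs(unname(got@overall["kappa"]) - oracle_fleiss(tab)), 1e-9)
    expect_equal(unname(got@overall["z"]),
                 unname(got@overall["kappa"] / got@overall["se"]))
  }

  ## near-zero kappa for independent uniform votes
  set.seed(77)
  votes <- matrix(sample(c("A", "B", "B'", "C", "C'"), 200 * 3, replace = TRUE), 200, 3)
  k0 <- fleissKappa(ratingTable(votes))
  expect_lt(abs(unname(k0@overall["kappa"])), 0.05)

  ## degenerate table flagged
  one <- ratingTable(matrix("A", 5, 3))
  expect_error(fleissKappa(one), class = "sinusplan_degenerate_ratings")
})

test_that("fleiss kappa is invariant to subject permutation", {
  set.seed(88)
  votes <- matrix(sample(c("A", "B", "C"), 30 * 3, replace = TRUE), 30, 3)
  tab <- ratingTable(votes)
  k1 <- fleissKappa(tab)
  k2 <- fleissKappa(tab[sample(nrow(tab)), ])
  expect_equal(k1@overall, k2@overall)
})

test_that("kappa agreement bands follow the conventional scale", {
  expect_identical(kappaBand(0.72), "good")
  expect_identical(kappaBand(c(0.1, 0.3, 0.5, 0.9)),
                   c("poor", "fair", "moderate", "almost perfect"))
})
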