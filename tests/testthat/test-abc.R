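# Modified ABC classification rules.

test_that("classifyRBH matches the published anchors", {
  expect_identical(as.character(classifyRBH(11, FALSE)), "A")
  expect_identical(as.character(classifyRBH(7, TRUE)), "B'")
  expect_identical(as.character(classifyRBH(4, FALSE)), "C")
  expect_identical(as.character(classifyRBH(5, TRUE)), "C'")
  ## the gap intervals are completed as C:(0,5], B:(5,10], A:(10,inf)
  expect_identical(as.character(classifyRBH(9.5, FALSE)), "B")
  expect_identical(as.character(classifyRBH(5.5, FALSE)), "B")
  expect_identical(as.character(classifyRBH(10, FALSE)), "B")
  ## abundant bone ignores the defect flag
  expect_identical(as.character(classifyRBH(12, TRUE)), "A")
  expect_error(classifyRBH(-1), class = "sinusplan_bad_rbh")
  expect_error(classifyRBH(Inf), class = "sinusplan_bad_rbh")
})

test_that("classes carry the recommended procedures verbatim", {
  expect_identical(procedureFor("A"), "Implant placement")
  expect_identical(procedureFor("B"), "Osteotome")
  expect_identical(procedureFor("B'"), "Osteotome + GBR")
  expect_identical(procedureFor("C"), "Lateral wall sinus elevation")
  expect_identical(procedureFor("C'"), "Lateral wall sinus elevation + GBR")
})

test_that("assessDefect applies the width and step thresholds", {
  mk <- function(width, step)
    landmarkSet(list(AC = c(10, 10, 8), SF = c(10, 10, 15),
                     MH = c(10 - width / 2, 10, 8), LH = c(10 + width / 2, 10, 8),
                     CEJ = c(10, 10, 8 - step)))
  d1 <- assessDefect(mk(8, 0))
  expect_false(as.logical(d1)); expect_identical(attr(d1, "kind"), "none")
  d2 <- assessDefect(mk(4, 1))
  expect_true(as.logical(d2)); expect_identical(attr(d2, "kind"), "horizontal")
  d3 <- assessDefect(mk(8, 5))
  expect_identical(attr(d3, "kind"), "vertical")
  d4 <- assessDefect(mk(4, 5))
  expect_identical(attr(d4, "kind"), "combined")
  expect_error(assessDefect(landmarkSet(list(AC = c(0, 0, 0)))),
               class = "sinusplan_missing_landmark")
})

test_that("plan_from_landmarks composes RBH and defect rules", {
  mk <- function(rbh, width, step)
    landmarkSet(list(AC = c(10, 10, 8), SF = c(10, 10, 8 + rbh),
                     MH = c(10 - width / 2, 10, 8), LH = c(10 + width / 2, 10, 8),
                     CEJ = c(10, 10, 8 - step)))
  expect_identical(planFromLandmarks(mk(12, 8, 0))$class, "A")
  expect_identical(planFromLandmarks(mk(4.5, 4, 0))$class, "C'")
  p <- planFromLandmarks(mk(7, 8, 0))
  expect_identical(p$class, "B")
  expect_equal(p$rbh_mm, 7)
  expect_equal(unname(priorValues(p$priors)), c(7, 8, 0))
})

test_that("exhaustive grid matches the hand-written lookup oracle exactly", {
  for (rbh in seq(0.5, 15, by = 0.5)) for (defect in c(TRUE, FALSE)) {
    got <- as.character(classifyRBH(rbh, defect))
    want <- oracle_abc(rbh, defect)
    expect_identical(got, want)
    expect_identical(procedureFor(got), unname(oracle_procedures[want]))
  }
})

test_that("class sequence along RBH is monotone with change points at 5 and 10", {
  for (defect in c(TRUE, FALSE)) {
    rbh <- (1:300) / 20   # exact binary fractions, boundaries land on 5 and 10
    cls <- as.character(classifyRBH(rbh, defect))
    base <- substr(cls, 1, 1)
    changes <- which(base[-1] != base[-length(base)])
    expect_length(changes, 2L)
    expect_equal(rbh[changes], c(5, 10))
    expect_identical(unique(base), c("C", "B", "A"))
  }
})

test_that("vertical RBH mode uses only the z component", {
  lm <- landmarkSet(list(AC = c(10, 10, 8), SF = c(13, 10, 12),
                         MH = c(6, 10, 8), LH = c(14, 10, 8),
                         CEJ = c(10, 10, 8)))
  eu <- planFromLandmarks(lm)                      # |AC-SF| = 5
  vt <- planFromLandmarks(lm, rbhMode = "vertical") # z gap = 4
  expect_equal(eu$rbh_mm, 5)
  expect_equal(vt$rbh_mm, 4)
})
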