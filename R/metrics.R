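## Evaluation statistics: mean radial error (MRE), successful detection rate
## (SDR), confusion matrix with per-class accuracy/sensitivity/specificity,
## one-vs-rest ROC AUC, majority-vote ground truth, and Fleiss kappa.

.pair_errors <- function(pred, gt) {
  if (is(pred, "LandmarkSet")) pred <- list(pred)
  if (is(gt, "LandmarkSet")) gt <- list(gt)
  if (length(pred) != length(gt))
    .err("pred and gt must contain the same number of landmark sets",
         "sinusplan_bad_pairing")
  errs <- list(); missing <- 0L
  for (i in seq_along(gt)) {
    gcc <- gt[[i]]@coords; pcc <- pred[[i]]@coords
    for (nm in rownames(gcc)) {
      if (nm %in% rownames(pcc)) {
        errs[[length(errs) + 1L]] <-
          c(name = nm, err = sqrt(sum((pcc[nm, ] - gcc[nm, ])^2)))
      } else missing <- missing + 1L
    }
  }
  if (!length(errs)) .err("no matched landmark pairs", "sinusplan_no_pairs")
  df <- data.frame(name = vapply(errs, `[[`, "", 1L),
                   err = as.numeric(vapply(errs, `[[`, "", 2L)))
  attr(df, "missing") <- missing
  df
}

#' Mean radial error of landmark predictions
#'
#' The radial error of one landmark is the Euclidean world-mm distance
#' between the predicted point and the ground-truth point; the MRE is its
#' mean.  Missing predictions are excluded from the mean and counted.
#'
#' @param pred,gt matched [LandmarkSet-class] objects or lists thereof
#'   (element i of `pred` is compared with element i of `gt`).
#' @return List with `perLandmark` (named mean error per landmark name, mm),
#'   `mean` (mm, mean over per-landmark means), `errors` (all radial errors)
#'   and `nMissing`.
#' @examples
#' gt <- landmarkSet(list(AC = c(0, 0, 0)))
#' pr <- landmarkSet(list(AC = c(0, 0, 2)), provenance = "predicted")
#' mre(pr, gt)$mean  # 2
#' @export
mre <- function(pred, gt) {
  df <- .pair_errors(pred, gt)
  per <- tapply(df$err, df$name, mean)
  per <- per[intersect(LANDMARK_NAMES, names(per))]
  list(perLandmark = per, mean = mean(per), errors = df$err,
       nMissing = attr(df, "missing"))
}

#' Successful detection rate of landmark predictions
#'
#' Percentage of predictions whose radial error is within each threshold
#' (inclusive: error <= threshold).
#'
#' @inheritParams mre
#' @param thresholds distance thresholds in mm; the default is the
#'   conventional 2.0, 2.5, 3.0, 3.5 mm ladder.
#' @return Named numeric vector of percentages, one per threshold, with the
#'   per-landmark breakdown in attribute `"perLandmark"`.
#' @export
sdr <- function(pred, gt, thresholds = c(2.0, 2.5, 3.0, 3.5)) {
  if (any(thresholds <= 0)) .err("thresholds must be > 0", "sinusplan_bad_threshold")
  df <- .pair_errors(pred, gt)
  out <- vapply(thresholds, function(t) 100 * mean(df$err <= t), 0)
  names(out) <- sprintf("%.1fmm", thresholds)
  per <- sapply(thresholds, function(t)
    tapply(df$err <= t, df$name, function(z) 100 * mean(z)))
  attr(out, "perLandmark") <- per
  out
}

#' Build a 5x5 confusion matrix in the fixed class order
#'
#' @param true,predicted character vectors of classes in `{A, B, B', C, C'}`.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusionMatrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    .err("true and predicted must have equal length", "sinusplan_bad_pairing")
  bad <- setdiff(unique(c(true, predicted)), SURGICAL_CLASSES)
  if (length(bad)) .err(paste0("unknown class label(s): ", paste(bad, collapse = ", ")),
                        "sinusplan_bad_class")
  t <- factor(true, levels = SURGICAL_CLASSES)
  p <- factor(predicted, levels = SURGICAL_CLASSES)
  unclass(table(true = t, predicted = p))
}

#' Per-class accuracy, sensitivity and specificity from a confusion matrix
#'
#' One-vs-rest counts are derived per class from the 5x5 matrix and the
#' standard formulas applied: ACC = (TP+TN)/(TP+TN+FP+FN),
#' Sens = TP/(TP+FN), Spec = TN/(FP+TN).  Macro means are the unweighted
#' means over the five classes.
#'
#' @param cm confusion matrix from [confusionMatrix()] (rows true, columns
#'   predicted, fixed class order).
#' @return List with `perClass` (data.frame of TP/TN/FP/FN, accuracy,
#'   sensitivity, specificity per class) and `macro` (named means).
#' @export
classMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(5L, 5L))) .err("expected a 5x5 confusion matrix",
                                       "sinusplan_bad_matrix")
  if (sum(cm) == 0) .err("empty confusion matrix", "sinusplan_bad_matrix")
  total <- sum(cm)
  per <- do.call(rbind, lapply(seq_len(5L), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = SURGICAL_CLASSES[i], TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = (tp + tn) / total,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
  }))
  macro <- c(accuracy = mean(per$accuracy),
             sensitivity = mean(per$sensitivity, na.rm = TRUE),
             specificity = mean(per$specificity, na.rm = TRUE))
  list(perClass = per, macro = macro)
}

## Rank-based AUC: equals the trapezoidal area under the ROC curve and the
## pairwise concordance probability with ties counted 1/2.
.auc_rank <- function(score, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest ROC AUC per surgical class
#'
#' For each class, the class-probability column is scored against the
#' binary indicator "true class == this class"; ties contribute 1/2
#' concordance.  Classes absent from the labels get `NA` and are flagged.
#'
#' @param scores numeric matrix, one row per case, columns named by class
#'   (probabilities or arbitrary monotone scores).
#' @param labels character vector of true classes.
#' @return List with `perClass` (named AUCs), `macro` (mean over defined
#'   classes) and `undefined` (classes absent from the labels).
#' @export
rocAUC <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- SURGICAL_CLASSES[seq_len(ncol(scores))]
  if (nrow(scores) != length(labels))
    .err("one score row per label required", "sinusplan_bad_pairing")
  per <- vapply(colnames(scores), function(cl)
    .auc_rank(scores[, cl], labels == cl), 0)
  undef <- names(per)[is.na(per)]
  list(perClass = per, macro = mean(per, na.rm = TRUE), undefined = undef)
}

#' Majority-vote ground truth from rater class votes
#'
#' Returns the strict-majority class per case; cases without a strict
#' majority (for example a 1/1/1 three-way split) are flagged for
#' adjudication (`NA` with the case listed in attribute `"adjudicate"`),
#' never silently resolved.
#'
#' @param votes a character vector of votes for one case, or a list of such
#'   vectors (one per case).
#' @return Character vector of classes (`NA` where adjudication is needed)
#'   with attribute `"adjudicate"` giving the indices of flagged cases.
#' @examples
#' majorityVote(c("B", "B", "C"))  # "B"
#' @export
majorityVote <- function(votes) {
  if (!is.list(votes)) votes <- list(votes)
  out <- vapply(votes, function(v) {
    if (length(v) < 2L) .err("at least two votes per case required",
                             "sinusplan_bad_votes")
    tab <- table(v)
    top <- max(tab)
    if (sum(tab == top) == 1L && 2L * top > length(v))
      names(tab)[which.max(tab)] else NA_character_
  }, "")
  attr(out, "adjudicate") <- which(is.na(out))
  out
}

#' KappaResult: Fleiss kappa agreement statistics
#'
#' @slot perCategory data.frame with per-category kappa, standard error,
#'   Z statistic, two-sided p value and agreement band.
#' @slot overall named numeric: kappa, se, z, p for the overall statistic.
#' @slot band character(1), agreement band of the overall kappa.
#' @slot m integer(1), raters per subject.
#' @slot nSubjects integer(1).
#' @exportClass KappaResult
setClass("KappaResult",
  representation(perCategory = "data.frame", overall = "numeric",
                 band = "character", m = "integer", nSubjects = "integer"))

setMethod("show", "KappaResult", function(object) {
  cat(sprintf("Fleiss kappa, %d subjects x %d raters\n",
              object@nSubjects, object@m))
  print(transform(object@perCategory,
                  kappa = round(kappa, 4), se = round(se, 4),
                  z = round(z, 2), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("Overall kappa %.4f (SE %.4f, Z %.2f, p %.3g) - %s agreement\n",
              object@overall["kappa"], object@overall["se"],
              object@overall["z"], object@overall["p"], object@band))
})

#' Agreement band of a kappa value
#'
#' The conventional verbal scale: poor (0-0.2), fair (0.21-0.4), moderate
#' (0.41-0.6), good (0.61-0.8), almost perfect (0.81-1.0).
#'
#' @param kappa numeric kappa value(s).
#' @return Character vector of band labels.
#' @examples
#' kappaBand(0.72)  # "good"
#' @export
kappaBand <- function(kappa) {
  vapply(kappa, function(k) {
    if (!is.finite(k)) return(NA_character_)
    if (k <= 0.2) "poor" else if (k <= 0.4) "fair" else if (k <= 0.6) "moderate"
    else if (k <= 0.8) "good" else "almost perfect"
  }, "")
}

#' Fleiss kappa for multiple raters
#'
#' Chance-corrected agreement for `m` raters assigning each of `N` subjects
#' to one of `k` categories: overall kappa is
#' \eqn{(\bar P - \bar P_e)/(1 - \bar P_e)} with the large-sample standard
#' error under the null of chance agreement; per-category kappas use the
#' standard single-category decomposition.  Z = kappa/SE with a two-sided
#' normal p value.
#'
#' @param table integer matrix, subjects x categories, entry = number of
#'   raters who assigned that subject to that category.  Every row must sum
#'   to the same number of raters `m >= 2`.  A vote matrix from
#'   rater-by-subject labels can be built with [ratingTable()].
#' @return A [KappaResult-class].
#' @export
fleissKappa <- function(table) {
  tab <- as.matrix(table)
  m <- sum(tab[1L, ])
  if (m < 2L || any(rowSums(tab) != m))
    .err("every subject must have the same number (>= 2) of raters",
         "sinusplan_bad_ratings")
  N <- nrow(tab); k <- ncol(tab)
  pj <- colSums(tab) / (N * m)
  if (any(pj >= 1 - 1e-12))
    .err("degenerate rating table: all votes in one category, kappa undefined",
         "sinusplan_degenerate_ratings")
  Pi <- (rowSums(tab^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  kap <- (Pbar - Pe) / (1 - Pe)
  ## large-sample SE under the null (Fleiss 1971)
  se <- sqrt(2 / (N * m * (m - 1))) *
    sqrt(Pe - (2 * m - 3) * Pe^2 + 2 * (m - 2) * sum(pj^3)) / (1 - Pe)
  z <- kap / se
  p <- 2 * stats::pnorm(-abs(z))
  qj <- 1 - pj
  kj <- 1 - colSums(tab * (m - tab)) / (N * m * (m - 1) * pj * qj)
  sej <- rep(sqrt(2 / (N * m * (m - 1))), k)
  zj <- kj / sej
  pjval <- 2 * stats::pnorm(-abs(zj))
  cats <- colnames(tab)
  if (is.null(cats)) cats <- as.character(seq_len(k))
  new("KappaResult",
      perCategory = data.frame(category = cats, kappa = unname(kj),
                               se = unname(sej), z = unname(zj),
                               p = unname(pjval), band = kappaBand(kj)),
      overall = c(kappa = kap, se = se, z = z, p = p),
      band = kappaBand(kap), m = as.integer(m), nSubjects = as.integer(N))
}

#' Build a subjects-by-categories rating table from rater labels
#'
#' @param labels matrix or data.frame, subjects in rows and raters in
#'   columns, entries are category labels.
#' @param categories category order; defaults to the surgical classes when
#'   all labels are classes, otherwise the sorted unique labels.
#' @return Integer matrix of vote counts suitable for [fleissKappa()].
#' @export
ratingTable <- function(labels, categories = NULL) {
  labels <- as.matrix(labels)
  if (is.null(categories)) {
    u <- unique(as.vector(labels))
    categories <- if (all(u %in% SURGICAL_CLASSES)) SURGICAL_CLASSES else sort(u)
  }
  t(apply(labels, 1L, function(r) table(factor(r, levels = categories))))
}
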