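# Independent brute-force oracles used across the suite.  These are written
# as plain elementwise loops or O(n^2) enumerations, deliberately sharing no
# code with the package implementations they check.

oracle_ce <- function(H, P, eps = 1e-7) {
  H <- as.numeric(H); P <- as.numeric(P)
  tot <- 0
  for (i in seq_along(H)) {
    p <- min(max(P[i], eps), 1 - eps)
    tot <- tot + H[i] * log(p) + (1 - H[i]) * log(1 - p)
  }
  -tot / length(H)
}

oracle_mre <- function(pred, gt) {
  errs <- c()
  for (i in seq_along(gt)) {
    g <- landmarkCoords(gt[[i]]); p <- landmarkCoords(pred[[i]])
    for (nm in rownames(g)) if (nm %in% rownames(p)) {
      d <- 0
      for (ax in 1:3) d <- d + (p[nm, ax] - g[nm, ax])^2
      errs <- c(errs, sqrt(d))
    }
  }
  errs
}

oracle_auc <- function(score, positive) {
  pos <- which(positive); neg <- which(!positive)
  if (!length(pos) || !length(neg)) return(NA_real_)
  conc <- 0
  for (i in pos) for (j in neg) {
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / (length(pos) * length(neg))
}

oracle_class_metrics <- function(cm) {
  k <- nrow(cm); total <- sum(cm)
  out <- matrix(NA_real_, k, 3, dimnames = list(rownames(cm),
                c("accuracy", "sensitivity", "specificity")))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- 0; for (j in seq_len(k)) if (j != i) fn <- fn + cm[i, j]
    fp <- 0; for (j in seq_len(k)) if (j != i) fp <- fp + cm[j, i]
    tn <- total - tp - fn - fp
    out[i, "accuracy"] <- (tp + tn) / (tp + tn + fp + fn)
    out[i, "sensitivity"] <- if (tp + fn > 0) tp / (tp + fn) else NA
    out[i, "specificity"] <- if (fp + tn > 0) tn / (fp + tn) else NA
  }
  out
}

# Fleiss kappa by explicit pairwise agreement counting: P_i is the fraction
# of agreeing rater pairs on subject i, chance agreement from category
# marginals.
oracle_fleiss <- function(tab) {
  N <- nrow(tab); m <- sum(tab[1, ])
  Pi <- numeric(N)
  for (i in seq_len(N)) {
    agree <- 0
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij >= 2) agree <- agree + choose(nij, 2)
    }
    Pi[i] <- agree / choose(m, 2)
  }
  pj <- colSums(tab) / (N * m)
  Pbar <- mean(Pi); Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

# Table-1 lookup oracle for the modified ABC classification.
oracle_abc <- function(rbh, defect) {
  if (rbh > 10) return("A")
  if (rbh > 5) return(if (defect) "B'" else "B")
  if (defect) "C'" else "C"
}

oracle_procedures <- c(
  "A"  = "Implant placement",
  "B"  = "Osteotome",
  "B'" = "Osteotome + GBR",
  "C"  = "Lateral wall sinus elevation",
  "C'" = "Lateral wall sinus elevation + GBR")

# Small phantom spec that keeps unit tests fast (32-cubed at 0.8 mm).
tinySpec <- function(rbh = 7, width = 8, step = 0, seed = 1L, noise = 0.03)
  phantomSpec(rbh = rbh, ridgeWidth = width, verticalStep = step,
              spacing = 0.8, shape = 32L, noiseSd = noise, seed = seed)

randomLandmarkSet <- function(lo = 2, hi = 18, provenance = "annotated") {
  landmarkSet(setNames(lapply(1:5, function(i) runif(3, lo, hi)),
                       c("AC", "SF", "MH", "LH", "CEJ")),
              provenance = provenance)
}
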