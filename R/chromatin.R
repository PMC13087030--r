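#' Spike-in normalization factors
#'
#' Brings all samples to the read depth of the sample with the fewest
#' spike-in (e.g. Drosophila-mapped) reads: `factor_s = min(counts) /
#' counts_s`, so the minimum-count sample gets factor 1 and factors lie in
#' (0, 1]. Factors are invariant to a common scaling of all counts.
#'
#' @param counts Named numeric vector (or two-column data frame
#'   `sample`/`count`) of spike-in read counts, all > 0.
#' @return A tibble with columns `sample`, `count`, `factor`.
#' @examples
#' spike_in_factors(c(ctrl = 100000, iaa = 200000))
#' @export
spike_in_factors <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts[[2]], counts[[1]])
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_bad_arg("spike-in counts must be named by sample.")
  }
  bad <- names(counts)[!is.finite(counts) | counts <= 0]
  if (length(bad)) {
    stop_bad_arg(sprintf("spike-in count must be > 0; offending sample(s): %s",
                         paste(bad, collapse = ", ")))
  }
  tibble(sample = names(counts), count = as.numeric(counts),
         factor = min(counts) / as.numeric(counts))
}

#' Classify peaks by relative enrichment change
#'
#' A peak changes if its relative score change versus control,
#' `r = (treat - ctrl) / (ctrl + pseudocount)`, reaches the class threshold
#' in magnitude: 20% for histone marks, 30% for transcription factors (and
#' for H2A.Z in the mitotic/asynchronous 1 h comparisons). The sign of `r`
#' assigns `up` or `down`; otherwise the peak is `stable`.
#'
#' @param score_ctrl,score_treat Non-negative score vectors (aligned).
#' @param mark_class `"histone"` (threshold 0.20) or `"tf"` (0.30).
#' @param pseudocount Added to the denominator (default 0.5).
#' @param threshold Override the class threshold explicitly.
#' @return Factor vector with levels `down`, `stable`, `up`.
#' @examples
#' classify_differential(10, 13, "histone")  # up
#' @export
classify_differential <- function(score_ctrl, score_treat,
                                  mark_class = c("histone", "tf"),
                                  pseudocount = 0.5, threshold = NULL) {
  if (length(mark_class) != 1 || !mark_class %in% c("histone", "tf")) {
    stop_bad_arg("`mark_class` must be \"histone\" or \"tf\".")
  }
  if (length(score_ctrl) != length(score_treat)) {
    stop_bad_arg("control and treatment score vectors must be aligned.")
  }
  if (any(score_ctrl < 0) || any(score_treat < 0)) {
    stop_bad_arg("scores must be non-negative.")
  }
  threshold <- threshold %||% switch(mark_class, histone = 0.20, tf = 0.30)
  r <- (score_treat - score_ctrl) / (score_ctrl + pseudocount)
  cls <- ifelse(abs(r) >= threshold, ifelse(r > 0, "up", "down"), "stable")
  factor(cls, levels = c("down", "stable", "up"))
}

#' Classify nucleosomes by H2A.Z level
#'
#' Rank-based classes: the 3% lowest scores are `No`, the remainder of the
#' first quartile is `Low`, the upper quartile is `High`, and everything in
#' between is `Intermediate`. Ties are broken by stable input order. On 100
#' distinct scores the class sizes are exactly 3 / 22 / 50 / 25.
#'
#' @param scores Per-nucleosome H2A.Z enrichment scores (>= 34 values so all
#'   classes are populated).
#' @return Factor with levels `No`, `Low`, `Intermediate`, `High`.
#' @export
classify_h2az_levels <- function(scores) {
  n <- length(scores)
  if (n == 0) stop_bad_arg("empty score vector.")
  if (n < 34) {
    stop_bad_arg("need >= 34 scores so that every H2A.Z class is non-empty.")
  }
  rk <- rank(scores, ties.method = "first")
  n_no <- max(1L, floor(0.03 * n))
  n_q1 <- floor(0.25 * n)
  n_hi <- floor(0.25 * n)
  cls <- ifelse(rk <= n_no, "No",
         ifelse(rk <= n_q1, "Low",
         ifelse(rk > n - n_hi, "High", "Intermediate")))
  factor(cls, levels = c("No", "Low", "Intermediate", "High"))
}

#' Nucleosome fragility ratio
#'
#' Ratio of enrichment under light micrococcal-nuclease digestion to
#' enrichment under heavy digestion; fragile nucleosomes score high.
#'
#' @param mnlow_score,mnhigh_score Score vectors (aligned).
#' @param pseudocount Optional pseudocount added to the denominator when it
#'   is zero; with `pseudocount = 0` (default) a zero denominator yields
#'   `NA` with a warning rather than an infinite ratio.
#' @return Numeric ratio vector.
#' @export
fragility <- function(mnlow_score, mnhigh_score, pseudocount = 0) {
  if (length(mnlow_score) != length(mnhigh_score)) {
    stop_bad_arg("MNase-low and MNase-high scores must be aligned.")
  }
  den <- mnhigh_score
  zero <- den <= 0
  if (any(zero)) {
    if (pseudocount > 0) {
      den[zero] <- den[zero] + pseudocount
    } else {
      rlang::warn(sprintf("%d nucleosome(s) with zero MNase-high score; fragility set to NA.",
                          sum(zero)))
      den[zero] <- NA_real_
    }
  }
  mnlow_score / den
}

#' Identify peaks rescued by remodeler re-expression
#'
#' For each peak the treatment-induced loss `delta = ctrl - iaa` is computed
#' in the catalytically dead (`cd`) and the wild-type (`wt`) rescue line. A
#' peak is rescued when the loss in the cd line exceeds the wt loss by more
#' than a 10% margin (`delta_cd > margin * delta_wt`) and there is a positive
#' loss to rescue (`delta_cd > 0`): the wt protein restored the signal the cd
#' line could not. With `rule = "results"` an alternative formulation is
#' applied: a peak is rescued when the wt-line IAA signal stays within 10% of
#' its control.
#'
#' @param wt_ctrl,wt_iaa,cd_ctrl,cd_iaa Aligned score vectors per peak.
#' @param margin Multiplicative margin on the wt loss (default 1.1).
#' @param rule `"methods"` (default) or `"results"`; see Details.
#' @return Logical vector, one element per peak.
#' @examples
#' rescued_peaks(wt_ctrl = 10, wt_iaa = 9, cd_ctrl = 10, cd_iaa = 8.8)  # TRUE
#' @export
rescued_peaks <- function(wt_ctrl, wt_iaa, cd_ctrl, cd_iaa, margin = 1.1,
                          rule = c("methods", "results")) {
  rule <- match.arg(rule)
  lens <- lengths(list(wt_ctrl, wt_iaa, cd_ctrl, cd_iaa))
  if (length(unique(lens)) != 1L) {
    stop_bad_arg("the four score vectors must be aligned on the same peaks.")
  }
  if (rule == "methods") {
    delta_wt <- wt_ctrl - wt_iaa
    delta_cd <- cd_ctrl - cd_iaa
    delta_cd > margin * delta_wt & delta_cd > 0
  } else {
    abs(wt_iaa - wt_ctrl) < (margin - 1) * wt_ctrl
  }
}

#' Group peaks by the timepoint at which most signal is lost
#'
#' For a score time series at 0, 2, 4, 6 and 8 h, the loss fraction at time
#' t is `L(t) = 1 - s(t)/s(0)`; the group is the earliest timepoint at which
#' `L >= loss` (default 0.5, i.e. "losing most" of the signal). Peaks never
#' reaching the loss threshold are `stable`.
#'
#' @param scores Numeric matrix or data frame with one column per timepoint
#'   (baseline first), or a numeric vector for a single peak.
#' @param timepoints Labels for the post-baseline columns.
#' @param loss Loss-fraction threshold (default 0.5).
#' @return Factor with levels `2h`, `4h`, `6h`, `8h`, `stable`.
#' @examples
#' turnover_groups(c(10, 4, 3, 2, 1))  # 2h
#' @export
turnover_groups <- function(scores, timepoints = c("2h", "4h", "6h", "8h"),
                            loss = 0.5) {
  m <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
  if (ncol(m) != length(timepoints) + 1L) {
    stop_bad_arg(sprintf("expected %d columns (baseline + %d timepoints).",
                         length(timepoints) + 1L, length(timepoints)))
  }
  if (any(m[, 1] <= 0)) {
    stop_bad_arg("baseline score must be > 0 for every peak.")
  }
  lossfrac <- 1 - m[, -1, drop = FALSE] / m[, 1]
  grp <- apply(lossfrac, 1, function(l) {
    hit <- which(l >= loss)
    if (length(hit)) timepoints[hit[1]] else "stable"
  })
  factor(grp, levels = c(timepoints, "stable"))
}

#' Classify regions by CpG methylation change
#'
#' A region is hypermethylated if the methylation percentage increases by at
#' least `margin` percentage points, hypomethylated if it decreases by at
#' least `margin`, otherwise stable. Boundaries are inclusive.
#'
#' @param pct_ctrl,pct_treat Methylation percentages in `[0, 100]` (aligned).
#' @param margin Margin in percentage points (default 5).
#' @return Factor with levels `hypo`, `stable`, `hyper`.
#' @examples
#' classify_methylation(40, 46)  # hyper
#' @export
classify_methylation <- function(pct_ctrl, pct_treat, margin = 5) {
  if (length(pct_ctrl) != length(pct_treat)) {
    stop_bad_arg("control and treatment percentages must be aligned.")
  }
  all_pct <- c(pct_ctrl, pct_treat)
  if (any(!is.finite(all_pct)) || any(all_pct < 0) || any(all_pct > 100)) {
    stop_bad_arg("methylation percentages must lie in [0, 100].")
  }
  d <- pct_treat - pct_ctrl
  cls <- ifelse(d >= margin, "hyper", ifelse(d <= -margin, "hypo", "stable"))
  factor(cls, levels = c("hypo", "stable", "hyper"))
}

#' Six-cluster k-means on per-row z-scores
#'
#' Standardizes each feature (row) to zero mean and unit variance across
#' samples, drops constant rows with a warning, and partitions the rows by
#' Euclidean k-means with `n_restarts` random starts, keeping the best
#' within-cluster sum of squares. Labels are identifiable only up to
#' permutation; compare partitions, not label values.
#'
#' @param mat Numeric matrix or data frame, features x samples.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed (k-means is seeded and thus deterministic).
#' @param n_restarts Random restarts (default 10).
#' @return A tibble with columns `feature` and `cluster`; dropped constant
#'   rows get `NA` clusters.
#' @export
zscore_cluster <- function(mat, k = 6, seed, n_restarts = 10) {
  seed <- check_seed(seed)
  m <- as.matrix(mat)
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%04d", seq_len(nrow(m)))
  rsd <- apply(m, 1, sd)
  constant <- rsd == 0 | !is.finite(rsd)
  if (any(constant)) {
    rlang::warn(sprintf("dropping %d constant row(s) before clustering.",
                        sum(constant)))
  }
  mv <- m[!constant, , drop = FALSE]
  if (nrow(mv) < k) {
    stop_bad_arg(sprintf("need at least %d variable rows for k = %d clusters.",
                         k, k))
  }
  z <- t(scale(t(mv)))
  km <- withr::with_seed(seed, kmeans(z, centers = k, nstart = n_restarts))
  out <- tibble(feature = rownames(m),
                cluster = rep(NA_integer_, nrow(m)))
  out$cluster[match(rownames(mv), out$feature)] <- as.integer(km$cluster)
  out
}
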