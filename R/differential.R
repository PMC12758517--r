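# Differential expression (Wilcoxon rank-sum) and differential accessibility
# (logistic-regression likelihood-ratio) with detection-fraction and
# fold-change pre-filters, Seurat-style.

# Exact permutation distribution of the group-1 rank sum under ties, via the
# shift algorithm: midranks are doubled to integers and dp[k, s] counts
# subsets of size k with (doubled) rank sum s. Returns the two-sided
# permutation p-value P(|W - mu| >= |w_obs - mu|).
exactRankSumP <- function(values, n1) {
  N <- length(values)
  r2 <- as.integer(round(2 * rank(values, ties.method = "average")))
  wObs <- sum(r2[seq_len(n1)])
  maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, n1 + 1, maxS + 1)
  dp[1, 1] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      shifted <- c(rep(0, r2[i]), dp[k, seq_len(maxS + 1 - r2[i])])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  countsBy <- dp[n1 + 1, ]
  sSupport <- which(countsBy > 0) - 1L
  probs <- countsBy[sSupport + 1L] / choose(N, n1)
  mu <- n1 * sum(r2) / N
  sum(probs[abs(sSupport - mu) >= abs(wObs - mu) - 1e-9])
}

# Normal approximation with tie correction (no continuity correction).
normalRankSumP <- function(values, n1) {
  N <- length(values)
  n2 <- N - n1
  r <- rank(values, ties.method = "average")
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tieTerm)
  if (sig2 <= 0) return(1)
  2 * stats::pnorm(-abs(w - mu) / sqrt(sig2))
}

# Two-sided Wilcoxon rank-sum p-value: exact permutation enumeration (shift
# algorithm, tie-aware) when both groups have <= `exact_limit` observations,
# normal approximation with tie correction otherwise.
rankSumTest <- function(x1, x2, exact_limit = 25) {
  values <- c(x1, x2)
  if (length(unique(values)) == 1) return(1)
  if (length(x1) <= exact_limit && length(x2) <= exact_limit)
    exactRankSumP(values, length(x1))
  else normalRankSumP(values, length(x1))
}

# Detection fractions and log2 fold change of group means. The matrices hold
# log2(x + 1) normalized values; means are taken on the de-logged scale
# (2^v - 1) so the fold change reflects normalized expression, not
# double-logged values.
featureStats <- function(m, g1, g2) {
  delog <- function(x) {
    if (methods::is(x, "sparseMatrix")) { x@x <- 2^x@x - 1; x } else 2^x - 1
  }
  m1 <- m[, g1, drop = FALSE]
  m2 <- m[, g2, drop = FALSE]
  mean1 <- Matrix::rowSums(delog(m1)) / length(g1)
  mean2 <- Matrix::rowSums(delog(m2)) / length(g2)
  list(pct1 = Matrix::rowSums(m1 > 0) / length(g1),
       pct2 = Matrix::rowSums(m2 > 0) / length(g2),
       lfc = log2((mean1 + 1) / (mean2 + 1)))
}

checkGroups <- function(m, group1, group2) {
  if (length(intersect(group1, group2))) stopf("groups must be disjoint")
  if (length(group1) < 2 || length(group2) < 2)
    stopf("each group needs >= 2 cells")
  if (!all(c(group1, group2) %in% colnames(m)))
    stopf("group barcodes absent from the matrix")
}

#' Wilcoxon rank-sum differential expression
#'
#' Features are pre-filtered to `max(pct_1, pct_2) >= min_pct` and
#' `|log2_fc| >= logfc_threshold`, where `log2_fc` is the log2 ratio of group
#' means of the (normalized) values with pseudocount 1 and `pct_*` the
#' detection fractions (value > 0). Surviving features get a two-sided
#' Wilcoxon rank-sum p (exact tie-aware permutation enumeration when both
#' groups have <= 25 cells, normal approximation with tie correction
#' otherwise) and a Bonferroni adjustment whose denominator is the total
#' number of features in the matrix, not the pre-filtered count.
#'
#' @param expr normalized matrix (features x cells), e.g. [normalizeCounts()].
#' @param group1,group2 disjoint barcode vectors (>= 2 cells each).
#' @param min_pct detection-fraction gate (default 0.25).
#' @param logfc_threshold absolute log2 fold-change gate (default 0.25).
#' @return data.frame with feature_id, log2_fc, pct_1, pct_2, p_value,
#'   p_adjusted, direction.
#' @export
wilcoxonDEG <- function(expr, group1, group2, min_pct = 0.25,
                        logfc_threshold = 0.25) {
  m <- if (is(expr, "CountMatrix")) counts(expr) else expr
  checkGroups(m, group1, group2)
  st <- featureStats(m, group1, group2)
  keep <- which(pmax(st$pct1, st$pct2) >= min_pct &
                abs(st$lfc) >= logfc_threshold)
  if (!length(keep))
    return(data.frame(feature_id = character(0), log2_fc = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  sub1 <- as.matrix(m[keep, group1, drop = FALSE])
  sub2 <- as.matrix(m[keep, group2, drop = FALSE])
  p <- vapply(seq_along(keep), function(i)
    rankSumTest(sub1[i, ], sub2[i, ]), numeric(1))
  data.frame(feature_id = rownames(m)[keep],
             log2_fc = st$lfc[keep], pct_1 = st$pct1[keep],
             pct_2 = st$pct2[keep], p_value = p,
             p_adjusted = adjustPvalues(p, "bonferroni", m = nrow(m)),
             direction = ifelse(st$lfc[keep] >= 0, "up_in_1", "up_in_2"),
             stringsAsFactors = FALSE)
}

# Log-likelihood of the 2-parameter logistic model at (b0, b1); used both by
# the LR test bookkeeping and by the brute-force grid oracle in the tests.
logisticLogLik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

#' Likelihood-ratio differential accessibility test
#'
#' Per peak, logistic regression of group membership on normalized
#' accessibility is fit by iteratively reweighted least squares (full model:
#' intercept + accessibility; null model: intercept only); the statistic is
#' `2 (l_full - l_null)` with p from a chi-square on 1 df. The same
#' detection-fraction / fold-change pre-filters and genome-wide Bonferroni
#' denominator as [wilcoxonDEG()] apply. Non-convergence or complete
#' separation are recorded in `convergence_flag` with the best achieved
#' likelihood (separation caps the statistic at the null-deviance bound).
#'
#' @param atac normalized accessibility matrix or [CountMatrix-class]
#'   (raw counts are normalized internally when a CountMatrix is given).
#' @param group1,group2 disjoint barcode vectors.
#' @param min_pct detection gate (default 0.01, the between-sex setting; the
#'   within-cluster setting uses 0.05).
#' @param logfc_threshold log2 fold-change gate (default 0.1; within-cluster
#'   0.25).
#' @return data.frame as [wilcoxonDEG()] plus `statistic`, `convergence_flag`.
#' @export
lrDAP <- function(atac, group1, group2, min_pct = 0.01, logfc_threshold = 0.1) {
  m <- if (is(atac, "CountMatrix")) normalizeCounts(atac) else atac
  checkGroups(m, group1, group2)
  st <- featureStats(m, group1, group2)
  keep <- which(pmax(st$pct1, st$pct2) >= min_pct &
                abs(st$lfc) >= logfc_threshold)
  empty <- data.frame(feature_id = character(0), log2_fc = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), direction = character(0),
                      convergence_flag = character(0), stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  y <- c(rep(1, length(group1)), rep(0, length(group2)))
  sub <- as.matrix(m[keep, c(group1, group2), drop = FALSE])
  res <- lapply(seq_along(keep), function(i) {
    x <- sub[i, ]
    if (stats::sd(x) == 0) return(c(stat = 0, p = 1, flag = "constant"))
    flag <- "ok"
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          flag <<- "separation"
        else if (grepl("did not converge", conditionMessage(w)))
          flag <<- "nonconvergence"
        invokeRestart("muffleWarning")
      })
    if (flag == "ok" && !fit$converged) flag <- "nonconvergence"
    ## complete separation can converge quietly with residual deviance -> 0
    if (flag == "ok" && fit$deviance < 1e-6) flag <- "separation"
    stat <- max(0, fit$null.deviance - fit$deviance)
    # separation: the achievable statistic is bounded by the null deviance
    if (flag == "separation") stat <- min(stat, fit$null.deviance)
    c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      flag = flag)
  })
  stat <- as.numeric(vapply(res, `[[`, "", "stat"))
  p <- as.numeric(vapply(res, `[[`, "", "p"))
  data.frame(feature_id = rownames(m)[keep], log2_fc = st$lfc[keep],
             pct_1 = st$pct1[keep], pct_2 = st$pct2[keep],
             statistic = stat, p_value = p,
             p_adjusted = adjustPvalues(p, "bonferroni", m = nrow(m)),
             direction = ifelse(st$lfc[keep] >= 0, "up_in_1", "up_in_2"),
             convergence_flag = vapply(res, `[[`, "", "flag"),
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment with an explicit denominator
#'
#' Bonferroni: `min(1, p * m)`. BH: step-up procedure with `m` as the number
#' of tests (features not passing the pre-filter still count toward `m`).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"BH"`.
#' @param m denominator; must be >= `length(p)`.
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "BH"), m = length(p)) {
  method <- match.arg(method)
  if (m < length(p)) stopf("denominator m must be >= length(p)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  if (method == "bonferroni") pmin(1, p * m)
  else stats::p.adjust(p, method = "BH", n = m)
}

#' One-vs-rest differential testing across all groups
#'
#' Convenience wrapper looping [wilcoxonDEG()] (or [lrDAP()]) over every group
#' label against all remaining cells.
#'
#' @param mat normalized matrix (features x cells).
#' @param groups named group label per barcode (names = barcodes).
#' @param test `"wilcoxon"` or `"lr"`.
#' @param ... passed to the underlying test.
#' @return data.frame with an extra `group` column.
#' @export
findAllMarkers <- function(mat, groups, test = c("wilcoxon", "lr"), ...) {
  test <- match.arg(test)
  fun <- if (test == "wilcoxon") wilcoxonDEG else lrDAP
  bcs <- names(groups)
  out <- lapply(unique(groups), function(g) {
    res <- fun(mat, bcs[groups == g], bcs[groups != g], ...)
    if (nrow(res)) res$group <- g
    res
  })
  do.call(rbind, out[vapply(out, nrow, 0L) > 0])
}
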