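#' Group summary (mean, SEM, n)
#'
#' Published contrasts are often reported only as mean +/- SEM with a group
#' size; this container carries exactly those three numbers into the
#' summary-statistic t tests.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (`>= 0`).
#' @param n Group size (`>= 2`).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  if (!is.finite(sem) || sem < 0) stop("sem must be a nonnegative number")
  if (!is.numeric(n) || n < 2) stop("n must be an integer >= 2")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Summarize a raw vector as a group summary
#'
#' @param x Numeric vector of length `>= 2`.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations")
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test computed from (mean, SEM, n) per group:
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)`, with Welch-Satterthwaite degrees
#' of freedom using `s_i^2 = n_i * sem_i^2`.  Welch is the default because
#' group sizes and variances typically differ in the contrasts this package
#' serves; set `pooled = TRUE` for the classical Student form.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param pooled Use the pooled-variance Student t instead of Welch.
#' @return A list with elements `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' welch_t_from_summary(group_summary(61.39, 2.76, 4),
#'                      group_summary(31.64, 1.60, 6))
welch_t_from_summary <- function(g1, g2, pooled = FALSE) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  delta <- g1$mean - g2$mean
  if (g1$sem == 0 && g2$sem == 0) {
    p <- if (delta == 0) 1 else 0
    return(list(t = if (delta == 0) 0 else sign(delta) * Inf,
                df = g1$n + g2$n - 2L, p = p))
  }
  if (pooled) {
    s1sq <- g1$n * g1$sem^2; s2sq <- g2$n * g2$sem^2
    df <- g1$n + g2$n - 2L
    sp2 <- ((g1$n - 1) * s1sq + (g2$n - 1) * s2sq) / df
    t <- delta / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    se2 <- g1$sem^2 + g2$sem^2
    t <- delta / sqrt(se2)
    df <- se2^2 / (g1$sem^4 / (g1$n - 1) + g2$sem^4 / (g2$n - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-sample t test from summary statistics
#'
#' `t = (mean - mu0) / sem` on `n - 1` degrees of freedom.
#'
#' @param g A [group_summary()].
#' @param mu0 Null-hypothesis mean.
#' @return A list with elements `t`, `df`, `p` (two-sided).
#' @export
one_sample_t_from_summary <- function(g, mu0) {
  stopifnot(inherits(g, "group_summary"))
  delta <- g$mean - mu0
  df <- g$n - 1L
  if (g$sem == 0) {
    return(list(t = if (delta == 0) 0 else sign(delta) * Inf,
                df = df, p = if (delta == 0) 1 else 0))
  }
  t <- delta / g$sem
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with the usual t-based p value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom),
#' delegated to [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return A list with elements `r`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' One-sided paired bootstrap test for an increase
#'
#' Resamples the paired differences `after - before` with replacement `B`
#' times and reports `p = (1 + #\{bootstrap mean <= 0\}) / (B + 1)` -- the
#' probability, under resampling, that the observed increase is not positive.
#' The `+1` continuity correction keeps p away from exactly 0.  The
#' resampling unit is the paired difference; what constitutes a pair
#' (patient, rarefied data set, ...) is the caller's choice.
#'
#' @param before,after Paired numeric vectors of equal positive length.
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @return One-sided bootstrap p value.
#' @export
paired_bootstrap_increase <- function(before, after, B = 10000L, seed = 1L) {
  if (length(before) != length(after)) stop("before/after must be paired")
  n <- length(before)
  if (n == 0L) stop("need at least one pair")
  if (B < 1L) stop("B must be >= 1")
  d <- after - before
  set.seed(seed)
  idx <- sample.int(n, n * B, replace = TRUE)
  means <- colMeans(matrix(d[idx], nrow = n))
  (1 + sum(means <= 0)) / (B + 1)
}

#' Hellinger transform
#'
#' Square root of relative abundances: element `i` maps to
#' `sqrt(counts_i / sum(counts))`.  The output has unit Euclidean norm, which
#' makes community composition suitable for Euclidean ordination (PCA).
#'
#' @param counts Nonnegative vector with positive sum.
#' @return Transformed vector of the same length.
#' @export
#' @examples
#' hellinger(c(9, 16))  # 0.6 0.8
hellinger <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop("Hellinger transform undefined for an all-zero vector")
  sqrt(counts / total)
}

#' Principal component analysis (column-centered)
#'
#' PCA on a samples-by-features matrix: columns are centered (not scaled),
#' components are the eigenvectors of the sample covariance, and explained
#' variance ratios are non-increasing and sum to at most 1.  Sign convention:
#' each component's largest-magnitude loading is positive, making runs
#' reproducible across platforms.
#'
#' @param m Numeric matrix, rows = samples (`>= 2`), columns = features.
#' @return A list with `components` (loadings, features x components),
#'   `explained_variance_ratios`, `scores` (samples x components), and
#'   `center`.
#' @export
pca_decompose <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("PCA needs at least 2 samples")
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2L, flip, `*`)
  scores <- sweep(fit$x, 2L, flip, `*`)
  total_var <- sum(apply(m, 2L, var))
  ratios <- if (total_var > 0) fit$sdev^2 / total_var else rep(0, length(fit$sdev))
  list(components = rotation,
       explained_variance_ratios = ratios,
       scores = scores,
       center = fit$center)
}

#' Rarefaction-consensus feature selection
#'
#' Combines per-rarefaction feature selections from two classification models
#' (e.g. support vector classification and logistic regression, supplied
#' upstream as arbitrary callables): a feature is kept when both models
#' selected it in at least `min_frac` of the `n_rarefactions` rarefied data
#' sets ("at least half" with the default 0.5; the boundary is inclusive).
#' Adding records can only grow the selected set (monotone).
#'
#' @param records Data frame with columns `rarefaction_id` (integer `>= 1`),
#'   `model_id`, and `feature`; one row per (rarefaction, model, selected
#'   feature).
#' @param n_rarefactions Total number of rarefied data sets considered.
#' @param min_frac Minimum fraction of rarefactions with both-model agreement
#'   (default 0.5).
#' @param models The two admissible model tags; records with any other tag
#'   are an error.
#' @return Sorted character vector of selected features.
#' @export
consensus_select <- function(records, n_rarefactions, min_frac = 0.5,
                             models = c("SVC", "LR")) {
  stopifnot(is.data.frame(records),
            all(c("rarefaction_id", "model_id", "feature") %in% names(records)))
  if (length(models) != 2L) stop("exactly two model tags are required")
  unknown <- setdiff(unique(records$model_id), models)
  if (length(unknown))
    stop("records reference unknown model tags: ",
         paste(unknown, collapse = ", "))
  if (any(records$rarefaction_id < 1L)) stop("rarefaction_id must be >= 1")
  if (nrow(records) == 0L) return(character(0))
  rec <- unique(records[, c("rarefaction_id", "model_id", "feature")])
  # rarefactions in which BOTH models picked the feature
  agree <- stats::aggregate(model_id ~ feature + rarefaction_id, data = rec,
                            FUN = function(m) length(unique(m)))
  agree <- agree[agree$model_id == 2L, , drop = FALSE]
  if (nrow(agree) == 0L) return(character(0))
  n_agree <- table(agree$feature)
  sort(names(n_agree)[as.numeric(n_agree) >= min_frac * n_rarefactions - 1e-9])
}
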