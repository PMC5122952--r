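#' Round half away from zero
#'
#' Percentage reporting uses conventional half-up rounding (87.5 -> 88)
#' rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places. Default 0.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' MANOVA with Pillai's trace
#'
#' Tests whether group mean vectors differ, via [stats::manova()] with the
#' Pillai trace statistic `V = tr(H (H + E)^-1)` and its standard F
#' approximation.
#'
#' @param X Numeric matrix of responses (rows = individuals, columns =
#'   variables, e.g. d13C and d15N).
#' @param groups Group labels, one per row of `X`.
#' @return List of class `manova_result`: `pillai`, `F`, `df1`, `df2`, `p`,
#'   `n`, `n_groups`.
#' @export
pillai_manova <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) <= ncol(X))) {
    stop("each group needs more observations than response variables",
         call. = FALSE)
  }
  fit <- stats::manova(X ~ groups)
  s <- summary(fit, test = "Pillai")$stats
  structure(list(pillai = unname(s[1, "Pillai"]),
                 F = unname(s[1, "approx F"]),
                 df1 = unname(s[1, "num Df"]),
                 df2 = unname(s[1, "den Df"]),
                 p = unname(s[1, "Pr(>F)"]),
                 n = nrow(X), n_groups = nlevels(groups)),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA (Pillai): V = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$pillai, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Kolmogorov-Smirnov check against a fitted Normal
#'
#' One-sample KS test of `x` against `Normal(mean(x), sd(x))`.
#'
#' @param x Numeric vector, length >= 3, non-degenerate.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance input", call. = FALSE)
  k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(k$statistic), p = k$p.value)
}

#' Levene's test for homogeneity of variance
#'
#' Group-mean-centred Levene test (ANOVA on absolute deviations from group
#' means), via [car::leveneTest()].
#'
#' @param x Numeric response vector.
#' @param groups Group labels.
#' @return List with `statistic`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, groups) {
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  lt <- car::leveneTest(x, factor(groups), center = mean)
  list(statistic = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
       p = lt[1, "Pr(>F)"])
}

#' Train the two-class linear discriminant
#'
#' Gaussian class-conditional model with a shared covariance matrix: class
#' mean vectors plus the bias-corrected pooled covariance, with (by default)
#' equal prior weight per class. Posterior class probabilities from
#' [lda_posterior()] are therefore Bayes posteriors under
#' `x | class ~ Normal(mu_class, Sigma)`.
#'
#' @param X Numeric matrix (rows = individuals, columns = tracers).
#' @param labels Class label per row; exactly two classes, each with at least
#'   2 members, and `nrow(X) > 4`.
#' @param priors Prior class probabilities in class-label order (sorted);
#'   default equal.
#' @return Object of class `discriminant_model`: `classes`, `means` (2 x p),
#'   `cov`, `cov_inv`, `priors`, `n`.
#' @export
lda_train <- function(X, labels, priors = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes required", call. = FALSE)
  if (nrow(X) <= 4) stop("need more than 4 training rows", call. = FALSE)
  counts <- table(factor(labels, classes))
  if (any(counts < 2)) stop("each class needs at least 2 members", call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / 2, 2)
  if (abs(sum(priors) - 1) > 1e-8 || any(priors <= 0)) {
    stop("priors must be positive and sum to 1", call. = FALSE)
  }
  means <- t(vapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                    numeric(ncol(X))))
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    (nrow(Xi) - 1) * stats::cov(Xi)
  })) / (nrow(X) - 2)
  cov_inv <- tryCatch(chol2inv(chol(pooled)),
                      error = function(e) stop("singular pooled covariance",
                                               call. = FALSE))
  structure(list(classes = classes, means = means, cov = pooled,
                 cov_inv = cov_inv, priors = stats::setNames(priors, classes),
                 n = nrow(X)),
            class = "discriminant_model")
}

#' Posterior class probabilities from a discriminant model
#'
#' Softmax of the linear discriminant scores
#' `x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log prior_k`, equivalent to
#' Bayes' rule with Gaussian class-conditional densities sharing one
#' covariance.
#'
#' @param model A [lda_train()] model.
#' @param x Numeric vector (one individual) or matrix (rows = individuals).
#' @return Matrix of posterior probabilities, one row per individual, columns
#'   named by class; each row sums to 1.
#' @export
lda_posterior <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  scores <- vapply(seq_along(model$classes), function(k) {
    mu <- model$means[k, ]
    drop(x %*% (model$cov_inv %*% mu)) -
      0.5 * drop(t(mu) %*% model$cov_inv %*% mu) + log(model$priors[k])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  scores <- scores - apply(scores, 1, max)
  p <- exp(scores) / rowSums(exp(scores))
  colnames(p) <- model$classes
  p
}

#' Assignment labels from posterior probabilities
#'
#' An individual is assigned to the class with the highest posterior only
#' when that posterior strictly exceeds the threshold; otherwise it is
#' `"unassigned"`. A posterior of exactly the threshold is not assigned.
#'
#' @param posteriors Matrix (or single row vector) of class posteriors with
#'   class column names; each row must sum to 1 (tolerance 1e-6).
#' @param threshold Assignment probability threshold, default 0.80.
#' @return Character vector of labels.
#' @export
assign_label <- function(posteriors, threshold = 0.80) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1,
                                                     dimnames = list(NULL, names(posteriors)))
  if (any(abs(rowSums(posteriors) - 1) > 1e-6) || any(posteriors < 0)) {
    stop("each posterior row must be non-negative and sum to 1", call. = FALSE)
  }
  apply(posteriors, 1, function(p) {
    k <- which.max(p)
    if (p[k] > threshold) colnames(posteriors)[k] else "unassigned"
  })
}

#' Jackknife (leave-one-out) cross-validation of the discriminant
#'
#' Each individual is removed in turn, the discriminant retrained on the
#' remaining n - 1, and the held-out individual predicted by maximum
#' posterior (no assignment threshold: every held-out individual receives a
#' prediction). Accuracy is the fraction predicted correctly.
#'
#' @inheritParams lda_train
#' @return List with `accuracy`, `predicted`, `actual`, `n_correct`, `n`.
#' @export
jackknife_cv <- function(X, labels, priors = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  predicted <- character(n)
  for (i in seq_len(n)) {
    keep_labels <- labels[-i]
    if (any(table(keep_labels) < 2) || length(unique(keep_labels)) < 2) {
      stop("class collapses when removing individual ", i, call. = FALSE)
    }
    m <- lda_train(X[-i, , drop = FALSE], keep_labels, priors)
    p <- lda_posterior(m, X[i, ])
    predicted[i] <- colnames(p)[which.max(p)]
  }
  list(accuracy = mean(predicted == labels), predicted = predicted,
       actual = labels, n_correct = sum(predicted == labels), n = n)
}

#' Assignment proportions among untracked individuals
#'
#' Counts and integer percentages (half-up rounding, untracked-sample
#' denominator) of untracked individuals assigned coastal, oceanic, or left
#' unassigned.
#'
#' @param labels Assignment label per untracked individual (`"coastal"`,
#'   `"oceanic"` or `"unassigned"`).
#' @param n_tracked Number of satellite-tracked (training) individuals,
#'   carried through for reporting.
#' @param n_untracked Denominator; defaults to `length(labels)` and must
#'   match it.
#' @return List of class `proportion_report`: `n_tracked`, `n_untracked`,
#'   `counts`, `percentages`, `n_assigned`.
#' @export
proportion_report <- function(labels, n_tracked = NA_integer_,
                              n_untracked = length(labels)) {
  if (n_untracked == 0) stop("no untracked individuals", call. = FALSE)
  if (n_untracked != length(labels)) {
    stop("n_untracked must equal the number of labels", call. = FALSE)
  }
  counts <- c(coastal = sum(labels == "coastal"),
              oceanic = sum(labels == "oceanic"),
              unassigned = sum(labels == "unassigned"))
  if (sum(counts) != n_untracked) {
    stop("labels contain values other than coastal/oceanic/unassigned",
         call. = FALSE)
  }
  structure(list(n_tracked = n_tracked, n_untracked = n_untracked,
                 counts = counts,
                 percentages = round_half_up(100 * counts / n_untracked),
                 n_assigned = unname(counts["coastal"] + counts["oceanic"])),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat(sprintf("Assignment of %d untracked individuals (%s tracked in training):\n",
              x$n_untracked, x$n_tracked))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-10s %3d (%d%%)\n", nm, x$counts[[nm]], x$percentages[[nm]]))
  }
  invisible(x)
}

#' Probability that no sampled individual is coastal
#'
#' Under independent sampling from a population with coastal proportion `p`,
#' the chance that none of `n` individuals forages coastally is
#' `(1 - p)^n`. Used to bound the probability that earlier tracking studies
#' would have missed the coastal strategy entirely.
#'
#' @param p_coastal Coastal proportion in `[0, 1]`.
#' @param n Number of independent individuals (>= 0).
#' @return Probability.
#' @export
prob_none_coastal <- function(p_coastal, n) {
  if (any(p_coastal < 0 | p_coastal > 1)) {
    stop("p_coastal must be in [0, 1]", call. = FALSE)
  }
  if (any(n < 0)) stop("n must be non-negative", call. = FALSE)
  (1 - p_coastal)^n
}
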