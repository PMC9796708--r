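#' Weighted degree of every marker in a kinectome
#'
#' s_i = sum_{j != i} |w_ij|: the sum of absolute correlation weights on
#' the edges of node i. With n markers, 0 <= s_i <= n - 1.
#'
#' @param k a [build_kinectome()] object or square weight matrix.
#' @return Named numeric vector, one degree per marker.
#' @export
weighted_degree <- function(k) {
  m <- if (inherits(k, "kinectome")) k$matrix else as.matrix(k)
  a <- abs(m)
  diag(a) <- 0
  s <- rowSums(a)
  names(s) <- rownames(m) %||% (if (inherits(k, "kinectome")) k$labels)
  s
}

#' Permutation comparison of one marker's degree between groups
#'
#' @param degrees_a,degrees_b matrices or data frames of per-subject
#'   degrees (subjects x markers) for the two groups, or plain per-subject
#'   vectors when `marker` is `NULL`.
#' @param marker marker label to compare.
#' @param n_perm,seed see [permutation_compare()].
#' @return A `perm_test` object.
#' @export
compare_degree <- function(degrees_a, degrees_b, marker = NULL,
                           n_perm = 10000, seed = NULL) {
  pick <- function(d) {
    if (is.null(marker)) return(as.numeric(d))
    d <- as.matrix(d)
    if (!marker %in% colnames(d)) stop_kin("marker '", marker, "' not found")
    d[, marker]
  }
  permutation_compare(pick(degrees_a), pick(degrees_b),
                      n_perm = n_perm, seed = seed)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks (midranks for ties) are Pearson-correlated; the p-value
#' uses the standard t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop_kin("x and y must have equal length >= 4")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_kin("constant input: Spearman correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Multilinear prediction of a clinical motor score
#'
#' Ordinary least squares of the motor score on the nodal degree plus the
#' nuisance predictors age, education and gender, with variance inflation
#' factors for multicollinearity and seeded k-fold cross-validation
#' (shuffled folds) producing out-of-fold predictions.
#'
#' @param features data frame with columns `degree`, `age`, `education`,
#'   `gender` (2-level factor or 0/1) and the target column.
#' @param target name of the target column (default `"motor_score"`).
#' @param k number of CV folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @return List of class `clinical_model`: `fit` (the `lm`),
#'   `coefficients` (table with estimate, p-value), `r_squared`
#'   (in-sample), `cv_r_squared` (on pooled out-of-fold predictions),
#'   `cv_predictions`, `cv_residuals`, `vif_per_predictor`, `folds`, `k`,
#'   `seed`, `vif_warning`.
#' @export
fit_clinical_model <- function(features, target = "motor_score", k = 5,
                               seed = NULL) {
  need <- c("degree", "age", "education", "gender", target)
  if (!all(need %in% names(features))) {
    stop_kin("features must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(features[need])) stop_kin("features contain missing values")
  n <- nrow(features)
  if (n < 2 * k) stop_kin("need at least 2k = ", 2 * k, " subjects")
  df <- features
  if (!is.numeric(df$gender)) df$gender <- as.integer(factor(df$gender)) - 1L
  if (length(unique(df$gender)) > 2) stop_kin("gender must be binary")
  fml <- stats::as.formula(paste(target, "~ degree + age + education + gender"))
  fit <- stats::lm(fml, data = df)
  if (any(!is.finite(stats::coef(fit)))) stop_kin("singular design matrix")
  smry <- summary(fit)
  coefs <- data.frame(
    term = rownames(smry$coefficients),
    estimate = smry$coefficients[, "Estimate"],
    p_value = smry$coefficients[, "Pr(>|t|)"],
    row.names = NULL
  )
  vifs <- car::vif(fit)
  vif_warning <- any(vifs > 10)
  if (vif_warning) {
    warning("VIF > 10 for predictor(s): ",
            paste(names(vifs)[vifs > 10], collapse = ", "))
  }
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  preds <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    m <- stats::lm(fml, data = df[!hold, , drop = FALSE])
    preds[hold] <- stats::predict(m, newdata = df[hold, , drop = FALSE])
  }
  y <- df[[target]]
  cv_res <- y - preds
  structure(
    list(
      fit = fit, coefficients = coefs,
      r_squared = smry$r.squared,
      cv_r_squared = 1 - sum(cv_res^2) / sum((y - mean(y))^2),
      cv_predictions = preds, cv_residuals = cv_res,
      vif_per_predictor = vifs, folds = folds, k = k, seed = seed,
      vif_warning = vif_warning
    ),
    class = "clinical_model"
  )
}

#' @export
print.clinical_model <- function(x, ...) {
  cat(
    "<clinical_model> R^2 =", format(x$r_squared, digits = 3),
    " CV R^2 =", format(x$cv_r_squared, digits = 3),
    " (", x$k, "-fold )\n"
  )
  print(x$coefficients)
  invisible(x)
}
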