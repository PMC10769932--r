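# Statistical comparisons: mixed models on sqrt(Jaro) and log(ND) with
# likelihood-ratio tests and Tukey post-hocs, kernel SVM classification
# from similarity profiles, and the nonparametric entropy comparisons.

choose_df_method <- function(df_method, n_obs) {
  if (df_method != "auto") return(df_method)
  # Kenward-Roger is O(n^2) in memory on the marginal covariance; fall
  # back to Satterthwaite on large dyadic datasets.
  if (requireNamespace("pbkrtest", quietly = TRUE) && n_obs <= 20000) {
    "kenward-roger"
  } else "satterthwaite"
}

lrt_report <- function(full, null) {
  a <- anova(null, full)
  list(chisq = a$Chisq[2L], df = a$Df[2L], p_value = a$`Pr(>Chisq)`[2L])
}

posthoc_table <- function(fit, spec, df_method) {
  em <- emmeans::emmeans(fit, spec, lmer.df = df_method)
  as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
}

#' Mixed model on square-root Jaro distances
#'
#' Fits a linear mixed model with response `sqrt(jd)`, the combined
#' distance-type/sex/status factor (up to 9 levels) as the fixed effect,
#' and dyad identity as a random intercept; tests it against the null
#' model holding only the random effect by a likelihood-ratio test, and
#' computes Tukey-adjusted all-pairs contrasts.
#'
#' @param records Dyad dataset from [build_dyad_dataset()].
#' @param posthoc Compute the Tukey contrast table (default `TRUE`).
#' @param df_method Denominator-df method for contrasts:
#'   `"auto"` (Kenward-Roger when available and the dataset is small
#'   enough, otherwise Satterthwaite), `"kenward-roger"`,
#'   `"satterthwaite"`, or `"asymptotic"`.
#' @return Object of class `indri_lmm_report`: list with `model_label`,
#'   `response`, `fixed_levels`, `random`, `chisq`, `df`, `p_value`,
#'   `posthoc` (data frame or `NULL`), `df_method`, `fit`, `null_fit`.
#' @export
fit_distance_lmm <- function(records, posthoc = TRUE, df_method = "auto") {
  records$category_factor <- droplevels(factor(records$category_factor))
  nlev <- nlevels(records$category_factor)
  if (nlev < 2L) stop("category_factor needs >= 2 levels to be identifiable")
  if (length(unique(records$dyad_id)) < 2L) stop("need >= 2 dyads")
  # thinned datasets can have one record per dyad; the dyad variance is
  # then boundary-estimated, which is fine for the fixed-effect LRT
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  full <- lme4::lmer(jd_sqrt ~ category_factor + (1 | dyad_id),
                     data = records, REML = FALSE, control = ctrl)
  null <- lme4::lmer(jd_sqrt ~ 1 + (1 | dyad_id), data = records,
                     REML = FALSE, control = ctrl)
  lrt <- lrt_report(full, null)
  dfm <- choose_df_method(df_method, nrow(records))
  ph <- if (posthoc) posthoc_table(full, ~category_factor, dfm) else NULL
  structure(list(
    model_label = "distance_lmm",
    response = "sqrt(Jaro similarity)",
    fixed_levels = levels(records$category_factor),
    random = "(1 | dyad_id)",
    chisq = lrt$chisq, df = lrt$df, p_value = lrt$p_value,
    posthoc = ph, df_method = if (posthoc) dfm else NA_character_,
    fit = full, null_fit = null
  ), class = "indri_lmm_report")
}

#' Mixed model on log normalized diversity
#'
#' Fits `log(nd)` on singer category (3 levels) with crossed random
#' intercepts for singer identity and song identity; likelihood-ratio
#' test against the random-effects-only null and Tukey contrasts between
#' categories.
#'
#' @param div Diversity table from [diversity_table()].
#' @inheritParams fit_distance_lmm
#' @return An `indri_lmm_report` (see [fit_distance_lmm()]).
#' @export
fit_diversity_lmm <- function(div, posthoc = TRUE, df_method = "auto") {
  div$category <- droplevels(factor(div$category))
  if (nlevels(div$category) < 2L) stop("need >= 2 categories")
  if (length(unique(div$singer_id)) < 2L) stop("need >= 2 singers")
  if (length(unique(div$song_id)) < 2L) stop("need >= 2 songs")
  full <- lme4::lmer(log_nd ~ category + (1 | singer_id) + (1 | song_id),
                     data = div, REML = FALSE)
  null <- lme4::lmer(log_nd ~ 1 + (1 | singer_id) + (1 | song_id),
                     data = div, REML = FALSE)
  lrt <- lrt_report(full, null)
  dfm <- choose_df_method(df_method, nrow(div))
  ph <- if (posthoc) posthoc_table(full, ~category, dfm) else NULL
  structure(list(
    model_label = "diversity_lmm",
    response = "log(normalized diversity)",
    fixed_levels = levels(div$category),
    random = "(1 | singer_id) + (1 | song_id)",
    chisq = lrt$chisq, df = lrt$df, p_value = lrt$p_value,
    posthoc = ph, df_method = if (posthoc) dfm else NA_character_,
    fit = full, null_fit = null
  ), class = "indri_lmm_report")
}

#' @export
print.indri_lmm_report <- function(x, ...) {
  cat(sprintf("%s: %s ~ %d-level factor + %s\n", x$model_label, x$response,
              length(x$fixed_levels), x$random))
  cat(sprintf("  LRT vs null: chisq = %.3f, df = %d, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  Tukey contrasts (%s df):\n", x$df_method))
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

stratified_split <- function(labels, train_fraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(train_fraction * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Kernel SVM classification of singer categories from similarity profiles
#'
#' Represents each contribution by its row of Jaro similarities to the
#' training reference set and classifies singer categories with an
#' RBF-kernel support vector machine. `(C, sigma)` are tuned by grid
#' search ranked on k-fold cross-validated accuracy within a stratified
#' training split; the winning model is then scored on the training and
#' held-out test sets.
#'
#' @param matrix Square Jaro similarity matrix over the selected
#'   contributions.
#' @param labels Category label per contribution (same order as the
#'   matrix).
#' @param seed Integer seed controlling the split, folds and any SVM
#'   randomness.
#' @param train_fraction Stratified training fraction (default 0.7).
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param C_grid,sigma_grid Tuning grids (defaults: powers of 4 spanning
#'   `2^-5..2^15` for C and `2^-15..2^3` for sigma).
#' @param kernel_mode `"features"` (default; similarity rows to the
#'   training set fed to an RBF kernel) or `"precomputed"` (the
#'   similarity matrix used directly as the kernel).
#' @return Object of class `indri_svm_report`: list with `classes`, `C`,
#'   `sigma`, `cv_accuracy`, `train_accuracy`, `test_accuracy`,
#'   `per_class_recall`, `confusion` (test-set confusion matrix,
#'   rows = truth), `n_train`, `n_test`, `cv_folds`, `train_fraction`,
#'   `kernel_mode`, `seed`.
#' @export
svm_classify_categories <- function(matrix, labels, seed = 1L,
                                    train_fraction = 0.7, cv_folds = 10,
                                    C_grid = 2^seq(-5, 15, by = 2),
                                    sigma_grid = 2^seq(-15, 3, by = 2),
                                    kernel_mode = c("features",
                                                    "precomputed")) {
  kernel_mode <- match.arg(kernel_mode)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  if (any(table(labels) < 10L)) stop("every class needs >= 10 strings")
  stopifnot(nrow(matrix) == length(labels), ncol(matrix) == length(labels))
  with_seed(seed, {
    train <- stratified_split(labels, train_fraction)
    y_tr <- labels[train]; y_te <- labels[!train]
    if (kernel_mode == "precomputed") {
      K <- kernlab::as.kernelMatrix(matrix[train, train, drop = FALSE])
      best <- list(err = Inf, C = NA_real_, sigma = NA_real_)
      for (C in C_grid) {
        fit <- kernlab::ksvm(K, y_tr, C = C, cross = cv_folds)
        if (kernlab::cross(fit) < best$err) {
          best <- list(err = kernlab::cross(fit), C = C, sigma = NA_real_)
        }
      }
      fit <- kernlab::ksvm(K, y_tr, C = best$C)
      sv <- kernlab::SVindex(fit)
      K_te <- kernlab::as.kernelMatrix(
        matrix[!train, train, drop = FALSE][, sv, drop = FALSE])
      pred_te <- kernlab::predict(fit, K_te)
      K_tr <- kernlab::as.kernelMatrix(
        matrix[train, train, drop = FALSE][, sv, drop = FALSE])
      pred_tr <- kernlab::predict(fit, K_tr)
    } else {
      X <- matrix[, train, drop = FALSE]  # reference set = training strings
      x_tr <- X[train, , drop = FALSE]
      x_te <- X[!train, , drop = FALSE]
      best <- list(err = Inf, C = NA_real_, sigma = NA_real_)
      for (sg in sigma_grid) {
        for (C in C_grid) {
          fit <- kernlab::ksvm(x_tr, y_tr, kernel = "rbfdot",
                               kpar = list(sigma = sg), C = C,
                               cross = cv_folds)
          if (kernlab::cross(fit) < best$err) {
            best <- list(err = kernlab::cross(fit), C = C, sigma = sg)
          }
        }
      }
      fit <- kernlab::ksvm(x_tr, y_tr, kernel = "rbfdot",
                           kpar = list(sigma = best$sigma), C = best$C)
      pred_tr <- kernlab::predict(fit, x_tr)
      pred_te <- kernlab::predict(fit, x_te)
    }
    conf <- table(truth = y_te, predicted = pred_te)
    recall <- diag(conf) / rowSums(conf)
    structure(list(
      classes = levels(labels), C = best$C, sigma = best$sigma,
      cv_accuracy = 1 - best$err,
      train_accuracy = mean(pred_tr == y_tr),
      test_accuracy = mean(pred_te == y_te),
      per_class_recall = recall,
      confusion = conf,
      n_train = sum(train), n_test = sum(!train),
      cv_folds = cv_folds, train_fraction = train_fraction,
      kernel_mode = kernel_mode, seed = seed
    ), class = "indri_svm_report")
  })
}

#' @export
print.indri_svm_report <- function(x, ...) {
  cat(sprintf(
    "SVM (%s, C = %.4g, sigma = %.4g): CV acc %.3f, train %.3f, test %.3f\n",
    x$kernel_mode, x$C, x$sigma, x$cv_accuracy, x$train_accuracy,
    x$test_accuracy))
  cat("  per-class test recall:\n")
  print(round(x$per_class_recall, 3))
  invisible(x)
}

#' Nonparametric comparisons of entropy rates
#'
#' Kruskal-Wallis rank-sum test of entropy rate across singer categories,
#' and the Spearman rank correlation between each group's dominant-male
#' and dominant-female entropy rates.
#'
#' @param entropy Entropy table from [entropy_table()].
#' @param min_pairs Minimum complete female/male group pairs for the
#'   correlation test (default 3; below it the correlation is reported
#'   untested).
#' @return List with `kruskal` (`chisq`, `df`, `p_value`, `n`) and
#'   `spearman` (`rho`, `n`, `p_value`, `status`).
#' @export
entropy_group_tests <- function(entropy, min_pairs = 3) {
  if (length(unique(entropy$category)) < 2L) {
    stop("need >= 2 categories for the Kruskal-Wallis test")
  }
  kw <- kruskal.test(entropy_rate ~ factor(category), data = entropy)
  dom <- entropy[entropy$category %in% c("dominant_female",
                                         "dominant_male"), ]
  wide <- merge(
    dom[dom$category == "dominant_female", c("group_id", "entropy_rate")],
    dom[dom$category == "dominant_male", c("group_id", "entropy_rate")],
    by = "group_id", suffixes = c("_female", "_male"))
  sp <- if (nrow(wide) >= min_pairs) {
    ct <- suppressWarnings(
      cor.test(wide$entropy_rate_female, wide$entropy_rate_male,
               method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), n = nrow(wide), p_value = ct$p.value,
         status = "tested")
  } else {
    list(rho = NA_real_, n = nrow(wide), p_value = NA_real_,
         status = "untested")
  }
  list(kruskal = list(chisq = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = kw$p.value, n = nrow(entropy)),
       spearman = sp)
}
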