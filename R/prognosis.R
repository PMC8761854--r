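#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, computed from ranks;
#' identical to trapezoidal integration of the ROC curve.
#'
#' @param scores_pos scores of the positive class.
#' @param scores_neg scores of the negative class.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_mw(c(0.9, 0.4), c(0.5, 0.1)) # 0.75
#' @export
auc_mw <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    abort("both classes must be non-empty")
  }
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(scores_neg))
}

roc_points <- function(scores, labels) {
  # descending-threshold sweep; tied scores are processed as one block so
  # ties trace a diagonal segment (keeps trapezoid AUC = Mann-Whitney AUC)
  lab <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(lab[scores >= t]) / sum(lab), numeric(1))
  fpr <- vapply(thr, function(t) sum((1 - lab)[scores >= t]) / sum(1 - lab),
                numeric(1))
  tibble(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

rf_cv_machinery <- function(m, y, n_folds, n_repeats, n_trees, seed,
                            importance = TRUE, n_perm_draws = 3) {
  set.seed(seed)
  n <- nrow(m)
  # all fold assignments are drawn up front so the held-out scores do not
  # depend on whether (or how often) permutation importance is computed
  folds_list <- lapply(seq_len(n_repeats), function(r) stratified_folds(y, n_folds))
  scores <- matrix(NA_real_, n, n_repeats)
  imp <- matrix(0, ncol(m), n_repeats * n_folds,
                dimnames = list(colnames(m), NULL))
  col_ix <- 0
  for (rep in seq_len(n_repeats)) {
    folds <- folds_list[[rep]]
    for (k in seq_len(n_folds)) {
      col_ix <- col_ix + 1
      tr <- folds != k
      fit <- ranger::ranger(x = m[tr, , drop = FALSE], y = y[tr],
                            num.trees = n_trees, probability = TRUE,
                            seed = seed + 7919L * col_ix, num.threads = 1)
      te <- m[!tr, , drop = FALSE]
      pr <- stats::predict(fit, data = te, num.threads = 1)$predictions[, levels(y)[2]]
      scores[!tr, rep] <- pr
      if (importance) {
        # per-tree mean decrease in held-out accuracy (the classic MDA,
        # measured on the test fold); per-tree votes are sensitive where
        # the thresholded ensemble probability is not
        nt <- nrow(te)
        truth <- y[!tr] == levels(y)[2]
        pos_col <- match(levels(y)[2], colnames(
          stats::predict(fit, data = te[1, , drop = FALSE],
                         num.threads = 1)$predictions))
        pa <- stats::predict(fit, data = te, num.threads = 1,
                             predict.all = TRUE)$predictions[, pos_col, , drop = FALSE]
        base_tree_acc <- colMeans((pa[, 1, ] > 0.5) == truth)
        delta <- numeric(ncol(m))
        for (d in seq_len(n_perm_draws)) {
          big <- te[rep(seq_len(nt), ncol(m)), , drop = FALSE]
          for (j in seq_len(ncol(m))) {
            rows <- (j - 1) * nt + seq_len(nt)
            big[rows, j] <- te[sample(nt), j]
          }
          pp <- stats::predict(fit, data = big, num.threads = 1,
                               predict.all = TRUE)$predictions[, pos_col, , drop = FALSE]
          cls <- pp[, 1, ] > 0.5
          delta <- delta + vapply(seq_len(ncol(m)), function(j) {
            rows <- (j - 1) * nt + seq_len(nt)
            mean(base_tree_acc - colMeans(cls[rows, , drop = FALSE] == truth))
          }, numeric(1))
        }
        imp[, col_ix] <- delta / n_perm_draws
      }
    }
  }
  list(scores = rowMeans(scores), imp = rowMeans(imp))
}

#' Random-forest outcome model with cross-validated permutation importance
#'
#' Probability random forest on the supplied features, evaluated by repeated
#' stratified k-fold cross-validation. Feature importance is the mean
#' decrease in held-out accuracy when the feature is permuted in the test
#' fold, averaged over folds and repeats. The ROC curve and AUC come from
#' pooled held-out scores (averaged over repeats); the AUC confidence
#' interval is a sample bootstrap, and sensitivity/specificity are reported
#' at the Youden point.
#'
#' @param features sample table of predictors (e.g. OTU relative
#'   abundances).
#' @param outcome two-level outcome aligned with samples (second level =
#'   positive/poor).
#' @param n_folds,n_repeats cross-validation scheme (default 5 x 5).
#' @param n_trees trees per forest (default 1000).
#' @param n_boot bootstrap replicates for the AUC CI (default 2000).
#' @param seed integer seed (controls folds, forests and permutations).
#' @return object of class `rf_outcome`: `importance` (tibble, sorted),
#'   `roc` (tibble of fpr/tpr), `auc`, `auc_ci`, `sensitivity`,
#'   `specificity`, `scores` (pooled held-out), `scheme`, `seed`.
#' @export
rf_outcome_model <- function(features, outcome, n_folds = 5, n_repeats = 5,
                             n_trees = 1000, n_boot = 2000, seed = 1) {
  m <- as_sample_matrix(features)
  y <- check_two_groups(outcome)
  if (length(y) != nrow(m)) abort("outcome must align with samples")
  if (min(table(y)) < n_folds) abort("too few samples per class for the folds")
  if (min(table(y)) < 10) warn("fewer than 10 samples per class; estimates will be noisy")
  if (all(apply(m, 2, sd) == 0)) abort("all features are constant")

  cv <- rf_cv_machinery(m, y, n_folds, n_repeats, n_trees, seed)
  pos <- y == levels(y)[2]
  auc <- auc_mw(cv$scores[pos], cv$scores[!pos])
  roc <- roc_points(cv$scores, pos)
  youden <- which.max(roc$tpr - roc$fpr)

  set.seed(seed + 1L)
  boot <- vapply(seq_len(n_boot), function(b) {
    ix <- sample(length(cv$scores), replace = TRUE)
    if (length(unique(pos[ix])) < 2) return(NA_real_)
    auc_mw(cv$scores[ix][pos[ix]], cv$scores[ix][!pos[ix]])
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))

  new_result(list(
    importance = arrange(tibble(feature = names(cv$imp),
                                mean_decrease_accuracy = cv$imp),
                         dplyr::desc(.data$mean_decrease_accuracy)),
    roc = roc, auc = auc, auc_ci = ci,
    sensitivity = roc$tpr[youden], specificity = 1 - roc$fpr[youden],
    scores = tibble(sample_id = rownames(m), score = cv$scores,
                    outcome = y),
    scheme = sprintf("repeated stratified %d x %d-fold CV, %d trees",
                     n_repeats, n_folds, n_trees),
    seed = seed
  ), "rf_outcome")
}

#' @export
print.rf_outcome <- function(x, ...) {
  cat(sprintf("<rf_outcome> %s\n", x$scheme))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f); sens %.2f / spec %.2f at Youden point\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity, x$specificity))
  cat("  top features:", paste(head(x$importance$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Combined clinical + microbial + metabolic marker model
#'
#' Runs the same cross-validated random-forest machinery on a small marker
#' panel (clinical score, microbial marker, and metabolite features) and
#' reports the AUC alongside the change versus a reference model.
#'
#' @param panel sample table whose columns are the panel features (e.g. NEOS
#'   score, prognostic OTU abundance, two serum and two fecal metabolites).
#' @param outcome two-level outcome aligned with samples.
#' @param baseline optional reference [rf_outcome_model()] fit; the AUC
#'   delta against it is reported.
#' @param ... passed to [rf_outcome_model()].
#' @return an `rf_outcome` object with an extra `auc_delta` element.
#' @export
combined_marker_model <- function(panel, outcome, baseline = NULL, ...) {
  fit <- rf_outcome_model(panel, outcome, ...)
  fit$auc_delta <- if (!is.null(baseline)) fit$auc - baseline$auc else NA_real_
  fit
}

#' Covariate-adjusted logistic odds ratio for a marker
#'
#' Maximum-likelihood logistic regression of a binary outcome on a marker
#' (dichotomised at its median by default, or entered as a continuous
#' z-score) plus covariates; returns the marker's odds ratio with Wald 95%
#' CI and p-value. Complete or quasi-complete separation is detected and
#' raises an error.
#'
#' @param marker numeric marker values (e.g. relative abundance of a taxon).
#' @param outcome binary outcome (0/1 or two-level factor), aligned.
#' @param covariates optional data frame of adjustment covariates.
#' @param dichotomize split the marker at its median (default TRUE; the
#'   coding is recorded in the output).
#' @return one-row tibble: `or`, `ci_low`, `ci_high`, `p_value`, `beta`,
#'   `se`, `n`, `marker_coding`.
#' @export
logistic_adjusted_or <- function(marker, outcome, covariates = NULL,
                                 dichotomize = TRUE) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  if (!all(y %in% 0:1)) abort("outcome must be binary")
  x <- if (dichotomize) {
    # an already-binary marker is taken as the exposure indicator itself
    if (all(marker %in% 0:1)) as.integer(marker)
    else as.integer(marker > median(marker))
  } else {
    as.numeric(scale(marker))
  }
  if (length(unique(x)) < 2) abort("marker is constant after coding")
  df <- data.frame(.y = y, .marker = x)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), ]
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  s <- summary(fit)$coefficients
  if (!".marker" %in% rownames(s)) abort("marker coefficient could not be estimated")
  beta <- s[".marker", 1]; se <- s[".marker", 2]
  if (!fit$converged || abs(beta) > 15 || se > 100 ||
      all(fit$fitted.values > 0.999) || all(fit$fitted.values < 0.001)) {
    abort("separation detected; a penalized fit would be needed")
  }
  tibble(or = exp(beta),
         ci_low = exp(beta - qnorm(0.975) * se),
         ci_high = exp(beta + qnorm(0.975) * se),
         p_value = s[".marker", 4], beta = beta, se = se, n = nrow(df),
         marker_coding = if (dichotomize) "above median (0/1)" else "z-score")
}

#' Relapse survival analysis by diversity stratum
#'
#' Kaplan-Meier curves per stratum, the two-group log-rank test, and a Cox
#' proportional-hazards fit (Efron tie handling) of relapse on the stratum
#' indicator. The default stratifier is a median split of the supplied
#' diversity values ("low" = below median, entered so that HR > 1 means
#' higher hazard in the low-diversity group). An at-risk table at monthly
#' ticks is included.
#'
#' @param clinical tibble with `sample_id`, `relapse_time` (months) and
#'   `relapse_event` (0/1); rows with missing relapse data are dropped.
#' @param diversity named (by sample id) or aligned numeric diversity values
#'   (e.g. Shannon); ignored when `strata` is given.
#' @param strata optional explicit two-level stratum per sample.
#' @return object of class `relapse_survival`: `km` (tibble of step
#'   curves), `logrank` (tibble), `cox` (tibble with HR and CI), `at_risk`
#'   (tibble), `flag`.
#' @export
relapse_survival <- function(clinical, diversity = NULL, strata = NULL) {
  cl <- clinical[!is.na(clinical$relapse_time) & !is.na(clinical$relapse_event), ]
  if (!nrow(cl)) abort("no relapse records")
  if (is.null(strata)) {
    if (is.null(diversity)) abort("supply `diversity` or `strata`")
    dv <- if (!is.null(names(diversity))) diversity[cl$sample_id] else diversity
    if (length(dv) != nrow(cl)) abort("diversity must cover the relapse records")
    if (sd(dv) == 0) abort("diversity is constant; median split undefined")
    strata <- ifelse(dv < median(dv), "low", "high")
  }
  # "high" is the reference when the strata use the high/low convention
  strata <- if (all(strata %in% c("high", "low"))) {
    factor(strata, levels = c("high", "low"))
  } else {
    as.factor(strata)
  }
  if (nlevels(droplevels(strata)) < 2) abort("need two strata")

  surv <- survival::Surv(cl$relapse_time, cl$relapse_event)
  km_fit <- survival::survfit(surv ~ strata)
  sm <- summary(km_fit)
  km <- tibble(stratum = sub("strata=", "", as.character(sm$strata)),
               time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
               survival = sm$surv)

  flag <- NA_character_
  logrank <- tibble(chisq = NA_real_, df = NA_integer_, p_value = NA_real_)
  cox <- tibble(log_hr = NA_real_, hr = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_)
  if (sum(cl$relapse_event) == 0) {
    flag <- "zero events; tests undefined"
  } else {
    lr <- survival::survdiff(surv ~ strata)
    logrank <- tibble(chisq = lr$chisq, df = length(lr$n) - 1L,
                      p_value = stats::pchisq(lr$chisq, length(lr$n) - 1L,
                                              lower.tail = FALSE))
    cx <- survival::coxph(surv ~ strata, ties = "efron")
    sc <- summary(cx)
    cox <- tibble(log_hr = unname(coef(cx)[1]), hr = unname(exp(coef(cx)[1])),
                  ci_low = sc$conf.int[1, 3], ci_high = sc$conf.int[1, 4],
                  p_value = sc$coefficients[1, 5])
  }

  ticks <- 0:ceiling(max(cl$relapse_time))
  ar <- summary(km_fit, times = ticks, extend = TRUE)
  at_risk <- tibble(stratum = sub("strata=", "", as.character(ar$strata)),
                    time = ar$time, n_risk = ar$n.risk)

  new_result(list(km = km, logrank = logrank, cox = cox, at_risk = at_risk,
                  n = nrow(cl), n_events = sum(cl$relapse_event), flag = flag),
             "relapse_survival")
}

#' @export
print.relapse_survival <- function(x, ...) {
  cat(sprintf("<relapse_survival> %d patients, %d events\n", x$n, x$n_events))
  if (!is.na(x$flag)) {
    cat("  ", x$flag, "\n")
  } else {
    cat(sprintf("  log-rank p = %.4g; HR (low vs high diversity) = %.2f (95%% CI %.2f-%.2f)\n",
                x$logrank$p_value, x$cox$hr, x$cox$ci_low, x$cox$ci_high))
  }
  invisible(x)
}
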