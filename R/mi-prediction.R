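# Myocardial-infarction prediction from the latent space: feature
# extraction, balanced logistic-regression cross-validation with the five
# standard binary metrics, Cox proportional-hazards survival analysis, and
# Harrell's concordance index, with ejection-fraction clinical baselines.

#' Extract latent features for a set of subjects
#'
#' Noiseless encodings (`z = mu`), one row per subject, in input order.
#'
#' @param model a trained [point_vae()].
#' @param samples list of [anatomy_sample()] objects.
#' @return A tibble: `subject_id` plus `z1 ... z<latent_dim>`.
#' @export
extract_features <- function(model, samples) {
  stopifnot(inherits(model, "point_vae"))
  if (model$trained_steps == 0L) {
    stop("model has not been trained; latent features would be meaningless",
         call. = FALSE)
  }
  mus <- latent_means(model, samples)
  colnames(mus) <- paste0("z", seq_len(ncol(mus)))
  out <- tibble::as_tibble(mus)
  out$subject_id <- vapply(samples, function(s) s$subject_id, character(1))
  out[, c("subject_id", paste0("z", seq_len(ncol(mus))))]
}

#' Balanced two-group subset
#'
#' Draws an equal number of subjects from two groups: both are downsampled
#' (without replacement, seeded) to the size of the smaller group.
#'
#' @param samples list of [anatomy_sample()] objects.
#' @param group_a,group_b group labels to balance.
#' @param seed integer seed.
#' @return A list of samples (group A first), a subset of the input.
#' @export
balanced_subset <- function(samples, group_a = "prevalent_mi",
                            group_b = "control", seed = 1L) {
  groups <- vapply(samples, function(s) s$group, character(1))
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop(sprintf("empty group: %s=%d, %s=%d subjects", group_a, length(ia),
                 group_b, length(ib)), call. = FALSE)
  }
  m <- min(length(ia), length(ib))
  with_seed(seed, {
    keep <- c(sample(ia, m), sample(ib, m))
    samples[keep]
  })
}

# Rank-statistic AUROC (equivalent to the concordant-pair fraction with
# ties counted 1/2).
auroc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validated logistic regression
#'
#' Trains an L2-penalized logistic regression on standardized features in
#' each fold (ridge via `glmnet`, inverse-regularization parameter `C` as
#' in scikit-learn; the default `C = 1` is a weak penalty) and evaluates
#' accuracy, AUROC (rank statistic), F1, precision and recall on the
#' held-out fold at probability threshold 0.5.  Folds are stratified by
#' class and seeded.
#'
#' @param features numeric matrix or data frame of predictors (rows =
#'   subjects).
#' @param labels binary labels (0/1, logical, or 2-level factor).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param C inverse L2 regularization strength (larger = weaker penalty).
#' @return An object of class `classification_report`: tibble `folds` plus
#'   the across-fold `means`.
#' @export
crossval_logistic <- function(features, labels, k = 10L, seed = 1L, C = 1) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  y <- as.integer(if (is.factor(labels)) labels == levels(labels)[2]
                  else as.logical(labels))
  if (length(y) != nrow(X)) stop("labels/features length mismatch", call. = FALSE)
  k <- assert_count(k, "k", minimum = 2L)
  if (min(table(y)) < k) {
    stop(sprintf("need at least k=%d subjects per class for stratified folds", k),
         call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  metrics <- matrix(NA_real_, k, 5,
                    dimnames = list(NULL, c("accuracy", "auroc", "f1",
                                            "precision", "recall")))
  assert_scalar_number(C, "C", lower = 1e-9)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    lambda <- 1 / (C * sum(tr))
    # glmnet needs >= 2 columns; duplicate a single feature (the ridge
    # penalty halves across the copies, a negligible change at weak C)
    Xtr <- Xs[tr, , drop = FALSE]; Xte <- Xs[te, , drop = FALSE]
    if (ncol(Xtr) == 1L) {
      Xtr <- cbind(Xtr, Xtr[, 1]); Xte <- cbind(Xte, Xte[, 1])
    }
    fit <- suppressWarnings(
      glmnet::glmnet(Xtr, y[tr], family = "binomial", alpha = 0,
                     lambda = lambda, standardize = FALSE))
    p <- as.numeric(predict(fit, newx = Xte, type = "response"))
    yhat <- as.integer(p > 0.5)
    yt <- y[te]
    tp <- sum(yhat == 1 & yt == 1); fp <- sum(yhat == 1 & yt == 0)
    fn <- sum(yhat == 0 & yt == 1)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    metrics[f, ] <- c(mean(yhat == yt), auroc_rank(p, yt),
                      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
                      prec, rec)
  }
  structure(list(folds = tibble::as_tibble(cbind(fold = seq_len(k),
                                                 as.data.frame(metrics))),
                 means = colMeans(metrics, na.rm = TRUE), k = k),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d-fold CV means:\n", x$k))
  print(round(x$means, 4))
  invisible(x)
}

#' Breslow partial log-likelihood and its gradient
#'
#' Hand-written Cox partial likelihood (Breslow tie handling), exposed so
#' the maximizer returned by [fit_cox()] can be verified against the score
#' identity and against brute-force maximization.
#'
#' @param beta coefficient vector.
#' @param covariates numeric matrix (rows = subjects).
#' @param times event/censoring times.
#' @param events logical/0-1 event indicators.
#' @return A list with `loglik` and `gradient`.
#' @export
cox_partial_loglik <- function(beta, covariates, times, events) {
  X <- as.matrix(covariates)
  ev <- as.logical(events)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0; gr <- numeric(ncol(X))
  for (i in which(ev)) {
    risk <- times >= times[i]
    sw <- sum(w[risk])
    xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sw
    ll <- ll + eta[i] - log(sw)
    gr <- gr + X[i, ] - xbar
  }
  list(loglik = ll, gradient = gr)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling (via
#' `survival::coxph`, Newton iterations).  Zero-variance covariates have a
#' score that is identically zero and are assigned coefficient 0.
#' Non-convergence or separation (diverging coefficients) is reported with
#' diagnostics rather than returned silently.
#'
#' @param covariates numeric matrix / data frame (rows = subjects).
#' @param times nonnegative event or censoring times.
#' @param events event indicators (TRUE = observed).
#' @return An object of class `cox_model`: `coefficients`, `loglik`,
#'   `converged`, and the underlying fit.
#' @export
fit_cox <- function(covariates, times, events) {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  ev <- as.logical(events)
  if (any(times < 0)) stop("negative survival times", call. = FALSE)
  if (sum(ev) < 2L) stop("need at least 2 observed events", call. = FALSE)
  keep <- apply(X, 2, function(v) sd(v) > 0)
  coefs <- setNames(numeric(ncol(X)),
                    colnames(X) %||% paste0("x", seq_len(ncol(X))))
  names(coefs) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  fit <- NULL
  if (any(keep)) {
    df <- data.frame(X[, keep, drop = FALSE])
    fit <- survival::coxph(survival::Surv(times, ev) ~ ., data = df,
                           ties = "breslow",
                           control = survival::coxph.control(
                             eps = 1e-10, toler.chol = 1e-12, iter.max = 50))
    beta <- coef(fit)
    if (any(!is.finite(beta)) || any(abs(beta) > 50)) {
      stop(sprintf(
        "Cox fit did not converge (max |beta| = %.3g); likely separation",
        max(abs(beta), na.rm = TRUE)), call. = FALSE)
    }
    coefs[keep] <- beta
  }
  grad <- cox_partial_loglik(coefs, X, times, ev)$gradient
  structure(list(coefficients = coefs,
                 loglik = cox_partial_loglik(coefs, X, times, ev)$loglik,
                 gradient_norm = sqrt(sum(grad^2)),
                 converged = TRUE, n = nrow(X), n_events = sum(ev),
                 fit = fit), class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("<cox_model> n=%d, events=%d, loglik=%.3f\n", x$n, x$n_events,
              x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.cox_model <- function(object, ...) object$coefficients

#' Harrell's concordance index
#'
#' Usable pairs are ordered pairs `(i, j)` with an observed event for `i`
#' and `t_i < t_j`; the index is the fraction of usable pairs whose
#' predicted risks satisfy `eta_i > eta_j`.  Risk ties count 0 under the
#' strict indicator (default); `ties = "half"` applies the common 1/2
#' convention instead.
#'
#' @param risk predicted risk scores (higher = earlier event expected).
#' @param time event/censoring times.
#' @param event event indicators.
#' @param ties `"strict"` (indicator, ties count 0) or `"half"`.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(risk, time, event, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(length(risk) == length(time), length(time) == length(event))
  if (any(!is.finite(risk))) stop("non-finite risk scores", call. = FALSE)
  ev <- as.logical(event)
  n <- length(risk)
  num <- 0; den <- 0
  for (i in which(ev)) {
    later <- time > time[i]
    den <- den + sum(later)
    num <- num + sum(risk[i] > risk[later])
    if (ties == "half") num <- num + 0.5 * sum(risk[i] == risk[later])
  }
  if (den == 0) stop("no usable pairs for concordance", call. = FALSE)
  num / den
}

#' Ejection-fraction clinical baselines
#'
#' LV and RV ejection fractions computed from the point clouds via
#' [cavity_volume()], the gold-standard clinical comparators for the
#' latent-space classifiers.
#'
#' @param samples list of [anatomy_sample()] objects.
#' @return A tibble: `subject_id`, `lv_ef`, `rv_ef`.
#' @export
ef_baselines <- function(samples) {
  rows <- lapply(samples, function(s) {
    m <- clinical_metrics(s)
    tibble::tibble(subject_id = s$subject_id, lv_ef = m$lv_ef, rv_ef = m$rv_ef)
  })
  do.call(rbind, rows)
}

#' Build survival records for the incident-MI cohort
#'
#' Prevalent-MI subjects (event before imaging) are excluded; everyone else
#' contributes their event time (if observed before the horizon) or is
#' right-censored at the horizon.
#'
#' @param samples list of [anatomy_sample()] objects.
#' @param horizon study endpoint in days after imaging.
#' @return A tibble: `subject_id`, `time_days`, `event`.
#' @export
build_survival_records <- function(samples, horizon) {
  assert_scalar_number(horizon, "horizon", lower = 0)
  keep <- Filter(function(s) s$group != "prevalent_mi", samples)
  if (length(keep) == 0L) stop("no non-prevalent subjects", call. = FALSE)
  tm <- vapply(keep, function(s) s$event_time_days, numeric(1))
  if (any(is.na(tm))) tm[is.na(tm)] <- horizon
  if (any(tm < 0)) stop("negative event times", call. = FALSE)
  ev <- vapply(keep, function(s) s$event_observed, logical(1)) & tm <= horizon
  tibble::tibble(
    subject_id = vapply(keep, function(s) s$subject_id, character(1)),
    time_days = pmin(tm, horizon), event = ev)
}

#' Cross-validated Cox survival analysis
#'
#' k-fold cross-validation of a Cox model: fit on the training folds,
#' predict linear risk on the held-out fold, and score Harrell's C (with
#' the 1/2 tie convention) on the held-out records; fold scores are
#' averaged unweighted.
#'
#' @inheritParams fit_cox
#' @param k folds (default 10).
#' @param seed integer seed for the fold assignment (stratified by event
#'   status).
#' @return A list with `mean_c`, per-fold `c_index`, and `k`.
#' @export
crossval_cox <- function(covariates, times, events, k = 10L, seed = 1L) {
  X <- as.matrix(as.data.frame(covariates))
  ev <- as.logical(events)
  k <- assert_count(k, "k", minimum = 2L)
  folds <- integer(length(ev))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(ev == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  cs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- fit_cox(X[tr, , drop = FALSE], times[tr], ev[tr])
    eta <- drop(X[!tr, , drop = FALSE] %*% fit$coefficients)
    harrell_c(eta, times[!tr], ev[!tr], ties = "half")
  }, numeric(1))
  list(mean_c = mean(cs), c_index = cs, k = k)
}

#' Latent-space versus ejection-fraction MI classification
#'
#' The complete evaluation protocol for one classification task: build a
#' balanced case/control subset, extract the requested feature set (latent
#' posterior means or EF baselines), and run stratified 10-fold logistic
#' regression.
#'
#' @param model a trained [point_vae()].
#' @param samples cohort (list of [anatomy_sample()]).
#' @param task `"prevalent"` or `"incident"`.
#' @param features `"latent"`, `"lvef"`, `"rvef"`, or `"bothef"`.
#' @param k folds.
#' @param seed integer seed (subset draw and fold assignment).
#' @param ef optional precomputed [ef_baselines()] table for the cohort (to
#'   avoid recomputing volumes).
#' @return A `classification_report`.
#' @export
mi_classification <- function(model, samples, task = c("prevalent", "incident"),
                              features = c("latent", "lvef", "rvef", "bothef"),
                              k = 10L, seed = 1L, ef = NULL) {
  task <- match.arg(task)
  features <- match.arg(features)
  case_group <- if (task == "prevalent") "prevalent_mi" else "incident_mi"
  sub <- balanced_subset(samples, case_group, "control", seed)
  labels <- vapply(sub, function(s) s$group == case_group, logical(1))
  X <- if (features == "latent") {
    as.matrix(extract_features(model, sub)[, -1])
  } else {
    tb <- if (is.null(ef)) {
      ef_baselines(sub)
    } else {
      ids <- vapply(sub, function(s) s$subject_id, character(1))
      tb0 <- ef[match(ids, ef$subject_id), ]
      if (anyNA(tb0$lv_ef)) stop("`ef` table does not cover the subset", call. = FALSE)
      tb0
    }
    switch(features,
           lvef = as.matrix(tb[, "lv_ef"]),
           rvef = as.matrix(tb[, "rv_ef"]),
           bothef = as.matrix(tb[, c("lv_ef", "rv_ef")]))
  }
  crossval_logistic(X, labels, k = k, seed = seed)
}
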