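#' Deciban / odds conversions
#'
#' Evidence in this package is expressed in decibans: `db = 10 * log10(r)`
#' for an odds or probability ratio `r`. On Jeffreys' scale, 5 db
#' corresponds to roughly 3:1 odds (substantial evidence), 10 db to 10:1
#' (strong), 15 db to roughly 30:1 (very strong) and 20 db to 100:1
#' (decisive).
#'
#' @param db Evidence in decibans.
#' @param odds Odds (or any positive ratio).
#' @return The converted value.
#' @examples
#' db_to_odds(20)  # 100
#' odds_to_db(10)  # 10
#' @export
db_to_odds <- function(db) 10^(db / 10)

#' @rdname db_to_odds
#' @export
odds_to_db <- function(odds) 10 * log10(odds)

#' Fit the multi-target naive Bayes coefficient model
#'
#' For every target diagnosis `t`, patients are split into the two classes
#' `Y(,t) = 1` and `Y(,t) = 0` and class-conditional feature probabilities
#' are estimated with additive smoothing `alpha`:
#' `theta_cf = (N_cf + alpha) / (N_c + alpha * N_F)`, where `N_cf` is the
#' number of class-`c` patients carrying feature `f` and, under the
#' multinomial event model, `N_c` is the total number of feature
#' occurrences in class `c` (so that `sum_f theta_cf = 1`). The model
#' coefficient `C(f, t) = 10 * log10(theta_1f / theta_0f)` is the weight of
#' evidence, in decibans, in favour of target `t` provided by the presence
#' of feature `f`; `pi(t) = 10 * log10(n_1 / n_0)` is the prior log-odds.
#' Under `event_model = "bernoulli"` the denominator is the class patient
#' count plus `2 * alpha` (per-feature presence/absence estimate).
#'
#' Targets without at least one positive and one negative patient are
#' dropped with a warning.
#'
#' @param X Sparse patients x features indicator ([assign_features()]).
#' @param Y Sparse patients x codes target indicator ([build_matrices()]).
#' @param alpha Positive smoothing parameter.
#' @param targets Character vector of target columns (default: all of `Y`).
#' @param event_model `"multinomial"` (default) or `"bernoulli"`.
#' @param features Optional `feature_set` tibble stored alongside the
#'   coefficients (used by the network and interaction stages).
#' @param order Model order recorded on the object (defaults to the
#'   largest feature cardinality when `features` is given).
#' @return An object of class `mnb_model` with elements `C` (features x
#'   targets deciban matrix), `prior` (named deciban vector), `alpha`,
#'   `event_model`, `order`, `features`, `theta1`, `theta0`.
#' @export
mnb_fit <- function(X, Y, alpha = 1, targets = NULL,
                    event_model = c("multinomial", "bernoulli"),
                    features = NULL, order = NULL) {
  event_model <- match.arg(event_model)
  stopifnot(alpha > 0, nrow(X) == nrow(Y))
  if (is.null(targets)) targets <- colnames(Y)
  targets <- intersect(targets, colnames(Y))
  Yt <- Y[, targets, drop = FALSE]
  n <- nrow(X)
  n1 <- Matrix::colSums(Yt)
  degenerate <- n1 == 0 | n1 == n
  if (any(degenerate)) {
    warning(sum(degenerate),
            " target(s) without both positive and negative patients dropped")
    Yt <- Yt[, !degenerate, drop = FALSE]
    n1 <- n1[!degenerate]
    targets <- targets[!degenerate]
  }
  if (!length(targets)) stop("no usable targets")
  n0 <- n - n1
  NF <- ncol(X)
  N1f <- as.matrix(Matrix::crossprod(X, Yt))        # features x targets
  colX <- Matrix::colSums(X)
  N0f <- colX - N1f
  if (event_model == "multinomial") {
    denom1 <- Matrix::colSums(N1f) + alpha * NF     # total occurrences + smoothing
    denom0 <- (sum(colX) - Matrix::colSums(N1f)) + alpha * NF
  } else {
    denom1 <- n1 + 2 * alpha
    denom0 <- n0 + 2 * alpha
  }
  theta1 <- sweep(N1f + alpha, 2, denom1, "/")
  theta0 <- sweep(N0f + alpha, 2, denom0, "/")
  C <- 10 * (log10(theta1) - log10(theta0))
  dimnames(C) <- list(colnames(X), targets)
  prior <- stats::setNames(10 * log10(n1 / n0), targets)
  if (is.null(order)) {
    order <- if (!is.null(features) && nrow(features))
      max(features$cardinality) else NA_integer_
  }
  structure(list(C = C, prior = prior, alpha = alpha,
                 event_model = event_model, order = order,
                 features = features, theta1 = theta1, theta0 = theta0),
            class = "mnb_model")
}

#' @export
print.mnb_model <- function(x, ...) {
  cat("Multi-target naive Bayes model (", x$event_model, " event model)\n",
      sep = "")
  cat("  ", nrow(x$C), " features x ", ncol(x$C), " targets, alpha = ",
      x$alpha, ", order = ", x$order, "\n", sep = "")
  invisible(x)
}

#' Predict target diagnoses
#'
#' Computes the linear decision function
#' `Delta(p, t) = sum over assigned features f of C(f, t) + pi(t)` and
#' classifies target `t` present for patient `p` iff `Delta(p, t) > 0`
#' (strictly; a patient without any assigned feature gets the majority
#' class `pi(t) > 0`).
#'
#' @param object Fitted [mnb_fit()] model.
#' @param X Patients x features matrix with columns exactly matching the
#'   model's features.
#' @param type `"class"` for the binary prediction matrix, `"decision"` for
#'   the deciban decision values `Delta`.
#' @param ... Unused.
#' @return Patients x targets matrix (logical for `"class"`).
#' @export
predict.mnb_model <- function(object, X, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (!identical(colnames(X), rownames(object$C)))
    stop("feature columns of X do not align with the model's feature set")
  delta <- as.matrix(X %*% object$C)
  delta <- sweep(delta, 2, object$prior, "+")
  dimnames(delta) <- list(rownames(X), colnames(object$C))
  if (type == "decision") delta else delta > 0
}

#' Score predictions with support-weighted F1
#'
#' Per-target precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their
#' harmonic mean), each defined as 0 when its denominator is 0. The support
#' of a target is its number of true positives, and the total F1 is the
#' support-weighted average of the per-target F1 scores, which emphasises
#' prevalent targets.
#'
#' @param y_true,y_pred Patients x targets binary matrices with matching
#'   dimnames (any targets absent from either are dropped).
#' @param targets Targets to score (default: all shared columns).
#' @return An object of class `mnb_score`: list with `per_target` (tibble:
#'   target, tp, fp, fn, precision, recall, f1, support), `total_f1` and
#'   `n_targets_scored`.
#' @export
mnb_score <- function(y_true, y_pred, targets = NULL) {
  if (is.null(targets)) targets <- intersect(colnames(y_true), colnames(y_pred))
  targets <- intersect(intersect(targets, colnames(y_true)), colnames(y_pred))
  if (!length(targets)) stop("no targets to score")
  yt <- as.matrix(y_true[, targets, drop = FALSE]) != 0
  yp <- as.matrix(y_pred[, targets, drop = FALSE]) != 0
  tp <- colSums(yt & yp)
  fp <- colSums(!yt & yp)
  fn <- colSums(yt & !yp)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- tp
  total_f1 <- if (sum(support) > 0) sum(support * f1) / sum(support) else 0
  per_target <- tibble::tibble(target = targets, tp = unname(as.numeric(tp)),
                               fp = unname(as.numeric(fp)),
                               fn = unname(as.numeric(fn)),
                               precision = unname(precision),
                               recall = unname(recall), f1 = unname(f1),
                               support = unname(as.numeric(support)))
  structure(list(per_target = per_target, total_f1 = total_f1,
                 n_targets_scored = length(targets)),
            class = "mnb_score")
}

#' @export
print.mnb_score <- function(x, ...) {
  cat("Support-weighted total F1:", round(x$total_f1, 4), "over",
      x$n_targets_scored, "targets\n")
  invisible(x)
}

#' Seeded fold assignment
#'
#' @param n Number of patients.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector in `1:k`, one entry per patient, with fold sizes
#'   differing by at most one.
#' @export
make_folds <- function(n, k = 5, seed = 1L) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Select scorable targets
#'
#' Keeps targets with at least `min_per_fold` positive patients in *every*
#' fold (so each cross-validation split can estimate them), ranks them by
#' total positive count (descending, ties broken lexicographically) and
#' truncates to the top `cap` targets, fixing the scored target list across
#' hyperparameter evaluations.
#'
#' @param Y Patients x codes target matrix.
#' @param folds Integer fold assignment ([make_folds()]).
#' @param min_per_fold Minimum positives per fold (default 200).
#' @param cap Maximum number of targets retained (default 1000).
#' @return Character vector of target codes, ranked.
#' @export
select_targets <- function(Y, folds, min_per_fold = 200, cap = 1000) {
  k <- max(folds)
  fold_dummies <- Matrix::sparseMatrix(i = seq_along(folds), j = folds, x = 1,
                                       dims = c(length(folds), k))
  per_fold <- as.matrix(Matrix::crossprod(Y, fold_dummies))  # targets x folds
  qual <- rowSums(per_fold >= min_per_fold) == k
  totals <- Matrix::colSums(Y)
  cand <- colnames(Y)[qual]
  cand <- cand[order(-totals[qual], cand, method = "radix")]
  utils::head(cand, cap)
}

#' Cross-validate the full mining + model pipeline
#'
#' Partitions patients into `k` seeded folds. For each fold, candidate
#' features are mined and pruned on the training patients only, the model
#' is fitted on the training patients, the final feature set is assigned to
#' the held-out patients, and predictions are scored over a fixed target
#' list (selected once with [select_targets()] unless supplied). Both the
#' held-out and the training total F1 are reported.
#'
#' @param X0 Patient x code feature-period matrix.
#' @param Y Patient x code target matrix (same row order).
#' @param model_order Maximum feature cardinality.
#' @param alpha Smoothing parameter.
#' @param support_min Minimum feature support.
#' @param minidp_min minIDP threshold in decibans.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param min_per_fold,cap Target-selection rule (see [select_targets()]).
#' @param event_model Passed to [mnb_fit()].
#' @param targets Optional fixed target list.
#' @return A list of class `mnb_cv`: `mean_f1` (mean held-out total F1),
#'   `fold_f1`, `train_f1`, `targets`, `n_features` (per-fold final feature
#'   count), plus the call parameters.
#' @export
cross_validate <- function(X0, Y, model_order, alpha = 1, support_min = 30,
                           minidp_min = 0, k = 5, seed = 1L,
                           min_per_fold = 200, cap = 1000,
                           event_model = "multinomial", targets = NULL) {
  stopifnot(k >= 2, nrow(X0) == nrow(Y))
  folds <- make_folds(nrow(X0), k, seed)
  if (is.null(targets))
    targets <- select_targets(Y, folds, min_per_fold, cap)
  if (!length(targets)) stop("no targets satisfy the selection rule")
  fold_f1 <- numeric(k)
  train_f1 <- numeric(k)
  n_features <- integer(k)
  for (i in seq_len(k)) {
    tr <- folds != i
    cand <- mine_candidates(X0[tr, , drop = FALSE], model_order,
                            support_min, minidp_min)
    fin <- prune_to_final(X0[tr, , drop = FALSE], cand, support_min)
    if (nrow(fin$features) == 0) stop("fold ", i, ": empty final feature set")
    n_features[i] <- nrow(fin$features)
    fit <- mnb_fit(fin$X, Y[tr, , drop = FALSE], alpha = alpha,
                   targets = targets, event_model = event_model,
                   features = fin$features)
    Xte <- assign_features(X0[!tr, , drop = FALSE], fin$features)
    pred <- predict(fit, Xte)
    sc <- mnb_score(Y[!tr, , drop = FALSE], pred, colnames(fit$C))
    if (sc$n_targets_scored == 0) stop("fold ", i, ": no scored targets")
    fold_f1[i] <- sc$total_f1
    pred_tr <- predict(fit, fin$X)
    train_f1[i] <- mnb_score(Y[tr, , drop = FALSE], pred_tr,
                             colnames(fit$C))$total_f1
  }
  structure(list(mean_f1 = mean(fold_f1), fold_f1 = fold_f1,
                 train_f1 = train_f1, targets = targets,
                 n_features = n_features, k = k, seed = seed,
                 model_order = model_order, alpha = alpha,
                 support_min = support_min, minidp_min = minidp_min),
            class = "mnb_cv")
}

#' @export
print.mnb_cv <- function(x, ...) {
  cat("Fivefold" , "cross-validation (k =", x$k, "): mean held-out total F1 =",
      round(x$mean_f1, 4), "\n")
  cat("  per fold:", paste(round(x$fold_f1, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted coefficient model into a long tibble
#'
#' @param x An `mnb_model`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `target`, `estimate` (the
#'   coefficient in decibans) and `prior` (target prior log-odds, db).
#' @export
tidy.mnb_model <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$C), times = ncol(x$C)),
    target = rep(colnames(x$C), each = nrow(x$C)),
    estimate = as.vector(x$C),
    prior = rep(unname(x$prior), each = nrow(x$C))
  )
}

#' @rdname tidy.mnb_model
#' @export
glance.mnb_model <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$C), n_targets = ncol(x$C),
                 alpha = x$alpha, order = x$order,
                 event_model = x$event_model)
}

#' Tidy / summarise a score report
#'
#' @param x An `mnb_score`.
#' @param ... Unused.
#' @return `tidy()`: the per-target metric tibble. `glance()`: one row with
#'   the support-weighted total F1 and the number of scored targets.
#' @export
tidy.mnb_score <- function(x, ...) x$per_target

#' @rdname tidy.mnb_score
#' @export
glance.mnb_score <- function(x, ...) {
  tibble::tibble(total_f1 = x$total_f1, n_targets_scored = x$n_targets_scored)
}

#' Export model coefficients and priors as TSV
#'
#' @param model An `mnb_model`.
#' @param coef_path,prior_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_coefficients <- function(model, coef_path = NULL, prior_path = NULL) {
  if (!is.null(coef_path)) {
    tbl <- tidy(model)
    tbl$order <- model$order
    readr::write_tsv(
      dplyr::select(tbl, "feature", "target", C_db = "estimate", "order"),
      coef_path, progress = FALSE)
  }
  if (!is.null(prior_path)) {
    readr::write_tsv(tibble::tibble(target = names(model$prior),
                                    pi_db = unname(model$prior)),
                     prior_path, progress = FALSE)
  }
  invisible(c(coef_path, prior_path))
}
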