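#' Default penalty grid
#'
#' 25 log-spaced values spanning effectively-unpenalized (1e-4) to
#' effectively-null (1e4).
#' @export
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 25L)

# binary response from labels / factors / 0-1
.binary_y <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("tumor", "normal"))
    if (length(bad))
      stop("labels must be tumor/normal; found ",
           paste(bad, collapse = ", "), call. = FALSE)
    as.numeric(y == "tumor")
  } else as.numeric(y)
}

# column standardization used inside the fit; zero-variance columns get
# scale 1 (their centered values, hence coefficients, are identically 0)
.col_standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2L, ctr), 2L, scl, `/`), center = ctr, scale = scl)
}

# SVD reduction to the row space: Xs = U D V', Z = U D (n x r), beta = V gamma
.svd_reduce <- function(Xs) {
  sv <- svd(Xs)
  r <- sum(sv$d > max(sv$d[1L], 0) * 1e-10)
  if (r == 0L) r <- 1L
  list(Z = sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r),
       V = sv$v[, seq_len(r), drop = FALSE])
}

#' Fit an L2-penalized (ridge) logistic regression
#'
#' Minimizes the summed negative log-likelihood plus `lambda *
#' ||coefficients||^2` with an unpenalized intercept, by Newton/IRLS with
#' step halving (convergence when the max parameter change drops below `tol`,
#' cap `maxit` iterations). Columns are centered and scaled internally with
#' the training statistics, which are frozen into the model for prediction.
#' When p > n the problem is reduced exactly to the training row space by
#' SVD, so cost scales with n.
#'
#' @param X numeric matrix, n x p, one spectrum per row
#' @param y labels (`"tumor"`/`"normal"`), factor, or 0/1 (1 = tumor)
#' @param lambda penalty, >= 0
#' @param standardize center/scale columns internally (default TRUE)
#' @param maxit,tol IRLS controls
#' @return object of class `ridge_logistic`: intercept, coefficients (on the
#'   standardized column scale), lambda, converged, n_iter, column_centers,
#'   column_scales
#' @export
fit_ridge_logistic <- function(X, y, lambda, standardize = TRUE,
                               maxit = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- .binary_y(y)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y", call. = FALSE)
  if (standardize) {
    std <- .col_standardize(X)
  } else {
    std <- list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  p <- ncol(X)
  if (p > nrow(X)) {
    red <- .svd_reduce(std$X)
    fit <- .ridge_logistic_core(red$Z, y, lambda,
                                rep(0, ncol(red$Z) + 1L), maxit, tol)
    beta <- drop(red$V %*% fit$theta[-1L])
  } else {
    fit <- .ridge_logistic_core(std$X, y, lambda, rep(0, p + 1L), maxit, tol)
    beta <- fit$theta[-1L]
  }
  structure(list(intercept = fit$theta[1L], coefficients = beta,
                 lambda = lambda, converged = fit$converged,
                 n_iter = fit$n_iter, column_centers = std$center,
                 column_scales = std$scale),
            class = "ridge_logistic")
}

#' @rdname fit_ridge_logistic
#' @param object a fitted `ridge_logistic`
#' @param newdata matrix with the training columns
#' @param ... unused
#' @return `predict()` returns tumor probabilities in (0, 1)
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$column_centers),
              2L, object$column_scales, `/`)
  eta <- object$intercept + drop(Xs %*% object$coefficients)
  pmin(pmax(plogis(eta), 1e-15), 1 - 1e-15)
}

#' Select the ridge penalty by leave-one-out cross-validation
#'
#' For every grid value, each observation is left out in turn, the model is
#' refit on the remainder, and its predictive log-likelihood on the held-out
#' observation is accumulated; the grid maximizer is returned, ties broken
#' toward the larger (more penalized) lambda. Columns are standardized once
#' on the full training set and the problem reduced to its row space, within
#' which all leave-one-out refits are exact.
#'
#' @param X numeric matrix, n x p (n >= 3)
#' @param y labels as in [fit_ridge_logistic()]
#' @param grid non-empty vector of penalties
#' @param maxit,tol IRLS controls
#' @return selected lambda (numeric scalar) with attribute `cv_loglik`, the
#'   per-grid-value leave-one-out log-likelihoods
#' @export
select_lambda_loocv <- function(X, y, grid = default_lambda_grid(),
                                maxit = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- .binary_y(y)
  if (!length(grid)) stop("empty lambda grid", call. = FALSE)
  if (nrow(X) < 3L) stop("leave-one-out selection needs n >= 3", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y", call. = FALSE)
  grid <- sort(as.numeric(grid))
  std <- .col_standardize(X)
  Z <- if (ncol(X) > nrow(X)) .svd_reduce(std$X)$Z else std$X
  ll <- as.numeric(.ridge_loo_loglik_core(Z, y, grid, maxit, tol))
  if (all(!is.finite(ll))) stop("all penalty fits failed", call. = FALSE)
  best <- max(which(ll == max(ll, na.rm = TRUE)))   # ties -> larger lambda
  structure(grid[best], cv_loglik = setNames(ll, signif(grid, 6)))
}

#' Leave-group-out cross-validated tumor probabilities
#'
#' One fold per `sample_id` (cell or mouse): all of a sample's spectra are
#' held out together, the penalty is chosen by leave-one-out cross-validation
#' on the remaining samples only, the model is refit there, and each held-out
#' spectrum receives its out-of-fold tumor probability. Borderline and
#' unknown spectra are excluded from both training and testing. The call is
#' tumor iff probability is strictly greater than 0.5 (exactly 0.5 is
#' normal).
#'
#' @param set a standardized `raman_set` with >= 2 distinct sample ids
#' @param grid penalty grid for the inner selection
#' @param allow_degenerate if TRUE, folds whose training portion is
#'   single-class are skipped (their spectra get `NA` probabilities) instead
#'   of raising an error
#' @param return_models also return the per-fold fitted models
#' @return data.frame of class `cv_predictions`: spectrum_id, fold_group,
#'   true_label, probability, call, lambda_selected (+ attribute `models`
#'   when requested)
#' @export
leave_group_out_predict <- function(set, grid = default_lambda_grid(),
                                    allow_degenerate = FALSE,
                                    return_models = FALSE) {
  keep <- set$meta$label %in% c("tumor", "normal")
  X <- set$intensities[keep, , drop = FALSE]
  meta <- set$meta[keep, , drop = FALSE]
  if (length(unique(meta$label)) < 2L)
    stop("all labels identical; nothing to classify", call. = FALSE)
  groups <- unique(meta$sample_id)
  if (length(groups) < 2L)
    stop("leave-group-out needs >= 2 distinct sample ids", call. = FALSE)
  out <- vector("list", length(groups))
  models <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    test <- meta$sample_id == g
    ytr <- meta$label[!test]
    if (length(unique(ytr)) < 2L) {
      if (!allow_degenerate)
        stop("training portion for fold ", g, " is single-class", call. = FALSE)
      out[[gi]] <- data.frame(spectrum_id = meta$spectrum_id[test],
                              fold_group = g, true_label = meta$label[test],
                              probability = NA_real_, call = NA_character_,
                              lambda_selected = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    Xtr <- X[!test, , drop = FALSE]
    lam <- select_lambda_loocv(Xtr, ytr, grid)
    fit <- fit_ridge_logistic(Xtr, ytr, as.numeric(lam))
    prob <- predict(fit, X[test, , drop = FALSE])
    if (return_models) models[[g]] <- fit
    out[[gi]] <- data.frame(spectrum_id = meta$spectrum_id[test],
                            fold_group = g, true_label = meta$label[test],
                            probability = prob,
                            call = ifelse(prob > 0.5, "tumor", "normal"),
                            lambda_selected = as.numeric(lam),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cv_predictions", "data.frame")
  if (return_models) attr(res, "models") <- models
  res
}

# round half-up to one decimal, for percentage reporting
.round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Confusion-matrix metrics for cross-validated calls
#'
#' Tumor is the positive class. Sensitivity = tp / (tp + fn), specificity =
#' tn / (tn + fp); the `_pct` fields are percentages rounded half-up to one
#' decimal. Borderline labels must have been excluded upstream.
#'
#' @param preds a `cv_predictions` data.frame (columns true_label, call), or
#'   omitted when the four counts are given directly
#' @param tp,fn,tn,fp confusion counts (alternative input)
#' @return list of class `confusion_metrics`
#' @export
confusion_metrics <- function(preds = NULL, tp = NULL, fn = NULL, tn = NULL,
                              fp = NULL) {
  if (!is.null(preds)) {
    if (!nrow(preds)) stop("no predictions", call. = FALSE)
    if (any(!preds$true_label %in% c("tumor", "normal")))
      stop("borderline/unknown labels present; exclude them upstream",
           call. = FALSE)
    ok <- !is.na(preds$call)
    tp <- sum(preds$true_label[ok] == "tumor" & preds$call[ok] == "tumor")
    fn <- sum(preds$true_label[ok] == "tumor" & preds$call[ok] == "normal")
    tn <- sum(preds$true_label[ok] == "normal" & preds$call[ok] == "normal")
    fp <- sum(preds$true_label[ok] == "normal" & preds$call[ok] == "tumor")
  }
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = .round_half_up1(100 * sens),
                 specificity_pct = .round_half_up1(100 * spec)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d tn=%d fp=%d\nsensitivity %.1f%%  specificity %.1f%%\n",
              x$tp, x$fn, x$tn, x$fp, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}
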