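# Internal IRLS for logistic regression on a design matrix already
# containing the intercept column. Returns beta, convergence flag, number
# of iterations. `ridge` adds an L2 penalty (never on the intercept).
logit_irls <- function(X, y, ridge = 0, max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(ridge, p - 1)), nrow = p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X, X * w) + pen
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    beta <- beta + step
    if (any(!is.finite(beta))) return(NULL)
    if (max(abs(score)) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged, iter = iter)
}

#' Fit a logistic model on miRNA features
#'
#' Maximum-likelihood logistic regression of a binary outcome on one or
#' more continuous features (e.g. log2 miR-16-normalized qPCR levels or
#' normalized log2 counts). Features are z-scored internally — which makes
#' every prediction invariant to positive affine rescaling of a feature —
#' and coefficients are reported back on the original scale. Under complete
#' separation the unpenalized likelihood has no maximum; the fit is then
#' stabilized with a tiny L2 ridge (1e-4 on the standardized scale) and
#' `converged` is recorded as `FALSE`. Zero-variance features get a zero
#' coefficient.
#'
#' @param data Data frame with the outcome and feature columns.
#' @param outcome Name of a binary column (logical, or a factor/character
#'   whose positive level is `"relapsed"`/`TRUE`).
#' @param features Character vector of feature column names.
#' @return Object of class `circmir_logit` with elements `intercept`,
#'   `coefficients`, `converged`, `n_iterations`, and the standardization
#'   parameters used for prediction.
#' @export
fit_logistic <- function(data, outcome, features) {
  y <- as_binary_outcome(data[[outcome]])
  if (length(unique(y)) < 2) abort("Outcome has a single class.")
  if (length(features) < 1) abort("At least one feature is required.")
  Xraw <- as.matrix(data[features])
  if (any(!is.finite(Xraw))) abort("Non-finite feature values.")
  center <- colMeans(Xraw)
  scale <- apply(Xraw, 2, sd)
  keep <- scale > 0
  scale[!keep] <- 1
  Z <- sweep(sweep(Xraw, 2, center), 2, scale, `/`)
  if (sum(keep) == 0) {
    # intercept-only: closed form, logit of prevalence
    fit <- list(beta = qlogis(mean(y)), converged = TRUE, iter = 0L)
  } else {
    X <- cbind(1, Z[, keep, drop = FALSE])
    fit <- logit_irls(X, y)
    separated <- is.null(fit) || !fit$converged ||
      max(abs(fit$beta[-1])) > 15
    if (separated) {
      fit <- logit_irls(X, y, ridge = 1e-4)
      if (is.null(fit)) abort("Logistic fit failed.")
      fit$converged <- FALSE
    }
  }
  bz <- rep(0, length(features))
  names(bz) <- features
  bz[keep] <- fit$beta[-1]
  coefs <- bz / scale
  intercept <- unname(fit$beta[1]) - sum(bz * center / scale)
  structure(list(intercept = intercept,
                 coefficients = coefs,
                 converged = fit$converged,
                 n_iterations = fit$iter,
                 features = features,
                 center = center, scale = scale,
                 std_beta = c(fit$beta[1], bz)),
            class = "circmir_logit")
}

as_binary_outcome <- function(v) {
  if (is.logical(v)) return(as.numeric(v))
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) abort("Numeric outcome must be 0/1.")
    return(v)
  }
  v <- as.character(v)
  lev <- sort(unique(v))
  if (length(lev) > 2) abort("Outcome must be binary.")
  pos <- if ("relapsed" %in% lev) "relapsed" else lev[length(lev)]
  as.numeric(v == pos)
}

#' Predict relapse probabilities from a fitted logistic model
#'
#' @param object A `circmir_logit` fit.
#' @param newdata Data frame holding the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.circmir_logit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  eta <- object$intercept + drop(X %*% object$coefficients)
  plogis(eta)
}

#' @export
print.circmir_logit <- function(x, ...) {
  cat("Logistic miRNA signature fit\n")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  for (f in x$features) {
    cat("  ", f, ":", format(x$coefficients[[f]], digits = 4), "\n")
  }
  cat("  converged:", x$converged, "in", x$n_iterations, "iterations\n")
  invisible(x)
}

#' Training-error-minimizing probability cutoff
#'
#' Scans candidate cutoffs — the midpoints between consecutive distinct
#' sorted predicted probabilities, plus one boundary candidate below the
#' smallest and one above the largest probability — and returns the cutoff
#' minimizing the training misclassification count, where a sample is
#' called positive when its probability is strictly greater than the
#' cutoff. Ties are broken toward the candidate with the largest margin to
#' the nearest probability, then toward the smallest cutoff.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Binary observed labels (see [fit_logistic()] coding).
#' @return List with `cutoff` (in (0, 1)) and `training_error`
#'   (misclassified count).
#' @export
choose_cutoff <- function(probabilities, labels) {
  y <- as_binary_outcome(labels)
  p <- probabilities
  if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  u <- sort(unique(p))
  cand <- c(min(u) / 2,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            (max(u) + 1) / 2)
  cand <- cand[cand > 0 & cand < 1]
  err <- vapply(cand, function(ct) sum((p > ct) != y), numeric(1))
  margin <- vapply(cand, function(ct) min(abs(ct - u)), numeric(1))
  best <- order(err, -margin, cand)[1]
  list(cutoff = cand[best], training_error = as.integer(err[best]))
}

#' Leave-one-out cross-validated signature classification
#'
#' For each sample, fits the logistic model and the training-error cutoff
#' on the remaining samples and predicts the held-out sample as
#' `"relapsed"` when its predicted probability exceeds that fold's cutoff.
#' No fold sees the held-out label. A fold whose training set degenerates
#' to a single class predicts the training-set majority and is flagged.
#'
#' @param data Data frame with `sample`, outcome and feature columns.
#' @param outcome Binary outcome column name.
#' @param features Feature column names.
#' @return Tibble of class `circmir_loocv`: `sample`, `observed`,
#'   `probability`, `cutoff`, `predicted` (`"relapsed"`/`"non-relapsed"`),
#'   `flagged`.
#' @export
loocv_classify <- function(data, outcome, features) {
  n <- nrow(data)
  if (n < 4) abort("LOOCV needs at least 4 samples.")
  y <- as_binary_outcome(data[[outcome]])
  res <- purrr::map_dfr(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      maj <- mean(ytr) > 0.5
      return(tibble(probability = as.numeric(maj), cutoff = NA_real_,
                    predicted_pos = maj, flagged = TRUE))
    }
    fit <- fit_logistic(train, outcome, features)
    ct <- choose_cutoff(predict(fit, train), ytr)
    pr <- predict(fit, data[i, , drop = FALSE])
    tibble(probability = pr, cutoff = ct$cutoff,
           predicted_pos = pr > ct$cutoff, flagged = FALSE)
  })
  out <- tibble(
    sample = data$sample %||% sprintf("S%02d", seq_len(n)),
    observed = ifelse(y == 1, "relapsed", "non-relapsed"),
    probability = res$probability,
    cutoff = res$cutoff,
    predicted = ifelse(res$predicted_pos, "relapsed", "non-relapsed"),
    flagged = res$flagged
  )
  class(out) <- c("circmir_loocv", class(out))
  out
}

#' Train on a full cohort, predict an external cohort
#'
#' Fits one logistic model and one training-error cutoff on the entire
#' training cohort and applies them unchanged to every test sample; test
#' features are standardized with the training parameters (handled inside
#' the fitted model).
#'
#' @param train Training data frame (outcome + features).
#' @param test Test data frame holding the same feature columns.
#' @param outcome Binary outcome column name in `train`.
#' @param features Feature column names.
#' @return Tibble `sample`, `probability`, `cutoff`, `predicted`, with the
#'   fitted model in attribute `model` and cutoff in attribute `cutoff`.
#' @export
train_full_predict_external <- function(train, test, outcome, features) {
  if (!all(features %in% names(test))) {
    abort("Test set is missing model features.")
  }
  fit <- fit_logistic(train, outcome, features)
  ct <- choose_cutoff(predict(fit, train),
                      as_binary_outcome(train[[outcome]]))
  if (nrow(test) == 0) {
    out <- tibble(sample = character(), probability = numeric(),
                  cutoff = numeric(), predicted = character())
  } else {
    pr <- predict(fit, test)
    out <- tibble(
      sample = test$sample %||% sprintf("T%02d", seq_len(nrow(test))),
      probability = pr,
      cutoff = ct$cutoff,
      predicted = ifelse(pr > ct$cutoff, "relapsed", "non-relapsed")
    )
  }
  attr(out, "model") <- fit
  attr(out, "cutoff") <- ct
  out
}
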