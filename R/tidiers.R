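# broom-style tidiers for fitted objects.

#' @method tidy circmir_logit
#' @export
tidy.circmir_logit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$features),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @method glance circmir_logit
#' @export
glance.circmir_logit <- function(x, ...) {
  tibble(converged = x$converged, n_iterations = x$n_iterations,
         n_features = length(x$features))
}

#' @method tidy circmir_loocv
#' @export
tidy.circmir_loocv <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Performance summary of a LOOCV classification
#'
#' Confusion counts, sensitivity, specificity, accuracy and the Youden
#' index (`sensitivity + specificity - 1`) of the cross-validated
#' predictions.
#'
#' @param x A `circmir_loocv` result.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance circmir_loocv
#' @export
glance.circmir_loocv <- function(x, ...) {
  ct <- confusion_table(x$observed, x$predicted)
  cm <- confusion_metrics(ct)
  tibble(tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         accuracy = (ct$tp + ct$tn) / nrow(x),
         youden = cm$sensitivity + cm$specificity - 1)
}

#' @method tidy circmir_da
#' @export
tidy.circmir_da <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance circmir_da
#' @export
glance.circmir_da <- function(x, ...) {
  tibble(contrast = attr(x, "contrast"), level_g1 = attr(x, "level_g1"),
         dispersion = attr(x, "phi"), n_genes = nrow(x),
         n_fdr_0.1 = sum(x$fdr < 0.1, na.rm = TRUE),
         n_fdr_0.05 = sum(x$fdr < 0.05, na.rm = TRUE))
}
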