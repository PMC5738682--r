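#' Fit a logistic-regression methylation panel
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary disease label on the panel's
#' beta values. The reported `deviance` is minus twice the maximized
#' log-likelihood (for Bernoulli data the saturated log-likelihood is zero).
#' Quasi-complete separation is flagged when any coefficient magnitude
#' exceeds `separation_bound` at the end of fitting; separated or
#' non-converged fits are retained but never auto-selected by
#' [rank_models()].
#'
#' @param features Data frame or matrix, samples x features (no missing
#'   values; impute or drop upstream).
#' @param labels 0/1 outcome per sample (both classes must be present).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param ridge Optional non-negative ridge penalty on the slopes (the
#'   intercept is never penalised); 0 (default) is plain maximum likelihood.
#'   A small positive value stabilises separated fits.
#' @param separation_bound Coefficient magnitude flagging separation
#'   (default 15 on the logit scale).
#' @return Object of class `panel_logit`: feature names, intercept,
#'   coefficients, deviance, null_deviance, converged, separation_detected,
#'   n.
#' @export
fit_logistic <- function(features, labels, max_iter = 100, tol = 1e-8,
                         ridge = 0, separation_bound = 15) {
  X <- as.matrix(features)
  if (is.null(colnames(X)) && ncol(X)) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) abort("`labels` must be 0/1.")
  if (length(unique(y)) < 2) abort("both classes must be present in `labels`.")
  if (nrow(X) && ncol(X) && anyNA(X)) abort("missing feature values; impute or drop upstream.")
  stopifnot(length(y) == max(nrow(X), length(y)))

  if (ridge > 0) {
    rfit <- ridge_logistic_irls(X, y, lambda = ridge,
                                max_iter = max_iter, tol = tol)
    intercept <- rfit$intercept
    beta <- stats::setNames(rfit$coefficients, colnames(X))
    dev <- rfit$deviance
    converged <- rfit$converged
    null_dev <- null_deviance(y)
  } else {
    df <- data.frame(.y = y, X, check.names = FALSE)
    fit <- stats::glm(
      .y ~ ., data = df, family = stats::binomial(),
      control = stats::glm.control(epsilon = tol, maxit = max_iter)
    )
    cf <- stats::coef(fit)
    if (anyNA(cf)) abort("collinear features: coefficients not estimable (consider `ridge`).")
    intercept <- unname(cf[1])
    beta <- cf[-1]
    names(beta) <- colnames(X)
    dev <- fit$deviance
    null_dev <- fit$null.deviance
    converged <- fit$converged
  }
  structure(
    list(
      features = colnames(X), intercept = intercept,
      coefficients = beta, deviance = dev, null_deviance = null_dev,
      converged = converged,
      separation_detected = any(abs(beta) > separation_bound) ||
        abs(intercept) > separation_bound,
      n = length(y), prevalence = mean(y)
    ),
    class = "panel_logit"
  )
}

null_deviance <- function(y) {
  p <- mean(y)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# penalized IRLS: quadratic (ridge) penalty on slopes only, intercept free;
# reported deviance is the unpenalized -2 log-likelihood at the solution
ridge_logistic_irls <- function(X, y, lambda, max_iter = 100, tol = 1e-8) {
  Xa <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xa)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  b <- rep(0, p)
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xa * w)
    b <- drop(solve(XtW %*% Xa + pen, XtW %*% z))
    new_dev <- -2 * sum(y * log(pmax(stats::plogis(drop(Xa %*% b)), 1e-300)) +
                          (1 - y) * log(pmax(1 - stats::plogis(drop(Xa %*% b)), 1e-300)))
    if (abs(dev - new_dev) / (abs(new_dev) + 0.1) < tol) {
      converged <- TRUE
      dev <- new_dev
      break
    }
    dev <- new_dev
  }
  list(intercept = b[1], coefficients = b[-1], deviance = dev,
       converged = converged)
}

#' @export
print.panel_logit <- function(x, ...) {
  cat("<panel_logit>", length(x$features), "features, n =", x$n, "\n")
  cat("  deviance:", format(x$deviance, digits = 4),
      "(null:", format(x$null_deviance, digits = 4), ")\n")
  if (x$separation_detected) cat("  note: separation detected\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted methylation panel
#' @param x A `panel_logit`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept first).
#' @method tidy panel_logit
#' @export
tidy.panel_logit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$features),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' One-row model summary of a fitted methylation panel
#' @param x A `panel_logit`.
#' @param ... Unused.
#' @return One-row tibble: deviance, null_deviance, df, n, converged,
#'   separation_detected.
#' @method glance panel_logit
#' @export
glance.panel_logit <- function(x, ...) {
  tibble(
    deviance = x$deviance, null_deviance = x$null_deviance,
    df = length(x$features), n = x$n,
    converged = x$converged, separation_detected = x$separation_detected
  )
}

#' Likelihood-ratio test between nested logistic panels
#'
#' The statistic is the deviance difference between the reduced and the full
#' model, referred to a chi-square distribution with degrees of freedom
#' equal to the difference in feature counts.
#'
#' @param full,reduced `panel_logit` fits on the same samples; the reduced
#'   feature set must be a subset of the full one.
#' @return One-row tibble: statistic, df, p_value.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "panel_logit"), inherits(reduced, "panel_logit"))
  if (!all(reduced$features %in% full$features) || full$n != reduced$n) {
    abort("models are not nested on the same samples.")
  }
  df <- length(full$features) - length(reduced$features)
  stat <- max(0, reduced$deviance - full$deviance)
  tibble(
    statistic = stat, df = df,
    p_value = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Predicted disease probabilities from a fitted panel
#'
#' @param model A `panel_logit`.
#' @param features Data frame or matrix containing (at least) the model's
#'   feature columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "panel_logit"))
  X <- as.matrix(as.data.frame(features)[, model$features, drop = FALSE])
  as.numeric(stats::plogis(model$intercept + X %*% model$coefficients))
}

#' Fit and rank candidate feature sets
#'
#' Fits a logistic panel for every candidate feature set on the training
#' beta values and ranks by ascending deviance (stronger likelihood first),
#' breaking ties by fewer features and then by lexicographic roster.
#' Non-converged fits are reported but ranked after all converged ones and
#' excluded from the top-k selection.
#'
#' @param candidates A `candidate_sets` tibble from
#'   [enumerate_candidate_sets()].
#' @param beta Beta tibble holding the training samples.
#' @param labels 0/1 outcome aligned with the sample columns of `beta`.
#' @param top How many models to mark as selected (default 3).
#' @param ... Passed to [fit_logistic()].
#' @return Tibble of class `ranked_models`: rank, set_id, probes, size,
#'   deviance, null_deviance, lrt_vs_null_p, converged,
#'   separation_detected, selected, model (list-column of `panel_logit`).
#' @export
rank_models <- function(candidates, beta, labels, top = 3, ...) {
  stopifnot(nrow(candidates) >= 1)
  m <- t(beta_to_matrix(beta))
  fits <- purrr::map(candidates$probes, function(probes) {
    tryCatch(fit_logistic(m[, probes, drop = FALSE], labels, ...),
             error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  if (all(failed)) abort("all candidate fits failed.")
  if (any(failed)) {
    warn(sprintf("%d candidate fit(s) failed and were dropped.", sum(failed)))
  }
  keep <- which(!failed)
  fits <- fits[keep]
  out <- tibble(
    set_id = candidates$set_id[keep],
    probes = candidates$probes[keep],
    size = lengths(candidates$probes[keep]),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    null_deviance = vapply(fits, `[[`, numeric(1), "null_deviance"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    separation_detected = vapply(fits, `[[`, logical(1), "separation_detected"),
    model = fits
  )
  roster_key <- vapply(out$probes, paste, character(1), collapse = "|")
  ord <- order(!out$converged, out$deviance, out$size, roster_key)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$lrt_vs_null_p <- stats::pchisq(
    pmax(0, out$null_deviance - out$deviance), df = out$size, lower.tail = FALSE
  )
  out$selected <- out$rank <= top & out$converged
  out <- out[, c("rank", "set_id", "probes", "size", "deviance",
                 "null_deviance", "lrt_vs_null_p", "converged",
                 "separation_detected", "selected", "model")]
  class(out) <- c("ranked_models", class(out))
  out
}
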