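#' Fit a micronucleus time-course model by weighted nonlinear least squares
#'
#' Fits one of the four candidate production--decay curves to individual
#' animal-by-day MN/BN observations, minimizing the weighted residual sum of
#' squares with weights from [compute_weights()] (inverse day-level SEM
#' squared, normalized to mean 1). Optimization uses bound-constrained
#' Levenberg--Marquardt with an analytic Jacobian, restarted from a
#' deterministic Latin-hypercube grid of starting points; the best local
#' optimum by weighted RSS is returned.
#'
#' The reported log-likelihood follows the weighted Gaussian convention with
#' the residual variance profiled out,
#' `loglik = 0.5 * sum(log w) - (n/2) * (log(2*pi) + 1 - log(n) + log(RSS_w))`,
#' and `aic = 2 * (k + 1) - 2 * loglik`, where the `+1` counts the estimated
#' residual scale. This matches the convention of `stats::nls`, so AIC-based
#' rankings are comparable with fits from that function.
#'
#' @param table MN table (data frame with `animal`, `day`, `bn`, `mn`);
#'   days `<= 0` are remapped to 0 before fitting.
#' @param spec Model name, one of [mn_model_names()].
#' @param starts Optional numeric matrix of extra starting points (columns
#'   named as the model's parameters), tried in addition to the
#'   Latin-hypercube grid.
#' @param seed Integer seed controlling the Latin-hypercube start grid.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param weights Optional data frame from [compute_weights()]; computed from
#'   `table` when missing.
#' @return An object of class `mn_fit`: a list with elements `spec`, `coef`
#'   (named vector of the model's free parameters), `params` (the full
#'   five-parameter set when the model is expressible in it, else `NULL`),
#'   `aic`, `loglik`, `rse` (weighted residual standard error,
#'   `sqrt(RSS_w / (n - k))`), `cov` (parameter covariance), `n_obs`,
#'   `converged`, `n_starts_tried`, plus the data used.
#' @seealso [compare_models()], [predict_curve()], [fit_mn_mixed()]
#' @export
fit_mn <- function(table, spec = "M3_mixture", starts = NULL, seed = 1L,
                   n_starts = 16L, weights = NULL) {
  model <- .get_model(spec)
  table <- validate_mn_table(table)
  day <- pmax(table$day, 0)
  y <- table$mn / table$bn
  n <- length(y)
  if (n < model$k + 2L || length(unique(day)) < 3L)
    stop("need at least k + 2 observations spanning >= 3 distinct days", call. = FALSE)
  if (is.null(weights)) weights <- compute_weights(table)
  w <- weights$weight
  sw <- sqrt(w)

  box <- .start_box(model, y)
  start_mat <- .lhs_starts(model, box, n_starts, seed)
  if (!is.null(starts)) {
    starts <- as.matrix(starts)
    if (!all(model$pars %in% colnames(starts)))
      stop("'starts' must have columns ", paste(model$pars, collapse = ", "), call. = FALSE)
    start_mat <- rbind(start_mat, starts[, model$pars, drop = FALSE])
  }

  resid_fn <- function(par) { names(par) <- model$pars; sw * (y - model$f(par, day)) }
  jac_fn <- function(par) { names(par) <- model$pars; -sw * model$grad(par, day) }

  best <- NULL
  for (i in seq_len(nrow(start_mat))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start_mat[i, ], lower = box$lower, upper = box$upper,
        fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed for model ", model$name, call. = FALSE)

  coefs <- stats::setNames(as.numeric(best$par), model$pars)
  rss_w <- best$deviance
  k <- model$k
  rse <- sqrt(rss_w / (n - k))
  loglik <- 0.5 * sum(log(w)) - (n / 2) * (log(2 * pi) + 1 - log(n) + log(rss_w))
  aic <- 2 * (k + 1) - 2 * loglik
  J <- jac_fn(coefs)
  cov <- tryCatch(rse^2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, k, k))
  dimnames(cov) <- list(model$pars, model$pars)
  converged <- best$info %in% 1:4

  structure(list(
    spec = model$name, coef = coefs, params = .full_params(model$name, coefs),
    aic = aic, loglik = loglik, rse = rse, cov = cov,
    n_obs = n, converged = converged,
    n_starts_tried = nrow(start_mat), rss_w = rss_w,
    data = data.frame(day = day, y = y, weight = w)),
    class = "mn_fit")
}

# Parameter bounds and the (narrower) box the multistart samples from.
.start_box <- function(model, y) {
  ymax <- max(y, 1e-6)
  lims <- list(
    C     = c(0, 2 * ymax,        0, ymax),
    Kprod = c(0, 50 * ymax,       1e-3 * ymax, 5 * ymax),
    Kdec1 = c(0, 5,               1e-3, 1),
    Kdec2 = c(0, 1,               1e-5, 0.1),
    P     = c(0, 1,               0.05, 0.95))
  m <- do.call(rbind, lims[model$pars])
  list(lower = m[, 1], upper = m[, 2], s_lower = m[, 3], s_upper = m[, 4])
}

.lhs_starts <- function(model, box, n_starts, seed) {
  k <- model$k
  u <- with_local_seed(seed, lhs::randomLHS(n_starts, k))
  m <- sweep(sweep(u, 2, box$s_upper - box$s_lower, `*`), 2, box$s_lower, `+`)
  colnames(m) <- model$pars
  m
}

#' @export
print.mn_fit <- function(x, ...) {
  cat("Micronucleus time-course fit:", x$spec, "\n")
  cat(sprintf("  n = %d, converged = %s (%d starts)\n",
              x$n_obs, x$converged, x$n_starts_tried))
  print(round(x$coef, 6))
  cat(sprintf("  weighted RSE = %.4g  logLik = %.4g  AIC = %.4g\n",
              x$rse, x$loglik, x$aic))
  invisible(x)
}

#' Compare candidate micronucleus models by AIC
#'
#' Fits each requested model to the same table and ranks the fits by AIC
#' (ascending). Ties are broken toward the model with fewer parameters, then
#' lexicographically by name; the ranking is therefore deterministic and
#' invariant to the order in which the specs are supplied.
#'
#' @inheritParams fit_mn
#' @param specs Character vector of model names (>= 2).
#' @return A list of `mn_fit` objects sorted by AIC, with attribute
#'   `"ranking"`: a data frame of model, k, aic, rse, converged.
#' @export
compare_models <- function(table, specs = mn_model_names(), seed = 1L,
                           n_starts = 16L) {
  if (length(specs) < 2L) stop("need at least 2 model specs", call. = FALSE)
  weights <- compute_weights(table)
  fits <- list(); failed <- character()
  for (s in specs) {
    f <- tryCatch(fit_mn(table, s, seed = seed, n_starts = n_starts, weights = weights),
                  error = function(e) NULL)
    if (is.null(f)) failed <- c(failed, s) else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("all model fits failed", call. = FALSE)
  if (length(failed) > 0L)
    warning("model(s) failed to fit and were excluded: ",
            paste(failed, collapse = ", "), call. = FALSE)
  k <- vapply(fits, function(f) .get_model(f$spec)$k, integer(1))
  nm <- vapply(fits, function(f) f$spec, character(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aic, k, nm)
  fits <- fits[ord]
  attr(fits, "ranking") <- data.frame(
    model = nm[ord], k = k[ord], aic = aic[ord],
    rse = vapply(fits, function(f) f$rse, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  fits
}

#' Evaluate a fitted curve on a day grid
#'
#' @param fit An `mn_fit` object from [fit_mn()].
#' @param days Numeric vector of non-negative days.
#' @return Data frame with columns `day` and `pred`.
#' @export
predict_curve <- function(fit, days) {
  if (!inherits(fit, "mn_fit")) stop("'fit' must be an mn_fit object", call. = FALSE)
  if (!fit$converged) stop("fit did not converge; refusing to predict", call. = FALSE)
  if (any(days < 0)) stop("'days' must be non-negative", call. = FALSE)
  model <- .get_model(fit$spec)
  data.frame(day = days, pred = model$f(fit$coef, days))
}
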