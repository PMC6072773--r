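#' Hill dose-response model for PGE2 decrease vs. pain relief
#'
#' `evaluate_hill` computes `y = a * x^b / (c^b + x^b)`: `a` is the
#' asymptotic pain-relief difference, `b` the Hill exponent and `c` the
#' PGE2 decrease at half-maximal effect.
#'
#' @param params named list/vector with `a`, `b`, `c` (all > 0).
#' @param x PGE2 decrease values (>= 0).
#' @return predicted pain-relief difference.
#' @export
evaluate_hill <- function(params, x) {
  a <- params[["a"]]; b <- params[["b"]]; cc <- params[["c"]]
  stopifnot(a > 0, b > 0, cc > 0, all(x >= 0))
  xb <- x^b
  ifelse(x == 0, 0, a * xb / (cc^b + xb))
}

#' Fit the Hill model by multi-start nonlinear least squares
#'
#' Point estimates come from Levenberg-Marquardt least squares
#' (`minpack.lm::nlsLM`) started from a deterministic grid of initial
#' values; 95% confidence intervals come from a seeded parametric
#' bootstrap (refitting data resampled from the fitted curve plus
#' Gaussian residual noise).
#'
#' @param pairs data.frame with columns `x` (PGE2 decrease, >= 0) and `y`
#'   (pain relief minus placebo).
#' @param n_starts number of multi-start initialisations.
#' @param seed RNG seed for the bootstrap.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @return an object of class `hill_fit` with `estimate`, `ci` (matrix),
#'   `r_squared`, `aic`, `rmse`, `n_boot`, and the `nls` fit object.
#' @export
fit_hill <- function(pairs, n_starts = 24, seed = 1, n_boot = 1000,
                     conf = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[, c("x", "y")]), ]
  if (nrow(pairs) < 5)
    stop("fit_hill: need at least 5 (x, y) pairs", call. = FALSE)
  if (any(pairs$x < 0))
    stop("fit_hill: x (PGE2 decrease) must be >= 0", call. = FALSE)
  if (stats::sd(pairs$x) == 0)
    stop("fit_hill: x values are all equal; model unidentifiable",
         call. = FALSE)
  if (stats::sd(pairs$y) < 1e-12)
    stop("fit_hill: constant y; model unidentifiable", call. = FALSE)

  fit <- best_hill_fit(pairs, n_starts)
  if (is.null(fit$fit))
    stop("fit_hill: no start converged; best residual sum of squares ",
         signif(fit$best_rss, 4), call. = FALSE)
  est <- stats::coef(fit$fit)
  pred <- evaluate_hill(as.list(est), pairs$x)
  rss <- sum((pairs$y - pred)^2)
  tss <- sum((pairs$y - mean(pairs$y))^2)
  n <- nrow(pairs)

  # parametric bootstrap CIs
  sigma <- sqrt(rss / max(n - 3, 1))
  set.seed(seed)
  ci <- matrix(NA_real_, nrow = 3, ncol = 2,
               dimnames = list(c("a", "b", "c"), c("lower", "upper")))
  n_ok <- 0
  if (n_boot > 0) {
    boots <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                    dimnames = list(NULL, c("a", "b", "c")))
    for (i in seq_len(n_boot)) {
      yb <- pred + stats::rnorm(n, 0, sigma)
      fb <- best_hill_fit(data.frame(x = pairs$x, y = yb),
                          n_starts = 4, start_at = est)
      if (!is.null(fb$fit)) boots[i, ] <- stats::coef(fb$fit)
    }
    ok <- stats::complete.cases(boots)
    n_ok <- sum(ok)
    alpha <- (1 - conf) / 2
    ci <- t(apply(boots[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(alpha, 1 - alpha), na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
  }

  structure(list(
    estimate = est, ci = ci, n = n,
    r_squared = 1 - rss / tss,
    aic = stats::AIC(fit$fit),
    rmse = sqrt(rss / n),
    sigma = sigma, n_boot = n_ok, conf = conf,
    fit = fit$fit, model = "hill"),
    class = "hill_fit")
}

# multi-start nlsLM; deterministic start grid, optionally seeded near
# `start_at` (used inside the bootstrap).  internal
best_hill_fit <- function(pairs, n_starts, start_at = NULL) {
  a0 <- max(pairs$y)
  if (a0 <= 0) a0 <- max(abs(pairs$y), 1e-3)
  c0 <- stats::median(pairs$x[pairs$x > 0])
  grid <- expand.grid(a = a0 * c(0.8, 1.0, 1.3),
                      b = c(1, 2, 4, 8),
                      c = c0 * c(0.5, 1, 2))
  if (!is.null(start_at)) grid <- rbind(as.data.frame(as.list(start_at)),
                                        grid)
  grid <- utils::head(grid, n_starts)
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(grid))) {
    st <- as.list(grid[i, ])
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ a * x^b / (c^b + x^b), data = pairs, start = st,
      lower = c(a = 1e-9, b = 1e-3, c = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (!inherits(f, "try-error")) {
      rss <- sum(stats::residuals(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
    }
  }
  list(fit = best, best_rss = best_rss)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> y = a*x^b/(c^b + x^b)\n")
  for (p in c("a", "b", "c"))
    cat(sprintf("  %s = %.4g  %g%% CI (%.4g, %.4g)\n", p, x$estimate[[p]],
                100 * x$conf, x$ci[p, "lower"], x$ci[p, "upper"]))
  cat(sprintf("  R^2 = %.4f, AIC = %.2f, RMSE = %.4g (n = %d)\n",
              x$r_squared, x$aic, x$rmse, x$n))
  invisible(x)
}

#' Compare candidate correlation models by information criteria
#'
#' Fits each candidate to the pairs and ranks them by AIC, reporting R^2
#' and RMSE alongside.  Candidates: `"hill"` (3 parameters), `"emax"`
#' (Hill with exponent fixed at 1), `"linear"` (straight line through the
#' origin plus intercept).
#'
#' @param pairs data.frame with `x` and `y` columns.
#' @param candidates character vector of model names.
#' @param ... passed to [fit_hill()] for the Hill candidate (the other
#'   candidates need no tuning).
#' @return data.frame ranked by AIC with columns `model`, `aic`,
#'   `r_squared`, `rmse`, `converged`, `delta_aic`.
#' @export
compare_models <- function(pairs, candidates = c("hill", "emax", "linear"),
                           ...) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(mod) {
    res <- try(switch(
      mod,
      hill = {
        f <- fit_hill(pairs, n_boot = 0, ...)
        c(aic = f$aic, r2 = f$r_squared, rmse = f$rmse)
      },
      emax = {
        f <- minpack.lm::nlsLM(y ~ a * x / (c + x), data = pairs,
                               start = list(a = max(pairs$y), c =
                                              stats::median(pairs$x)),
                               lower = c(a = 1e-9, c = 1e-9))
        rss <- sum(stats::residuals(f)^2)
        c(aic = stats::AIC(f),
          r2 = 1 - rss / sum((pairs$y - mean(pairs$y))^2),
          rmse = sqrt(rss / nrow(pairs)))
      },
      linear = {
        f <- stats::lm(y ~ x, data = pairs)
        rss <- sum(stats::residuals(f)^2)
        c(aic = stats::AIC(f),
          r2 = summary(f)$r.squared,
          rmse = sqrt(rss / nrow(pairs)))
      },
      stop("compare_models: unknown candidate '", mod, "'",
           call. = FALSE)), silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(model = mod, aic = NA_real_, r_squared = NA_real_,
                 rmse = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(model = mod, aic = res[["aic"]], r_squared = res[["r2"]],
                 rmse = res[["rmse"]], converged = TRUE,
                 stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(!tab$converged, tab$aic), ]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  rownames(tab) <- NULL
  tab
}

#' Export a Hill fit report as JSON
#' @param fit a `hill_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_hill_json <- function(fit, path) {
  out <- list(model = fit$model,
              estimate = as.list(fit$estimate),
              ci = apply(fit$ci, 1, as.list),
              r_squared = fit$r_squared, aic = fit$aic, rmse = fit$rmse,
              n = fit$n, n_boot = fit$n_boot, conf = fit$conf)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
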