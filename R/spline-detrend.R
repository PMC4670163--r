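#' Sliding-window estimate of the noise variance
#'
#' The spline-fit tolerance sigma^2 is estimated as the mean of the
#' sample variances over a sliding (stride-1, overlapping) window of
#' `window` age-ordered data points. Variances are computed on the raw
#' values without local detrending, so steep trends inflate the
#' estimate; that bias is intentional — it is what makes the estimate a
#' usable upper bound for the spline's mean squared error.
#'
#' @param values numeric vector of expression values sorted by age, or
#'   a profile tibble with `age_pcd` and `value` columns (sorted
#'   internally).
#' @param window window width in data points; default 10. Profiles
#'   shorter than the window fall back to a single window of all points
#'   (with a warning).
#' @return the estimated noise variance (>= 0).
#' @export
estimate_noise_variance <- function(values, window = 10) {
  if (is.data.frame(values)) {
    values <- values$value[order(values$age_pcd)]
  }
  n <- length(values)
  if (n < 3) stop("need at least 3 samples to estimate a noise variance",
                  call. = FALSE)
  if (n < window) {
    warning("profile shorter than the window (", n, " < ", window,
            "): using a single window of all points", call. = FALSE)
    window <- n
  }
  starts <- seq_len(n - window + 1)
  mean(vapply(starts, function(s) stats::var(values[s:(s + window - 1)]),
              numeric(1)))
}

.age_x <- function(age_pcd, age_transform) {
  switch(age_transform, log2 = log2(age_pcd), linear = age_pcd,
         stop("unknown age transform: ", age_transform, call. = FALSE))
}

# Interior knots for k knots: quantiles of the unique transformed ages,
# strictly inside the boundary; returns NULL if k is not realisable
# (coincident quantiles would duplicate a smaller-k basis).
.interior_knots <- function(ux, k) {
  if (k == 0) return(numeric())
  kn <- stats::quantile(ux, probs = seq_len(k) / (k + 1), names = FALSE)
  kn <- kn[kn > min(ux) & kn < max(ux)]
  if (anyDuplicated(kn) || length(kn) < k) return(NULL)
  kn
}

.spline_basis <- function(x, knots, boundary, degree) {
  suppressWarnings(splines::bs(x, knots = knots, degree = degree,
                               Boundary.knots = boundary, intercept = FALSE))
}

.fit_k <- function(x, y, k, boundary, degree) {
  ux <- sort(unique(x))
  knots <- .interior_knots(ux, k)
  if (is.null(knots) && k > 0) return(NULL)
  B <- cbind(1, .spline_basis(x, knots, boundary, degree))
  fit <- stats::lm.fit(B, y)
  if (anyNA(fit$coefficients)) return(NULL)   # rank-deficient basis
  list(knots = knots, coef = fit$coefficients,
       fitted = unname(fit$fitted.values),
       residuals = unname(fit$residuals),
       mse = mean(fit$residuals^2))
}

#' Fit the population age-trend spline of one gene
#'
#' Models the population trend of a gene's expression over life as a
#' least-squares cubic regression spline on transformed age, with
#' interior knots at empirical age quantiles. The number of knots is
#' the smallest k = 0, 1, 2, ... for which the in-sample mean squared
#' error drops below the sliding-window noise variance sigma^2
#' ([estimate_noise_variance()]). If no k up to `max_knots` satisfies
#' the bound, the bound is relaxed (doubled by default) and the search
#' repeated; if still unsatisfied, the max-knot fit is returned with
#' `relaxed = TRUE` and a warning.
#'
#' @param profile tibble with columns `age_pcd` and `value` (extra
#'   columns retained); sorted by age internally.
#' @param sigma2_hat noise variance; estimated from the profile when
#'   `NULL`.
#' @param max_knots largest knot count searched; default `floor(n / 4)`
#'   (capped so the basis stays identifiable).
#' @param age_transform `"log2"` (default — developmental change
#'   concentrates perinatally, and the log axis spreads the fetal
#'   period) or `"linear"`.
#' @param degree spline degree; 3 (cubic) by default. `degree = 1` with
#'   `n_knots = 0` reduces the model to a straight line in transformed
#'   age, the classical partial-correlation limit.
#' @param n_knots force a fixed knot count, skipping the search.
#' @param relaxation how to relax the bound when unsatisfiable:
#'   `"double_variance"` (MSE < 2 sigma^2, default) or `"double_sd"`
#'   (MSE < (2 sigma)^2).
#' @param window sliding-window width for the internal sigma^2 estimate.
#' @param boundary boundary knots on the transformed-age scale; default
#'   the range of the profile's transformed ages. Supplying a wider
#'   range (e.g. the full cohort's) keeps leave-one-out predictions
#'   interpolative.
#' @return an object of class `trend_fit`.
#' @export
fit_trend_spline <- function(profile, sigma2_hat = NULL, max_knots = NULL,
                             age_transform = c("log2", "linear"), degree = 3,
                             n_knots = NULL,
                             relaxation = c("double_variance", "double_sd"),
                             window = 10, boundary = NULL) {
  age_transform <- match.arg(age_transform)
  relaxation <- match.arg(relaxation)
  stopifnot(is.data.frame(profile),
            all(c("age_pcd", "value") %in% names(profile)))
  profile <- profile[order(profile$age_pcd), , drop = FALSE]
  if (any(profile$age_pcd <= 0)) stop("ages must be positive", call. = FALSE)
  y <- profile$value
  n <- length(y)
  if (n < 8) stop("need at least 8 samples to fit a trend", call. = FALSE)
  x <- .age_x(profile$age_pcd, age_transform)
  if (length(unique(x)) < 2) {
    stop("degenerate design: all ages identical", call. = FALSE)
  }
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(sigma2_hat)) {
    sigma2_hat <- estimate_noise_variance(y, window = window)
  }
  n_free <- length(unique(x))
  if (is.null(max_knots)) max_knots <- floor(n / 4)
  max_knots <- max(0, min(max_knots, n_free - degree - 2))

  relax_factor <- switch(relaxation, double_variance = 2, double_sd = 4)

  pick <- NULL
  relaxed <- FALSE
  if (!is.null(n_knots)) {
    pick <- .fit_k(x, y, n_knots, boundary, degree)
    if (is.null(pick)) stop("requested knot count not realisable for this design",
                            call. = FALSE)
  } else {
    accepts <- function(mse, bound) mse < bound || mse < 1e-12
    fits <- vector("list", max_knots + 1)
    for (k in 0:max_knots) {
      f <- .fit_k(x, y, k, boundary, degree)
      fits[[k + 1]] <- f
      if (!is.null(f) && accepts(f$mse, sigma2_hat)) { pick <- f; break }
    }
    if (is.null(pick)) {
      relaxed <- TRUE
      for (k in 0:max_knots) {
        f <- fits[[k + 1]]
        if (!is.null(f) && accepts(f$mse, relax_factor * sigma2_hat)) {
          pick <- f
          break
        }
      }
    }
    if (is.null(pick)) {
      valid <- Filter(Negate(is.null), fits)
      pick <- valid[[length(valid)]]
      warning("noise bound unsatisfiable even after relaxation; ",
              "returning the max-knot fit", call. = FALSE)
    }
  }

  structure(list(
    profile = tibble::as_tibble(profile),
    x = x,
    gene = if ("gene" %in% names(profile)) profile$gene[1] else NA_character_,
    region = if ("region" %in% names(profile)) profile$region[1] else NA_character_,
    age_transform = age_transform,
    degree = degree,
    boundary = boundary,
    knots = pick$knots,
    n_knots = length(pick$knots),
    coef = pick$coef,
    fitted = pick$fitted,
    residuals = pick$residuals,
    mse = pick$mse,
    sigma2_hat = sigma2_hat,
    relaxed = relaxed,
    window = window,
    relaxation = relaxation
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s: n = %d, knots = %d, mse = %.4g, sigma2_hat = %.4g%s\n",
    ifelse(is.na(x$gene), "profile", x$gene), length(x$fitted), x$n_knots,
    x$mse, x$sigma2_hat, if (x$relaxed) " (relaxed bound)" else ""))
  invisible(x)
}

#' Predict the fitted trend at new ages
#'
#' @param object a `trend_fit`.
#' @param age_pcd ages (post-conception days) at which to evaluate the
#'   trend; defaults to the training ages.
#' @param ... unused.
#' @return numeric vector of trend values.
#' @export
predict.trend_fit <- function(object, age_pcd = NULL, ...) {
  if (is.null(age_pcd)) return(object$fitted)
  x <- .age_x(age_pcd, object$age_transform)
  B <- cbind(1, .spline_basis(x, object$knots, object$boundary, object$degree))
  unname(drop(B %*% object$coef))
}

#' @export
fitted.trend_fit <- function(object, ...) object$fitted

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-sample view of a fitted trend
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return tibble with the (age-sorted) profile plus `fitted` and
#'   `residual` columns.
#' @export
tidy.trend_fit <- function(x, ...) {
  dplyr::mutate(x$profile, fitted = x$fitted, residual = x$residuals)
}

#' One-row summary of a fitted trend
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return tibble: `gene`, `region`, `n_samples`, `n_knots`, `mse`,
#'   `sigma2_hat`, `relaxed`.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, region = x$region,
                 n_samples = length(x$fitted), n_knots = x$n_knots,
                 mse = x$mse, sigma2_hat = x$sigma2_hat, relaxed = x$relaxed)
}

#' Leave-one-sample-out goodness of fit
#'
#' For each sample i the trend model is refitted on the other n - 1
#' points (by default re-running the whole knot-count selection with
#' sigma^2 re-estimated on those points) and used to predict y_i; the
#' score is `R^2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar)^2)`.
#' It is bounded above by 1; values near zero mean no detectable trend,
#' and negative values indicate overfitting. Boundary knots are taken
#' from the full profile so that predictions at the extreme ages remain
#' interpolative.
#'
#' @inheritParams fit_trend_spline
#' @param refit_selection re-run knot selection per fold (default); if
#'   `FALSE`, the knot count of the full-data fit is reused (faster).
#' @return the leave-one-out R^2 (scalar, <= 1), or `NA` for a constant
#'   profile.
#' @export
loo_r2 <- function(profile, max_knots = NULL,
                   age_transform = c("log2", "linear"), degree = 3,
                   relaxation = c("double_variance", "double_sd"),
                   window = 10, refit_selection = TRUE) {
  age_transform <- match.arg(age_transform)
  relaxation <- match.arg(relaxation)
  profile <- profile[order(profile$age_pcd), , drop = FALSE]
  y <- profile$value
  n <- length(y)
  if (n < 10) stop("leave-one-out R^2 needs at least 10 samples", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  boundary <- range(.age_x(profile$age_pcd, age_transform))
  fixed_k <- if (!refit_selection) {
    fit_trend_spline(profile, age_transform = age_transform, degree = degree,
                     relaxation = relaxation, window = window,
                     max_knots = max_knots, boundary = boundary)$n_knots
  } else NULL
  pred <- vapply(seq_len(n), function(i) {
    sub <- profile[-i, , drop = FALSE]
    fit <- suppressWarnings(fit_trend_spline(
      sub, age_transform = age_transform, degree = degree,
      relaxation = relaxation, window = window, max_knots = max_knots,
      n_knots = fixed_k, boundary = boundary))
    predict(fit, age_pcd = profile$age_pcd[i])
  }, numeric(1))
  1 - sum((y - pred)^2) / sst
}

#' Detrend an expression profile
#'
#' Fits the population age-trend spline and returns the profile with
#' its fitted trend and the residual fluctuations around it — the
#' subject-level signal the age-corrected correlation is computed on.
#'
#' @inheritParams fit_trend_spline
#' @param ... passed to [fit_trend_spline()].
#' @return tibble: the age-sorted profile plus `fitted` and `residual`
#'   columns.
#' @export
detrend <- function(profile, ...) {
  tidy(fit_trend_spline(profile, ...))
}
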