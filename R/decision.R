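#' Across-CF correlation between paired fluctuation profiles
#'
#' For each time segment `k`, computes the Pearson correlation across the CF
#' dimension between the noisy-speech profile `sn(k, CF)` and the noise-alone
#' profile `n(k, CF)`. Segments in which either profile is (numerically) flat
#' across CF are marked invalid and excluded from the mean. The dissimilarity
#' metric is `d = 1 - r_bar`; since each `r_k` lies in \[-1, 1\], `d` lies in
#' \[0, 2\], with `d = 0` when noisy speech and noise alone are
#' indistinguishable (very low SNR) and larger `d` the more the speech imposes
#' its own across-CF fluctuation contrast.
#'
#' @param sn_prof,n_prof `fluctuation_profile` objects on identical frame and
#'   CF grids.
#' @param var_tol relative variance tolerance: a segment is valid when its
#'   across-CF variance exceeds `var_tol` times its mean-square value.
#' @return An object of class `correlation_series`: `r_k`, `valid_mask`,
#'   `r_bar`, `d`.
#' @export
across_cf_correlation <- function(sn_prof, n_prof, var_tol = 1e-12) {
  stopifnot(inherits(sn_prof, "fluctuation_profile"),
            inherits(n_prof, "fluctuation_profile"))
  A <- sn_prof$values
  B <- n_prof$values
  if (!all(dim(A) == dim(B)))
    stop("profile shapes differ (", nrow(A), "x", ncol(A), " vs ",
         nrow(B), "x", ncol(B), ")")
  if (length(sn_prof$cf_hz) != length(n_prof$cf_hz) ||
      any(sn_prof$cf_hz != n_prof$cf_hz))
    stop("CF grids differ")
  m <- ncol(A)
  ca <- A - rowMeans(A)
  cb <- B - rowMeans(B)
  va <- rowSums(ca^2) / (m - 1)
  vb <- rowSums(cb^2) / (m - 1)
  valid <- va > var_tol * pmax(rowMeans(A^2), .Machine$double.xmin) &
           vb > var_tol * pmax(rowMeans(B^2), .Machine$double.xmin)
  r_k <- rep(NA_real_, nrow(A))
  r_k[valid] <- rowSums(ca * cb)[valid] / ((m - 1) * sqrt(va * vb))[valid]
  r_k <- pmin(pmax(r_k, -1), 1)
  if (!any(valid)) stop("no analyzable segments")
  r_bar <- mean(r_k[valid])
  structure(list(r_k = r_k, valid_mask = valid, r_bar = r_bar, d = 1 - r_bar),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %d/%d valid segments, r_bar = %.4f, d = %.4f\n",
              sum(x$valid_mask), length(x$r_k), x$r_bar, x$d))
  invisible(x)
}

#' Map dissimilarity to speech intelligibility
#'
#' `SI = 100 / (1 + exp(a1 * d + a2))` percent. With `a1 < 0`, SI grows
#' monotonically with the dissimilarity `d`.
#'
#' @param d dissimilarity value(s).
#' @param params an `si_logistic` fit or a list/vector with elements `a1`,
#'   `a2`.
#' @return SI in percent.
#' @export
si_from_d <- function(d, params) {
  p <- as.numeric(unlist(params[c("a1", "a2")]))
  100 / (1 + exp(p[1] * d + p[2]))
}

#' Fit the logistic SI transformation
#'
#' Nonlinear least-squares fit of `SI = 100 / (1 + exp(a1 * d + a2))` to
#' paired (d, SI%) observations, with multi-start over sign combinations of
#' the initial parameters plus a logit-linearized start. The fitted
#' parameters define the model's transformation from dissimilarity to
#' intelligibility; they are estimated once on a fitting condition and then
#' frozen for all predictions.
#'
#' @param d dissimilarity values.
#' @param si_pct target SI scores in percent (same length, at least 2 points).
#' @param tol convergence tolerance on the residual sum of squares.
#' @return An object of class `si_logistic` with components `a1`, `a2`,
#'   `fitted`, `residuals`, `data`, `rss`. Methods: `print`, `coef`,
#'   `summary`, `predict` (on new `d`), `residuals`, `plot`.
#' @examples
#' d <- seq(0.05, 0.95, length.out = 12)
#' fit <- fit_logistic(d, si_from_d(d, list(a1 = -8, a2 = 4)))
#' coef(fit)
#' @export
fit_logistic <- function(d, si_pct, tol = 1e-10) {
  if (length(d) != length(si_pct)) stop("d and si_pct lengths differ")
  if (length(d) < 2) stop("need at least 2 fitting points")
  if (!any(si_pct > 50) || !any(si_pct < 50))
    warning("fitting targets do not span both sides of 50% SI")
  dat <- data.frame(d = d, si = si_pct)
  starts <- list()
  ok <- si_pct > 1e-9 & si_pct < 100 - 1e-9
  if (sum(ok) >= 2) {
    lf <- lm(log(100 / si_pct[ok] - 1) ~ d[ok])
    starts[[1]] <- c(a1 = unname(coef(lf)[2]), a2 = unname(coef(lf)[1]))
  }
  for (s1 in c(-8, 8)) for (s2 in c(-4, 4))
    starts[[length(starts) + 1]] <- c(a1 = s1, a2 = s2)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(si ~ 100 / (1 + exp(a1 * d + a2)), data = dat,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("logistic fit did not converge from any start; check target values")
  cf <- coef(best$fit)
  structure(list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
                 fitted = as.numeric(fitted(best$fit)),
                 residuals = as.numeric(residuals(best$fit)),
                 data = dat, rss = best$rss),
            class = "si_logistic")
}

#' @export
print.si_logistic <- function(x, ...) {
  cat(sprintf("Logistic SI transformation: SI = 100 / (1 + exp(a1*d + a2))\n"))
  cat(sprintf("  a1 = %.4f, a2 = %.4f  (RSS = %.3g on %d points)\n",
              x$a1, x$a2, x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.si_logistic <- function(object, ...) c(a1 = object$a1, a2 = object$a2)

#' @export
residuals.si_logistic <- function(object, ...) object$residuals

#' @export
predict.si_logistic <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d
       else if (is.list(newdata)) newdata$d else newdata
  si_from_d(d, object)
}

#' @export
summary.si_logistic <- function(object, ...) {
  cat("Logistic SI transformation fit\n")
  cat(sprintf("  a1 = %.4f (slope on d), a2 = %.4f (offset)\n", object$a1, object$a2))
  cat(sprintf("  50%% SI at d = %.4f\n", -object$a2 / object$a1))
  cat(sprintf("  %d fitting points, RSS = %.4g, RMSE = %.3g %%SI\n",
              nrow(object$data), object$rss, sqrt(mean(object$residuals^2))))
  invisible(object)
}

#' @export
plot.si_logistic <- function(x, ...) {
  dd <- seq(0, max(2, max(x$data$d)), length.out = 200)
  plot(dd, si_from_d(dd, x), type = "l", xlab = "dissimilarity d",
       ylab = "SI (%)", ylim = c(0, 100), ...)
  points(x$data$d, x$data$si, pch = 19)
  abline(h = 50, lty = 3)
  invisible(x)
}

#' Speech reception threshold from a psychometric function
#'
#' The SRT is the SNR of the first upward 50% crossing of the SI-vs-SNR
#' function, located by linear interpolation between bracketing grid points.
#' If SI stays on one side of 50% over the whole grid, the nearer grid edge is
#' returned with `srt_defined = FALSE`.
#'
#' @param snr_grid_db SNR grid (increasing), dB.
#' @param si_pct SI values in percent on the grid.
#' @return List with `srt_db` and `srt_defined`.
#' @export
estimate_srt <- function(snr_grid_db, si_pct) {
  stopifnot(length(snr_grid_db) == length(si_pct), length(si_pct) >= 2)
  if (all(si_pct >= 50)) {
    hit <- which(si_pct == 50)
    if (length(hit) && !all(si_pct == 50))
      return(list(srt_db = snr_grid_db[hit[1]], srt_defined = TRUE))
    return(list(srt_db = snr_grid_db[1], srt_defined = FALSE))
  }
  if (all(si_pct <= 50))
    return(list(srt_db = snr_grid_db[length(si_pct)], srt_defined = FALSE))
  for (i in seq_len(length(si_pct) - 1)) {
    if (si_pct[i] == 50)
      return(list(srt_db = snr_grid_db[i], srt_defined = TRUE))
    if (si_pct[i] < 50 && si_pct[i + 1] >= 50) {
      frac <- (50 - si_pct[i]) / (si_pct[i + 1] - si_pct[i])
      return(list(srt_db = snr_grid_db[i] + frac * (snr_grid_db[i + 1] - snr_grid_db[i]),
                  srt_defined = TRUE))
    }
  }
  if (si_pct[length(si_pct)] == 50)
    return(list(srt_db = snr_grid_db[length(si_pct)], srt_defined = TRUE))
  list(srt_db = snr_grid_db[length(si_pct)], srt_defined = FALSE)
}
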