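#' FRAP trace
#'
#' A bleach-recovery time series: strictly increasing times (s), intensities
#' (a.u.), the index of the first post-bleach frame and the number of
#' pre-bleach frames.
#'
#' @param time numeric vector of acquisition times, s, strictly increasing.
#' @param intensity numeric vector, same length.
#' @param bleach_index 1-based index of the first post-bleach frame (>= 2).
#' @param prebleach_frames number of pre-bleach frames (defaults to
#'   `bleach_index - 1`).
#' @return An object of class `FrapTrace`.
#' @export
frap_trace <- function(time, intensity, bleach_index,
                       prebleach_frames = bleach_index - 1L) {
  if (length(time) != length(intensity)) {
    sq_stop("FORMAT_ERROR", "time and intensity lengths differ")
  }
  if (any(diff(time) <= 0)) {
    sq_stop("FORMAT_ERROR", "time must be strictly increasing")
  }
  if (bleach_index < 2L) {
    sq_stop("FORMAT_ERROR", "bleach_index must be >= 2")
  }
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 bleach_index = as.integer(bleach_index),
                 prebleach_frames = as.integer(prebleach_frames)),
            class = "FrapTrace")
}

#' Normalise a FRAP trace to its pre-bleach mean
#'
#' Divides all intensities by the mean of the pre-bleach frames, so the
#' pre-bleach level of the output is 1. Idempotent.
#'
#' @param trace a [frap_trace()].
#' @return The normalised [frap_trace()].
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "FrapTrace"))
  if (trace$prebleach_frames < 2L) {
    sq_stop("DEGENERATE_TRACE", "need >= 2 pre-bleach frames")
  }
  pre <- mean(trace$intensity[seq_len(trace$prebleach_frames)])
  if (pre == 0) sq_stop("DEGENERATE_TRACE", "pre-bleach mean is zero")
  trace$intensity <- trace$intensity / pre
  if (!is.null(trace$truth)) {
    trace$truth$prebleach <- trace$truth$prebleach / pre
    trace$truth$I_post <- trace$truth$I_post / pre
  }
  trace
}

#' Fit a single-exponential recovery to a FRAP trace
#'
#' Least-squares fit of
#' `I(t) = I_post + (I_plateau - I_post) * (1 - exp(-(t - t_bleach) / tau))`
#' to the post-bleach frames. The recovery half-time is `t_half = tau ln 2`
#' and the mobile fraction `(I_plateau - I_post) / (I_pre - I_post)`, with
#' `I_pre` the pre-bleach mean; a mobile fraction outside `[0, 1]` is
#' clipped with a warning. Initial guesses: `I_post` from the first
#' post-bleach frame, `I_plateau` from the last three frames, `tau` from the
#' time to reach halfway between them.
#'
#' @param trace a [frap_trace()] with at least 5 post-bleach frames.
#' @return An object of class `FrapFit`: list with `tau`, `t_half`,
#'   `mobile_fraction`, `mobile_fraction_raw`, `I_pre`, `I_post`,
#'   `I_plateau`, `rss`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "FrapTrace"))
  n <- length(trace$time)
  post <- trace$bleach_index:n
  if (length(post) < 5L) {
    sq_stop("FIT_FAILED", "need >= 5 post-bleach frames, have %d",
            length(post))
  }
  tt <- trace$time[post] - trace$time[trace$bleach_index]
  yy <- trace$intensity[post]
  i_pre <- mean(trace$intensity[seq_len(trace$prebleach_frames)])
  i_post0 <- yy[1L]
  i_pl0 <- mean(utils::tail(yy, 3L))
  if (abs(i_pl0 - i_post0) < 1e-12 * max(1, abs(i_pre))) {
    # flat recovery: no mobile pool, tau unidentifiable
    fit <- list(tau = NA_real_, I_post = i_post0, I_plateau = mean(yy),
                rss = sum((yy - mean(yy))^2))
  } else {
    half <- i_post0 + (i_pl0 - i_post0) / 2
    tau0 <- tt[which(yy >= half)[1L]]
    if (is.na(tau0) || tau0 <= 0) tau0 <- max(tt) / 4
    mod <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ Ipost + (Ipl - Ipost) * (1 - exp(-tt / tau)),
        start = list(Ipost = i_post0, Ipl = i_pl0, tau = tau0),
        lower = c(-Inf, -Inf, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        sq_stop("FIT_FAILED", "recovery fit did not converge: %s",
                conditionMessage(e))
      })
    cf <- stats::coef(mod)
    fit <- list(tau = unname(cf["tau"]), I_post = unname(cf["Ipost"]),
                I_plateau = unname(cf["Ipl"]),
                rss = sum(stats::residuals(mod)^2))
  }
  mf_raw <- if (abs(i_pre - fit$I_post) < 1e-12) 0 else
    (fit$I_plateau - fit$I_post) / (i_pre - fit$I_post)
  mf <- mf_raw
  if (is.na(fit$tau)) mf <- 0
  if (mf < 0 || mf > 1) {
    warning(sprintf("mobile fraction %.3f outside [0, 1]; clipped", mf))
    mf <- min(max(mf, 0), 1)
  }
  structure(list(tau = fit$tau, t_half = fit$tau * log(2),
                 mobile_fraction = mf, mobile_fraction_raw = mf_raw,
                 I_pre = i_pre, I_post = fit$I_post,
                 I_plateau = fit$I_plateau, rss = fit$rss),
            class = "FrapFit")
}

#' @export
print.FrapFit <- function(x, ...) {
  cat(sprintf("FrapFit: tau = %.3g s, t1/2 = %.3g s, mobile fraction = %.3f\n",
              x$tau, x$t_half, x$mobile_fraction))
  invisible(x)
}

#' Group recovery-speed and mobile-fraction ratios
#'
#' Compares two groups of FRAP fits as ratios of group means:
#' the speed ratio `mean(1 / t_half_a) / mean(1 / t_half_b)` (how many times
#' faster group a recovers) and the mobile-fraction ratio
#' `mean(mf_a) / mean(mf_b)`.
#'
#' @param fits_a,fits_b non-empty lists of [fit_recovery()] results.
#' @return List with `speed_ratio`, `mobile_fraction_ratio`, and the group
#'   means behind them.
#' @export
group_ratio <- function(fits_a, fits_b) {
  if (!length(fits_a) || !length(fits_b)) {
    sq_stop("INVALID_PARAM", "both groups must be non-empty")
  }
  th_a <- vapply(fits_a, `[[`, numeric(1), "t_half")
  th_b <- vapply(fits_b, `[[`, numeric(1), "t_half")
  mf_a <- vapply(fits_a, `[[`, numeric(1), "mobile_fraction")
  mf_b <- vapply(fits_b, `[[`, numeric(1), "mobile_fraction")
  list(speed_ratio = mean(1 / th_a) / mean(1 / th_b),
       mobile_fraction_ratio = mean(mf_a) / mean(mf_b),
       mean_t_half_a = mean(th_a), mean_t_half_b = mean(th_b),
       mean_mobile_a = mean(mf_a), mean_mobile_b = mean(mf_b))
}

#' Read / write FRAP traces as two-column CSV
#'
#' @param path CSV path with columns `time_s`, `intensity`.
#' @param bleach_index 1-based first post-bleach frame.
#' @return [read_frap_csv()] returns a [frap_trace()];
#'   [write_frap_csv()] returns `path` invisibly.
#' @export
read_frap_csv <- function(path, bleach_index) {
  df <- utils::read.csv(path)
  frap_trace(df$time_s, df$intensity, bleach_index)
}

#' @rdname read_frap_csv
#' @param trace a [frap_trace()].
#' @export
write_frap_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time,
                              intensity = trace$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
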