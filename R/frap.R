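#' FRAP trace container
#'
#' Raw fluorescence-recovery-after-photobleaching measurements: mean intensity
#' of the bleached region of interest (ROI), of an extracellular background
#' ROI, and of the whole nucleus, over strictly increasing time points, with
#' the index of the first post-bleach frame. At least one pre-bleach and five
#' post-bleach frames are required for fitting.
#'
#' @param t Time points in seconds, strictly increasing.
#' @param F_roi,F_bg,F_whole Mean intensities of the bleached ROI, the
#'   extracellular background ROI, and the whole nucleus.
#' @param bleach_index Index (into `t`) of the first post-bleach frame.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(t, F_roi, F_bg, F_whole, bleach_index) {
  n <- length(t)
  stopifnot(length(F_roi) == n, length(F_bg) == n, length(F_whole) == n)
  if (any(diff(t) <= 0)) stopf("`t` must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L) stopf("need >= 1 pre-bleach frame")
  if (n - bleach_index + 1L < 5L) stopf("need >= 5 post-bleach frames")
  structure(list(t = as.numeric(t), F_roi = as.numeric(F_roi),
                 F_bg = as.numeric(F_bg), F_whole = as.numeric(F_whole),
                 bleach_index = bleach_index),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d pre-bleach), t = %.3g..%.3g s\n",
              length(x$t), x$bleach_index - 1L, min(x$t), max(x$t)))
  invisible(x)
}

#' Normalize a FRAP trace
#'
#' Double normalization: background subtraction, division by the whole-nucleus
#' intensity (which cancels acquisition photobleaching exactly, since it
#' multiplies ROI and whole-nucleus signal alike), and scaling by the
#' pre-bleach ratio so the pre-bleach level is 1:
#' \deqn{F_{norm}(t) = \frac{F_{roi}(t)-F_{bg}(t)}{F_{whole}(t)-F_{bg}(t)}
#'       \cdot \frac{\bar F_{whole,pre}-\bar F_{bg,pre}}
#'                  {\bar F_{roi,pre}-\bar F_{bg,pre}},}
#' with pre-bleach quantities averaged over pre-bleach frames. The result is
#' invariant to a common positive gain on the raw trace.
#'
#' @param trace A [frap_trace()].
#' @return A list with `t_post` (seconds since bleach), `F_post` (normalized
#'   post-bleach curve), `t`, `F_norm` (full curve), `valid`, `reason`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- seq_len(trace$bleach_index - 1L)
  roi_pre <- mean(trace$F_roi[pre]) - mean(trace$F_bg[pre])
  whole_pre <- mean(trace$F_whole[pre]) - mean(trace$F_bg[pre])
  denom <- trace$F_whole - trace$F_bg
  if (roi_pre <= 0 || whole_pre <= 0 || any(denom <= 0)) {
    return(list(t_post = numeric(0), F_post = numeric(0), t = trace$t,
                F_norm = rep(NA_real_, length(trace$t)), valid = FALSE,
                reason = "non-positive background-corrected intensity"))
  }
  F_norm <- ((trace$F_roi - trace$F_bg) / denom) * (whole_pre / roi_pre)
  post <- seq(trace$bleach_index, length(trace$t))
  t0 <- trace$t[trace$bleach_index]
  list(t_post = trace$t[post] - t0, F_post = F_norm[post],
       t = trace$t, F_norm = F_norm, valid = TRUE, reason = NA_character_)
}

frap_model <- function(tp, F0, A1, k1, A2, k2) {
  F0 + A1 * (1 - exp(-k1 * tp)) + A2 * (1 - exp(-k2 * tp))
}

#' Fit a two-component exponential FRAP recovery
#'
#' Fits the bounded-amplitude recovery model
#' \deqn{F(t') = F_0 + A_1(1 - e^{-k_1 t'}) + A_2(1 - e^{-k_2 t'})}
#' to a normalized post-bleach curve by constrained nonlinear least squares
#' (`A1, A2 >= 0`, `k1, k2 > 0`; components canonicalized so `k1 >= k2`).
#' Starting values are deterministic: `F0` from the first post-bleach point,
#' the plateau from the mean of the final 10\% of points, and rate seeds from
#' a coarse log-spaced grid with amplitudes solved by non-negative linear
#' least squares at each grid point. The recovery half-time `T_half` is the
#' numeric root of `F(T) = F0 + (plateau - F0)/2` on the fitted composite
#' curve. If the fitted rates are nearly degenerate (`k1/k2 < ratio_guard`),
#' the fit is re-run as a single component (`A2 = 0`) and flagged.
#'
#' @param t_post Time since bleach (s), or a list from [normalize_trace()].
#' @param F_post Normalized intensities (ignored when `t_post` is a
#'   normalized-trace list).
#' @param ratio_guard Identifiability guard on `k1/k2` (default 1.5).
#' @return An object of class `frap_fit` with elements `F0`, `A1`, `k1`,
#'   `A2`, `k2`, `plateau`, `T_half`, `residual_rms`, `converged`,
#'   `single_component`, and the data.
#' @export
fit_recovery <- function(t_post, F_post = NULL, ratio_guard = 1.5) {
  if (is.list(t_post) && !is.null(t_post$t_post)) {
    if (!isTRUE(t_post$valid)) stopf("cannot fit an invalid normalized trace (%s)", t_post$reason)
    F_post <- t_post$F_post
    t_post <- t_post$t_post
  }
  stopifnot(length(t_post) == length(F_post))
  if (length(t_post) < 5L) stopf("need >= 5 post-bleach points")
  if (any(!is.finite(t_post)) || any(!is.finite(F_post)))
    stopf("curve must be finite")
  o <- order(t_post)
  tp <- t_post[o]; y <- F_post[o]

  fit2 <- fit_two_component(tp, y)
  fit1 <- fit_single_component(tp, y)
  use_single <-
    (!fit2$converged && fit1$converged) ||
    (fit2$converged && fit2$A2 > 0 && fit2$k2 > 0 &&
       fit2$k1 / fit2$k2 < ratio_guard) ||
    (fit1$converged && fit1$rss <= fit2$rss * (1 + 1e-9))
  fit <- if (use_single) fit1 else fit2
  fit$single_component <- use_single
  if (!fit$converged)
    warning("FRAP fit did not converge; parameters are best available")
  fit$plateau <- fit$F0 + fit$A1 + ifelse(is.na(fit$A2), 0, fit$A2)
  fit$T_half <- t_half_numeric(fit)
  pred <- frap_model(tp, fit$F0, fit$A1, fit$k1, fit$A2, fit$k2)
  fit$residual_rms <- sqrt(mean((y - pred)^2))
  fit$data <- data.frame(t_post = tp, F_post = y)
  class(fit) <- "frap_fit"
  fit
}

# Non-negative amplitude solution for fixed rates (active-set on 2 columns).
solve_amplitudes <- function(tp, y, F0, k1, k2) {
  X <- cbind(1 - exp(-k1 * tp), 1 - exp(-k2 * tp))
  z <- y - F0
  a <- tryCatch(stats::coef(stats::lm.fit(X, z)), error = function(e) c(0, 0))
  a[!is.finite(a)] <- 0
  if (any(a < 0)) {
    for (j in 1:2) {
      aj <- sum(X[, j] * z) / sum(X[, j]^2)
      cand <- c(0, 0); cand[j] <- max(aj, 0)
      if (j == 1L || sum((z - X %*% cand)^2) < best_rss) { a_best <- cand; best_rss <- sum((z - X %*% cand)^2) }
    }
    a <- a_best
  }
  pmax(a, 0)
}

fit_two_component <- function(tp, y) {
  F0 <- y[1L]
  n_tail <- max(1L, ceiling(0.1 * length(y)))
  plateau0 <- mean(utils::tail(y, n_tail))
  span <- max(tp[length(tp)] - tp[1L], .Machine$double.eps)
  kgrid <- exp(seq(log(0.1 / span), log(50 / span), length.out = 12L))
  best <- NULL
  for (i in seq_along(kgrid)) for (j in seq_len(i - 1L)) {
    k1 <- kgrid[i]; k2 <- kgrid[j]
    a <- solve_amplitudes(tp, y, F0, k1, k2)
    rss <- sum((y - frap_model(tp, F0, a[1L], k1, a[2L], k2))^2)
    if (is.null(best) || rss < best$rss)
      best <- list(A1 = a[1L], k1 = k1, A2 = a[2L], k2 = k2, rss = rss)
  }
  st <- list(F0 = F0, A1 = max(best$A1, 1e-6), k1 = best$k1,
             A2 = max(best$A2, 1e-6), k2 = best$k2)
  fit <- tryCatch({
    nls <- minpack.lm::nlsLM(
      y ~ F0 + A1 * (1 - exp(-k1 * tp)) + A2 * (1 - exp(-k2 * tp)),
      start = st,
      lower = c(F0 = -Inf, A1 = 0, k1 = 1e-8, A2 = 0, k2 = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- as.list(stats::coef(nls))
    c(cf, list(converged = nls$convInfo$isConv))
  }, error = function(e) c(st, list(converged = FALSE)))
  out <- fit
  # canonical order: k1 is the faster rate
  if (out$k2 > out$k1) {
    out[c("A1", "k1", "A2", "k2")] <- out[c("A2", "k2", "A1", "k1")]
  }
  out$rss <- sum((y - frap_model(tp, out$F0, out$A1, out$k1, out$A2, out$k2))^2)
  out
}

fit_single_component <- function(tp, y) {
  F0 <- y[1L]
  span <- max(tp[length(tp)] - tp[1L], .Machine$double.eps)
  kgrid <- exp(seq(log(0.1 / span), log(50 / span), length.out = 25L))
  rss1 <- vapply(kgrid, function(k) {
    X <- 1 - exp(-k * tp)
    a <- max(sum(X * (y - F0)) / sum(X^2), 0)
    sum((y - F0 - a * X)^2)
  }, numeric(1L))
  k0 <- kgrid[which.min(rss1)]
  X <- 1 - exp(-k0 * tp)
  a0 <- max(sum(X * (y - F0)) / sum(X^2), 1e-6)
  fit <- tryCatch({
    nls <- minpack.lm::nlsLM(
      y ~ F0 + A1 * (1 - exp(-k1 * tp)),
      start = list(F0 = F0, A1 = a0, k1 = k0),
      lower = c(F0 = -Inf, A1 = 0, k1 = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- as.list(stats::coef(nls))
    list(F0 = cf$F0, A1 = cf$A1, k1 = cf$k1, A2 = 0, k2 = NA_real_,
         converged = nls$convInfo$isConv)
  }, error = function(e) list(F0 = F0, A1 = a0, k1 = k0, A2 = 0,
                              k2 = NA_real_, converged = FALSE))
  fit$rss <- sum((y - frap_model(tp, fit$F0, fit$A1, fit$k1, 0, 1))^2)
  fit
}

# T_half: bisection root of F(T) = F0 + (plateau - F0)/2 on the fitted curve.
t_half_numeric <- function(fit) {
  total <- fit$A1 + ifelse(is.na(fit$A2), 0, fit$A2)
  if (total <= 0) return(NA_real_)
  A2 <- ifelse(is.na(fit$A2), 0, fit$A2)
  k2 <- ifelse(is.na(fit$k2), 1, fit$k2)
  f <- function(T) fit$A1 * (1 - exp(-fit$k1 * T)) + A2 * (1 - exp(-k2 * T)) - total / 2
  upper <- 1 / min(fit$k1, if (A2 > 0) k2 else fit$k1)
  while (f(upper) < 0 && upper < 1e12) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit>%s F0=%.4g  A1=%.4g k1=%.4g/s  A2=%.4g k2=%s/s\n  plateau=%.4g  T_half=%.4g s  rms=%.3g  converged=%s\n",
    if (x$single_component) " [single-component]" else "",
    x$F0, x$A1, x$k1, x$A2, format(x$k2, digits = 4), x$plateau, x$T_half,
    x$residual_rms, x$converged))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(F0 = object$F0, A1 = object$A1, k1 = object$k1,
    A2 = object$A2, k2 = object$k2)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  tp <- if (is.null(newdata)) object$data$t_post else
    if (is.list(newdata)) newdata$t_post else newdata
  A2 <- ifelse(is.na(object$A2), 0, object$A2)
  k2 <- ifelse(is.na(object$k2), 1, object$k2)
  frap_model(tp, object$F0, object$A1, object$k1, A2, k2)
}

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
residuals.frap_fit <- function(object, ...) object$data$F_post - fitted(object)

#' @export
summary.frap_fit <- function(object, ...) {
  cat(sprintf("Two-component FRAP recovery fit on %d post-bleach points\n",
              nrow(object$data)))
  print(object)
  invisible(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$t_post, x$data$F_post, xlab = "time since bleach (s)",
                 ylab = "normalized intensity", pch = 16, cex = 0.6, ...)
  tp <- seq(0, max(x$data$t_post), length.out = 200L)
  graphics::lines(tp, predict(x, tp), col = "red3", lwd = 2)
  graphics::abline(h = x$F0 + (x$plateau - x$F0) / 2, lty = 3)
  graphics::abline(v = x$T_half, lty = 3)
  invisible(x)
}

#' Summarize FRAP fits by group
#'
#' Group means and SDs of `T_half` over converged fits, plus Welch two-sample
#' t-tests of every other group against a reference group. Groups with fewer
#' than two converged fits are reported but skipped in comparisons.
#'
#' @param fits List of [fit_recovery()] objects.
#' @param groups Character/factor vector, one group label per fit.
#' @param reference Reference group for comparisons (default: first level).
#' @return A list with `summary` (per-group n, mean, sd) and `comparisons`
#'   (group, p_value vs reference, or NA when skipped).
#' @export
summarize_frap <- function(fits, groups, reference = NULL) {
  stopifnot(length(fits) == length(groups))
  th <- vapply(fits, function(f) f$T_half, numeric(1L))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1L)) & is.finite(th)
  groups <- as.character(groups)
  if (is.null(reference)) reference <- groups[1L]
  gl <- unique(groups)
  summ <- do.call(rbind, lapply(gl, function(g) {
    v <- th[ok & groups == g]
    data.frame(group = g, n = length(v),
               mean_t_half = if (length(v)) mean(v) else NA_real_,
               sd_t_half = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  ref_v <- th[ok & groups == reference]
  comp <- do.call(rbind, lapply(setdiff(gl, reference), function(g) {
    v <- th[ok & groups == g]
    p <- if (length(v) >= 2L && length(ref_v) >= 2L)
      stats::t.test(v, ref_v)$p.value else NA_real_
    data.frame(group = g, reference = reference, p_value = p,
               skipped = is.na(p))
  }))
  if (!is.null(comp) && any(comp$skipped))
    message("comparison skipped for group(s) with < 2 converged fits: ",
            paste(comp$group[comp$skipped], collapse = ", "))
  list(summary = summ, comparisons = comp)
}

#' Read/write FRAP trace CSVs
#'
#' Trace CSVs have columns `t_s`, `F_roi`, `F_bg`, `F_whole` and carry the
#' bleach index as a `# bleach_index: <n>` header comment.
#'
#' @param path CSV path.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- readLines(path, n = 5L)
  bl <- grep("^#\\s*bleach_index:", hdr, value = TRUE)
  if (!length(bl)) stopf("trace CSV must carry '# bleach_index: <n>' header")
  bleach <- as.integer(sub("^#\\s*bleach_index:\\s*", "", bl[1L]))
  d <- utils::read.csv(path, comment.char = "#")
  frap_trace(d$t_s, d$F_roi, d$F_bg, d$F_whole, bleach)
}

#' @rdname read_frap_trace
#' @param trace A [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bleach_index: %d", trace$bleach_index), con)
  utils::write.csv(data.frame(t_s = trace$t, F_roi = trace$F_roi,
                              F_bg = trace$F_bg, F_whole = trace$F_whole),
                   con, row.names = FALSE)
  invisible(path)
}
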