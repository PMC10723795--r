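test_that("trace normalization handles identity, steps, and gain", {
  n <- 30
  # constant trace, no bleach: F_norm identically 1
  tr <- frap_trace(t = 0:(n - 1), F_roi = rep(500, n), F_bg = rep(50, n),
                   F_whole = rep(900, n), bleach_index = 6)
  nt <- normalize_trace(tr)
  expect_equal(nt$F_norm, rep(1, n))
  # ROI halved at bleach, whole unchanged: 1 -> 0.5 step
  roi <- c(rep(450, 5), rep(250, n - 5))  # signal 400 -> 200 over bg 50
  tr2 <- frap_trace(0:(n - 1), roi, rep(50, n), rep(900, n), 6)
  nt2 <- normalize_trace(tr2)
  expect_equal(nt2$F_norm[1:5], rep(1, 5))
  expect_equal(nt2$F_post, rep(0.5, n - 5))
  # common positive gain leaves the normalized curve unchanged
  g <- 7.7
  tr3 <- frap_trace(0:(n - 1), roi * g, rep(50 * g, n), rep(900 * g, n), 6)
  expect_equal(normalize_trace(tr3)$F_norm, nt2$F_norm)
  # non-positive denominators flag the trace rather than crash
  tr4 <- frap_trace(0:(n - 1), roi, rep(1000, n), rep(900, n), 6)
  expect_false(normalize_trace(tr4)$valid)
  expect_error(fit_recovery(normalize_trace(tr4)), "invalid")
})

test_that("acquisition-bleaching correction is exact by construction", {
  clean <- normalize_trace(generate_frap_trace(noise_sd = 0,
                                               acquisition_bleach = 0, seed = 1))
  bleached_raw <- generate_frap_trace(noise_sd = 0, acquisition_bleach = 0.015,
                                      seed = 1)
  corrected <- normalize_trace(bleached_raw)
  expect_lt(max(abs(corrected$F_post - clean$F_post)), 1e-6)
  # without the whole-nucleus correction the curve is visibly different
  pre <- seq_len(bleached_raw$bleach_index - 1)
  raw_norm <- (bleached_raw$F_roi - bleached_raw$F_bg) /
    mean(bleached_raw$F_roi[pre] - bleached_raw$F_bg[pre])
  post <- seq(bleached_raw$bleach_index, length(bleached_raw$t))
  expect_gt(max(abs(raw_norm[post] - clean$F_post)), 0.05)
})

test_that("noiseless fits recover their generating parameters", {
  # two-component with well-separated rates: <= 0.1% error
  for (pars in list(c(A1 = 0.4, k1 = 0.5, A2 = 0.3, k2 = 0.05),
                    c(A1 = 0.2, k1 = 1.2, A2 = 0.5, k2 = 0.1))) {
    tr <- generate_frap_trace(A1 = pars["A1"], k1 = pars["k1"],
                              A2 = pars["A2"], k2 = pars["k2"], F0 = 0.25,
                              noise_sd = 0, acquisition_bleach = 0,
                              n_post = 120, seed = 1)
    fit <- fit_recovery(normalize_trace(tr))
    expect_true(fit$converged)
    got <- coef(fit)[c("A1", "k1", "A2", "k2")]
    expect_lt(max(abs(got - pars) / pars), 1e-3)
  }
})

test_that("half-time matches closed forms and independent root finding", {
  # single exponential: T_half = ln 2 / k
  tp <- seq(0, 30, by = 0.5)
  fit <- fit_recovery(tp, 1 - exp(-(log(2) / 5) * tp))
  expect_true(fit$single_component)
  expect_equal(fit$T_half, 5, tolerance = 1e-6)
  # A2 = 0 through the generator: same reduction
  tr0 <- generate_frap_trace(A1 = 0.7, k1 = 0.3, A2 = 0, k2 = 0.01, F0 = 0.3,
                             noise_sd = 0, acquisition_bleach = 0, seed = 2)
  fit0 <- fit_recovery(normalize_trace(tr0))
  expect_equal(fit0$T_half, log(2) / 0.3, tolerance = 1e-4)
  # two-component: bisection oracle for A1=A2=0.5, k1=1, k2=0.1
  tp2 <- seq(0, 60, by = 0.25)
  y2 <- 0.5 * (1 - exp(-tp2)) + 0.5 * (1 - exp(-0.1 * tp2))
  fit2 <- fit_recovery(tp2, y2)
  oracle <- uniroot(function(T) 0.5 * exp(-T) + 0.5 * exp(-0.1 * T) - 0.5,
                    c(0, 100), tol = 1e-12)$root
  expect_equal(fit2$T_half, oracle, tolerance = 1e-6)
  # the fitted curve is at half recovery at T_half
  expect_equal(predict(fit2, fit2$T_half),
               fit2$F0 + (fit2$plateau - fit2$F0) / 2, tolerance = 1e-8)
})

test_that("T_half falls when both rates are scaled up", {
  th <- sapply(c(0.5, 1, 2, 4), function(s) {
    tr <- generate_frap_trace(k1 = 0.4 * s, k2 = 0.04 * s, noise_sd = 0,
                              acquisition_bleach = 0, seed = 1)
    attr(tr, "truth")$T_half
  })
  expect_true(all(diff(th) < 0))
})

test_that("noisy traces recover the generator half-time in the median", {
  ths <- vapply(1:60, function(s) {
    tr <- generate_frap_trace(noise_sd = 0.02, seed = s)
    fit_recovery(normalize_trace(tr))$T_half
  }, numeric(1))
  truth <- attr(generate_frap_trace(seed = 1), "truth")$T_half
  expect_lt(abs(median(ths) - truth) / truth, 0.1)
})

test_that("group summaries and comparisons follow the Welch t-test", {
  mk_fit <- function(th) structure(list(T_half = th, converged = TRUE),
                                   class = "frap_fit")
  a <- c(5.0, 5.1, 4.9, 5.05)
  b <- c(2.0, 2.1, 1.95, 2.02)
  fits <- lapply(c(a, b), mk_fit)
  res <- summarize_frap(fits, rep(c("ctrl", "drug"), each = 4), reference = "ctrl")
  expect_equal(res$summary$mean_t_half, c(mean(a), mean(b)))
  expect_equal(res$comparisons$p_value, t.test(b, a)$p.value)
  expect_lt(res$comparisons$p_value, 0.05)
  # identical groups: p = 1 within tolerance
  res2 <- summarize_frap(lapply(c(a, a), mk_fit),
                         rep(c("g1", "g2"), each = 4), reference = "g1")
  expect_gt(res2$comparisons$p_value, 0.99)
  # hand Welch formula
  tstat <- (mean(b) - mean(a)) / sqrt(var(b) / 4 + var(a) / 4)
  expect_equal(unname(t.test(b, a)$statistic), tstat)
  # group with < 2 converged fits is skipped with a notice
  bad <- lapply(c(5, 2), mk_fit)
  bad[[2]]$converged <- FALSE
  expect_message(res3 <- summarize_frap(c(fits[1:4], bad[2]),
                                        c(rep("ctrl", 4), "drug"),
                                        reference = "ctrl"), "skipped")
  expect_true(is.na(res3$comparisons$p_value))
})

test_that("trace CSVs round-trip through read/write", {
  tr <- generate_frap_trace(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_trace(tr, path)
  back <- read_frap_trace(path)
  expect_equal(back$t, tr$t)
  expect_equal(back$F_roi, tr$F_roi)
  expect_identical(back$bleach_index, tr$bleach_index)
})

test_that("frap_fit behaves like a model object", {
  tr <- generate_frap_trace(noise_sd = 0.01, seed = 10)
  fit <- fit_recovery(normalize_trace(tr))
  expect_s3_class(fit, "frap_fit")
  expect_named(coef(fit), c("F0", "A1", "k1", "A2", "k2"))
  expect_length(fitted(fit), nrow(fit$data))
  expect_equal(residuals(fit), fit$data$F_post - fitted(fit))
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$residual_rms)
  expect_output(print(fit), "T_half")
})
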