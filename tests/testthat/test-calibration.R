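# endpoint calibration, matching-condition search, width-function fit

test_that("endpoint calibration recovers the printed tanh constants", {
  rep <- calibrate_tanh_endpoints(roper_linear_params(), 15, 40)
  ps <- rep$pset
  expect_lt(abs(ps$b0 - 0.4475), 1e-3)
  expect_lt(abs(ps$A0 - 0.3325), 1e-3)
  expect_lt(abs(ps$Omega0 - 3 * pi / 200) / (3 * pi / 200), 0.005)
  expect_equal(ps$Omega0, ps$Omega1)          # deep-cold saturation
  # b and A reproduce the linear endpoint values exactly by construction
  expect_equal(rep$residuals[["b_low"]], 0, tolerance = 1e-12)
  expect_equal(rep$residuals[["b_high"]], 0, tolerance = 1e-12)
  expect_equal(rep$residuals[["A_low"]], 0, tolerance = 1e-12)
  expect_equal(rep$residuals[["A_high"]], 0, tolerance = 1e-12)
  # Omega anchored at the high endpoint; the low-end mismatch is reported
  expect_equal(rep$residuals[["Omega_high"]], 0, tolerance = 1e-12)
  expect_gt(abs(rep$residuals[["Omega_low"]]), 0)
})

test_that("degenerate endpoints make the calibration system singular", {
  expect_error(calibrate_tanh_endpoints(roper_linear_params(), 15, 40,
                                        C = 1e-18),
               "singular")
  expect_error(calibrate_tanh_endpoints(roper_linear_params(), 40, 15))
})

test_that("width-function self-consistency at the deep matching point", {
  # the fitted exponential law evaluated at the 40->15 final state must
  # land on the matched width parameter within 1 percent
  spec <- make_transition(40, 15)
  a_fit <- width_function(default_width_fit(), sqrt(spec$Tf_eff - spec$T0_eff),
                          spec)
  expect_lt(abs(a_fit - 0.002) / 0.002, 0.01)
})

test_that("matching search is deterministic and honours its bounds", {
  spec <- make_transition(40, 15)
  # degenerate bounds far from any root: reported non-converged
  mr_bad <- find_matching_a(default_set, spec, bounds = c(0.05, 0.1),
                            n_scan = 8L)
  expect_false(mr_bad$converged)
  expect_true(is.finite(mr_bad$residual))
  mr1 <- find_matching_a(default_set, spec, bounds = c(5e-4, 0.01),
                         n_scan = 16L)
  mr2 <- find_matching_a(default_set, spec, bounds = c(5e-4, 0.01),
                         n_scan = 16L)
  expect_identical(mr1, mr2)
  expect_true(mr1$converged)
  expect_lt(abs(mr1$residual), 1)
})

test_that("width-function fit recovers exact synthetic samples", {
  truth <- width_fit(a0 = 3.2e-4, alpha = 0.08)
  Tf <- c(12, 18, 24, 31, 38)
  samples <- data.frame(Tf_eff = Tf, a = truth$a0 * exp(truth$alpha * Tf))
  fit <- fit_width_function(samples)
  expect_equal(fit$a0, truth$a0, tolerance = 1e-10)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-10)
  expect_lt(max(abs(attr(fit, "residuals"))), 1e-10)
})

test_that("two-point fit through the printed anchors gives alpha = 0.1", {
  fit <- fit_width_function(data.frame(Tf_eff = c(15, 35),
                                       a = c(0.002, 0.002 * exp(2))))
  expect_equal(fit$alpha, 0.1, tolerance = 1e-12)
  expect_equal(fit$a0, 0.002 * exp(-1.5), tolerance = 1e-12)
})

test_that("fit input validation", {
  expect_error(fit_width_function(data.frame(Tf_eff = 15, a = 0.002)),
               "two distinct")
  expect_error(fit_width_function(data.frame(Tf_eff = c(15, 15),
                                             a = c(1e-3, 2e-3))),
               "two distinct")
  expect_error(fit_width_function(data.frame(Tf_eff = c(15, 20),
                                             a = c(-1e-3, 2e-3))),
               "positive")
  # list-of-(spec, a) input form
  fit <- fit_width_function(list(
    list(spec = make_transition(40, 15), a = 0.002),
    list(spec = make_transition(40, 35), a = 0.002 * exp(2))))
  expect_equal(fit$alpha, 0.1, tolerance = 1e-12)
})

test_that("calibration artefacts serialise to key-value configs", {
  rep <- calibrate_tanh_endpoints(roper_linear_params(), 15, 40)
  p <- withr::local_tempfile(fileext = ".cfg")
  write_calibration_report(rep, p)
  back <- read_param_config(p)
  expect_equal(back$b0, rep$pset$b0, tolerance = 1e-12)

  mr <- structure(list(a = 0.002, residual = -0.5, iterations = 12L,
                       converged = TRUE), class = "match_result")
  write_match_result(mr, p)
  kv <- coldburst:::read_keyvals(p)
  expect_equal(as.numeric(kv$a), 0.002)
  expect_equal(kv$converged, "true")
})

test_that("matched widths across transitions follow the exponential law", {
  # one matching search per cooling step from 40 degC; the matched width
  # must grow with the final temperature and refit the exponential law.
  # The per-transition alignment is only loosely pinned down (several
  # burst-grid roots exist), so the prefactor is checked to a factor of
  # two while the temperature sensitivity is tight.
  Tf <- c(15, 20, 25, 30, 35)
  mrs <- lapply(Tf, function(x)
    find_matching_a(default_set, make_transition(40, x)))
  a <- vapply(mrs, `[[`, numeric(1), "a")
  expect_true(all(vapply(mrs, `[[`, logical(1), "converged")))
  expect_true(all(diff(a) > 0))
  fit <- fit_width_function(data.frame(Tf_eff = Tf, a = a))
  expect_lt(abs(fit$alpha - 0.1) / 0.1, 0.25)
  expect_lt(abs(log(fit$a0 / 4.5e-4)), log(2))
})
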