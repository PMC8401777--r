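test_that("the SHAP kernel weight matches its closed form", {
  expect_equal(shap_kernel_weight(2, 4), 3 / (6 * 2 * 2))
  expect_equal(shap_kernel_weight(1, 2), 0.5)
  z <- 1:5
  expect_equal(shap_kernel_weight(z, 6), shap_kernel_weight(6 - z, 6))
  expect_error(shap_kernel_weight(0, 4), "0 < z < N")
  expect_error(shap_kernel_weight(4, 4), "0 < z < N")
})

test_that("Shapley values of a linear game match the closed form", {
  wts <- c(0.5, -0.3, 0.2, 1.0)
  f <- function(bits) sum(wts[intersect(bits, 1:4)])
  bg <- list(2L, c(2L, 3L), integer(0), 1:4)
  x <- c(1L, 3L)
  res <- shap_values(f, x, 1:4, bg, n_samples = 64, seed = 5,
                     bg_per_coalition = 4)
  pbar <- vapply(1:4, function(i)
    mean(vapply(bg, function(b) i %in% b, logical(1))), numeric(1))
  expect_equal(unname(res$phis), wts * ((1:4 %in% x) - pbar),
               tolerance = 1e-10)
  expect_equal(res$phi0 + sum(res$phis), res$fx, tolerance = 1e-10)
})

test_that("constant models yield a bare baseline", {
  fx <- fig5_fixture()
  # zero dual weight, bias -c: decision is the constant c everywhere
  model <- manual_ac_svm(list(fx$support), dual_coef = 0, b = -0.7)
  sh <- shap_explain(model, fx$test, n_samples = 256, seed = 1)
  expect_equal(unname(sh$phis), rep(0, length(sh$phis)))
  expect_equal(sh$phi0, 0.7)
})

test_that("features constant across instance and background are dummies", {
  f <- function(bits) 0.7 * (1 %in% bits) + 0.1
  bg <- list(3L, c(1L, 3L))
  res <- shap_values(f, c(1L, 3L), c(1L, 2L, 3L), bg, n_samples = 64,
                     seed = 2)
  expect_lt(abs(res$phis[["2"]]), 1e-8)  # never present anywhere
  expect_lt(abs(res$phis[["3"]]), 1e-8)  # present everywhere
  expect_equal(res$phis[["1"]], 0.7 * (1 - 0.5), tolerance = 1e-10)
})

test_that("local accuracy holds on a fitted model, exhaustively", {
  mm <- fixture_mmps()
  fit <- ac_svm(mm, C = 1)
  sh <- shap_explain(fit, mm[2, ], n_samples = 1024, seed = 9,
                     max_features = 8) |> suppressWarnings()
  expect_true(sh$exhaustive)
  d <- predict(fit, mm[2, ], type = "decision")
  expect_equal(sh$phi0 + sum(sh$phis), d, tolerance = 1e-6)
  expect_equal(sh$fx, d, tolerance = 1e-10)
})

test_that("sampled coalitions are reproducible under a seed", {
  mm <- fixture_mmps()
  fit <- ac_svm(mm, C = 1)
  a <- suppressWarnings(shap_explain(fit, mm[1, ], n_samples = 300,
                                     seed = 4, max_features = 12))
  b <- suppressWarnings(shap_explain(fit, mm[1, ], n_samples = 300,
                                     seed = 4, max_features = 12))
  expect_false(a$exhaustive)
  expect_identical(a$phis, b$phis)
})

test_that("force reports order by magnitude and flag absent features", {
  expl <- structure(list(phi0 = 0.1,
                         phis = c(`3` = 0.3, `7` = -0.2, `9` = 0.05),
                         present = c(`3` = TRUE, `7` = FALSE, `9` = TRUE),
                         fx = 0.25, n_samples = 6, exhaustive = TRUE),
                    class = "shap_explanation")
  fr <- force_report(expl)
  expect_equal(fr$phi, c(0.3, -0.2, 0.05))
  expect_equal(fr$present, c(1, 0, 1))
  expect_equal(attr(fr, "phi0"), 0.1)
})

test_that("comparison reports quantify Shapley mass on absent features", {
  mm <- fixture_mmps()
  fit <- ac_svm(mm, C = 1)
  ex <- explain(fit, mm[1, ])
  sh <- suppressWarnings(shap_explain(fit, mm[1, ], n_samples = 512,
                                      seed = 3, max_features = 9))
  cr <- compare_report(ex, sh)
  expect_s3_class(cr, "ac_comparison")
  # the exact method cannot weight absent features
  expect_equal(cr$summary$exact_absent_mass_fraction, 0)
  fr <- force_report(sh)
  want <- sum(abs(fr$phi[fr$present == 0])) / sum(abs(fr$phi))
  expect_equal(cr$summary$shap_absent_mass_fraction, want)
  # all-absent mass: fraction is 1 by definition
  expl2 <- structure(list(phi0 = 0, phis = c(`1` = 0.3, `2` = -0.1),
                          present = c(`1` = FALSE, `2` = FALSE),
                          fx = ex$decision, n_samples = 2,
                          exhaustive = TRUE), class = "shap_explanation")
  cr2 <- compare_report(ex, expl2)
  expect_equal(cr2$summary$shap_absent_mass_fraction, 1)
  # mismatched decision values are rejected
  expl3 <- expl2; expl3$fx <- ex$decision + 1
  expect_error(compare_report(ex, expl3), "disagree")
  # exact-only report leaves SHAP columns empty
  cr3 <- compare_report(ex)
  expect_true(all(is.na(cr3$table$phi)))
})
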