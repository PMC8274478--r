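test_that("bar table rejects duplicates and missing columns", {
  d <- data.frame(subject = "s", piece = "p", bar = c(1, 1), pupil = 0:1)
  expect_error(bar_table(d), "duplicate")
  expect_error(bar_table(data.frame(subject = "s", bar = 1)), "columns")
})

test_that("with the variance structure held at an iid identity, the fit is OLS", {
  set.seed(21)
  n <- 120
  d <- bar_table(data.frame(subject = "s1", piece = "p1", bar = 1:n,
                            pupil = NA, x1 = rnorm(n), x2 = rnorm(n)))
  d$pupil <- 0.5 + 0.3 * d$x1 - 0.2 * d$x2 + rnorm(n, 0, 0.4)
  spec <- model_spec(c("x1", "x2"), random = character(0))
  fit <- fit_lmm(d, spec, fix = list(sigma_ar = 1e-6, rho = 0, sigma_e = 0.4))
  ols <- coef(lm(pupil ~ x1 + x2, data = d))
  est <- fit$coefficients$estimate
  expect_lt(max(abs(est - ols) / abs(ols)), 1e-4)
})

test_that("single-group likelihood matches the dense multivariate-normal oracle", {
  set.seed(22)
  n <- 40
  rho <- 0.5
  sar <- 0.4
  se <- 0.2
  d <- bar_table(data.frame(subject = "s1", piece = "p1", bar = 1:n,
                            pupil = rnorm(n, 2), x = rnorm(n)))
  spec <- model_spec("x", random = character(0))
  fit <- fit_lmm(d, spec, fix = list(sigma_ar = sar, rho = rho, sigma_e = se))
  # dense GLS oracle: V = sar^2 rho^|i-j| + se^2 I
  V <- sar^2 * rho^abs(outer(1:n, 1:n, "-")) + diag(se^2, n)
  X <- cbind(1, d$x)
  Vi <- solve(V)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$pupil)
  r <- d$pupil - X %*% bh
  ll <- -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
                  as.numeric(t(r) %*% Vi %*% r))
  expect_lt(abs(fit$logLik - ll), 1e-6)
  expect_lt(max(abs(fit$coefficients$estimate - bh)), 1e-6)
  # the mapped parameters really were held fixed
  expect_equal(fit$varcomp$sigma_ar, sar, tolerance = 1e-8)
  expect_equal(fit$varcomp$rho, rho, tolerance = 1e-8)
  expect_equal(fit$varcomp$sigma_e, se, tolerance = 1e-8)
})

test_that("BIC satisfies k log(n) - 2 logLik and matches stats::BIC", {
  tab <- sim_bar_data(3, 2, 30, beta = c(x = 0.4), rho = 0.4,
                      sigma_ar = 0.3, sigma_e = 0.2, sigma_subject = 0.2,
                      sigma_piece = 0.1, seed = 23)
  fit <- fit_lmm(tab, model_spec("x"))
  expect_equal(fit$BIC, fit$k * log(fit$n) - 2 * fit$logLik,
               tolerance = 1e-8)
  expect_equal(fit$BIC, BIC(fit$model), tolerance = 1e-8)
  expect_true(fit$varcomp$rho > -1 && fit$varcomp$rho < 1)
})

test_that("estimates recover the generating coefficients and rho at scale", {
  tab <- sim_bar_data(4, 4, 120, beta = c(x1 = 0.3, x2 = -0.15), rho = 0.6,
                      sigma_ar = 0.25, sigma_e = 0.15, sigma_subject = 0.2,
                      sigma_piece = 0.15, seed = 24)
  fit <- fit_lmm(tab, model_spec(c("x1", "x2")))
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "x1"] - 0.3), 3 * co$se[co$term == "x1"])
  expect_lt(abs(co$estimate[co$term == "x2"] + 0.15),
            3 * co$se[co$term == "x2"])
  expect_lt(abs(fit$varcomp$rho - 0.6), 0.12)
})

test_that("hierarchical addition reports df-1 chi-squares against the previous model", {
  tab <- sim_bar_data(3, 2, 60, beta = c(strong = 0.5, null = 0), rho = 0.3,
                      sigma_ar = 0.2, sigma_e = 0.2, seed = 25)
  cmp <- hierarchical_compare(tab, model_spec(character(0)),
                              c("strong", "null"))
  expect_identical(cmp$predictor, c("(null)", "strong", "null"))
  expect_true(all(cmp$chisq[-1] >= 0))
  expect_gt(cmp$chisq[2], cmp$chisq[3])
  expect_lt(cmp$p[2], 0.001)
  # likelihood monotonicity along the chain, via the reported chi-squares
  expect_true(all(cmp$chisq[-1] > -1e-6))
  # empty predictor list degenerates to the null row alone
  cmp0 <- hierarchical_compare(tab, model_spec(character(0)), character(0))
  expect_identical(nrow(cmp0), 1L)
})

test_that("a redundant copy adds no information and each new parameter costs log(n)", {
  tab <- sim_bar_data(3, 2, 60, beta = c(x = 0.4), rho = 0.3,
                      sigma_ar = 0.2, sigma_e = 0.2, sigma_subject = 0.2,
                      sigma_piece = 0.15, seed = 26)
  # an exact copy is aliased: the fit drops it, so the likelihood and the
  # parameter count (hence BIC) are unchanged
  tab$x_copy <- tab$x
  cmp <- suppressWarnings(
    hierarchical_compare(tab, model_spec(character(0)), c("x", "x_copy")))
  expect_lt(cmp$chisq[3], 1e-6)
  expect_equal(cmp$BIC[3], cmp$BIC[2], tolerance = 1e-6)
  # an informative second predictor costs exactly log(n) on top of its
  # likelihood gain: BIC_step = log(n) - chisq
  set.seed(27)
  tab$z <- rnorm(nrow(tab))
  cmp2 <- hierarchical_compare(tab, model_spec(character(0)), c("x", "z"))
  expect_equal(cmp2$BIC[3] - cmp2$BIC[2], log(nrow(tab)) - cmp2$chisq[3],
               tolerance = 1e-6)
})

test_that("centering a predictor changes only the intercept", {
  tab <- sim_bar_data(3, 2, 40, beta = c(x = 0.4), rho = 0.3,
                      sigma_ar = 0.2, sigma_e = 0.2, sigma_subject = 0.2,
                      sigma_piece = 0.15, seed = 28)
  f1 <- fit_lmm(tab, model_spec("x"))
  tab2 <- tab
  tab2$x <- tab2$x + 5
  f2 <- fit_lmm(tab2, model_spec("x"))
  s1 <- f1$coefficients$estimate[f1$coefficients$term == "x"]
  s2 <- f2$coefficients$estimate[f2$coefficients$term == "x"]
  expect_lt(abs(s1 - s2), 1e-6)
  i1 <- f1$coefficients$estimate[1]
  i2 <- f2$coefficients$estimate[1]
  expect_equal(i2, i1 - 5 * s1, tolerance = 1e-4)
})

test_that("rows with missing fields are excluded and counted", {
  tab <- sim_bar_data(2, 2, 30, beta = c(x = 0.4), rho = 0.3,
                      sigma_ar = 0.2, sigma_e = 0.2, seed = 29)
  tab$x[c(3, 17, 40)] <- NA
  fit <- fit_lmm(tab, model_spec("x"))
  expect_identical(fit$n_excluded, 3L)
  expect_identical(fit$n, nrow(tab) - 3L)
})

test_that("piece contrasts cover all pairs, are antisymmetric, and detect offsets", {
  set.seed(30)
  n_bars <- 120
  mk <- function(pieces, offs) {
    rows <- lapply(seq_along(pieces), function(i) {
      ar <- as.numeric(arima.sim(list(ar = 0.4), n_bars, sd = 0.15))
      data.frame(subject = "perf1", piece = pieces[i], bar = 1:n_bars,
                 pupil = offs[i] + ar + rnorm(n_bars, 0, 0.1))
    })
    bar_table(do.call(rbind, rows))
  }
  tab <- mk(c("A", "B", "C"), c(0, 0.3, 0))
  ct <- piece_contrasts(tab)
  expect_identical(nrow(ct), 3L)
  expect_setequal(paste(ct$piece_a, ct$piece_b),
                  c("A B", "A C", "B C"))
  ab <- ct[ct$piece_a == "A" & ct$piece_b == "B", ]
  expect_true(ab$significant)
  expect_gt(ab$estimate, 0.1)
  # antisymmetry under relabelling that reverses the base ordering
  tab2 <- tab
  tab2$piece <- c(A = "Z", B = "Y", C = "X")[tab$piece]
  ct2 <- piece_contrasts(tab2)
  zy <- ct2[ct2$piece_a == "X" & ct2$piece_b == "Y", ]   # C vs B reversed
  bc <- ct[ct$piece_a == "B" & ct$piece_b == "C", ]
  expect_equal(zy$estimate, -bc$estimate, tolerance = 1e-4)
})

test_that("Wilcoxon signed-rank matches the textbook small cases", {
  w <- wilcoxon_signed_rank(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(w$W, 0)
  expect_equal(w$p, 0.125)
  # swapping the samples changes nothing
  w2 <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(w2$W, w$W)
  expect_equal(w2$p, w$p)
  # negative ranks summing to 4 give W = 4
  w3 <- wilcoxon_signed_rank(c(2, 3, 4, -5), c(1, 1, 1, 1))
  expect_equal(w3$W, 4)
  # zero differences are dropped; all-zero is undefined
  w4 <- wilcoxon_signed_rank(c(1, 5, 6, 7, 8), c(1, 1, 2, 3, 4))
  expect_equal(w4$n, 4L)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "undefined")
})

test_that("exact p-values agree with full sign-pattern enumeration and wilcox.test", {
  set.seed(31)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      x <- round(rnorm(n, 0.3), 2)
      y <- round(rnorm(n), 2)
      d <- x - y
      if (any(d == 0)) next
      got <- wilcoxon_signed_rank(x, y)
      oracle <- brute_wilcoxon(x, y)
      expect_equal(got$W, oracle$W)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
      if (!any(duplicated(abs(d)))) {
        ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                            exact = TRUE))
        expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      }
    }
  }
})
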