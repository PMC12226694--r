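# Independent oracle: maximize the penalized log-likelihood directly with
# optim over (intercept, slope), no IWLS involved.
pll_oracle <- function(X, y) {
  obj <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    info <- crossprod(X, X * (mu * (1 - mu)))
    -(sum(y * eta - log1p(exp(eta))) +
        0.5 * determinant(info, logarithm = TRUE)$modulus)
  }
  optim(c(0, 0), obj, method = "BFGS", control = list(maxit = 500))
}

test_that("balanced 2x2 table gives a zero estimate and p = 1", {
  d <- data.frame(y = rep(c(1, 0, 1, 0), 5), x = rep(c(1, 1, 0, 0), 5))
  fit <- firth_logistic(y ~ x, d)
  expect_lt(abs(coef(fit)["x"]), 1e-6)
  expect_equal(fit$p_value[["x"]], 1, tolerance = 1e-6)
})

test_that("complete separation yields a finite estimate matching the direct maximizer", {
  d <- data.frame(y = c(rep(1, 5), rep(0, 5)), x = c(rep(1, 5), rep(0, 5)))
  fit <- firth_logistic(y ~ x, d)
  expect_true(all(is.finite(coef(fit))))
  expect_gt(coef(fit)["x"], 0)
  expect_lt(fit$p_value[["x"]], 0.05)

  X <- cbind(1, d$x)
  oracle <- pll_oracle(X, d$y)
  expect_equal(unname(coef(fit)), oracle$par, tolerance = 1e-4)
  expect_equal(unname(fit$loglik), -oracle$value, tolerance = 1e-6)
})

test_that("a known log-odds is recovered with small bias at n = 2000", {
  set.seed(202)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
  fit <- firth_logistic(y ~ x, data.frame(y = y, x = x))
  expect_lt(abs(coef(fit)["x"] - 1.5) / 1.5, 0.15)
  # ordinary ML is consistent here and must land close to the same estimate
  ml <- glm(y ~ x, family = binomial)
  expect_equal(unname(coef(fit)["x"]), unname(coef(ml)["x"]),
               tolerance = 0.02)
})

test_that("constant outcomes are rejected", {
  d <- data.frame(y = rep(0, 10), x = rnorm(10))
  expect_error(firth_logistic(y ~ x, d), "constant")
  cc <- canonical_cohort()
  cc$malignant <- FALSE
  expect_error(screen_predictors(cc), "constant")
})

test_that("canonical-cohort screening ranks peritoneal disease and composition first", {
  eff <- screen_predictors(canonical_cohort())
  ord <- eff$name[order(eff$p_value)]
  expect_setequal(ord[1:2], c("peritoneal_disease", "composition"))
  expect_gt(eff$estimate[eff$name == "peritoneal_disease"], 0)
  expect_gt(eff$estimate[eff$name == "composition"], 0)
  # intralesional fat points toward benignity
  expect_lt(eff$estimate[eff$name == "fat_present"], 0)
  # age, size, septa and fluid type carry no signal
  ns <- eff$p_value[eff$name %in% c("age_years", "max_diameter_mm",
                                    "locularity", "fluid_type")]
  expect_true(all(ns > 0.10))
})

test_that("screening requires known outcomes and flags unknown predictors", {
  cc <- canonical_cohort()
  cc$malignant[3] <- NA
  expect_error(screen_predictors(cc), "malignant")
  expect_error(screen_predictors(canonical_cohort(), predictors = "bogus"),
               "unknown predictor")
})

test_that("joint model keeps estimates finite under quasi-separation", {
  fit <- attr(screen_predictors(canonical_cohort(), joint = TRUE), "fit")
  expect_true(all(is.finite(coef(fit))))
  expect_true(fit$converged)
})
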