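test_that("nodes-from-root depths match hand counts", {
  t2 <- ape::read.tree(text = "(A,B);")
  d2 <- nodes_from_root(t2)
  expect_equal(d2$nodes_from_root, c(1, 1))

  cat_tree <- ape::read.tree(text = "(((A,B),C),D);")
  d <- nodes_from_root(cat_tree, c("A", "B", "C", "D"))
  expect_equal(d$nodes_from_root, c(3, 3, 2, 1))

  # invariant under tip-label permutation of the same topology
  perm <- ape::read.tree(text = "(((B,A),C),D);")
  dp <- nodes_from_root(perm, c("A", "B", "C", "D"))
  expect_equal(dp$nodes_from_root, d$nodes_from_root)

  expect_error(nodes_from_root(cat_tree, c("A", "Z")), "Z")

  # the bundled family tree: depths increase toward the derived families
  fam <- nodes_from_root(synthetic_family_tree())
  get <- function(f) fam$nodes_from_root[fam$tip == f]
  expect_gt(get("Lycosidae"), get("Zodariidae"))
  expect_gt(get("Lycosidae"), get("Atypidae"))
  expect_true(all(fam$nodes_from_root >= 1))
})

test_that("IRLS matches glm() and a direct likelihood-maximisation oracle", {
  x <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(2, 3, 2, 5, 8, 7, 12, 15, 19, 28)
  fit <- fit_poisson_glm(y, x)
  expect_true(fit$converged)
  # independent oracle 1: direct BFGS maximisation of the log-likelihood
  par <- oracle_poisson_fit(y, x)
  expect_equal(unname(fit$coefficients), par, tolerance = 1e-6)
  # independent oracle 2: stats::glm
  g <- stats::glm(y ~ x, family = stats::poisson())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(fit$deviance, g$deviance, tolerance = 1e-8)
  expect_equal(fit$null_deviance, g$null.deviance, tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(summary(g)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$lrt_chi2, g$null.deviance - g$deviance, tolerance = 1e-8)
})

test_that("constant counts give zero slope and zero LRT", {
  fit <- fit_poisson_glm(rep(7L, 10), 1:10)
  expect_equal(unname(fit$coefficients[["slope"]]), 0, tolerance = 1e-12)
  expect_equal(fit$lrt_chi2, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["intercept"]]), log(7),
               tolerance = 1e-10)
})

test_that("slope is recovered within 3 SE on simulated data (n = 200)", {
  set.seed(61)
  x <- runif(200, 0, 8)
  y <- rpois(200, exp(0.5 + 0.3 * x))
  fit <- fit_poisson_glm(y, x)
  expect_lt(abs(fit$coefficients[["slope"]] - 0.3),
            3 * fit$se[["slope"]])
  expect_lt(abs(fit$coefficients[["intercept"]] - 0.5),
            3 * fit$se[["intercept"]])
  expect_lt(fit$p_value, 1e-10)
})

test_that("slope sign follows the empirical trend and exclusion flag works", {
  set.seed(62)
  x <- rep(1:6, each = 8)
  y_up <- rpois(48, exp(0.2 + 0.25 * x))
  expect_gt(fit_poisson_glm(y_up, x)$coefficients[["slope"]], 0)
  y_down <- rpois(48, exp(2.5 - 0.3 * x))
  expect_lt(fit_poisson_glm(y_down, x)$coefficients[["slope"]], 0)
  # excluding an extreme point changes the fit accordingly
  y_out <- y_up; y_out[1] <- 500
  f_all <- fit_poisson_glm(y_out, x)
  f_ex <- fit_poisson_glm(y_out, x, exclude = 1)
  expect_equal(f_ex$n, 47)
  expect_false(isTRUE(all.equal(f_all$coefficients, f_ex$coefficients)))
  # degenerate input
  expect_error(fit_poisson_glm(rep(0L, 5), 1:5), "zero")
  expect_error(fit_poisson_glm(c(1.5, 2, 3), 1:3), "integer")
})

test_that("Wald 95% interval coverage over seeded replicates at n = 48", {
  set.seed(63)
  covered <- 0; reps <- 200
  for (r in 1:reps) {
    x <- sample(1:12, 48, replace = TRUE)
    y <- rpois(48, exp(0.3 + 0.2 * x))
    fit <- fit_poisson_glm(y, x)
    lo <- fit$coefficients[["slope"]] - 1.96 * fit$se[["slope"]]
    hi <- fit$coefficients[["slope"]] + 1.96 * fit$se[["slope"]]
    if (lo <= 0.2 && 0.2 <= hi) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.90)
  expect_lte(covered / reps, 0.99)
})

test_that("deviance decreases monotonically across IRLS iterations", {
  # re-run the IRLS loop manually, tracking deviance trajectories
  set.seed(64)
  for (r in 1:10) {
    x <- runif(30, 0, 5)
    y <- rpois(30, exp(0.4 + 0.35 * x))
    X <- cbind(1, x)
    beta <- c(log(mean(y)), 0)
    devs <- numeric()
    for (it in 1:25) {
      eta <- drop(X %*% beta); mu <- exp(eta)
      beta <- stats::lm.wfit(X, eta + (y - mu) / mu, mu)$coefficients
      mu2 <- exp(drop(X %*% beta))
      devs <- c(devs, 2 * sum(ifelse(y > 0, y * log(y / mu2), 0) - (y - mu2)))
    }
    expect_true(all(diff(devs) <= 1e-8))
    fit <- fit_poisson_glm(y, x)
    expect_lte(fit$deviance, fit$null_deviance)
    expect_gte(fit$lrt_chi2, 0)
  }
})
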