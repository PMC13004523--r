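make_out <- function(mu_adjusted, pi, theta, mu = mu_adjusted) {
  list(mu_adjusted = mu_adjusted, pi = pi, theta = theta, mu = mu)
}

test_that("mean-Frobenius reconstruction loss matches hand values", {
  X <- matrix(3, 1, 1)
  expect_equal(nmf_loss(X, X), 0)
  expect_equal(nmf_loss(X, matrix(1, 1, 1)), 2)          # |3-1| / 1
  X2 <- matrix(0, 2, 2)
  expect_equal(nmf_loss(X2, matrix(1, 2, 2)), 0.5)       # sqrt(4) / 4
  expect_error(nmf_loss(X2, matrix(1, 2, 3)), "shape")
})

test_that("ZINB log-PMF agrees with hand evaluations", {
  expect_equal(zinb_log_pmf(0, 1, 1, 1), 0)
  expect_equal(zinb_log_pmf(0, 1, 1, 0), log(0.5))       # (theta/(mu+theta))^theta
  expect_equal(zinb_log_pmf(1, 1, 1, 0.5), log(0.125))   # 0.5 * 1/2 * 1/2
  expect_identical(zinb_log_pmf(2, 1, 1, 1), -Inf)       # pi = 1 with x > 0
})

test_that("ZINB PMF is properly normalized over the parameter grid", {
  for (mu in c(0.1, 1, 10)) {
    for (theta in c(0.5, 1, 5)) {
      for (pi in c(0, 0.3, 0.9)) {
        upper <- max(50, qnbinom(1e-9, size = theta, mu = mu, lower.tail = FALSE))
        total <- sum(exp(zinb_log_pmf(0:upper, mu, theta, pi)))
        expect_equal(total, 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("ZINB reduces to NB at pi = 0 and to Poisson as theta grows", {
  x <- 0:20
  for (mu in c(0.3, 1, 5, 10)) {
    expect_equal(zinb_log_pmf(x, mu, 2.5, 0),
                 dnbinom(x, size = 2.5, mu = mu, log = TRUE),
                 tolerance = 1e-10)
    expect_equal(zinb_log_pmf(x, mu, 1e6, 0),
                 dpois(x, mu, log = TRUE), tolerance = 1e-4)
  }
})

test_that("mean ZINB negative log-likelihood matches hand evaluation", {
  X0 <- matrix(0, 1, 1, dimnames = list("c", "g"))
  out0 <- make_out(matrix(1, 1, 1), pi = stats::plogis(100), theta = 1)
  expect_lt(abs(zinb_nll(X0, out0)), 1e-10)

  # entries (0, 1) with mu = 1, theta = 1, pi = 0:
  # -log P(0) = log 2, -log P(1) = log 4
  X <- matrix(c(0, 1), 1, 2)
  out <- make_out(matrix(1, 1, 2), pi = c(0, 0), theta = 1)
  expect_equal(zinb_nll(X, out), (log(2) + log(4)) / 2)
})

test_that("the NLL decreases as the mean approaches the best fit on a grid", {
  X <- matrix(c(3, 5, 2, 7), 2, 2)
  grid <- seq(0.5, 8, by = 0.25)
  nll <- vapply(grid, function(mu) {
    zinb_nll(X, make_out(matrix(mu, 2, 2), pi = rep(0.01, 2), theta = 2))
  }, numeric(1))
  best <- grid[which.min(nll)]
  # moving the mean toward the grid optimum never increases the NLL
  left <- nll[grid <= best]
  right <- nll[grid >= best]
  expect_true(all(diff(left) <= 1e-12))
  expect_true(all(diff(right) >= -1e-12))
  expect_gt(best, 3)   # near the data mean 4.25, not at the boundary
})

test_that("row z-scores use the population standard deviation", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-7)
  expect_equal(as.numeric(zscore_rows(matrix(5, 1, 3))), rep(0, 3))
  M <- matrix(runif(12), 3, 4)
  expect_equal(zscore_rows(2.5 * M + 7), zscore_rows(M), tolerance = 1e-6)
})

test_that("z-score loss matches hand evaluation and is depth-invariant", {
  X <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  mu <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(zscore_loss(X, mu), 2, tolerance = 1e-6)
  expect_equal(zscore_loss(X, X), 0)
  expect_equal(zscore_loss(X, 2 * X + 7), 0, tolerance = 1e-12)

  set.seed(1)
  A <- matrix(rpois(40, 4) + 1, 5, 8)
  M <- matrix(runif(40, 0.5, 3), 5, 8)
  s <- runif(5, 0.2, 5)
  expect_equal(zscore_loss(A, M), zscore_loss(A, s * M), tolerance = 1e-6)
})

test_that("classification loss behaves like a softmax cross-entropy", {
  W_plus <- diag(2)
  y <- c(1L, 2L)
  # near-certain probe: huge aligned weights
  expect_lt(classification_loss(W_plus, y, 100 * diag(2), c(0, 0)), 1e-10)
  # zero probe: uniform over C classes
  expect_equal(classification_loss(W_plus, y, matrix(0, 2, 3), numeric(3)),
               log(3))
  # shift invariance
  expect_equal(classification_loss(W_plus, y, diag(2), c(5, 5)),
               classification_loss(W_plus, y, diag(2), c(0, 0)))
  # unlabeled cells are excluded
  expect_equal(classification_loss(rbind(W_plus, c(0.5, 0.5)),
                                   c(1L, 2L, NA), 100 * diag(2), c(0, 0)),
               classification_loss(W_plus, y, 100 * diag(2), c(0, 0)))
  expect_error(classification_loss(W_plus, c(NA, NA), diag(2), c(0, 0)),
               "labeled")
})

test_that("the switched total is the lambda-weighted sum of its terms", {
  inst <- grad_instance()
  out <- model_forward(inst$params, inst$s, inst$prior)
  all_on <- total_loss(inst$X, out, loss_weights(1, 1, 1, 1), inst$y, inst$params)
  expect_equal(all_on$total,
               all_on$nmf + all_on$zinb + all_on$zscore + all_on$class_,
               tolerance = 1e-9)
  off <- total_loss(inst$X, out, loss_weights(0, 0, 0, 0))
  expect_equal(off$total, 0)
  expect_setequal(off$disabled, c("nmf", "zinb", "zscore", "class_"))
  only_nmf <- total_loss(inst$X, out, loss_weights(1, 0, 0, 0))
  expect_equal(only_nmf$total, only_nmf$nmf)
  expect_error(total_loss(inst$X, out, loss_weights(1, 1, 1, 1)),
               "label")
  expect_error(loss_weights(nmf = 0.5), "0 or 1")
})

test_that("analytic gradients match central finite differences per term", {
  inst <- grad_instance()
  for (w in list(loss_weights(1, 0, 0, 0), loss_weights(0, 1, 0, 0),
                 loss_weights(0, 0, 1, 0), loss_weights(0, 0, 0, 1),
                 loss_weights(1, 1, 1, 1))) {
    analytic <- flatten_params(
      loss_and_grad(inst$X, inst$params, inst$s, w, inst$prior, NULL,
                    inst$y)$grads)
    numeric <- numeric_gradient(inst, w)
    rel <- abs(analytic - numeric) / pmax(abs(numeric), 1e-8)
    rel[abs(numeric) < 1e-10 & abs(analytic) < 1e-10] <- 0
    expect_lt(max(rel), 1e-4)
  }
})
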