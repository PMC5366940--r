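# instance generator: gaussian noise features with an optional planted
# class difference in the first column(s)
plr_instance <- function(seed, n = 30, p = 40, effect = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- rep(c("F", "M"), length.out = n)
  x[, 1] <- x[, 1] + ifelse(y == "M", effect, 0)
  list(x = x, y = y)
}

test_that("the ridge solver reaches a stationary point of the criterion", {
  set.seed(20)
  X <- cbind(1, matrix(rnorm(60), 30, 2))
  y <- rbinom(30, 1, plogis(X[, 2]))
  f <- methylsex:::ridge_logistic(X, y, 1 / 32)
  expect_lt(f$grad_norm, 1e-6)
  expect_true(f$converged)
  # optimum beats 1000 random coefficient vectors (random-search oracle)
  crit <- function(b) {
    eta <- drop(X %*% b)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      (1 / 32) * sum(b[-1]^2)
  }
  rand <- replicate(1000, crit(rnorm(3, sd = 2)))
  expect_lte(f$criterion, min(rand))
  # and agrees with an independent BFGS fit
  ref <- ref_ridge_fit(X, y, 1 / 32)
  expect_equal(f$criterion, ref$criterion, tolerance = 1e-9)
})

test_that("a huge penalty shrinks slopes to zero and leaves the prevalence", {
  set.seed(21)
  X <- cbind(1, rnorm(40), rnorm(40))
  y <- rep(c(0, 1), c(15, 25))
  f <- methylsex:::ridge_logistic(X, y, 1e6)
  expect_true(all(abs(f$beta[-1]) < 1e-3))
  expect_equal(f$beta[1], qlogis(mean(y)), tolerance = 1e-3)
})

test_that("perfect separation stays finite under the ridge penalty", {
  z <- c(rep(-1, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  f <- methylsex:::ridge_logistic(cbind(1, z), y, 1 / 32)
  expect_true(all(is.finite(f$beta)))
  expect_true(f$converged)
  null <- methylsex:::ridge_logistic(cbind(1, z * 0), y, 1 / 32)
  expect_lt(f$criterion, null$criterion)
})

test_that("a strongly informative feature founds the first cluster", {
  inst <- plr_instance(22)
  fit <- plr(inst$x, inst$y, n_clusters = 3)
  expect_equal(fit$clusters[[1]]$feature[1], "f1")
  expect_equal(fit$clusters[[1]]$sign[1], 1)
  expect_equal(fit$levels, c("F", "M"))
})

test_that("greedy search matches the independent brute-force search rule", {
  set.seed(23)
  n <- 20; p <- 6
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(0:1, each = 10)
  x[, 3] <- x[, 3] + y
  Xs <- scale(x)
  got <- methylsex:::grow_cluster(Xs, y, matrix(0, n, 0), 1 / 32,
                                  max_size = 3, screen = Inf)
  ref <- ref_greedy_cluster(Xs, y, 1 / 32, max_size = 3)
  expect_equal(got$criterion, ref$criterion, tolerance = 1e-9)
  expect_setequal(got$members, ref$members)
})

test_that("the criterion decreases strictly along accepted clusters", {
  inst <- plr_instance(24, p = 30)
  fit <- plr(inst$x, inst$y, n_clusters = 5)
  path <- c(fit$null_criterion, fit$criterion_path)
  expect_true(all(diff(path) < 0))
  expect_lte(fit$criterion, fit$null_criterion)
  # pure noise still never accepts a worsening step
  set.seed(25)
  xn <- matrix(rnorm(20 * 15), 20, 15,
               dimnames = list(NULL, paste0("f", 1:15)))
  yn <- rep(c("a", "b"), 10)
  fn <- plr(xn, yn, n_clusters = 4)
  expect_true(all(diff(c(fn$null_criterion, fn$criterion_path)) < 0))
})

test_that("q = 1 yields exactly one cluster", {
  inst <- plr_instance(26)
  fit <- plr(inst$x, inst$y, n_clusters = 1)
  expect_equal(fit$n_clusters, 1L)
  expect_length(fit$coefficients, 2L)
})

test_that("an identical duplicate feature is never co-selected", {
  inst <- plr_instance(27, p = 10)
  x <- cbind(inst$x, dup = inst$x[, 1])
  fit <- plr(x, inst$y, n_clusters = 1)
  members <- fit$clusters[[1]]$feature
  expect_false(all(c("f1", "dup") %in% members))
})

test_that("location shifts of a feature do not change the fit", {
  inst <- plr_instance(28)
  f1 <- plr(inst$x, inst$y, n_clusters = 2)
  x2 <- inst$x; x2[, 5] <- x2[, 5] + 100
  f2 <- plr(x2, inst$y, n_clusters = 2)
  expect_equal(f1$criterion, f2$criterion, tolerance = 1e-9)
  expect_equal(predict(f1, inst$x), predict(f2, x2), tolerance = 1e-9)
})

test_that("sign-flipping a feature leaves fitted probabilities unchanged", {
  inst <- plr_instance(29)
  f1 <- plr(inst$x, inst$y, n_clusters = 2)
  x2 <- inst$x; x2[, 1] <- -x2[, 1]
  f2 <- plr(x2, inst$y, n_clusters = 2)
  expect_equal(f2$criterion, f1$criterion, tolerance = 1e-9)
  expect_equal(predict(f2, x2), predict(f1, inst$x), tolerance = 1e-9)
})

test_that("prediction reuses training standardization and flags absences", {
  inst <- plr_instance(30, effect = 4)
  tr <- 1:20; te <- 21:30
  fit <- plr(inst$x[tr, ], inst$y[tr], n_clusters = 2)
  # training samples reproduce the fit-time error
  pr_tr <- predict(fit, inst$x[tr, ], type = "class")
  expect_equal(mean(pr_tr != inst$y[tr]),
               mean((fitted(fit) >= 0.5) != (fit$training$y == 1)))
  # held-out strong signal is classified cleanly
  pr_te <- predict(fit, inst$x[te, ], type = "class")
  expect_equal(mean(pr_te != inst$y[te]), 0)
  # a matrix missing model features is an explicit error
  used <- fit$clusters[[1]]$feature[1]
  xbad <- inst$x[te, setdiff(colnames(inst$x), used)]
  expect_error(predict(fit, xbad), "absent")
})

test_that("probabilities are monotone in a centroid along its coefficient", {
  inst <- plr_instance(31)
  fit <- plr(inst$x, inst$y, n_clusters = 1)
  b <- fit$coefficients["cluster1"]
  pr <- project_centroids(fit, inst$x)[, 1]
  pp <- predict(fit, inst$x)
  ord <- order(pr * sign(b))
  expect_true(all(diff(pp[ord]) >= -1e-12))
})

test_that("centroid projection behaves and separates planted classes", {
  inst <- plr_instance(32)
  f1 <- plr(inst$x, inst$y, n_clusters = 1)
  pj <- project_centroids(f1, inst$x)
  expect_true(all(pj[, 2] == 0))
  f2 <- plr(inst$x, inst$y, n_clusters = 3)
  pj2 <- project_centroids(f2, inst$x)
  expect_equal(dim(pj2), c(30L, 2L))
  # extra unused features do not perturb coordinates
  xplus <- cbind(inst$x, extra = rnorm(30))
  expect_equal(project_centroids(f2, xplus), pj2)
  # class means separate along predictor 1 by > 2 pooled SDs
  g <- split(pj2[, 1], inst$y)
  pooled_sd <- sqrt(mean(c(var(g$F), var(g$M))))
  expect_gt(abs(mean(g$M) - mean(g$F)), 2 * pooled_sd)
})

test_that("degenerate inputs are rejected", {
  inst <- plr_instance(33)
  expect_error(plr(inst$x, rep("M", 30)), "two classes")
  expect_error(plr(inst$x, c(rep("F", 29), "M")), "2 samples")
  xna <- inst$x; xna[1, 1] <- NA
  expect_error(plr(xna, inst$y), "missing")
  # zero-variance features are dropped with a warning, not an error
  xz <- inst$x; xz[, 2] <- 0.5
  expect_warning(fz <- plr(xz, inst$y, n_clusters = 1), "zero-variance")
  expect_false("f2" %in% fz$clusters[[1]]$feature)
})

test_that("JSON serialization restores an equivalent classifier", {
  inst <- plr_instance(34)
  fit <- plr(inst$x, inst$y, n_clusters = 2)
  tf <- tempfile(fileext = ".json")
  write_plr(fit, tf)
  back <- read_plr(tf)
  expect_equal(predict(back, inst$x), predict(fit, inst$x), tolerance = 1e-12)
  expect_equal(project_centroids(back, inst$x),
               project_centroids(fit, inst$x), tolerance = 1e-12)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
})

test_that("residuals and summary expose the fit state", {
  inst <- plr_instance(35)
  fit <- plr(inst$x, inst$y, n_clusters = 2)
  r <- residuals(fit)
  expect_length(r, 30L)
  expect_equal(sign(r), sign(fit$training$y - fitted(fit)))
  s <- summary(fit)
  expect_s3_class(s, "summary.plr")
  expect_equal(s$training_error, 0)
})
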