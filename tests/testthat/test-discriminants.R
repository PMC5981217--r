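test_that("LDA discriminants respect symmetry, ties and monotonicity", {
  set.seed(41)
  mu <- rbind(a = c(-1, 0), b = c(1, 0))
  Z <- rbind(matrix(rnorm(60, sd = 0.3), 30) + rep(mu["a", ], each = 30),
             matrix(rnorm(60, sd = 0.3), 30) + rep(mu["b", ], each = 30))
  lab <- rep(c("a", "b"), each = 30)
  m <- fit_lda(Z, lab, priors = "uniform")
  # the midpoint of the class means scores (numerically) equally
  mid <- colMeans(m$class_means)
  d <- predict_lda(m, mid)$discriminant
  expect_equal(unname(d[1, "a"]), unname(d[1, "b"]), tolerance = 1e-8)
  # exact tie resolves to the earlier class, with a message
  sym <- fit_lda(rbind(c(-1, 0), c(-1, 2), c(1, 0), c(1, 2)),
                 c("a", "a", "b", "b"), priors = "uniform")
  expect_message(tie <- predict_lda(sym, c(0, 1))$label, "tie")
  expect_equal(tie, "a")
  # class means classify to their own class
  expect_equal(predict_lda(m, m$class_means)$label, c("a", "b"))
  # moving toward a class mean raises its discriminant monotonically
  steps <- seq(0, 1, 0.1)
  dvals <- predict_lda(m, outer(steps, m$class_means["b", ]))$discriminant
  expect_true(all(diff(dvals[, "b"]) > 0))
  expect_error(predict_lda(m, c(1, 2, 3)), "dimension")
})

test_that("LDA equals the Mahalanobis-distance rule under equal priors", {
  set.seed(42)
  k <- 4
  mu <- 6 * rbind(a = rnorm(k), b = rnorm(k), c = rnorm(k))
  A <- matrix(rnorm(k * k), k); S <- crossprod(A) / k + diag(k)
  L <- chol(S)
  Z <- NULL; lab <- NULL
  for (cl in rownames(mu)) {
    Z <- rbind(Z, matrix(rnorm(40 * k), 40) %*% L +
                 rep(mu[cl, ], each = 40))
    lab <- c(lab, rep(cl, 40))
  }
  m <- fit_lda(Z, lab, priors = "uniform")
  pts <- matrix(rnorm(100 * k, sd = 2), 100)
  expect_equal(predict_lda(m, pts)$label,
               mahalanobis_oracle(pts, m$class_means, m$cov))
  # and a well-separated fixture trains to 100 percent
  expect_equal(mean(predict_lda(m, Z)$label == lab), 1)
})

test_that("Q-squared is the squared residual norm", {
  expect_equal(q_squared(numeric(5)), 0)
  expect_equal(q_squared(c(3, 4)), 25)
  expect_equal(q_squared(rbind(c(3, 4), c(0, 2))), c(25, 4))
  # with K = n-1 components the training data are reconstructed exactly
  set.seed(43)
  X <- matrix(rnorm(6 * 10), 6)
  m <- fit_plsda(X, c("a", "a", "b", "b", "a", "b"), K = 5)
  q2 <- q_squared(pls_project(m, X, k = ncol(m$W))$residual)
  expect_lt(max(q2) / sum(X^2), 1e-16)
})

test_that("Jackson-Mudholkar threshold matches Monte-Carlo quantiles", {
  # single eigenvalue: h0 = 1/3 and the closed form is within 3 percent of
  # the simulated 95 percent quantile of lambda * chi-square(1)
  set.seed(44)
  lam <- 2.7
  res <- matrix(rnorm(4000, sd = sqrt(lam)), ncol = 1)
  res <- cbind(res, matrix(0, nrow(res), 3))     # p > 1, rank 1
  qm <- fit_q_model(res, alpha = 0.05)
  expect_equal(qm$h0, 1 / 3, tolerance = 0.05)
  mc <- quantile(lam * rnorm(1e6)^2, 0.95)
  # exact-theta version of the threshold against the Monte-Carlo oracle
  z <- qnorm(0.95)
  thr_exact <- lam * (1 + (1 / 3) * ((1 / 3) - 1) +
                        z * sqrt(2 / 9))^3
  expect_lt(abs(thr_exact - mc) / mc, 0.03)
  expect_lt(abs(qm$q_threshold - thr_exact) / thr_exact, 0.1)

  # thresholds grow as alpha shrinks
  a <- fit_q_model(res, 0.05)$q_threshold
  b <- fit_q_model(res, 0.005)$q_threshold
  cc <- fit_q_model(res, 5e-5)$q_threshold
  expect_true(a < b && b < cc)

  # multi-eigenvalue spectrum: empirical exceedance of the 0.005 threshold
  set.seed(45)
  lams <- c(4, 2, 1, 0.5, 0.25, 0.125, 0.0625, 0.03125)
  train <- sweep(matrix(rnorm(3000 * 8), 3000), 2, sqrt(lams), "*")
  qm8 <- fit_q_model(train, alpha = 0.005)
  draws <- sweep(matrix(rnorm(1e5 * 8), 1e5), 2, sqrt(lams), "*")
  exc <- mean(rowSums(draws^2) > qm8$q_threshold)
  expect_gte(exc, 0.002)
  expect_lte(exc, 0.010)

  expect_error(fit_q_model(matrix(0, 5, 3), 0.05), "degenerate")
})

test_that("Q-test uses a strict threshold", {
  qm <- structure(list(q_threshold = 2), class = "q_model")
  expect_false(q_test(0, qm))
  expect_false(q_test(2, qm))
  expect_true(q_test(4, qm))
})

test_that("Q-squared ignores components in the span of the loadings", {
  s <- toy_two_fluids()
  m <- fit_plsda(s$X, s$meta$fluid, K = 2)
  x <- s$X[3, ]
  q0 <- q_squared(pls_project(m, x)$residual)
  for (j in 1:2) {
    q1 <- q_squared(pls_project(m, x + 0.05 * m$P[, j])$residual)
    expect_equal(q1, q0, tolerance = 1e-8)
  }
  # while off-span perturbations do change it
  v <- rnorm(length(x)); v <- v / sqrt(sum(v^2))
  q2 <- q_squared(pls_project(m, x + 0.05 * v)$residual)
  expect_gt(abs(q2 - q0) / q0, 1e-4)
})

test_that("flat scheme assigns fluids and rejects interferents end to end", {
  train <- fresh_reference()
  flat <- fit_flat_scheme(train, alpha = 0.005, seed = 11)
  expect_setequal(names(flat$qmodels), fluid_labels())

  # class mean spectra belong to their own class and pass the Q-test
  means <- t(sapply(fluid_labels(),
                    function(f) summarize_class(train, f)$mean))
  pm <- classify_flat(flat, means)
  expect_equal(pm$predicted, fluid_labels())

  # fresh in-class draws are assigned to their fluid
  set.seed(46)
  tpl <- default_fluid_templates()
  X <- area_normalize_matrix(simulate_fluid_matrix(tpl$blood, 20, 5))
  pb <- classify_flat(flat, X)
  expect_true(all(pb$candidate == "blood"))
  expect_gt(mean(pb$predicted == "blood"), 0.97)

  # interferents are flagged as outliers
  nb <- preprocess_spectra(simulate_non_bf(seed = 47))
  pn <- classify_flat(flat, nb$X)
  expect_true(all(pn$predicted == "OUTLIER"))

  # a missing Q model is a configuration error
  broken <- flat; broken$qmodels$blood <- NULL
  expect_error(classify_flat(broken, means["blood", ]), "configuration")
})

test_that("flat Q-test false-rejection rate tracks its significance level", {
  train <- fresh_reference()
  flat5 <- fit_flat_scheme(train, alpha = 0.05, seed = 11)
  tpl <- default_fluid_templates()
  set.seed(48)
  acc <- sapply(fluid_labels(), function(f) {
    X <- area_normalize_matrix(simulate_fluid_matrix(tpl[[f]], 400, 5))
    q2 <- q_squared(pls_project(flat5$plsda, X)$residual)
    mean(q2 <= flat5$qmodels[[f]]$q_threshold)
  })
  p <- mean(acc)
  ci <- 2.576 * sqrt(0.95 * 0.05 / 10000)
  expect_lt(abs(p - 0.95), ci + 0.01)
})
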