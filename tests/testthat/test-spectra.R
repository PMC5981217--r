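test_that("grid construction and validation", {
  g <- default_grid()
  expect_length(g, 776)
  expect_equal(g[1], 600)
  expect_equal(g[776], 3700)

  meta <- data.frame(sample_id = "s1", fluid = "blood", donor_id = "d1",
                     age_days = 1L)
  expect_error(spectra_set(matrix(1, 1, 3), c(600, 604, 604), meta),
               "monoton|grid")
  expect_error(spectra_set(matrix(1, 1, 3), c(600, 604, 612), meta),
               "uniform")
  expect_error(spectra_set(matrix(1, 1, 2), c(600, 604),
                           data.frame(sample_id = "s1", fluid = "plasma",
                                      donor_id = "d1", age_days = 1L)),
               "fluid")
  expect_error(spectra_set(matrix(NA_real_, 1, 2), c(600, 604), meta),
               "finite")
})

test_that("absorbance transform follows log10(1/T)", {
  g <- c(600, 604, 608)
  meta <- data.frame(sample_id = "s1", fluid = "blood", donor_id = "d1",
                     age_days = 1L)
  s <- spectra_set(matrix(c(1, 0.01, 0.5), 1), g, meta, "transmittance")
  a <- to_absorbance(s)
  expect_equal(as.vector(a$X), c(0, 2, log10(2)), tolerance = 1e-12)
  expect_identical(a$mode, "absorbance")
  expect_error(to_absorbance(a), "mode")
  expect_error(spectra_set(matrix(c(1, -0.1, 0.5), 1), g, meta,
                           "transmittance"), "positive")
  # round trip back through T = 10^(-A)
  s2 <- spectra_set(10^(-a$X), g, meta, "transmittance")
  expect_equal(to_absorbance(s2)$X, a$X, tolerance = 1e-12)
})

test_that("total-area normalization is idempotent and scale invariant", {
  g <- default_grid()
  meta <- data.frame(sample_id = c("s1", "s2"), fluid = "urine",
                     donor_id = "d1", age_days = 1L)
  x <- abs(sin(seq_along(g))) + 0.1
  s <- spectra_set(rbind(x, 7 * x), g, meta, "absorbance")
  n1 <- normalize_total_area(s)
  expect_equal(unname(rowSums(n1$X) * 4), c(1, 1), tolerance = 1e-12)
  # scalar multiples collapse to the same spectrum
  expect_equal(n1$X[1, ], n1$X[2, ], tolerance = 1e-12)
  # idempotent
  expect_equal(normalize_total_area(n1)$X, n1$X, tolerance = 1e-12)
  # constant spectrum maps to 1 / (n * spacing)
  sc <- spectra_set(matrix(0.3, 1, length(g)), g, meta[1, ], "absorbance")
  expect_equal(unique(as.vector(normalize_total_area(sc)$X)),
               1 / (length(g) * 4), tolerance = 1e-12)
  bad <- spectra_set(matrix(0, 1, length(g)), g, meta[1, ], "absorbance")
  expect_error(normalize_total_area(bad), "normalization")
})

test_that("CSV round trips are bit-identical in both layouts", {
  set.seed(3)
  g <- default_grid()
  meta <- data.frame(sample_id = sprintf("s%d", 1:5),
                     fluid = c("blood", "saliva", "semen", "urine", "sweat"),
                     donor_id = sprintf("d%d", 1:5), age_days = c(1L, 1L, 7L, 1L, 30L))
  s <- spectra_set(matrix(rexp(5 * length(g)), 5), g, meta, "absorbance")
  for (fmt in c("csv_wide", "csv_long")) {
    path <- file.path(withr::local_tempdir(), "spec.csv")
    write_spectra(s, path, fmt)
    r <- read_spectra(path, fmt)
    expect_identical(unname(r$X), unname(s$X))
    expect_identical(r$meta, s$meta)
  }
  # empty set round trip
  e <- spectra_set(matrix(numeric(0), 0, length(g)), g,
                   meta[0, ], "absorbance")
  path <- file.path(withr::local_tempdir(), "empty.csv")
  write_spectra(e, path, "csv_wide")
  expect_equal(nrow(read_spectra(path, "csv_wide")$X), 0L)
  expect_error(read_spectra(file.path(tempdir(), "nope.csv")), "no such")
})

test_that("duplicated wavenumber rows are rejected on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dup.csv")
  writeLines(c("wavenumber,s1", "600,0.1", "600,0.2", "604,0.3"), path)
  utils::write.csv(data.frame(sample_id = "s1", fluid = "blood",
                              donor_id = "d1", age_days = 1L),
                   file.path(dir, "dup_meta.csv"), row.names = FALSE)
  expect_error(read_spectra(path, "csv_wide"), "grid")
})

test_that("mean centering and class summaries match loop oracles", {
  cc <- mean_center(matrix(1:6, 2, 3))
  expect_equal(colSums(cc$Xc), c(0, 0, 0), tolerance = 1e-12)
  one <- mean_center(matrix(c(4, 5), 1))
  expect_equal(as.vector(one$Xc), c(0, 0))
  expect_equal(one$mean, c(4, 5))
  r <- c(1, -2, 3)
  sym <- mean_center(rbind(r, -r))
  expect_equal(unname(sym$Xc), unname(rbind(r, -r)))

  set.seed(4)
  g <- seq(600, 640, 4)
  X <- matrix(rnorm(33), 3)
  meta <- data.frame(sample_id = c("a", "b", "c"), fluid = "semen",
                     donor_id = "d1", age_days = 1L)
  s <- spectra_set(X, g, meta, "absorbance")
  sm <- summarize_class(s, "semen")
  mu <- numeric(11); sdv <- numeric(11)
  for (j in 1:11) { mu[j] <- mean(X[, j]); sdv[j] <- sd(X[, j]) }
  expect_equal(sm$mean, mu)
  expect_equal(sm$sd, sdv)
  expect_equal(summarize_class(subset_spectra(s, 1), "semen")$sd,
               numeric(11))
  expect_error(summarize_class(s, "blood"), "selection")

  fresh <- rnorm(11); bump <- dnorm(seq(-2, 2, length.out = 11))
  expect_equal(difference_spectrum(fresh + bump, fresh), bump,
               tolerance = 1e-12)
  expect_error(difference_spectrum(1:3, 1:4), "grid")
})

test_that("PCA agrees with an eigendecomposition oracle", {
  set.seed(9)
  n <- 12; p <- 20
  X <- tcrossprod(rnorm(n), rnorm(p)) + 0.4 * tcrossprod(rnorm(n), rnorm(p))
  Xc <- mean_center(X)$Xc
  pc <- pca_spectra(Xc, 3)
  # orthonormal loadings; scores reproduce Xc projections
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pc$scores, Xc %*% pc$loadings, tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # oracle: eigen of the covariance computed by an independent routine
  ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  for (k in 1:2) {
    expect_equal(abs(sum(pc$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-6)
  }
  expect_equal(pc$explained_variance[1:2], ev$values[1:2], tolerance = 1e-8)
  # score covariance is diagonal; score column means are zero
  sc_cov <- crossprod(pc$scores) / (n - 1)
  expect_lt(max(abs(sc_cov[upper.tri(sc_cov)])), 1e-10 * max(diag(sc_cov)))
  expect_equal(unname(colMeans(pc$scores)), numeric(3), tolerance = 1e-10)
  # total variance conserved at full rank
  full <- pca_spectra(Xc, n - 1)
  expect_equal(sum(full$explained_variance),
               sum(diag(crossprod(Xc) / (n - 1))), tolerance = 1e-10)
  expect_error(pca_spectra(Xc, n), "dimension")
})

test_that("explicit regridding interpolates linearly and checks bounds", {
  g <- seq(600, 700, 4)
  meta <- data.frame(sample_id = "s1", fluid = "sweat", donor_id = "d1",
                     age_days = 1L)
  s <- spectra_set(matrix(2 * g + 1, 1), g, meta, "absorbance")
  r <- regrid_spectra(s, seq(600, 700, 2))
  expect_equal(as.vector(r$X), 2 * seq(600, 700, 2) + 1, tolerance = 1e-10)
  expect_error(regrid_spectra(s, seq(500, 700, 4)), "grid")
})
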