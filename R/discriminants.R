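#' Linear discriminant analysis on PLS scores
#'
#' Pooled-within-class-covariance LDA. The discriminant value of class c at
#' a point x is x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c; the class
#' with the largest value wins. The pooled covariance uses the n - C
#' denominator and is ridge-regularized by 1e-8 x trace/k on the diagonal
#' when its condition number exceeds 1e10.
#'
#' @param scores n x k matrix of PLS-DA scores.
#' @param labels Class label per row.
#' @param priors Named class priors; default the training proportions. Use
#'   `"uniform"` for equal priors.
#' @param class_order Class vocabulary.
#' @return An object of class `lda_model` with `class_means`, `cov`,
#'   `cov_inv`, `priors` and `class_labels`.
#' @export
fit_lda <- function(scores, labels, priors = NULL,
                    class_order = unique(labels)) {
  scores <- as.matrix(scores)
  k <- ncol(scores); n <- nrow(scores); C <- length(class_order)
  if (C < 2L || k < 1L) {
    stop("dimension error: LDA needs at least two classes and one score",
         call. = FALSE)
  }
  mu <- matrix(0, C, k, dimnames = list(class_order, NULL))
  S <- matrix(0, k, k)
  for (ci in seq_len(C)) {
    i <- which(labels == class_order[ci])
    if (length(i) == 0L) {
      stop("label error: class '", class_order[ci], "' has no samples",
           call. = FALSE)
    }
    Z <- scores[i, , drop = FALSE]
    mu[ci, ] <- colMeans(Z)
    S <- S + crossprod(sweep(Z, 2L, mu[ci, ], "-"))
  }
  S <- S / max(n - C, 1L)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > 1e10) {
    S <- S + diag(1e-8 * sum(diag(S)) / k, k)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("numerical error: pooled covariance is singular", call. = FALSE)
    }
  }
  if (is.null(priors)) {
    priors <- as.vector(table(factor(labels, class_order))) / n
  } else if (identical(priors, "uniform")) {
    priors <- rep(1 / C, C)
  }
  names(priors) <- class_order
  structure(list(class_means = mu, cov = S, cov_inv = solve(S),
                 priors = priors, class_labels = class_order),
            class = "lda_model")
}

#' Predict classes from an LDA model
#'
#' @param m An `lda_model`.
#' @param scores Score vector of length k or an n x k matrix.
#' @return List with `label` (predicted class per row; ties broken toward
#'   the earlier class in the vocabulary, with a message) and `discriminant`
#'   (n x C matrix of discriminant values).
#' @export
predict_lda <- function(m, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  scores <- as.matrix(scores)
  if (ncol(scores) != ncol(m$class_means)) {
    stop("dimension error: score dimension does not match the model",
         call. = FALSE)
  }
  A <- m$cov_inv %*% t(m$class_means)            # k x C
  const <- -0.5 * colSums(t(m$class_means) * A) + log(m$priors)
  D <- sweep(scores %*% A, 2L, const, "+")
  colnames(D) <- m$class_labels
  win <- max.col(D, ties.method = "first")
  tie <- vapply(seq_len(nrow(D)), function(i) {
    sum(abs(D[i, ] - D[i, win[i]]) < 1e-12 * max(1, abs(D[i, win[i]]))) > 1L
  }, logical(1))
  if (any(tie)) {
    message(sum(tie), " tied discriminant value(s); earlier class chosen")
  }
  list(label = m$class_labels[win], discriminant = D)
}

#' Q-statistic of a residual spectrum
#'
#' The squared prediction error: the sum of squared elements of the
#' x-residual left after projecting a spectrum onto the adopted latent
#' variables.
#'
#' @param residual Residual vector, or an n x p matrix of residuals.
#' @return Scalar (or n-vector) of Q-squared values.
#' @export
q_squared <- function(residual) {
  if (is.null(dim(residual))) sum(residual^2) else rowSums(residual^2)
}

#' Fit a one-class Q-statistic model
#'
#' Computes the Jackson-Mudholkar control limit for the Q (squared
#' prediction error) distribution of one class. The residual second-moment
#' matrix about zero (n - 1 denominator) is eigendecomposed; eigenvalues
#' below 1e-12 of the largest are treated as numerical noise and dropped.
#' With theta_i = sum(lambda^i) and
#' h0 = 1 - 2 theta1 theta3 / (3 theta2^2), the threshold at upper-tail
#' significance `alpha` is
#' theta1 (1 + theta2 h0 (h0 - 1) / theta1^2 +
#' z_alpha sqrt(2 theta2 h0^2) / theta1)^(1/h0).
#' For pathological eigenvalue spectra giving h0 <= 0 the empirical
#' (1 - alpha) quantile of the training Q values is used instead, with a
#' warning.
#'
#' The second moment is taken about zero, not about the class's own
#' residual mean, because Q-squared itself sums squared residuals about
#' zero. When the projection model explains the class well the residual
#' mean vanishes and this is the residual covariance; when some class-mean
#' structure is left unexplained, the moment matrix absorbs that offset as
#' an additional eigen-direction, which keeps the threshold on the scale
#' of the Q values actually produced instead of rejecting the whole class.
#'
#' @param residuals n x p matrix of training residuals of one class
#'   (n >= 3).
#' @param alpha Upper-tail significance level in (0, 1): e.g. 0.005 for a
#'   99.5 percent acceptance region.
#' @return An object of class `q_model` with `theta1..theta3`, `h0`,
#'   `alpha`, `z_alpha`, `q_threshold` and the retained `eigenvalues`.
#' @export
fit_q_model <- function(residuals, alpha) {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  stopifnot(n >= 3L, alpha > 0, alpha < 1)
  # eigenvalues of the second moment via whichever Gram matrix is smaller
  M <- if (n <= ncol(residuals)) tcrossprod(residuals)
  else crossprod(residuals)
  lam <- eigen(M / (n - 1L), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(lam)]
  if (length(lam) == 0L || max(lam) <= 0) {
    stop("degenerate-residual error: residual covariance is zero",
         call. = FALSE)
  }
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  z <- stats::qnorm(1 - alpha)
  if (h0 > 0) {
    thr <- th1 * (1 + th2 * h0 * (h0 - 1) / th1^2 +
                    z * sqrt(2 * th2 * h0^2) / th1)^(1 / h0)
  } else {
    warning("h0 <= 0; falling back to the empirical training quantile",
            call. = FALSE)
    thr <- unname(stats::quantile(rowSums(residuals^2), 1 - alpha,
                                  type = 7))
  }
  structure(list(theta1 = th1, theta2 = th2, theta3 = th3, h0 = h0,
                 alpha = alpha, z_alpha = z, q_threshold = thr,
                 eigenvalues = lam),
            class = "q_model")
}

#' Q-test for outliers
#'
#' @param q2 Q-squared value(s), >= 0.
#' @param m A `q_model`.
#' @return Logical: `TRUE` when `q2` strictly exceeds the threshold (the
#'   spectrum is an outlier); a value exactly at the threshold is accepted.
#' @export
q_test <- function(q2, m) {
  q2 > m$q_threshold
}

#' Fit the flat five-class PLS-LDA-Q scheme
#'
#' Fits one multi-class PLS-DA model (components adopted by the
#' cross-validated PRESS/RSS rule on donor-wise folds), an LDA on its
#' training scores, and a per-class Q model from each class's own training
#' residuals under the shared PLS model.
#'
#' @param train A preprocessed [spectra_set()] containing only body-fluid
#'   spectra.
#' @param alpha Q-test upper-tail significance (0.005 gives the 99.5
#'   percent acceptance region used with this scheme).
#' @param K_max,k_folds,seed Component-selection settings passed to
#'   [fit_plsda_cv()].
#' @param class_order Class vocabulary.
#' @return Object of class `flat_scheme` with `plsda`, `lda` and `qmodels`.
#' @export
fit_flat_scheme <- function(train, alpha = 0.005, K_max = 10L, k_folds = 5L,
                            seed = 1L,
                            class_order = intersect(fluid_labels(),
                                                    unique(train$meta$fluid))) {
  m <- fit_plsda_cv(train$X, train$meta$fluid, train$meta$donor_id,
                    K_max = K_max, k_folds = k_folds, seed = seed,
                    class_order = class_order)
  pr <- pls_project(m, train$X)
  # with a single class there is nothing to discriminate: the scheme
  # degenerates to a one-class Q-test about the class mean
  lda <- if (length(class_order) >= 2L && m$n_lv >= 1L) {
    fit_lda(pr$scores, train$meta$fluid, class_order = class_order)
  }
  qmodels <- lapply(class_order, function(cl) {
    fit_q_model(pr$residual[train$meta$fluid == cl, , drop = FALSE], alpha)
  })
  names(qmodels) <- class_order
  structure(list(plsda = m, lda = lda, qmodels = qmodels, alpha = alpha),
            class = "flat_scheme")
}

#' Classify spectra with the flat PLS-LDA-Q scheme
#'
#' Projects each spectrum onto the PLS-DA model, lets the LDA nominate a
#' candidate class from the scores, then applies that class's Q-test to the
#' projection residual: spectra whose Q-squared exceeds the candidate
#' class's threshold are returned as `"OUTLIER"`.
#'
#' @param scheme A `flat_scheme` (or its parts via `plsda`, `lda`,
#'   `qmodels`).
#' @param x Preprocessed spectrum vector or n x p matrix.
#' @return Data frame with columns `predicted`, `candidate`, `q2`,
#'   `q_threshold` and the score columns `lv1..lvk`.
#' @export
classify_flat <- function(scheme, x) {
  pr <- pls_project(scheme$plsda, x)
  cand <- if (is.null(scheme$lda)) {
    rep(scheme$plsda$class_labels[1], nrow(pr$scores))
  } else {
    predict_lda(scheme$lda, pr$scores)$label
  }
  q2 <- q_squared(pr$residual)
  thr <- vapply(cand, function(cl) {
    qm <- scheme$qmodels[[cl]]
    if (is.null(qm)) {
      stop("configuration error: no Q model for class '", cl, "'",
           call. = FALSE)
    }
    qm$q_threshold
  }, numeric(1))
  out <- data.frame(predicted = ifelse(q2 > thr, "OUTLIER", cand),
                    candidate = cand, q2 = q2, q_threshold = thr)
  sc <- pr$scores
  if (ncol(sc) > 0) {
    colnames(sc) <- paste0("lv", seq_len(ncol(sc)))
    out <- cbind(out, sc)
  }
  out
}
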