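#' One-hot response matrix
#'
#' Dummy-codes class labels for PLS-DA: `Y[i, c]` is 1 when sample `i`
#' belongs to class `c`, else 0, so each row sums to one.
#'
#' @param labels Vector of class labels.
#' @param class_order Ordered class vocabulary; every label must occur here.
#' @return n x C indicator matrix with `class_order` as column names.
#' @export
one_hot <- function(labels, class_order) {
  j <- match(labels, class_order)
  if (anyNA(j)) {
    stop("label error: unknown label(s): ",
         paste(unique(labels[is.na(j)]), collapse = ", "), call. = FALSE)
  }
  Y <- matrix(0, length(labels), length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(j), j)] <- 1
  Y
}

#' Fit a PLS2 model by NIPALS
#'
#' Extracts `K` latent variables from mean-centered predictor and response
#' matrices. Each component iterates the NIPALS recursion (w from the
#' y-scores, x-score t = Xc w, y-loading q, y-score u) to a relative score
#' change below `tol`, then deflates both blocks by the rank-one
#' approximation t p' / t q'. Weight vectors are unit norm and sign-fixed so
#' that each one's largest-magnitude element is positive; x-scores are
#' mutually orthogonal by construction.
#'
#' @param Xc n x p mean-centered predictors.
#' @param Yc n x C mean-centered responses.
#' @param K Number of latent variables, at most `min(n - 1, p)`.
#' @param tol Relative convergence tolerance of the inner iteration.
#' @param max_iter Iteration cap per component.
#' @return List with `W` (p x K weights), `P` (p x K x-loadings), `Qy`
#'   (C x K y-loadings) and `T` (n x K x-scores). If the response block is
#'   exhausted early the matrices are truncated and carry an attribute
#'   `K_actual`.
#' @export
fit_pls2 <- function(Xc, Yc, K, tol = 1e-10, max_iter = 5000L) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  n <- nrow(Xc); p <- ncol(Xc)
  if (K > min(n - 1L, p)) {
    stop("dimension error: K exceeds min(n-1, p)", call. = FALSE)
  }
  if (sum(Xc^2) < 1e-300) {
    stop("degenerate-input error: predictor block has no variance",
         call. = FALSE)
  }
  W <- matrix(0, p, K); P <- matrix(0, p, K)
  Q <- matrix(0, ncol(Yc), K); Tm <- matrix(0, n, K)
  Xd <- Xc; Yd <- Yc
  k_actual <- K
  for (k in seq_len(K)) {
    ssy <- colSums(Yd^2)
    if (max(ssy) < 1e-24 * max(1, sum(Yc^2))) { k_actual <- k - 1L; break }
    u <- Yd[, which.max(ssy)]
    t_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- as.vector(Xd %*% w)
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- as.vector(Yd %*% q) / sum(q^2)
      if (!is.null(t_old) &&
          sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) break
      if (it == max_iter) {
        stop("convergence error: NIPALS did not converge in ", max_iter,
             " iterations (component ", k, ")", call. = FALSE)
      }
      t_old <- tt
    }
    jmax <- which.max(abs(w))
    if (w[jmax] < 0) { w <- -w; tt <- -tt; q <- -q }
    pv <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, q)
    W[, k] <- w; P[, k] <- pv; Q[, k] <- q; Tm[, k] <- tt
  }
  if (k_actual < K) {
    ix <- seq_len(k_actual)
    W <- W[, ix, drop = FALSE]; P <- P[, ix, drop = FALSE]
    Q <- Q[, ix, drop = FALSE]; Tm <- Tm[, ix, drop = FALSE]
  }
  out <- list(W = W, P = P, Qy = Q, T = Tm)
  attr(out, "K_actual") <- min(k_actual, K)
  out
}

#' Fit a PLS-DA model
#'
#' Centers the spectra and the one-hot response, runs [fit_pls2()] and
#' packages everything needed to project new spectra: centering means,
#' weights, loadings, y-loadings, training scores and the class vocabulary.
#'
#' @param X n x p matrix of preprocessed spectra.
#' @param labels Class label per row.
#' @param K Number of latent variables to extract.
#' @param class_order Class vocabulary (defaults to the sorted unique
#'   labels in first-appearance order).
#' @param n_lv Number of adopted latent variables (defaults to `K`); kept
#'   separately so a model can store more components than it uses.
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(X, labels, K, class_order = unique(labels),
                      n_lv = NULL) {
  X <- as.matrix(X)
  Y <- one_hot(labels, class_order)
  cx <- mean_center(X)
  cy <- mean_center(Y)
  fit <- fit_pls2(cx$Xc, cy$Xc, K)
  K_actual <- attr(fit, "K_actual")
  structure(list(x_mean = cx$mean, y_mean = cy$mean,
                 W = fit$W, P = fit$P, Qy = fit$Qy, T_train = fit$T,
                 class_labels = class_order,
                 n_lv = min(if (is.null(n_lv)) K_actual else n_lv, K_actual)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d classes (%s), %d of %d LVs adopted, p = %d\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              x$n_lv, ncol(x$W), length(x$x_mean)))
  invisible(x)
}

#' Project spectra onto a PLS-DA model
#'
#' Sequential NIPALS prediction with deflation: starting from the centered
#' spectrum, each score is the inner product with that component's weight
#' vector, after which the loading direction is deflated away. Returns the
#' scores, the x-residual after `k` components (whose squared norm is the
#' Q-statistic) and the predicted response values.
#'
#' @param m A `plsda_model`.
#' @param x Spectrum vector of length p, or an n x p matrix of spectra.
#' @param k Number of components to use (default: the adopted `n_lv`).
#' @return List with `scores` (n x k), `residual` (n x p) and `y_hat`
#'   (n x C); vectors in, vectors out is preserved via drop = FALSE
#'   matrices with one row.
#' @export
pls_project <- function(m, x, k = m$n_lv) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(m$x_mean)) {
    stop("dimension error: spectrum length does not match the model",
         call. = FALSE)
  }
  if (k > ncol(m$W)) {
    stop("dimension error: k exceeds the stored components", call. = FALSE)
  }
  X0 <- sweep(x, 2L, m$x_mean, "-")
  Tm <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    tj <- as.vector(X0 %*% m$W[, j])
    Tm[, j] <- tj
    X0 <- X0 - tcrossprod(tj, m$P[, j])
  }
  y_hat <- sweep(Tm %*% t(m$Qy[, seq_len(k), drop = FALSE]), 2L,
                 m$y_mean, "+")
  colnames(y_hat) <- m$class_labels
  list(scores = Tm, residual = X0, y_hat = y_hat)
}

#' PRESS / RSS latent-variable selection report
#'
#' For each candidate number of latent variables `k` and each class,
#' computes the cross-validated predicted residual sum of squares PRESS(k)
#' (donor-wise folds, the fold model centered on its own training data),
#' the residual sum of squares RSS(k) of the full training fit, and the
#' per-component explained-variance increment
#' 100 (RSS(k-1) - RSS(k)) / TSS with RSS(0) = TSS.
#'
#' @param X n x p preprocessed spectra.
#' @param labels Class label per row.
#' @param folds Integer fold id per row; every donor's spectra must share a
#'   fold (see [donor_kfold()]).
#' @param K_max Largest number of components examined.
#' @param class_order Class vocabulary.
#' @return An `lv_report`: list with matrices `PRESS`, `RSS`, `ev_increment`
#'   (K_max x C), vector `TSS` and `K_max`.
#' @export
press_rss <- function(X, labels, folds, K_max,
                      class_order = unique(labels)) {
  X <- as.matrix(X)
  Y <- one_hot(labels, class_order)
  C <- ncol(Y)
  K_max <- min(K_max, nrow(X) - 1L, ncol(X))
  for (f in unique(folds)) {
    te <- folds == f
    miss <- class_order[colSums(Y[!te, , drop = FALSE]) == 0 |
                          colSums(Y[te, , drop = FALSE]) == 0]
    if (length(miss)) {
      warning("stratification warning: fold ", f,
              " lacks train or test samples of: ",
              paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  # full-fit RSS
  cx <- mean_center(X); cy <- mean_center(Y)
  full <- fit_pls2(cx$Xc, cy$Xc, K_max)
  Kf <- attr(full, "K_actual")
  TSS <- colSums(cy$Xc^2)
  RSS <- matrix(NA_real_, K_max, C, dimnames = list(NULL, class_order))
  Yres <- cy$Xc
  for (k in seq_len(Kf)) {
    Yres <- Yres - tcrossprod(full$T[, k], full$Qy[, k])
    RSS[k, ] <- colSums(Yres^2)
  }
  if (Kf < K_max) for (k in (Kf + 1L):K_max) RSS[k, ] <- RSS[Kf, ]
  # cross-validated PRESS
  PRESS <- matrix(0, K_max, C, dimnames = list(NULL, class_order))
  for (f in unique(folds)) {
    te <- folds == f
    cxf <- mean_center(X[!te, , drop = FALSE])
    cyf <- mean_center(Y[!te, , drop = FALSE])
    fit <- fit_pls2(cxf$Xc, cyf$Xc, K_max)
    Kk <- attr(fit, "K_actual")
    X0 <- sweep(X[te, , drop = FALSE], 2L, cxf$mean, "-")
    Yhat <- matrix(0, sum(te), C)
    for (k in seq_len(K_max)) {
      if (k <= Kk) {
        tk <- as.vector(X0 %*% fit$W[, k])
        X0 <- X0 - tcrossprod(tk, fit$P[, k])
        Yhat <- Yhat + tcrossprod(tk, fit$Qy[, k])
      }
      err <- Y[te, , drop = FALSE] -
        sweep(Yhat, 2L, cyf$mean, "+")
      PRESS[k, ] <- PRESS[k, ] + colSums(err^2)
    }
  }
  ev <- 100 * (rbind(TSS, RSS[-K_max, , drop = FALSE]) -
                 RSS) / rep(TSS, each = K_max)
  dimnames(ev) <- dimnames(RSS)
  structure(list(PRESS = PRESS, RSS = RSS, ev_increment = ev, TSS = TSS,
                 K_max = K_max), class = "lv_report")
}

#' Adopt latent variables from a selection report
#'
#' Scans `k` upward; the k-th latent variable is adopted when, in strictly
#' more than half of the classes, both (i) PRESS(k) / RSS(k-1) <
#' `threshold_ratio` and (ii) the explained-variance increment exceeds
#' `min_ev_pct` percent. Adoption stops at the first rejected `k`
#' (contiguous prefix). When not even the first component qualifies, 1 is
#' returned with a warning, since a zero-component model is unusable.
#'
#' @param report An `lv_report` from [press_rss()].
#' @param threshold_ratio PRESS/RSS adoption bound.
#' @param min_ev_pct Minimum explained-variance increment, in percent.
#' @return Number of adopted latent variables (integer >= 1).
#' @export
select_n_lv <- function(report, threshold_ratio = 0.8, min_ev_pct = 1.0) {
  C <- ncol(report$PRESS)
  n_lv <- 0L
  for (k in seq_len(report$K_max)) {
    rss_prev <- if (k == 1L) report$TSS else report$RSS[k - 1L, ]
    pass <- (report$PRESS[k, ] / rss_prev < threshold_ratio) &
      (report$ev_increment[k, ] > min_ev_pct)
    if (sum(pass) > C / 2) n_lv <- k else break
  }
  if (n_lv == 0L) {
    warning("no latent variable met the adoption criteria; using 1",
            call. = FALSE)
    n_lv <- 1L
  }
  n_lv
}

#' Fit a PLS-DA model with cross-validated component selection
#'
#' Convenience wrapper: runs [press_rss()] with donor-wise folds,
#' [select_n_lv()], then fits the final model with the adopted number of
#' components on all rows.
#'
#' @param X n x p preprocessed spectra.
#' @param labels Class label per row.
#' @param donors Donor id per row.
#' @param K_max Largest candidate component count.
#' @param k_folds Number of donor-wise folds.
#' @param seed Seed for the fold assignment.
#' @param class_order Class vocabulary.
#' @return A `plsda_model` with the selection report in attribute
#'   `lv_report`.
#' @export
fit_plsda_cv <- function(X, labels, donors, K_max = 10L, k_folds = 5L,
                         seed = 1L, class_order = unique(labels)) {
  n_donors <- length(unique(donors))
  k_eff <- min(k_folds, n_donors)
  if (length(class_order) < 2L) {
    # a single class has a zero-variance response: no component can be
    # extracted and the model reduces to the class mean (0 latent variables)
    return(fit_plsda(X, labels, K = min(1L, nrow(X) - 1L),
                     class_order = class_order))
  }
  if (k_eff < 2L) {
    # a single training donor leaves nothing to cross-validate against
    warning("too few donors for cross-validated component selection; ",
            "fitting ", length(class_order), " component(s) directly",
            call. = FALSE)
    K <- min(length(class_order), nrow(X) - 1L, ncol(X), K_max)
    return(fit_plsda(X, labels, K = K, class_order = class_order))
  }
  split <- donor_kfold(donors, k = k_eff, seed = seed,
                       strata = labels)
  folds <- split$fold[match(donors, split$donor_id)]
  rep <- press_rss(X, labels, folds, K_max, class_order)
  n_lv <- select_n_lv(rep)
  m <- fit_plsda(X, labels, K = n_lv, class_order = class_order)
  attr(m, "lv_report") <- rep
  m
}
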