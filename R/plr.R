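# Penalized logistic regression with supervised feature clustering.
#
# The classifier greedily builds "meta-features": clusters of (oriented,
# standardized) features whose arithmetic mean - the cluster centroid -
# enters a logistic model as one predictor. Clusters are grown by forward
# selection with recurrent pruning, each step accepted only if it strictly
# lowers the l2-penalized negative log-likelihood
#     crit(beta) = -loglik(beta) + lambda * sum(beta_noint^2).
# Earlier clusters' centroids stay in the model as fixed covariates while
# later clusters are built; all coefficients are refitted at every step.

# stable negative log-likelihood of a logistic model
logistic_nll <- function(eta, y) {
  sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
}

# inline logistic function (avoids plogis dispatch in the hot path)
sigmoid <- function(eta) 1 / (1 + exp(-pmin(pmax(eta, -700), 700)))

# Ridge-penalized logistic regression by Newton iteration (IRLS) with
# step-halving. X must contain the intercept column; `penalized` marks the
# coefficients subject to the l2 penalty (never the intercept). Thin wrapper
# around the compiled solver.
ridge_logistic <- function(X, y, lambda, penalized = c(FALSE, rep(TRUE, ncol(X) - 1L)),
                           beta = rep(0, ncol(X)), tol = 1e-8, maxit = 100L) {
  pen <- as.numeric(rep_len(penalized, ncol(X)))
  f <- .ridge_logistic_cpp(X, y, lambda, pen, beta, tol, maxit)
  f$beta <- drop(f$beta)
  f$fitted <- drop(f$fitted)
  f
}

# oriented-mean centroid of standardized member features
cluster_centroid <- function(Xs, members, signs) {
  if (length(members) == 1L) return(signs * Xs[, members])
  rowMeans(sweep(Xs[, members, drop = FALSE], 2, signs, "*"))
}

# Grow one cluster by forward selection with recurrent pruning.
# fixed: n x k matrix of earlier centroids (may have 0 columns).
grow_cluster <- function(Xs, y, fixed, lambda, max_size = 15L, screen = 25L,
                         tol = 1e-12, irls_tol = 1e-8, irls_maxit = 100L) {
  n <- nrow(Xs); p <- ncol(Xs)
  X0 <- cbind(1, fixed)
  pen0 <- c(FALSE, rep(TRUE, ncol(fixed)))
  base_fit <- ridge_logistic(X0, y, lambda, pen0, tol = irls_tol,
                             maxit = irls_maxit)

  members <- integer(0); signs <- numeric(0)
  centroid <- NULL
  fit <- base_fit          # fit of the current model (with centroid if any)
  crit <- base_fit$criterion

  exact_fit <- function(z, warm) {
    Xn <- cbind(X0, z)
    ridge_logistic(Xn, y, lambda, c(pen0, TRUE), beta = warm,
                   tol = irls_tol, maxit = irls_maxit)
  }

  repeat {
    if (length(members) >= max_size) break
    cand <- setdiff(seq_len(p), members)
    if (length(cand) == 0L) break
    m <- length(members)
    # candidate centroid columns, both orientations, ordered so that ties
    # resolve to the lowest feature index with "+" orientation first
    cand2 <- rep(cand, each = 2L)
    sgn2 <- rep(c(1, -1), times = length(cand))
    if (m == 0L) {
      Z <- Xs[, cand2, drop = FALSE] * rep(sgn2, each = n)
    } else {
      Z <- (m * centroid + Xs[, cand2, drop = FALSE] * rep(sgn2, each = n)) /
        (m + 1)
    }

    idx_try <- seq_len(ncol(Z))
    if (ncol(Z) > 2L * screen) {
      # score-test screening at the current fit: approximate criterion
      # decrease of swapping the centroid column for each candidate column
      pc <- fit$fitted
      r <- pc - y
      w <- pmax(pc * (1 - pc), 1e-10)
      beta_c <- if (m == 0L) 0 else fit$beta[length(fit$beta)]
      gamma <- drop(crossprod(Z, r)) + 2 * lambda * beta_c
      H00 <- crossprod(X0 * w, X0)
      diag(H00) <- diag(H00) + 2 * lambda * as.numeric(pen0)
      A <- crossprod(X0, Z * w)
      s <- colSums(Z * Z * w) + 2 * lambda - colSums(A * solve(H00, A))
      score <- gamma^2 / pmax(s, 1e-12)
      idx_try <- order(-score)[seq_len(2L * screen)]
      idx_try <- idx_try[order(idx_try)]  # keep tie-break ordering
    }

    warm <- if (m == 0L) c(fit$beta, 0) else fit$beta
    pen_full <- as.numeric(c(pen0, TRUE))
    crits <- .eval_candidates_cpp(X0, Z[, idx_try, drop = FALSE], y, lambda,
                                  pen_full, warm, irls_tol, irls_maxit)
    rel <- which.min(crits)   # first minimum honours the tie-break ordering
    if (length(rel) == 0L || crits[rel] >= crit - tol)
      break                   # no strict improvement: stop growing
    best_i <- idx_try[rel]
    members <- c(members, cand2[best_i])
    signs <- c(signs, sgn2[best_i])
    centroid <- Z[, best_i]
    fit <- exact_fit(centroid, warm)
    crit <- fit$criterion

    # recurrent pruning: drop members while a removal strictly improves
    while (length(members) >= 2L) {
      Zp <- vapply(seq_along(members), function(j)
        cluster_centroid(Xs, members[-j], signs[-j]), numeric(n))
      crits <- .eval_candidates_cpp(X0, Zp, y, lambda, pen_full, fit$beta,
                                    irls_tol, irls_maxit)
      j <- which.min(crits)
      if (crits[j] >= crit - tol) break
      members <- members[-j]; signs <- signs[-j]
      centroid <- cluster_centroid(Xs, members, signs)
      fit <- exact_fit(centroid, fit$beta)
      crit <- fit$criterion
    }
  }

  list(members = members, signs = signs, centroid = centroid,
       fit = fit, criterion = crit, base_criterion = base_fit$criterion)
}

#' Penalized logistic regression with supervised feature clustering
#'
#' Fits a binary classifier that selects features into up to `n_clusters`
#' meta-feature clusters by greedy forward selection with recurrent pruning
#' under an l2-penalized negative log-likelihood. Each cluster's predictor
#' is the arithmetic mean (centroid) of its oriented, standardized member
#' features; feature orientation (+x or -x) is searched explicitly, since a
#' region may be hypo- or hyper-methylated in either class. Clusters are
#' built sequentially, earlier centroids remaining in the model as fixed
#' covariates; a feature may appear in several clusters. Fitting stops early
#' when a new cluster cannot strictly lower the criterion.
#'
#' @param x numeric samples x features matrix with column names, or a
#'   [build_feature_matrix()] result (filtered and imputed).
#' @param y binary response: factor/character with two levels, or 0/1; for a
#'   `feature_matrix` with `y` missing, the samples' sex labels are used
#'   (F = 0, M = 1).
#' @param lambda ridge penalty on the non-intercept coefficients
#'   (default 1/32).
#' @param n_clusters maximum number of clusters `q` (default 10).
#' @param max_cluster_size cap on features per cluster.
#' @param screen number of candidates exactly refitted per greedy step;
#'   candidates are pre-ranked by a score-test approximation when the
#'   feature count exceeds this (set to `Inf` for fully exact search).
#' @param tol strict-improvement tolerance for accepting greedy steps.
#' @param irls_tol,irls_maxit convergence control of the inner Newton/IRLS
#'   solver (gradient max-norm, iteration cap).
#' @return An object of class `plr` with methods `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot`.
#' @seealso [project_centroids()], [run_cv()]
#' @export
plr <- function(x, y = NULL, lambda = 1 / 32, n_clusters = 10L,
                max_cluster_size = 15L, screen = 25L, tol = 1e-12,
                irls_tol = 1e-8, irls_maxit = 100L) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$samples$sex
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)), lambda > 0, n_clusters >= 1)
  if (anyNA(x)) stop("x contains missing values; impute first")
  if (is.numeric(y)) y <- factor(y, levels = sort(unique(y)))
  y <- factor(y)
  if (nlevels(y) != 2)
    stop("y must have exactly two classes; got ", nlevels(y))
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  yy <- as.numeric(y) - 1

  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  drop_f <- scale_ <= 0 | !is.finite(scale_)
  if (any(drop_f)) {
    warning(sum(drop_f), " zero-variance feature(s) removed")
    x <- x[, !drop_f, drop = FALSE]
    center <- center[!drop_f]; scale_ <- scale_[!drop_f]
  }
  Xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  clusters <- list()
  fixed <- matrix(numeric(0), nrow(Xs), 0)
  crit_path <- numeric(0)
  null_fit <- ridge_logistic(cbind(1, fixed), yy, lambda, FALSE)
  crit <- null_fit$criterion
  fit <- null_fit
  for (k in seq_len(n_clusters)) {
    gc_ <- grow_cluster(Xs, yy, fixed, lambda, max_size = max_cluster_size,
                        screen = screen, tol = tol, irls_tol = irls_tol,
                        irls_maxit = irls_maxit)
    if (length(gc_$members) == 0L || gc_$criterion >= crit - tol) break
    clusters[[k]] <- data.frame(feature = colnames(Xs)[gc_$members],
                                sign = gc_$signs, stringsAsFactors = FALSE)
    fixed <- cbind(fixed, gc_$centroid)
    crit <- gc_$criterion
    fit <- gc_$fit
    crit_path <- c(crit_path, crit)
  }
  if (length(clusters) == 0L)
    stop("no cluster improved on the null model; nothing to fit")
  if (!fit$converged)
    warning("IRLS did not reach the gradient tolerance; ",
            "returning the last iterate (grad max-norm ",
            format(fit$grad_norm, digits = 3), ")")

  coefs <- setNames(fit$beta,
                    c("(Intercept)", paste0("cluster", seq_along(clusters))))
  structure(list(clusters = clusters, coefficients = coefs,
                 center = center, scale = scale_,
                 levels = levels(y), lambda = lambda,
                 n_clusters = length(clusters),
                 criterion = crit, criterion_path = crit_path,
                 null_criterion = null_fit$criterion,
                 nll = fit$nll, grad_norm = fit$grad_norm,
                 converged = fit$converged,
                 training = list(y = yy, fitted = fit$fitted,
                                 sample_ids = rownames(x)),
                 call = match.call()),
            class = "plr")
}

# centroid matrix (n x n_clusters) of new data under a fitted model
plr_centroids <- function(object, x) {
  need <- unique(unlist(lapply(object$clusters, `[[`, "feature")))
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("model features absent from input: ", paste(miss, collapse = ", "))
  used <- names(object$center)
  common <- intersect(used, colnames(x))
  Xs <- sweep(sweep(x[, common, drop = FALSE], 2, object$center[common]),
              2, object$scale[common], "/")
  vapply(object$clusters, function(cl) {
    cluster_centroid(Xs, match(cl$feature, common), cl$sign)
  }, numeric(nrow(x)))
}

#' Predict sex (class) from a fitted classifier
#'
#' Test samples are standardized with the *training* means and SDs, cluster
#' centroids are formed with the stored memberships and orientations, and
#' the logistic model gives per-sample class-1 probabilities. Class is
#' assigned at probability 0.5.
#'
#' @param object a [plr()] fit.
#' @param newdata samples x features matrix or `feature_matrix`.
#' @param type "response" (probability), "class", or "link".
#' @param ... unused.
#' @return Numeric vector of probabilities/link values, or a factor of
#'   classes with the training levels.
#' @export
predict.plr <- function(object, newdata,
                        type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  ctr <- plr_centroids(object, newdata)
  eta <- drop(cbind(1, ctr) %*% object$coefficients)
  names(eta) <- rownames(newdata)
  switch(type,
         link = eta,
         response = plogis(eta),
         class = factor(object$levels[(plogis(eta) >= 0.5) + 1L],
                        levels = object$levels))
}

#' Two-dimensional centroid projection
#'
#' Coordinates of each sample on the first two cluster centroids
#' (predictors 1 and 2) - the classical discrimination plot. With a
#' single-cluster model the second coordinate is 0.
#'
#' @param object a [plr()] fit.
#' @param newdata samples x features matrix or `feature_matrix`.
#' @return Numeric matrix `n x 2` with columns `predictor1`, `predictor2`.
#' @export
project_centroids <- function(object, newdata) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  ctr <- plr_centroids(object, newdata)
  out <- cbind(predictor1 = ctr[, 1],
               predictor2 = if (ncol(ctr) >= 2) ctr[, 2] else 0)
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.plr <- function(x, ...) {
  nf <- sum(vapply(x$clusters, nrow, 0L))
  cat("Penalized logistic regression with supervised feature clustering\n")
  cat(sprintf("  %d cluster(s), %d feature selections (%d unique); lambda = %g\n",
              x$n_clusters, nf,
              length(unique(unlist(lapply(x$clusters, `[[`, "feature")))),
              x$lambda))
  err <- mean((x$training$fitted >= 0.5) != (x$training$y == 1))
  cat(sprintf("  penalized criterion %.4f (null %.4f); training error %.3f\n",
              x$criterion, x$null_criterion, err))
  invisible(x)
}

#' @export
summary.plr <- function(object, ...) {
  out <- list(model = object,
              coefficients = object$coefficients,
              clusters = object$clusters,
              training_error = mean((object$training$fitted >= 0.5) !=
                                      (object$training$y == 1)))
  class(out) <- "summary.plr"
  out
}

#' @export
print.summary.plr <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n"); print(x$coefficients)
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("\nCluster %d (%d features):\n", k, nrow(cl)))
    print(cl, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.plr <- function(object, ...) object$coefficients

#' @export
fitted.plr <- function(object, ...) object$training$fitted

#' @export
residuals.plr <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$training$y; p <- object$training$fitted
  if (type == "response") return(y - p)
  d <- -2 * (y * log(pmax(p, 1e-15)) + (1 - y) * log(pmax(1 - p, 1e-15)))
  sign(y - p) * sqrt(pmax(d, 0))
}

#' Plot the centroid projection of a fitted classifier
#'
#' Training samples as circles (optionally test samples as triangles) in the
#' plane of predictors 1 and 2, coloured by class.
#'
#' @param x a [plr()] fit.
#' @param newdata training data matrix/`feature_matrix` used for the fit.
#' @param test optional held-out matrix/`feature_matrix` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plr <- function(x, newdata, test = NULL, ...) {
  pr <- project_centroids(x, newdata)
  yy <- x$training$y
  cols <- ifelse(yy == 1, "black", "red")
  graphics::plot(pr[, 1], pr[, 2], col = cols, pch = 1,
                 xlab = "predictor 1 (centroid)",
                 ylab = "predictor 2 (centroid)", ...)
  if (!is.null(test)) {
    pt <- project_centroids(x, test)
    cls <- predict(x, test, type = "class")
    graphics::points(pt[, 1], pt[, 2], pch = 2,
                     col = ifelse(cls == x$levels[2], "black", "red"))
  }
  graphics::legend("topleft", bty = "n", pch = 1, col = c("red", "black"),
                   legend = x$levels)
  invisible(x)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Versioned plain-text representation of the full classifier state
#' (standardization parameters, cluster memberships and orientations,
#' coefficients), sufficient for prediction and projection.
#'
#' @param object a [plr()] fit.
#' @param path output / input file.
#' @return `write_plr` returns `path` invisibly; `read_plr` a `plr` object.
#' @export
write_plr <- function(object, path) {
  doc <- list(format = "methylsex-plr", version = 1L,
              levels = object$levels, lambda = object$lambda,
              center = as.list(object$center),
              scale = as.list(object$scale),
              coefficients = as.list(object$coefficients),
              clusters = lapply(object$clusters, function(cl)
                list(feature = cl$feature, sign = cl$sign)),
              criterion = object$criterion,
              null_criterion = object$null_criterion)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plr
#' @export
read_plr <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "methylsex-plr"))
    stop("not a methylsex PLR model file: ", path)
  obj <- list(clusters = lapply(doc$clusters, function(cl)
    data.frame(feature = unlist(cl$feature), sign = unlist(cl$sign),
               stringsAsFactors = FALSE)),
    coefficients = unlist(doc$coefficients),
    center = unlist(doc$center), scale = unlist(doc$scale),
    levels = unlist(doc$levels), lambda = doc$lambda,
    n_clusters = length(doc$clusters),
    criterion = doc$criterion, null_criterion = doc$null_criterion,
    training = NULL)
  class(obj) <- "plr"
  obj
}
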