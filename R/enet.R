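#' Elastic-net configuration
#'
#' Defaults follow the method's reference settings: mixing 0.5 between the
#' l1 and l2 penalties, and model selection at 75% of variance explained.
#' The penalized objective solved along the path is
#' \deqn{RSS/(2T) + s [\lambda \|\omega\|_1 + ((1-\lambda)/2) \|\omega\|_2^2]}
#' with an intercept, where `mixing` is \eqn{\lambda} and the overall
#' strength `s` is swept over a geometric grid from `s_max` (the smallest
#' strength at which every coefficient is exactly zero) down to
#' `s_max * penalty_ratio`.
#'
#' @param mixing l1/l2 mixing weight, in (0, 1]; 1 is the lasso.
#' @param variance_target fraction of variance the selected model must
#'   explain, in (0, 1).
#' @param n_penalties number of grid points on the penalty path.
#' @param penalty_ratio smallest/largest penalty on the grid.
#' @param zero_tol coefficients with absolute value at or below this are
#'   treated as zero when calling neighbors (distinguishes solver-exact zeros
#'   from numerically tiny values).
#' @param convergence solver convergence threshold (passed to the coordinate
#'   descent backend); tight by default so path points satisfy the objective's
#'   stationarity conditions to ~1e-7.
#' @return an `enet_config` list.
#' @export
enet_config <- function(mixing = 0.5, variance_target = 0.75,
                        n_penalties = 100, penalty_ratio = 1e-3,
                        zero_tol = 1e-10, convergence = 1e-15) {
  stopifnot(mixing > 0, mixing <= 1,
            variance_target > 0, variance_target < 1,
            n_penalties >= 2, penalty_ratio > 0, penalty_ratio < 1,
            zero_tol >= 0)
  structure(list(mixing = mixing, variance_target = variance_target,
                 n_penalties = as.integer(n_penalties),
                 penalty_ratio = penalty_ratio, zero_tol = zero_tol,
                 convergence = convergence),
            class = "enet_config")
}

#' Fit an elastic-net regularization path
#'
#' Fits the penalized objective of [enet_config()] for one response over a
#' decreasing geometric penalty grid, returning coefficients and training
#' variance explained (1 - RSS/TSS) at every grid point. The first grid point
#' is `s_max = max_j |x_j'(y - mean(y))| / (T * mixing)`, where all
#' coefficients are exactly zero.
#'
#' The solver is glmnet's coordinate descent. glmnet internally rescales the
#' gaussian response by its 1/T standard deviation, which would distort the
#' ridge component of the penalty for a response on any other scale, so the
#' call is routed through an exact reparameterization (the mixing weight and
#' penalty grid are transformed jointly and the coefficients scaled back);
#' solutions then satisfy the stated objective's stationarity conditions.
#' A single-predictor design (P = 1) is solved by the univariate closed form
#' (soft-thresholding with ridge shrinkage).
#'
#' @param y numeric response of length T (an expression profile, typically
#'   z-scored).
#' @param X numeric T x P predictor matrix (profiles of the pool genes in
#'   columns, typically z-scored). Columns are used as given; no internal
#'   re-standardization.
#' @param config an [enet_config()].
#' @param target_gene optional id of the modeled gene, carried in the result.
#' @return a `regression_path`: list with `target_gene`, `penalties`
#'   (strictly decreasing), `coefficients` (P x n_penalties matrix, predictor
#'   ids as rownames), `intercepts`, and `variance_explained`.
#' @export
fit_enet_path <- function(y, X, config = enet_config(), target_gene = NA_character_) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y))
  T <- length(y)
  P <- ncol(X)
  if (T < 3) stop("need at least 3 samples (got ", T, ")")
  if (P < 1) stop("need at least one predictor")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in y or X")
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(P))
  a <- config$mixing
  yc <- y - mean(y)
  if (sum(yc^2) == 0) stop("response has zero variance")
  s_max <- max(abs(crossprod(X, yc))) / (T * a)
  if (!is.finite(s_max) || s_max <= 0)
    stop("response is orthogonal to every predictor; no penalty path exists")
  penalties <- exp(seq(log(s_max), log(s_max * config$penalty_ratio),
                       length.out = config$n_penalties))

  if (P == 1) {
    # univariate closed form: beta = S(x'(y-ybar)/T, s*a) / (x'x/T + s*(1-a))
    xc <- X[, 1]
    g <- sum(xc * yc) / T
    xn <- sum(xc^2) / T
    beta <- vapply(penalties, function(s) {
      sign(g) * max(0, abs(g) - s * a) / (xn + s * (1 - a))
    }, numeric(1))
    b0 <- mean(y) - beta * mean(xc)
    rss <- vapply(seq_along(penalties), function(l)
      sum((y - b0[l] - xc * beta[l])^2), numeric(1))
    ve <- 1 - rss / sum(yc^2)
    coefs <- matrix(beta, nrow = 1, dimnames = list(colnames(X), NULL))
    a0 <- b0
  } else {
    # exact reparameterization around glmnet's internal response scaling
    ys <- sqrt(mean(yc^2))
    alpha_t <- min(1, (a / ys) / (a / ys + 1 - a))
    lambda_t <- penalties * (a / ys + 1 - a)
    fit <- glmnet::glmnet(X, y / ys, family = "gaussian", alpha = alpha_t,
                          lambda = lambda_t, standardize = FALSE,
                          intercept = TRUE, thresh = config$convergence,
                          maxit = 1e7)
    coefs <- as.matrix(fit$beta) * ys
    a0 <- as.numeric(fit$a0) * ys
    ve <- fit$dev.ratio
    rownames(coefs) <- colnames(X)
    if (a < 1) {
      # polish each path point to the exact minimizer by active-set linear
      # solves (the ridge term makes the subproblems strictly convex); this
      # pins down stationarity to machine precision and makes coefficients of
      # identical predictors exactly equal
      xm <- colMeans(X)
      Xc <- sweep(X, 2, xm)
      G <- crossprod(Xc) / T
      gy <- as.numeric(crossprod(Xc, yc)) / T
      tss <- sum(yc^2)
      for (l in seq_along(penalties)) {
        w <- exact_enet_point(G, gy, penalties[l], a, coefs[, l])
        coefs[, l] <- w
        a0[l] <- mean(y) - sum(xm * w)
        ve[l] <- 1 - sum((yc - Xc %*% w)^2) / tss
      }
    }
    # the first grid point is s_max by construction: all-zero, ve exactly 0
    coefs[, 1] <- 0
    a0[1] <- mean(y)
    ve[1] <- 0
  }
  structure(list(target_gene = target_gene, penalties = penalties,
                 coefficients = coefs, intercepts = a0,
                 variance_explained = as.numeric(ve)),
            class = "regression_path")
}

#' @export
print.regression_path <- function(x, ...) {
  cat(sprintf("regression_path for '%s': %d penalties, %d predictors, ve %.3f-%.3f\n",
              x$target_gene, length(x$penalties), nrow(x$coefficients),
              min(x$variance_explained), max(x$variance_explained)))
  invisible(x)
}

# Exact minimizer of  |yc - Xc w|^2/(2T) + s(a|w|_1 + (1-a)/2 |w|_2^2)
# for mixing a < 1, by active-set iteration from a warm start:
#   G = Xc'Xc/T, gy = Xc'yc/T. On an active set A with signs sg, the
# stationarity system is (G[A,A] + s(1-a) I) w_A = gy[A] - s a sg; entries
# whose solved sign contradicts sg are dropped, then the worst KKT violator
# outside A (|gradient| > s a) is added, until none remain.
exact_enet_point <- function(G, gy, s, a, w0, max_iter = 200L) {
  A <- which(w0 != 0)
  sg <- sign(w0[A])
  w <- numeric(length(gy))
  for (it in seq_len(max_iter)) {
    wa <- numeric(0)
    while (length(A)) {
      M <- G[A, A, drop = FALSE]
      diag(M) <- diag(M) + s * (1 - a)
      wa <- solve(M, gy[A] - s * a * sg)
      bad <- which(wa * sg <= 0)
      if (!length(bad)) break
      A <- A[-bad]
      sg <- sg[-bad]
    }
    w[] <- 0
    w[A] <- wa
    g <- if (length(A)) gy - as.numeric(G[, A, drop = FALSE] %*% wa) else gy
    viol <- abs(g) > s * a + 1e-12
    viol[A] <- FALSE
    if (!any(viol)) return(w)
    j <- which.max(abs(g) * viol)
    A <- c(A, j)
    sg <- c(sg, sign(g[j]))
  }
  w  # iteration cap: return the best iterate (warm starts make this moot)
}

#' Select coefficients from a path by a variance-explained target
#'
#' Returns the model at the *largest* penalty whose training variance
#' explained reaches the target, i.e. the sparsest qualifying model. If no
#' grid point reaches the target, the smallest-penalty (best-fitting) model
#' is returned with `met_target = FALSE`.
#'
#' @param path a `regression_path` from [fit_enet_path()].
#' @param variance_target required fraction of variance explained.
#' @return list with `coefficients` (named vector over the predictors),
#'   `intercept`, `penalty`, `achieved_variance`, `met_target`.
#' @export
select_coefficients <- function(path, variance_target = 0.75) {
  stopifnot(inherits(path, "regression_path"))
  i <- which(path$variance_explained >= variance_target)[1]
  met <- !is.na(i)
  if (!met) i <- length(path$penalties)
  list(coefficients = path$coefficients[, i],
       intercept = path$intercepts[i],
       penalty = path$penalties[i],
       achieved_variance = path$variance_explained[i],
       met_target = met)
}

#' Call the neighbors of one modeled gene
#'
#' Neighbors are the predictors with coefficient magnitude above `zero_tol`.
#'
#' @param coefficients named numeric vector over the predictor pool.
#' @param zero_tol tolerance separating exact zeros from active coefficients.
#' @return character vector of neighbor gene ids.
#' @export
neighbors_of_gene <- function(coefficients, zero_tol = 1e-10) {
  names(coefficients)[abs(coefficients) > zero_tol]
}
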