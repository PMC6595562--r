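# REML variance-component estimation and BLUP for linear mixed models
#   y = X b + sum_i u_i + e,   u_i ~ N(0, K_i s2_i),   e ~ N(0, I s2_e)
#
# Three computational routes maximise the same restricted likelihood
#   lR = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]:
#  * one kernel: eigendecomposition of K, 1-D profile likelihood in the
#    heritability ratio (exact boundary at 0 permitted);
#  * one dense kernel + one low-rank marker kernel (K = ZZ'): rotation by
#    the dense kernel's eigenvectors plus the Woodbury identity, maximised
#    by bounded quasi-Newton over the raw variance components (the regional
#    heritability mapping case);
#  * general: average-information REML with 3 EM burn-in iterations,
#    boundary components pinned at zero after two consecutive negative
#    updates.

# ---- kernel normalisation -------------------------------------------------

# Accepts: RelationshipMatrix, plain matrix, or list with any of
# K (dense), Z (factor with K = ZZ'), eigen (list(values, vectors)).
normalizeKernel <- function(k, n) {
  out <- list(K = NULL, Z = NULL, eigen = NULL)
  if (methods::is(k, "RelationshipMatrix")) {
    out$K <- relMatrix(k)
    if (!is.null(k@factor)) out$Z <- k@factor
  } else if (is.matrix(k)) {
    if (nrow(k) == n && ncol(k) == n && isSymmetric(unname(k),
                                                    tol = 1e-8)) {
      out$K <- unname(k)
    } else if (nrow(k) == n) {
      out$Z <- unname(k)
    } else stop("kernel matrix has wrong dimensions")
  } else if (is.list(k)) {
    out$K <- k$K
    out$Z <- k$Z
    out$eigen <- k$eigen
  } else stop("unsupported kernel specification")
  if (is.null(out$K) && is.null(out$Z) && is.null(out$eigen))
    stop("kernel must provide a matrix, a factor or an eigendecomposition")
  out
}

kernelDense <- function(k) {
  if (!is.null(k$K)) return(k$K)
  if (!is.null(k$eigen))
    return(k$eigen$vectors %*% (k$eigen$values * t(k$eigen$vectors)))
  tcrossprod(k$Z)
}

kernelEigen <- function(k) {
  if (!is.null(k$eigen)) return(k$eigen)
  E <- eigen(kernelDense(k), symmetric = TRUE)
  list(values = E$values, vectors = E$vectors)
}

#' Precompute a kernel eigendecomposition
#'
#' Wraps a relationship matrix with its eigendecomposition so that repeated
#' [remlFit()] calls against the same kernel (e.g. the pedigree matrix during
#' a genome scan) skip the decomposition.
#'
#' @param rel a [RelationshipMatrix-class] or symmetric matrix
#' @return a kernel object usable in the `K` list of [remlFit()].
#' @export
precomputeEigen <- function(rel) {
  K <- if (methods::is(rel, "RelationshipMatrix")) relMatrix(rel) else rel
  E <- eigen(K, symmetric = TRUE)
  list(K = K, eigen = list(values = E$values, vectors = E$vectors))
}

# ---- restricted likelihood pieces ----------------------------------------

remlConst <- function(n, p) -0.5 * (n - p) * log(2 * pi)

# dense-V restricted loglik + derived quantities
denseRemlPieces <- function(y, X, Vchol) {
  n <- length(y)
  p <- ncol(X)
  logdetV <- 2 * sum(log(diag(Vchol)))
  ViX <- backsolve(Vchol, forwardsolve(t(Vchol), X))
  Viy <- backsolve(Vchol, forwardsolve(t(Vchol), y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  cX <- chol(XtViX)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  yPy <- sum(y * Viy) - sum(XtViy * beta)
  ll <- remlConst(n, p) -
    0.5 * (logdetV + 2 * sum(log(diag(cX))) + yPy)
  list(ll = ll, beta = beta, Viy = Viy, ViX = ViX, XtViX = XtViX)
}

# ---- path 1: single kernel, eigen-rotated profile likelihood --------------

remlEigenPath <- function(y, X, kern, label, computeSe, tol) {
  n <- length(y)
  E <- kernelEigen(kern)
  lam <- pmax(E$values, 0)
  U <- E$vectors
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  if (sd(lam) < 1e-10 * max(1, mean(lam)))
    warning("remlFit: kernel is proportional to the identity; ",
            "genetic and residual variances are not separately identifiable")

  profile <- function(h) {
    sig <- h * lam + (1 - h)
    w <- 1 / sig
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    cX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cX)) return(list(ll = -Inf))
    b <- backsolve(cX, forwardsolve(t(cX), crossprod(Xt, w * yt)))
    r <- yt - Xt %*% b
    q <- sum(w * r^2)
    s2 <- q / (n - p)
    ll <- remlConst(n, p) - 0.5 * ((n - p) * log(s2) + sum(log(sig)) +
                                     2 * sum(log(diag(cX))) + (n - p))
    list(ll = ll, s2 = s2, beta = b)
  }
  opt <- optimize(function(h) profile(h)$ll, c(0, 1 - 1e-8), maximum = TRUE,
                  tol = 1e-9)
  cands <- c(0, opt$maximum)
  lls <- vapply(cands, function(h) profile(h)$ll, numeric(1))
  h <- cands[which.max(lls)]
  pr <- profile(h)
  sigma2 <- stats::setNames(c(h * pr$s2, (1 - h) * pr$s2),
                            c(label, "residual"))
  out <- list(sigma2 = sigma2, loglik = pr$ll, converged = TRUE,
              iterations = 1L, method = "eigen", n = n,
              beta = as.vector(pr$beta))
  if (computeSe) {
    ai <- aiMatrixRotated(yt, Xt, list(lam), sigma2)
    out$ai <- ai
    out$se <- sqrt(pmax(diag(solve(ai)), 0))
    names(out$se) <- names(sigma2)
  }
  out
}

# AI matrix in a rotated basis where every kernel is diagonal (list of
# eigenvalue vectors) plus the implicit residual identity.
aiMatrixRotated <- function(yt, Xt, lambdas, sigma2) {
  n <- length(yt)
  k <- length(lambdas)
  v <- rep(sigma2[k + 1], n)
  for (i in seq_len(k)) v <- v + sigma2[i] * lambdas[[i]]
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  Pv <- function(x) {
    wx <- w * x
    wx - XtW %*% solve(XtWX, crossprod(XtW, x))
  }
  Py <- Pv(yt)
  Ts <- vector("list", k + 1)
  for (i in seq_len(k)) Ts[[i]] <- lambdas[[i]] * Py
  Ts[[k + 1]] <- Py
  ai <- matrix(0, k + 1, k + 1)
  PT <- vapply(Ts, Pv, numeric(n))
  for (i in seq_len(k + 1))
    for (j in i:(k + 1))
      ai[i, j] <- ai[j, i] <- 0.5 * sum(Ts[[i]] * PT[, j])
  ai
}

# ---- path 2: dense + low-rank kernel via Woodbury -------------------------

remlWoodburyPath <- function(y, X, denseK, lowK, labels, init, computeSe,
                             tol) {
  n <- length(y)
  p <- ncol(X)
  E <- kernelEigen(denseK)
  d <- pmax(E$values, 0)
  U <- E$vectors
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  M <- crossprod(U, lowK$Z)
  q <- ncol(M)

  loglik <- function(th) {
    s2a <- th[1]; s2u <- th[2]; s2e <- th[3]
    Dv <- s2a * d + s2e
    if (any(Dv <= 0)) return(-Inf)
    Tm <- cbind(yt, Xt) / Dv
    if (s2u > 0) {
      B <- diag(q) + s2u * crossprod(M, M / Dv)
      cB <- tryCatch(chol(B), error = function(e) NULL)
      if (is.null(cB)) return(-Inf)
      MtT <- crossprod(M, Tm)
      Tm <- Tm - s2u * (M %*% backsolve(cB, forwardsolve(t(cB), MtT))) / Dv
      logdetV <- sum(log(Dv)) + 2 * sum(log(diag(cB)))
    } else {
      logdetV <- sum(log(Dv))
    }
    XtViX <- crossprod(Xt, Tm[, -1, drop = FALSE])
    XtViy <- crossprod(Xt, Tm[, 1])
    cXX <- tryCatch(chol((XtViX + t(XtViX)) / 2), error = function(e) NULL)
    if (is.null(cXX)) return(-Inf)
    beta <- backsolve(cXX, forwardsolve(t(cXX), XtViy))
    yPy <- sum(yt * Tm[, 1]) - sum(XtViy * beta)
    remlConst(n, p) - 0.5 * (logdetV + 2 * sum(log(diag(cXX))) + yPy)
  }

  vy <- var(y)
  th0 <- if (!is.null(init)) pmax(init, c(0, 0, 1e-6 * vy)) else
    c(0.3 * vy, 0.05 * vy, 0.65 * vy)
  ctl <- list(parscale = rep(vy, 3), factr = 1e4, ndeps = rep(1e-6, 3),
              maxit = 200L)
  opt <- optim(th0, function(th) -loglik(th), method = "L-BFGS-B",
               lower = c(0, 0, 1e-8 * vy), control = ctl)
  th <- opt$par
  ll <- -opt$value
  # explicit boundary candidate: no low-rank component
  opt0 <- optim(c(th[1] + th[2] * q / n, max(th[3], 1e-6 * vy)),
                function(th2) -loglik(c(th2[1], 0, th2[2])),
                method = "L-BFGS-B", lower = c(0, 1e-8 * vy),
                control = list(parscale = rep(vy, 2), factr = 1e4,
                               ndeps = rep(1e-6, 2), maxit = 200L))
  ll0 <- -opt0$value
  if (ll0 >= ll - 1e-9) {
    th <- c(opt0$par[1], 0, opt0$par[2])
    ll <- ll0
  }
  sigma2 <- stats::setNames(th[c(1, 2, 3)],
                            c(labels[1], labels[2], "residual"))
  out <- list(sigma2 = sigma2, loglik = ll,
              converged = opt$convergence == 0,
              iterations = as.integer(opt$counts[1]),
              method = "woodbury", n = n)
  if (computeSe) {
    Kd <- kernelDense(denseK)
    Kl <- tcrossprod(lowK$Z)
    ai <- aiMatrixDense(y, X, list(Kd, Kl), sigma2)
    out$ai <- ai
    out$se <- sqrt(pmax(diag(solve(ai)), 0))
    names(out$se) <- names(sigma2)
  }
  out
}

aiMatrixDense <- function(y, X, Ks, sigma2) {
  n <- length(y)
  k <- length(Ks)
  V <- diag(as.numeric(sigma2[k + 1]), n)
  for (i in seq_len(k)) V <- V + sigma2[i] * Ks[[i]]
  R <- chol(V)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  Py <- P %*% y
  Ts <- c(lapply(Ks, function(K) K %*% Py), list(Py))
  ai <- matrix(0, k + 1, k + 1)
  PT <- vapply(Ts, function(t) as.vector(P %*% t), numeric(n))
  for (i in seq_len(k + 1))
    for (j in i:(k + 1))
      ai[i, j] <- ai[j, i] <- 0.5 * sum(Ts[[i]] * PT[, j])
  ai
}

# ---- path 3: general dense AI-REML ---------------------------------------

remlAiPath <- function(y, X, Ks, labels, init, computeSe, tol, maxit,
                       emIter = 3L) {
  n <- length(y)
  k <- length(Ks)
  vy <- var(y)
  theta <- if (!is.null(init)) pmax(init, 1e-8 * vy) else
    rep(vy / (k + 1), k + 1)
  pinned <- rep(FALSE, k + 1)
  negCount <- rep(0L, k + 1)
  llOld <- -Inf
  converged <- FALSE
  iter <- 0L

  pieces <- function(theta) {
    V <- diag(theta[k + 1], n)
    for (i in seq_len(k)) if (theta[i] > 0) V <- V + theta[i] * Ks[[i]]
    R <- chol(V)
    pr <- denseRemlPieces(y, X, R)
    Vi <- chol2inv(R)
    ViX <- pr$ViX
    P <- Vi - ViX %*% solve(pr$XtViX, t(ViX))
    Py <- P %*% y
    Ts <- c(lapply(Ks, function(K) K %*% Py), list(Py))
    trPK <- c(vapply(Ks, function(K) sum(P * K), numeric(1)),
              sum(diag(P)))
    yPKPy <- vapply(Ts, function(t) sum(Py * t), numeric(1))
    list(ll = pr$ll, P = P, Py = Py, Ts = Ts, trPK = trPK, yPKPy = yPKPy,
         beta = pr$beta)
  }

  pc <- pieces(theta)
  for (iter in seq_len(maxit)) {
    grad <- -0.5 * (pc$trPK - pc$yPKPy)
    if (iter <= emIter) {
      prop <- theta + theta^2 * (pc$yPKPy - pc$trPK) / n
      prop[k + 1] <- max(prop[k + 1], 1e-8 * vy)
      prop[pinned] <- 0
      prop <- pmax(prop, 0)
    } else {
      free <- !pinned
      PT <- vapply(pc$Ts, function(t) as.vector(pc$P %*% t), numeric(n))
      ai <- matrix(0, k + 1, k + 1)
      for (i in seq_len(k + 1))
        for (j in i:(k + 1))
          ai[i, j] <- ai[j, i] <- 0.5 * sum(pc$Ts[[i]] * PT[, j])
      delta <- rep(0, k + 1)
      sol <- tryCatch(solve(ai[free, free, drop = FALSE], grad[free]),
                      error = function(e) NULL)
      if (is.null(sol)) {            # non-PD AI step: fall back to EM
        prop <- theta + theta^2 * (pc$yPKPy - pc$trPK) / n
      } else {
        delta[free] <- sol
        prop <- theta + delta
        halve <- 0L
        while (any(prop[free] < 0) && halve < 10L) {
          delta <- delta / 2
          prop <- theta + delta
          halve <- halve + 1L
        }
      }
      neg <- prop < 0
      negCount[neg] <- negCount[neg] + 1L
      negCount[!neg] <- 0L
      pinned <- pinned | (negCount >= 2L & seq_len(k + 1) <= k)
      prop[neg] <- pmax(prop[neg], theta[neg] / 10)
      prop[pinned] <- 0
      prop[k + 1] <- max(prop[k + 1], 1e-8 * vy)
    }
    pcNew <- tryCatch(pieces(prop), error = function(e) NULL)
    if (is.null(pcNew)) break
    theta <- prop
    pc <- pcNew
    if (abs(pc$ll - llOld) < tol) { converged <- TRUE; llOld <- pc$ll; break }
    llOld <- pc$ll
  }

  sigma2 <- stats::setNames(theta, c(labels, "residual"))
  out <- list(sigma2 = sigma2, loglik = pc$ll, converged = converged,
              iterations = iter, method = "ai", n = n,
              beta = as.vector(pc$beta))
  if (computeSe) {
    ai <- aiMatrixDense(y, X, Ks, sigma2)
    out$ai <- ai
    se <- rep(NA_real_, k + 1)
    free <- theta > 0
    inv <- tryCatch(solve(ai[free, free, drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(inv)) se[free] <- sqrt(pmax(diag(inv), 0))
    out$se <- stats::setNames(se, names(sigma2))
    out$ai <- ai
  }
  out
}

# ---- public API -----------------------------------------------------------

#' REML variance-component estimation
#'
#' Fits `y = X b + sum_i u_i + e` with `u_i ~ N(0, K_i s2_i)` by restricted
#' maximum likelihood.  Components are constrained nonnegative; boundary
#' estimates of exactly zero are permitted (required for the mixture
#' likelihood-ratio test of a variance component).  The computational route
#' is chosen from the structure of `K`; all routes maximise the identical
#' restricted likelihood, so fits are comparable across routes.
#'
#' @param y numeric response vector (no missing values)
#' @param X fixed-effect design matrix; default intercept only
#' @param K named list of kernels: [RelationshipMatrix-class] objects, plain
#'   symmetric matrices, factor matrices `Z` (implying `K = ZZ'`), or lists
#'   with elements `K`/`Z`/`eigen` (see [precomputeEigen()])
#' @param init optional numeric starting values (one per kernel plus
#'   residual)
#' @param computeSe compute standard errors from the inverse
#'   average-information matrix at the optimum
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood
#' @param maxit maximum iterations for the average-information route
#' @return object of class `"remlFit"`: list with `sigma2` (named, includes
#'   `residual`), `loglik`, `converged`, `iterations`, `method`, and when
#'   requested `se` and `ai`.
#' @export
remlFit <- function(y, X = NULL, K = list(), init = NULL, computeSe = TRUE,
                    tol = 1e-6, maxit = 100L) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("remlFit: response contains missing values")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])]
    stop("remlFit: singular fixed-effect design; aliased columns: ",
         paste(if (length(aliased)) aliased else "(unnamed)", collapse = ", "))
  }
  if (length(K) == 0) stop("remlFit: need at least one kernel")
  if (n < ncol(X) + length(K) + 1)
    stop("remlFit: too few observations for the requested model")
  labels <- names(K)
  if (is.null(labels)) labels <- paste0("K", seq_along(K))
  kerns <- lapply(K, normalizeKernel, n = n)

  isLowRank <- vapply(kerns, function(k)
    is.null(k$K) && is.null(k$eigen) && !is.null(k$Z) &&
      ncol(k$Z) <= 0.75 * n, logical(1))

  fit <- if (length(K) == 1 && !isLowRank[1]) {
    remlEigenPath(y, X, kerns[[1]], labels[1], computeSe, tol)
  } else if (length(K) == 2 && sum(isLowRank) == 1) {
    di <- which(!isLowRank); li <- which(isLowRank)
    f <- remlWoodburyPath(y, X, kerns[[di]], kerns[[li]],
                          c(labels[di], labels[li]), init, computeSe, tol)
    # restore caller's kernel order
    ord <- c(labels, "residual")
    f$sigma2 <- f$sigma2[ord]
    if (!is.null(f$se)) f$se <- f$se[ord]
    f
  } else {
    Ks <- lapply(kerns, kernelDense)
    remlAiPath(y, X, Ks, labels, init, computeSe, tol, maxit)
  }
  class(fit) <- "remlFit"
  fit
}

#' @export
print.remlFit <- function(x, ...) {
  cat("REML fit (", x$method, " route): n = ", x$n, "\n", sep = "")
  tab <- data.frame(component = names(x$sigma2), sigma2 = x$sigma2)
  if (!is.null(x$se)) tab$se <- x$se
  print(tab, row.names = FALSE)
  cat(sprintf("logLik = %.4f  converged = %s (%d iterations)\n",
              x$loglik, x$converged, x$iterations))
  invisible(x)
}

#' BLUP solutions given variance components
#'
#' Solves the mixed model for fixed effects and per-component random-effect
#' predictions at fixed variance components.  Individuals with a missing
#' (masked) response contribute no information but receive predictions for
#' every random term - the prediction contract used for validation animals
#' in cross-validation.
#'
#' @param y numeric response over all individuals; `NA` marks masked records
#' @param X fixed-effect design over all individuals (default intercept)
#' @param K named list of kernels over all individuals (same order as `y`)
#' @param vc a [remlFit()] object, or a named numeric vector of variance
#'   components ending in `residual`
#' @return list with `beta` (fixed effects), `u` (named list of
#'   random-effect predictions over all individuals) and `total` (their
#'   elementwise sum).
#' @export
blupSolve <- function(y, X = NULL, K = list(), vc) {
  sigma2 <- if (inherits(vc, "remlFit")) vc$sigma2 else vc
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  obs <- !is.na(y)
  no <- sum(obs)
  labels <- names(K)
  if (is.null(labels)) labels <- paste0("K", seq_along(K))
  kerns <- lapply(K, normalizeKernel, n = n)

  Vo <- diag(as.numeric(sigma2["residual"]), no)
  for (i in seq_along(kerns)) {
    Kd <- kernelDense(kerns[[i]])
    Vo <- Vo + sigma2[labels[i]] * Kd[obs, obs, drop = FALSE]
  }
  R <- tryCatch(chol(Vo), error = function(e)
    stop("blupSolve: covariance of observed records is not positive definite",
         call. = FALSE))
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  ViX <- backsolve(R, forwardsolve(t(R), Xo))
  Viy <- backsolve(R, forwardsolve(t(R), yo))
  XtViX <- crossprod(Xo, ViX)
  beta <- solve(XtViX, crossprod(Xo, Viy))
  r <- yo - Xo %*% beta
  Vir <- backsolve(R, forwardsolve(t(R), r))
  u <- vector("list", length(kerns))
  names(u) <- labels
  for (i in seq_along(kerns)) {
    k <- kerns[[i]]
    ui <- if (!is.null(k$Z)) {
      as.vector(k$Z %*% crossprod(k$Z[obs, , drop = FALSE], Vir))
    } else {
      Kd <- kernelDense(k)
      as.vector(Kd[, obs, drop = FALSE] %*% Vir)
    }
    u[[i]] <- sigma2[labels[i]] * ui
  }
  total <- Reduce(`+`, u)
  list(beta = as.vector(beta), u = u, total = total)
}

#' Mixture likelihood-ratio test for a boundary variance component
#'
#' A variance component tested at its boundary (`s2 >= 0`) gives an LRT
#' distributed, under the null, as an equal mixture of a point mass at zero
#' and chi-square with 1 df.  Hence `p = 0.5` when `LRT = 0` and
#' `p = 0.5 * P(chisq_1 > LRT)` otherwise.
#'
#' @param loglikFull restricted log-likelihood of the full model
#' @param loglikBase restricted log-likelihood of the nested base model
#' @param tol tolerance below which the LRT is treated as exactly zero; a
#'   deficit beyond `tol` (full below base) triggers an optimizer-failure
#'   warning and the LRT is clamped to zero
#' @return list with `lrt` and `p`.
#' @export
lrtMixtureP <- function(loglikFull, loglikBase, tol = 1e-6) {
  lrt <- 2 * (loglikFull - loglikBase)
  if (lrt < -tol)
    warning("lrtMixtureP: full-model likelihood below base model ",
            "(optimizer failure); LRT clamped to 0")
  lrt <- max(0, lrt)
  if (lrt <= tol) lrt <- 0
  p <- if (lrt == 0) 0.5 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  list(lrt = lrt, p = p)
}
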