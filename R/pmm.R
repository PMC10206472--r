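# Shared model preparation: drops incomplete rows, builds X, the species
# incidence, and the eigenbasis of Z A Z' in which every profile evaluation
# is O(n p^2).
pmm_design <- function(formula, data, species, A) {
  if (!species %in% names(data))
    stop("species column '", species, "' not found in data", call. = FALSE)

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  sp <- as.character(data[[species]])
  keep <- stats::complete.cases(mf) & !is.na(sp) & nzchar(sp)
  mf <- mf[keep, , drop = FALSE]
  sp <- sp[keep]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L)
    stop("too few complete observations (", n, ") for ", p,
         " fixed effects", call. = FALSE)
  if (qr(X)$rank < p)
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)

  lev <- sort(unique(sp))
  s <- length(lev)
  if (s < 2L) stop("need at least 2 species", call. = FALSE)
  g <- factor(sp, levels = lev)

  identity_A <- is.null(A)
  if (identity_A) {
    A <- diag(s)
    dimnames(A) <- list(lev, lev)
  } else {
    A <- as.matrix(A)
    if (is.null(rownames(A)))
      stop("species covariance must carry species names as dimnames",
           call. = FALSE)
    missing <- setdiff(lev, rownames(A))
    if (length(missing))
      stop("species missing from covariance matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    A <- A[lev, lev, drop = FALSE]
    if (max(abs(A - t(A))) > 1e-8 * max(abs(A), 1))
      stop("species covariance is not symmetric", call. = FALSE)
  }

  off_diag <- A; diag(off_diag) <- 0
  if (max(abs(off_diag)) < 1e-12 && max(table(g)) == 1L)
    stop("variance components are not identifiable: independent species ",
         "effects with a single observation per species", call. = FALSE)

  # K = Z A Z'; its eigenbasis rotates the model to independent coordinates
  Z <- stats::model.matrix(~ 0 + g)
  K <- Z %*% A %*% t(Z)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8 * max(abs(lam), 1))
    stop("species covariance is not positive semi-definite (min eigenvalue ",
         format(min(lam)), ")", call. = FALSE)
  lam <- pmax(lam, 0)
  Qt <- t(eig$vectors)
  yt <- drop(Qt %*% y)
  Xt <- Qt %*% X

  list(yt = yt, Xt = Xt, lam = lam, n = n, p = p, s = s, lev = lev,
       X_names = colnames(X), identity_A = identity_A)
}

pmm_profile_point <- function(design, theta) {
  yt <- design$yt; Xt <- design$Xt; lam <- design$lam
  n <- design$n; p <- design$p
  w <- 1 / (1 + theta * lam)
  XtW <- Xt * w
  XtVX <- crossprod(Xt, XtW)
  cf <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  beta <- backsolve(cf, forwardsolve(t(cf), crossprod(XtW, yt)))
  r <- yt - drop(Xt %*% beta)
  rss <- sum(w * r * r)
  ldV <- sum(log1p(theta * lam))
  ldI <- 2 * sum(log(diag(cf)))
  s2_ml <- rss / n
  s2_reml <- rss / (n - p)
  list(
    theta = theta, beta = drop(beta), XtVX = XtVX,
    sigma2_ml = s2_ml, sigma2_reml = s2_reml,
    ll_ml = -0.5 * (n * log(2 * pi * s2_ml) + ldV + n),
    ll_reml = -0.5 * ((n - p) * log(2 * pi * s2_reml) + ldV + ldI +
                        (n - p))
  )
}

#' Profiled log-likelihood over the variance ratio
#'
#' Evaluates the profiled REML or ML log-likelihood of the mixed model of
#' [fit_pmm()] at given values of `theta = sigma2_p / sigma2_e` (fixed
#' effects and residual variance profiled out in closed form). Useful for
#' plotting the profile or verifying that the optimizer's solution
#' dominates a brute-force grid.
#'
#' @inheritParams fit_pmm
#' @param theta Numeric vector of non-negative variance ratios.
#' @return Numeric vector of profiled log-likelihoods (`-Inf` where the
#'   GLS system is singular).
#' @export
pmm_profile_loglik <- function(formula, data, species = "species", A = NULL,
                               theta = 1, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  stopifnot(all(theta >= 0))
  design <- pmm_design(formula, data, species, A)
  vapply(theta, function(th) {
    pr <- pmm_profile_point(design, th)
    if (is.null(pr)) return(-Inf)
    if (criterion == "REML") pr$ll_reml else pr$ll_ml
  }, numeric(1))
}

#' Fit a phylogenetic (or ordinary) linear mixed model
#'
#' Fits `y = X beta + Z u + e` with a single species-level random effect
#' `u ~ N(0, sigma2_p * A)` and residual `e ~ N(0, sigma2_e * I)`, where
#' `Z` is the observation-to-species incidence matrix and `A` is either a
#' standardized phylogenetic covariance (see [phylo_covariance()]) or, when
#' `A = NULL`, the identity (an ordinary species random intercept).
#'
#' Estimation profiles the variance ratio `theta = sigma2_p / sigma2_e`:
#' after one symmetric eigendecomposition of `Z A Z'`, the GLS fixed
#' effects and the profiled residual variance are available in closed form
#' at any `theta`, so the 1-D profile is maximized deterministically by a
#' log-spaced grid over `theta_bounds` followed by bounded refinement
#' (absolute tolerance 1e-8), with `theta = 0` always evaluated as a
#' boundary candidate. The REML criterion includes the log-determinant of
#' the GLS information matrix `X' V^-1 X`. There is no random
#' initialization: fits are reproducible bit-for-bit.
#'
#' Phylogenetic heritability is `H2 = sigma2_p / (sigma2_p + sigma2_e)`,
#' the proportion of (observation-level) variance attributable to
#' phylogeny; `H2 = 0` means no phylogenetic signal and `H2 = 1` is the
#' Brownian-motion expectation (the same interpretation as Pagel's lambda
#' in phylogenetic GLS).
#'
#' @param formula Model formula, e.g. `Sa ~ parasitic`; variables are taken
#'   from `data`.
#' @param data A `data.frame` of observations (typically an egg table);
#'   rows with missing response, predictors or species label are dropped.
#' @param species Name of the column holding the species (grouping) label.
#' @param A Species-by-species covariance matrix with dimnames covering all
#'   species in `data`, typically `phylo_covariance(tree)$A`; `NULL` for
#'   the identity.
#' @param criterion `"REML"` (default, for variance components) or `"ML"`
#'   (for likelihood-ratio tests of fixed effects).
#' @param theta_bounds Search interval for `theta`; the default
#'   `c(1e-6, 1e6)` reaches both near-zero and near-one heritability.
#' @return An object of class `pmm_fit` with components `beta` (estimate,
#'   SE, t per fixed effect), `sigma2_p`, `sigma2_e`, `H2`, `loglik_reml`,
#'   `loglik_ml` (both evaluated at the optimum of the requested
#'   criterion), `theta`, `converged`, `boundary`, `n`, `p`,
#'   `criterion`, `species_levels`.
#' @export
fit_pmm <- function(formula, data, species = "species", A = NULL,
                    criterion = c("REML", "ML"),
                    theta_bounds = c(1e-6, 1e6)) {
  criterion <- match.arg(criterion)
  stopifnot(is.numeric(theta_bounds), length(theta_bounds) == 2L,
            theta_bounds[1] > 0, theta_bounds[1] < theta_bounds[2])
  design <- pmm_design(formula, data, species, A)
  n <- design$n; p <- design$p

  profile <- function(theta) pmm_profile_point(design, theta)
  obj <- function(theta) {
    pr <- profile(theta)
    if (is.null(pr)) return(-Inf)
    if (criterion == "REML") pr$ll_reml else pr$ll_ml
  }

  # theta = 0 is a legitimate boundary solution (no phylogenetic variance)
  cand_theta <- c(0, exp(seq(log(theta_bounds[1]), log(theta_bounds[2]),
                             length.out = 61L)))
  cand_ll <- vapply(cand_theta, obj, numeric(1))
  best <- which.max(cand_ll)
  converged <- TRUE
  theta_hat <- cand_theta[best]
  if (best > 1L) {
    lo <- cand_theta[max(best - 1L, 2L)]
    hi <- cand_theta[min(best + 1L, length(cand_theta))]
    opt <- tryCatch(
      stats::optimize(function(lt) obj(exp(lt)), lower = log(lo),
                      upper = log(hi), maximum = TRUE, tol = 1e-10),
      error = function(e) NULL)
    if (is.null(opt)) {
      converged <- FALSE
    } else if (opt$objective >= cand_ll[best]) {
      theta_hat <- exp(opt$maximum)
    }
    if (obj(0) >= obj(theta_hat)) theta_hat <- 0
  }

  pr <- profile(theta_hat)
  sigma2_e <- if (criterion == "REML") pr$sigma2_reml else pr$sigma2_ml
  sigma2_p <- theta_hat * sigma2_e
  H2 <- if (sigma2_p == 0) 0 else sigma2_p / (sigma2_p + sigma2_e)
  boundary <- theta_hat == 0 ||
    theta_hat <= theta_bounds[1] * (1 + 1e-6) ||
    theta_hat >= theta_bounds[2] * (1 - 1e-6)

  se <- sqrt(diag(solve(pr$XtVX)) * sigma2_e)
  beta <- data.frame(term = design$X_names, estimate = pr$beta, se = se,
                     t = pr$beta / se, row.names = NULL)

  structure(list(
    formula = formula, beta = beta, sigma2_p = sigma2_p,
    sigma2_e = sigma2_e, H2 = H2, theta = theta_hat,
    loglik_reml = pr$ll_reml, loglik_ml = pr$ll_ml,
    converged = converged, boundary = boundary,
    n = n, p = p, n_species = design$s, criterion = criterion,
    species_levels = design$lev, identity_A = design$identity_A
  ), class = "pmm_fit")
}

#' @export
print.pmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model (", x$criterion, "), ",
      x$n, " obs / ", x$n_species, " species",
      if (x$identity_A) " [identity species covariance]", "\n", sep = "")
  print(x$beta, digits = 4)
  cat(sprintf("sigma2_p = %.6g  sigma2_e = %.6g  H2 = %.4f%s\n",
              x$sigma2_p, x$sigma2_e, x$H2,
              if (x$boundary) "  (boundary)" else ""))
  cat(sprintf("logLik: REML %.4f  ML %.4f\n", x$loglik_reml, x$loglik_ml))
  invisible(x)
}

#' Phylogenetic heritability of a fitted model
#'
#' `H2 = sigma2_p / (sigma2_p + sigma2_e)`, in `[0, 1]`; exact 0 and 1 are
#' returned at the boundaries.
#'
#' @param fit A `pmm_fit`.
#' @return H2 in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "pmm_fit"))
  if (!isTRUE(fit$converged))
    stop("heritability is only defined for a converged fit", call. = FALSE)
  tot <- fit$sigma2_p + fit$sigma2_e
  if (tot <= 0)
    stop("both variance components are zero; H2 undefined", call. = FALSE)
  if (fit$sigma2_p == 0) return(0)
  if (fit$sigma2_e == 0) return(1)
  fit$sigma2_p / tot
}

#' Likelihood-ratio chi-square test of nested fixed effects
#'
#' Both models are fitted by ML (REML likelihoods are not comparable
#' across fixed-effect structures); the statistic is
#' `chi2 = 2 (logLik_full - logLik_reduced)` clamped at zero, with degrees
#' of freedom equal to the difference in fixed-effect count and an upper
#' chi-square tail p-value. This is how predictor p-values are obtained
#' for the mixed models, whose t ratios carry no denominator df.
#'
#' @param full,reduced Model formulas; the reduced fixed effects must be a
#'   subset of the full ones (same response).
#' @param data,species,A,theta_bounds As in [fit_pmm()]; the random
#'   structure is shared by both fits.
#' @return An object of class `lrt_result`: list with `chi2`, `df`, `p`,
#'   and the two `pmm_fit`s.
#' @export
lrt_fixed_effect <- function(full, reduced, data, species = "species",
                             A = NULL, theta_bounds = c(1e-6, 1e6)) {
  tf <- attr(stats::terms(full), "term.labels")
  tr <- attr(stats::terms(reduced), "term.labels")
  if (!all(tr %in% tf))
    stop("models are not nested: reduced terms [",
         paste(setdiff(tr, tf), collapse = ", "),
         "] absent from the full model", call. = FALSE)
  if (!identical(deparse(full[[2]]), deparse(reduced[[2]])))
    stop("full and reduced models must share the response", call. = FALSE)
  fit_full <- fit_pmm(full, data, species = species, A = A,
                      criterion = "ML", theta_bounds = theta_bounds)
  fit_red <- fit_pmm(reduced, data, species = species, A = A,
                     criterion = "ML", theta_bounds = theta_bounds)
  if (fit_full$n != fit_red$n)
    stop("full and reduced fits use different observation sets (",
         fit_full$n, " vs ", fit_red$n, "); align missing data first",
         call. = FALSE)
  df <- fit_full$p - fit_red$p
  chi2 <- max(0, 2 * (fit_full$loglik_ml - fit_red$loglik_ml))
  # identical fixed effects (df = 0): the statistic is degenerate at 0
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(
    chi2 = chi2, df = df, p = p,
    fit_full = fit_full, fit_reduced = fit_red
  ), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped);
#'   at least 4 complete pairs, each with positive variance.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `correlation_result`: list with `r`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 complete pairs (got ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
                 ci_high = ct$conf.int[2], n = n,
                 conf_level = conf_level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, %d%% CI [%.3f, %.3f], n = %d\n",
              x$r, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n))
  invisible(x)
}
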