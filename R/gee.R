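#' Generalized estimating equations with gamma variance and inverse link
#'
#' Marginal-model fit for positive, right-skewed span measurements that are
#' correlated within participants.  The mean model is `1/mu = X beta`
#' (canonical inverse link of the gamma family), the variance function is
#' `V(mu) = phi * mu^2`, and within-cluster dependence is absorbed by a
#' working correlation matrix: `"exchangeable"` (every pair of a cluster's
#' observations shares one correlation `alpha`, estimated from Pearson
#' residual cross-products) or `"independence"`.  Standard errors come from
#' the cluster-robust sandwich estimator, so inference is valid even when
#' the working correlation is misspecified.  Term significance is reported
#' as Wald chi-square tests on the coefficient blocks.
#'
#' @details The robust covariance is built from the empirical covariance of
#' the `G` cluster score contributions.  For a `q`-df term this makes the
#' asymptotic chi-square reference seriously anticonservative when `q` is
#' not small relative to `G` (a Hotelling T-squared situation), so the
#' reported `p` refers `chisq * (G - q) / (q * (G - 1))` to `F(q, G - q)`;
#' this converges to the chi-square p-value (`p_asymp`) as `G` grows.
#'
#' @param formula Model formula, e.g.
#'   `ets_beats ~ condition * factor(note_factor) + tempo_bpm`.
#' @param data A data.frame of span records; rows with `excluded != "none"`
#'   are dropped automatically when an `excluded` column is present.
#' @param id Name of the cluster (participant) column.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on
#'   `max|delta beta|`.
#' @return An object of class `gee_fit` with elements `coefficients`,
#'   `vcov` (robust), `vcov_naive`, `alpha`, `phi` (Pearson dispersion),
#'   `wald` (per-term data.frame: `term`, `df`, `chisq`, `p` -- a
#'   small-sample F-calibrated p-value, see Details -- and the asymptotic
#'   chi-square `p_asymp`), `terms`,
#'   `xlevels`, `contrasts`, `n`, `n_clusters`, `niter`, `converged`.
#' @examples
#' cfg <- sim_config(seed = 42, n_participants = 8, trials_per_tempo = 3)
#' rec <- measure_experiment(simulate_experiment(cfg))
#' fit <- fit_gee(ets_beats ~ condition * factor(note_factor), rec,
#'                id = "participant_id")
#' fit$wald
#' @export
fit_gee <- function(formula, data, id = "participant_id",
                    corstr = c("exchangeable", "independence"),
                    maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  if (!id %in% names(data)) stop("cluster column '", id, "' not found")
  if (!is.null(data$excluded)) data <- data[data$excluded == "none", , drop = FALSE]

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf) & !is.na(data[[id]])
  mf <- mf[keep, , drop = FALSE]
  cl <- factor(data[[id]][keep])
  if (nlevels(cl) < 2L) stop("need at least 2 clusters")
  y <- stats::model.response(mf)
  if (any(y <= 0))
    stop("response must be strictly positive for the gamma model; offending rows: ",
         paste(utils::head(which(y <= 0), 10L), collapse = ", "))
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  p <- ncol(X)
  N <- length(y)
  idx <- split(seq_len(N), cl)
  ni <- lengths(idx)

  # independence GLM start values (canonical link)
  beta <- tryCatch(
    stats::glm.fit(X, y, family = stats::Gamma(link = "inverse"))$coefficients,
    error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) {
    beta <- rep(0, p); beta[1] <- 1 / mean(y)
  }

  alpha <- 0
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (any(eta <= 0))
      stop("linear predictor left the positive range (inverse link); ",
           "rescale covariates or simplify the model")
    mu <- 1 / eta
    r_pear <- (y - mu) / mu
    phi <- sum(r_pear^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- sum(vapply(idx, function(ii) {
        e <- r_pear[ii]
        (sum(e)^2 - sum(e^2)) / 2
      }, numeric(1)))
      den <- phi * (sum(ni * (ni - 1) / 2) - p)
      alpha <- if (den > 0) num / den else 0
      alpha <- max(min(alpha, 0.95), -1 / (max(ni) - 1) + 1e-6)
    }

    B <- matrix(0, p, p)
    u <- numeric(p)
    for (ii in idx) {
      mui <- mu[ii]
      n_i <- length(ii)
      # D = d mu / d beta = -mu^2 X; V = phi diag(mu) R diag(mu)
      # work with standardized residuals: solve R z = (y-mu)/mu
      Di_std <- -(mui) * X[ii, , drop = FALSE]    # A^{-1/2} D
      ei <- (y[ii] - mui) / mui
      if (corstr == "exchangeable" && n_i > 1L) {
        # R^{-1} v = (v - c * sum(v) 1) / (1 - alpha), c = alpha/(1+(n-1)alpha)
        cc <- alpha / (1 + (n_i - 1) * alpha)
        Rinv_D <- (Di_std - cc * matrix(colSums(Di_std), n_i, p, byrow = TRUE)) /
          (1 - alpha)
        Rinv_e <- (ei - cc * sum(ei)) / (1 - alpha)
      } else {
        Rinv_D <- Di_std
        Rinv_e <- ei
      }
      B <- B + crossprod(Di_std, Rinv_D)
      u <- u + drop(crossprod(Rinv_D, ei))
    }
    delta <- solve(B, u)
    beta <- beta + delta
    trace <- c(trace, max(abs(delta)))
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GEE did not converge in ", maxit,
         " iterations; |delta beta| trace: ",
         paste(signif(utils::tail(trace, 8L), 3), collapse = ", "))

  # final quantities at the solution
  eta <- drop(X %*% beta); mu <- 1 / eta
  r_pear <- (y - mu) / mu
  phi <- sum(r_pear^2) / (N - p)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    mui <- mu[ii]; n_i <- length(ii)
    Di_std <- -(mui) * X[ii, , drop = FALSE]
    ei <- (y[ii] - mui) / mui
    if (corstr == "exchangeable" && n_i > 1L) {
      cc <- alpha / (1 + (n_i - 1) * alpha)
      Rinv_D <- (Di_std - cc * matrix(colSums(Di_std), n_i, p, byrow = TRUE)) /
        (1 - alpha)
      Rinv_e <- (ei - cc * sum(ei)) / (1 - alpha)
    } else {
      Rinv_D <- Di_std
      Rinv_e <- ei
    }
    B <- B + crossprod(Di_std, Rinv_D)
    gi <- drop(crossprod(Rinv_D, ei))      # cluster score (phi cancels)
    M <- M + tcrossprod(gi)
  }
  Binv <- solve(B)
  vcov_rob <- Binv %*% M %*% Binv
  vcov_naive <- Binv * phi
  dimnames(vcov_rob) <- dimnames(vcov_naive) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  # term-block Wald statistics on the robust covariance; p-values use a
  # Hotelling-type F reference, F(q, G - q) after scaling by (G-q)/(q(G-1)):
  # with few clusters the empirical covariance of the G cluster scores makes
  # the asymptotic chi-square reference badly liberal for multi-df terms,
  # while the F reference holds its nominal size (the asymptotic p is kept
  # in p_asymp; the two agree as G grows)
  asg <- attr(X, "assign")
  labels <- attr(mt, "term.labels")
  G <- nlevels(cl)
  wald <- do.call(rbind, lapply(seq_along(labels), function(j) {
    sel <- which(asg == j)
    q <- length(sel)
    w <- tryCatch(
      drop(t(beta[sel]) %*% solve(vcov_rob[sel, sel, drop = FALSE], beta[sel])),
      error = function(e) NA_real_)
    p_f <- if (G - q > 0)
      stats::pf(w * (G - q) / (q * (G - 1)), q, G - q, lower.tail = FALSE)
    else NA_real_
    data.frame(term = labels[j], df = q, chisq = w,
               p = p_f,
               p_asymp = stats::pchisq(w, q, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  structure(list(coefficients = beta, vcov = vcov_rob, vcov_naive = vcov_naive,
                 alpha = if (corstr == "exchangeable") alpha else NA_real_,
                 phi = phi, wald = wald, formula = formula, corstr = corstr,
                 terms = mt, xlevels = stats::.getXlevels(mt, mf),
                 contrasts = attr(X, "contrasts"),
                 n = N, n_clusters = nlevels(cl), cluster_sizes = ni,
                 niter = iter, converged = converged,
                 fitted = mu, residuals_pearson = r_pear),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE marginal model (gamma variance, inverse link, ", x$corstr,
      " working correlation)\n", sep = "")
  cat("  ", x$n, " observations in ", x$n_clusters, " clusters; dispersion ",
      signif(x$phi, 4), sep = "")
  if (!is.na(x$alpha)) cat("; working alpha ", signif(x$alpha, 4), sep = "")
  cat("\n\nCoefficients (robust SE):\n")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = signif(x$coefficients, 5),
                   robust_se = signif(se, 4),
                   z = signif(x$coefficients / se, 4)))
  cat("\nWald tests:\n")
  print(transform(x$wald, chisq = signif(chisq, 4), p = signif(p, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' Predictions from a GEE fit
#'
#' @param object A `gee_fit`.
#' @param newdata Data frame of covariate values.
#' @param type `"response"` (mean scale) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gee_fit <- function(object, newdata,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else 1 / eta
}

#' Drop non-significant expertise interactions and refit
#'
#' Screening step of the analysis: interaction terms involving the expertise
#' factor whose Wald p-value is above `alpha` are discarded from the model,
#' which is then refitted once.  Main effects and interactions not involving
#' expertise are always retained.
#'
#' @param formula Full model formula.
#' @param data,id,... Passed to [fit_gee()].
#' @param expertise_var Name of the expertise variable as it appears in term
#'   labels.
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `full` and `reduced` (`gee_fit`s; identical object if
#'   nothing was dropped) and `dropped` (character vector of term labels).
#' @export
model_selection_expertise <- function(formula, data, id = "participant_id",
                                      expertise_var = "expertise",
                                      alpha = 0.05, ...) {
  full <- fit_gee(formula, data, id = id, ...)
  w <- full$wald
  involves <- grepl(":", w$term, fixed = TRUE) &
    vapply(strsplit(w$term, ":", fixed = TRUE),
           function(parts) any(grepl(expertise_var, parts, fixed = TRUE)),
           logical(1))
  drop_terms <- w$term[involves & w$p >= alpha]
  if (length(drop_terms) == 0L)
    return(list(full = full, reduced = full, dropped = character(0)))
  reduced_formula <- stats::update(
    formula, paste("~ . -", paste(drop_terms, collapse = " - ")))
  reduced <- fit_gee(reduced_formula, data, id = id, ...)
  list(full = full, reduced = reduced, dropped = drop_terms)
}

#' Post hoc pairwise contrasts of GEE predictions
#'
#' Pairwise differences of model predictions on the response scale between
#' the levels of `across`, evaluated separately at each level of `within`
#' (e.g. conditions compared within each note position).  Remaining factors
#' in the model are averaged over with equal weights on the linear-predictor
#' scale and numeric covariates are held at their mean, following the
#' estimated-marginal-means convention.  Standard errors use the delta
#' method on the robust covariance; p-values are adjusted over each
#' `within`-level family of pairwise comparisons by the multivariate-normal
#' (Tukey-style single-step) method.
#'
#' @param fit A `gee_fit`.
#' @param data The data the model was fitted to (for factor levels and
#'   covariate means).
#' @param across Factor whose levels are compared pairwise.
#' @param within Optional conditioning factor; `NULL` compares marginally.
#' @return A `data.frame`: `within`, `contrast`, `estimate` (response
#'   scale), `se`, `z`, `p_adj`.
#' @export
posthoc_contrasts <- function(fit, data, across, within = NULL) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!is.null(fit$xlevels) && !across %in% names(fit$xlevels) &&
      !any(grepl(across, names(fit$xlevels), fixed = TRUE)))
    stop("factor '", across, "' is not in the fitted model")
  if (!is.null(data$excluded)) data <- data[data$excluded == "none", , drop = FALSE]

  vars <- all.vars(stats::delete.response(fit$terms))
  grid_levels <- function(v) {
    col <- data[[v]]
    as_factor <- paste0("factor(", v, ")") %in% names(fit$xlevels)
    if (is.numeric(col) && !as_factor && !v %in% c(across, within))
      return(mean(col, na.rm = TRUE))
    sort(unique(col))
  }
  if (!is.null(within) && !within %in% vars)
    stop("factor '", within, "' is not in the fitted model")
  if (!across %in% vars) stop("factor '", across, "' is not in the fitted model")

  full_grid <- expand.grid(lapply(stats::setNames(vars, vars), grid_levels),
                           stringsAsFactors = FALSE)
  tt <- stats::delete.response(fit$terms)
  Xg <- stats::model.matrix(tt, stats::model.frame(tt, full_grid,
                                                  xlev = fit$xlevels),
                            contrasts.arg = fit$contrasts)
  cell <- interaction(full_grid[[across]],
                      if (is.null(within)) "all" else full_grid[[within]],
                      drop = TRUE, sep = "\r")
  # equal-weight average of linear-predictor rows per (across, within) cell
  Xbar <- rowsum(Xg, cell) / as.vector(table(cell))
  lab <- do.call(rbind, strsplit(rownames(Xbar), "\r", fixed = TRUE))
  a_lev <- lab[, 1]; w_lev <- lab[, 2]

  eta <- drop(Xbar %*% fit$coefficients)
  mu <- 1 / eta
  G <- -(mu^2) * Xbar                     # d mu / d beta, row-wise

  out <- NULL
  for (w in unique(w_lev)) {
    rows <- which(w_lev == w)
    pairs <- utils::combn(rows, 2)
    est <- se <- numeric(ncol(pairs))
    Cg <- matrix(0, ncol(pairs), length(fit$coefficients))
    nm <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      est[j] <- mu[i1] - mu[i2]
      Cg[j, ] <- G[i1, ] - G[i2, ]
      nm[j] <- paste(a_lev[i1], "-", a_lev[i2])
    }
    V <- Cg %*% fit$vcov %*% t(Cg)
    se <- sqrt(diag(V))
    z <- est / se
    p_adj <- .mvn_adjust(z, stats::cov2cor(V))
    out <- rbind(out, data.frame(
      within = if (is.null(within)) NA_character_ else w,
      contrast = nm, estimate = est, se = se, z = z, p_adj = p_adj,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# single-step multivariate-normal adjustment: P(max |Z| >= |z_j|) under the
# joint null with the estimated contrast correlation
.mvn_adjust <- function(z, corr) {
  k <- length(z)
  if (k == 1L) return(2 * stats::pnorm(-abs(z)))
  vapply(seq_len(k), function(j) {
    a <- abs(z[j])
    pr <- .with_seed(271828L,
      mvtnorm::pmvnorm(lower = rep(-a, k), upper = rep(a, k),
                       corr = corr,
                       algorithm = mvtnorm::GenzBretz(abseps = 1e-6)))
    min(1, max(0, 1 - as.numeric(pr)))
  }, numeric(1))
}

#' Spearman association between ETS and incoming saccade length
#'
#' Rank correlation (average ranks for ties) on paired span measurements,
#' with the usual large-sample test.
#'
#' @param ets,sacc Paired numeric vectors, equal length >= 3.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_association <- function(ets, sacc) {
  if (length(ets) != length(sacc)) stop("ets and sacc must have equal length")
  ok <- stats::complete.cases(ets, sacc)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(ets[ok], sacc[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
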