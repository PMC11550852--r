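#' Fit the convergence regression
#'
#' Estimates the slope of the growth ratio on base fertility — the
#' convergence coefficient. A negative slope whose 95% interval excludes
#' zero means countries lagging in the indicator are catching up
#' (convergence); a positive one, falling behind (divergence).
#'
#' With `fixed_effects = TRUE` country intercepts are absorbed by the within
#' transformation (each variable demeaned by its country mean), so the model
#' assumes country-specific levels but a common convergence slope. Standard
#' errors come from the cluster-robust sandwich with countries as clusters
#' and the CR1 small-sample factor `G/(G-1) * (N-1)/(N-K)`; confidence
#' intervals and p-values use the t distribution on `G - 1` degrees of
#' freedom, `G` the number of clusters. Pass the sample through
#' [trim_outliers()] and [standardize_sample()] first to reproduce the
#' standardized-coefficient convention; an unstandardized sample yields the
#' raw slope in indicator units.
#'
#' @param sample a `conv_sample`.
#' @param fixed_effects absorb country intercepts? Default `TRUE`.
#' @param covariates names of covariate columns to include as extra slopes.
#' @return a `conv_fit` list: `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `alpha` (grand intercept), `n_obs`, `n_countries`, `n_trimmed`,
#'   `n_zero_delta`, `df`, `converged_flag`, plus the full coefficient
#'   vector and variance matrix.
#' @export
fit_convergence <- function(sample, fixed_effects = TRUE, covariates = NULL) {
  covariates <- covariates %||% attr(sample, "covariates") %||% character(0)
  miss <- setdiff(covariates, names(sample))
  if (length(miss) > 0) {
    fc_abort(paste0("covariate column(s) not in sample: ",
                    paste(miss, collapse = ", ")),
             class = "fc_specification_error")
  }
  y <- sample$ratio
  X <- cbind(base_fertility = sample$base_fertility)
  for (cv in covariates) X <- cbind(X, sample[[cv]])
  colnames(X) <- c("base_fertility", covariates)
  cluster <- sample$country_id
  G <- length(unique(cluster))
  N <- length(y)
  p <- ncol(X)

  if (G < 2) {
    fc_abort("cluster-robust inference needs at least 2 countries (clusters)",
             class = "fc_inference_error")
  }

  if (fixed_effects) {
    K <- p + G
    if (N < K + 1) {
      fc_abort("too few observations to identify fixed effects and slopes",
               class = "fc_identification_error")
    }
    Xd <- demean_by(X, cluster)
    yd <- demean_by(matrix(y, ncol = 1), cluster)[, 1]
    XtX <- crossprod(Xd)
    if (!is_full_rank(XtX)) {
      fc_abort(paste0("design is singular after the within transformation ",
                      "(no within-country variation in a regressor)"),
               class = "fc_identification_error")
    }
    beta_hat <- solve(XtX, crossprod(Xd, yd))[, 1]
    resid <- yd - Xd %*% beta_hat
    alpha <- mean(y) - sum(colMeans(X) * beta_hat)
    V <- cluster_vcov(Xd, resid, cluster, n_params = K)
    slope_idx <- 1L
  } else {
    K <- p + 1L
    Xi <- cbind(`(Intercept)` = 1, X)
    XtX <- crossprod(Xi)
    if (!is_full_rank(XtX)) {
      fc_abort("design matrix is singular", class = "fc_identification_error")
    }
    coef_hat <- solve(XtX, crossprod(Xi, y))[, 1]
    resid <- y - Xi %*% coef_hat
    alpha <- coef_hat[1]
    beta_hat <- coef_hat[-1]
    V <- cluster_vcov(Xi, resid, cluster, n_params = K)
    V <- V[-1, -1, drop = FALSE]
    slope_idx <- 1L
  }

  se_all <- sqrt(diag(V))
  beta <- unname(beta_hat[slope_idx])
  se <- unname(se_all[slope_idx])
  df <- G - 1L
  tcrit <- stats::qt(0.975, df)
  ci_low <- beta - tcrit * se
  ci_high <- beta + tcrit * se
  p_value <- 2 * stats::pt(-abs(beta / se), df)
  flag <- if (ci_high < 0) "convergence" else if (ci_low > 0) "divergence" else "null"

  structure(list(
    beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, alpha = unname(alpha),
    n_obs = N, n_countries = G,
    n_trimmed = attr(sample, "n_trimmed") %||% 0L,
    n_zero_delta = attr(sample, "n_zero_delta") %||% 0L,
    df = df, converged_flag = flag,
    coefficients = stats::setNames(as.numeric(beta_hat), colnames(X)),
    vcov = V, fixed_effects = fixed_effects, covariates = covariates
  ), class = "conv_fit")
}

demean_by <- function(M, g) {
  g <- as.character(g)
  gm <- rowsum(M, g)
  cnt <- as.vector(rowsum(rep(1, nrow(M)), g))
  gm <- gm / cnt
  M - gm[match(g, rownames(gm)), , drop = FALSE]
}

is_full_rank <- function(XtX, tol = 1e-10) {
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev), 1)
}

#' Cluster-robust sandwich variance (CR1)
#'
#' Computes `(X'X)^-1 [ sum_g X_g' e_g e_g' X_g ] (X'X)^-1` scaled by the
#' CR1 small-sample factor `G/(G-1) * (N-1)/(N-K)`. When fixed effects have
#' been absorbed by demeaning, pass the demeaned design and set `n_params`
#' to the slope count plus the number of absorbed intercepts so the
#' degrees-of-freedom correction matches the equivalent dummy-variable
#' regression.
#'
#' @param X design matrix (rows = observations).
#' @param resid residual vector.
#' @param cluster cluster id per observation.
#' @param n_params number of estimated parameters K for the CR1 factor
#'   (default `ncol(X)`).
#' @return the variance matrix of the coefficients of `X`.
#' @export
cluster_vcov <- function(X, resid, cluster, n_params = ncol(X)) {
  X <- as.matrix(X)
  resid <- as.numeric(resid)
  G <- length(unique(cluster))
  N <- nrow(X)
  K <- n_params
  if (G < 2) {
    fc_abort("need at least 2 clusters", class = "fc_inference_error")
  }
  XtX <- crossprod(X)
  if (!is_full_rank(XtX)) {
    fc_abort("X'X is singular", class = "fc_identification_error")
  }
  bread <- solve(XtX)
  # score per cluster: X_g' e_g, accumulated with rowsum on X * e
  scores <- rowsum(X * resid, cluster)
  meat <- crossprod(scores)
  adj <- (G / (G - 1)) * ((N - 1) / (N - K))
  adj * bread %*% meat %*% bread
}

#' Dummy-variable (LSDV) oracle for the fixed-effects fit
#'
#' Computes the same estimand as [fit_convergence()] with
#' `fixed_effects = TRUE` by brute force: an explicit regression on country
#' indicator variables via [stats::lm()], with the cluster sandwich
#' assembled by a literal per-cluster loop. It exists to cross-validate the
#' within-transformation route (the two are algebraically equivalent) and is
#' not meant for large samples.
#'
#' @inheritParams fit_convergence
#' @return a `conv_fit` (slopes only; dummy coefficients are dropped).
#' @export
lsdv_oracle <- function(sample, covariates = NULL) {
  covariates <- covariates %||% attr(sample, "covariates") %||% character(0)
  if (length(unique(sample$country_id)) < 2) {
    fc_abort("cluster-robust inference needs at least 2 clusters",
             class = "fc_inference_error")
  }
  df <- data.frame(
    ratio = sample$ratio,
    base_fertility = sample$base_fertility,
    country = factor(sample$country_id),
    check.names = FALSE
  )
  for (cv in covariates) df[[cv]] <- sample[[cv]]
  rhs <- paste(c("0", "country", "base_fertility", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("ratio ~", rhs)), data = df)
  if (anyNA(stats::coef(fit))) {
    fc_abort("LSDV design is rank deficient", class = "fc_identification_error")
  }
  Xfull <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  G <- nlevels(df$country)
  N <- nrow(df)
  K <- ncol(Xfull)
  if (G < 2) {
    fc_abort("cluster-robust inference needs at least 2 clusters",
             class = "fc_inference_error")
  }
  bread <- solve(crossprod(Xfull))
  meat <- matrix(0, K, K)
  for (g in levels(df$country)) {
    idx <- which(df$country == g)
    sg <- crossprod(Xfull[idx, , drop = FALSE], e[idx])
    meat <- meat + tcrossprod(sg)
  }
  V <- (G / (G - 1)) * ((N - 1) / (N - K)) * bread %*% meat %*% bread
  slopes <- c("base_fertility", covariates)
  beta <- stats::coef(fit)[["base_fertility"]]
  se <- sqrt(V["base_fertility", "base_fertility"])
  dfree <- G - 1L
  tcrit <- stats::qt(0.975, dfree)
  flag <- if (beta + tcrit * se < 0) "convergence"
          else if (beta - tcrit * se > 0) "divergence" else "null"
  structure(list(
    beta = beta, se = se,
    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
    p_value = 2 * stats::pt(-abs(beta / se), dfree),
    alpha = mean(stats::coef(fit)[seq_len(G)]),
    n_obs = N, n_countries = G,
    n_trimmed = attr(sample, "n_trimmed") %||% 0L,
    n_zero_delta = attr(sample, "n_zero_delta") %||% 0L,
    df = dfree, converged_flag = flag,
    coefficients = stats::coef(fit)[slopes],
    vcov = V[slopes, slopes, drop = FALSE],
    fixed_effects = TRUE, covariates = covariates
  ), class = "conv_fit")
}

#' @export
print.conv_fit <- function(x, digits = 4, ...) {
  cat("<conv_fit> ", if (x$fixed_effects) "country fixed effects" else "pooled",
      ", cluster-robust (CR1) SE, t(", x$df, ")\n", sep = "")
  cat(sprintf("  beta = %.*g (se %.*g), 95%% CI [%.*g, %.*g], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$p_value))
  cat(sprintf("  n = %d observations, %d countries, %d trimmed, %d zero-delta; %s\n",
              x$n_obs, x$n_countries, x$n_trimmed, x$n_zero_delta,
              x$converged_flag))
  invisible(x)
}

#' Flatten a fit to a one-row data frame
#' @param x a `conv_fit`.
#' @param ... unused.
#' @return one-row tibble of the scalar fields.
#' @export
as.data.frame.conv_fit <- function(x, ...) {
  data.frame(
    beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, alpha = x$alpha, n_obs = x$n_obs,
    n_countries = x$n_countries, n_trimmed = x$n_trimmed,
    n_zero_delta = x$n_zero_delta, df = x$df,
    converged_flag = x$converged_flag, stringsAsFactors = FALSE
  )
}

#' Serialize a fit to JSON
#' @param x a `conv_fit`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(x, path = NULL) {
  obj <- x[c("beta", "se", "ci_low", "ci_high", "p_value", "alpha", "n_obs",
             "n_countries", "n_trimmed", "n_zero_delta", "df",
             "converged_flag", "fixed_effects", "covariates")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
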