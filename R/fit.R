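#' Least-squares fit with rank checking
#'
#' QR-based ordinary least squares.  A rank-deficient design raises an
#' error naming the collinear columns (e.g. the constant relatedness column
#' produced by single-zygosity data), rather than silently dropping them.
#'
#' @param X Numeric design matrix with column names.
#' @param y Response vector.
#' @return List with `coefficients`, `residuals`, `fitted`, `r_squared`.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X)) stop("fewer rows than columns")
  if (anyNA(X) || anyNA(y)) stop("design or response contains missing values")
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    dropped <- colnames(X)[dec$pivot[(dec$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(dec, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sst <- sum((y - mean(y))^2)
  # a constant response has no variance to explain; report 0, not 0/0
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 0
  list(coefficients = beta, residuals = resid, fitted = fitted,
       r_squared = r2)
}

#' Cluster-robust (Huber-White) covariance of OLS coefficients
#'
#' Sandwich estimator \eqn{(X'X)^{-1} \left[\sum_g X_g' u_g u_g' X_g\right]
#' (X'X)^{-1}} with the cluster sum taken over pairs, correcting the
#' deflated standard errors that double entry would otherwise produce.
#' `type = "CR1"` applies the small-sample factor
#' \eqn{G/(G-1) \cdot (N-1)/(N-k)} (the convention of survey-regression
#' software); `type = "CR0"` applies none.  With every row its own cluster
#' and `type = "CR0"` this reduces to the heteroskedasticity-robust HC0
#' covariance.
#'
#' @param X Design matrix used in the fit.
#' @param residuals OLS residuals.
#' @param cluster Cluster identifier per row (pair id).
#' @param type `"CR1"` (default) or `"CR0"`.
#' @return Covariance matrix of the coefficients.
#' @export
cluster_robust_cov <- function(X, residuals, cluster, type = c("CR1", "CR0")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  residuals <- as.numeric(residuals)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(residuals) == n, length(cluster) == n)
  if (is.factor(cluster) && any(table(cluster) == 0L))
    stop("cluster factor has empty level(s)")
  g <- length(unique(cluster))
  if (g < 2L) stop("need at least two clusters")
  scores <- X * residuals
  S <- rowsum(scores, group = cluster, reorder = FALSE)
  meat <- crossprod(S)
  bread <- solve(crossprod(X))
  V <- bread %*% meat %*% bread
  if (type == "CR1")
    V <- V * (g / (g - 1)) * ((n - 1) / (n - k))
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Fit a DeFries-Fulker twin regression
#'
#' Runs the full DF pipeline on a one-row-per-twin table: pair-level
#' listwise deletion on the model's variables, double entry, co-twin
#' mean-centering (EQ2/EQ3), design construction, least squares, and
#' Huber-White cluster-robust standard errors over pairs.  Inference uses
#' the t distribution with G - 1 degrees of freedom, G the number of pairs.
#'
#' Under EQ2/EQ3 the coefficient on the centered co-twin score estimates
#' the shared-environmental variance share (c2) and the coefficient on the
#' relatedness interaction estimates heritability (h2); ENVDIF coefficients
#' are ordinary regression effects in outcome units per covariate unit.
#' Estimates are reported unconstrained — values outside \[0, 1\] signal
#' misfit and trigger a warning, not truncation.
#'
#' @param data Data frame with columns `pair_id`, `twin_index`, `zygosity`,
#'   `outcome`, plus any ENVDIF covariates.  Pairs with zygosity other than
#'   `"MZ"`/`"DZ"` are excluded with a message.
#' @param spec A [df_model_spec()]; defaults to the baseline EQ2 model.
#' @param cr_type Cluster-robust small-sample correction, `"CR1"` or
#'   `"CR0"`.
#' @return An object of class `"df_fit"`: coefficients, cluster-robust
#'   `se`, `t`, `p` (two-tailed), `vcov`, `r_squared`, `n_rows` (twins,
#'   = 2 x pairs), `n_pairs`, `df` (= pairs - 1), `Km`, the model `spec`,
#'   and `variance_decomposition` (c2, h2, residual).
#' @examples
#' d <- simulate_twins(sim_config(300, 300, h2 = 0.3, c2 = 0.4, seed = 7,
#'                                percentile_output = FALSE))
#' fit_df(d)
#' @export
fit_df <- function(data, spec = df_model_spec("EQ2"),
                   cr_type = c("CR1", "CR0")) {
  cr_type <- match.arg(cr_type)
  stopifnot(inherits(spec, "df_model_spec"))
  need <- c("pair_id", "twin_index", "zygosity", "outcome", spec$envdif)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))

  unknown <- !(data$zygosity %in% c("MZ", "DZ"))
  if (any(unknown)) {
    excl <- unique(data$pair_id[unknown])
    message("excluding ", length(excl),
            " pair(s) of undetermined zygosity")
    data <- data[!(data$pair_id %in% excl), , drop = FALSE]
  }

  # pair-level listwise deletion on this model's variable set
  vars <- c("outcome", spec$envdif)
  incomplete <- !stats::complete.cases(data[vars])
  if (any(incomplete)) {
    excl <- unique(data$pair_id[incomplete])
    message("listwise deletion: dropping ", length(excl),
            " pair(s) with missing model variables")
    data <- data[!(data$pair_id %in% excl), , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("all pairs deleted; no data to fit")

  zyg_pairs <- table(unique(data[c("pair_id", "zygosity")])$zygosity)
  if (length(zyg_pairs) < 2L || any(zyg_pairs[c("MZ", "DZ")] < 2L))
    stop("identifiability requires at least two pairs of each zygosity ",
         "(single-zygosity data leave relatedness without contrast)")

  rows <- double_enter(data, envdif = spec$envdif)
  km <- NA_real_
  if (spec$variant != "EQ1") {
    rows <- center_cotwin(rows)
    km <- attr(rows, "Km")
  }
  design <- build_design(rows, spec)
  fit <- ols_fit(design$X, design$y)
  V <- cluster_robust_cov(design$X, fit$residuals, design$cluster,
                          type = cr_type)
  se <- sqrt(diag(V))
  tval <- fit$coefficients / se
  g <- length(unique(design$cluster))
  df <- g - 1L
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)

  res <- structure(list(
    coefficients = fit$coefficients,
    se = se, t = tval, p = pval,
    vcov = V,
    r_squared = fit$r_squared,
    n_rows = nrow(design$X),
    n_pairs = g,
    df = df,
    Km = km,
    spec = spec,
    cr_type = cr_type
  ), class = "df_fit")
  res$variance_decomposition <- decompose_variance(res)
  res
}

#' Variance decomposition from a DF fit
#'
#' Reads the shared-environmental (c2) and genetic (h2) variance shares off
#' the fitted coefficients — for EQ2/EQ3 the centered co-twin slope and the
#' relatedness interaction; for EQ1 the `K2` slope and the `R_x_K2`
#' interaction — and reports the residual share `1 - c2 - h2`, which
#' absorbs the nonshared environment together with error.  Values are
#' passed through unconstrained; shares outside \[0, 1\] raise a warning.
#'
#' Can also be applied to a bare numeric vector `c(b1, b2)` (shared
#' environment first), e.g. to published estimates.
#'
#' @param object A `"df_fit"` or a numeric vector of length 2.
#' @param ... Unused.
#' @return List with components `c2`, `h2`, `residual`.
#' @examples
#' decompose_variance(c(0.44, 0.27))  # residual 0.29
#' @export
decompose_variance <- function(object, ...) UseMethod("decompose_variance")

#' @export
decompose_variance.df_fit <- function(object, ...) {
  b <- object$coefficients
  if (object$spec$variant == "EQ1") {
    c2 <- unname(b["K2"]); h2 <- unname(b["R_x_K2"])
  } else {
    c2 <- unname(b["K2_centered"]); h2 <- unname(b["R_x_K2_centered"])
  }
  decompose_variance(c(c2, h2))
}

#' @export
decompose_variance.numeric <- function(object, ...) {
  stopifnot(length(object) == 2L)
  c2 <- unname(object[1L]); h2 <- unname(object[2L])
  residual <- 1 - c2 - h2
  out <- list(c2 = c2, h2 = h2, residual = residual)
  if (any(unlist(out) < 0 | unlist(out) > 1))
    warning("variance shares outside [0, 1]; reported unconstrained")
  out
}

#' @export
coef.df_fit <- function(object, ...) object$coefficients

#' @export
vcov.df_fit <- function(object, ...) object$vcov

#' @export
nobs.df_fit <- function(object, ...) object$n_rows

signif_stars <- function(p) ifelse(p <= 0.01, "**",
                            ifelse(p <= 0.05, "*", ""))

#' @export
print.df_fit <- function(x, digits = 3, ...) {
  cat(sprintf("DeFries-Fulker twin regression (%s), %s cluster-robust SEs\n",
              x$spec$variant, x$cr_type))
  cat(sprintf("N = %d twins in %d pairs; R-squared = %.*f\n",
              x$n_rows, x$n_pairs, digits, x$r_squared))
  tab <- data.frame(
    Estimate = x$coefficients,
    SE = x$se, t = x$t, p = x$p,
    ` ` = signif_stars(x$p),
    check.names = FALSE
  )
  print(format(tab, digits = digits))
  vd <- x$variance_decomposition
  cat(sprintf(
    "Variance shares: c2 = %.*f, h2 = %.*f, residual (e2 + error) = %.*f\n",
    digits, vd$c2, digits, vd$h2, digits, vd$residual))
  cat("Signif.: ** p <= 0.01, * p <= 0.05 (two-tailed, t on G-1 df)\n")
  invisible(x)
}

#' Double-entered twin correlations and Falconer estimates
#'
#' `twin_correlations()` computes the within-pair outcome correlation per
#' zygosity from the double-entered sample (equivalent to the intraclass
#' correlation under double entry).  `falconer_estimates()` converts them
#' into the moment-based heritability `h2 = 2 (rMZ - rDZ)` and shared
#' environment `c2 = 2 rDZ - rMZ` — an estimator independent of the DF
#' regression, useful as a cross-check.
#'
#' @param data One-row-per-twin table with `pair_id`, `twin_index`,
#'   `zygosity`, `outcome`.
#' @return `twin_correlations()`: named vector `c(rMZ, rDZ)`;
#'   `falconer_estimates()`: named vector `c(h2, c2)`.
#' @export
twin_correlations <- function(data) {
  rows <- double_enter(data)
  r_for <- function(z) {
    sub <- rows[rows$zygosity == z, ]
    if (nrow(sub) < 4L) return(NA_real_)
    stats::cor(sub$K1, sub$K2)
  }
  c(rMZ = r_for("MZ"), rDZ = r_for("DZ"))
}

#' @rdname twin_correlations
#' @export
falconer_estimates <- function(data) {
  r <- twin_correlations(data)
  c(h2 = unname(2 * (r["rMZ"] - r["rDZ"])),
    c2 = unname(2 * r["rDZ"] - r["rMZ"]))
}
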