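# Quantile transform of a copula uniform into a covariate's marginal family.
q_covariate <- function(u, spec) {
  switch(spec$family,
    count = stats::qbinom(u, spec$size, spec$prob),
    binary = stats::qbinom(u, 1L, spec$prob),
    proportion = round(stats::qbeta(u, spec$shape1, spec$shape2) *
                         spec$levels) / spec$levels,
    ordinal = findInterval(u, cumsum(spec$probs)[1:3]),
    stop("unknown distribution family: ", spec$family))
}

#' Simulate MZ/DZ twin pairs under an ACE model
#'
#' Generates twin pairs whose latent outcome decomposes into additive
#' genetic (A), shared environmental (C) and nonshared environmental (E)
#' components with variance shares `h2`, `c2`, `e2`, plus optional causal
#' contributions from measured covariates.  The genetic component has
#' within-pair correlation 1 for MZ pairs and 0.5 for DZ pairs (constructed
#' as \eqn{\sqrt{0.5}A_{shared} + \sqrt{0.5}A_{unique}} per DZ member); C is
#' shared within a pair and E is independent per twin.  The implied
#' within-pair outcome correlations are `h2 + c2` (MZ) and `0.5 * h2 + c2`
#' (DZ).
#'
#' @param config A [sim_config()] object.
#' @return A data frame with one row per twin and columns `pair_id`,
#'   `twin_index` (1 or 2), `zygosity` (`"MZ"`/`"DZ"`), `outcome`, then one
#'   column per covariate.  The generating config is attached as attribute
#'   `"config"` and a ground-truth table (latent score and A/C/E draws per
#'   twin) as attribute `"truth"`, for use in recovery tests.
#' @examples
#' d <- simulate_twins(sim_config(100, 100, h2 = 0.3, c2 = 0.4, seed = 1))
#' head(d)
#' @export
simulate_twins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_mz_pairs + config$n_dz_pairs
  if (n == 0L) stop("no pairs requested")
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))

  A_sh <- stats::rnorm(n)
  A_u1 <- stats::rnorm(n)
  A_u2 <- stats::rnorm(n)
  C <- stats::rnorm(n)
  E1 <- stats::rnorm(n)
  E2 <- stats::rnorm(n)
  mz <- zyg == "MZ"
  A1 <- ifelse(mz, A_sh, sqrt(0.5) * A_sh + sqrt(0.5) * A_u1)
  A2 <- ifelse(mz, A_sh, sqrt(0.5) * A_sh + sqrt(0.5) * A_u2)

  with_h <- sqrt(config$h2); with_c <- sqrt(config$c2); with_e <- sqrt(config$e2)
  y1 <- with_h * A1 + with_c * C + with_e * E1
  y2 <- with_h * A2 + with_c * C + with_e * E2

  # covariates via a Gaussian copula so co-twins can share part of a draw
  rho <- config$within_pair_cor
  covs1 <- list(); covs2 <- list()
  for (spec in config$covariates) {
    z_pair <- stats::rnorm(n)
    z1 <- sqrt(rho) * z_pair + sqrt(1 - rho) * stats::rnorm(n)
    z2 <- sqrt(rho) * z_pair + sqrt(1 - rho) * stats::rnorm(n)
    x1 <- q_covariate(stats::pnorm(z1), spec)
    x2 <- q_covariate(stats::pnorm(z2), spec)
    covs1[[spec$name]] <- x1
    covs2[[spec$name]] <- x2
    y1 <- y1 + spec$beta * x1
    y2 <- y2 + spec$beta * x2
  }
  if (config$derive_insufficient_exercise) {
    need <- c("low_sport", "low_cycle", "low_exercise")
    if (!all(need %in% names(covs1)))
      stop("deriving insufficient exercise requires covariates ",
           paste(need, collapse = ", "))
    covs1$insuff_ex <- insufficient_exercise(3 - covs1$low_sport,
                                             3 - covs1$low_cycle,
                                             3 - covs1$low_exercise)
    covs2$insuff_ex <- insufficient_exercise(3 - covs2$low_sport,
                                             3 - covs2$low_cycle,
                                             3 - covs2$low_exercise)
  }

  keep <- rep(TRUE, n)
  if (config$pair_dropout > 0)
    keep <- stats::runif(n) >= config$pair_dropout

  interleave <- function(a, b) as.vector(rbind(a, b))
  out <- data.frame(
    pair_id = rep(seq_len(n), each = 2L),
    twin_index = rep(1:2, n),
    zygosity = rep(zyg, each = 2L),
    outcome = interleave(y1, y2),
    stringsAsFactors = FALSE
  )
  for (nm in names(covs1)) out[[nm]] <- interleave(covs1[[nm]], covs2[[nm]])
  truth <- data.frame(
    pair_id = out$pair_id, twin_index = out$twin_index,
    latent = out$outcome,
    A = interleave(A1, A2), C = interleave(C, C), E = interleave(E1, E2)
  )
  out <- out[rep(keep, each = 2L), , drop = FALSE]
  truth <- truth[rep(keep, each = 2L), , drop = FALSE]
  rownames(out) <- rownames(truth) <- NULL
  if (config$percentile_output) {
    truth$latent <- out$outcome
    out$outcome <- percentile_transform(out$outcome)
  }
  attr(out, "config") <- config
  attr(out, "truth") <- truth
  out
}

#' Percentile-rank transform of scores
#'
#' Replaces each score by `100 * (number of strictly lower scores) / N`, the
#' convention under which a vocabulary-test percentile gives the percentage
#' of the reference sample scoring lower.  Ties share a value; the output
#' lies in \[0, 100).  `NA` scores propagate and are excluded from the
#' reference counts.
#'
#' @param scores Numeric vector (at least one value).
#' @return Numeric vector of percentile scores in \[0, 100).
#' @examples
#' percentile_transform(c(10, 20, 30, 40))  # 0 25 50 75
#' @export
percentile_transform <- function(scores) {
  if (length(scores) == 0L) stop("at least one score is required")
  out <- rep(NA_real_, length(scores))
  ok <- !is.na(scores)
  x <- scores[ok]
  out[ok] <- 100 * (rank(x, ties.method = "min") - 1) / length(x)
  out
}

#' Write or read a twin-pair table as CSV
#'
#' `write_twins()` writes the one-row-per-twin table to CSV and, optionally,
#' a JSON manifest alongside it carrying the generating configuration and a
#' ground-truth summary (latent-score variance, empirical within-pair
#' correlations).  `read_twins()` reads such a CSV back.
#'
#' @param data Twin table as returned by [simulate_twins()].
#' @param file CSV path.
#' @param manifest Optional path for a JSON manifest; `NULL` to skip.
#' @return `write_twins()` returns `file` invisibly; `read_twins()` returns
#'   a data frame.
#' @export
write_twins <- function(data, file, manifest = NULL) {
  utils::write.csv(data, file, row.names = FALSE)
  if (!is.null(manifest)) {
    config <- attr(data, "config")
    truth <- attr(data, "truth")
    m <- list(
      n_pairs = length(unique(data$pair_id)),
      n_twins = nrow(data),
      config = if (!is.null(config)) lapply(unclass(config), function(x) {
        if (is.list(x)) lapply(x, unclass) else x
      }),
      truth_summary = if (!is.null(truth)) {
        merged <- merge(data[c("pair_id", "twin_index", "zygosity")], truth)
        r <- tryCatch(twin_correlations(
          transform(merged, outcome = latent)),
          error = function(e) c(rMZ = NA_real_, rDZ = NA_real_))
        list(latent_var = stats::var(truth$latent),
             r_mz = unname(r["rMZ"]), r_dz = unname(r["rDZ"]))
      }
    )
    jsonlite::write_json(m, manifest, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(file)
}

#' @rdname write_twins
#' @export
read_twins <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
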