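#' Genetic relatedness coefficient from zygosity
#'
#' MZ pairs share all segregating genes (R = 1.0); same-sex DZ pairs share
#' half on average (R = 0.5).  Any other kinship label is outside the
#' supported design and raises an error; callers that tolerate undetermined
#' zygosity should exclude those pairs first (see [fit_df()], which logs
#' such exclusions).
#'
#' @param zygosity Character vector of `"MZ"` / `"DZ"`.
#' @return Numeric vector of relatedness coefficients.
#' @export
compute_r <- function(zygosity) {
  bad <- !(zygosity %in% c("MZ", "DZ"))
  if (any(bad))
    stop("unsupported zygosity value(s): ",
         paste(unique(zygosity[bad]), collapse = ", "),
         " (pairs of undetermined zygosity must be excluded)")
  ifelse(zygosity == "MZ", 1.0, 0.5)
}

#' Double-enter twin pairs for DF regression
#'
#' Expands a one-row-per-twin table into the double-entered analysis rows:
#' each twin appears once as the focal twin (outcome `K1`) and once as the
#' co-twin (predictor `K2`), so a pair contributes exactly two rows with
#' `K1`/`K2` swapped.  For each requested ENVDIF covariate the within-pair
#' difference (focal minus co-twin) is computed; these difference scores are
#' antisymmetric across a pair's two rows.  Pairs with a missing outcome in
#' either member are dropped with a message (listwise deletion at the pair
#' level).
#'
#' @param data Data frame with columns `pair_id`, `twin_index`, `zygosity`,
#'   `outcome` and any ENVDIF covariates.
#' @param envdif Character vector of covariate names to difference.
#' @return Data frame with columns `pair_id`, `zygosity`, `R`, `K1`, `K2`
#'   and one `envdif_<name>` column per requested covariate.
#' @export
double_enter <- function(data, envdif = character()) {
  need <- c("pair_id", "twin_index", "zygosity", "outcome", envdif)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("twin table lacks columns: ", paste(missing_cols, collapse = ", "))
  counts <- table(data$pair_id)
  bad_pairs <- names(counts)[counts != 2L]
  if (length(bad_pairs)) {
    message("dropping ", length(bad_pairs),
            " pair(s) without exactly two members")
    data <- data[!(data$pair_id %in% bad_pairs), , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no complete pairs")
  data <- data[order(data$pair_id, data$twin_index), , drop = FALSE]
  i1 <- seq(1L, nrow(data), by = 2L)
  i2 <- i1 + 1L
  if (any(data$zygosity[i1] != data$zygosity[i2]))
    stop("zygosity differs within a pair")

  na_out <- is.na(data$outcome[i1]) | is.na(data$outcome[i2])
  if (any(na_out)) {
    message("dropping ", sum(na_out), " pair(s) with a missing outcome")
    keep <- !na_out
    i1 <- i1[keep]; i2 <- i2[keep]
  }
  if (!length(i1)) stop("no complete pairs")

  interleave <- function(a, b) as.vector(rbind(a, b))
  rows <- data.frame(
    pair_id = interleave(data$pair_id[i1], data$pair_id[i2]),
    zygosity = interleave(data$zygosity[i1], data$zygosity[i2]),
    K1 = interleave(data$outcome[i1], data$outcome[i2]),
    K2 = interleave(data$outcome[i2], data$outcome[i1]),
    stringsAsFactors = FALSE
  )
  rows$R <- compute_r(rows$zygosity)
  for (nm in envdif) {
    d <- data[[nm]][i1] - data[[nm]][i2]
    rows[[paste0("envdif_", nm)]] <- interleave(d, -d)
  }
  rownames(rows) <- NULL
  rows
}

#' Center the co-twin score on its analysis-sample mean
#'
#' Adds `K2_centered = K2 - Km`, where `Km` is the mean co-twin score over
#' the rows supplied — i.e. over the post-deletion analysis sample of the
#' model at hand, so each fitted model is self-contained.  After double
#' entry every outcome appears once in `K1` and once in `K2`, so `Km` equals
#' the sample mean outcome.
#'
#' @param rows Double-entered rows from [double_enter()].
#' @return `rows` with a `K2_centered` column; `Km` is attached as an
#'   attribute.
#' @export
center_cotwin <- function(rows) {
  if (nrow(rows) == 0L) stop("no rows to center")
  km <- mean(rows$K2)
  rows$K2_centered <- rows$K2 - km
  attr(rows, "Km") <- km
  rows
}

#' Specify a DF model variant
#'
#' * `EQ1` — classic DF equation: intercept, co-twin score `K2`,
#'   relatedness `R`, and the interaction `R x K2`.
#' * `EQ2` — revised equation: intercept, mean-centered co-twin score, and
#'   relatedness-by-centered-score interaction; its two slope coefficients
#'   estimate the shared-environmental (c2) and genetic (h2) variance
#'   shares directly.
#' * `EQ3` — `EQ2` plus one ENVDIF difference-score column per named
#'   covariate, estimating specific nonshared-environment effects.
#'
#' @param variant `"EQ1"`, `"EQ2"` or `"EQ3"`.
#' @param envdif Covariate names to enter as difference scores (required,
#'   non-empty, for `EQ3`; must be empty otherwise).
#' @return An object of class `"df_model_spec"`.
#' @export
df_model_spec <- function(variant = c("EQ2", "EQ1", "EQ3"),
                          envdif = character()) {
  variant <- match.arg(variant)
  envdif <- as.character(envdif)
  if (variant == "EQ3" && length(envdif) == 0L)
    stop("EQ3 requires at least one ENVDIF covariate")
  if (variant != "EQ3" && length(envdif) > 0L)
    stop(variant, " takes no ENVDIF covariates")
  structure(list(variant = variant, envdif = envdif),
            class = "df_model_spec")
}

#' Build the DF design matrix and response
#'
#' Assembles the regression layout of the requested model variant from
#' double-entered (and, for EQ2/EQ3, centered) rows.  Column layouts:
#' `EQ1`: intercept, `K2`, `R`, `R_x_K2`; `EQ2`: intercept, `K2_centered`,
#' `R_x_K2_centered`; `EQ3`: the EQ2 columns followed by `envdif_<name>`
#' columns in specification order.  The response is `K1`.
#'
#' @param rows Rows from [double_enter()] (run through [center_cotwin()]
#'   for EQ2/EQ3).
#' @param spec A [df_model_spec()].
#' @return List with elements `X` (numeric matrix), `y` (response vector)
#'   and `cluster` (pair identifiers).
#' @export
build_design <- function(rows, spec) {
  stopifnot(inherits(spec, "df_model_spec"))
  n <- nrow(rows)
  if (spec$variant == "EQ1") {
    X <- cbind(`(Intercept)` = rep(1, n), K2 = rows$K2, R = rows$R,
               R_x_K2 = rows$R * rows$K2)
  } else {
    if (is.null(rows$K2_centered))
      stop("EQ2/EQ3 designs need K2_centered; run center_cotwin() first")
    X <- cbind(`(Intercept)` = rep(1, n),
               K2_centered = rows$K2_centered,
               R_x_K2_centered = rows$R * rows$K2_centered)
    if (spec$variant == "EQ3") {
      cols <- paste0("envdif_", spec$envdif)
      absent <- setdiff(cols, names(rows))
      if (length(absent))
        stop("ENVDIF column(s) absent from rows: ",
             paste(absent, collapse = ", "))
      X <- cbind(X, as.matrix(rows[cols]))
    }
  }
  list(X = X, y = rows$K1, cluster = rows$pair_id)
}
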