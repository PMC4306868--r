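#' Measure sets used by the standard model suite
#'
#' @keywords internal
nutrition_measures <- c("fast_food", "low_veg", "meal_dep")

#' @keywords internal
exercise_measures <- c("low_sport", "low_cycle", "low_exercise", "insuff_ex")

suite_model_list <- function() {
  blocks <- list(list(label = "baseline", spec = df_model_spec("EQ2")))
  add_eq3 <- function(blocks, label, vars) {
    c(blocks, list(list(label = label,
                        spec = df_model_spec("EQ3", envdif = vars))))
  }
  blocks <- add_eq3(blocks, "nutrition_all", nutrition_measures)
  for (v in nutrition_measures)
    blocks <- add_eq3(blocks, paste0("nutrition_", v), v)
  blocks <- add_eq3(blocks, "exercise_all", exercise_measures)
  for (v in exercise_measures)
    blocks <- add_eq3(blocks, paste0("exercise_", v), v)
  add_eq3(blocks, "full", c(nutrition_measures, exercise_measures))
}

#' Fit the standard suite of DF models
#'
#' Reproduces the layout of a twin study of nutrition, physical activity
#' and verbal ability: a baseline EQ2 model estimating only the variance
#' decomposition; an all-nutrition EQ3 model and one-at-a-time models for
#' each of the three nutrition measures; an all-exercise EQ3 model and
#' one-at-a-time models for each of the four activity measures; and a full
#' sensitivity model entering all seven measures together — eleven model
#' blocks in all.  Each model performs its own pair-level listwise deletion
#' and its own co-twin centering, so reported N may differ across blocks.
#'
#' @param data One-row-per-twin table with `pair_id`, `twin_index`,
#'   `zygosity`, `outcome` and the seven derived measures (`fast_food`,
#'   `low_veg`, `meal_dep`, `low_sport`, `low_cycle`, `low_exercise`,
#'   `insuff_ex`).
#' @param cr_type Cluster-robust correction passed to [fit_df()].
#' @return An object of class `"df_suite"`: a list of blocks, each holding
#'   `label`, the `"df_fit"`, `n` and `r_squared`.
#' @export
run_model_suite <- function(data, cr_type = c("CR1", "CR0")) {
  cr_type <- match.arg(cr_type)
  need <- c("pair_id", "twin_index", "zygosity", "outcome",
            nutrition_measures, exercise_measures)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  blocks <- lapply(suite_model_list(), function(b) {
    fit <- fit_df(data, spec = b$spec, cr_type = cr_type)
    list(label = b$label, fit = fit, n = fit$n_rows,
         r_squared = fit$r_squared)
  })
  structure(blocks, class = "df_suite")
}

#' @export
print.df_suite <- function(x, digits = 3, ...) {
  cat("DF model suite (", length(x), " models)\n", sep = "")
  for (b in x) {
    vd <- b$fit$variance_decomposition
    cat(sprintf("\n-- %s: N = %d twins (%d pairs), R-squared = %.*f\n",
                b$label, b$n, b$fit$n_pairs, digits, b$r_squared))
    cat(sprintf("   c2 = %.*f, h2 = %.*f, residual = %.*f\n",
                digits, vd$c2, digits, vd$h2, digits, vd$residual))
    env <- grep("^envdif_", names(b$fit$coefficients), value = TRUE)
    for (nm in env)
      cat(sprintf("   %s = %.*f (SE %.*f)%s\n",
                  sub("^envdif_", "", nm),
                  digits, b$fit$coefficients[nm],
                  digits, b$fit$se[nm],
                  paste0(" ", signif_stars(b$fit$p[nm]))))
  }
  invisible(x)
}

#' Tidy coefficient table from a model suite
#'
#' @param x A `"df_suite"`.
#' @param row.names,optional Ignored (base generic signature).
#' @param ... Unused.
#' @return Data frame with one row per coefficient per model: `model`,
#'   `term`, `estimate`, `se`, `t`, `p`, `stars`, `n`, `n_pairs`,
#'   `r_squared`.
#' @export
as.data.frame.df_suite <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  do.call(rbind, lapply(x, function(b) {
    data.frame(model = b$label,
               term = names(b$fit$coefficients),
               estimate = unname(b$fit$coefficients),
               se = unname(b$fit$se),
               t = unname(b$fit$t),
               p = unname(b$fit$p),
               stars = signif_stars(unname(b$fit$p)),
               n = b$n,
               n_pairs = b$fit$n_pairs,
               r_squared = b$r_squared,
               stringsAsFactors = FALSE)
  }))
}

#' Write a model suite as JSON
#'
#' @param suite A `"df_suite"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_suite_json <- function(suite, path) {
  blocks <- lapply(suite, function(b) {
    list(model = b$label,
         n = b$n, n_pairs = b$fit$n_pairs, r_squared = b$r_squared,
         variance_decomposition = b$fit$variance_decomposition,
         coefficients = as.list(b$fit$coefficients),
         se = as.list(b$fit$se),
         p = as.list(b$fit$p))
  })
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
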