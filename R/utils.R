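# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg, class = "grazemetry_error") {
  rlang::abort(msg, class = c(class, "grazemetry_error"))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) abort_bad_arg(sprintf("`%s` must be numeric.", name))
  if (finite && any(!is.finite(x))) {
    abort_bad_arg(sprintf("`%s` must be finite.", name))
  }
  if (positive && any(x <= 0)) {
    abort_bad_arg(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_bad_arg(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ), class = "grazemetry_validation_error")
  }
  invisible(df)
}

# deterministic stream of child seeds, kept below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 1103 * as.numeric(index)) %% 2147483629 + 1
}

# run expr with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# z-score with guard against zero variance
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort_bad_arg("covariate has zero variance; cannot standardize.",
                  class = "grazemetry_degenerate_error")
  }
  (x - mean(x)) / s
}
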