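# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed; kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 7919L * as.integer(offset)) %% 2147483629L
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_na = FALSE) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("`%s` must not contain missing values", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name, allow_na = FALSE) {
  assert_number(x, name, lower = 0, allow_na = allow_na)
}

assert_prob <- function(x, name, allow_na = FALSE) {
  assert_number(x, name, lower = 0, upper = 1, allow_na = allow_na)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# Drop constant (zero-variance) columns from a design matrix, keeping the
# intercept; used by imputation models fitted on arm-restricted subsets.
drop_constant_cols <- function(X) {
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  keep[colnames(X) == "(Intercept)"] <- TRUE
  X[, keep, drop = FALSE]
}
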