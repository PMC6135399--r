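# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      (finite && any(!is.finite(x)))) {
    stop(sprintf("`%s` must be finite numeric, got %s", name,
                 paste(utils::head(format(x), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
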