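# shared validation helpers (internal)

stop_input <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input("'", name, "' must be TRUE or FALSE")
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'", name, "' must be a single finite number")
  }
  if (x < min || x > max) {
    stop_input("'", name, "' must be in [", min, ", ", max, "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) stop_input("'", name, "' must be an integer")
  invisible(as.integer(x))
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    stop_input("'", name, "' must be a nonempty string")
  }
  invisible(x)
}

# trim whitespace; labels are case-sensitive, uniqueness checks case-fold
norm_label <- function(x) trimws(x)
fold_label <- function(x) tolower(trimws(x))

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
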