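#' @keywords internal
"_PACKAGE"

# All repetition and echo times are carried in milliseconds; all relaxation
# rates are in s^-1. Conversions happen only through these two helpers so the
# unit convention lives in one place.
ms_to_s <- function(x) x / 1000

deg_to_rad <- function(x) x * pi / 180

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

check_same_dim <- function(a, b, name_a, name_b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("grid mismatch: `%s` has dim [%s] but `%s` has dim [%s]",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never disturb user RNG streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
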