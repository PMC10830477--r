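# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding to integer percent, the convention used in clinical
# characteristics tables (round(0.5) in R rounds to even, which is not).
#' @keywords internal
#' @noRd
percent_half_up <- function(count, total) {
  if (total == 0) return(rep(0, length(count)))
  as.integer(floor(count * 100 / total + 0.5))
}

#' @keywords internal
#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user code.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic JSON writer: bit-exact doubles (17 significant digits),
# unboxed scalars, no timestamps.
#' @keywords internal
#' @noRd
write_json_exact <- function(x, path) {
  json <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
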