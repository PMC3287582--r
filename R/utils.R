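# Internal helpers shared across modules.

IDENT_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(IDENT_RE, x)
}

assert_identifier <- function(x, what = "name") {
  if (!is_identifier(x)) {
    stop(sprintf("%s must be an identifier matching [A-Za-z_][A-Za-z0-9_]*, got %s",
                 what, paste(deparse(x), collapse = "")), call. = FALSE)
  }
  invisible(x)
}

#' Evaluate code under a fixed RNG seed without leaking global state
#'
#' Saves and restores `.Random.seed` so that seeded generators never perturb
#' (nor depend on) the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic logical clock: ISO-8601 timestamps advancing one second per
# tick from a fixed origin. Tests and event-sourcing replay rely on this.
logical_clock <- function(origin = "2020-01-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  i <- 0L
  function() {
    i <<- i + 1L
    format(t0 + i, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
}

sanitize_identifier <- function(x) {
  y <- gsub("[^A-Za-z0-9_]+", "_", x)
  if (!grepl("^[A-Za-z_]", y)) y <- paste0("X", y)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
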