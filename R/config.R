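#' Package configuration
#'
#' Reads a YAML key-value file; absent file (or absent keys) fall back to the
#' documented defaults:
#' \itemize{
#'   \item \code{store_path}: \code{"npdl_store"} — repository directory.
#'   \item \code{loop_bound}: 2 — default unroll bound of the trace oracle.
#'   \item \code{state_cap}: 1e5 — cap on visited residual states.
#'   \item \code{tau_cap}: 10000 — cap on consecutive silent steps.
#'   \item \code{seed}: 1 — seed for generators and demo runs.
#'   \item \code{log_level}: \code{"info"}.
#' }
#'
#' @param path optional YAML file path.
#' @return a named list of settings.
#' @export
npdl_config <- function(path = NULL) {
  defaults <- list(store_path = "npdl_store", loop_bound = 2L, state_cap = 1e5,
                   tau_cap = 10000L, seed = 1L, log_level = "info")
  if (is.null(path) || !file.exists(path)) return(defaults)
  user <- yaml::read_yaml(path)
  bad <- vapply(c("loop_bound", "state_cap", "tau_cap"), function(k)
    !is.null(user[[k]]) && user[[k]] <= 0, logical(1))
  if (any(bad))
    stop("configuration caps must be positive: ",
         paste(c("loop_bound", "state_cap", "tau_cap")[bad], collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, user)
}

npdl_log <- function(level, fmt, ..., cfg_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[cfg_level]])
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  invisible(NULL)
}
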