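#' Procedure catalog and test definitions
#'
#' End users define a genetic test as a list of procedures with
#' execution-order integers plus metadata (name, description, duration in
#' days, cost). Procedures with the same execution order run in parallel;
#' ascending order numbers run sequentially. Only the ascending ranking of
#' the order numbers matters; they need not be consecutive.
#'
#' @param procedures for \code{procedure_catalog}: a character vector of
#'   procedure names, or a data.frame with columns \code{name} and optionally
#'   \code{description}, \code{technique}, \code{reagents} (reagents as a
#'   single \code{;}-separated string). For \code{test_definition}: a
#'   data.frame with columns \code{name} and \code{order}.
#' @return \code{procedure_catalog}: a data.frame of class
#'   \code{npdl_catalog}; \code{test_definition}: a list of class
#'   \code{npdl_test_def}.
#' @examples
#' catalog <- procedure_catalog(c("DNA_extraction", "PCR_exon7", "PCR_exon8"))
#' sma <- test_definition("SMA",
#'   procedures = data.frame(name = c("PCR_exon7", "PCR_exon8"), order = c(1, 1)),
#'   description = "SMN1 exon 7/8 deletion screen", duration_days = 7, cost = 150)
#' validate_test(sma, catalog)
#' @export
procedure_catalog <- function(procedures) {
  if (is.character(procedures))
    procedures <- data.frame(name = procedures, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(procedures), "name" %in% names(procedures))
  for (col in c("description", "technique", "reagents"))
    if (!col %in% names(procedures)) procedures[[col]] <- ""
  bad <- procedures$name[!vapply(procedures$name, is_identifier, logical(1))]
  if (length(bad))
    stop(sprintf("invalid procedure identifier(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(procedures$name))
    stop("duplicate procedure name(s) in catalog", call. = FALSE)
  structure(procedures[, c("name", "description", "technique", "reagents")],
            class = c("npdl_catalog", "data.frame"))
}

#' @rdname procedure_catalog
#' @param name test name (free text; sanitized to an identifier when the
#'   process is registered).
#' @param description free-text description.
#' @param attachment optional file path (stored as a string only).
#' @param duration_days non-negative expected duration.
#' @param cost non-negative cost.
#' @export
test_definition <- function(name, procedures, description = "",
                            attachment = NULL, duration_days = 0, cost = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, description = description,
                 attachment = attachment,
                 duration_days = as.numeric(duration_days),
                 cost = as.numeric(cost),
                 items = as.data.frame(procedures, stringsAsFactors = FALSE)),
            class = "npdl_test_def")
}

#' Validate a test definition against a procedure catalog
#'
#' Violations are data, not errors: the empty character vector means valid.
#'
#' @param test_def an \code{npdl_test_def}.
#' @param catalog an \code{npdl_catalog}.
#' @return character vector of violation messages (empty = valid).
#' @export
validate_test <- function(test_def, catalog) {
  v <- character(0)
  items <- test_def$items
  if (!is.data.frame(items) || nrow(items) == 0L) {
    return("a test must contain at least one procedure")
  }
  if (!all(c("name", "order") %in% names(items)))
    return("procedure items must have 'name' and 'order' columns")
  dup <- unique(items$name[duplicated(items$name)])
  if (length(dup))
    v <- c(v, sprintf("duplicate procedure within test: %s",
                      paste(dup, collapse = ", ")))
  unknown <- setdiff(items$name, catalog$name)
  if (length(unknown))
    v <- c(v, sprintf("procedure not in catalog: %s", paste(unknown, collapse = ", ")))
  if (any(is.na(items$order)) || any(items$order != as.integer(items$order)) ||
      any(items$order < 1))
    v <- c(v, "execution orders must be positive integers")
  if (!is.na(test_def$duration_days) && test_def$duration_days < 0)
    v <- c(v, "duration_days must be non-negative")
  if (!is.na(test_def$cost) && test_def$cost < 0)
    v <- c(v, "cost must be non-negative")
  v
}

#' Compile a test definition into a process expression
#'
#' The canonical compiled form groups procedures by ascending execution order
#' into groups G1..Gk. Each procedure \code{p} compiles to
#' \preformatted{  (p ?*) . (GO \% ok_p)}
#' (the procedure is performed at least once and may be repeated as needed;
#' its silent continuation is gated on the last outcome being ok). Each group
#' is the \code{||}-composition of its wrapped procedures; the whole test is
#' \preformatted{  G1 . G2 . ... . Gk . END}
#' so procedures of the same order run in parallel, distinct orders run in
#' ascending sequence, and the terminal \code{END} is released exactly when
#' every gate has been passed. The expression is registered under the
#' sanitized test name.
#'
#' For the SMA example (PCR_exon7 and PCR_exon8, both order 1) the generated
#' expression is
#' \preformatted{  ((PCR_exon7 ?* . (GO \% ok_PCR_exon7)) ||
#'    (PCR_exon8 ?* . (GO \% ok_PCR_exon8))) . END}
#'
#' @param test_def an \code{npdl_test_def}; must validate cleanly.
#' @param registry a \code{\link{process_registry}} to register into (or
#'   \code{NULL} to skip registration).
#' @param catalog an \code{npdl_catalog} for validation.
#' @return list with \code{expr} (the \code{npdl_expr}) and \code{name} (the
#'   registered process name).
#' @export
build_expression <- function(test_def, registry = NULL, catalog = NULL) {
  if (!is.null(catalog)) {
    v <- validate_test(test_def, catalog)
    if (length(v))
      stop(paste(c("invalid test definition:", v), collapse = "\n  "), call. = FALSE)
  }
  items <- test_def$items
  wrap <- function(p) {
    rule <- paste0("ok_", p)
    px_seq(px_star(px_atom(p)), px_guard(px_atom("GO"), rule))
  }
  groups <- split(items$name, items$order)          # split() orders keys ascending
  group_exprs <- lapply(groups, function(ps) Reduce(px_par, lapply(ps, wrap)))
  expr <- px_seq(Reduce(px_seq, group_exprs), px_atom("END"))
  proc_name <- sanitize_identifier(test_def$name)
  if (!is.null(registry)) {
    reg_define(registry, proc_name, expr)
  }
  list(expr = expr, name = proc_name)
}

# ---- JSON / CSV interchange --------------------------------------------

#' Read and write test definitions and catalogs
#'
#' JSON layout for a test:
#' \code{{"name": ..., "description": ..., "duration_days": ..., "cost": ...,
#' "procedures": [{"name": ..., "order": ...}, ...]}}. CSV layout: one row
#' per procedure item with test-level metadata repeated.
#'
#' @param path file path.
#' @return \code{read_test_json}: an \code{npdl_test_def};
#'   \code{read_catalog_json}: an \code{npdl_catalog}.
#' @export
read_test_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  test_definition(x$name, procedures = x$procedures,
                  description = x$description %||% "",
                  attachment = x$attachment,
                  duration_days = x$duration_days %||% 0,
                  cost = x$cost %||% 0)
}

#' @rdname read_test_json
#' @param test_def an \code{npdl_test_def}.
#' @export
write_test_json <- function(test_def, path) {
  jsonlite::write_json(
    list(name = test_def$name, description = test_def$description,
         attachment = test_def$attachment,
         duration_days = test_def$duration_days, cost = test_def$cost,
         procedures = test_def$items),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname read_test_json
#' @export
read_test_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("test", "procedure", "exec_order") %in% names(x)))
  test_definition(x$test[[1L]],
                  procedures = data.frame(name = x$procedure,
                                          order = x$exec_order,
                                          stringsAsFactors = FALSE),
                  description = if ("description" %in% names(x)) x$description[[1L]] else "",
                  duration_days = if ("duration_days" %in% names(x)) x$duration_days[[1L]] else 0,
                  cost = if ("cost" %in% names(x)) x$cost[[1L]] else 0)
}

#' @rdname read_test_json
#' @export
write_test_csv <- function(test_def, path) {
  df <- data.frame(test = test_def$name,
                   procedure = test_def$items$name,
                   exec_order = test_def$items$order,
                   description = test_def$description,
                   duration_days = test_def$duration_days,
                   cost = test_def$cost, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_test_json
#' @export
read_catalog_json <- function(path) {
  procedure_catalog(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
}

#' @rdname read_test_json
#' @param catalog an \code{npdl_catalog}.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, pretty = TRUE)
  invisible(path)
}
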