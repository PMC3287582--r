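#' Evaluation context
#'
#' Holds the facts a running instance accumulates (per-procedure execution
#' counts and last outcomes), the rule registry used by guards, and the
#' function registry used by function-limited repetition.
#'
#' Rules are side-effect-free predicates over the facts. The built-in rule
#' family \code{ok_<procedure>} needs no registration: \code{ok_PCR_exon7} is
#' true iff the last reported outcome of \code{PCR_exon7} is \code{ok}. Guards
#' are re-evaluated against the current facts on every query, never cached.
#'
#' @param rules named list of functions \code{function(facts) -> logical}.
#' @param funcs named list of functions \code{function(facts) -> positive
#'   integer}, resolved by \code{?f(name)} at instantiation.
#' @param facts optional named list seeding the fact base; each element is a
#'   list with \code{times} and \code{last} (\code{"ok"}, \code{"failed"} or
#'   \code{"pending"}).
#' @return an object of class \code{npdl_ctx}.
#' @examples
#' ctx <- eval_context(rules = list(approved = function(f) TRUE))
#' ctx_record(ctx, "PCR_exon7", "ok")
#' ctx_rule(ctx, "ok_PCR_exon7")
#' @export
eval_context <- function(rules = list(), funcs = list(), facts = list()) {
  ctx <- new.env(parent = emptyenv())
  ctx$facts <- new.env(parent = emptyenv())
  ctx$rules <- rules
  ctx$funcs <- funcs
  class(ctx) <- "npdl_ctx"
  for (nm in names(facts)) {
    f <- facts[[nm]]
    assign(nm, list(times = as.integer(f$times %||% 0L),
                    last = f$last %||% "pending"), envir = ctx$facts)
  }
  ctx
}

#' Constant-rule context for static analysis
#'
#' A context in which every rule evaluates to a fixed value — all true by
#' default, with optional per-rule overrides. This is the default context of
#' the trace oracle (where no instance facts exist); overrides let analyses
#' ask what-if questions, e.g. which traces survive when a completion gate is
#' forced false.
#'
#' @param overrides named list of logical rule values.
#' @param default value of every other rule.
#' @return an \code{npdl_ctx}.
#' @examples
#' traces(parse_expression("(a % r) + b"), ctx = const_context(list(r = FALSE)))
#' @export
const_context <- function(overrides = list(), default = TRUE) {
  ctx <- eval_context()
  ctx$const_default <- isTRUE(default)
  ctx$const_overrides <- overrides
  ctx
}

#' @export
is_ctx <- function(x) inherits(x, "npdl_ctx")

ctx_facts_list <- function(ctx) {
  nms <- ls(ctx$facts)
  stats::setNames(lapply(nms, function(nm) ctx$facts[[nm]]), nms)
}

#' @describeIn eval_context record an execution of a procedure (increments the
#'   count and stores the outcome; the latest outcome wins).
#' @param ctx a context.
#' @param procedure procedure name.
#' @param outcome \code{"ok"} or \code{"failed"}.
#' @export
ctx_record <- function(ctx, procedure, outcome = "ok") {
  stopifnot(outcome %in% c("ok", "failed"))
  cur <- ctx$facts[[procedure]] %||% list(times = 0L, last = "pending")
  assign(procedure, list(times = cur$times + 1L, last = outcome), envir = ctx$facts)
  invisible(ctx)
}

#' @describeIn eval_context evaluate a rule by name against the current facts;
#'   errors if the rule is neither registered nor of the built-in
#'   \code{ok_<procedure>} family.
#' @param name rule name.
#' @param negated logical; negate the result.
#' @export
ctx_rule <- function(ctx, name, negated = FALSE) {
  val <-
    if (!is.null(ctx$const_default)) {
      if (name %in% names(ctx$const_overrides)) isTRUE(ctx$const_overrides[[name]])
      else ctx$const_default
    } else if (name %in% names(ctx$rules)) {
      isTRUE(ctx$rules[[name]](ctx_facts_list(ctx)))
    } else if (grepl("^ok_", name)) {
      proc <- sub("^ok_", "", name)
      f <- ctx$facts[[proc]]
      !is.null(f) && identical(f$last, "ok")
    } else {
      stop(sprintf("unresolved rule '%s'", name), call. = FALSE)
    }
  if (isTRUE(negated)) !val else val
}

# Check that every rule name is resolvable in this context (registered,
# built-in family, or a constant context).
ctx_check_rules <- function(ctx, rule_names) {
  if (!is.null(ctx$const_default)) return(invisible(TRUE))
  bad <- rule_names[!(rule_names %in% names(ctx$rules) | grepl("^ok_", rule_names))]
  if (length(bad))
    stop(sprintf("unresolved rule(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' @describeIn eval_context evaluate a registered positive-integer function.
#' @export
ctx_func <- function(ctx, name) {
  f <- ctx$funcs[[name]]
  if (is.null(f)) stop(sprintf("unresolved function '%s'", name), call. = FALSE)
  n <- f(ctx_facts_list(ctx))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1)
    stop(sprintf("function '%s' must return a positive integer", name), call. = FALSE)
  as.integer(n)
}

#' @export
print.npdl_ctx <- function(x, ...) {
  nms <- ls(x$facts)
  cat(sprintf("<npdl_ctx> %d fact(s), %d rule(s), %d function(s)\n",
              length(nms), length(x$rules), length(x$funcs)))
  for (nm in sort(nms)) {
    f <- x$facts[[nm]]
    cat(sprintf("  %s: times=%d last=%s\n", nm, f$times, f$last))
  }
  invisible(x)
}
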