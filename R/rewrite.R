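#' Rewrite extended operators to basic operators and recursion
#'
#' Eliminates the workflow operators \code{^}, \code{&}, \code{|*}, \code{?n},
#' \code{?*} and \code{?f} from an expression, producing a trace-equivalent
#' expression over the basic operators \code{.}, \code{+}, \code{||} (plus
#' \code{name_ref} and, unless stripped, guards):
#'
#' \itemize{
#'   \item \code{e ?n} unrolls to \code{n} sequential copies of \code{e}.
#'   \item \code{e ?*} becomes a fresh guarded recursive definition
#'     \code{X ::= e + e . X} added to the returned registry.
#'   \item \code{e ?f(g)} is replaced by \code{e ?*} (function-limited
#'     repetition is indistinguishable from unlimited repetition to static
#'     analysis; the engine resolves \code{g} at instantiation instead).
#'   \item \code{l |* r} becomes \code{(l . r) + (r . l)}: the two no-overlap
#'     orders of the branches.
#'   \item \code{(l & r) . c} becomes \code{(l . c) || (r . c)}; a bare
#'     \code{l & r} becomes \code{l || r}.
#'   \item \code{(l ^ r) . c} becomes \code{((l . c) || r) + ((r . c) || l)};
#'     a bare \code{l ^ r} becomes \code{l || r}.
#'   \item guards \code{e \% r} are preserved by default; with
#'     \code{strip_guards = TRUE} they are removed (the rule is assumed
#'     satisfiable), matching their eliminability from static analysis.
#' }
#'
#' Definitions reachable from \code{expr} through \code{name_ref} are
#' rewritten too, so the result is fully basic. Trace sets are preserved at
#' any loop bound; this is property-tested against the enumeration oracle.
#'
#' @inheritParams traces
#' @param strip_guards logical; drop guard nodes instead of preserving them.
#' @return a list with components \code{expr} (the rewritten expression) and
#'   \code{registry} (a copy of the input registry with rewritten and fresh
#'   definitions).
#' @examples
#' r <- rewrite_extended(parse_expression("a ?3"))
#' npdl_serialize(r$expr)
#' r2 <- rewrite_extended(parse_expression("a ?*"))
#' npdl_serialize(r2$expr)
#' print(r2$registry)
#' @export
rewrite_extended <- function(expr, registry = NULL, strip_guards = FALSE) {
  out_reg <- if (is.null(registry)) process_registry() else reg_clone(registry)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  fresh_name <- function() {
    repeat {
      counter$i <- counter$i + 1L
      nm <- sprintf("REP%d", counter$i)
      if (!(nm %in% reg_names(out_reg))) return(nm)
    }
  }
  done <- new.env(parent = emptyenv())  # definitions already rewritten

  rw <- function(e) {
    e <- norm_head(e)  # same transformation the interpreter applies
    switch(e$kind,
      nil = ,
      dead = ,
      atom = e,
      name_ref = { rw_def(e$ref_name); e },
      seq = px_seq(rw(e$left), rw(e$right)),
      alt = px_alt(rw(e$left), rw(e$right)),
      par = px_par(rw(e$left), rw(e$right)),
      ipar = {
        l <- rw(e$left); r <- rw(e$right)
        px_alt(px_seq(l, r), px_seq(r, l))
      },
      rep_n = {
        body <- rw(e$left)
        out <- body
        if (e$n > 1L) for (i in seq_len(e$n - 1L)) out <- px_seq(body, out)
        out
      },
      rep_star = {
        body <- rw(e$left)
        nm <- fresh_name()
        reg_define(out_reg, nm, px_alt(body, px_seq(body, px_ref(nm))))
        px_ref(nm)
      },
      guard = {
        if (strip_guards) rw(e$left)
        else px_guard(rw(e$left), e$rule$name, negated = e$rule$negated)
      },
      stop("unknown kind ", e$kind)
    )
  }
  rw_def <- function(name) {
    if (!is.null(done[[name]])) return(invisible(NULL))
    assign(name, TRUE, envir = done)
    reg_define(out_reg, name, rw(reg_get(out_reg, name)))
  }

  list(expr = rw(expr), registry = out_reg)
}

# TRUE iff an expression is in basic form: atom/name_ref/seq/alt/par
# (+ guard unless guards were stripped).
is_basic <- function(e, allow_guard = TRUE) {
  ok <- switch(e$kind,
    nil = , atom = , name_ref = TRUE,
    seq = , alt = , par = TRUE,
    guard = allow_guard,
    FALSE
  )
  if (!ok) return(FALSE)
  if (!is.null(e$left) && !is_basic(e$left, allow_guard)) return(FALSE)
  if (!is.null(e$right) && !is_basic(e$right, allow_guard)) return(FALSE)
  TRUE
}
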