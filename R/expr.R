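#' Process expressions
#'
#' The central formal object of the package: an abstract syntax tree over an
#' ACP-style process algebra extended with the workflow operators used to
#' describe genetic-testing control flow. Node kinds:
#'
#' \describe{
#'   \item{atom}{a single labelled action (a laboratory procedure, the silent
#'     action \code{GO}, or the terminal action \code{END}).}
#'   \item{name_ref}{a reference to a named process definition in a
#'     \code{\link{process_registry}}, enabling recursion and reuse.}
#'   \item{seq}{sequential composition \code{l . r}.}
#'   \item{alt}{alternative composition (choice) \code{l + r}.}
#'   \item{par}{parallel merge \code{l || r} (pure interleaving).}
#'   \item{ipar}{interleaved parallel routing \code{l |* r}: branches run one
#'     at a time, in either order, without overlap.}
#'   \item{mmerge}{multi-merge \code{l & r}: each branch completion
#'     independently enables one execution of the sequential continuation.}
#'   \item{disc}{discriminator \code{l ^ r}: the first branch completion
#'     enables the continuation exactly once; the other branch still runs to
#'     completion but its completion is absorbed.}
#'   \item{rep_star}{unlimited repetition \code{e ?*} (one or more times).}
#'   \item{rep_n}{number-limited repetition \code{e ?n}, exactly \code{n}
#'     sequential executions.}
#'   \item{rep_f}{function-limited repetition \code{e ?f(name)}: \code{name}
#'     is resolved against a function registry at instantiation time, yielding
#'     \code{rep_n}; for static analysis it is read as \code{rep_star}.}
#'   \item{guard}{conditional execution \code{e \% r} / \code{e \%! r}: the
#'     initial actions of \code{e} are enabled iff the Boolean rule \code{r}
#'     evaluates true (resp. false) at query time.}
#' }
#'
#' Atoms carry an action symbol with a kind: \code{regular}, \code{silent}
#' (only \code{GO}) or \code{terminal} (only \code{END}). Silent actions are
#' fired by the system and elided from traces; a terminal action marks test
#' completion and may only occur at the tail of a trace.
#'
#' \code{px_make()} is the generic constructor; the \code{px_*} helpers are
#' convenience wrappers. All constructors validate arity and parameters.
#'
#' @param kind node kind, one of the kinds listed above.
#' @param ... operands and parameters as required by \code{kind}.
#' @param name action or process name (identifier).
#' @param l,r,e operand expressions.
#' @param n positive integer repetition count.
#' @param func_name identifier of a registered positive-integer function.
#' @param rule identifier of a Boolean rule.
#' @param negated logical; \code{TRUE} for the negated guard \code{\%!}.
#' @return an object of class \code{npdl_expr}.
#' @examples
#' e <- px_seq(px_par(px_atom("PCR_exon7"), px_atom("PCR_exon8")), px_atom("END"))
#' npdl_serialize(e)
#' @export
px_make <- function(kind, ...) {
  args <- list(...)
  switch(kind,
    atom = px_atom(args[[1L]]),
    name_ref = px_ref(args[[1L]]),
    seq = px_seq(args[[1L]], args[[2L]]),
    alt = px_alt(args[[1L]], args[[2L]]),
    par = px_par(args[[1L]], args[[2L]]),
    ipar = px_ipar(args[[1L]], args[[2L]]),
    mmerge = px_mmerge(args[[1L]], args[[2L]]),
    disc = px_disc(args[[1L]], args[[2L]]),
    rep_star = px_star(args[[1L]]),
    rep_n = px_rep(args[[1L]], args$n %||% args[[2L]]),
    rep_f = px_frep(args[[1L]], args$func_name %||% args[[2L]]),
    guard = px_guard(args[[1L]], args$rule %||% args[[2L]],
                     negated = isTRUE(args$negated)),
    stop(sprintf("unknown expression kind '%s'", kind), call. = FALSE)
  )
}

new_expr <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "npdl_expr")
}

#' @export
is_expr <- function(x) inherits(x, "npdl_expr")

assert_expr <- function(x, what = "operand") {
  if (!is_expr(x)) stop(sprintf("%s must be an npdl_expr", what), call. = FALSE)
  invisible(x)
}

action_symbol <- function(name) {
  assert_identifier(name, "action name")
  kind <- if (name == "GO") "silent" else if (name == "END") "terminal" else "regular"
  list(name = name, kind = kind)
}

#' @rdname px_make
#' @export
px_atom <- function(name) new_expr("atom", list(symbol = action_symbol(name)))

#' @rdname px_make
#' @export
px_ref <- function(name) {
  assert_identifier(name, "process name")
  new_expr("name_ref", list(ref_name = name))
}

binary_expr <- function(kind) {
  force(kind)
  function(l, r) {
    assert_expr(l, "left operand"); assert_expr(r, "right operand")
    new_expr(kind, list(left = l, right = r))
  }
}

#' @rdname px_make
#' @export
px_seq <- binary_expr("seq")

#' @rdname px_make
#' @export
px_alt <- binary_expr("alt")

#' @rdname px_make
#' @export
px_par <- binary_expr("par")

#' @rdname px_make
#' @export
px_ipar <- binary_expr("ipar")

#' @rdname px_make
#' @export
px_mmerge <- binary_expr("mmerge")

#' @rdname px_make
#' @export
px_disc <- binary_expr("disc")

#' @rdname px_make
#' @export
px_star <- function(e) {
  assert_expr(e)
  new_expr("rep_star", list(left = e))
}

#' @rdname px_make
#' @export
px_rep <- function(e, n) {
  assert_expr(e)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1)
    stop("repetition count n must be a positive integer (n >= 1)", call. = FALSE)
  new_expr("rep_n", list(left = e, n = as.integer(n)))
}

#' @rdname px_make
#' @export
px_frep <- function(e, func_name) {
  assert_expr(e)
  assert_identifier(func_name, "function name")
  new_expr("rep_f", list(left = e, func_name = func_name))
}

#' @rdname px_make
#' @export
px_guard <- function(e, rule, negated = FALSE) {
  assert_expr(e)
  assert_identifier(rule, "rule name")
  new_expr("guard", list(left = e, rule = list(name = rule, negated = isTRUE(negated))))
}

# The successfully-terminated empty process; arises only as a residual.
px_nil <- function() new_expr("nil", list())

# Deadlocked process: no moves, no termination. Used internally when bounded
# enumeration cuts a recursion off at its unroll budget.
px_dead <- function() new_expr("dead", list())

#' Structural equality of process expressions
#'
#' The equality used by round-trip and rewrite tests: two expressions are
#' equal iff their trees are node-for-node identical (no algebraic laws are
#' applied; use \code{\link{trace_equivalent}} for behavioural comparison).
#'
#' @param a,b expressions.
#' @return logical.
#' @export
px_equal <- function(a, b) identical(unclass_deep(a), unclass_deep(b))

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# Unambiguous canonical key for memo tables; distinct from the user-facing
# serializer so that internal node kinds (nil/dead) and atom-vs-ref are
# always distinguishable.
expr_key <- function(e) {
  switch(e$kind,
    nil = "0",
    dead = "!",
    atom = paste0("a:", e$symbol$name),
    name_ref = paste0("@", e$ref_name),
    rep_star = paste0("(* ", expr_key(e$left), ")"),
    rep_n = paste0("(#", e$n, " ", expr_key(e$left), ")"),
    rep_f = paste0("(f:", e$func_name, " ", expr_key(e$left), ")"),
    guard = paste0("(%", if (e$rule$negated) "!" else "", e$rule$name, " ",
                   expr_key(e$left), ")"),
    # binary kinds
    paste0("(", e$kind, " ", expr_key(e$left), " ", expr_key(e$right), ")")
  )
}

#' @export
print.npdl_expr <- function(x, ...) {
  cat("<npdl_expr> ", npdl_serialize(x), "\n", sep = "")
  invisible(x)
}

# Walk an expression bottom-up, applying f to every node.
expr_map <- function(e, f) {
  e2 <- e
  if (!is.null(e$left)) e2$left <- expr_map(e$left, f)
  if (!is.null(e$right)) e2$right <- expr_map(e$right, f)
  f(e2)
}

#' Unrolled action count of an expression
#'
#' The number of action occurrences a complete run can perform when every
#' repetition is unrolled \code{loop_bound} times — a cheap upper-bound proxy
#' for the cost of exhaustive trace enumeration, used to keep property sweeps
#' inside the enumeration caps.
#'
#' @param expr an \code{npdl_expr} (closed; name_refs count as size 1).
#' @param loop_bound unroll factor for unbounded repetition.
#' @return integer.
#' @export
expr_size <- function(expr, loop_bound = 2L) {
  switch(expr$kind,
    nil = , dead = 0L,
    atom = , name_ref = 1L,
    rep_star = , rep_f = loop_bound * expr_size(expr$left, loop_bound),
    rep_n = expr$n * expr_size(expr$left, loop_bound),
    guard = expr_size(expr$left, loop_bound),
    expr_size(expr$left, loop_bound) + expr_size(expr$right, loop_bound)
  )
}

# All atom names occurring in an expression (regular actions only by default).
expr_atoms <- function(e, kinds = c("regular", "silent", "terminal")) {
  out <- character(0)
  rec <- function(x) {
    if (x$kind == "atom") {
      if (x$symbol$kind %in% kinds) out[[length(out) + 1L]] <<- x$symbol$name
    }
    if (!is.null(x$left)) rec(x$left)
    if (!is.null(x$right)) rec(x$right)
  }
  rec(e)
  out
}

# Names referenced by name_ref nodes anywhere in the expression.
expr_refs <- function(e) {
  out <- character(0)
  rec <- function(x) {
    if (x$kind == "name_ref") out[[length(out) + 1L]] <<- x$ref_name
    if (!is.null(x$left)) rec(x$left)
    if (!is.null(x$right)) rec(x$right)
  }
  rec(e)
  unique(out)
}

# Rule names used by guard nodes.
expr_rules <- function(e) {
  out <- character(0)
  rec <- function(x) {
    if (x$kind == "guard") out[[length(out) + 1L]] <<- x$rule$name
    if (!is.null(x$left)) rec(x$left)
    if (!is.null(x$right)) rec(x$right)
  }
  rec(e)
  unique(out)
}

# Function names used by rep_f nodes.
expr_funcs <- function(e) {
  out <- character(0)
  rec <- function(x) {
    if (x$kind == "rep_f") out[[length(out) + 1L]] <<- x$func_name
    if (!is.null(x$left)) rec(x$left)
    if (!is.null(x$right)) rec(x$right)
  }
  rec(e)
  unique(out)
}
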