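#' Process registry
#'
#' A mutable map from process names to definitions, with a version counter per
#' name: the in-memory face of the common process repository. Re-defining an
#' existing name is a versioning event (the definition is replaced and its
#' version incremented), mirroring how a laboratory refines a test protocol
#' over time while old instances keep running against the text they were
#' instantiated from.
#'
#' @param defs optional named list of \code{npdl_expr} used to seed the
#'   registry.
#' @return an object of class \code{npdl_registry}.
#' @examples
#' reg <- process_registry()
#' reg_define(reg, "X", parse_expression("a + a . X", known = "X"))
#' reg_names(reg)
#' @export
process_registry <- function(defs = list()) {
  reg <- new.env(parent = emptyenv())
  reg$defs <- new.env(parent = emptyenv())
  class(reg) <- "npdl_registry"
  for (nm in names(defs)) reg_define(reg, nm, defs[[nm]])
  reg
}

#' @export
is_registry <- function(x) inherits(x, "npdl_registry")

#' @describeIn process_registry add or replace a definition (version bump on
#'   replacement). Returns the new version, invisibly.
#' @param reg a registry.
#' @param name process name (identifier).
#' @param expr the defining \code{npdl_expr}.
#' @export
reg_define <- function(reg, name, expr) {
  assert_identifier(name, "process name")
  assert_expr(expr, "definition")
  prev <- reg$defs[[name]]
  version <- if (is.null(prev)) 1L else prev$version + 1L
  assign(name, list(expr = expr, version = version), envir = reg$defs)
  invisible(version)
}

#' @describeIn process_registry retrieve a definition expression; error if
#'   unknown.
#' @export
reg_get <- function(reg, name) {
  d <- reg$defs[[name]]
  if (is.null(d)) stop(sprintf("unknown process definition '%s'", name), call. = FALSE)
  d$expr
}

#' @describeIn process_registry current version of a definition.
#' @export
reg_version <- function(reg, name) {
  d <- reg$defs[[name]]
  if (is.null(d)) stop(sprintf("unknown process definition '%s'", name), call. = FALSE)
  d$version
}

#' @describeIn process_registry all defined names, sorted.
#' @export
reg_names <- function(reg) sort(ls(reg$defs))

#' @describeIn process_registry deep copy (definitions are immutable lists, so
#'   a shallow environment copy suffices).
#' @export
reg_clone <- function(reg) {
  out <- process_registry()
  for (nm in ls(reg$defs)) assign(nm, reg$defs[[nm]], envir = out$defs)
  out
}

#' @export
print.npdl_registry <- function(x, ...) {
  nms <- reg_names(x)
  cat(sprintf("<npdl_registry> %d definition(s)\n", length(nms)))
  for (nm in nms)
    cat(sprintf("  %s (v%d) = %s\n", nm, reg_version(x, nm),
                npdl_serialize(reg_get(x, nm))))
  invisible(x)
}

# ---- static validation -------------------------------------------------

# Nullability: can the expression terminate successfully without performing
# any action, assuming every guard may be true? Fixpoint over the registry.
nullable_table <- function(reg) {
  nms <- reg_names(reg)
  nullable <- stats::setNames(rep(FALSE, length(nms)), nms)
  eval_nullable <- function(e) {
    switch(e$kind,
      nil = TRUE,
      dead = FALSE,
      atom = FALSE,
      name_ref = isTRUE(nullable[[e$ref_name]]),
      seq = eval_nullable(e$left) && eval_nullable(e$right),
      alt = eval_nullable(e$left) || eval_nullable(e$right),
      par = ,
      ipar = ,
      mmerge = ,
      disc = eval_nullable(e$left) && eval_nullable(e$right),
      rep_star = ,
      rep_n = ,
      rep_f = ,
      guard = eval_nullable(e$left),
      stop("unknown kind ", e$kind)
    )
  }
  repeat {
    changed <- FALSE
    for (nm in nms) {
      v <- eval_nullable(reg_get(reg, nm))
      if (v != nullable[[nm]]) { nullable[[nm]] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  list(table = nullable, eval = eval_nullable)
}

# Names occurring in *initial* (unguarded) position of e: reachable before
# any atom is executed.
initial_refs <- function(e, eval_nullable) {
  switch(e$kind,
    nil = ,
    dead = ,
    atom = character(0),
    name_ref = e$ref_name,
    seq = {
      u <- initial_refs(e$left, eval_nullable)
      if (eval_nullable(e$left))
        u <- union(u, initial_refs(e$right, eval_nullable))
      u
    },
    alt = ,
    par = ,
    ipar = ,
    mmerge = ,
    disc = union(initial_refs(e$left, eval_nullable),
                 initial_refs(e$right, eval_nullable)),
    rep_star = ,
    rep_n = ,
    rep_f = ,
    guard = initial_refs(e$left, eval_nullable),
    stop("unknown kind ", e$kind)
  )
}

#' Validate a registry: resolution and guardedness
#'
#' Checks that every \code{name_ref} reachable from any definition resolves,
#' and that recursion is guarded: on every cycle of name references at least
#' one atom must be executed before the recursive call (so each derivative
#' step does a finite amount of work). \code{X ::= X + a} is rejected;
#' \code{X ::= a + a . X} is accepted.
#'
#' @param reg a registry.
#' @param expr optional extra expression that must also resolve against
#'   \code{reg}.
#' @return invisibly \code{TRUE}; errors describe the violation.
#' @export
reg_validate <- function(reg, expr = NULL) {
  nms <- reg_names(reg)
  all_exprs <- lapply(nms, function(nm) reg_get(reg, nm))
  if (!is.null(expr)) all_exprs <- c(all_exprs, list(expr))
  for (e in all_exprs) {
    missing <- setdiff(expr_refs(e), nms)
    if (length(missing))
      stop(sprintf("unresolved process reference(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(nms)) {
    nt <- nullable_table(reg)
    # Edge X -> Y iff Y occurs in initial position of def(X); a cycle in this
    # graph is an unguarded recursion.
    edges <- lapply(stats::setNames(nms, nms), function(nm)
      intersect(initial_refs(reg_get(reg, nm), nt$eval), nms))
    color <- stats::setNames(rep(0L, length(nms)), nms)  # 0 new, 1 open, 2 done
    visit <- function(nm, stack) {
      if (color[[nm]] == 1L)
        stop(sprintf("unguarded recursion through: %s",
                     paste(c(stack, nm), collapse = " -> ")), call. = FALSE)
      if (color[[nm]] == 2L) return(invisible(NULL))
      color[[nm]] <<- 1L
      for (nxt in edges[[nm]]) visit(nxt, c(stack, nm))
      color[[nm]] <<- 2L
    }
    for (nm in nms) visit(nm, character(0))
  }
  invisible(TRUE)
}
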