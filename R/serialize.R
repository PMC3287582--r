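#' Serialize expressions and registries to NPDL text
#'
#' Precedence-aware printer emitting minimal parentheses; chains of one
#' left-associative operator print flat (\code{a + b + c}). The output
#' round-trips: \code{parse_expression(npdl_serialize(e))} is structurally
#' equal to \code{e} (for registries, \code{parse_program} restores
#' \code{name_ref} nodes).
#'
#' @param x an \code{npdl_expr} or an \code{npdl_registry}.
#' @return a single string.
#' @examples
#' npdl_serialize(px_alt(px_seq(px_atom("a"), px_atom("b")), px_atom("c")))
#' @export
npdl_serialize <- function(x) {
  if (is_registry(x)) {
    nms <- ls(x$defs)  # insertion order is not tracked; use sorted names
    return(paste0(vapply(sort(nms), function(nm)
      sprintf("define %s = %s ;", nm, ser_expr(reg_get(x, nm), 0L)),
      character(1)), collapse = "\n"))
  }
  assert_expr(x, "x")
  ser_expr(x, 0L)
}

# Precedence levels: alt=1 < merge family=2 < seq=3 < postfix=4 < primary=5.
prec_of <- function(kind) {
  switch(kind,
    alt = 1L,
    par = , ipar = , mmerge = , disc = 2L,
    seq = 3L,
    rep_star = , rep_n = , rep_f = , guard = 4L,
    atom = , name_ref = , nil = , dead = 5L
  )
}

infix_sym <- function(kind) {
  switch(kind, alt = "+", par = "||", ipar = "|*", mmerge = "&", disc = "^",
         seq = ".")
}

ser_expr <- function(e, parent_prec, right_side = FALSE) {
  p <- prec_of(e$kind)
  txt <- switch(e$kind,
    atom = e$symbol$name,
    name_ref = e$ref_name,
    nil = "()",   # never produced by the parser; residual printing only
    dead = "<dead>",
    rep_star = paste0(ser_expr(e$left, p), " ?*"),
    rep_n = paste0(ser_expr(e$left, p), " ?", e$n),
    rep_f = paste0(ser_expr(e$left, p), " ?f(", e$func_name, ")"),
    guard = paste0(ser_expr(e$left, p), if (e$rule$negated) " %! " else " % ",
                   e$rule$name),
    # infix, left-associative: right child of the same level needs parens
    paste0(ser_expr(e$left, p), " ", infix_sym(e$kind), " ",
           ser_expr(e$right, p, right_side = TRUE))
  )
  needs_parens <- p < parent_prec || (right_side && p == parent_prec)
  if (needs_parens) paste0("(", txt, ")") else txt
}

#' Write an `.npdl` file
#'
#' @param x an \code{npdl_expr} or \code{npdl_registry}.
#' @param path output path (conventionally with extension \code{.npdl}).
#' @export
write_npdl <- function(x, path) {
  writeLines(npdl_serialize(x), path, useBytes = TRUE)
  invisible(path)
}
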