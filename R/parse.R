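# Concrete textual syntax: tokenizer and recursive-descent parser.
#
# Grammar (loosest to tightest; all infix operators left-associative):
#
#   program  := { "define" IDENT "=" choice ";" }
#   choice   := merge { "+" merge }
#   merge    := sequence { ("||" | "|*" | "&" | "^") sequence }
#   sequence := postfix { "." postfix }
#   postfix  := primary { "?*" | "?" INT | "?f" "(" IDENT ")"
#                       | "%" IDENT | "%!" IDENT }
#   primary  := IDENT | "(" choice ")"
#
# "." binds tighter than the merge family, which binds tighter than "+";
# postfix operators bind tightest. The four merge-family operators share one
# precedence level and may be mixed. Whitespace is insignificant; "#" starts
# a line comment; files carry the .npdl extension.

TOKEN_PATTERNS <- list(
  c("ident",  "[A-Za-z_][A-Za-z0-9_]*"),
  c("repf",   "\\?f"),
  c("repstar", "\\?\\*"),
  c("repn",   "\\?[0-9]+"),
  c("guardn", "%!"),
  c("guard",  "%"),
  c("par",    "\\|\\|"),
  c("ipar",   "\\|\\*"),
  c("alt",    "\\+"),
  c("seq",    "\\."),
  c("amp",    "&"),
  c("caret",  "\\^"),
  c("lpar",   "\\("),
  c("rpar",   "\\)"),
  c("eq",     "="),
  c("semi",   ";")
)

npdl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) lines <- ""
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[[ln]])
    col <- 1L
    while (col <= nchar(s)) {
      rest <- substr(s, col, nchar(s))
      ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
      if (length(ws)) { col <- col + nchar(ws); next }
      matched <- FALSE
      for (tp in TOKEN_PATTERNS) {
        m <- regmatches(rest, regexpr(paste0("^(", tp[[2L]], ")"), rest))
        if (length(m)) {
          toks[[length(toks) + 1L]] <-
            list(type = tp[[1L]], text = m, line = ln, col = col)
          col <- col + nchar(m)
          matched <- TRUE
          break
        }
      }
      if (!matched)
        stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                     ln, col, substr(rest, 1, 1)), call. = FALSE)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", text = "<end of input>",
                                    line = length(lines),
                                    col = nchar(lines[[length(lines)]]) + 1L)
  toks
}

new_parser <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  env
}

p_peek <- function(p) p$toks[[p$pos]]
p_next <- function(p) { t <- p$toks[[p$pos]]; p$pos <- p$pos + 1L; t }

p_fail <- function(p, expected) {
  t <- p_peek(p)
  stop(sprintf("syntax error at line %d, column %d: expected %s, found '%s'",
               t$line, t$col, expected, t$text), call. = FALSE)
}

p_expect <- function(p, type, expected = type) {
  if (p_peek(p)$type != type) p_fail(p, expected)
  p_next(p)
}

p_choice <- function(p) {
  e <- p_merge(p)
  while (p_peek(p)$type == "alt") {
    p_next(p)
    e <- px_alt(e, p_merge(p))
  }
  e
}

p_merge <- function(p) {
  e <- p_sequence(p)
  repeat {
    t <- p_peek(p)$type
    ctor <- switch(t, par = px_par, ipar = px_ipar, amp = px_mmerge,
                   caret = px_disc, NULL)
    if (is.null(ctor)) break
    p_next(p)
    e <- ctor(e, p_sequence(p))
  }
  e
}

p_sequence <- function(p) {
  e <- p_postfix(p)
  while (p_peek(p)$type == "seq") {
    p_next(p)
    e <- px_seq(e, p_postfix(p))
  }
  e
}

p_postfix <- function(p) {
  e <- p_primary(p)
  repeat {
    t <- p_peek(p)
    if (t$type == "repstar") { p_next(p); e <- px_star(e) }
    else if (t$type == "repn") {
      p_next(p)
      e <- px_rep(e, as.integer(sub("^\\?", "", t$text)))
    } else if (t$type == "repf") {
      p_next(p)
      p_expect(p, "lpar", "'(' after ?f")
      fn <- p_expect(p, "ident", "function name")
      p_expect(p, "rpar", "')'")
      e <- px_frep(e, fn$text)
    } else if (t$type == "guard") {
      p_next(p)
      rn <- p_expect(p, "ident", "rule name")
      e <- px_guard(e, rn$text)
    } else if (t$type == "guardn") {
      p_next(p)
      rn <- p_expect(p, "ident", "rule name")
      e <- px_guard(e, rn$text, negated = TRUE)
    } else break
  }
  e
}

p_primary <- function(p) {
  t <- p_peek(p)
  if (t$type == "ident") { p_next(p); return(px_atom(t$text)) }
  if (t$type == "lpar") {
    p_next(p)
    if (p_peek(p)$type == "rpar") {  # "()" is the terminated empty process
      p_next(p)
      return(px_nil())
    }
    e <- p_choice(p)
    p_expect(p, "rpar", "')'")
    return(e)
  }
  p_fail(p, "an action name or '('")
}

#' Parse a process expression from text
#'
#' @param text expression source, e.g. \code{"(PCR_exon7 || PCR_exon8) . END"}.
#' @param known character vector of process names: bare identifiers matching
#'   one of these parse as \code{name_ref} nodes rather than atoms (this is
#'   how \code{\link{parse_program}} resolves references to definitions).
#' @return an \code{npdl_expr}. Syntax errors report line, column and the
#'   expected tokens.
#' @examples
#' parse_expression("a . b + c")   # "." binds tighter than "+"
#' @export
parse_expression <- function(text, known = character(0)) {
  p <- new_parser(npdl_tokenize(text))
  e <- p_choice(p)
  if (p_peek(p)$type != "eof") p_fail(p, "end of input or an operator")
  if (length(known)) e <- resolve_refs(e, known)
  e
}

resolve_refs <- function(e, known) {
  expr_map(e, function(x) {
    if (x$kind == "atom" && x$symbol$name %in% known) px_ref(x$symbol$name) else x
  })
}

#' Parse a program of named process definitions
#'
#' A program is a sequence of \code{define Name = <expr> ;} statements.
#' Identifiers naming a defined process (anywhere in the program) are
#' resolved to \code{name_ref} nodes. Defining the same name twice is a
#' versioning event: the later definition wins and the version counter is
#' incremented. The resulting registry is validated (resolution and
#' guardedness).
#'
#' @param text program source.
#' @return an \code{npdl_registry}.
#' @examples
#' reg <- parse_program("define X = a + a . X ;")
#' reg_get(reg, "X")
#' @export
parse_program <- function(text) {
  p <- new_parser(npdl_tokenize(text))
  defs <- list()  # list of (name, expr) in source order
  while (p_peek(p)$type != "eof") {
    kw <- p_expect(p, "ident", "'define'")
    if (kw$text != "define")
      stop(sprintf("syntax error at line %d, column %d: expected 'define', found '%s'",
                   kw$line, kw$col, kw$text), call. = FALSE)
    nm <- p_expect(p, "ident", "process name")
    p_expect(p, "eq", "'='")
    e <- p_choice(p)
    p_expect(p, "semi", "';'")
    defs[[length(defs) + 1L]] <- list(name = nm$text, expr = e)
  }
  known <- unique(vapply(defs, `[[`, character(1), "name"))
  reg <- process_registry()
  for (d in defs) reg_define(reg, d$name, resolve_refs(d$expr, known))
  reg_validate(reg)
  reg
}

#' Read an `.npdl` file
#'
#' Parses a UTF-8 text file either as a program (if it contains `define`
#' statements) or as a single expression.
#'
#' @param path file path.
#' @return an \code{npdl_registry} or an \code{npdl_expr}.
#' @export
read_npdl <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  stripped <- gsub("#[^\n]*", "", text)
  if (grepl("(^|[^A-Za-z0-9_])define[[:space:]]", stripped)) parse_program(text)
  else parse_expression(text)
}
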