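# Partially specified Boolean expressions: AST, parser, evaluation.
#
# Core grammar: 0 | 1 | v | !e | e & e | f(e1, ..., ea) for an uninterpreted
# function symbol f of arity a.  The sugar operators |, =>, <=>, ^ are kept in
# the AST for pretty-printing and desugared on demand.

expr_node <- function(op, ...) structure(list(op = op, ...), class = "bn_expr")

e_const <- function(value) expr_node("const", value = as.logical(value))
e_var   <- function(name)  expr_node("var", name = name)
e_not   <- function(arg)   expr_node("not", arg = arg)
e_bin   <- function(op, lhs, rhs) expr_node(op, lhs = lhs, rhs = rhs)
e_apply <- function(sym, args) expr_node("apply", sym = sym, args = args)

BIN_OPS <- c("and", "or", "imp", "iff", "xor")

#' @export
print.bn_expr <- function(x, ...) {
  cat(format_expression(x), "\n")
  invisible(x)
}

#' Render an expression back to its concrete syntax
#'
#' @param e expression AST as produced by [parse_expression()]
#' @return character scalar
#' @export
format_expression <- function(e) {
  prec <- c(const = 9, var = 9, apply = 9, not = 6, and = 5, or = 4, xor = 3, imp = 2, iff = 1)
  opch <- c(and = "&", or = "|", xor = "^", imp = "=>", iff = "<=>")
  fmt <- function(e) {
    switch(e$op,
      const = if (e$value) "1" else "0",
      var   = e$name,
      not   = paste0("!", wrap(e$arg, prec[["not"]])),
      apply = if (length(e$args) == 0L) e$sym$name else
        paste0(e$sym$name, "(", paste(vapply(e$args, fmt, ""), collapse = ", "), ")"),
      if (e$op == "imp") {
        # right-associative: parenthesize an implication on the left
        paste0(wrap(e$lhs, prec[[e$op]] + 1), " => ", wrap(e$rhs, prec[[e$op]]))
      } else {
        paste0(wrap(e$lhs, prec[[e$op]]), " ", opch[[e$op]], " ", wrap(e$rhs, prec[[e$op]] + 1))
      }
    )
  }
  wrap <- function(e, outer) {
    s <- fmt(e)
    if (prec[[e$op]] < outer) paste0("(", s, ")") else s
  }
  fmt(e)
}

# --- tokenizer shared by expression and property parsers ---------------------

tokenize_expr <- function(text) {
  pats <- c(ws = "^\\s+", op = "^(<=>|=>|[!&|^(),01])", id = "^[A-Za-z_][A-Za-z0-9_]*")
  toks <- list(); pos <- 1L; s <- text
  while (nchar(s) > 0L) {
    matched <- FALSE
    for (kind in names(pats)) {
      m <- regmatches(s, regexpr(pats[[kind]], s, perl = TRUE))
      if (length(m) == 1L) {
        if (kind != "ws") toks[[length(toks) + 1L]] <- list(kind = kind, text = m, pos = pos)
        pos <- pos + nchar(m)
        s <- substr(s, nchar(m) + 1L, nchar(s))
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("syntax error at position %d: unexpected character '%s'",
                   pos, substr(s, 1, 1)), call. = FALSE)
    }
  }
  toks
}

token_stream <- function(toks) {
  i <- 0L
  list(
    peek = function() if (i < length(toks)) toks[[i + 1L]] else NULL,
    next_tok = function() { i <<- i + 1L; toks[[i]] },
    eat = function(text) {
      tk <- if (i < length(toks)) toks[[i + 1L]] else NULL
      if (is.null(tk) || tk$text != text) {
        stop(sprintf("syntax error at position %d: expected '%s'",
                     if (is.null(tk)) nchar(text) else tk$pos, text), call. = FALSE)
      }
      i <<- i + 1L
      tk
    },
    done = function() i >= length(toks)
  )
}

#' Parse a partially specified Boolean expression
#'
#' Concrete syntax: literals `0`/`1`, variable and symbol identifiers,
#' `!` (negation), `&`, `|`, `^` (xor), `=>` (right-associative implication),
#' `<=>` (equivalence), parentheses, and application `f(e1, e2)`.  Precedence,
#' tightest first: `!`, `&`, `|`, `^`, `=>`, `<=>`.  A zero-arity symbol may be
#' written bare (`f`) or applied (`f()`).
#'
#' @param text expression string
#' @param variables character vector of network variable names
#' @param symbols data frame with columns `name`, `arity` declaring the
#'   uninterpreted function symbols in scope (may be empty)
#' @return expression AST (class `bn_expr`)
#' @examples
#' sym <- data.frame(name = "f", arity = 1)
#' parse_expression("v2 & !f(v3)", c("v1", "v2", "v3"), sym)
#' @export
parse_expression <- function(text, variables, symbols = empty_symbols()) {
  symbols <- as_symbol_table(symbols)
  ts <- token_stream(tokenize_expr(text))

  parse_atom <- function() {
    tk <- ts$peek()
    if (is.null(tk)) stop("syntax error: unexpected end of input", call. = FALSE)
    if (tk$text == "(") {
      ts$next_tok()
      e <- parse_iff()
      ts$eat(")")
      return(e)
    }
    if (tk$text == "0" || tk$text == "1") {
      ts$next_tok()
      return(e_const(tk$text == "1"))
    }
    if (tk$kind == "id") {
      ts$next_tok()
      nm <- tk$text
      nxt <- ts$peek()
      if (!is.null(nxt) && nxt$text == "(") {
        srow <- symbols[symbols$name == nm, ]
        if (nrow(srow) == 0L) {
          stop(sprintf("undeclared function symbol '%s' at position %d", nm, tk$pos), call. = FALSE)
        }
        ts$next_tok()
        args <- list()
        if (!identical(ts$peek()$text, ")")) {
          repeat {
            args[[length(args) + 1L]] <- parse_iff()
            if (identical(ts$peek()$text, ",")) ts$next_tok() else break
          }
        }
        ts$eat(")")
        if (length(args) != srow$arity) {
          stop(sprintf("arity mismatch: '%s' declared with arity %d, applied to %d argument(s)",
                       nm, srow$arity, length(args)), call. = FALSE)
        }
        return(e_apply(list(name = nm, arity = srow$arity), args))
      }
      if (nm %in% variables) return(e_var(nm))
      srow <- symbols[symbols$name == nm, ]
      if (nrow(srow) == 1L && srow$arity == 0L) {
        return(e_apply(list(name = nm, arity = 0L), list()))
      }
      stop(sprintf("undeclared identifier '%s' at position %d", nm, tk$pos), call. = FALSE)
    }
    stop(sprintf("syntax error at position %d: unexpected '%s'", tk$pos, tk$text), call. = FALSE)
  }
  parse_not <- function() {
    if (identical(ts$peek()$text, "!")) {
      ts$next_tok()
      return(e_not(parse_not()))
    }
    parse_atom()
  }
  parse_left <- function(opch, opname, sub) {
    e <- sub()
    while (!is.null(ts$peek()) && ts$peek()$text == opch) {
      ts$next_tok()
      e <- e_bin(opname, e, sub())
    }
    e
  }
  parse_and <- function() parse_left("&", "and", parse_not)
  parse_or  <- function() parse_left("|", "or", parse_and)
  parse_xor <- function() parse_left("^", "xor", parse_or)
  parse_imp <- function() {
    e <- parse_xor()
    if (!is.null(ts$peek()) && ts$peek()$text == "=>") {
      ts$next_tok()
      e <- e_bin("imp", e, parse_imp())   # right-associative
    }
    e
  }
  parse_iff <- function() parse_left("<=>", "iff", parse_imp)

  e <- parse_iff()
  if (!ts$done()) {
    tk <- ts$peek()
    stop(sprintf("syntax error at position %d: trailing input '%s'", tk$pos, tk$text), call. = FALSE)
  }
  e
}

empty_symbols <- function() data.frame(name = character(0), arity = integer(0))

as_symbol_table <- function(symbols) {
  if (is.null(symbols)) return(empty_symbols())
  symbols <- as.data.frame(symbols)
  if (nrow(symbols) == 0L) return(empty_symbols())
  stopifnot(all(c("name", "arity") %in% names(symbols)))
  if (anyDuplicated(symbols$name)) stop("duplicate function symbol names", call. = FALSE)
  if (!all(is_identifier(symbols$name))) stop("invalid symbol name", call. = FALSE)
  symbols$arity <- as.integer(symbols$arity)
  if (any(symbols$arity < 0L)) stop("negative symbol arity", call. = FALSE)
  symbols
}

#' Network variables occurring syntactically in an expression
#'
#' Collects every variable referenced anywhere in the expression, including
#' inside the arguments of uninterpreted symbol applications.
#'
#' @inheritParams format_expression
#' @return character vector of variable names (each once)
#' @export
syntactic_inputs <- function(e) {
  acc <- character(0)
  walk <- function(e) {
    switch(e$op,
      const = NULL,
      var   = acc[[length(acc) + 1L]] <<- e$name,
      not   = walk(e$arg),
      apply = for (a in e$args) walk(a),
      { walk(e$lhs); walk(e$rhs) }
    )
    invisible(NULL)
  }
  walk(e)
  unique(acc)
}

# symbols occurring in an expression, as a name->arity list
expr_symbols <- function(e) {
  acc <- list()
  walk <- function(e) {
    switch(e$op,
      const = NULL, var = NULL,
      not   = walk(e$arg),
      apply = { acc[[e$sym$name]] <<- e$sym$arity; for (a in e$args) walk(a) },
      { walk(e$lhs); walk(e$rhs) }
    )
    invisible(NULL)
  }
  walk(e)
  acc
}

#' Evaluate an expression at a state under an interpretation
#'
#' @inheritParams format_expression
#' @param state named logical/0-1 vector giving the value of every network
#'   variable the expression mentions
#' @param interpretation named list mapping each uninterpreted symbol to its
#'   truth table: a logical vector of length `2^arity`, rows ordered with
#'   argument 1 most significant
#' @return logical scalar
#' @export
evaluate_expression <- function(e, state, interpretation = list()) {
  st <- as.logical(state)
  names(st) <- names(state)
  ev <- function(e) {
    switch(e$op,
      const = e$value,
      var   = {
        v <- st[[e$name]]
        if (is.null(v) || is.na(v)) stop(sprintf("no value for variable '%s'", e$name), call. = FALSE)
        v
      },
      not   = !ev(e$arg),
      and   = ev(e$lhs) && ev(e$rhs),
      or    = ev(e$lhs) || ev(e$rhs),
      imp   = !ev(e$lhs) || ev(e$rhs),
      iff   = ev(e$lhs) == ev(e$rhs),
      xor   = ev(e$lhs) != ev(e$rhs),
      apply = {
        tab <- interpretation[[e$sym$name]]
        if (is.null(tab)) stop(sprintf("no interpretation for symbol '%s'", e$sym$name), call. = FALSE)
        if (length(tab) != 2^e$sym$arity) {
          stop(sprintf("interpretation of '%s' has length %d, expected %d",
                       e$sym$name, length(tab), 2^e$sym$arity), call. = FALSE)
        }
        argv <- vapply(e$args, ev, logical(1))
        as.logical(tab)[bits_to_code(argv) + 1L]
      }
    )
  }
  ev(e)
}

#' Rewrite sugar operators into the negation-conjunction-application core
#'
#' `a | b`, `a => b`, `a <=> b` and `a ^ b` are rewritten using only `!` and
#' `&`; the rewriting preserves the value of [evaluate_expression()] at every
#' state and interpretation.
#'
#' @inheritParams format_expression
#' @return expression AST containing only const/var/not/and/apply nodes
#' @export
desugar_expression <- function(e) {
  d <- desugar_expression
  switch(e$op,
    const = e,
    var   = e,
    not   = e_not(d(e$arg)),
    and   = e_bin("and", d(e$lhs), d(e$rhs)),
    or    = e_not(e_bin("and", e_not(d(e$lhs)), e_not(d(e$rhs)))),
    imp   = e_not(e_bin("and", d(e$lhs), e_not(d(e$rhs)))),
    iff   = {
      l <- d(e$lhs); r <- d(e$rhs)
      # (l & r) | (!l & !r)
      e_not(e_bin("and", e_not(e_bin("and", l, r)), e_not(e_bin("and", e_not(l), e_not(r)))))
    },
    xor   = {
      l <- d(e$lhs); r <- d(e$rhs)
      e_not(e_bin("and", e_not(e_bin("and", l, e_not(r))), e_not(e_bin("and", e_not(l), r))))
    },
    apply = e_apply(e$sym, lapply(e$args, d))
  )
}
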