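# Hybrid CTL: syntax, parser, closedness, desugaring, named formulae.
#
# Concrete syntax: atomic propositions are network variable names; state
# variables are `{x}`-delimited; `!{x}:` binds the current state, `3{x}:` is
# existential and `V{x}:` universal state quantification, `@{x}:` jumps to the
# state named x.  Temporal operators: EX EF EG AX AF AG, E[p U q], A[p U q].
# Boolean connectives: ~  &  |  =>  <=>.

hctl_node <- function(op, ...) structure(list(op = op, ...), class = "hctl")

h_const  <- function(value) hctl_node("const", value = as.logical(value))
h_prop   <- function(name) hctl_node("prop", name = name)
h_svar   <- function(var, orig = var) hctl_node("svar", var = var, orig = orig)
h_not    <- function(arg) hctl_node("not", arg = arg)
h_bin    <- function(op, lhs, rhs) hctl_node(op, lhs = lhs, rhs = rhs)
h_un     <- function(op, arg) hctl_node(op, arg = arg)
h_quant  <- function(op, var, arg, orig = var) hctl_node(op, var = var, orig = orig, arg = arg)

HCTL_UNARY <- c("ex", "ef", "eg", "ax", "af", "ag")
HCTL_QUANT <- c("bind", "exists", "forall", "at")

#' @export
print.hctl <- function(x, ...) {
  cat(format_hctl(x), "\n")
  invisible(x)
}

#' Render an HCTL formula back to its concrete syntax
#'
#' @param f an `hctl` formula
#' @return character scalar
#' @export
format_hctl <- function(f) {
  unch <- c(ex = "EX", ef = "EF", eg = "EG", ax = "AX", af = "AF", ag = "AG")
  qch  <- c(bind = "!", exists = "3", forall = "V", at = "@")
  opch <- c(and = "&", or = "|", imp = "=>", iff = "<=>")
  prec <- c(const = 9, prop = 9, svar = 9, not = 6, ex = 6, ef = 6, eg = 6, ax = 6,
            af = 6, ag = 6, eu = 9, au = 9, and = 5, or = 4, imp = 3, iff = 2,
            bind = 1, exists = 1, forall = 1, at = 1)
  fmt <- function(f) {
    switch(f$op,
      const = if (f$value) "1" else "0",
      prop  = f$name,
      svar  = paste0("{", f$orig, "}"),
      not   = paste0("~", wrap(f$arg, 7)),
      eu    = paste0("E[", fmt(f$lhs), " U ", fmt(f$rhs), "]"),
      au    = paste0("A[", fmt(f$lhs), " U ", fmt(f$rhs), "]"),
      bind  = , exists = , forall = , at =
        paste0(qch[[f$op]], "{", f$orig, "}: ", wrap(f$arg, prec[[f$op]])),
      ex = , ef = , eg = , ax = , af = , ag =
        paste0(unch[[f$op]], " ", wrap(f$arg, 6)),
      if (f$op == "imp") {
        paste0(wrap(f$lhs, prec[[f$op]] + 1), " => ", wrap(f$rhs, prec[[f$op]]))
      } else {
        paste0(wrap(f$lhs, prec[[f$op]]), " ", opch[[f$op]], " ", wrap(f$rhs, prec[[f$op]] + 1))
      }
    )
  }
  wrap <- function(f, outer) {
    s <- fmt(f)
    if (prec[[f$op]] < outer) paste0("(", s, ")") else s
  }
  fmt(f)
}

tokenize_hctl <- function(text) {
  pats <- c(ws = "^\\s+", op = "^(<=>|=>|[~&|!3V@{}:()\\[\\]01])",
            id = "^[A-Za-z_][A-Za-z0-9_]*")
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
    if (!matched) stop(sprintf("HCTL syntax error at position %d", pos), call. = FALSE)
  }
  toks
}

#' Parse an HCTL formula
#'
#' Quantified state variables are alpha-renamed at parse time so that every
#' binder introduces a distinct internal name; the original spelling is kept
#' for printing.  The formula may be open -- use [check_closed()] to test for
#' free state variables.
#'
#' @param text formula string
#' @param variables character vector of network variable names (the atomic
#'   propositions)
#' @return object of class `hctl`
#' @examples
#' parse_hctl("!{x}: AG EF {x}", c("v1", "v2"))
#' @export
parse_hctl <- function(text, variables) {
  ts <- token_stream(tokenize_hctl(text))
  temporal2 <- c(EX = "ex", EF = "ef", EG = "eg", AX = "ax", AF = "af", AG = "ag")
  quants <- c("!" = "bind", "3" = "exists", "V" = "forall", "@" = "at")

  parse_svar_head <- function() {
    ts$eat("{")
    v <- ts$next_tok()
    if (v$kind != "id") stop("expected state-variable name inside {}", call. = FALSE)
    ts$eat("}")
    v$text
  }
  parse_formula <- function() {
    tk <- ts$peek()
    if (!is.null(tk) && tk$text %in% names(quants)) {
      ts$next_tok()
      v <- parse_svar_head()
      ts$eat(":")
      return(h_quant(quants[[tk$text]], v, parse_formula()))
    }
    parse_iff()
  }
  parse_left <- function(opch, opname, sub) {
    e <- sub()
    while (!is.null(ts$peek()) && ts$peek()$text == opch) {
      ts$next_tok(); e <- h_bin(opname, e, sub())
    }
    e
  }
  parse_iff <- function() parse_left("<=>", "iff", parse_imp)
  parse_imp <- function() {
    e <- parse_or()
    if (!is.null(ts$peek()) && ts$peek()$text == "=>") {
      ts$next_tok(); e <- h_bin("imp", e, parse_imp())
    }
    e
  }
  parse_or  <- function() parse_left("|", "or", parse_and)
  parse_and <- function() parse_left("&", "and", parse_unary)
  parse_unary <- function() {
    tk <- ts$peek()
    if (is.null(tk)) stop("HCTL syntax error: unexpected end of input", call. = FALSE)
    if (tk$text == "~") {
      ts$next_tok()
      return(h_not(parse_unary()))
    }
    if (tk$kind == "id" && tk$text %in% names(temporal2)) {
      ts$next_tok()
      return(h_un(temporal2[[tk$text]], parse_unary()))
    }
    if (tk$kind == "id" && tk$text %in% c("E", "A")) {
      ts$next_tok()
      ts$eat("[")
      lhs <- parse_formula()
      u <- ts$next_tok()
      if (u$kind != "id" || u$text != "U") stop("expected 'U' in until operator", call. = FALSE)
      rhs <- parse_formula()
      ts$eat("]")
      return(h_bin(if (tk$text == "E") "eu" else "au", lhs, rhs))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tk <- ts$peek()
    if (is.null(tk)) stop("HCTL syntax error: unexpected end of input", call. = FALSE)
    if (tk$text == "(") {
      ts$next_tok(); e <- parse_formula(); ts$eat(")"); return(e)
    }
    if (tk$text == "{") {
      v <- parse_svar_head()
      return(h_svar(v))
    }
    if (tk$text %in% c("0", "1")) {
      ts$next_tok(); return(h_const(tk$text == "1"))
    }
    if (tk$kind == "id") {
      ts$next_tok()
      if (!(tk$text %in% variables)) {
        stop(sprintf("unknown proposition '%s' at position %d", tk$text, tk$pos), call. = FALSE)
      }
      return(h_prop(tk$text))
    }
    stop(sprintf("HCTL syntax error at position %d: unexpected '%s'", tk$pos, tk$text), call. = FALSE)
  }

  f <- parse_formula()
  if (!ts$done()) {
    stop(sprintf("HCTL syntax error: trailing input at position %d", ts$peek()$pos), call. = FALSE)
  }
  alpha_rename(f)
}

# give every binder a distinct internal name; free occurrences keep their own
alpha_rename <- function(f) {
  used <- character(0)
  fresh <- function(orig) {
    cand <- orig; k <- 1L
    while (cand %in% used) { k <- k + 1L; cand <- paste0(orig, "_", k) }
    used <<- c(used, cand)
    cand
  }
  walk <- function(f, env) {
    switch(f$op,
      const = , prop = f,
      svar  = h_svar(env[[f$orig]] %||% f$orig, f$orig),
      not   = h_not(walk(f$arg, env)),
      ex = , ef = , eg = , ax = , af = , ag = h_un(f$op, walk(f$arg, env)),
      and = , or = , imp = , iff = , eu = , au =
        h_bin(f$op, walk(f$lhs, env), walk(f$rhs, env)),
      at    = h_quant("at", env[[f$orig]] %||% f$orig, walk(f$arg, env), f$orig),
      bind = , exists = , forall = {
        nv <- fresh(f$orig)
        env2 <- env; env2[[f$orig]] <- nv
        h_quant(f$op, nv, walk(f$arg, env2), f$orig)
      }
    )
  }
  walk(f, list())
}

#' Free state variables of a formula
#'
#' @param f an `hctl` formula
#' @return character vector of free state-variable names
#' @export
free_state_vars <- function(f) {
  walk <- function(f, bound) {
    switch(f$op,
      const = , prop = character(0),
      svar  = if (f$var %in% bound) character(0) else f$var,
      not   = walk(f$arg, bound),
      ex = , ef = , eg = , ax = , af = , ag = walk(f$arg, bound),
      and = , or = , imp = , iff = , eu = , au =
        c(walk(f$lhs, bound), walk(f$rhs, bound)),
      at    = c(f$var[!(f$var %in% bound)], walk(f$arg, bound)),
      bind = , exists = , forall = walk(f$arg, c(bound, f$var))
    )
  }
  unique(walk(f, character(0)))
}

#' Does a formula contain no free state variables?
#'
#' Sketch dynamic properties must be closed.
#'
#' @param f an `hctl` formula
#' @return logical scalar
#' @export
check_closed <- function(f) length(free_state_vars(f)) == 0L

#' Desugar a formula to the HCTL core
#'
#' Rewrites `EF p` as `E[1 U p]`, `AF p` as `A[1 U p]`, `EG`/`AG` by duality,
#' `AX p` as `~EX ~p`, universal state quantification as negated existential,
#' and `|`, `=>`, `<=>` via `~` and `&`.  The core operators are
#' const/prop/svar/~/&/EX/EU/AU/bind/exists/at.
#'
#' @param f an `hctl` formula
#' @return core `hctl` formula
#' @export
desugar_hctl <- function(f) {
  d <- desugar_hctl
  switch(f$op,
    const = , prop = , svar = f,
    not   = h_not(d(f$arg)),
    and   = h_bin("and", d(f$lhs), d(f$rhs)),
    or    = h_not(h_bin("and", h_not(d(f$lhs)), h_not(d(f$rhs)))),
    imp   = h_not(h_bin("and", d(f$lhs), h_not(d(f$rhs)))),
    iff   = {
      l <- d(f$lhs); r <- d(f$rhs)
      h_not(h_bin("and", h_not(h_bin("and", l, r)), h_not(h_bin("and", h_not(l), h_not(r)))))
    },
    ex    = h_un("ex", d(f$arg)),
    ef    = h_bin("eu", h_const(TRUE), d(f$arg)),
    af    = h_bin("au", h_const(TRUE), d(f$arg)),
    eg    = h_not(h_bin("au", h_const(TRUE), h_not(d(f$arg)))),
    ag    = h_not(h_bin("eu", h_const(TRUE), h_not(d(f$arg)))),
    ax    = h_not(h_un("ex", h_not(d(f$arg)))),
    eu    = h_bin("eu", d(f$lhs), d(f$rhs)),
    au    = h_bin("au", d(f$lhs), d(f$rhs)),
    bind  = h_quant("bind", f$var, d(f$arg), f$orig),
    exists = h_quant("exists", f$var, d(f$arg), f$orig),
    forall = h_not(h_quant("exists", f$var, h_not(d(f$arg)), f$orig)),
    at    = h_quant("at", f$var, d(f$arg), f$orig)
  )
}

#' Named dynamic-property formulae
#'
#' `attractor_formula()` characterizes attractor membership: a state is in an
#' attractor exactly when every state reachable from it can reach it back
#' (`!{x}: AG EF {x}`).  `fixed_point_formula()` characterizes fixed points
#' under the self-loop convention (`!{x}: AX {x}`).  `shared_basin_formula()`
#' is closed and states that some state can reach two different attractors --
#' two attractors share a (weak) basin.
#'
#' @param var state-variable name used by the binder
#' @return an `hctl` formula
#' @name named_formulae
NULL

#' @rdname named_formulae
#' @export
attractor_formula <- function(var = "x") {
  h_quant("bind", var, h_un("ag", h_un("ef", h_svar(var))))
}

#' @rdname named_formulae
#' @export
fixed_point_formula <- function(var = "x") {
  h_quant("bind", var, h_un("ax", h_svar(var)))
}

#' @rdname named_formulae
#' @export
shared_basin_formula <- function() {
  in_attr <- function(v) h_quant("bind", v, h_un("ag", h_un("ef", h_svar(v))))
  body <- h_bin("and",
    h_bin("and", h_un("ef", h_svar("a")), h_un("ef", h_svar("b"))),
    h_bin("and",
      h_quant("at", "a", in_attr("y")),
      h_quant("at", "b", h_bin("and", in_attr("z"), h_not(h_un("ef", h_svar("a")))))))
  alpha_rename(
    h_quant("exists", "c",
      h_quant("at", "c", h_quant("exists", "a", h_quant("exists", "b", body)))))
}
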