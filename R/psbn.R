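# Partially specified Boolean networks, interpretations, symbol elimination.

#' Construct a partially specified Boolean network
#'
#' A PSBN holds one partially specified update expression per network
#' variable.  Expressions may be given as strings (parsed with
#' [parse_expression()]) or as ASTs.
#'
#' @param variables ordered character vector of variable names
#' @param expressions named list (one entry per variable) of expression
#'   strings or `bn_expr` ASTs
#' @param symbols data frame with columns `name`, `arity`; symbols used by
#'   the expressions must be declared here
#' @return object of class `psbn`
#' @examples
#' psbn(c("v1", "v2"), list(v1 = "g()", v2 = "v1 & !v2"),
#'      symbols = data.frame(name = "g", arity = 0))
#' @export
psbn <- function(variables, expressions, symbols = empty_symbols()) {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (anyDuplicated(variables)) stop("duplicate variable names", call. = FALSE)
  if (!all(is_identifier(variables))) stop("invalid variable name", call. = FALSE)
  symbols <- as_symbol_table(symbols)
  if (any(symbols$name %in% variables)) {
    stop("function symbol names must not clash with variable names", call. = FALSE)
  }
  if (is.null(names(expressions)) || !setequal(names(expressions), variables)) {
    stop("expressions must be a named list covering exactly the variables", call. = FALSE)
  }
  exprs <- lapply(variables, function(v) {
    e <- expressions[[v]]
    if (is.character(e)) e <- parse_expression(e, variables, symbols)
    stopifnot(inherits(e, "bn_expr"))
    bad <- setdiff(syntactic_inputs(e), variables)
    if (length(bad)) stop(sprintf("expression for '%s' references unknown variable '%s'", v, bad[[1]]), call. = FALSE)
    e
  })
  names(exprs) <- variables
  # keep only symbols actually used, in declaration order
  used <- unique(unlist(lapply(exprs, function(e) names(expr_symbols(e)))))
  symbols <- symbols[symbols$name %in% c(used, symbols$name), , drop = FALSE]
  structure(list(variables = variables, expressions = exprs, symbols = symbols),
            class = "psbn")
}

#' @export
print.psbn <- function(x, ...) {
  cat(sprintf("Partially specified Boolean network over %d variable(s)\n", length(x$variables)))
  for (v in x$variables) cat(sprintf("  %s <- %s\n", v, format_expression(x$expressions[[v]])))
  if (nrow(x$symbols)) {
    cat("  symbols:", paste(sprintf("%s/%d", x$symbols$name, x$symbols$arity), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a fully specified Boolean network
#'
#' @param variables ordered character vector of variable names
#' @param tables named list of logical truth tables, one per variable, each of
#'   length `2^n` over the full state space (state bits read with `v1` most
#'   significant)
#' @return object of class `boolean_network`
#' @export
boolean_network <- function(variables, tables) {
  n <- length(variables)
  stopifnot(is.character(variables), n >= 1L)
  if (is.null(names(tables)) || !setequal(names(tables), variables)) {
    stop("tables must be a named list covering exactly the variables", call. = FALSE)
  }
  tables <- lapply(tables[variables], function(tab) {
    tab <- as.logical(tab)
    if (length(tab) != 2^n || anyNA(tab)) stop("each truth table must be logical of length 2^n", call. = FALSE)
    tab
  })
  names(tables) <- variables
  structure(list(variables = variables, tables = tables), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network over %d variable(s): %s\n",
              length(x$variables), paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' @export
format.boolean_network <- function(x, ...) {
  paste(vapply(x$variables, function(v) paste(as.integer(x$tables[[v]]), collapse = ""), ""),
        collapse = "|")
}

bn_equal <- function(a, b) {
  identical(a$variables, b$variables) && identical(format(a), format(b))
}

#' Specialize a PSBN under an interpretation
#'
#' Substitutes a concrete Boolean function (truth table) for every
#' uninterpreted symbol, producing a fully specified network.
#'
#' @param x a `psbn`
#' @param interpretation named list mapping every symbol of `x` to a logical
#'   truth table of length `2^arity` (rows ordered argument-1-most-significant)
#' @return a `boolean_network`
#' @export
specialize <- function(x, interpretation = list()) {
  stopifnot(inherits(x, "psbn"))
  missing <- setdiff(x$symbols$name, names(interpretation))
  if (length(missing)) {
    stop(sprintf("interpretation does not cover symbol(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- length(x$variables)
  states <- all_bit_rows(n)
  tables <- lapply(x$expressions, function(e) {
    vapply(seq_len(2^n), function(s) {
      st <- states[s, ] == 1L
      names(st) <- x$variables
      evaluate_expression(e, st, interpretation)
    }, logical(1))
  })
  boolean_network(x$variables, tables)
}

#' Essential inputs of an update function
#'
#' A variable is essential (a member of the dependency set) when toggling it
#' changes the function's output in at least one state.
#'
#' @param table logical truth table of length `2^n` over the full state space
#' @param variables character vector of the `n` variable names ordering the
#'   table rows (first name most significant)
#' @return character vector: the essential variables
#' @export
dep_set <- function(table, variables) {
  n <- length(variables)
  table <- as.logical(table)
  if (length(table) != 2^n) stop("table length must be 2^(number of variables)", call. = FALSE)
  ess <- vapply(seq_len(n), function(j) {
    flip <- flip_index(n, j)
    any(table != table[flip])
  }, logical(1))
  variables[ess]
}

# fresh constant names encoding a symbol's truth table, one per row
constant_names <- function(sym_name, arity, taken) {
  rows <- apply(all_bit_rows(arity), 1L, paste, collapse = "")
  nms <- if (arity == 0L) sym_name else paste0(sym_name, "_", rows)
  while (any(nms %in% taken)) nms <- paste0(nms, "_")
  nms
}

#' Eliminate uninterpreted function symbols of positive arity
#'
#' Every application `f(e1, ..., ea)` with `a > 0` is replaced by its
#' row-selection expansion over `2^a` fresh zero-arity constants encoding the
#' truth table of `f`: the disjunction over all argument rows `b` of
#' `c_f_b & (e1 <=> b1) & ... & (ea <=> ba)`.  Zero-arity symbols pass through
#' unchanged and serve as their own constants.
#'
#' @param x a `psbn`
#' @param arity_cap refuse symbols above this arity (the expansion has `2^a`
#'   constants per symbol)
#' @return list with components `psbn` (the eliminated network, containing
#'   only zero-arity symbols) and `table`: the symbol table, a named list
#'   mapping each original symbol to the character vector of its constants in
#'   truth-table row order
#' @export
eliminate_symbols <- function(x, arity_cap = 8L) {
  stopifnot(inherits(x, "psbn"))
  if (any(x$symbols$arity > arity_cap)) {
    stop(sprintf("symbol arity above cap (%d); raise arity_cap if intended", arity_cap), call. = FALSE)
  }
  taken <- c(x$variables, x$symbols$name)
  symtab <- list()
  for (i in seq_len(nrow(x$symbols))) {
    nm <- x$symbols$name[i]; a <- x$symbols$arity[i]
    cn <- if (a == 0L) nm else {
      cn <- constant_names(nm, a, taken)
      taken <- c(taken, cn)
      cn
    }
    symtab[[nm]] <- cn
  }
  rewrite <- function(e) {
    switch(e$op,
      const = e, var = e,
      not   = e_not(rewrite(e$arg)),
      apply = {
        a <- e$sym$arity
        if (a == 0L) return(e)
        args <- lapply(e$args, rewrite)
        consts <- symtab[[e$sym$name]]
        rows <- all_bit_rows(a)
        terms <- lapply(seq_len(2^a), function(r) {
          sel <- e_apply(list(name = consts[r], arity = 0L), list())
          for (j in seq_len(a)) {
            lit <- if (rows[r, j] == 1L) args[[j]] else e_not(args[[j]])
            sel <- e_bin("and", sel, lit)
          }
          sel
        })
        Reduce(function(l, r) e_bin("or", l, r), terms)
      },
      e_bin(e$op, rewrite(e$lhs), rewrite(e$rhs))
    )
  }
  exprs <- lapply(x$expressions, rewrite)
  consts <- unlist(symtab, use.names = FALSE)
  out <- structure(list(
    variables = x$variables,
    expressions = exprs,
    symbols = data.frame(name = consts, arity = rep(0L, length(consts)))
  ), class = "psbn")
  list(psbn = out, table = symtab)
}

#' Reconstruct an interpretation from a constant valuation
#'
#' Inverts [eliminate_symbols()]: given a truth value for every constant, the
#' original symbols' truth tables are read off row by row, so that
#' specializing the original PSBN under the result equals specializing the
#' eliminated PSBN under the valuation.
#'
#' @param table symbol table returned by [eliminate_symbols()]
#' @param valuation named logical vector covering every constant in `table`
#' @return named list of truth tables (an interpretation)
#' @export
interpretation_from_constants <- function(table, valuation) {
  val <- as.logical(valuation)
  names(val) <- names(valuation)
  lapply(table, function(consts) {
    missing <- setdiff(consts, names(val))
    if (length(missing)) {
      stop(sprintf("valuation does not cover constant(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
    }
    unname(val[consts])
  })
}

# all interpretations of a symbol table (for small oracle-scale enumeration)
enumerate_interpretations <- function(symbols) {
  symbols <- as_symbol_table(symbols)
  tabs <- lapply(seq_len(nrow(symbols)), function(i) {
    k <- 2^symbols$arity[i]
    lapply(0:(2^k - 1L), function(code) code_to_bits(code, k) == 1L)
  })
  if (length(tabs) == 0L) return(list(stats::setNames(list(), character(0))))
  grid <- do.call(expand.grid, c(lapply(rev(tabs), seq_along), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # first symbol slowest
  lapply(seq_len(nrow(grid)), function(r) {
    ii <- as.integer(grid[r, ])
    stats::setNames(lapply(seq_along(tabs), function(j) tabs[[j]][[ii[j]]]), symbols$name)
  })
}
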