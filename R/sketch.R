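# Influence graphs, update-function properties, and the sketch container.

#' Construct an influence graph
#'
#' A binary relation of admissible regulator -> target dependencies.  A
#' Boolean network is consistent with the graph when every essential input of
#' every update function is a listed regulator of that variable (the converse
#' is not required).
#'
#' @param variables ordered character vector of variable names
#' @param edges two-column matrix or data frame of `(regulator, target)` pairs
#' @return object of class `influence_graph`
#' @export
influence_graph <- function(variables, edges) {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (anyDuplicated(variables)) stop("duplicate variable names", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns (regulator, target)", call. = FALSE)
  mode(edges) <- "character"
  bad <- setdiff(c(edges), variables)
  if (length(bad)) stop(sprintf("edge references unknown variable '%s'", bad[[1]]), call. = FALSE)
  edges <- unique(edges)
  colnames(edges) <- c("regulator", "target")
  structure(list(variables = variables, edges = edges), class = "influence_graph")
}

#' @export
print.influence_graph <- function(x, ...) {
  cat(sprintf("Influence graph: %d variable(s), %d edge(s)\n",
              length(x$variables), nrow(x$edges)))
  invisible(x)
}

#' Regulators admitted for a target variable
#'
#' @param ig an `influence_graph`
#' @param target variable name
#' @return character vector of regulators
#' @export
predecessors <- function(ig, target) {
  stopifnot(inherits(ig, "influence_graph"))
  unname(ig$edges[ig$edges[, "target"] == target, "regulator"])
}

#' Syntactic consistency of a PSBN with an influence graph
#'
#' True when, for every variable, the variables occurring in its update
#' expression are all admitted regulators.
#'
#' @param x a `psbn`
#' @param ig an `influence_graph` over the same variables
#' @return logical scalar
#' @export
check_ig_consistency <- function(x, ig) {
  stopifnot(inherits(x, "psbn"), inherits(ig, "influence_graph"))
  if (!identical(x$variables, ig$variables)) {
    stop("PSBN and influence graph must share one variable ordering", call. = FALSE)
  }
  all(vapply(x$variables, function(v) {
    all(syntactic_inputs(x$expressions[[v]]) %in% predecessors(ig, v))
  }, logical(1)))
}

#' Count the Boolean networks consistent with an influence graph
#'
#' Any function over the admitted regulators of each variable qualifies, so
#' the count is the product over variables of `2^(2^in_degree)` -- always a
#' power of two, returned exactly at arbitrary precision.
#'
#' @param ig an `influence_graph`
#' @return a `bnsketch_count`: exact decimal string with an `exponent`
#'   attribute; coerce with `as.numeric()` when small enough
#' @examples
#' ig <- influence_graph(c("v1", "v2"), rbind(c("v1", "v1"), c("v2", "v2")))
#' count_ig_consistent(ig)  # 16
#' @export
count_ig_consistent <- function(ig) {
  stopifnot(inherits(ig, "influence_graph"))
  indeg <- vapply(ig$variables, function(v) length(predecessors(ig, v)), integer(1))
  big_count(sum(2^indeg))
}

# --- update-function properties ---------------------------------------------

prop_node <- function(op, ...) structure(list(op = op, ...), class = "bn_prop")

#' Update-function property atoms and connectives
#'
#' First-order predicates over the Boolean function computed by an update
#' expression.  Atoms reference network variables (mapped to state bits):
#' `prop_essential(v)` -- toggling `v` changes the output somewhere;
#' `prop_positive(v)` / `prop_negative(v)` -- non-strict monotonicity in `v`;
#' `prop_canalizing(v, in_value, out_value)` -- `v = in_value` forces the
#' output to `out_value`; `prop_veto(v, sign)` -- `v = sign` forces output 0.
#' Atoms combine with `prop_not`, `prop_and`, `prop_or`, `prop_imp`.
#'
#' @param variable network variable name the atom refers to
#' @param in_value,out_value,sign 0/1 values parameterizing canalization
#' @param p,q properties to combine
#' @return object of class `bn_prop`
#' @name function_properties
NULL

#' @rdname function_properties
#' @export
prop_essential <- function(variable) prop_node("essential", variable = variable)

#' @rdname function_properties
#' @export
prop_positive <- function(variable) prop_node("positive", variable = variable)

#' @rdname function_properties
#' @export
prop_negative <- function(variable) prop_node("negative", variable = variable)

#' @rdname function_properties
#' @export
prop_canalizing <- function(variable, in_value, out_value) {
  prop_node("canalizing", variable = variable,
            in_value = as.integer(in_value), out_value = as.integer(out_value))
}

#' @rdname function_properties
#' @export
prop_veto <- function(variable, sign) prop_canalizing(variable, sign, 0L)

#' @rdname function_properties
#' @export
prop_not <- function(p) prop_node("not", arg = p)

#' @rdname function_properties
#' @export
prop_and <- function(p, q) prop_node("and", lhs = p, rhs = q)

#' @rdname function_properties
#' @export
prop_or <- function(p, q) prop_node("or", lhs = p, rhs = q)

#' @rdname function_properties
#' @export
prop_imp <- function(p, q) prop_node("imp", lhs = p, rhs = q)

#' @export
print.bn_prop <- function(x, ...) {
  cat(format_property(x), "\n")
  invisible(x)
}

#' @export
format_property <- function(p) {
  fmt <- function(p) {
    switch(p$op,
      essential  = sprintf("essential(%s)", p$variable),
      positive   = sprintf("positive(%s)", p$variable),
      negative   = sprintf("negative(%s)", p$variable),
      canalizing = sprintf("canalizing(%s, %d, %d)", p$variable, p$in_value, p$out_value),
      not        = sprintf("!(%s)", fmt(p$arg)),
      and        = sprintf("(%s) & (%s)", fmt(p$lhs), fmt(p$rhs)),
      or         = sprintf("(%s) | (%s)", fmt(p$lhs), fmt(p$rhs)),
      imp        = sprintf("(%s) => (%s)", fmt(p$lhs), fmt(p$rhs))
    )
  }
  fmt(p)
}

#' Parse a property string
#'
#' Concrete syntax: atoms `essential(v)`, `positive(v)`, `negative(v)`,
#' `canalizing(v, a, b)`, `veto(v, s)` with `a`, `b`, `s` in `{0, 1}`;
#' connectives `!`, `&`, `|`, `=>` with the same precedence as expressions.
#'
#' @param text property string
#' @param variables character vector of network variable names
#' @return a `bn_prop`
#' @export
parse_property <- function(text, variables) {
  ts <- token_stream(tokenize_expr(text))
  atoms1 <- c("essential", "positive", "negative")
  parse_atom <- function() {
    tk <- ts$peek()
    if (is.null(tk)) stop("syntax error: unexpected end of property", call. = FALSE)
    if (tk$text == "(") {
      ts$next_tok(); e <- parse_imp(); ts$eat(")"); return(e)
    }
    if (tk$text == "!") {
      ts$next_tok(); return(prop_not(parse_atom()))
    }
    if (tk$kind != "id") stop(sprintf("syntax error at position %d in property", tk$pos), call. = FALSE)
    ts$next_tok()
    kind <- tk$text
    ts$eat("(")
    v <- ts$next_tok()
    if (v$kind != "id" || !(v$text %in% variables)) {
      stop(sprintf("unknown variable '%s' in property", v$text), call. = FALSE)
    }
    res <- if (kind %in% atoms1) {
      prop_node(kind, variable = v$text)
    } else if (kind == "canalizing") {
      ts$eat(","); a <- ts$next_tok(); ts$eat(","); b <- ts$next_tok()
      prop_canalizing(v$text, as.integer(a$text), as.integer(b$text))
    } else if (kind == "veto") {
      ts$eat(","); s <- ts$next_tok()
      prop_veto(v$text, as.integer(s$text))
    } else {
      stop(sprintf("unknown property atom '%s'", kind), call. = FALSE)
    }
    ts$eat(")")
    res
  }
  parse_left <- function(opch, ctor, sub) {
    e <- sub()
    while (!is.null(ts$peek()) && ts$peek()$text == opch) {
      ts$next_tok(); e <- ctor(e, sub())
    }
    e
  }
  parse_and <- function() parse_left("&", prop_and, parse_atom)
  parse_or  <- function() parse_left("|", prop_or, parse_and)
  parse_imp <- function() {
    e <- parse_or()
    if (!is.null(ts$peek()) && ts$peek()$text == "=>") {
      ts$next_tok(); e <- prop_imp(e, parse_imp())
    }
    e
  }
  res <- parse_imp()
  if (!ts$done()) stop("trailing input in property", call. = FALSE)
  res
}

#' Colours for which a property holds of an eliminated expression
#'
#' Evaluates a first-order update-function property against a symbol-free
#' expression (only zero-arity constants remain), returning the set of
#' constant valuations -- colours -- under which the induced Boolean function
#' satisfies the property.  State quantifiers inside the atoms are eliminated
#' bit-parallel across all colours at once.
#'
#' @param p a `bn_prop`
#' @param e expression containing only zero-arity symbols (from
#'   [eliminate_symbols()])
#' @param variables network variable names
#' @param constants character vector fixing the colour bit order (first
#'   constant most significant)
#' @return logical vector of length `2^length(constants)`: `TRUE` for colours
#'   satisfying the property
#' @export
evaluate_property <- function(p, e, variables, constants) {
  n <- length(variables)
  M <- compile_truth_matrix(e, variables, constants)  # 2^n x 2^m
  ev <- function(p) {
    switch(p$op,
      essential = {
        j <- match(p$variable, variables)
        if (is.na(j)) stop(sprintf("unknown variable '%s'", p$variable), call. = FALSE)
        colSums(M != M[flip_index(n, j), , drop = FALSE]) > 0L
      },
      positive = {
        j <- match(p$variable, variables)
        r0 <- which(!state_bit_column(n, j))
        r1 <- flip_index(n, j)[r0]
        colSums(M[r0, , drop = FALSE] & !M[r1, , drop = FALSE]) == 0L
      },
      negative = {
        j <- match(p$variable, variables)
        r0 <- which(!state_bit_column(n, j))
        r1 <- flip_index(n, j)[r0]
        colSums(M[r1, , drop = FALSE] & !M[r0, , drop = FALSE]) == 0L
      },
      canalizing = {
        j <- match(p$variable, variables)
        rows <- which(state_bit_column(n, j) == (p$in_value == 1L))
        colSums(M[rows, , drop = FALSE] != (p$out_value == 1L)) == 0L
      },
      not = !ev(p$arg),
      and = ev(p$lhs) & ev(p$rhs),
      or  = ev(p$lhs) | ev(p$rhs),
      imp = !ev(p$lhs) | ev(p$rhs)
    )
  }
  ev(p)
}

#' A property attached to one update expression
#'
#' @param target variable name whose update expression the property constrains
#' @param property a `bn_prop` or property string (parsed against `variables`
#'   when the item is added to a sketch)
#' @return object of class `ufp_item`
#' @export
ufp_item <- function(target, property) {
  structure(list(target = target, property = property), class = "ufp_item")
}

#' Intersection of property evaluations over a PSBN
#'
#' @param items list of [ufp_item()]s
#' @param x eliminated `psbn` (only zero-arity symbols)
#' @return logical colour vector; all-`FALSE` signals an unrealizable
#'   property set
#' @export
ufp_constraint <- function(items, x) {
  stopifnot(inherits(x, "psbn"))
  constants <- x$symbols$name
  res <- rep(TRUE, 2^length(constants))
  for (it in items) {
    if (!(it$target %in% x$variables)) {
      stop(sprintf("property targets unknown variable '%s'", it$target), call. = FALSE)
    }
    p <- it$property
    if (is.character(p)) p <- parse_property(p, x$variables)
    res <- res & evaluate_property(p, x$expressions[[it$target]], x$variables, constants)
  }
  res
}

#' Assemble a Boolean network sketch
#'
#' The sketch is the tuple of an influence graph, a partially specified
#' network, a set of update-function properties and a set of closed HCTL
#' formulae (dynamic properties, including any data-derived constraints).
#'
#' @param ig an `influence_graph`
#' @param network a `psbn` over the same variables
#' @param properties list of [ufp_item()]s (property strings are parsed)
#' @param dynamics list of HCTL formulae or formula strings; every formula
#'   must be closed
#' @return object of class `bn_sketch`
#' @export
bn_sketch <- function(ig, network, properties = list(), dynamics = list()) {
  stopifnot(inherits(ig, "influence_graph"), inherits(network, "psbn"))
  if (!identical(ig$variables, network$variables)) {
    stop("influence graph and PSBN must share one variable ordering", call. = FALSE)
  }
  properties <- lapply(properties, function(it) {
    stopifnot(inherits(it, "ufp_item"))
    p <- it$property
    if (is.character(p)) p <- parse_property(p, network$variables)
    ufp_item(it$target, p)
  })
  dynamics <- lapply(dynamics, function(f) {
    if (is.character(f)) f <- parse_hctl(f, network$variables)
    stopifnot(inherits(f, "hctl"))
    if (!check_closed(f)) stop("dynamic properties must not contain free state variables", call. = FALSE)
    f
  })
  structure(list(ig = ig, network = network, properties = properties, dynamics = dynamics),
            class = "bn_sketch")
}

#' @export
print.bn_sketch <- function(x, ...) {
  cat(sprintf("Boolean network sketch: %d variable(s), %d influence(s), %d propert%s, %d dynamic formula(e)\n",
              length(x$network$variables), nrow(x$ig$edges), length(x$properties),
              if (length(x$properties) == 1L) "y" else "ies", length(x$dynamics)))
  invisible(x)
}
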