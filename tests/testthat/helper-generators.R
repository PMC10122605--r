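# Shared generators and tiny reference helpers for the test suite.

# a fully specified one-variable network from a truth table
bn1 <- function(bits) boolean_network("v1", list(v1 = as.logical(bits)))

# random expression tree over given variables/symbols (concrete-syntax level)
random_expr_string <- function(variables, symbols, depth = 3L) {
  gen <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.25) {
      pick <- stats::runif(1)
      if (pick < 0.15) return(sample(c("0", "1"), 1L))
      if (pick < 0.75 || nrow(symbols) == 0L) return(sample(variables, 1L))
      i <- sample.int(nrow(symbols), 1L)
      args <- replicate(symbols$arity[i], gen(d - 1L))
      return(sprintf("%s(%s)", symbols$name[i], paste(args, collapse = ", ")))
    }
    op <- sample(c("!", "&", "|", "^", "=>", "<=>"), 1L)
    if (op == "!") sprintf("!(%s)", gen(d - 1L))
    else sprintf("(%s) %s (%s)", gen(d - 1L), op, gen(d - 1L))
  }
  gen(depth)
}

# random closed HCTL formula in concrete syntax; at most `max_quant` binders
random_hctl_string <- function(variables, depth = 4L, max_quant = 2L) {
  quant_used <- 0L
  gen <- function(d, bound) {
    atoms <- c(variables, "0", "1", if (length(bound)) paste0("{", bound, "}"))
    if (d <= 0L) return(sample(atoms, 1L))
    r <- stats::runif(1)
    if (r < 0.18 && quant_used < max_quant) {
      quant_used <<- quant_used + 1L
      v <- paste0("q", quant_used)
      q <- sample(c("!", "3", "V"), 1L)
      return(sprintf("(%s{%s}: %s)", q, v, gen(d - 1L, c(bound, v))))
    }
    if (r < 0.26 && length(bound)) {
      return(sprintf("(@{%s}: %s)", sample(bound, 1L), gen(d - 1L, bound)))
    }
    if (r < 0.5) {
      op <- sample(c("EX", "EF", "EG", "AX", "AF", "AG"), 1L)
      return(sprintf("%s (%s)", op, gen(d - 1L, bound)))
    }
    if (r < 0.62) {
      pq <- sample(c("E", "A"), 1L)
      return(sprintf("%s[(%s) U (%s)]", pq, gen(d - 1L, bound), gen(d - 1L, bound)))
    }
    if (r < 0.72) return(sprintf("~(%s)", gen(d - 1L, bound)))
    op <- sample(c("&", "|", "=>", "<=>"), 1L)
    sprintf("(%s) %s (%s)", gen(d - 1L, bound), op, gen(d - 1L, bound))
  }
  gen(depth, character(0))
}

# random fully specified network over n variables
random_bn <- function(n) {
  vars <- paste0("v", seq_len(n))
  tabs <- lapply(vars, function(v) stats::runif(2^n) < 0.5)
  names(tabs) <- vars
  boolean_network(vars, tabs)
}

# a psbn whose expressions reproduce a concrete network (for symbolic runs)
bn_as_psbn <- function(bn) {
  exprs <- lapply(bn$variables, function(v) {
    ex <- bnsketch:::table_to_expression(bn$tables[[v]], bn$variables)
    format_expression(ex)
  })
  names(exprs) <- bn$variables
  psbn(bn$variables, exprs)
}

# reference truth table of an expression under an interpretation (scalar path)
expr_table <- function(e, variables, interp = list()) {
  n <- length(variables)
  vapply(seq_len(2^n), function(s) {
    st <- bnsketch:::code_to_bits(s - 1L, n) == 1L
    names(st) <- variables
    evaluate_expression(e, st, interp)
  }, logical(1))
}

# independent in-test checker for property atoms on a concrete table
check_atom <- function(kind, table, variables, v, in_value = NULL, out_value = NULL) {
  n <- length(variables)
  j <- match(v, variables)
  states <- bnsketch:::all_bit_rows(n)
  val <- function(bits) table[bnsketch:::bits_to_code(bits) + 1L]
  pairs <- lapply(which(states[, j] == 0L), function(r) {
    b0 <- states[r, ]; b1 <- b0; b1[j] <- 1L
    c(val(b0), val(b1))
  })
  switch(kind,
    essential = any(vapply(pairs, function(p) p[1] != p[2], logical(1))),
    positive  = all(vapply(pairs, function(p) !p[1] || p[2], logical(1))),
    negative  = all(vapply(pairs, function(p) !p[2] || p[1], logical(1))),
    canalizing = {
      rows <- which(states[, j] == in_value)
      all(table[rows] == (out_value == 1L))
    })
}
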