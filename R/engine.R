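# Bit-parallel symbolic engine: truth matrices, the coloured asynchronous
# state-transition graph, and relational image operators.
#
# A "colour" is a valuation of the zero-arity parameter constants produced by
# symbol elimination; the engine evaluates all colours of interest at once.
# Symbolic sets are dense logical arrays with one dimension for the state,
# one dimension per bound/free HCTL state variable and one for the colour:
# the same set-level algorithm structure (relational products, fixpoints,
# quantifier elimination) as a decision-diagram engine, represented flat.
# This is adequate for the desk-scale networks the package targets
# (state bits + colour bits of a few dozen in total).

MAX_CELLS <- 2^27  # guard on state x colour matrix size

#' Compile a symbol-free expression to a state-by-colour truth matrix
#'
#' @param e expression whose only symbols are zero-arity constants
#' @param variables network variable names (state bits, first most
#'   significant)
#' @param constants constant names fixing the colour bit order
#' @param colour_bits optional logical matrix (colours x constants) selecting
#'   and ordering the colours to evaluate; defaults to the full colour space
#'   in lexicographic order
#' @return logical matrix `2^n x n_colours`; entry `(s, c)` is the value of
#'   `e` at state `s` under colour `c`
#' @export
compile_truth_matrix <- function(e, variables, constants, colour_bits = NULL) {
  n <- length(variables)
  m <- length(constants)
  if (is.null(colour_bits)) {
    colour_bits <- all_bit_rows(m) == 1L
    if (m == 0L) colour_bits <- matrix(logical(0), nrow = 1L, ncol = 0L)
  }
  colnames(colour_bits) <- constants
  S <- 2^n; K <- nrow(colour_bits)
  if (S * K > MAX_CELLS) stop("state x colour space too large for the dense engine", call. = FALSE)
  ev <- function(e) {
    switch(e$op,
      const = matrix(e$value, S, K),
      var   = {
        j <- match(e$name, variables)
        matrix(state_bit_column(n, j), S, K)
      },
      apply = {
        if (e$sym$arity != 0L) stop("expression not eliminated: positive-arity symbol remains", call. = FALSE)
        j <- match(e$sym$name, constants)
        if (is.na(j)) stop(sprintf("unknown constant '%s'", e$sym$name), call. = FALSE)
        matrix(rep(colour_bits[, j], each = S), S, K)
      },
      not   = !ev(e$arg),
      and   = ev(e$lhs) & ev(e$rhs),
      or    = ev(e$lhs) | ev(e$rhs),
      imp   = !ev(e$lhs) | ev(e$rhs),
      iff   = ev(e$lhs) == ev(e$rhs),
      xor   = ev(e$lhs) != ev(e$rhs)
    )
  }
  ev(e)
}

#' Build the coloured asynchronous state-transition graph
#'
#' For every network variable `i` and colour `c` the graph contains the
#' transition `s -> s[i := E'_i(s, c)]` whenever that changes `s`; a state
#' carries a self-loop exactly when no variable can change (making the
#' relation total).  All colours are represented at once; per-variable
#' transition structure is kept separate, the standard practice for
#' asynchronous semantics.
#'
#' @param x eliminated `psbn` (only zero-arity symbols)
#' @param colours optional restriction of the colour space: a logical vector
#'   over the full lexicographic colour space, or a logical matrix of colour
#'   bit rows
#' @return object of class `coloured_stg`
#' @export
build_coloured_stg <- function(x, colours = NULL) {
  stopifnot(inherits(x, "psbn"))
  constants <- x$symbols$name
  m <- length(constants)
  colour_bits <-
    if (is.null(colours)) {
      if (m == 0L) matrix(logical(0), 1L, 0L) else all_bit_rows(m) == 1L
    } else if (is.matrix(colours)) {
      colours
    } else {
      full <- if (m == 0L) matrix(logical(0), 1L, 0L) else all_bit_rows(m) == 1L
      full[as.logical(colours), , drop = FALSE]
    }
  n <- length(x$variables)
  S <- 2^n; K <- nrow(colour_bits)
  Fmat <- lapply(x$expressions, compile_truth_matrix,
                 variables = x$variables, constants = constants, colour_bits = colour_bits)
  can_flip <- lapply(seq_len(n), function(i) {
    Fmat[[i]] != matrix(state_bit_column(n, i), S, K)
  })
  fixed <- Reduce(`&`, lapply(can_flip, `!`))
  flips <- lapply(seq_len(n), function(i) flip_index(n, i))
  structure(list(variables = x$variables, n = n, S = S,
                 constants = constants, colour_bits = colour_bits, K = K,
                 Fmat = Fmat, can_flip = can_flip, fixed = fixed, flips = flips),
            class = "coloured_stg")
}

#' @export
print.coloured_stg <- function(x, ...) {
  cat(sprintf("Coloured asynchronous STG: %d state(s) x %d colour(s), %d parameter constant(s)\n",
              x$S, x$K, length(x$constants)))
  invisible(x)
}

# 0-based lexicographic code of each colour row (constant 1 most significant)
colour_codes <- function(colour_bits) {
  m <- ncol(colour_bits)
  if (m == 0L) return(rep(0, nrow(colour_bits)))
  as.numeric(colour_bits %*% 2^((m - 1L):0L))
}

# --- symbolic sets -----------------------------------------------------------

# arr has dim c(S, S^..one per var in sorted order.., K); vars sorted
symbolic_set <- function(stg, arr, vars = character(0)) {
  structure(list(stg = stg, arr = arr, vars = vars), class = "symbolic_set")
}

ss_fill <- function(stg, value, vars = character(0)) {
  d <- c(stg$S, rep(stg$S, length(vars)), stg$K)
  symbolic_set(stg, array(value, d), vars)
}

#' @export
print.symbolic_set <- function(x, ...) {
  cat(sprintf("Symbolic set over (state%s, colour): %d of %d cells\n",
              if (length(x$vars)) paste0(", ", paste(x$vars, collapse = ", ")) else "",
              sum(x$arr), length(x$arr)))
  invisible(x)
}

# insert a dimension of given size at position pos (1-based) of an array
insert_dim <- function(arr, pos, size) {
  d <- dim(arr)
  pre <- if (pos == 1L) 1L else prod(d[seq_len(pos - 1L)])
  post <- prod(d) / pre
  m <- matrix(arr, nrow = pre)
  out <- m[, rep(seq_len(post), each = size), drop = FALSE]
  array(out, c(d[seq_len(pos - 1L)], size, d[seq(pos, length(d))]))
}

# extend a set with extra (unconstrained) state-variable dimensions
ss_expand <- function(x, vars_target) {
  add <- setdiff(vars_target, x$vars)
  for (v in add) {
    newvars <- sort(c(x$vars, v))
    pos <- match(v, newvars) + 1L  # dim 1 is the state
    x$arr <- insert_dim(x$arr, pos, x$stg$S)
    x$vars <- newvars
  }
  x
}

ss_align <- function(x, y) {
  vars <- sort(union(x$vars, y$vars))
  list(ss_expand(x, vars), ss_expand(y, vars))
}

ss_not <- function(x) { x$arr <- !x$arr; x }
ss_and <- function(x, y) { a <- ss_align(x, y); a[[1]]$arr <- a[[1]]$arr & a[[2]]$arr; a[[1]] }
ss_or  <- function(x, y) { a <- ss_align(x, y); a[[1]]$arr <- a[[1]]$arr | a[[2]]$arr; a[[1]] }
ss_equal <- function(x, y) identical(x$arr, y$arr) && identical(x$vars, y$vars)

# characteristic set of "current state equals state variable v"
ss_svar_eq <- function(stg, v) {
  eq <- outer(seq_len(stg$S), seq_len(stg$S), `==`)
  arr <- array(rep(eq, stg$K), c(stg$S, stg$S, stg$K))
  symbolic_set(stg, arr, v)
}

# broadcast an S x K matrix across the aux dimensions of a set shaped like x
stg_matrix_cols <- function(stg, M, A) {
  if (A == 1L) M else M[, rep(seq_len(stg$K), each = A), drop = FALSE]
}

#' Predecessor and successor images under the coloured transition relation
#'
#' `pre_image(x)` returns the states (per colour, per bound-state-variable
#' context) with at least one successor in `x`; `post_image(x)` the states
#' with at least one predecessor in `x`.  Each colour steps only under its
#' own transition relation; self-loops at fixed points are included.
#'
#' @param x a `symbolic_set`
#' @return a `symbolic_set` over the same variables
#' @export
pre_image <- function(x) {
  stg <- x$stg
  d <- dim(x$arr)
  S <- stg$S
  m <- matrix(x$arr, nrow = S)
  A <- ncol(m) / stg$K
  res <- stg_matrix_cols(stg, stg$fixed, A) & m
  for (i in seq_len(stg$n)) {
    cf <- stg_matrix_cols(stg, stg$can_flip[[i]], A)
    res <- res | (cf & m[stg$flips[[i]], , drop = FALSE])
  }
  symbolic_set(stg, array(res, d), x$vars)
}

#' @rdname pre_image
#' @export
post_image <- function(x) {
  stg <- x$stg
  d <- dim(x$arr)
  S <- stg$S
  m <- matrix(x$arr, nrow = S)
  A <- ncol(m) / stg$K
  res <- stg_matrix_cols(stg, stg$fixed, A) & m
  for (i in seq_len(stg$n)) {
    cf <- stg_matrix_cols(stg, stg$can_flip[[i]], A)
    fl <- stg$flips[[i]]
    res <- res | (cf[fl, , drop = FALSE] & m[fl, , drop = FALSE])
  }
  symbolic_set(stg, array(res, d), x$vars)
}

# index list for subsetting an array with fixed values at some dims
dim_index <- function(d, fixed) {
  idx <- lapply(d, seq_len)
  for (p in names(fixed)) idx[[as.integer(p)]] <- fixed[[p]]
  idx
}

arr_get <- function(arr, fixed) {
  idx <- dim_index(dim(arr), fixed)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

arr_set <- function(arr, fixed, value) {
  idx <- dim_index(dim(arr), fixed)
  do.call(`[<-`, c(list(arr), idx, list(value = value)))
}

# bind: constrain state variable v to the current state, then drop it
ss_bind <- function(x, v) {
  x <- ss_expand(x, union(x$vars, v))
  q <- match(v, x$vars) + 1L
  d <- dim(x$arr)
  dout <- d[-q]
  out <- array(FALSE, dout)
  for (s in seq_len(x$stg$S)) {
    slice <- arr_get(x$arr, stats::setNames(list(s, s), c("1", as.character(q))))
    out <- arr_set(out, stats::setNames(list(s), "1"), slice)
  }
  symbolic_set(x$stg, out, setdiff(x$vars, v))
}

# at: evaluate at the state named v; the current state becomes unconstrained
ss_at <- function(x, v) {
  x <- ss_expand(x, union(x$vars, v))
  q <- match(v, x$vars) + 1L
  d <- dim(x$arr)
  out <- array(FALSE, d)
  S <- x$stg$S
  for (a in seq_len(S)) {
    slice <- arr_get(x$arr, stats::setNames(list(a, a), c("1", as.character(q))))
    rep_slice <- array(rep(as.logical(slice), each = S), replace(d, q, 1L))
    out <- arr_set(out, stats::setNames(list(a), as.character(q)), rep_slice)
  }
  symbolic_set(x$stg, out, x$vars)
}

# existential quantification of a state variable
ss_exists <- function(x, v) {
  if (!(v %in% x$vars)) return(x)
  q <- match(v, x$vars) + 1L
  d <- dim(x$arr)
  pre <- prod(d[seq_len(q - 1L)])
  post <- prod(d) / (pre * d[q])
  marr <- array(x$arr, c(pre, d[q], post))
  res <- matrix(FALSE, pre, post)
  for (j in seq_len(d[q])) res <- res | marr[, j, , drop = TRUE]
  symbolic_set(x$stg, array(res, d[-q]), setdiff(x$vars, v))
}
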