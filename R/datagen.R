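# Encoding binarized observations as HCTL, the bundled running example, and
# synthetic ground-truth sketch generation.

#' Construct a table of binarized observations
#'
#' @param values matrix or data frame of 0/1/NA values; columns named by
#'   network variables, one row per experiment (rows of a time series are
#'   taken in order)
#' @param kind `"steady_state"` or `"time_series"`
#' @return object of class `observation_table`
#' @export
observation_table <- function(values, kind = c("steady_state", "time_series")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  mode(values) <- "integer"
  if (is.null(colnames(values))) stop("observation columns must be named by variables", call. = FALSE)
  if (!all(values %in% c(0L, 1L, NA_integer_))) stop("observations must be 0, 1 or NA", call. = FALSE)
  structure(list(values = values, kind = kind), class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("%s observations: %d experiment(s) over %d variable(s)\n",
              gsub("_", "-", x$kind), nrow(x$values), ncol(x$values)))
  invisible(x)
}

# conjunction of observed literals of one row, as an HCTL AST
row_conjunction <- function(row) {
  lits <- list()
  for (v in names(row)) {
    if (is.na(row[[v]])) next
    lits[[length(lits) + 1L]] <- if (row[[v]] == 1L) h_prop(v) else h_not(h_prop(v))
  }
  if (length(lits) == 0L) return(NULL)
  Reduce(function(l, r) h_bin("and", l, r), lits)
}

#' Encode steady-state observations as HCTL formulae
#'
#' Each observed (possibly partial) state yields one closed formula asserting
#' that some state matching the observed literals lies in an attractor
#' (default) or is a fixed point: `3{x}: @{x}: (literals & A)` with `A` the
#' attractor- or fixed-point-membership formula.  Unobserved variables
#' contribute no literal, so an apparent steady state may still correspond to
#' a cyclic or complex attractor of the unobserved part.
#'
#' @param x an `observation_table` of kind `steady_state`
#' @param mode `"attractor"` (default) or `"fixed_point"`
#' @return list of closed `hctl` formulae, one per row
#' @export
encode_steady_state <- function(x, mode = c("attractor", "fixed_point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "observation_table"))
  if (x$kind != "steady_state") stop("table is not steady-state data", call. = FALSE)
  anchor <- if (mode == "attractor") attractor_formula("y") else fixed_point_formula("y")
  lapply(seq_len(nrow(x$values)), function(r) {
    row <- x$values[r, ]
    names(row) <- colnames(x$values)
    conj <- row_conjunction(row)
    if (is.null(conj)) stop(sprintf("observation row %d has no observed value", r), call. = FALSE)
    alpha_rename(h_quant("exists", "x", h_quant("at", "x", h_bin("and", conj, anchor))))
  })
}

#' Encode a time series as one reachability formula
#'
#' The measurements are chained by reachability: some state matching the
#' first row can reach a state matching the second, and so on
#' (`3{x}: @{x}: d1 & EF (d2 & EF (...))`), optionally requiring the final
#' matching state to lie in an attractor.
#'
#' @param x an `observation_table` of kind `time_series` with at least two
#'   rows
#' @param end_in_attractor require the last measurement to be an attractor
#'   state
#' @return a closed `hctl` formula
#' @export
encode_time_series <- function(x, end_in_attractor = FALSE) {
  stopifnot(inherits(x, "observation_table"))
  if (x$kind != "time_series") stop("table is not time-series data", call. = FALSE)
  k <- nrow(x$values)
  if (k < 2L) stop("a time series needs at least two measurements", call. = FALSE)
  conjs <- lapply(seq_len(k), function(r) {
    row <- x$values[r, ]
    names(row) <- colnames(x$values)
    conj <- row_conjunction(row)
    if (is.null(conj)) stop(sprintf("observation row %d has no observed value", r), call. = FALSE)
    conj
  })
  acc <- conjs[[k]]
  if (end_in_attractor) acc <- h_bin("and", acc, attractor_formula("y"))
  for (r in (k - 1L):1L) acc <- h_bin("and", conjs[[r]], h_un("ef", acc))
  alpha_rename(h_quant("exists", "x", h_quant("at", "x", acc)))
}

#' Restrict the attractor landscape to given phenotype patterns
#'
#' Produces the closed formula `V{x}: @{x}: (attractor-membership => p1 | p2
#' | ...)`: every attractor state matches one of the given (possibly
#' partial) patterns, i.e. there is no attractor beyond those expected.
#'
#' @param patterns list of named 0/1/NA vectors (or a matrix with named
#'   columns), one per admitted phenotype
#' @return a closed `hctl` formula
#' @export
prohibit_other_attractors <- function(patterns) {
  if (is.matrix(patterns) || is.data.frame(patterns)) {
    patterns <- lapply(seq_len(nrow(patterns)), function(r) {
      row <- as.matrix(patterns)[r, ]
      stats::setNames(as.integer(row), colnames(patterns))
    })
  }
  if (length(patterns) == 0L) stop("at least one admitted pattern is required", call. = FALSE)
  disj <- NULL
  for (p in patterns) {
    conj <- row_conjunction(as.list(p)) %||% h_const(TRUE)
    disj <- if (is.null(disj)) conj else h_bin("or", disj, conj)
  }
  alpha_rename(
    h_quant("forall", "x",
      h_quant("at", "x", h_bin("imp", attractor_formula("y"), disj))))
}

#' The bundled three-variable running example
#'
#' A small sketch over variables `v1, v2, v3`: influence graph
#' `v1 -> v1, v3 -> v1, v1 -> v2, v1 -> v3, v2 -> v3`; partially specified
#' update functions `v1 <- v1 & f(v3)`, `v2 <- g(v1)`, `v3 <- h(v1, v2)`
#' with unknown functions `f/1`, `g/1`, `h/2`; update-function properties
#' making `v3` essential and inhibiting in `E1` and both inputs of `h`
#' essential with `v1` activating; a shared-basin dynamic property (two
#' attractors reachable from a common state); and two steady-state
#' observations `(0,0,0)` and `(1,1,0)` encoded as attractor-membership
#' constraints.  The candidate cascade is 1024 influence-graph-consistent
#' networks, 256 after the partial specification, 16 after the
#' update-function properties, 4 after the shared-basin property and a
#' single network after the data, decoding to `g = v1`, `h = v1 & !v2`.
#'
#' @param dynamics which dynamic properties to include: any of
#'   `"shared_basin"`, `"data"`
#' @return a `bn_sketch`
#' @export
running_example_sketch <- function(dynamics = c("shared_basin", "data")) {
  if (length(dynamics)) dynamics <- match.arg(dynamics, several.ok = TRUE)
  vars <- c("v1", "v2", "v3")
  ig <- influence_graph(vars, rbind(
    c("v1", "v1"), c("v3", "v1"),
    c("v1", "v2"),
    c("v1", "v3"), c("v2", "v3")))
  net <- psbn(vars,
              list(v1 = "v1 & f(v3)", v2 = "g(v1)", v3 = "h(v1, v2)"),
              symbols = data.frame(name = c("f", "g", "h"), arity = c(1L, 1L, 2L)))
  props <- list(
    ufp_item("v1", "essential(v3) & negative(v3)"),
    ufp_item("v3", "essential(v1) & essential(v2) & positive(v1)"))
  dyn <- list()
  if ("shared_basin" %in% dynamics) dyn <- c(dyn, list(shared_basin_formula()))
  if ("data" %in% dynamics) {
    dyn <- c(dyn, encode_steady_state(running_example_observations()))
  }
  bn_sketch(ig, net, props, dyn)
}

#' @rdname running_example_sketch
#' @export
running_example_observations <- function() {
  m <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L))
  colnames(m) <- c("v1", "v2", "v3")
  observation_table(m, "steady_state")
}

# expression AST computing a given local truth table over regulator variables
table_to_expression <- function(table, regulators) {
  k <- length(regulators)
  rows <- all_bit_rows(k)
  on <- which(as.logical(table))
  if (length(on) == 0L) return(e_const(FALSE))
  if (length(on) == 2^k) return(e_const(TRUE))
  terms <- lapply(on, function(r) {
    term <- NULL
    for (j in seq_len(k)) {
      lit <- if (rows[r, j] == 1L) e_var(regulators[j]) else e_not(e_var(regulators[j]))
      term <- if (is.null(term)) lit else e_bin("and", term, lit)
    }
    term
  })
  Reduce(function(l, r) e_bin("or", l, r), terms)
}

#' Generate a random sketch with a known ground truth
#'
#' Samples a Boolean network with bounded in-degree, derives its influence
#' graph, hides a fraction of the update functions behind fresh uninterpreted
#' symbols over their regulators, emits monotonicity/essentiality properties
#' for hidden functions where the true function is monotone and essential in
#' a regulator, and samples steady-state observations from the true
#' network's attractor states.  The true network is consistent with every
#' component of the generated sketch by construction.
#'
#' @param n number of variables (keep small for oracle cross-checks)
#' @param max_in_degree regulators per variable are drawn from
#'   `1..max_in_degree`
#' @param hidden_fraction fraction of update functions replaced by
#'   uninterpreted symbols (rounded to a count)
#' @param n_observations number of steady-state observations sampled from
#'   attractor states
#' @param seed integer seed; the bundle is deterministic given the seed
#' @return object of class `ground_truth_bundle` with components `truth`
#'   (the true `boolean_network`), `sketch` (a `bn_sketch`) and `params`
#' @export
random_sketch <- function(n, max_in_degree = 2L, hidden_fraction = 0.5,
                          n_observations = 2L, seed = 1L) {
  stopifnot(n >= 1L, max_in_degree >= 1L, max_in_degree <= n,
            hidden_fraction >= 0, hidden_fraction <= 1, n_observations >= 1L)
  withr::with_seed(seed, {
    vars <- paste0("v", seq_len(n))
    regulators <- lapply(seq_len(n), function(i) {
      k <- sample.int(max_in_degree, 1L)
      sort(sample.int(n, k))
    })
    local_tables <- lapply(regulators, function(regs) {
      stats::runif(2^length(regs)) < 0.5
    })
    n_hidden <- round(hidden_fraction * n)
    hidden <- sort(sample.int(n, n_hidden))
    if (sum(2^lengths(regulators[hidden])) > 16L) {
      stop("infeasible parameters: hidden functions would need too many parameter constants", call. = FALSE)
    }

    exprs_true <- lapply(seq_len(n), function(i) {
      table_to_expression(local_tables[[i]], vars[regulators[[i]]])
    })
    names(exprs_true) <- vars
    truth <- specialize(psbn(vars, exprs_true), list())

    ig <- influence_graph(vars, do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(vars[regulators[[i]]], vars[i])
    })))

    symbols <- data.frame(name = character(0), arity = integer(0))
    exprs <- exprs_true
    props <- list()
    for (i in hidden) {
      regs <- regulators[[i]]
      sym <- paste0("u_", vars[i])
      symbols <- rbind(symbols, data.frame(name = sym, arity = length(regs)))
      exprs[[vars[i]]] <- e_apply(list(name = sym, arity = length(regs)),
                                  lapply(vars[regs], e_var))
      # signed-edge knowledge: keep monotone essential regulators constrained
      tab <- truth$tables[[vars[i]]]
      for (vj in vars[regs]) {
        j <- match(vj, vars)
        r0 <- which(!state_bit_column(n, j)); r1 <- flip_index(n, j)[r0]
        ess <- any(tab != tab[flip_index(n, j)])
        if (!ess) next
        if (all(!tab[r0] | tab[r1])) {
          props <- c(props, list(ufp_item(vars[i], sprintf("positive(%s) & essential(%s)", vj, vj))))
        } else if (all(!tab[r1] | tab[r0])) {
          props <- c(props, list(ufp_item(vars[i], sprintf("negative(%s) & essential(%s)", vj, vj))))
        }
      }
    }
    net <- psbn(vars, exprs, symbols)

    atts <- explicit_attractors(explicit_stg(truth))
    att_states <- unlist(lapply(atts, `[[`, "states"))
    pick <- att_states[sample.int(length(att_states), n_observations,
                                  replace = length(att_states) < n_observations)]
    obs <- t(vapply(pick, function(s) code_to_bits(s - 1L, n), integer(n)))
    colnames(obs) <- vars
    dyn <- encode_steady_state(observation_table(obs, "steady_state"))

    structure(list(truth = truth,
                   sketch = bn_sketch(ig, net, props, dyn),
                   params = list(n = n, max_in_degree = max_in_degree,
                                 hidden_fraction = hidden_fraction, hidden = vars[hidden],
                                 n_observations = n_observations, seed = seed)),
              class = "ground_truth_bundle")
  })
}

#' @export
print.ground_truth_bundle <- function(x, ...) {
  cat(sprintf("Ground-truth bundle: n = %d, hidden: %s, seed = %d\n",
              x$params$n,
              if (length(x$params$hidden)) paste(x$params$hidden, collapse = ", ") else "none",
              x$params$seed))
  invisible(x)
}
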