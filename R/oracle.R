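# Explicit-state reference implementation: enumerative state-transition
# graphs, Tarjan-style attractor detection (via igraph), recursive HCTL
# evaluation with explicit environments, and brute-force inference.
#
# Deliberately naive and entirely separate from the bit-parallel symbolic
# path, so the two can verify each other.

#' Explicit asynchronous state-transition graph of a Boolean network
#'
#' @param bn a `boolean_network`
#' @param max_vars refuse larger networks (the graph has `2^n` nodes)
#' @return object of class `explicit_stg` with an adjacency list (state
#'   indices, 1-based) and the underlying [igraph::graph()] object
#' @export
explicit_stg <- function(bn, max_vars = 20L) {
  stopifnot(inherits(bn, "boolean_network"))
  n <- length(bn$variables)
  if (n > max_vars) stop("network too large for explicit state enumeration", call. = FALSE)
  S <- 2^n
  adj <- vector("list", S)
  for (s in seq_len(S)) {
    bits <- code_to_bits(s - 1L, n)
    succ <- integer(0)
    for (i in seq_len(n)) {
      fi <- bn$tables[[i]][s]
      if (fi != (bits[i] == 1L)) {
        succ <- c(succ, bitwXor(s - 1L, 2^(n - i)) + 1L)
      }
    }
    if (length(succ) == 0L) succ <- s  # fixed point: self-loop keeps the relation total
    adj[[s]] <- succ
  }
  edges <- cbind(rep(seq_len(S), lengths(adj)), unlist(adj))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  structure(list(network = bn, n = n, S = S, adj = adj, graph = g),
            class = "explicit_stg")
}

#' @export
print.explicit_stg <- function(x, ...) {
  cat(sprintf("Explicit asynchronous STG: %d states, %d transitions\n",
              x$S, sum(lengths(x$adj))))
  invisible(x)
}

#' Attractors of an explicit state-transition graph
#'
#' Attractors are the bottom (terminal) strongly connected components.  Each
#' is classified as `fixed_point` (a singleton), `cyclic` (the component is a
#' single cycle) or `complex` (anything else).
#'
#' @param g an `explicit_stg`
#' @return list of attractors; each has `states` (1-based state indices) and
#'   `type`
#' @export
explicit_attractors <- function(g) {
  stopifnot(inherits(g, "explicit_stg"))
  comp <- igraph::components(g$graph, mode = "strong")
  membership <- comp$membership
  out <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(membership == cid)
    succ <- unique(unlist(g$adj[members]))
    if (!all(membership[succ] == cid)) next  # escapes: not bottom
    type <- if (length(members) == 1L) {
      "fixed_point"
    } else {
      indeg_ok <- all(vapply(members, function(s) {
        within <- intersect(g$adj[[s]], members)
        length(within) == 1L
      }, logical(1)))
      if (indeg_ok) "cyclic" else "complex"
    }
    out[[length(out) + 1L]] <- list(states = members, type = type)
  }
  out
}

# states with at least one successor inside `set` (logical S-vector)
oracle_pre <- function(g, set) {
  vapply(seq_len(g$S), function(s) any(set[g$adj[[s]]]), logical(1))
}

#' Recursive HCTL evaluation on an explicit graph
#'
#' Structural recursion over the desugared core with an explicit environment
#' for free state variables; state quantifiers iterate over all `2^n` states.
#'
#' @param f an `hctl` formula
#' @param g an `explicit_stg`
#' @param env named list mapping free state-variable names to 1-based state
#'   indices
#' @return logical vector over states: which states satisfy `f` under `env`
#' @export
explicit_hctl <- function(f, g, env = list()) {
  stopifnot(inherits(f, "hctl"), inherits(g, "explicit_stg"))
  core <- desugar_hctl(f)
  ev <- function(f, env) {
    switch(f$op,
      const = rep(f$value, g$S),
      prop  = {
        j <- match(f$name, g$network$variables)
        if (is.na(j)) stop(sprintf("unknown proposition '%s'", f$name), call. = FALSE)
        state_bit_column(g$n, j)
      },
      svar  = {
        tgt <- env[[f$var]]
        if (is.null(tgt)) stop(sprintf("unbound state variable '%s'", f$orig), call. = FALSE)
        seq_len(g$S) == tgt
      },
      not   = !ev(f$arg, env),
      and   = ev(f$lhs, env) & ev(f$rhs, env),
      ex    = oracle_pre(g, ev(f$arg, env)),
      eu    = {
        phi <- ev(f$lhs, env); psi <- ev(f$rhs, env)
        z <- psi
        repeat {
          nz <- psi | (phi & oracle_pre(g, z))
          if (identical(nz, z)) break
          z <- nz
        }
        z
      },
      au    = {
        phi <- ev(f$lhs, env); psi <- ev(f$rhs, env)
        z <- psi
        repeat {
          nz <- psi | (phi & !oracle_pre(g, !z))
          if (identical(nz, z)) break
          z <- nz
        }
        z
      },
      bind  = vapply(seq_len(g$S), function(s) {
        env2 <- env; env2[[f$var]] <- s
        ev(f$arg, env2)[s]
      }, logical(1)),
      at    = {
        tgt <- env[[f$var]]
        if (is.null(tgt)) stop(sprintf("unbound state variable '%s'", f$orig), call. = FALSE)
        rep(ev(f$arg, env)[tgt], g$S)
      },
      exists = {
        acc <- rep(FALSE, g$S)
        for (s in seq_len(g$S)) {
          env2 <- env; env2[[f$var]] <- s
          acc <- acc | ev(f$arg, env2)
          if (all(acc)) break
        }
        acc
      }
    )
  }
  ev(core, env)
}

# property evaluation on a concrete truth table (independent of the symbolic
# property compiler)
oracle_property <- function(p, table, variables) {
  n <- length(variables)
  ev <- function(p) {
    switch(p$op,
      essential = {
        j <- match(p$variable, variables)
        any(table != table[flip_index(n, j)])
      },
      positive = {
        j <- match(p$variable, variables)
        r0 <- which(!state_bit_column(n, j))
        all(!table[r0] | table[flip_index(n, j)[r0]])
      },
      negative = {
        j <- match(p$variable, variables)
        r0 <- which(!state_bit_column(n, j))
        all(!table[flip_index(n, j)[r0]] | table[r0])
      },
      canalizing = {
        j <- match(p$variable, variables)
        rows <- which(state_bit_column(n, j) == (p$in_value == 1L))
        all(table[rows] == (p$out_value == 1L))
      },
      not = !ev(p$arg),
      and = ev(p$lhs) && ev(p$rhs),
      or  = ev(p$lhs) || ev(p$rhs),
      imp = !ev(p$lhs) || ev(p$rhs)
    )
  }
  ev(p)
}

#' Brute-force sketch inference
#'
#' Enumerates every interpretation of the sketch's function symbols, filters
#' by influence-graph consistency of the dependency sets, by the
#' update-function properties evaluated on the concrete functions, and by
#' recursive HCTL evaluation of every dynamic property, then deduplicates by
#' network equality.
#'
#' @param sketch a `bn_sketch`
#' @param mode model-level satisfaction convention for closed formulae
#' @param max_colour_bits refuse sketches with more than `2^max_colour_bits`
#'   interpretations
#' @return list of distinct consistent `boolean_network`s, in enumeration
#'   order
#' @export
oracle_infer <- function(sketch, mode = c("all_states", "some_state"), max_colour_bits = 16L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sketch, "bn_sketch"))
  net <- sketch$network
  total_bits <- sum(2^net$symbols$arity)
  if (nrow(net$symbols) > 0L && total_bits > max_colour_bits) {
    stop("too many interpretations for brute-force enumeration", call. = FALSE)
  }
  props <- lapply(sketch$properties, function(it) {
    p <- it$property
    if (is.character(p)) p <- parse_property(p, net$variables)
    list(target = it$target, p = p)
  })
  preds <- lapply(net$variables, function(v) predecessors(sketch$ig, v))
  names(preds) <- net$variables
  out <- list(); seen <- character(0)
  for (interp in enumerate_interpretations(net$symbols)) {
    bn <- specialize(net, interp)
    ok <- all(vapply(net$variables, function(v) {
      all(dep_set(bn$tables[[v]], net$variables) %in% preds[[v]])
    }, logical(1)))
    if (!ok) next
    ok <- all(vapply(props, function(pr) {
      oracle_property(pr$p, bn$tables[[pr$target]], net$variables)
    }, logical(1)))
    if (!ok) next
    if (length(sketch$dynamics)) {
      g <- explicit_stg(bn)
      ok <- all(vapply(sketch$dynamics, function(f) {
        sat <- explicit_hctl(f, g)
        if (mode == "all_states") all(sat) else any(sat)
      }, logical(1)))
      if (!ok) next
    }
    sig <- format(bn)
    if (!(sig %in% seen)) {
      seen <- c(seen, sig)
      out[[length(out) + 1L]] <- bn
    }
  }
  out
}
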