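# Sketch inference: the reject/accept pipeline, candidate sets, counting,
# enumeration, membership, attractors.

bns_error <- function(class, message) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = message, call = NULL)))
}

#' Infer all Boolean networks consistent with a sketch
#'
#' Runs the inference pipeline: (1) reject if the PSBN syntactically violates
#' the influence graph; (2) eliminate positive-arity function symbols,
#' introducing parameter constants; (3) evaluate the update-function
#' properties on the eliminated expressions, rejecting if contradictory;
#' (4) build the coloured asynchronous state-transition graph over the
#' surviving colours; (5) model-check every dynamic property, intersecting
#' the satisfying colour sets, rejecting if empty.  The result is a compact
#' set of colours plus the decoding tables needed to reconstruct concrete
#' networks and interpretations.
#'
#' @param sketch a `bn_sketch`
#' @param mode model-level satisfaction convention for the closed dynamic
#'   properties: hold in all states (default) or in at least one
#' @param arity_cap refuse function symbols above this arity
#' @param max_colour_bits refuse sketches whose elimination yields more than
#'   this many parameter constants
#' @return object of class `candidate_set`
#' @section Rejection: signalled as classed errors `bnsketch_ig_violation`,
#'   `bnsketch_unsat_properties`, `bnsketch_unsat_dynamics`, matching the
#'   three reject points of the pipeline.
#' @examples
#' s <- running_example_sketch()
#' cs <- infer(s)
#' count_distinct_networks(cs)
#' @export
infer <- function(sketch, mode = c("all_states", "some_state"),
                  arity_cap = 8L, max_colour_bits = 16L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sketch, "bn_sketch"))
  if (!check_ig_consistency(sketch$network, sketch$ig)) {
    bns_error("bnsketch_ig_violation",
              "PSBN violates the influence graph: an expression mentions a non-regulator")
  }
  elim <- eliminate_symbols(sketch$network, arity_cap = arity_cap)
  constants <- elim$psbn$symbols$name
  m <- length(constants)
  if (m > max_colour_bits) {
    bns_error("bnsketch_too_large",
              sprintf("elimination yields %d parameter constants (cap %d)", m, max_colour_bits))
  }
  stages <- list(ig = count_ig_consistent(sketch$ig))

  full_stg <- build_coloured_stg(elim$psbn)
  stages$ig_psbn <- length(unique(stg_signatures(full_stg)))
  stages$ig_psbn_interpretations <- full_stg$K

  ufp_ok <- ufp_constraint(sketch$properties, elim$psbn)
  stages$ig_psbn_ufp_interpretations <- sum(ufp_ok)
  if (!any(ufp_ok)) {
    bns_error("bnsketch_unsat_properties", "update-function properties are contradictory")
  }
  stg <- build_coloured_stg(elim$psbn, colours = ufp_ok)
  stages$ig_psbn_ufp <- length(unique(stg_signatures(stg)))

  log <- list()
  for (f in sketch$dynamics) {
    r <- model_check(f, stg)
    sel <- colours_satisfying(r, mode)
    stg <- stg_subset(stg, sel)
    log[[length(log) + 1L]] <- list(formula = format_hctl(f), interpretations = stg$K)
    if (stg$K == 0L) {
      bns_error("bnsketch_unsat_dynamics",
                sprintf("no candidate satisfies dynamic property %s", format_hctl(f)))
    }
  }
  stages$ig_psbn_ufp_dp_interpretations <- stg$K
  stages$ig_psbn_ufp_dp <- length(unique(stg_signatures(stg)))

  structure(list(sketch = sketch, eliminated = elim$psbn, table = elim$table,
                 constants = constants, colour_bits = stg$colour_bits,
                 stages = stages, dynamics_log = log, mode = mode),
            class = "candidate_set")
}

# restrict a coloured STG to a subset of its colour columns
stg_subset <- function(stg, keep) {
  keep <- which(keep)
  stg$colour_bits <- stg$colour_bits[keep, , drop = FALSE]
  stg$K <- length(keep)
  stg$Fmat <- lapply(stg$Fmat, function(M) M[, keep, drop = FALSE])
  stg$can_flip <- lapply(stg$can_flip, function(M) M[, keep, drop = FALSE])
  stg$fixed <- stg$fixed[, keep, drop = FALSE]
  stg
}

# one signature string per colour: the concatenated update-function tables
stg_signatures <- function(stg) {
  if (stg$K == 0L) return(character(0))
  big <- do.call(rbind, stg$Fmat)
  vapply(seq_len(stg$K), function(k) rawToChar(as.raw(big[, k] + 48L)), "")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %g interpretation(s), %g distinct network(s)\n",
              count_interpretations(x), count_distinct_networks(x)))
  cat("  cascade:",
      sprintf("IG %s | +PSBN %g | +UFP %g | +DP %g",
              unclass(x$stages$ig), x$stages$ig_psbn,
              x$stages$ig_psbn_ufp, x$stages$ig_psbn_ufp_dp), "\n")
  invisible(x)
}

# coloured STG restricted to the candidate colours
candidate_stg <- function(x) {
  build_coloured_stg(x$eliminated, colours = x$colour_bits)
}

#' Candidate-set counting
#'
#' `count_interpretations()` counts satisfying valuations of the parameter
#' constants; `count_distinct_networks()` counts the equivalence classes of
#' colours inducing the same Boolean network (two interpretations may
#' specialize to identical update functions).
#'
#' @param x a `candidate_set`
#' @return a number (exact; counts are bounded by `2^max_colour_bits`)
#' @export
count_interpretations <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  nrow(x$colour_bits)
}

#' @rdname count_interpretations
#' @export
count_distinct_networks <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  if (nrow(x$colour_bits) == 0L) return(0L)
  length(unique(stg_signatures(candidate_stg(x))))
}

#' Per-stage candidate counts
#'
#' The cascade of candidate counts as the sketch components are applied
#' gradually: influence graph only, plus the partial network specification,
#' plus the update-function properties, plus the dynamic properties.
#' Counts after the PSBN stage are reported both as distinct networks and as
#' interpretations.
#'
#' @param x a `candidate_set`
#' @return named list of counts
#' @export
stage_counts <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  x$stages
}

#' Decode candidates into interpretations and networks
#'
#' @param x a `candidate_set`
#' @param limit maximum number of candidates to decode
#' @return list of decoded candidates in lexicographic colour order, each
#'   with components `interpretation` (for the original symbols), `network`
#'   (a `boolean_network`) and `colour` (the constant valuation)
#' @export
enumerate_candidates <- function(x, limit = 10L) {
  stopifnot(inherits(x, "candidate_set"), limit >= 0L)
  K <- nrow(x$colour_bits)
  ord <- order(colour_codes(x$colour_bits))
  take <- ord[seq_len(min(limit, K))]
  lapply(take, function(k) {
    val <- x$colour_bits[k, ]
    names(val) <- x$constants
    interp <- interpretation_from_constants(x$table, val)
    list(interpretation = interp,
         network = specialize(x$sketch$network, interp),
         colour = val)
  })
}

#' Membership of a concrete network in a candidate set
#'
#' @param x a `candidate_set`
#' @param bn a `boolean_network` over the sketch's variables
#' @return `TRUE` when some candidate colour decodes to a network with the
#'   same update functions
#' @export
contains_network <- function(x, bn) {
  stopifnot(inherits(x, "candidate_set"), inherits(bn, "boolean_network"))
  if (!identical(bn$variables, x$sketch$network$variables)) {
    stop("network variables do not match the sketch", call. = FALSE)
  }
  if (nrow(x$colour_bits) == 0L) return(FALSE)
  sig <- paste(vapply(bn$variables, function(v)
    rawToChar(as.raw(as.integer(bn$tables[[v]]) + 48L)), ""), collapse = "")
  sig %in% stg_signatures(candidate_stg(x))
}

#' Attractor states of every candidate at once
#'
#' Model-checks the attractor-membership formula `!{x}: AG EF {x}` over the
#' candidate colours, returning the symbolic set of (state, colour) pairs
#' where the state lies in some attractor of that colour's network.
#'
#' @param x a `candidate_set`
#' @return a `symbolic_set`
#' @export
attractor_states <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  model_check(attractor_formula(), candidate_stg(x))
}

#' Number of attractors of each candidate
#'
#' Partitions each colour's attractor states (from [attractor_states()]) into
#' individual attractors by forward-reachability closure within the colour's
#' own transition graph.
#'
#' @param x a `candidate_set`
#' @return integer vector, one count per candidate colour
#' @export
count_attractors <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  stg <- candidate_stg(x)
  att <- model_check(attractor_formula(), stg)
  m <- matrix(att$arr, nrow = stg$S)
  vapply(seq_len(stg$K), function(k) {
    remaining <- which(m[, k])
    cnt <- 0L
    while (length(remaining)) {
      # forward closure of one attractor state is exactly its attractor
      frontier <- remaining[1L]
      closure <- logical(stg$S)
      while (length(frontier)) {
        s <- frontier[[1L]]; frontier <- frontier[-1L]
        if (closure[s]) next
        closure[s] <- TRUE
        succ <- integer(0)
        for (i in seq_len(stg$n)) {
          if (stg$can_flip[[i]][s, k]) succ <- c(succ, stg$flips[[i]][s])
        }
        frontier <- c(frontier, succ[!closure[succ]])
      }
      cnt <- cnt + 1L
      remaining <- setdiff(remaining, which(closure))
    }
    cnt
  }, integer(1))
}
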