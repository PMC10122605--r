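# Bottom-up coloured HCTL model checking over the coloured STG.

#' Coloured HCTL model checking
#'
#' Evaluates a formula simultaneously over every colour of a coloured
#' asynchronous state-transition graph.  The result is a symbolic set over
#' (state, free state variables, colour); for a closed formula no state
#' variables remain.
#'
#' Semantics by structural recursion on the desugared core: a proposition is
#' its state bit; a state variable `x` is equality of the current state with
#' the state stored in `x`; `EX` is the predecessor image; `E[p U q]` and
#' `A[p U q]` are least fixpoints (the universal one via "all successors",
#' well-defined because self-loops make the relation total); `!{x}:` equates
#' `x` with the current state and discharges it; `@{x}:` re-evaluates at the
#' state stored in `x`; `3{x}:` quantifies `x` existentially.
#'
#' @param f an `hctl` formula (sugar allowed; desugared internally)
#' @param stg a `coloured_stg`
#' @return a `symbolic_set`
#' @export
model_check <- function(f, stg) {
  stopifnot(inherits(f, "hctl"), inherits(stg, "coloured_stg"))
  core <- desugar_hctl(f)
  rec <- function(f) {
    switch(f$op,
      const = ss_fill(stg, f$value),
      prop  = {
        j <- match(f$name, stg$variables)
        if (is.na(j)) stop(sprintf("unknown proposition '%s'", f$name), call. = FALSE)
        symbolic_set(stg, array(state_bit_column(stg$n, j), c(stg$S, stg$K)))
      },
      svar  = ss_svar_eq(stg, f$var),
      not   = ss_not(rec(f$arg)),
      and   = ss_and(rec(f$lhs), rec(f$rhs)),
      ex    = pre_image(rec(f$arg)),
      eu    = {
        phi <- rec(f$lhs); psi <- rec(f$rhs)
        al <- ss_align(phi, psi); phi <- al[[1]]; psi <- al[[2]]
        z <- psi
        repeat {
          nz <- ss_or(psi, ss_and(phi, pre_image(z)))
          if (ss_equal(nz, z)) break
          z <- nz
        }
        z
      },
      au    = {
        phi <- rec(f$lhs); psi <- rec(f$rhs)
        al <- ss_align(phi, psi); phi <- al[[1]]; psi <- al[[2]]
        z <- psi
        repeat {
          all_succ_in <- ss_not(pre_image(ss_not(z)))
          nz <- ss_or(psi, ss_and(phi, all_succ_in))
          if (ss_equal(nz, z)) break
          z <- nz
        }
        z
      },
      bind   = ss_bind(rec(f$arg), f$var),
      at     = ss_at(rec(f$arg), f$var),
      exists = ss_exists(rec(f$arg), f$var),
      stop(sprintf("unexpected operator '%s' after desugaring", f$op), call. = FALSE)
    )
  }
  rec(core)
}

#' Colours on which a closed check result holds
#'
#' A colour is consistent with a closed formula either when the formula holds
#' in all states of its transition graph (`all_states`, the default: safe for
#' the existentially anchored, state-independent formulae the package
#' generates, and required for universal properties such as forbidding
#' additional attractors) or in at least one state (`some_state`).
#'
#' @param r a `symbolic_set` with no remaining state variables
#' @param mode `"all_states"` or `"some_state"`
#' @return logical vector over the colours of the underlying graph
#' @export
colours_satisfying <- function(r, mode = c("all_states", "some_state")) {
  mode <- match.arg(mode)
  stopifnot(inherits(r, "symbolic_set"))
  if (length(r$vars)) {
    stop("result has free state variables; model-level satisfaction requires a closed formula", call. = FALSE)
  }
  m <- matrix(r$arr, nrow = r$stg$S)
  if (mode == "all_states") colSums(m) == r$stg$S else colSums(m) > 0L
}
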