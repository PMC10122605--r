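test_that("compiled truth matrices match pointwise evaluation", {
  withr::with_seed(3, {
    vars <- c("v1", "v2", "v3")
    sym <- data.frame(name = c("f", "h"), arity = c(1, 2))
    for (rep in 1:6) {
      net <- psbn(vars, list(v1 = random_expr_string(vars, sym, 3),
                             v2 = "v1", v3 = random_expr_string(vars, sym, 2)), sym)
      el <- eliminate_symbols(net)
      consts <- el$psbn$symbols$name
      m <- length(consts)
      M <- compile_truth_matrix(el$psbn$expressions$v1, vars, consts)
      for (k in sample.int(2^m, 4)) {
        val <- bnsketch:::code_to_bits(k - 1L, m) == 1L
        names(val) <- consts
        expect_identical(M[, k], expr_table(el$psbn$expressions$v1, vars, as.list(val)))
      }
    }
    # simple shapes: a plain variable and a bare constant
  })
  Mv <- compile_truth_matrix(parse_expression("v1", c("v1", "v2")), c("v1", "v2"), "c1")
  expect_identical(Mv[, 1], bnsketch:::state_bit_column(2, 1))
  expect_identical(Mv[, 2], bnsketch:::state_bit_column(2, 1))
  g0 <- parse_expression("g", "v1", data.frame(name = "g", arity = 0))
  Mg <- compile_truth_matrix(g0, "v1", "g")
  expect_identical(Mg, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
})

test_that("fixed single-colour graphs have the expected transitions", {
  neg <- psbn("v1", list(v1 = "!v1"))
  stg <- build_coloured_stg(neg)
  expect_equal(stg$K, 1)
  expect_true(all(stg$can_flip[[1]]))   # 0 -> 1 and 1 -> 0
  expect_false(any(stg$fixed))

  idn <- build_coloured_stg(psbn("v1", list(v1 = "v1")))
  expect_false(any(idn$can_flip[[1]]))  # only self-loops
  expect_true(all(idn$fixed))
})

test_that("every colour slice equals the explicitly constructed graph", {
  withr::with_seed(13, {
    vars <- c("v1", "v2", "v3")
    sym <- data.frame(name = c("f", "g"), arity = c(1, 2))
    for (rep in 1:5) {
      net <- psbn(vars, list(v1 = random_expr_string(vars, sym, 2),
                             v2 = random_expr_string(vars, sym, 2),
                             v3 = "v1"), sym)
      el <- eliminate_symbols(net)
      stg <- build_coloured_stg(el$psbn)
      consts <- el$psbn$symbols$name
      for (k in sample.int(stg$K, min(4, stg$K))) {
        val <- stg$colour_bits[k, ]
        names(val) <- consts
        bn <- specialize(net, interpretation_from_constants(el$table, val))
        ex <- explicit_stg(bn)
        for (s in seq_len(stg$S)) {
          succ <- integer(0)
          for (i in seq_len(stg$n)) {
            if (stg$can_flip[[i]][s, k]) succ <- c(succ, stg$flips[[i]][s])
          }
          if (length(succ) == 0L) succ <- s
          expect_setequal(succ, ex$adj[[s]])
        }
        # totality within the colour
        expect_true(all(stg$fixed[, k] | Reduce(`|`, lapply(stg$can_flip, function(M) M[, k]))))
      }
    }
  })
})

test_that("image operators respect colours and self-loops", {
  # colour decides between F1 = v1 and F1 = !v1
  net <- psbn("v1", list(v1 = "v1 <=> f"), symbols = data.frame(name = "f", arity = 0))
  stg <- build_coloured_stg(net)
  # colour 1: f = 0 -> F1 = !v1 (a 2-cycle); colour 2: f = 1 -> F1 = v1 (two fixed points)
  x0 <- bnsketch:::symbolic_set(stg, array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2)))
  post <- post_image(x0)
  expect_identical(post$arr[, 1], c(FALSE, TRUE))  # 0 -> 1 under negation
  expect_identical(post$arr[, 2], c(TRUE, FALSE))  # self-loop under identity

  # post of the empty set is empty
  empty <- bnsketch:::ss_fill(stg, FALSE)
  expect_false(any(post_image(empty)$arr))

  # pre of a fixed point contains the fixed point itself (self-loop)
  fix <- psbn("v1", list(v1 = "v1"))
  stgf <- build_coloured_stg(fix)
  x <- bnsketch:::symbolic_set(stgf, array(c(TRUE, FALSE), c(2, 1)))
  expect_true(pre_image(x)$arr[1, 1])
})

test_that("pre and post agree with explicit adjacency on random coloured graphs", {
  withr::with_seed(17, {
    vars <- c("v1", "v2")
    sym <- data.frame(name = "f", arity = 1)
    for (rep in 1:5) {
      net <- psbn(vars, list(v1 = random_expr_string(vars, sym, 2),
                             v2 = random_expr_string(vars, sym, 2)), sym)
      el <- eliminate_symbols(net)
      stg <- build_coloured_stg(el$psbn)
      x <- bnsketch:::symbolic_set(stg, array(stats::runif(stg$S * stg$K) < 0.4,
                                              c(stg$S, stg$K)))
      pr <- pre_image(x)$arr
      po <- post_image(x)$arr
      for (k in seq_len(stg$K)) {
        val <- stg$colour_bits[k, ]
        names(val) <- el$psbn$symbols$name
        bn <- specialize(net, interpretation_from_constants(el$table, val))
        adj <- explicit_stg(bn)$adj
        expect_identical(pr[, k], vapply(seq_len(stg$S), function(s)
          any(x$arr[adj[[s]], k]), logical(1)))
        expect_identical(po[, k], vapply(seq_len(stg$S), function(t)
          any(vapply(seq_len(stg$S), function(s)
            (t %in% adj[[s]]) && x$arr[s, k], logical(1))), logical(1)))
      }
    }
  })
})
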