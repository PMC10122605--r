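test_that("influence-graph consistency is a syntactic inclusion check", {
  vars <- c("v1", "v2", "v3")
  ig <- influence_graph(vars, rbind(c("v1", "v3"), c("v2", "v3"), c("v3", "v2"), c("v2", "v1")))
  ok <- psbn(vars, list(v1 = "v2", v2 = "v3", v3 = "v1 & v2"))
  expect_true(check_ig_consistency(ok, ig))

  bad <- psbn(vars, list(v1 = "v3", v2 = "v3", v3 = "v1"))
  expect_false(check_ig_consistency(bad, ig))

  # fully unspecified expressions over the admitted regulators are consistent
  free <- psbn(vars, list(v1 = "u1(v2)", v2 = "u2(v3)", v3 = "u3(v1, v2)"),
               symbols = data.frame(name = c("u1", "u2", "u3"), arity = c(1, 1, 2)))
  expect_true(check_ig_consistency(free, ig))
})

test_that("influence-graph counting matches the closed form and brute force", {
  v2 <- c("v1", "v2")
  self <- influence_graph(v2, rbind(c("v1", "v1"), c("v2", "v2")))
  expect_equal(as.numeric(count_ig_consistent(self)), 16)
  expect_identical(as.character(count_ig_consistent(self)), "16")

  empty <- influence_graph(v2, matrix(character(0), ncol = 2))
  expect_equal(as.numeric(count_ig_consistent(empty)), 4)

  # brute force for a 2-variable graph: count all network pairs whose
  # dependency sets respect the graph
  ig <- influence_graph(v2, rbind(c("v1", "v1"), c("v2", "v1"), c("v1", "v2")))
  brute <- 0
  for (c1 in 0:15) for (c2 in 0:15) {
    t1 <- bnsketch:::code_to_bits(c1, 4) == 1L
    t2 <- bnsketch:::code_to_bits(c2, 4) == 1L
    ok1 <- all(dep_set(t1, v2) %in% predecessors(ig, "v1"))
    ok2 <- all(dep_set(t2, v2) %in% predecessors(ig, "v2"))
    if (ok1 && ok2) brute <- brute + 1
  }
  expect_equal(as.numeric(count_ig_consistent(ig)), brute)

  # arbitrary precision beyond doubles
  big <- influence_graph(paste0("v", 1:8),
                         do.call(rbind, lapply(paste0("v", 1:8), function(t)
                           cbind(paste0("v", 1:8), t))))
  expect_equal(as.character(count_ig_consistent(big)), pow2_decimal(8 * 256))
})

test_that("property evaluation agrees with brute-force enumeration of colours", {
  withr::with_seed(5, {
    vars <- c("v1", "v2", "v3")
    sym <- data.frame(name = c("f", "h"), arity = c(1, 2))
    for (rep in 1:8) {
      exprs <- list(v1 = random_expr_string(vars, sym, 2), v2 = "v1", v3 = "v2")
      net <- psbn(vars, exprs, sym)
      el <- eliminate_symbols(net)
      consts <- el$psbn$symbols$name
      e1 <- el$psbn$expressions$v1
      m <- length(consts)
      atoms <- list(
        list(p = prop_essential("v2"), kind = "essential", v = "v2"),
        list(p = prop_positive("v1"), kind = "positive", v = "v1"),
        list(p = prop_negative("v3"), kind = "negative", v = "v3"),
        list(p = prop_canalizing("v2", 1, 0), kind = "canalizing", v = "v2",
             iv = 1, ov = 0))
      for (a in atoms) {
        sym_res <- evaluate_property(a$p, e1, vars, consts)
        brute <- vapply(seq_len(2^m), function(k) {
          val <- bnsketch:::code_to_bits(k - 1L, m) == 1L
          names(val) <- consts
          tab <- expr_table(e1, vars, as.list(val))
          check_atom(a$kind, tab, vars, a$v, a$iv, a$ov)
        }, logical(1))
        expect_identical(sym_res, brute)
      }
      # a random Boolean combination of atoms
      comb <- prop_imp(prop_and(prop_essential("v1"), prop_not(prop_positive("v2"))),
                       prop_or(prop_negative("v3"), prop_canalizing("v1", 0, 1)))
      sym_res <- evaluate_property(comb, e1, vars, consts)
      brute <- vapply(seq_len(2^m), function(k) {
        val <- bnsketch:::code_to_bits(k - 1L, m) == 1L
        names(val) <- consts
        tab <- expr_table(e1, vars, as.list(val))
        a <- check_atom("essential", tab, vars, "v1") &&
          !check_atom("positive", tab, vars, "v2")
        b <- check_atom("negative", tab, vars, "v3") ||
          check_atom("canalizing", tab, vars, "v1", 0, 1)
        !a || b
      }, logical(1))
      expect_identical(sym_res, brute)
    }
  })
})

test_that("veto is canalization to output zero", {
  p <- prop_veto("v1", 1)
  expect_equal(p$op, "canalizing")
  expect_equal(p$in_value, 1L)
  expect_equal(p$out_value, 0L)
})

test_that("the running-example properties pin down the documented functions", {
  s <- running_example_sketch(dynamics = character(0))
  el <- eliminate_symbols(s$network)
  consts <- el$psbn$symbols$name

  # essential + negative on E1 forces f to be the negation
  p1 <- parse_property("essential(v3) & negative(v3)", s$network$variables)
  r1 <- evaluate_property(p1, el$psbn$expressions$v1, s$network$variables, consts)
  surviving_f <- unique(lapply(which(r1), function(k) {
    val <- bnsketch:::code_to_bits(k - 1L, length(consts)) == 1L
    names(val) <- consts
    interpretation_from_constants(el$table, val)$f
  }))
  expect_length(surviving_f, 1)
  expect_identical(surviving_f[[1]], c(TRUE, FALSE))

  # essentiality of both inputs plus positivity in v1 leaves four options for h
  p3 <- parse_property("essential(v1) & essential(v2) & positive(v1)", s$network$variables)
  r3 <- evaluate_property(p3, el$psbn$expressions$v3, s$network$variables, consts)
  surviving_h <- unique(lapply(which(r3), function(k) {
    val <- bnsketch:::code_to_bits(k - 1L, length(consts)) == 1L
    names(val) <- consts
    interpretation_from_constants(el$table, val)$h
  }))
  expect_length(surviving_h, 4)
  or_  <- c(FALSE, TRUE, TRUE, TRUE)   # v1 | v2
  and_ <- c(FALSE, FALSE, FALSE, TRUE) # v1 & v2
  orn  <- c(TRUE, FALSE, TRUE, TRUE)   # v1 | !v2
  andn <- c(FALSE, FALSE, TRUE, FALSE) # v1 & !v2
  for (h in list(or_, and_, orn, andn)) {
    expect_true(any(vapply(surviving_h, identical, logical(1), h)))
  }

  # the full property set leaves 16 interpretations
  expect_equal(sum(ufp_constraint(s$properties, el$psbn)), 16)
})

test_that("property intersection is monotone and detects contradictions", {
  s <- running_example_sketch(dynamics = character(0))
  el <- eliminate_symbols(s$network)
  expect_equal(sum(ufp_constraint(list(), el$psbn)), 2^8)
  counts <- vapply(seq_along(s$properties), function(k) {
    sum(ufp_constraint(s$properties[seq_len(k)], el$psbn))
  }, numeric(1))
  expect_true(all(diff(c(2^8, counts)) <= 0))

  f1 <- psbn("v1", list(v1 = "f(v1)"), symbols = data.frame(name = "f", arity = 1))
  elf <- eliminate_symbols(f1)
  contradictory <- list(ufp_item("v1", "positive(v1) & negative(v1) & essential(v1)"))
  expect_equal(sum(ufp_constraint(contradictory, elf$psbn)), 0)
})

test_that("properties hold identically when the expression ignores the colours", {
  r <- evaluate_property(prop_positive("v1"), parse_expression("v1", "v1"), "v1", character(0))
  expect_identical(r, TRUE)
})
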