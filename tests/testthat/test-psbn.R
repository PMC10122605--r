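test_that("specialization produces the induced truth tables", {
  vars <- c("v1", "v2", "v3")
  net <- psbn(vars,
              list(v1 = "v1 & f(v3)", v2 = "g(v1)", v3 = "h(v1, v2)"),
              symbols = data.frame(name = c("f", "g", "h"), arity = c(1, 1, 2)))
  interp <- list(f = c(TRUE, FALSE),            # negation
                 g = c(FALSE, TRUE),            # identity
                 h = c(FALSE, FALSE, TRUE, FALSE))  # v1 & !v2
  bn <- specialize(net, interp)
  # F2(x) = x1 for all states
  expect_identical(bn$tables$v2, bnsketch:::state_bit_column(3, 1))
  # F1 = v1 & !v3, F3 = v1 & !v2
  expect_identical(bn$tables$v1,
                   bnsketch:::state_bit_column(3, 1) & !bnsketch:::state_bit_column(3, 3))
  expect_identical(bn$tables$v3,
                   bnsketch:::state_bit_column(3, 1) & !bnsketch:::state_bit_column(3, 2))

  # no symbols: independent of the interpretation argument
  plain <- psbn(vars, list(v1 = "v2", v2 = "v1 & v3", v3 = "0"))
  expect_identical(specialize(plain, list()), specialize(plain, interp["f"]))

  one <- psbn("v1", list(v1 = "f"), symbols = data.frame(name = "f", arity = 0))
  expect_identical(specialize(one, list(f = FALSE))$tables$v1, c(FALSE, FALSE))
  expect_error(specialize(net, interp[c("f", "g")]), "cover")
})

test_that("dependency sets contain exactly the essential inputs", {
  vars <- c("v1", "v2", "v3")
  tab <- bnsketch:::state_bit_column(3, 2) & !bnsketch:::state_bit_column(3, 3)  # v2 & !v3
  expect_setequal(dep_set(tab, vars), c("v2", "v3"))
  expect_length(dep_set(rep(FALSE, 8), vars), 0)

  # xor: brute-force the definition over all 4 states
  vars2 <- c("v1", "v2")
  xtab <- bnsketch:::state_bit_column(2, 1) != bnsketch:::state_bit_column(2, 2)
  brute <- Filter(function(v) {
    j <- match(v, vars2)
    any(vapply(0:3, function(code) {
      b <- bnsketch:::code_to_bits(code, 2)
      b0 <- b; b0[j] <- 0L; b1 <- b; b1[j] <- 1L
      xtab[bnsketch:::bits_to_code(b0) + 1] != xtab[bnsketch:::bits_to_code(b1) + 1]
    }, logical(1)))
  }, vars2)
  expect_setequal(dep_set(xtab, vars2), brute)
  expect_setequal(dep_set(xtab, vars2), vars2)
  expect_error(dep_set(rep(FALSE, 3), vars2), "length")
})

test_that("symbol elimination expands applications into constant selections", {
  vars <- c("v1", "v2", "v3")
  net <- psbn(vars,
              list(v1 = "v1 & f(v3)", v2 = "g(v1)", v3 = "h(v1, v2)"),
              symbols = data.frame(name = c("f", "g", "h"), arity = c(1, 1, 2)))
  el <- eliminate_symbols(net)
  # 2^1 + 2^1 + 2^2 fresh constants, all zero-arity
  expect_length(el$psbn$symbols$name, 8)
  expect_true(all(el$psbn$symbols$arity == 0))
  expect_identical(el$table$f, c("f_0", "f_1"))
  expect_identical(el$table$h, c("h_00", "h_01", "h_10", "h_11"))

  # arity-1 expansion shape: (f_0 & !v3) | (f_1 & v3)
  one <- psbn("v3", list(v3 = "f(v3)"), symbols = data.frame(name = "f", arity = 1))
  ex <- eliminate_symbols(one)$psbn$expressions$v3
  expect_equal(ex$op, "or")
  expect_equal(format_expression(ex), "f_0 & !v3 | f_1 & v3")

  # zero-arity symbols pass through unchanged and map to themselves
  z <- psbn("v1", list(v1 = "g()"), symbols = data.frame(name = "g", arity = 0))
  elz <- eliminate_symbols(z)
  expect_identical(format_expression(elz$psbn$expressions$v1), "g")
  expect_identical(elz$table$g, "g")

  expect_error(eliminate_symbols(net, arity_cap = 1L), "cap")
})

test_that("constant valuations decode to interpretations (truth-table read-off)", {
  one <- psbn("v3", list(v3 = "f(v3)"), symbols = data.frame(name = "f", arity = 1))
  el <- eliminate_symbols(one)
  interp <- interpretation_from_constants(el$table, c(f_0 = TRUE, f_1 = FALSE))
  expect_identical(interp$f, c(TRUE, FALSE))  # negation

  h <- psbn(c("v1", "v2"), list(v1 = "h(v1, v2)", v2 = "0"),
            symbols = data.frame(name = "h", arity = 2))
  elh <- eliminate_symbols(h)
  iv <- c(h_00 = FALSE, h_01 = FALSE, h_10 = TRUE, h_11 = TRUE)
  interp_h <- interpretation_from_constants(elh$table, iv)
  # h(a, b) = a: enumerate the four rows
  rows <- bnsketch:::all_bit_rows(2)
  expect_identical(interp_h$h, rows[, 1] == 1)

  all0 <- interpretation_from_constants(elh$table,
                                        stats::setNames(rep(FALSE, 4), names(iv)))
  expect_identical(all0$h, rep(FALSE, 4))
  expect_error(interpretation_from_constants(elh$table, c(h_00 = TRUE)), "cover")
})

test_that("elimination is sound: interpretations and colours induce the same networks", {
  withr::with_seed(11, {
    vars <- c("v1", "v2", "v3")
    for (rep in 1:10) {
      sym <- data.frame(name = c("f", "g"), arity = sample(0:2, 2, replace = TRUE))
      exprs <- list(v1 = random_expr_string(vars, sym, 2),
                    v2 = random_expr_string(vars, sym, 2),
                    v3 = random_expr_string(vars, sym, 2))
      net <- tryCatch(psbn(vars, exprs, sym), error = function(e) NULL)
      if (is.null(net)) next
      el <- eliminate_symbols(net)
      consts <- el$psbn$symbols$name

      sig_direct <- sort(vapply(
        bnsketch:::enumerate_interpretations(net$symbols),
        function(i) format(specialize(net, i)), ""))

      m <- length(consts)
      sig_col <- sort(vapply(seq_len(2^m), function(k) {
        val <- bnsketch:::code_to_bits(k - 1L, m) == 1L
        names(val) <- consts
        interp <- interpretation_from_constants(el$table, val)
        format(specialize(net, interp))
      }, ""))
      # multiset equality: same networks with the same multiplicities
      expect_identical(sig_col, sig_direct)

      # dependency sets never exceed the syntactic inputs
      for (i in bnsketch:::enumerate_interpretations(net$symbols)[1:2]) {
        bn <- specialize(net, i)
        for (v in vars) {
          expect_true(all(dep_set(bn$tables[[v]], vars) %in%
                          syntactic_inputs(net$expressions[[v]])))
        }
      }
    }
  })
})

test_that("apply evaluation uses the argument-most-significant row order", {
  vars <- c("v1", "v2")
  sym <- data.frame(name = "h", arity = 2)
  e <- parse_expression("h(v1, v2)", vars, sym)
  tab <- c(FALSE, TRUE, TRUE, FALSE)
  for (code in 0:3) {
    st <- bnsketch:::code_to_bits(code, 2) == 1L
    names(st) <- vars
    expect_identical(evaluate_expression(e, st, list(h = tab)), tab[code + 1])
  }
})
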