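test_that("the running-example refinement cascade narrows to one network", {
  s_ufp <- running_example_sketch(dynamics = character(0))
  cs_ufp <- infer(s_ufp)
  expect_equal(count_interpretations(cs_ufp), 16)
  expect_equal(count_distinct_networks(cs_ufp), 16)

  s_dp <- running_example_sketch(dynamics = "shared_basin")
  expect_equal(count_distinct_networks(infer(s_dp)), 4)

  cs <- infer(running_example_sketch())
  expect_equal(count_distinct_networks(cs), 1)
  cand <- enumerate_candidates(cs, 5)
  expect_length(cand, 1)
  expect_identical(cand[[1]]$interpretation$g, c(FALSE, TRUE))          # g = v1
  expect_identical(cand[[1]]$interpretation$h, c(FALSE, FALSE, TRUE, FALSE))  # h = v1 & !v2
  expect_identical(cand[[1]]$interpretation$f, c(TRUE, FALSE))          # f = negation
})

test_that("interpretation counting and network counting can differ", {
  # constant-true expression: two colours, one network
  s <- bn_sketch(
    influence_graph("v1", matrix(character(0), ncol = 2)),
    psbn("v1", list(v1 = "f | 1"), symbols = data.frame(name = "f", arity = 0)))
  cs <- infer(s)
  expect_equal(count_interpretations(cs), 2)
  expect_equal(count_distinct_networks(cs), 1)
  expect_true(count_distinct_networks(cs) <= count_interpretations(cs))

  # empty candidate handling in enumerate
  expect_length(enumerate_candidates(cs, 0), 0)
})

test_that("enumeration is deterministic in lexicographic colour order", {
  cs <- infer(running_example_sketch(dynamics = character(0)))
  cand <- enumerate_candidates(cs, 16)
  codes <- vapply(cand, function(cd) bnsketch:::bits_to_code(cd$colour), numeric(1))
  expect_identical(codes, sort(codes))
  expect_identical(enumerate_candidates(cs, 3), cand[1:3])
})

test_that("membership testing agrees with enumeration and brute force", {
  cs <- infer(running_example_sketch())
  final <- enumerate_candidates(cs, 1)[[1]]$network
  expect_true(contains_network(cs, final))

  wrong <- final
  wrong$tables$v2 <- !bnsketch:::state_bit_column(3, 1)  # F2 = !v1
  expect_false(contains_network(cs, wrong))

  # against the pre-dynamics set, membership equals brute-force search
  cs16 <- infer(running_example_sketch(dynamics = character(0)))
  nets16 <- oracle_infer(running_example_sketch(dynamics = character(0)))
  withr::with_seed(47, {
    for (rep in 1:5) {
      bn <- random_bn(3)
      brute <- any(vapply(nets16, bnsketch:::bn_equal, logical(1), bn))
      expect_identical(contains_network(cs16, bn), brute)
    }
  })
  expect_true(all(vapply(nets16, contains_network, logical(1), x = cs16)))
})

test_that("rejection surfaces as the three classed errors", {
  vars <- c("v1", "v2")
  ig <- influence_graph(vars, rbind(c("v1", "v1"), c("v1", "v2")))
  # v2 regulates v1 but is not an admitted regulator
  bad <- bn_sketch(ig, psbn(vars, list(v1 = "v2", v2 = "v1")))
  expect_error(infer(bad), class = "bnsketch_ig_violation")

  contradictory <- bn_sketch(
    ig,
    psbn(vars, list(v1 = "f(v1)", v2 = "v1"), symbols = data.frame(name = "f", arity = 1)),
    list(ufp_item("v1", "positive(v1) & negative(v1) & essential(v1)")))
  expect_error(infer(contradictory), class = "bnsketch_unsat_properties")

  unsat_dyn <- bn_sketch(
    ig,
    psbn(vars, list(v1 = "f(v1)", v2 = "v1"), symbols = data.frame(name = "f", arity = 1)),
    dynamics = list("3{x}: @{x}: (v1 & ~v1)"))
  expect_error(infer(unsat_dyn), class = "bnsketch_unsat_dynamics")
})

test_that("attractor analysis of the candidate set matches the oracle", {
  cs <- infer(running_example_sketch(dynamics = character(0)))
  att <- attractor_states(cs)
  counts <- count_attractors(cs)
  cand <- enumerate_candidates(cs, 16)
  # candidates are enumerated in colour order; align via signatures
  sigs <- bnsketch:::stg_signatures(bnsketch:::candidate_stg(cs))
  m <- matrix(att$arr, nrow = att$stg$S)
  for (cd in cand) {
    sig <- paste(vapply(cd$network$variables, function(v)
      rawToChar(as.raw(as.integer(cd$network$tables[[v]]) + 48L)), ""), collapse = "")
    k <- match(sig, sigs)
    oracle_atts <- explicit_attractors(explicit_stg(cd$network))
    expect_identical(which(m[, k]), sort(unlist(lapply(oracle_atts, `[[`, "states"))))
    expect_equal(counts[k], length(oracle_atts))
  }
  # the final network's fixed point (1,1,0) is an attractor state
  cs1 <- infer(running_example_sketch())
  att1 <- attractor_states(cs1)
  s110 <- bnsketch:::bits_to_code(c(1, 1, 0)) + 1
  expect_true(matrix(att1$arr, nrow = 8)[s110, 1])
})

test_that("refinement never enlarges the candidate set", {
  s0 <- running_example_sketch(dynamics = character(0))
  n0 <- count_interpretations(infer(s0))
  with_item <- bn_sketch(s0$ig, s0$network,
                         c(s0$properties, list(ufp_item("v2", "positive(v1)"))),
                         s0$dynamics)
  expect_lte(count_interpretations(infer(with_item)), n0)
  with_formula <- bn_sketch(s0$ig, s0$network, s0$properties,
                            list(shared_basin_formula()))
  expect_lte(count_interpretations(infer(with_formula)), n0)
})
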