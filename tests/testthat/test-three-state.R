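# The fully connected three-state model: invariants, star/chain
# reductions, the continuous equivalence family, classification, and the
# detailed-balance curve.

test_that("invariants of a star model are read off its rates", {
  st <- three_state(0, 3, 0, 1, 2, 2)
  inv <- ts_invariants(st)
  expect_equal(inv$lambda1, 3)
  expect_equal(inv$lambda2, 1)
  expect_equal(inv$lambda_O, 4)
  expect_equal(inv$rho, 0.5)
  expect_equal(inv$S, 0.5 * (3 - 1) * 4)
})

test_that("equal star exit rates give a degenerate closed spectrum", {
  st <- three_state(0, 2, 0, 2, 1, 3)
  inv <- ts_invariants(st)
  expect_true(inv$degenerate)
  expect_error(to_star(inv), "degenerate")
  expect_error(ts_classify(inv), "degenerate")
})

test_that("star reduction round-trips and preserves the invariants", {
  st0 <- make_fixture(1, 2, "star", seed = 31)
  inv <- ts_invariants(st0)
  back <- to_star(inv)
  expect_true(back$feasible)
  expect_equal(sort(aggmarkov:::ts_rates(st0)), sort(back$rates), tolerance = 1e-10)
  inv2 <- ts_invariants(back$model)
  for (f in c("lambda1", "lambda2", "lambda_O", "rho"))
    expect_equal(inv2[[f]], inv[[f]], tolerance = 1e-10)
})

test_that("chain reduction round-trips through the invariants", {
  ch0 <- three_state(0.8, 0, 1.7, 0.6, 0, 3.2)   # C1-C2-O3 chain
  inv <- ts_invariants(ch0)
  back <- to_chain(inv)
  expect_true(back$feasible)
  expect_equal(sort(aggmarkov:::ts_rates(ch0)), sort(back$rates), tolerance = 1e-9)
})

test_that("reductions of a mixture-class model are equivalent to it", {
  for (s in seeds_in_regime(5, "reducible_mixture")) {
    m <- rand_three_state(s)
    inv <- ts_invariants(m)
    st <- to_star(inv); ch <- to_chain(inv)
    expect_true(st$feasible); expect_true(ch$feasible)
    expect_true(are_equivalent(m, st$model, 1e-8))
    expect_true(are_equivalent(m, ch$model, 1e-8))
    # identifiable reduced models sit exactly at the parameter bound
    for (red in list(st$model, ch$model)) {
      pb <- parameter_bound(red)
      expect_equal(pb$n_rates, pb$bound)
    }
  }
})

test_that("signed-mixture models only reduce with negative rates", {
  for (s in seeds_in_regime(5, "irreducible_signed_mixture")) {
    inv <- ts_invariants(rand_three_state(s))
    st <- to_star(inv)
    expect_false(st$feasible)
    expect_lt(min(st$rates), 0)     # q31 = rho * lambda_O < 0
    expect_false(to_chain(inv)$feasible)
  }
})

test_that("the equivalence family recovers its generating model", {
  for (s in 1:25) {
    m <- rand_three_state(s)
    inv <- ts_invariants(m)
    if (inv$degenerate) next
    q <- aggmarkov:::ts_rates(m)
    fm <- family_member(inv, q["q13"], q["q23"])
    expect_true(fm$feasible)
    expect_equal(fm$rates, q, tolerance = 1e-8)
    # the star is the boundary member at (lambda1, lambda2)
    fst <- family_member(inv, inv$lambda1, inv$lambda2)
    expect_equal(unname(fst$rates["q12"]), 0, tolerance = 1e-10)
    expect_equal(unname(fst$rates["q21"]), 0, tolerance = 1e-10)
  }
})

test_that("distinct feasible family members are mutually equivalent", {
  m <- rand_three_state(2)
  inv <- ts_invariants(m)
  a <- family_member(inv, inv$lambda1 * 0.9, inv$lambda2 * 0.5)
  b <- family_member(inv, inv$lambda1 * 0.97, inv$lambda2 * 0.2)
  if (a$feasible && b$feasible)
    expect_true(are_equivalent(a$model, b$model, 1e-8))
  expect_error(family_member(inv, 1, 1), "out of domain")
})

test_that("reduction dichotomy: star, chain and mixture class coincide", {
  for (s in 1:200) {
    inv <- ts_invariants(rand_three_state(s))
    if (inv$degenerate) next
    cls <- ts_classify(inv)
    if (cls == "degenerate_boundary") next
    st <- to_star(inv); ch <- to_chain(inv)
    expect_identical(st$feasible, cls == "reducible_mixture")
    expect_identical(ch$feasible, cls == "reducible_mixture")
  }
})

test_that("signed-mixture closed densities are non-monotone", {
  for (s in seeds_in_regime(3, "irreducible_signed_mixture")) {
    m <- rand_three_state(s)
    sj <- sojourn(m, "closed")
    expect_true(any(sj$weights < 0))
    grid <- exp(seq(log(1e-4 / max(sj$rates)), log(20 / min(sj$rates)),
                    length.out = 4000))
    d <- sojourn_density(sj, grid)
    expect_true(all(d >= 0))
    expect_true(any(diff(d) > 0))   # interior extremum: density rises somewhere
  }
  for (s in seeds_in_regime(3, "reducible_mixture")) {
    sj <- sojourn(rand_three_state(s), "closed")
    grid <- exp(seq(log(1e-4 / max(sj$rates)), log(20 / min(sj$rates)),
                    length.out = 4000))
    expect_true(all(diff(sojourn_density(sj, grid)) <= 1e-12))  # monotone decreasing
  }
})

test_that("feasible region contains the star point only in the mixture class", {
  s_mix <- seeds_in_regime(1, "reducible_mixture")
  inv <- ts_invariants(rand_three_state(s_mix))
  g13 <- seq(0.1 * inv$lambda1, inv$lambda1, length.out = 7)
  g23 <- seq(0, inv$lambda2, length.out = 7)
  mask <- feasible_region(inv, g13, g23)
  expect_true(mask[length(g13), length(g23)])  # (lambda1, lambda2) = star
  # every feasible grid point is equivalent to the star reduction
  st <- to_star(inv)
  for (i in seq_along(g13)) for (j in seq_along(g23)) {
    if (!mask[i, j]) next
    fm <- family_member(inv, g13[i], g23[j])
    expect_true(are_equivalent(fm$model, st$model, 1e-8))
  }
  s_sgn <- seeds_in_regime(1, "irreducible_signed_mixture")
  inv2 <- ts_invariants(rand_three_state(s_sgn))
  g13b <- seq(0.05 * inv2$lambda1, 1.5 * inv2$lambda1, length.out = 12)
  g23b <- seq(0, 1.5 * inv2$lambda2, length.out = 12)
  mask2 <- feasible_region(inv2, g13b, g23b)
  # star point infeasible, but the equivalence class is not empty
  expect_false(mask2[which.min(abs(g13b - inv2$lambda1)),
                     which.min(abs(g23b - inv2$lambda2))])
  expect_true(any(mask2))
})

test_that("the detailed-balance curve joins the chain to the star", {
  inv <- ts_invariants(rand_three_state(seeds_in_regime(1, "reducible_mixture")))
  curve <- detailed_balance_curve(inv, n_points = 25)
  expect_length(curve, 25)
  # endpoints: chain (q23 = 0) and star (q12 = q21 = 0)
  expect_equal(curve[[1]]$q23, 0)
  expect_equal(curve[[1]]$q13, inv$rho * inv$lambda1 + (1 - inv$rho) * inv$lambda2,
               tolerance = 1e-10)
  expect_equal(unname(curve[[25]]$rates[c("q12", "q21")]), c(0, 0), tolerance = 1e-9)
  expect_equal(curve[[25]]$q13, inv$lambda1)
  st <- to_star(inv)
  for (fm in curve) {
    expect_true(fm$feasible)
    expect_true(detailed_balance(fm$model, tol = 1e-7)$holds)
    expect_true(are_equivalent(fm$model, st$model, 1e-8))
  }
  # no curve exists in the signed regime
  inv2 <- ts_invariants(rand_three_state(seeds_in_regime(1, "irreducible_signed_mixture")))
  empty <- detailed_balance_curve(inv2)
  expect_length(empty, 0)
  expect_match(attr(empty, "status"), "signed")
})

test_that("the non-reversible q13 = 0 chain variant stays in the class", {
  inv <- ts_invariants(rand_three_state(seeds_in_regime(1, "reducible_mixture")))
  alt <- to_chain(inv, detailed_balance = FALSE)
  expect_equal(unname(alt$rates["q13"]), 0)
  if (alt$feasible) {
    expect_true(are_equivalent(alt$model, to_star(inv)$model, 1e-8))
    expect_false(detailed_balance(alt$model)$holds)
  }
})
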