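# Ligand-dependent star models and the functional forms their chain
# equivalents inherit.  The closed-form constants of the named schemes are
# the oracles here.

rand_ks <- function(seed) {
  set.seed(seed)
  exp(stats::runif(4, log(0.1), log(10)))
}

test_that("scheme constructor binds the named assignments", {
  sch <- ligand_scheme("two_activating", 1, 2, 3, 4)
  expect_equal(unname(sch$kinds),
               c("mass_action", "mass_action", "constant", "constant"))
  expect_error(ligand_scheme("one_activating", -1, 2, 3, 4), "positive")
  expect_error(ligand_scheme("custom", 1, 2, 3, 4), "kinds")
  cust <- ligand_scheme("custom", 1, 2, 3, 4,
                        kinds = c(q13 = "constant", q23 = "constant",
                                  q31 = "constant", q32 = "constant"))
  expect_equal(unname(star_rates_at <- aggmarkov:::star_rates_at(cust, 5)),
               c(1, 2, 3, 4))
})

test_that("star and chain models are equivalent at every concentration", {
  for (s in 1:6) {
    k <- rand_ks(s)
    for (nm in c("two_activating", "one_activating", "activating_inhibitory")) {
      sch <- ligand_scheme(nm, k[1], k[2], k[3], k[4])
      for (c in c(0.05, 0.7, 9)) {
        st <- star_model_at(sch, c)
        if (ts_invariants(st)$degenerate) next
        ch <- chain_model_at(sch, c)
        expect_true(are_equivalent(st, ch, 1e-8))
        # the chain route through the generic reduction agrees
        red <- to_chain(ts_invariants(st))
        r <- chain_rates_at(sch, c)
        expect_equal(unname(red$rates[c("q12", "q21", "q23", "q32")]),
                     as.numeric(r), tolerance = 1e-9)
      }
    }
  }
})

test_that("two activating sites: all chain binding rates are mass action", {
  for (s in 1:20) {
    k <- rand_ks(100 + s)
    sch <- ligand_scheme("two_activating", k[1], k[2], k[3], k[4])
    forms <- classify_forms(sch)
    expect_equal(vapply(forms, `[[`, character(1), "kind"),
                 c(q12 = "mass_action", q21 = "mass_action",
                   q23 = "mass_action", q32 = "constant"))
    expect_equal(unname(forms$q32$constants["k"]), k[3] + k[4], tolerance = 1e-9)
    rep <- unexpected_dependency_report(sch)
    expect_equal(rep$rate, "q21")
  }
})

test_that("one activating site: printed closed-form constants reproduce", {
  for (s in 1:20) {
    k <- rand_ks(200 + s)
    k13 <- k[1]; k23 <- k[2]; k31 <- k[3]; k32 <- k[4]
    sch <- ligand_scheme("one_activating", k13, k23, k31, k32)
    forms <- classify_forms(sch)
    expect_equal(forms$q12$kind, "michaelis_menten")
    expect_equal(unname(forms$q12$constants["F"]), k23 * (k31 + k32) / k31,
                 tolerance = 1e-9)
    expect_equal(unname(forms$q12$constants["H"]), k23 * k32 / (k13 * k31),
                 tolerance = 1e-9)
    expect_equal(forms$q21$kind, "quadratic_over_linear")
    expect_equal(unname(forms$q21$constants["root"]), k23 / k13, tolerance = 1e-9)
    expect_equal(unname(forms$q21$constants["F"]), k13 * k32 / (k31 + k32),
                 tolerance = 1e-9)
    expect_equal(unname(forms$q21$constants["H"]), k23 * k32 / (k13 * k31),
                 tolerance = 1e-9)
    expect_equal(forms$q23$kind, "mass_action_offset")
    expect_equal(unname(forms$q23$constants["k"]), k13 * k31 / (k31 + k32),
                 tolerance = 1e-9)
    expect_equal(unname(forms$q23$constants["K"]), k23 * k32 / (k31 + k32),
                 tolerance = 1e-9)
    expect_equal(forms$q32$kind, "constant")
    expect_equal(unname(forms$q32$constants["k"]), k31 + k32, tolerance = 1e-9)
  }
})

test_that("one activating site: asymptotics and the q21 double root", {
  k <- rand_ks(7)
  k13 <- k[1]; k23 <- k[2]; k31 <- k[3]; k32 <- k[4]
  sch <- ligand_scheme("one_activating", k13, k23, k31, k32)
  H12 <- k23 * k32 / (k13 * k31)
  F12 <- k23 * (k31 + k32) / k31
  F21 <- k13 * k32 / (k31 + k32)
  # q12 saturates to F12, q21 grows like F21 * c, far above half saturation
  far <- 1e6 * H12
  r <- chain_rates_at(sch, far)
  expect_equal(unname(r["q12"]) / F12, 1, tolerance = 1e-3)
  expect_equal(unname(r["q21"]) / (F21 * far), 1, tolerance = 1e-3)
  # q21 >= 0 with equality exactly at c = k23 / k13
  cr <- k23 / k13
  expect_equal(unname(chain_rates_at(sch, cr)["q21"]), 0, tolerance = 1e-12)
  cs <- cr * c(0.2, 0.5, 0.9, 1.1, 2, 10)
  q21s <- vapply(cs, function(c) chain_rates_at(sch, c)["q21"], numeric(1))
  expect_true(all(q21s > 0))
})

test_that("activating + inhibitory site: printed constants reproduce", {
  for (s in 1:20) {
    k <- rand_ks(300 + s)
    k13 <- k[1]; k23 <- k[2]; k31 <- k[3]; k32 <- k[4]
    sch <- ligand_scheme("activating_inhibitory", k13, k23, k31, k32)
    forms <- classify_forms(sch)
    expect_equal(forms$q23$kind, "michaelis_menten")
    expect_equal(unname(forms$q23$constants["H"]), k31 / k32, tolerance = 1e-9)
    expect_equal(unname(forms$q23$constants["F"]),
                 (k13 * k31 + k23 * k32) / k32, tolerance = 1e-9)
    expect_equal(forms$q21$kind, "quadratic_over_linear")
    expect_equal(unname(forms$q21$constants["H"]), k31 / k32, tolerance = 1e-9)
    expect_equal(unname(forms$q21$constants["F"]),
                 k13^2 * k31 / (k13 * k31 + k23 * k32), tolerance = 1e-9)
    expect_equal(forms$q32$kind, "mass_action_offset")
    expect_equal(unname(forms$q32$constants["k"]), k32, tolerance = 1e-9)
    expect_equal(unname(forms$q32$constants["K"]), k31, tolerance = 1e-9)
    expect_equal(forms$q12$kind, "mass_action_offset")
  }
})

test_that("classified constants do not depend on the grid", {
  k <- rand_ks(4)
  sch <- ligand_scheme("one_activating", k[1], k[2], k[3], k[4])
  g1 <- exp(seq(log(2e-3), log(0.9), length.out = 25))
  g2 <- exp(seq(log(1.7), log(800), length.out = 25))
  f1 <- classify_forms(sch, g1); f2 <- classify_forms(sch, g2)
  for (r in names(f1)) {
    expect_identical(f1[[r]]$kind, f2[[r]]$kind)
    expect_equal(f1[[r]]$constants, f2[[r]]$constants, tolerance = 1e-9)
  }
})

test_that("all-constant schemes report nothing unexpected", {
  cust <- ligand_scheme("custom", 1.2, 0.4, 2, 5,
                        kinds = c(q13 = "constant", q23 = "constant",
                                  q31 = "constant", q32 = "constant"))
  rep <- unexpected_dependency_report(cust)
  expect_equal(nrow(rep), 0L)
  rep1 <- unexpected_dependency_report(
    ligand_scheme("one_activating", 1.2, 0.4, 2, 5))
  expect_setequal(rep1$rate, c("q21", "q23"))
})
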