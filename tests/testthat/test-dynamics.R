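test_that("closed-form equilibrium matches the reference values", {
  expect_equal(equilibrium_population(ecology_params()), 309.08,
               tolerance = 1e-4)
  expect_equal(equilibrium_population(ecology_params(alpha = 0.7)), 8.83,
               tolerance = 1e-3)
  expect_equal(round(equilibrium_population(ecology_params(beta = 2.75))), 104)
  expect_equal(round(equilibrium_population(ecology_params(beta = 3.5))), 89)
  expect_equal(equilibrium_population(ecology_params(rho = 0.12)), 0)
  expect_error(equilibrium_population(ecology_params(rho = 0.1)),
               "no positive equilibrium")
})

test_that("equilibrium responds monotonically to the ecological parameters", {
  Ns <- function(...) equilibrium_population(ecology_params(...))
  expect_true(all(diff(sapply(c(0.01, 0.02, 0.1, 0.7), function(a)
    Ns(alpha = a))) < 0))
  expect_true(all(diff(sapply(c(0.12, 0.15, 0.3, 0.6), function(m)
    Ns(mu = m))) < 0))
  expect_true(all(diff(sapply(c(0.5, 1.01, 2, 4), function(r)
    Ns(rho = r))) > 0))
})

test_that("the wild-type equilibrium is a fixed point of all model variants", {
  eco <- ecology_params()
  N <- equilibrium_population(eco)
  wt <- unlist(make_state(aabb = N))
  for (system in c("UD", "KR")) {
    for (timing in c("early", "late")) {
      cfg <- drive_config(system, timing = timing, eps_A = 0.95)
      expect_lt(max(abs(drive_rhs(wt, wt, cfg, eco))), 1e-9)
    }
  }
  # and of the empty state
  z <- numeric(18)
  expect_equal(unname(drive_rhs(z, z, drive_config("UD"), eco)), numeric(18))
})

test_that("early and late timing coincide when every produced genotype is viable", {
  # a-locus-free population: only aa?? genotypes arise, none lethal under KR
  eco <- ecology_params()
  st <- unlist(make_state(aabb = 100, aaBb = 60, aaBB = 40))
  early <- drive_rhs(st, st, drive_config("KR", timing = "early"), eco)
  late <- drive_rhs(st, st, drive_config("KR", timing = "late"), eco)
  expect_equal(early, late, tolerance = 1e-12)
  # but they differ once lethal/costly genotypes are produced
  st2 <- unlist(make_state(aabb = 100, AABB = 100))
  e2 <- drive_rhs(st2, st2, drive_config("KR", timing = "early", eps_A = 0.9), eco)
  l2 <- drive_rhs(st2, st2, drive_config("KR", timing = "late", eps_A = 0.9), eco)
  expect_gt(max(abs(e2 - l2)), 1e-6)
})

test_that("two-deme coupling reduces to independent demes at psi = 0", {
  eco <- ecology_params()
  cfg <- drive_config("UD", eps_A = 0.9)
  s1 <- unlist(make_state(aabb = 200, AABB = 50))
  s2 <- unlist(make_state(aabb = 120, AaBb = 30))
  both <- c(s1, s2)
  d0 <- drive_rhs(both, both, cfg, eco, psi = 0)
  expect_equal(unname(d0),
               unname(c(drive_rhs(s1, s1, cfg, eco),
                        drive_rhs(s2, s2, cfg, eco))),
               tolerance = 1e-14)
})

test_that("migration exchanges counts conservatively and symmetrically", {
  eco <- ecology_params()
  cfg <- drive_config("KR", eps_A = 0.95)
  s1 <- unlist(make_state(aabb = 200, AABB = 50))
  s2 <- unlist(make_state(aabb = 120, AaBb = 30))
  both <- c(s1, s2)
  base <- drive_rhs(both, both, cfg, eco, psi = 0)
  mig <- drive_rhs(both, both, cfg, eco, psi = 0.01)
  flux <- mig - base
  # antisymmetric exchange: deme totals conserved per genotype and sex
  expect_equal(unname(flux[1:18] + flux[19:36]), numeric(18),
               tolerance = 1e-12)
  expect_equal(unname(flux[1:18]), unname(0.01 * (s2 - s1)),
               tolerance = 1e-12)
  # identical demes: no net migration
  same <- c(s1, s1)
  expect_equal(drive_rhs(same, same, cfg, eco, psi = 0.01),
               drive_rhs(same, same, cfg, eco, psi = 0),
               tolerance = 1e-14)
  # one empty deme: pure linear exchange on top of the uncoupled dynamics
  empty_t <- c(numeric(18), s2)
  f <- drive_rhs(empty_t, empty_t, cfg, eco, psi = 0.01) -
    drive_rhs(empty_t, empty_t, cfg, eco, psi = 0)
  expect_equal(unname(f[1:18]), unname(0.01 * s2), tolerance = 1e-12)
  expect_equal(unname(f[19:36]), unname(-0.01 * s2), tolerance = 1e-12)
  expect_error(drive_rhs(both, both, cfg, eco, psi = -0.1), "non-negative")
})
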