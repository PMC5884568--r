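test_that("wild-type and double-homozygote populations are fixed points", {
  wt <- discrete_release_freqs(theta = 0)
  nxt <- discrete_step(wt, drive_config("UD", eps_A = 0.9))
  expect_equal(nxt$m, wt$m, tolerance = 1e-14)
  expect_equal(nxt$f, wt$f, tolerance = 1e-14)
  hom <- list(m = c(numeric(8), 1), f = c(numeric(8), 1))
  nxt <- discrete_step(hom, drive_config("UD", eps_A = 0.5))
  expect_equal(unname(nxt$m), hom$m, tolerance = 1e-14)
})

test_that("one neutral generation reaches Hardy-Weinberg proportions", {
  eta_A <- rep(0:2, each = 3)
  eta_B <- rep(0:2, times = 3)
  gen_dist <- function(pm, pf) {
    c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
  }
  # arbitrary parental composition: each locus reaches single-locus HW in
  # one generation and allele frequencies are conserved (the joint
  # distribution still carries parental linkage disequilibrium)
  fr <- list(m = c(0.3, 0, 0, 0.2, 0.1, 0, 0, 0, 0.4),
             f = c(0.5, 0, 0, 0, 0.2, 0, 0, 0, 0.3))
  pA_m <- sum(eta_A * fr$m) / 2; pA_f <- sum(eta_A * fr$f) / 2
  pB_m <- sum(eta_B * fr$m) / 2; pB_f <- sum(eta_B * fr$f) / 2
  nxt <- discrete_step(fr, drive_config("none", eps_A = 1))
  margA <- sapply(0:2, function(a) sum(nxt$m[eta_A == a]))
  margB <- sapply(0:2, function(b) sum(nxt$m[eta_B == b]))
  expect_equal(margA, gen_dist(pA_m, pA_f), tolerance = 1e-12)
  expect_equal(margB, gen_dist(pB_m, pB_f), tolerance = 1e-12)
  expect_equal(sum(eta_A * nxt$m) / 2, (pA_m + pA_f) / 2, tolerance = 1e-12)
  expect_equal(sum(eta_B * nxt$f) / 2, (pB_m + pB_f) / 2, tolerance = 1e-12)
  # parents at linkage equilibrium: the loci stay independent, so the full
  # nine-genotype distribution is the product of per-locus HW distributions
  dA0 <- c(0.25, 0.5, 0.25)
  dB0 <- c(0.49, 0.42, 0.09)
  le <- numeric(9)
  for (a in 0:2) for (b in 0:2) le[3 * a + b + 1] <- dA0[a + 1] * dB0[b + 1]
  fr_le <- list(m = le, f = le)
  nxt <- discrete_step(fr_le, drive_config("none", eps_A = 1))
  expect_equal(unname(nxt$m), le, tolerance = 1e-12)
  expect_equal(unname(nxt$f), le, tolerance = 1e-12)
})

test_that("neutral allele frequencies are conserved over many generations", {
  tr <- discrete_simulate(drive_config("none", eps_A = 1), theta = 1,
                          generations = 50, conv_tol = 0)
  expect_lt(max(abs(tr$freq_overall - 0.5)), 1e-12)
})

test_that("a population of pure lethal homozygotes goes extinct", {
  fr <- list(m = c(numeric(6), 1, 0, 0), f = c(numeric(6), 1, 0, 0)) # AAbb
  nxt <- discrete_step(fr, drive_config("UD"))
  expect_true(attr(nxt, "extinct"))
  expect_equal(unname(nxt$m), numeric(9))
})

test_that("the discrete UD release is bistable in construct fitness", {
  hi <- discrete_simulate(drive_config("UD", eps_A = 0.95), theta = 1)
  expect_gt(hi$freq_overall[nrow(hi)], 0.9)
  lo <- discrete_simulate(drive_config("UD", eps_A = 0.8), theta = 1)
  expect_lt(lo$freq_overall[nrow(lo)], 1e-6)
})

test_that("the discrete KR release rises transiently then self-eliminates", {
  tr <- discrete_simulate(drive_config("KR", eps_A = 0.95), theta = 1,
                          generations = 2000)
  dipped <- cummin(tr$freq_B)
  expect_gt(max(tr$freq_B - dipped), 0.01)   # clear rise while killer common
  expect_lt(tr$freq_overall[nrow(tr)], 1e-4) # eventual elimination
})

test_that("discrete thresholds order as UD weak > UD strong > KR", {
  ud_s <- discrete_fitness_threshold(drive_config("UD", suppression = "strong"))
  kr_s <- discrete_fitness_threshold(drive_config("KR", suppression = "strong"),
                                     criterion = "kr_increase")
  kr_w <- discrete_fitness_threshold(drive_config("KR", suppression = "weak"),
                                     criterion = "kr_increase")
  expect_gt(ud_s, kr_s)
  expect_gt(ud_s, kr_w)
  expect_gt(kr_w, kr_s)
  scan <- discrete_threshold_scan(drive_config("UD"), thetas = 1,
                                  eps = c(0.5, 0.99))
  expect_equal(scan$grid$criterion_met, c(FALSE, TRUE))
})
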