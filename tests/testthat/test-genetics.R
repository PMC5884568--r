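test_that("the nine genotypes cover the copy-number grid in canonical order", {
  gt <- genotype_table()
  expect_equal(nrow(gt), 9)
  expect_equal(gt$index, 1:9)
  expect_setequal(paste(gt$eta_A, gt$eta_B),
                  paste(rep(0:2, each = 3), rep(0:2, times = 3)))
  expect_equal(gt$index, 3 * gt$eta_A + gt$eta_B + 1)
  expect_equal(gt$label[c(1, 5, 9)], c("aabb", "AaBb", "AABB"))
  expect_equal(gt$eta_A[5], 1)
  expect_equal(gt$eta_B[5], 1)
})

test_that("lethal-effect tables match the four drive configurations", {
  leth <- function(...) lethality(drive_config(...))$gamma_F
  expect_equal(leth("UD", "strong"), c(0, 1, 1, 1, 0, 0, 1, 0, 0))
  expect_equal(leth("UD", "weak"),   c(0, 1, 1, 1, 0, 1, 1, 1, 0))
  expect_equal(leth("KR", "strong"), c(0, 0, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(leth("KR", "weak"),   c(0, 0, 0, 1, 0, 0, 1, 1, 0))
  # females and males receive the same effect under bisex lethality
  bis <- lethality(drive_config("UD", "weak"))
  expect_equal(bis$gamma_M, bis$gamma_F)
  # female-specific lethality zeroes the male column only
  fs <- lethality(drive_config("UD", "strong", lethality = "female_specific"))
  expect_equal(fs$gamma_M, rep(0, 9))
  expect_equal(fs$gamma_F, c(0, 1, 1, 1, 0, 0, 1, 0, 0))
  expect_equal(unlist(lethality(
    drive_config("UD", "strong", lethality = "female_specific"), "Aabb"
  )[, c("gamma_M", "gamma_F")], use.names = FALSE), c(0, 1))
  expect_error(lethality(drive_config("UD"), 10), "1..9")
})

test_that("total fitness is multiplicative across construct copies", {
  # cost-free viable genotypes have fitness 1
  f <- fitness(drive_config("KR", "strong", eps_A = 1))
  expect_equal(f$Omega_M[c(1, 5, 9)], c(1, 1, 1))
  # double heterozygote pays one copy of each cost
  f <- fitness(drive_config("KR", "strong", eps_A = 0.95))
  expect_equal(f$Omega_M[5], 0.9025)
  expect_equal(f$Omega_F[5], 0.9025)
  # a lethal genotype has fitness 0 regardless of eps
  f <- fitness(drive_config("UD", "strong", eps_A = 0.95))
  expect_equal(f$Omega_M[4], 0)
  expect_equal(f$Omega_F[4], 0)
  # asymmetric costs
  f <- fitness(drive_config("none", eps_A = 0.9, eps_B = 0.5))
  expect_equal(f$Omega_F, 0.9^f$eta_A * 0.5^f$eta_B)
})

test_that("fitness is non-increasing in copy number for viable genotypes", {
  for (eps in c(0.2, 0.7, 0.95, 1)) {
    f <- fitness(drive_config("none", eps_A = eps))
    m <- matrix(f$Omega_M, 3, 3, byrow = TRUE) # rows eta_A, cols eta_B
    expect_true(all(diff(m) <= 1e-14))      # along eta_A
    expect_true(all(t(diff(t(m))) <= 1e-14)) # along eta_B
  }
})

test_that("cross() reproduces the brute-force gamete enumeration", {
  bf <- cross_table_bruteforce()
  labs <- genotype_table()$label
  for (j in 1:9) {
    for (k in 1:9) {
      cd <- cross(mother = labs[k], father = labs[j])
      expect_equal(cd$fraction, unname(bf[(j - 1) * 9 + k, ]),
                   tolerance = 1e-14)
      expect_equal(sum(cd$fraction), 1, tolerance = 1e-12)
    }
  }
})

test_that("crosses are symmetric and conserve expected allele counts", {
  gt <- genotype_table()
  for (j in 1:9) {
    for (k in 1:9) {
      ab <- cross(j, k)$fraction
      ba <- cross(k, j)$fraction
      expect_equal(ab, ba, tolerance = 1e-14)
      # expected offspring copy number = mean of parental transmitted copies
      expect_equal(sum(ab * gt$eta_A), (gt$eta_A[j] + gt$eta_A[k]) / 2,
                   tolerance = 1e-12)
      expect_equal(sum(ab * gt$eta_B), (gt$eta_B[j] + gt$eta_B[k]) / 2,
                   tolerance = 1e-12)
    }
  }
})

test_that("canonical crosses give the textbook distributions", {
  forced <- cross("aabb", "AABB")
  expect_equal(forced$fraction[forced$offspring == "AaBb"], 1)
  selfed <- cross("aabb", "aabb")
  expect_equal(selfed$fraction[selfed$offspring == "aabb"], 1)
  dihybrid <- cross("AaBb", "AaBb")
  expect_equal(
    setNames(dihybrid$fraction, dihybrid$offspring),
    c(aabb = 1, aaBb = 2, aaBB = 1, Aabb = 2, AaBb = 4, AaBB = 2,
      AAbb = 1, AABb = 2, AABB = 1) / 16
  )
})

test_that("offspring pools are female-limited and male-frequency weighted", {
  # all-wild-type: every female lays wild-type eggs, one unit per sex
  wt <- make_state(aabb = 300)
  p <- offspring_pools(wt$M, wt$F)
  expect_equal(p$v, c(150, rep(0, 8)))
  expect_equal(p$w, p$v)
  # no males -> no mating -> empty pools
  fem <- make_state(F = c(aabb = 100))
  expect_equal(offspring_pools(fem$M, fem$F)$v, rep(0, 9))
  # pure AABB
  hom <- make_state(AABB = 80)
  expect_equal(offspring_pools(hom$M, hom$F)$v, c(rep(0, 8), 40))
  # mixed state: total egg output is one male + one female unit per female,
  # independent of the male pool size
  st <- make_state(M = c(aabb = 10, AaBb = 5, AABB = 200),
                   F = c(aabb = 30, AABb = 12))
  p <- offspring_pools(st$M, st$F)
  expect_equal(sum(p$v) + sum(p$w), 2 * sum(st$F), tolerance = 1e-12)
  expect_error(offspring_pools(-st$M, st$F), "non-negative")
})
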