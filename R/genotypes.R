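#' The nine two-locus genotypes
#'
#' Two unlinked, independently inherited transgenic constructs (A and B) give
#' nine possible genotypes.  Genotypes are indexed 1..9 in the canonical order
#' `aabb`, `aaBb`, `aaBB`, `Aabb`, `AaBb`, `AaBB`, `AAbb`, `AABb`, `AABB`, so
#' that `index = 3 * eta_A + eta_B + 1` where `eta_A` and `eta_B` are the copy
#' numbers (0, 1 or 2) of each construct.
#'
#' @return A tibble with columns `index`, `label`, `eta_A`, `eta_B`.
#' @examples
#' genotype_table()
#' @export
genotype_table <- function() {
  eta_A <- rep(0:2, each = 3)
  eta_B <- rep(0:2, times = 3)
  code <- function(eta, up, lo) {
    c(paste0(lo, lo), paste0(up, lo), paste0(up, up))[eta + 1]
  }
  tibble(
    index = 1:9,
    label = paste0(code(eta_A, "A", "a"), code(eta_B, "B", "b")),
    eta_A = eta_A,
    eta_B = eta_B
  )
}

genotype_labels <- function() genotype_table()$label

# copy numbers as plain vectors (hot paths)
eta_A_vec <- function() rep(0:2, each = 3)
eta_B_vec <- function() rep(0:2, times = 3)

# resolve a genotype given as label or index to an index 1..9
genotype_index <- function(g) {
  if (is.character(g)) {
    i <- match(g, genotype_labels())
    if (anyNA(i)) abort(paste0("unknown genotype label: ", g[is.na(i)][1]))
    return(i)
  }
  i <- as.integer(g)
  if (anyNA(i) || any(i < 1L) || any(i > 9L)) {
    abort("genotype index must be in 1..9")
  }
  i
}

# per-locus transmission: probability that a parent with `eta` copies passes
# one copy to a gamete (homozygote 1, heterozygote 1/2, absent 0)
transmit_prob <- function(eta) eta / 2

#' Mendelian cross between two genotypes
#'
#' Offspring genotype distribution for a mating pair, assuming the two
#' constructs segregate independently at unlinked autosomal loci.  Per-locus
#' gamete probabilities (1 for homozygotes, 1/2 each for heterozygotes) are
#' convolved across the two parents and multiplied across loci.
#'
#' @param mother,father Genotype label (e.g. `"AaBb"`) or index 1..9.
#' @return A tibble with columns `mother`, `father`, `offspring`, `fraction`;
#'   fractions over the nine offspring genotypes sum to 1.
#' @examples
#' cross("AABB", "aabb") # all offspring AaBb
#' cross("AaBb", "AaBb")
#' @export
cross <- function(mother, father) {
  im <- genotype_index(mother)
  ip <- genotype_index(father)
  frac <- cross_matrix()[(ip - 1L) * 9L + im, ]
  tibble(
    mother = genotype_labels()[im],
    father = genotype_labels()[ip],
    offspring = genotype_labels(),
    fraction = as.numeric(frac)
  )
}

# offspring copy-number distribution at one locus given parental copy numbers
locus_offspring_dist <- function(eta_m, eta_p) {
  tm <- transmit_prob(eta_m)
  tp <- transmit_prob(eta_p)
  c(
    (1 - tm) * (1 - tp),
    tm * (1 - tp) + (1 - tm) * tp,
    tm * tp
  )
}

#' Full 81 x 9 cross table
#'
#' Offspring genotype fractions for every ordered (father, mother) pair.
#' Row `(j - 1) * 9 + k` holds the distribution for father `j` x mother `k`.
#'
#' @return A 81 x 9 numeric matrix; rows sum to 1.
#' @keywords internal
cross_matrix <- function() {
  if (!is.null(the$cross_matrix)) {
    return(the$cross_matrix)
  }
  eA <- eta_A_vec()
  eB <- eta_B_vec()
  P <- matrix(0, 81, 9)
  for (j in 1:9) {
    for (k in 1:9) {
      dA <- locus_offspring_dist(eA[k], eA[j])
      dB <- locus_offspring_dist(eB[k], eB[j])
      row <- numeric(9)
      for (a in 0:2) for (b in 0:2) row[3 * a + b + 1] <- dA[a + 1] * dB[b + 1]
      P[(j - 1L) * 9L + k, ] <- row
    }
  }
  colnames(P) <- genotype_labels()
  the$cross_matrix <- P
  P
}

# transposed (9 x 81) layout consumed by the C++ right-hand side
cross_matrix_t <- function() {
  if (is.null(the$cross_matrix_t)) the$cross_matrix_t <- t(cross_matrix())
  the$cross_matrix_t
}
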