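#' Build a population state from genotype counts
#'
#' Convenience constructor for test states.  Counts given for a genotype are
#' split equally between the sexes unless `M`/`F` overrides are supplied.
#'
#' @param ... Named total adult counts per genotype label, e.g.
#'   `aabb = 300, AABB = 150`.
#' @param M,F Optional named vectors of per-sex counts, added to the split
#'   from `...`.
#' @return A list with numeric vectors `M` and `F` (length 9, canonical
#'   order).
#' @examples
#' make_state(aabb = 309.08)
#' make_state(M = c(AABB = 10))
#' @export
make_state <- function(..., M = NULL, F = NULL) {
  tot <- c(...)
  m <- f <- setNames(numeric(9), genotype_labels())
  if (length(tot)) {
    i <- genotype_index(names(tot))
    m[i] <- m[i] + tot / 2
    f[i] <- f[i] + tot / 2
  }
  if (!is.null(M)) m[genotype_index(names(M))] <- m[genotype_index(names(M))] + M
  if (!is.null(F)) f[genotype_index(names(F))] <- f[genotype_index(names(F))] + F
  if (any(m < 0) || any(f < 0)) abort("counts must be non-negative")
  list(M = m, F = f)
}

#' Brute-force cross table by gamete enumeration
#'
#' Independent oracle for [cross()]: enumerates the 2 x 2 x 2 x 2 equally
#' weighted gamete draws (one allele per locus per parent, heterozygotes
#' contributing each allele with probability 1/2) and tallies offspring
#' genotypes directly.  Kept deliberately separate from the production
#' per-locus convolution.
#'
#' @return A 81 x 9 matrix of offspring fractions; row `(j-1)*9 + k` is
#'   father `j` x mother `k`.
#' @examples
#' bf <- cross_table_bruteforce()
#' all(abs(rowSums(bf) - 1) < 1e-12)
#' @export
cross_table_bruteforce <- function() {
  eA <- rep(0:2, each = 3)
  eB <- rep(0:2, times = 3)
  # alleles carried at a locus given copy number: two slots, each 0 or 1
  slots <- function(eta) switch(eta + 1, c(0, 0), c(0, 1), c(1, 1))
  P <- matrix(0, 81, 9, dimnames = list(NULL, genotype_labels()))
  for (j in 1:9) {
    for (k in 1:9) {
      fa_A <- slots(eA[j]); fa_B <- slots(eB[j])
      mo_A <- slots(eA[k]); mo_B <- slots(eB[k])
      for (sa in 1:2) for (sb in 1:2) for (ta in 1:2) for (tb in 1:2) {
        off_A <- fa_A[sa] + mo_A[ta]
        off_B <- fa_B[sb] + mo_B[tb]
        i <- 3L * off_A + off_B + 1L
        P[(j - 1L) * 9L + k, i] <- P[(j - 1L) * 9L + k, i] + 1 / 16
      }
    }
  }
  P
}
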