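# internal helpers

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# is `x` a permutation of 1..n?
isPermutation <- function(x, n) {
  length(x) == n && !anyNA(x) && identical(sort(as.integer(x)), seq_len(n))
}

checkSequence <- function(order, Z) {
  order <- as.integer(order)
  if (!isPermutation(order, Z))
    stop("`order` must be a permutation of 1..", Z, call. = FALSE)
  order
}

# deterministic sub-stream seeds: one stream per operation so adding
# phenotypes or visits never perturbs the biomarker draws
streamSeed <- function(seed, op) {
  offsets <- c(cohort = 0L, visits = 10007L, phenotypes = 20011L,
               bootstrap = 30013L, mcmc = 40031L, restart = 50021L)
  (as.integer(seed) + offsets[[op]]) %% .Machine$integer.max
}

# all permutations of 1..n in lexicographic order, as a matrix (n! rows)
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
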