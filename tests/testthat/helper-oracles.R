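# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms/recurrences than the package.

# pair weights of the documented proxy scoring model
oracle_pair_weight <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, CG = 1.5, AT = 1.0, GT = 0.5, 0)
}

# maximum-weight non-crossing pairing by memoized recursion on the
# *leftmost* base (the package kernel iterates on the rightmost base)
oracle_fold_energy <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  E <- function(i, j) {
    if (j - i <= min_loop) return(0)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- E(i + 1, j)  # leftmost base unpaired
    for (k in (i + min_loop + 1):j) {
      w <- oracle_pair_weight(ch[i], ch[k])
      if (w > 0)
        best <- max(best, w + E(i + 1, k - 1) +
                      if (k < j) E(k + 1, j) else 0)
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) 0 else -E(1, n)
}

# all-pairs shortest path (Floyd-Warshall) on backbone + pair edges
oracle_structure_distance <- function(n, pairs, a, b) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n - 1)) D[i, i + 1] <- D[i + 1, i] <- 1
  if (nrow(pairs))
    for (r in seq_len(nrow(pairs)))
      D[pairs[r, 1], pairs[r, 2]] <- D[pairs[r, 2], pairs[r, 1]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) {
    cand <- D[i, k] + D[k, ]
    upd <- cand < D[i, ]
    D[i, upd] <- cand[upd]
  }
  D[a, b]
}

# hypergeometric upper tail P(X >= a) by explicit enumeration of the
# 2x2 tables (no phyper)
oracle_hyper_tail <- function(a, b, n_target, n_other) {
  K <- a + b
  xs <- a:min(K, n_target)
  xs <- xs[K - xs <= n_other]
  sum(choose(n_target, xs) * choose(n_other, K - xs)) /
    choose(n_target + n_other, K)
}

# position-by-position PWM scan (R loop, no kernel)
oracle_pwm_best <- function(seq, lom) {
  ch <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  L <- nrow(lom); n <- length(ch)
  if (n < L) return(NA_real_)
  best <- -Inf
  for (s in 0:(n - L)) {
    idx <- ch[s + seq_len(L)]
    if (anyNA(idx)) next
    best <- max(best, sum(lom[cbind(seq_len(L), idx)]))
  }
  best
}

# random intron-free test sequence containing only ACGT
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
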