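DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Encode a DNA/RNA string as integers
#'
#' A=0, C=1, G=2, T/U=3; any other letter becomes -1.
#' @param seq single character string.
#' @return integer vector, one element per letter.
#' @keywords internal
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- match(strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1]], DNA_BASES)
  v[is.na(v)] <- 0L
  v - 1L
}

#' GC fraction of a sequence
#' @param seq DNA string.
#' @return real in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) == 0L) return(NA_real_)
  mean(ch %in% c("G", "C"))
}

#' Random DNA with a target GC content
#'
#' Letters are drawn i.i.d.; the GC mass is split evenly between G and C and
#' the AT mass between A and T.
#' @param n length in nucleotides.
#' @param gc target GC fraction in (0, 1).
#' @return DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Hamming distance between two equal-length strings
#' @param a,b character strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming_distance() requires equal-length strings")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a pipeline seed
#'
#' Counter-based scheme so each pipeline stage is independently reproducible
#' from the single top-level seed. Always below 2^31.
#' @param seed integer master seed.
#' @param stage integer stage counter.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483629)
}

# Spearman rho between two numeric vectors (pairwise complete).
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(cor(rank(x[ok]), rank(y[ok])))
}

# Asymptotic two-sided p-value for a Spearman correlation (t approximation).
spearman_p <- function(rho, n) {
  if (!is.finite(rho) || n < 4L) return(NA_real_)
  r <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}
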