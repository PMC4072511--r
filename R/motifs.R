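# De-novo discovery of candidate splicing-regulatory motifs from high- vs
# low-expression intron sets (hypergeometric k-mer enrichment with BH FDR),
# positional localization against a motif-permutation null, probability-
# matrix similarity and clan merging, and the enhancer->silencer swap used
# as a worked example.

#' Construct a motif object
#'
#' @param id motif identifier.
#' @param ppm L x 4 position probability matrix (columns A,C,G,T; each row
#'   sums to 1); 4 <= L <= 12.
#' @param class `"enhancer"`, `"silencer"` or `"unknown"`.
#' @param enrichment_p discovery p-value.
#' @param pseudocount added to the PPM before log-odds conversion.
#' @return object of class `motif` with consensus and score range
#'   precomputed.
#' @export
motif <- function(id, ppm, class = c("unknown", "enhancer", "silencer"),
                  enrichment_p = NA_real_, pseudocount = 0.01) {
  class <- match.arg(class)
  ppm <- as.matrix(ppm)
  colnames(ppm) <- DNA_BASES
  L <- nrow(ppm)
  if (L < 4 || L > 12) stop("motif length must be between 4 and 12")
  if (any(abs(rowSums(ppm) - 1) > 1e-9))
    stop("each PPM row must sum to 1")
  lom <- log2((ppm + pseudocount) / (1 + 4 * pseudocount) / 0.25)
  structure(list(id = as.character(id), ppm = ppm,
                 consensus = .ppm_consensus(ppm), class = class,
                 enrichment_p = enrichment_p, clan = NA_integer_,
                 pseudocount = pseudocount, logodds = lom,
                 min_score = sum(apply(lom, 1, min)),
                 max_score = sum(apply(lom, 1, max))),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif %s> %s (%s, p=%.3g, clan=%s)\n", x$id, x$consensus,
              x$class, x$enrichment_p,
              if (is.na(x$clan)) "-" else x$clan))
  invisible(x)
}

# log-odds matrix of a motif (uniform 0.25 background)
motif_logodds <- function(m) m$logodds

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R",
            AT = "W", CG = "S", CT = "Y", GT = "K", ACG = "V", ACT = "H",
            AGT = "D", CGT = "B", ACGT = "N")

.ppm_consensus <- function(ppm) {
  paste(apply(ppm, 1, function(p) {
    keep <- DNA_BASES[p >= 0.25]
    if (!length(keep)) keep <- DNA_BASES[which.max(p)]
    .IUPAC[[paste(keep, collapse = "")]]
  }), collapse = "")
}

#' Build a near-one-hot motif from a consensus sequence
#'
#' @param consensus ACGT string, 4-12 nt.
#' @param id motif id (defaults to the consensus).
#' @param class motif class.
#' @param certainty probability mass on the consensus letter per position.
#' @return a [motif()].
#' @export
motif_from_consensus <- function(consensus, id = consensus,
                                 class = "unknown", certainty = 0.97) {
  enc <- encode_dna(consensus) + 1L
  if (any(enc < 1L)) stop("consensus must be an ACGT string")
  L <- length(enc)
  ppm <- matrix((1 - certainty) / 3, L, 4)
  ppm[cbind(seq_len(L), enc)] <- certainty
  motif(id, ppm, class = class)
}

# distinct k-mers of each sequence
.kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(toupper(s), 1:(n - k + 1), k:n))
  })
}

#' Hypergeometric enrichment p-value for k-mer presence
#'
#' One-sided tail probability that at least `a` of the `a + b` sequences
#' containing the k-mer fall in the target set, when `n_target` of the
#' `n_target + n_other` sequences are targets.
#'
#' @param a k-mer-containing sequences in the target set.
#' @param b k-mer-containing sequences in the other set.
#' @param n_target,n_other set sizes.
#' @return one-sided p-value.
#' @export
hypergeom_enrichment_p <- function(a, b, n_target, n_other) {
  phyper(a - 1, n_target, n_other, a + b, lower.tail = FALSE)
}

#' Discover enhancer/silencer k-mer motifs
#'
#' For every k-mer in the given length range, presence/absence counts in
#' the high- and low-expression sets are tested with a one-sided
#' hypergeometric tail in each direction; Benjamini-Hochberg FDR is applied
#' across all tests, and surviving k-mers are expanded into position
#' probability matrices by aligning their occurrences with 1 nt of flanking
#' sequence.
#'
#' @param high_set,low_set character vectors of intron sequences.
#' @param k_range k-mer lengths to test (default 6:8).
#' @param alpha_fdr BH threshold (default 0.05).
#' @param max_motifs cap on the number of motifs returned (most significant
#'   first).
#' @return list of [motif()] objects, sorted by enrichment p; the BH q-value
#'   is carried in field `q`.
#' @export
discover_motifs <- function(high_set, low_set, k_range = 6:8,
                            alpha_fdr = 0.05, max_motifs = 50) {
  if (!length(high_set) || !length(low_set))
    stop("both sequence sets must be non-empty")
  if (min(nchar(c(high_set, low_set))) < max(k_range))
    stop("all sequences must be at least max(k_range) long")
  nH <- length(high_set); nL <- length(low_set)
  tab <- list()
  for (k in k_range) {
    hi <- .kmer_sets(high_set, k)
    lo <- .kmer_sets(low_set, k)
    cnt_h <- table(unlist(hi)); cnt_l <- table(unlist(lo))
    kmers <- union(names(cnt_h), names(cnt_l))
    a <- as.integer(cnt_h[kmers]); a[is.na(a)] <- 0L
    b <- as.integer(cnt_l[kmers]); b[is.na(b)] <- 0L
    p_enh <- hypergeom_enrichment_p(a, b, nH, nL)
    p_sil <- hypergeom_enrichment_p(b, a, nL, nH)
    tab[[length(tab) + 1L]] <- tibble::tibble(
      kmer = rep(kmers, 2L),
      class = rep(c("enhancer", "silencer"), each = length(kmers)),
      a = c(a, b), p = c(p_enh, p_sil))
  }
  tab <- do.call(rbind, tab)
  tab$q <- p.adjust(tab$p, method = "BH")
  hits <- tab[tab$q <= alpha_fdr & tab$a > 0, , drop = FALSE]
  if (!nrow(hits)) return(list())
  # a k-mer is reported once, in its more significant direction
  hits <- hits[order(hits$p), , drop = FALSE]
  hits <- hits[!duplicated(hits$kmer), , drop = FALSE]
  hits <- head(hits, max_motifs)
  out <- lapply(seq_len(nrow(hits)), function(i) {
    kmer <- hits$kmer[i]
    src <- if (hits$class[i] == "enhancer") high_set else low_set
    m <- motif(sprintf("%s_%s",
                       if (hits$class[i] == "enhancer") "enh" else "sil",
                       kmer),
               .ppm_from_occurrences(src, kmer),
               class = hits$class[i], enrichment_p = hits$p[i])
    m$q <- hits$q[i]
    m
  })
  out
}

# PPM from all occurrences of `kmer` in `seqs`, extended 1 nt on each side;
# out-of-range flanks contribute a uniform background observation
.ppm_from_occurrences <- function(seqs, kmer, pseudo = 0.5) {
  k <- nchar(kmer)
  counts <- matrix(pseudo, k + 2L, 4L)
  for (s in seqs) {
    s <- toupper(s)
    starts <- gregexpr(kmer, s, fixed = TRUE)[[1]]
    if (starts[1] == -1L) next
    for (st in starts) {
      ext <- substr(s, max(1L, st - 1L), st + k)  # substr clips at the end
      enc <- encode_dna(ext) + 1L
      pos <- (if (st == 1L) 2L else 1L) + seq_along(enc) - 1L
      okc <- enc >= 1L & enc <= 4L
      counts[cbind(pos[okc], enc[okc])] <-
        counts[cbind(pos[okc], enc[okc])] + 1L
    }
  }
  counts / rowSums(counts)
}

#' Positional enrichment of a motif relative to a splice site
#'
#' Counts PWM hits (score at least `score_frac * max_score`) at every
#' offset from the anchor across introns, and compares them with a null
#' obtained by shuffling the motif's position rows (which preserves length,
#' per-column composition and total information content). The permutation
#' null at each position is summarized as an add-one-smoothed Poisson hit
#' rate, from which two-sided tail p-values are taken and BH-corrected
#' across offsets. (A raw empirical p is floored at `2/(n_perm + 1)` and
#' could never clear the BH correction for a single enriched position at
#' practical permutation depths; the rate summary keeps the permutation
#' null in charge while making the test continuous.)
#'
#' @param motif a [motif()].
#' @param introns list of [intron_record()]s.
#' @param anchor `"5ss"` (offsets count from the first intron base) or
#'   `"3ss"` (offsets count back from the last intron base).
#' @param offsets offsets to evaluate; defaults to `0:60` for the 5'SS and
#'   `-60:-(L-1)` for the 3'SS.
#' @param n_perm number of motif permutations (>= 100).
#' @param alpha flag threshold after BH correction.
#' @param score_frac hit threshold as a fraction of the maximal score.
#' @param seed RNG seed.
#' @return tibble with `anchor, offset, observed, null_mean, p, q, flag`
#'   (`flag` in `enriched`, `deprived`, `ns`).
#' @export
positional_enrichment <- function(motif, introns, anchor = c("5ss", "3ss"),
                                  offsets = NULL, n_perm = 1000,
                                  alpha = 0.05, score_frac = 0.8,
                                  seed = NULL) {
  anchor <- match.arg(anchor)
  if (n_perm < 100) stop("n_perm must be at least 100")
  L <- nrow(motif$ppm)
  if (is.null(offsets))
    offsets <- if (anchor == "5ss") 0:60 else -60:-(L - 1)
  thr <- score_frac * motif$max_score
  encs <- lapply(introns, function(ir) encode_dna(ir$sequence))
  lens <- vapply(encs, length, 0L)
  count_hits <- function(lom) {
    counts <- setNames(numeric(length(offsets)), offsets)
    for (i in seq_along(encs)) {
      sc <- .pwm_scan(encs[[i]], lom)
      if (!length(sc)) next
      hit_pos <- which(!is.na(sc) & sc >= thr) - 1L    # 0-based starts
      if (!length(hit_pos)) next
      off <- if (anchor == "5ss") hit_pos else hit_pos - (lens[i] - 1L)
      keep <- off %in% offsets
      if (any(keep)) {
        t_off <- table(off[keep])
        counts[names(t_off)] <- counts[names(t_off)] + as.integer(t_off)
      }
    }
    counts
  }
  observed <- count_hits(motif$logodds)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p)
      count_hits(motif$logodds[sample(L), , drop = FALSE]),
      numeric(length(offsets)))
  })
  null_counts <- matrix(null_counts, nrow = length(offsets))
  null_mean <- rowMeans(null_counts)
  rate <- (rowSums(null_counts) + 1) / (n_perm + 1)
  p_up <- stats::ppois(observed - 1, rate, lower.tail = FALSE)
  p_dn <- stats::ppois(observed, rate)
  p <- pmin(1, 2 * pmin(p_up, p_dn))
  q <- p.adjust(p, method = "BH")
  flag <- rep("ns", length(offsets))
  flag[q <= alpha & observed > null_mean] <- "enriched"
  flag[q <= alpha & observed < null_mean] <- "deprived"
  tibble::tibble(anchor = anchor, offset = as.integer(offsets),
                 observed = as.numeric(observed), null_mean = null_mean,
                 p = p, q = q, flag = flag)
}

#' Similarity between two motifs' probability matrices
#'
#' Best ungapped offset alignment of the two PPMs; at each alignment the
#' score is the mean over overlapping positions of `1 - total variation
#' distance` between the position distributions, and at least 4 positions
#' must overlap (otherwise the motifs are incomparable and score 0).
#' Symmetric, in \[0, 1\].
#'
#' @param m1,m2 [motif()] objects.
#' @return similarity in \[0, 1\].
#' @export
motif_similarity <- function(m1, m2) {
  p1 <- m1$ppm; p2 <- m2$ppm
  L1 <- nrow(p1); L2 <- nrow(p2)
  best <- 0
  for (shift in -(L2 - 4):(L1 - 4)) {
    i1 <- max(1, 1 + shift):min(L1, L2 + shift)
    i2 <- i1 - shift
    if (length(i1) < 4) next
    tv <- rowSums(abs(p1[i1, , drop = FALSE] - p2[i2, , drop = FALSE])) / 2
    best <- max(best, mean(1 - tv))
  }
  best
}

#' Merge similar motifs into clans
#'
#' Single-linkage clustering of the similarity graph: motifs with pairwise
#' similarity strictly above the threshold are connected, connected
#' components become clans, and each clan is represented by its most
#' significant member.
#'
#' @param motifs list of [motif()]s.
#' @param threshold similarity merge threshold (default 0.6).
#' @return the motif list with `clan` fields set; the attribute
#'   `representatives` holds one motif id per clan.
#' @export
merge_clans <- function(motifs, threshold = 0.6) {
  n <- length(motifs)
  if (!n) return(motifs)
  sim <- diag(1, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      sim[i, j] <- sim[j, i] <- motif_similarity(motifs[[i]], motifs[[j]])
  g <- igraph::graph_from_adjacency_matrix(sim > threshold, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  reps <- character(max(comp))
  for (cl in seq_len(max(comp))) {
    members <- which(comp == cl)
    ps <- vapply(motifs[members], function(m)
      if (is.na(m$enrichment_p)) Inf else m$enrichment_p, 0)
    reps[cl] <- motifs[[members[order(ps, members)[1]]]]$id
  }
  for (i in seq_len(n)) motifs[[i]]$clan <- as.integer(comp[i])
  attr(motifs, "representatives") <- reps
  motifs
}

#' Swap a motif occurrence inside a sequence
#'
#' Replaces one occurrence of `from_motif` by `to_motif` (equal lengths),
#' e.g. turning the enhancer `TTTATGCT` into the silencer `TTTGTGTA` (a
#' 3-nt change). Without an explicit position the occurrence must be
#' unique.
#'
#' @param seq DNA string.
#' @param from_motif motif currently present.
#' @param to_motif replacement of the same length.
#' @param at optional 1-based occurrence start to disambiguate.
#' @return list with `sequence`, `position` (1-based) and `hamming` (the
#'   number of changed nucleotides).
#' @export
mutate_motif_in_sequence <- function(seq, from_motif = "TTTATGCT",
                                     to_motif = "TTTGTGTA", at = NULL) {
  if (nchar(from_motif) != nchar(to_motif))
    stop("from_motif and to_motif must have equal length")
  seq <- toupper(seq)
  starts <- gregexpr(from_motif, seq, fixed = TRUE)[[1]]
  if (starts[1] == -1L) stop("motif '", from_motif, "' not found")
  if (is.null(at)) {
    if (length(starts) > 1L)
      stop("motif occurs ", length(starts),
           " times; disambiguate with `at`")
    at <- starts[1]
  } else if (!at %in% starts) {
    stop("no occurrence of '", from_motif, "' at position ", at)
  }
  substr(seq, at, at + nchar(to_motif) - 1L) <- to_motif
  list(sequence = seq, position = as.integer(at),
       hamming = hamming_distance(from_motif, to_motif))
}
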