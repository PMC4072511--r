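test_that("GC profile equals a direct window recount", {
  expect_true(all(gc_profile(strrep("G", 200), 100, 50, -20:20) == 1))
  # window size a multiple of the repeat period: GC exactly one half
  expect_true(all(gc_profile(strrep("ATGC", 50), 100, 48, -10:10) == 0.5))
  s <- rand_seq(500, seed = 12)
  prof <- gc_profile(s, 250, 50, -60:60)
  for (d in seq(-60, 60, by = 7)) {
    win <- substr(s, 250 + d + 1, 250 + d + 50)
    expect_equal(unname(prof[as.character(d)]), gc_fraction(win))
  }
  # out-of-range windows are NaN
  expect_true(is.na(gc_profile("ACGT", 0, 50, 0)[["0"]]))
  expect_error(gc_profile("ACGT", 0, window = 0), "window")
})

test_that("proxy folding energies match the independent DP oracle", {
  be <- folding_backend("nussinov_proxy")
  expect_identical(be$fold(strrep("A", 40))$energy, 0)
  # sanity of the oracle itself on hand-computable cases
  expect_identical(oracle_fold_energy("AAAA"), 0)
  expect_identical(oracle_fold_energy("GAAAC"), -1.5)  # one G-C pair
  expect_identical(oracle_fold_energy("GGGGAAAACCCC"), -6)
  set.seed(33)
  for (i in 1:60) {
    s <- rand_seq(sample(8:20, 1))
    expect_equal(be$fold(s)$energy, oracle_fold_energy(s),
                 info = s)
  }
  # reported pairs are consistent with the reported energy
  r <- be$fold("GGGGAAAACCCC")
  w <- sum(apply(r$pairs, 1, function(p) {
    ch <- strsplit("GGGGAAAACCCC", "")[[1]]
    oracle_pair_weight(ch[p[1]], ch[p[2]])
  }))
  expect_equal(-w, r$energy)
})

test_that("a hairpin folds more strongly than its shuffled version", {
  be <- folding_backend("nussinov_proxy")
  hairpin <- "GGGGGAAAACCCCC"
  set.seed(5)
  for (i in 1:10) {
    shuf <- paste(sample(strsplit(hairpin, "")[[1]]), collapse = "")
    expect_lte(be$fold(hairpin)$energy, be$fold(shuf)$energy)
  }
  # proxy energies are never positive
  for (i in 1:30) expect_lte(be$fold(rand_seq(25))$energy, 0)
})

test_that("the ViennaRNA backend folds a hairpin and leaves polyA open", {
  be <- folding_backend("vienna")
  hp <- be$fold("GGGGGGAAAAAACCCCCC")
  expect_lt(hp$energy, 0)
  expect_gt(nrow(hp$pairs), 0)
  expect_identical(be$fold(strrep("A", 30))$energy, 0)
})

test_that("folding-energy profile windows the sequence correctly", {
  be <- folding_backend("nussinov_proxy")
  s <- paste0(strrep("A", 50), "GGGGGAAAACCCCC", strrep("A", 50))
  prof <- folding_energy_profile(s, 50, window = 14, offsets = c(-50, 0, 40),
                                 backend = be)
  expect_identical(unname(prof[["0"]]), be$fold("GGGGGAAAACCCCC")$energy)
  expect_identical(unname(prof[["-50"]]), 0)  # all-A window
  expect_true(is.na(folding_energy_profile(s, 110, window = 40,
                                           offsets = 0, backend = be)[["0"]]))
})

test_that("structure distances agree with all-pairs shortest paths", {
  be <- folding_backend("nussinov_proxy")
  # no pairs: backbone distance
  expect_identical(structure_distance(strrep("A", 20), 3, 17, be), 14L)
  set.seed(77)
  for (i in 1:20) {
    s <- rand_seq(sample(10:25, 1))
    n <- nchar(s)
    pairs <- be$fold(s)$pairs
    for (j in 1:5) {
      ab <- sample(n, 2)
      expect_identical(
        structure_distance(s, ab[1], ab[2], be),
        as.integer(oracle_structure_distance(n, pairs, ab[1], ab[2])))
    }
  }
  # directly paired ends are one step apart
  d <- structure_distance("GGGGAAAACCCC", 1, 12, be)
  expect_identical(d, 1L)
})

test_that("simple features are exact coordinate arithmetic", {
  ir <- generate_intron(100, seed = 8, bp_offset = 60)
  f <- simple_features(ir)
  expect_identical(unname(f["intron_length"]), 100)
  expect_identical(unname(f["bp_to_5ss"]), 60)
  expect_identical(unname(f["bp_to_3ss"]), 39)
  expect_identical(unname(f["is_rpg"]), 0)
  expect_equal(unname(f["intron_gc"]), gc_fraction(ir$sequence))
})

test_that("motif scores equal the brute-force best-window scan", {
  m <- motif_from_consensus("TACGTA")
  expect_equal(unname(motif_scores("GGTACGTAGG", list(m))["TACGTA"]),
               m$max_score)
  # uniform PWM scores zero everywhere (log-odds against uniform background)
  u <- uniform_motif(6)
  expect_equal(unname(motif_scores(rand_seq(50, seed = 3), list(u))["unif"]),
               0)
  set.seed(19)
  for (i in 1:25) {
    s <- rand_seq(sample(10:80, 1))
    expect_equal(unname(motif_scores(s, list(m))["TACGTA"]),
                 oracle_pwm_best(s, m$logodds))
  }
  # sequence shorter than the motif
  expect_true(is.na(motif_scores("ACG", list(m))["TACGTA"]))
})

test_that("the feature matrix is deterministic with stable metadata", {
  introns <- lapply(1:4, function(i) generate_intron(80, seed = 400 + i))
  ccs <- lapply(introns, generate_reporter_construct,
                exon_seq = example_reporter_cds(), insertion_offset = 195)
  cfg <- feature_config(gc_offsets = c(-12L, 3L), fe_offsets = c(-12L, 3L))
  ms <- list(motif_from_consensus("TTTATGCT", id = "enh"))
  X1 <- build_feature_matrix(ccs, ms, cfg)
  X2 <- build_feature_matrix(ccs, ms, cfg)
  expect_identical(X1, X2)
  info <- attr(X1, "feature_info")
  expect_identical(nrow(info), ncol(X1))
  expect_setequal(unique(info$category),
                  c("simple", "gc", "folding", "motif", "structure"))
  # 5 simple + 2 anchors x 2 offsets x 2 window types + 1 motif + 3 structure
  expect_identical(ncol(X1), 5L + 8L + 1L + 3L)
  expect_error(build_feature_matrix(c(ccs, ccs[1]), ms, cfg), "duplicate")
  # out-of-range windows propagate NaN: anchor near the transcript end
  short <- generate_reporter_construct(introns[[1]], "AAAAACCCCC", 5)
  Xs <- build_feature_matrix(list(short), NULL,
                             feature_config(gc_offsets = c(60L),
                                            fe_offsets = c(60L)))
  expect_true(anyNA(Xs))
})

test_that("correlation profiles recover a planted offset exactly", {
  set.seed(55)
  P <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, as.character(c(-2, -1, 0, 1, 2))))
  y <- P[, "1"]                      # expression equals the +1 column
  cp <- correlation_profile(P, y)
  expect_equal(cp$rho[cp$offset == 1], 1)
  # every reported offset matches a direct rank correlation
  for (k in seq_len(nrow(cp))) {
    j <- as.character(cp$offset[k])
    expect_equal(cp$rho[k],
                 suppressWarnings(cor(P[, j], y, method = "spearman")))
  }
  # offsets with too few complete pairs are dropped
  P2 <- P; P2[1:27, "0"] <- NA
  expect_false(0 %in% correlation_profile(P2, y)$offset)
})
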