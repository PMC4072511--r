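# Intron/junction feature database: sliding-window GC and folding-energy
# profiles anchored at the splice sites, simple coordinate features, motif
# scores and structure-graph distances, assembled into a feature matrix.
#
# Coordinates are 0-based and windows half-open [start, start + window); the
# 5'SS anchor is the first intron base, the 3'SS anchor the last intron
# base, and negative offsets extend into the exon.

#' Sliding-window GC profile around an anchor
#'
#' Value at offset `d` is the GC fraction of the window starting at
#' `anchor_pos + d` (0-based); windows extending outside the sequence give
#' NaN.
#'
#' @param pre_mrna DNA string.
#' @param anchor_pos 0-based anchor position.
#' @param window window size in nt (default 50).
#' @param offsets integer vector of window-start offsets.
#' @return named numeric vector (names = offsets) in \[0, 1\].
#' @export
gc_profile <- function(pre_mrna, anchor_pos, window = 50,
                       offsets = -60:60) {
  if (window <= 0) stop("window must be positive")
  enc <- encode_dna(pre_mrna)
  n <- length(enc)
  cs <- c(0, cumsum(enc == 1L | enc == 2L))  # C or G
  starts <- anchor_pos + offsets             # 0-based window starts
  val <- rep(NA_real_, length(offsets))
  ok <- starts >= 0 & (starts + window) <= n
  val[ok] <- (cs[starts[ok] + window + 1L] - cs[starts[ok] + 1L]) / window
  setNames(val, as.character(offsets))
}

#' Sliding-window local folding-energy profile around an anchor
#'
#' Value at offset `d` is the backend's free-energy-like score of the
#' window's RNA transcript; more negative means a stronger fold. Windows
#' outside the sequence give NaN.
#'
#' @inheritParams gc_profile
#' @param window window size in nt (default 40).
#' @param backend a [folding_backend()].
#' @return named numeric vector (names = offsets), values <= 0 for the
#'   proxy backend.
#' @export
folding_energy_profile <- function(pre_mrna, anchor_pos, window = 40,
                                   offsets = -60:60,
                                   backend = folding_backend()) {
  if (window <= 0) stop("window must be positive")
  n <- nchar(pre_mrna)
  starts <- anchor_pos + offsets
  val <- rep(NA_real_, length(offsets))
  for (i in seq_along(offsets)) {
    s <- starts[i]
    if (s < 0 || s + window > n) next
    win <- substr(pre_mrna, s + 1L, s + window)
    e <- tryCatch(backend$fold(win)$energy, error = function(err)
      stop("folding backend failed on window [", s, ", ", s + window,
           "): ", conditionMessage(err)))
    val[i] <- e
  }
  setNames(val, as.character(offsets))
}

#' Simple coordinate features of an intron
#'
#' @param intron an [intron_record()].
#' @return named numeric vector: `intron_length`, `bp_to_5ss`, `bp_to_3ss`,
#'   `intron_gc`, `is_rpg`.
#' @export
simple_features <- function(intron) {
  stopifnot(inherits(intron, "intron_record"))
  c(intron_length = nchar(intron$sequence),
    bp_to_5ss = intron$bp_offset,
    bp_to_3ss = intron$three_ss_offset - intron$bp_offset,
    intron_gc = gc_fraction(intron$sequence),
    is_rpg = as.numeric(intron$is_rpg))
}

#' Best PWM log-odds score of each motif in a sequence
#'
#' Maximum log-likelihood-ratio score over all start positions on the
#' forward strand only (introns are transcribed-strand features).
#'
#' @param seq DNA string (intron or pre-mRNA).
#' @param motif_set list of motifs (see [motif()]).
#' @return named numeric vector (names = motif ids); NaN when the sequence
#'   is shorter than the motif.
#' @export
motif_scores <- function(seq, motif_set) {
  enc <- encode_dna(seq)
  vapply(motif_set, function(m) {
    sc <- .pwm_scan(enc, motif_logodds(m))
    if (!length(sc) || all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
  }, 0, USE.NAMES = FALSE) |>
    setNames(vapply(motif_set, `[[`, "", "id"))
}

#' Feature-extraction configuration
#'
#' @param gc_window,fe_window sliding-window sizes (50 / 40 nt).
#' @param gc_offsets,fe_offsets window-start offsets relative to each
#'   splice-site anchor.
#' @param anchors which splice sites to anchor window profiles at.
#' @param backend folding backend name.
#' @param include_structure add secondary-structure graph distances between
#'   the splice signals of each intron.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(gc_window = 50, fe_window = 40,
                           gc_offsets = -60:60, fe_offsets = -60:60,
                           anchors = c("5ss", "3ss"),
                           backend = "nussinov_proxy",
                           include_structure = TRUE) {
  structure(list(gc_window = gc_window, fe_window = fe_window,
                 gc_offsets = gc_offsets, fe_offsets = fe_offsets,
                 anchors = match.arg(anchors, c("5ss", "3ss"),
                                     several.ok = TRUE),
                 backend = backend,
                 include_structure = isTRUE(include_structure)),
            class = "feature_config")
}

.anchor_pos <- function(construct, anchor) {
  if (anchor == "5ss") construct$junction_5p else construct$junction_3p
}

#' Build the intron-by-feature matrix
#'
#' Concatenates simple features, GC and folding-energy window profiles at
#' both splice-site anchors, motif scores and structure distances, in a
#' deterministic column order, with per-column metadata attached as the
#' `feature_info` attribute (a tibble with `name`, `category`, `anchor`,
#' `offset`).
#'
#' @param constructs list of [generate_reporter_construct()] objects (each
#'   carries its intron record).
#' @param motif_set optional list of motifs to score.
#' @param config a [feature_config()].
#' @return numeric matrix (introns x features, NaN-capable) with rownames =
#'   intron ids.
#' @export
build_feature_matrix <- function(constructs, motif_set = NULL,
                                 config = feature_config()) {
  ids <- vapply(constructs, `[[`, "", "intron_id")
  if (anyDuplicated(ids)) stop("duplicate intron ids in constructs")
  backend <- folding_backend(config$backend)
  rows <- vector("list", length(constructs))
  for (i in seq_along(constructs)) {
    cc <- constructs[[i]]
    v <- simple_features(cc$intron)
    for (anchor in config$anchors) {
      gp <- gc_profile(cc$pre_mrna, .anchor_pos(cc, anchor),
                       config$gc_window, config$gc_offsets)
      names(gp) <- sprintf("gc_%s_%+d", anchor, config$gc_offsets)
      v <- c(v, gp)
    }
    for (anchor in config$anchors) {
      fp <- folding_energy_profile(cc$pre_mrna, .anchor_pos(cc, anchor),
                                   config$fe_window, config$fe_offsets,
                                   backend)
      names(fp) <- sprintf("fe_%s_%+d", anchor, config$fe_offsets)
      v <- c(v, fp)
    }
    if (!is.null(motif_set) && length(motif_set)) {
      ms <- motif_scores(cc$intron$sequence, motif_set)
      names(ms) <- paste0("motif_", names(ms))
      v <- c(v, ms)
    }
    if (config$include_structure) {
      ir <- cc$intron
      v <- c(v,
             dist2d_5ss_3ss = structure_distance(ir$sequence, 1,
                                                 nchar(ir$sequence),
                                                 backend),
             dist2d_5ss_bp = structure_distance(ir$sequence, 1,
                                                ir$bp_offset + 1L, backend),
             dist2d_bp_3ss = structure_distance(ir$sequence,
                                                ir$bp_offset + 1L,
                                                nchar(ir$sequence),
                                                backend))
    }
    rows[[i]] <- v
  }
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  nm <- colnames(X)
  cat_of <- ifelse(grepl("^gc_", nm), "gc",
                   ifelse(grepl("^fe_", nm), "folding",
                          ifelse(grepl("^motif_", nm), "motif",
                                 ifelse(grepl("^dist2d_", nm), "structure",
                                        "simple"))))
  anch <- ifelse(grepl("_5ss_", nm), "5ss",
                 ifelse(grepl("_3ss_", nm), "3ss", "none"))
  off <- suppressWarnings(as.integer(sub("^(gc|fe)_[35]ss_", "", nm)))
  attr(X, "feature_info") <- tibble::tibble(name = nm, category = cat_of,
                                            anchor = anch, offset = off)
  X
}

#' Per-offset correlation between a window profile and expression
#'
#' Spearman correlation across introns between the feature value at each
#' offset and the expression index, with pairwise NaN removal; offsets with
#' fewer than `min_n` complete pairs are dropped.
#'
#' @param profiles numeric matrix (introns x offsets; column names are the
#'   offsets), e.g. rows of [gc_profile()] outputs.
#' @param expression numeric vector aligned with the profile rows (or named
#'   by intron id).
#' @param min_n minimum complete pairs per offset (default 5).
#' @return tibble with columns `offset`, `rho`, `p`, `n`.
#' @export
correlation_profile <- function(profiles, expression, min_n = 5) {
  stopifnot(is.matrix(profiles))
  if (!is.null(names(expression)) && !is.null(rownames(profiles)))
    expression <- expression[rownames(profiles)]
  stopifnot(length(expression) == nrow(profiles))
  out <- lapply(seq_len(ncol(profiles)), function(j) {
    x <- profiles[, j]
    ok <- is.finite(x) & is.finite(expression)
    if (sum(ok) < min_n) return(NULL)
    rho <- spearman_rho(x[ok], expression[ok])
    tibble::tibble(offset = as.integer(colnames(profiles)[j]), rho = rho,
                   p = spearman_p(rho, sum(ok)), n = sum(ok))
  })
  do.call(rbind, out)
}
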