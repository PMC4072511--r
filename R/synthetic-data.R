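# Synthetic intron-reporter libraries with known ground truth.
#
# The generator emulates the statistical structure of a yeast intron reporter
# library: ~240 native-like introns with canonical splice signals (GTATGT
# donor, TACTAAC branch-point heptamer, terminal AG), RPG/non-RPG length
# classes (means ~400 / ~100 bp), reporter constructs with the intron inserted
# a fixed distance into the CDS, and 24 h plate-reader OD/YFP traces in four
# replicate plates with control wells.

#' Construct an intron record
#'
#' @param id strain/intron identifier.
#' @param sequence intron DNA string (expected to start `GT`, end `AG`).
#' @param bp_offset 0-based start of the branch-point heptamer.
#' @param is_rpg logical, ribosomal-protein-gene intron class.
#' @param gene_name optional host gene name.
#' @param source `"synthetic"` or `"natural"`. Synthetic records must carry
#'   the canonical `TACTAAC` heptamer at `bp_offset`; natural records may
#'   carry annotated variants.
#' @param true_efficiency optional ground-truth splicing efficiency in
#'   \[0, 1.5\].
#' @param validate check the type invariants (disable only for records
#'   loaded from external annotation that are flagged non-canonical).
#' @return object of class `intron_record`.
#' @export
intron_record <- function(id, sequence, bp_offset, is_rpg = FALSE,
                          gene_name = NA_character_,
                          source = c("synthetic", "natural"),
                          true_efficiency = NA_real_, validate = TRUE) {
  source <- match.arg(source)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  rec <- structure(
    list(id = as.character(id), gene_name = gene_name, sequence = sequence,
         five_ss_offset = 0L, bp_offset = as.integer(bp_offset),
         three_ss_offset = len - 1L, is_rpg = isTRUE(is_rpg),
         source = source, true_efficiency = true_efficiency,
         canonical = TRUE),
    class = "intron_record")
  if (validate) {
    if (substr(sequence, 1, 2) != "GT" ||
        substr(sequence, len - 1, len) != "AG")
      stop("intron '", id, "': sequence must start with GT and end with AG")
    if (!(rec$bp_offset > 0L && rec$bp_offset < rec$three_ss_offset))
      stop("intron '", id, "': bp_offset out of range")
    if (source == "synthetic" &&
        substr(sequence, bp_offset + 1, bp_offset + 7) != "TACTAAC")
      stop("intron '", id, "': branch-point heptamer TACTAAC not at bp_offset")
    if (!is.na(true_efficiency) &&
        (true_efficiency < 0 || true_efficiency > 1.5))
      stop("true_efficiency must lie in [0, 1.5]")
  }
  rec
}

#' @export
print.intron_record <- function(x, ...) {
  cat(sprintf("<intron_record %s> %d nt, bp@%d, %s, %s\n", x$id,
              nchar(x$sequence), x$bp_offset,
              if (x$is_rpg) "RPG" else "non-RPG", x$source))
  invisible(x)
}

# canonical splice-signal footprints of a synthetic intron (0-based, closed)
.signal_ranges <- function(len, bp_offset) {
  rbind(c(0L, 5L), c(bp_offset, bp_offset + 6L), c(len - 2L, len - 1L))
}

#' Generate a synthetic intron
#'
#' Background nucleotides are drawn i.i.d. at the target GC content; the
#' canonical donor (`GTATGT`), branch-point heptamer (`TACTAAC`) and terminal
#' `AG` are then written over the background. Planted motifs that would
#' collide with a canonical signal are skipped with a warning (signals win).
#'
#' @param length intron length in nt (>= 30).
#' @param gc_target background GC fraction in (0, 1).
#' @param is_rpg logical intron class flag.
#' @param planted_motifs list of `list(motif=, anchor = "5ss"|"3ss", offset=)`;
#'   `offset` counts nt from the first intron base (`5ss`) or from the last
#'   intron base (`3ss`, usually negative) to the motif start.
#' @param bp_offset optional branch-point start; by default the BP-to-3'SS
#'   distance is drawn uniformly from 20..50 nt (clipped to what the length
#'   allows).
#' @param seed optional RNG seed; identical seeds give identical records.
#' @param id identifier (default derived from the seed).
#' @param true_efficiency optional ground truth carried on the record.
#' @return an [intron_record()].
#' @export
generate_intron <- function(length, gc_target = 0.33, is_rpg = FALSE,
                            planted_motifs = list(), bp_offset = NULL,
                            seed = NULL, id = NULL,
                            true_efficiency = NA_real_) {
  if (length < 30)
    stop("intron length must be at least 30 nt (room for splice signals)")
  if (is.null(id))
    id <- sprintf("syn_%s", seed %||% "intron")
  with_seed(seed, {
    if (is.null(bp_offset)) {
      # BP heptamer must fit after the donor and before the terminal AG
      d_lo <- max(20L, length - 1L - (length - 9L))   # bp_offset <= len - 9
      d_hi <- min(50L, length - 1L - 7L)              # bp_offset >= 7
      d <- if (d_lo >= d_hi) d_hi else sample(d_lo:d_hi, 1L)
      bp_offset <- length - 1L - d
    }
    bp_offset <- as.integer(bp_offset)
    if (bp_offset < 7L || bp_offset > length - 9L)
      stop("bp_offset leaves no room for the canonical signals")
    ch <- strsplit(random_dna(length, gc_target), "")[[1]]
    sig <- .signal_ranges(length, bp_offset)
    for (pm in planted_motifs) {
      m <- toupper(pm$motif)
      anchor <- match.arg(pm$anchor, c("5ss", "3ss"))
      start <- if (anchor == "5ss") pm$offset else (length - 1L) + pm$offset
      end <- start + nchar(m) - 1L
      if (start < 0L || end > length - 1L)
        stop("planted motif '", m, "' falls outside the intron")
      hits_signal <- any(start <= sig[, 2] & end >= sig[, 1])
      if (hits_signal) {
        warning("planted motif '", m,
                "' collides with a canonical splice signal; not planted")
        next
      }
      ch[(start + 1L):(end + 1L)] <- strsplit(m, "")[[1]]
    }
    ch[1:6] <- c("G", "T", "A", "T", "G", "T")
    ch[(bp_offset + 1L):(bp_offset + 7L)] <-
      c("T", "A", "C", "T", "A", "A", "C")
    ch[(length - 1L):length] <- c("A", "G")
    intron_record(id, paste(ch, collapse = ""), bp_offset, is_rpg = is_rpg,
                  source = "synthetic", true_efficiency = true_efficiency)
  })
}

#' Generate a library of synthetic introns
#'
#' Lengths follow the two intron classes of yeast (RPG introns ~N(400, 80),
#' others ~N(100, 25), truncated); ground-truth efficiencies are drawn
#' log-uniformly so the library spans roughly two orders of magnitude.
#'
#' @param n number of introns (default 240).
#' @param prop_rpg fraction of RPG-class introns.
#' @param efficiency_range range of the log-uniform ground-truth efficiencies.
#' @param gc_mean,gc_sd background GC distribution across introns.
#' @param seed RNG seed.
#' @return list of [intron_record()] objects.
#' @export
generate_intron_library <- function(n = 240, prop_rpg = 0.35,
                                    efficiency_range = c(0.01, 1.2),
                                    gc_mean = 0.33, gc_sd = 0.05,
                                    seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    is_rpg <- runif(n) < prop_rpg
    len <- ifelse(is_rpg, round(rnorm(n, 400, 80)), round(rnorm(n, 100, 25)))
    len <- pmax(len, 60L)
    gc <- pmin(pmax(rnorm(n, gc_mean, gc_sd), 0.15), 0.55)
    eff <- 10^runif(n, log10(efficiency_range[1]), log10(efficiency_range[2]))
    lapply(seq_len(n), function(i)
      generate_intron(len[i], gc_target = gc[i], is_rpg = is_rpg[i],
                      id = sprintf("YIN%03d", i), true_efficiency = eff[i]))
  })
}

#' Deterministic synthetic reporter CDS
#'
#' A fixed 718-nt synthetic stand-in for a fluorescent-reporter coding
#' sequence, used as the exonic context for reporter constructs. Purely
#' synthetic; regenerated from a hard-coded seed so it is identical across
#' sessions.
#' @return DNA string of length 718.
#' @export
example_reporter_cds <- function() {
  with_seed(718203L, paste0("ATG", random_dna(712, gc = 0.41), "TAA"))
}

#' Assemble a reporter construct
#'
#' Splits the exon at `insertion_offset` and inserts the intron, recording
#' the 0-based junction coordinates of the first and last intron base within
#' the pre-mRNA.
#'
#' @param intron an [intron_record()].
#' @param exon_seq reporter CDS DNA string.
#' @param insertion_offset nt from the CDS start (0 < offset < CDS length);
#'   the study's junction-strength positions are 165/195/370/461, with 195
#'   the standard library position.
#' @return object of class `reporter_construct`.
#' @export
generate_reporter_construct <- function(intron, exon_seq,
                                        insertion_offset = 195) {
  stopifnot(inherits(intron, "intron_record"))
  exon_seq <- toupper(exon_seq)
  if (insertion_offset <= 0 || insertion_offset >= nchar(exon_seq))
    stop("insertion_offset must satisfy 0 < offset < length(exon)")
  ilen <- nchar(intron$sequence)
  structure(
    list(intron_id = intron$id, intron = intron,
         insertion_offset = as.integer(insertion_offset),
         pre_mrna = paste0(substr(exon_seq, 1, insertion_offset),
                           intron$sequence,
                           substr(exon_seq, insertion_offset + 1,
                                  nchar(exon_seq))),
         junction_5p = as.integer(insertion_offset),
         junction_3p = as.integer(insertion_offset + ilen - 1L)),
    class = "reporter_construct")
}

#' Ground-truth efficiency from a planted linear model
#'
#' `clamp(intercept + sum(weights * features) + N(0, noise_sd), lower, upper)`.
#' Accepts a single named feature vector or a feature matrix (rows =
#' introns); deterministic given `seed`.
#'
#' @param features named numeric vector, or numeric matrix/data.frame with
#'   named columns.
#' @param weights named numeric vector; names must be a subset of the
#'   feature names.
#' @param intercept baseline efficiency.
#' @param noise_sd Gaussian noise standard deviation.
#' @param lower,upper clamp bounds (upper default 1.2 permits rare >1
#'   strains without letting noise explode).
#' @param seed optional RNG seed.
#' @return numeric vector of efficiencies.
#' @export
ground_truth_efficiency <- function(features, weights, intercept = 0,
                                    noise_sd = 0, lower = 0, upper = 1.2,
                                    seed = NULL) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  if (!all(names(weights) %in% colnames(features)))
    stop("weights refer to features that are not present")
  lin <- as.numeric(intercept +
                      features[, names(weights), drop = FALSE] %*% weights)
  with_seed(seed, {
    out <- lin + rnorm(length(lin), 0, noise_sd)
    pmin(pmax(out, lower), upper)
  })
}

#' Plate-reader experiment design
#'
#' Growth is 3-parameter logistic (start OD, carrying capacity, rate, plus a
#' lag) with multiplicative lognormal OD noise; fluorescence is
#' `background + efficiency * k_expr * OD_net` with additive Gaussian noise.
#' Defaults are calibrated so that a zero-efficiency strain fails the
#' SNR > 5 splicing call while efficiencies of ~0.01 still pass, giving the
#' >= 100-fold measured expression span of the reference library design.
#'
#' @param n_replicates replicate plates (default 4).
#' @param duration_h run length in hours.
#' @param sampling_interval_h time between reads (default 15 min).
#' @param noise_sd additive fluorescence noise (a.u.).
#' @param background_level autofluorescence/background (a.u.).
#' @param k_expr fluorescence per OD unit at efficiency 1.
#' @param od_baseline medium-only absorbance.
#' @param od_start,carrying_capacity,growth_rate,lag_h logistic growth
#'   parameters (per hour rate).
#' @param od_noise_cv lognormal sd of the multiplicative OD noise.
#' @param growth_jitter per-well lognormal sd applied to the growth rate.
#' @param n_control_wells wells per control role per plate.
#' @param seed RNG seed.
#' @return object of class `plate_design`.
#' @export
plate_design <- function(n_replicates = 4, duration_h = 24,
                         sampling_interval_h = 0.25, noise_sd = 1,
                         background_level = 50, k_expr = 10000,
                         od_baseline = 0.09, od_start = 0.1,
                         carrying_capacity = 1.4, growth_rate = 0.5,
                         lag_h = 1, od_noise_cv = 0.02,
                         growth_jitter = 0.03, n_control_wells = 4,
                         seed = NULL) {
  stopifnot(n_replicates >= 1, duration_h > 0, sampling_interval_h > 0,
            n_control_wells >= 1)
  structure(as.list(environment()), class = "plate_design")
}

# net (above-medium) OD of a logistic culture at times t (hours)
.logistic_od <- function(t, od0, K, r, lag) {
  te <- pmax(0, t - lag)
  K * od0 * exp(r * te) / (K + od0 * (exp(r * te) - 1))
}

.well_names <- function(n) {
  if (n > 384) stop("plate capacity exceeded (384 wells per replicate plate)")
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
}

#' Simulate plate-reader time series for a strain list
#'
#' Each replicate is an independent plate carrying every strain plus control
#' wells: intron-less reporter (`YFP_wt`, efficiency 1), a no-YFP strain
#' (`cherry_only`) and medium blanks.
#'
#' @param strains data.frame with columns `id` and `true_efficiency`, or a
#'   list of [intron_record()]s carrying `true_efficiency`.
#' @param design a [plate_design()].
#' @return tibble with columns
#'   `well,strain,role,replicate,time_h,od,yfp`.
#' @export
simulate_plate_timeseries <- function(strains, design = plate_design()) {
  stopifnot(inherits(design, "plate_design"))
  if (is.list(strains) && length(strains) && inherits(strains[[1]], "intron_record"))
    strains <- data.frame(
      id = vapply(strains, `[[`, "", "id"),
      true_efficiency = vapply(strains, `[[`, 0, "true_efficiency"))
  if (NROW(strains) == 0) stop("at least one strain is required")
  if (anyNA(strains$true_efficiency))
    stop("every strain needs a true_efficiency")
  t <- seq(0, design$duration_h, by = design$sampling_interval_h)
  nt <- length(t)
  roles <- c(rep("YiFP", nrow(strains)),
             rep(c("YFP_wt", "cherry_only", "blank"),
                 each = design$n_control_wells))
  ids <- c(as.character(strains$id),
           sprintf("YFP_wt_%d", seq_len(design$n_control_wells)),
           sprintf("cherry_%d", seq_len(design$n_control_wells)),
           sprintf("blank_%d", seq_len(design$n_control_wells)))
  eff <- c(strains$true_efficiency,
           rep(1, design$n_control_wells), rep(0, design$n_control_wells),
           rep(NA_real_, design$n_control_wells))
  wells <- .well_names(length(ids))
  with_seed(design$seed, {
    out <- vector("list", design$n_replicates * length(ids))
    k <- 0L
    for (rep_i in seq_len(design$n_replicates)) {
      for (w in seq_along(ids)) {
        role <- roles[w]
        if (role == "blank") {
          od <- design$od_baseline * exp(rnorm(nt, 0, design$od_noise_cv))
          yfp <- design$background_level + rnorm(nt, 0, design$noise_sd)
        } else {
          r_w <- design$growth_rate * exp(rnorm(1, 0, design$growth_jitter))
          od_net <- .logistic_od(t, design$od_start,
                                 design$carrying_capacity, r_w,
                                 design$lag_h)
          od <- design$od_baseline +
            od_net * exp(rnorm(nt, 0, design$od_noise_cv))
          signal <- if (role == "cherry_only") 0 else
            eff[w] * design$k_expr * od_net
          yfp <- design$background_level + signal +
            rnorm(nt, 0, design$noise_sd)
        }
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          well = wells[w], strain = ids[w], role = role,
          replicate = rep_i, time_h = t, od = od, yfp = yfp)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a library with three planted expression drivers
#'
#' Builds a reporter library whose ground-truth efficiency is a linear
#' function of three real sequence features: local folding energy of the
#' 40-nt window starting 3 nt into the intron at the 5'SS junction, and the
#' PWM scores of one enhancer and one silencer 8-mer, each planted in an
#' independent random half of the introns. The noise level is chosen so
#' single-feature Spearman correlations land around 0.4-0.6.
#'
#' @param n library size.
#' @param insertion_offset intron position within the reporter CDS.
#' @param enhancer,silencer planted 8-mers (defaults are the worked-example
#'   enhancer/silencer pair).
#' @param plant_prob planting probability per intron and motif.
#' @param weights length-3 numeric: weights on the standardized folding,
#'   enhancer and silencer features.
#' @param intercept,noise_sd linear ground-truth parameters on the
#'   standardized feature scale.
#' @param seed RNG seed.
#' @return list with `introns`, `constructs`, `efficiency` (named vector),
#'   `motif_set` (the two planted motifs as PWMs) and `drivers` (the three
#'   feature-matrix column names that generated the signal).
#' @export
simulate_recovery_library <- function(n = 240, insertion_offset = 195,
                                      enhancer = "TTTATGCT",
                                      silencer = "TTTGTGTA",
                                      plant_prob = 0.5,
                                      weights = c(0.15, 0.15, -0.15),
                                      intercept = 0.6, noise_sd = 0.15,
                                      seed = NULL) {
  with_seed(seed, {
    lib_seed <- sample.int(2^31 - 1, 1)
    introns <- generate_intron_library(n, seed = lib_seed)
    exon <- example_reporter_cds()
    introns <- lapply(introns, function(ir) {
      len <- nchar(ir$sequence)
      plant <- list()
      for (m in list(enhancer, silencer)) {
        hi <- ir$bp_offset - nchar(m) - 1L  # keep clear of the BP heptamer
        if (runif(1) < plant_prob && hi >= 8L) {
          off <- if (hi == 8L) 8L else sample(8:hi, 1L)
          plant <- c(plant, list(list(motif = m, anchor = "5ss",
                                      offset = off)))
        }
      }
      if (!length(plant)) return(ir)
      suppressWarnings(
        generate_intron(len, gc_target = gc_fraction(ir$sequence),
                        is_rpg = ir$is_rpg, planted_motifs = plant,
                        bp_offset = ir$bp_offset,
                        seed = sample.int(2^31 - 1, 1), id = ir$id))
    })
    constructs <- lapply(introns, generate_reporter_construct,
                         exon_seq = exon,
                         insertion_offset = insertion_offset)
    motif_set <- list(motif_from_consensus(enhancer, id = paste0("enh_", enhancer),
                                           class = "enhancer"),
                      motif_from_consensus(silencer, id = paste0("sil_", silencer),
                                           class = "silencer"))
    backend <- folding_backend("nussinov_proxy")
    fe <- vapply(constructs, function(cc)
      folding_energy_profile(cc$pre_mrna, cc$junction_5p, window = 40,
                             offsets = 3, backend = backend), 0)
    sc <- t(vapply(introns, function(ir)
      motif_scores(ir$sequence, motif_set), numeric(2)))
    feats <- cbind(fe = as.numeric(scale(fe)),
                   enh = as.numeric(scale(sc[, 1])),
                   sil = as.numeric(scale(sc[, 2])))
    eff_seed <- sample.int(2^31 - 1, 1)
    eff <- ground_truth_efficiency(
      feats, setNames(weights, c("fe", "enh", "sil")),
      intercept = intercept, noise_sd = noise_sd, seed = eff_seed)
    ids <- vapply(introns, `[[`, "", "id")
    for (i in seq_along(introns)) {
      introns[[i]]$true_efficiency <- eff[i]
      constructs[[i]]$intron <- introns[[i]]
    }
    list(introns = introns, constructs = constructs,
         efficiency = setNames(eff, ids), motif_set = motif_set,
         drivers = c("fe_5ss_+3",
                     paste0("motif_enh_", enhancer),
                     paste0("motif_sil_", silencer)))
  })
}
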