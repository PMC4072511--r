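# Readers and writers: intron FASTA + sidecar TSV, tidy plate CSV, result
# tables, MEME-minimal motif files and serialized models. All tables are
# UTF-8 with header rows; missing values are written as "NA".

#' Write introns as FASTA plus a sidecar TSV
#'
#' @param introns list of [intron_record()]s.
#' @param fasta_path output FASTA path.
#' @param sidecar_path output TSV path (`id, gene_name, bp_offset, is_rpg,
#'   source, true_efficiency`).
#' @export
write_intron_fasta <- function(introns, fasta_path, sidecar_path) {
  seqs <- Biostrings::DNAStringSet(vapply(introns, `[[`, "", "sequence"))
  names(seqs) <- vapply(introns, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  side <- tibble::tibble(
    id = names(seqs),
    gene_name = vapply(introns, function(x)
      as.character(x$gene_name %||% NA_character_), ""),
    bp_offset = vapply(introns, `[[`, 0L, "bp_offset"),
    is_rpg = vapply(introns, `[[`, TRUE, "is_rpg"),
    source = vapply(introns, `[[`, "", "source"),
    true_efficiency = vapply(introns, `[[`, 0, "true_efficiency"))
  readr::write_tsv(side, sidecar_path, na = "NA")
  invisible(c(fasta_path, sidecar_path))
}

#' Read introns from FASTA plus sidecar TSV
#'
#' Records that fail the canonical GT...AG check are loaded with a warning
#' and flagged `canonical = FALSE` instead of being rejected (natural
#' annotation may carry variants).
#'
#' @param fasta_path FASTA of intron sequences.
#' @param sidecar_path TSV with at least `id` and `bp_offset`; optional
#'   `gene_name`, `is_rpg`, `source`, `true_efficiency`.
#' @return list of [intron_record()]s.
#' @export
read_intron_fasta <- function(fasta_path, sidecar_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  side <- readr::read_tsv(sidecar_path, show_col_types = FALSE)
  if (!all(c("id", "bp_offset") %in% names(side)))
    stop("sidecar TSV needs columns id and bp_offset")
  missing_ids <- setdiff(ids, side$id)
  if (length(missing_ids))
    stop("FASTA records missing from sidecar TSV: ",
         paste(missing_ids, collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    row <- side[side$id == ids[i], ][1, ]
    s <- as.character(seqs[[i]])
    canon <- substr(s, 1, 2) == "GT" &&
      substr(s, nchar(s) - 1, nchar(s)) == "AG"
    if (!canon)
      warning("intron '", ids[i], "' lacks canonical GT...AG boundaries")
    rec <- intron_record(
      ids[i], s, row$bp_offset,
      is_rpg = "is_rpg" %in% names(row) && isTRUE(row$is_rpg),
      gene_name = if ("gene_name" %in% names(row))
        as.character(row$gene_name) else NA_character_,
      source = if ("source" %in% names(row) && !is.na(row$source))
        row$source else "natural",
      true_efficiency = if ("true_efficiency" %in% names(row))
        as.numeric(row$true_efficiency) else NA_real_,
      validate = FALSE)
    rec$canonical <- canon
    rec
  })
}

#' Write a plate table as tidy CSV
#' @param plate tibble from [simulate_plate_timeseries()].
#' @param path output CSV path.
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(plate, path, na = "NA")
  invisible(path)
}

#' Read a tidy plate CSV
#' @param path CSV with header `well,strain,role,replicate,time_h,od,yfp`.
#' @return tibble.
#' @export
read_plate_csv <- function(path) {
  plate <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well", "strain", "role", "replicate", "time_h", "od", "yfp")
  if (!all(need %in% names(plate)))
    stop("plate CSV must have columns ", paste(need, collapse = ","))
  plate
}

#' Write motifs in MEME minimal format
#' @param motifs list of [motif()]s.
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +",
               "", "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= %g",
      nrow(m$ppm), if (is.na(m$enrichment_p)) 1 else m$enrichment_p), con)
    for (r in seq_len(nrow(m$ppm)))
      writeLines(sprintf(" %8.6f %8.6f %8.6f %8.6f", m$ppm[r, 1],
                         m$ppm[r, 2], m$ppm[r, 3], m$ppm[r, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#' @param path MEME file.
#' @return list of [motif()]s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\s+", lines)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]
    mat_line <- idx[i] + which(grepl("^letter-probability matrix:",
                                     lines[(idx[i] + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[mat_line]))
    e <- suppressWarnings(as.numeric(sub(".*E=\\s*([-0-9.eE+]+).*", "\\1",
                                         lines[mat_line])))
    rows <- lines[(mat_line + 1):(mat_line + w)]
    ppm <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    ppm <- ppm / rowSums(ppm)  # guard against rounding in the file
    out[[i]] <- motif(hdr[2], ppm, enrichment_p = e)
  }
  out
}

#' Serialize a regressor model to JSON
#' @param model a `regressor_model`.
#' @param path output JSON path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(selected = model$selected, weights = as.list(model$weights),
         intercept = model$intercept, cum_rho = model$cum_rho,
         adj_rho = model$adj_rho,
         impute_means = as.list(model$impute_means), n = model$n,
         target = model$target),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a regressor model from JSON
#' @param path JSON written by [write_model_json()].
#' @return a `regressor_model` (prediction-capable subset of fields).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(selected = as.character(j$selected %||% character(0)),
         weights = unlist(j$weights) %||% setNames(numeric(0), character(0)),
         intercept = j$intercept, cum_rho = as.numeric(j$cum_rho),
         adj_rho = as.numeric(j$adj_rho),
         impute_means = unlist(j$impute_means), n = j$n,
         target = j$target),
    class = "regressor_model")
}
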