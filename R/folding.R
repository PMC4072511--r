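# Pluggable RNA folding backends.
#
# The default backend is a transparent Nussinov-style proxy: maximize the
# total weight of non-crossing base pairs with a minimum hairpin loop of 3,
# scoring G-C pairs 1.5, A-U pairs 1.0 and G-U wobbles 0.5; the reported
# energy is minus the total weight, so more negative means a stronger fold
# and an unpairable sequence scores exactly 0. An optional backend shells
# out to ViennaRNA's RNAfold for thermodynamic minimum-free-energy folds.

#' Create a folding backend
#'
#' A backend is a list with a `name` and a `fold(seq)` function returning
#' `list(energy = <real>, pairs = <2-column 1-based matrix>)`.
#'
#' @param name `"nussinov_proxy"` (default, built in) or `"vienna"`
#'   (requires the `RNAfold` executable on the PATH).
#' @param min_loop minimum hairpin loop size for the proxy backend.
#' @return object of class `folding_backend`.
#' @export
folding_backend <- function(name = c("nussinov_proxy", "vienna"),
                            min_loop = 3) {
  name <- match.arg(name)
  fold <- switch(name,
    nussinov_proxy = function(seq) {
      res <- .nussinov_fold(encode_dna(seq), as.integer(min_loop))
      list(energy = res$energy, pairs = res$pairs)
    },
    vienna = function(seq) .rnafold_vienna(seq))
  structure(list(name = name, min_loop = min_loop, fold = fold),
            class = "folding_backend")
}

# run RNAfold on a single sequence and parse energy + dot-bracket pairs
.rnafold_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (exe == "") stop("folding backend error: RNAfold executable not found")
  out <- system2(exe, args = c("--noPS"), input = chartr("Tt", "Uu", seq),
                 stdout = TRUE, stderr = FALSE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3)
    stop("folding backend error: could not parse RNAfold output: ", line)
  db <- strsplit(m[2], "")[[1]]
  stack <- integer(0); pairs <- NULL
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  list(energy = as.numeric(m[3]),
       pairs = if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs)
}

#' Secondary-structure graph distance between two positions
#'
#' Shortest path in the graph whose nodes are sequence positions and whose
#' unit-weight edges are the backbone neighbours plus the predicted base
#' pairs (directly paired positions are one step apart).
#'
#' @param seq DNA/RNA string.
#' @param pos_a,pos_b 1-based positions within the sequence.
#' @param backend a [folding_backend()].
#' @return integer path length.
#' @export
structure_distance <- function(seq, pos_a, pos_b,
                               backend = folding_backend()) {
  n <- nchar(seq)
  stopifnot(pos_a >= 1, pos_a <= n, pos_b >= 1, pos_b <= n)
  if (pos_a == pos_b) return(0L)
  pairs <- backend$fold(seq)$pairs
  edges <- cbind(seq_len(n - 1), 2:n)
  if (nrow(pairs)) edges <- rbind(edges, pairs)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  as.integer(igraph::distances(g, v = pos_a, to = pos_b))
}
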