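# Greedy linear predictor of expression from intron features: iterative
# forward selection maximizing the Spearman correlation of the OLS fit with
# expression, gated on per-feature significance, quantified with an
# adjusted correlation, permutation empirical p-values and leakage-free
# cross-validation (the feature database is rebuilt inside each training
# fold).

#' Correlation adjusted for the number of selected features
#'
#' Carries the adjusted-R^2 penalty back to the correlation scale:
#' `adj = sign(rho) * sqrt(max(0, 1 - (1 - rho^2) (n - 1) / (n - k - 1)))`,
#' where `n` is the number of introns and `k` the number of features; at
#' `k = 0` the correlation is returned unchanged.
#'
#' @param rho Spearman correlation at iteration `k`.
#' @param n number of observations.
#' @param k number of features in the model.
#' @return adjusted correlation.
#' @export
adjusted_correlation <- function(rho, n, k) {
  if (abs(rho) > 1) stop("|rho| must not exceed 1")
  if (n <= k + 1) stop("adjusted correlation undefined for n <= k + 1")
  sign(rho) * sqrt(max(0, 1 - (1 - rho^2) * (n - 1) / (n - k - 1)))
}

# OLS fit of y on the selected columns; returns fitted values and coefs.
# Fitted values are snapped to 10 significant digits so that rows with
# identical feature values stay exactly tied (QR jitter at the 1e-15 level
# would otherwise break ties and distort rank correlations on the heavily
# tied motif-score columns).
.ols_fit <- function(X, cols, y) {
  A <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  fit <- lm.fit(A, y)
  list(fitted = signif(fit$fitted.values, 10), coef = fit$coefficients)
}

#' Assemble the greedy linear expression predictor
#'
#' At each iteration every unused candidate feature is added to the current
#' set, an ordinary least-squares model is fitted, and the Spearman
#' correlation of the fitted values with expression is computed; the best
#' candidate is accepted if it improves the correlation by at least
#' `min_improve`. Candidates must first pass a per-feature significance
#' gate (BH-adjusted single-feature Spearman p below `gate_alpha`). NaN
#' feature cells are mean-imputed per feature and the imputation constants
#' are stored in the model. Ties are broken by feature name.
#'
#' @param X numeric feature matrix (introns x features, NaN-capable) with
#'   column names; e.g. from [build_feature_matrix()].
#' @param y expression values (named by intron id or aligned with rows).
#' @param max_k maximum number of features (default 38).
#' @param min_improve minimum Spearman improvement to accept a feature.
#' @param gate_alpha BH threshold for the single-feature gate; `NULL`
#'   disables the gate.
#' @param target label stored on the model (`"mean_expression"` or
#'   `"max_expression"`).
#' @return object of class `regressor_model` with fields `selected`,
#'   `weights`, `intercept`, `cum_rho`, `adj_rho`, `impute_means`,
#'   `fitted`, `n`, `single_rho`, `single_q`.
#' @export
greedy_assemble <- function(X, y, max_k = 38, min_improve = 1e-4,
                            gate_alpha = 0.05,
                            target = "mean_expression") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  if (!is.null(names(y)) && !is.null(rownames(X))) y <- y[rownames(X)]
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 10) stop("need at least 10 introns with expression values")
  impute_means <- apply(X, 2, function(col) {
    m <- mean(col[is.finite(col)])
    if (is.finite(m)) m else 0
  })
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- impute_means[j]
  }
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  y_rank <- rank(y)
  single_rho <- vapply(seq_len(ncol(X)), function(j)
    if (constant[j]) 0 else suppressWarnings(cor(rank(X[, j]), y_rank)), 0)
  single_p <- vapply(single_rho, spearman_p, 0, n = n)
  single_q <- p.adjust(single_p, method = "BH")
  eligible <- !constant &
    (if (is.null(gate_alpha)) TRUE else (!is.na(single_q) &
                                           single_q < gate_alpha))
  names(single_rho) <- names(single_q) <- colnames(X)

  selected <- character(0)
  cum_rho <- adj_rho <- numeric(0)
  prev <- 0
  cand_order <- order(colnames(X))  # deterministic tie-break
  while (length(selected) < max_k && n > length(selected) + 2) {
    cands <- setdiff(colnames(X)[cand_order][eligible[cand_order]],
                     selected)
    if (!length(cands)) break
    rhos <- vapply(cands, function(f) {
      fit <- .ols_fit(X, c(selected, f), y)
      r <- suppressWarnings(cor(rank(fit$fitted), y_rank))
      if (is.finite(r)) r else -Inf
    }, 0)
    best <- cands[which.max(rhos)]   # first max in name order
    if (rhos[[best]] < prev + min_improve) break
    selected <- c(selected, best)
    prev <- rhos[[best]]
    cum_rho <- c(cum_rho, prev)
    adj_rho <- c(adj_rho, adjusted_correlation(prev, n, length(selected)))
  }
  fit <- if (length(selected)) .ols_fit(X, selected, y) else
    list(fitted = rep(mean(y), n),
         coef = c(`(Intercept)` = mean(y)))
  coefs <- fit$coef
  coefs[is.na(coefs)] <- 0
  structure(
    list(selected = selected,
         weights = coefs[setdiff(names(coefs), "(Intercept)")],
         intercept = unname(coefs["(Intercept)"]),
         cum_rho = cum_rho, adj_rho = adj_rho,
         single_rho = single_rho, single_q = single_q,
         impute_means = impute_means, fitted = unname(fit$fitted),
         y = unname(y), n = n, target = target,
         gate_alpha = gate_alpha, max_k = max_k,
         min_improve = min_improve),
    class = "regressor_model")
}

#' @export
print.regressor_model <- function(x, ...) {
  cat(sprintf("<regressor_model> %d features, n = %d, target = %s\n",
              length(x$selected), x$n, x$target))
  if (length(x$selected))
    cat(sprintf("  final Spearman %.3f (adjusted %.3f); first: %s\n",
                tail(x$cum_rho, 1), tail(x$adj_rho, 1),
                paste(head(x$selected, 5), collapse = ", ")))
  invisible(x)
}

#' Predict expression for new introns
#'
#' `intercept + sum(weight * feature)`; NaN cells are replaced by the
#' training-set imputation means stored in the model. All selected
#' features must be present.
#'
#' @param object a `regressor_model`.
#' @param newdata numeric matrix or data.frame with named feature columns.
#' @param ... unused.
#' @return numeric predictions, one per row of `newdata`.
#' @export
predict.regressor_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing_f <- setdiff(object$selected, colnames(newdata))
  if (length(missing_f))
    stop("missing selected features: ", paste(missing_f, collapse = ", "))
  if (!length(object$selected))
    return(rep(object$intercept, nrow(newdata)))
  M <- newdata[, object$selected, drop = FALSE]
  for (f in object$selected) {
    bad <- !is.finite(M[, f])
    if (any(bad)) M[bad, f] <- object$impute_means[[f]]
  }
  as.numeric(object$intercept + M %*% object$weights[object$selected])
}

#' Permutation empirical p-value of a fitted model
#'
#' Rebuilds the full greedy model on uniformly permuted expression labels
#' and reports `(1 + #{permuted final rho >= observed}) / (1 + n_perm)`.
#'
#' @param X feature matrix.
#' @param y expression values.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param ... passed to [greedy_assemble()] for both the observed and the
#'   permuted rebuilds.
#' @return empirical p-value.
#' @export
empirical_pvalue <- function(X, y, n_perm = 200, seed = NULL, ...) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  final_rho <- function(model)
    if (length(model$cum_rho)) tail(model$cum_rho, 1) else 0
  obs <- final_rho(greedy_assemble(X, y, ...))
  with_seed(seed, {
    ge <- 0L
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      names(yp) <- names(y)
      if (final_rho(greedy_assemble(X, yp, ...)) >= obs) ge <- ge + 1L
    }
    (1 + ge) / (1 + n_perm)
  })
}

#' Cross-validate the predictor with in-fold feature rebuilding
#'
#' Per repeat, the introns are split into training and test folds; motif
#' discovery (when enabled) runs on the training fold only, the feature
#' matrix is rebuilt for both folds from the training-derived motif set,
#' the greedy model is assembled on the training fold, and the Spearman
#' correlation between its predictions and the held-out expression values
#' is reported.
#'
#' @param constructs list of reporter constructs.
#' @param expression named expression vector (by intron id).
#' @param config a [feature_config()].
#' @param discover run in-fold motif discovery on training terciles
#'   (top/bottom thirds of training expression).
#' @param motif_set optional fixed motif set scored in addition to (or
#'   instead of) discovered motifs.
#' @param frac_train training fraction in (0, 1), default 0.8.
#' @param n_repeats number of random splits.
#' @param seed RNG seed.
#' @param k_range,alpha_fdr,max_motifs discovery parameters.
#' @param ... passed to [greedy_assemble()].
#' @return numeric vector of test-fold Spearman correlations, one per
#'   repeat.
#' @export
cross_validate <- function(constructs, expression,
                           config = feature_config(), discover = TRUE,
                           motif_set = NULL, frac_train = 0.8,
                           n_repeats = 20, seed = NULL, k_range = 6:8,
                           alpha_fdr = 0.05, max_motifs = 20, ...) {
  if (frac_train <= 0 || frac_train >= 1)
    stop("frac_train must lie strictly between 0 and 1")
  ids <- vapply(constructs, `[[`, "", "intron_id")
  expression <- expression[ids]
  n <- length(ids)
  n_train <- round(frac_train * n)
  if (n_train < 5 || n - n_train < 5)
    stop("folds too small: need at least 5 introns in each")
  seqs <- vapply(constructs, function(cc) cc$intron$sequence, "")
  with_seed(seed, {
    vapply(seq_len(n_repeats), function(rep_i) {
      tr <- sort(sample.int(n, n_train))
      te <- setdiff(seq_len(n), tr)
      ms <- motif_set
      if (discover) {
        y_tr <- expression[tr]
        qs <- quantile(y_tr, c(1 / 3, 2 / 3), na.rm = TRUE)
        found <- discover_motifs(seqs[tr][y_tr >= qs[2]],
                                 seqs[tr][y_tr <= qs[1]],
                                 k_range = k_range, alpha_fdr = alpha_fdr,
                                 max_motifs = max_motifs)
        ms <- c(ms, found)
      }
      X_tr <- build_feature_matrix(constructs[tr], ms, config)
      X_te <- build_feature_matrix(constructs[te], ms, config)
      model <- greedy_assemble(X_tr, expression[tr], ...)
      pred <- predict(model, X_te)
      spearman_rho(pred, expression[te])
    }, 0)
  })
}
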