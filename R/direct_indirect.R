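#' Split sequence-specific factors into direct/indirect pseudo-factors
#'
#' For every factor X in `sequence_specific`, calls carrying a motif match
#' are relabeled `dX` (direct binding) and calls without one `iX`
#' (indirect binding); other factors pass through unchanged, so the
#' vocabulary grows by one label per split factor.
#'
#' @param calls [binding_calls()]; every call of a sequence-specific factor
#'   must have a non-NA `motif_present` flag.
#' @param sequence_specific character vector of factor labels eligible for
#'   splitting.
#' @return the relabeled calls, with attribute `split_spec`: list with
#'   `sequence_specific`, `d_labels`, `i_labels`.
#' @export
split_factors <- function(calls, sequence_specific) {
  sel <- calls$factor %in% sequence_specific
  if (any(sel & is.na(calls$motif_present))) {
    bad <- unique(calls$factor[sel & is.na(calls$motif_present)])
    stop("sequence-specific call(s) missing motif_present flag: ",
         paste(bad, collapse = ", "))
  }
  out <- calls
  out$factor[sel] <- paste0(ifelse(calls$motif_present[sel], "d", "i"),
                            calls$factor[sel])
  attr(out, "split_spec") <- list(
    sequence_specific = sequence_specific,
    d_labels = paste0("d", sequence_specific),
    i_labels = paste0("i", sequence_specific))
  class(out) <- c("binding_calls", "data.frame")
  out
}

# module participation columns for the d/i variants of the split factors;
# variants never assigned to any module get an all-zero column
di_columns <- function(module_tf, factors) {
  get_col <- function(lab) {
    if (lab %in% colnames(module_tf)) module_tf[, lab]
    else rep(0, nrow(module_tf))
  }
  list(d = vapply(paste0("d", factors), get_col, numeric(nrow(module_tf))),
       i = vapply(paste0("i", factors), get_col, numeric(nrow(module_tf))))
}

#' Correlation between direct and indirect binding across factors
#'
#' Pearson correlation between every `dX` column and every `iY` column of
#' the module-TF matrix (module participation profiles).
#'
#' @param module_tf module-TF matrix fitted on the split vocabulary.
#' @param factors split factor labels (without the d/i prefix).
#' @return matrix, rows `d<X>` x columns `i<Y>`.
#' @export
direct_indirect_correlation <- function(module_tf, factors) {
  cols <- di_columns(module_tf, factors)
  r <- suppressWarnings(cor(cols$d, cols$i))
  rownames(r) <- paste0("d", factors)
  colnames(r) <- paste0("i", factors)
  r
}

#' TF diversification scores
#'
#' The diversification score of a factor is the Pearson correlation
#' distance `1 - r(dX, iX)` between its direct and indirect module
#' participation vectors; 0 means identical co-binding partners, values
#' above 1 mean anti-correlated (disjoint) partner sets.
#'
#' @inheritParams direct_indirect_correlation
#' @return data frame with columns `factor` and `score` (in \[0, 2\]; NA if
#'   either profile is constant).
#' @export
diversification_scores <- function(module_tf, factors) {
  cols <- di_columns(module_tf, factors)
  score <- vapply(seq_along(factors), function(j) {
    suppressWarnings(1 - cor(cols$d[, j], cols$i[, j]))
  }, 0)
  data.frame(factor = factors, score = score, stringsAsFactors = FALSE)
}

#' Predict direct vs indirect binding of a factor from its co-binding
#'
#' Random forest classification following an 80/20 design: rows of the
#' split-vocabulary region-TF matrix containing `dX` or `iX` sites are
#' labeled by the variant present (regions containing both are excluded
#' and counted); features are the other factors' columns with every other
#' split pair's d/i columns summed (so motif information of the co-binding
#' factors is withheld) and the target factor's own columns removed.  Five
#' forests are fitted on distinct seeded stratified 80% subsets and tested
#' on the held-out 20%.
#'
#' @param m region x split-vocabulary count matrix.
#' @param target factor label (without prefix); `d<target>`/`i<target>`
#'   must be columns of `m`.
#' @param seeds integer seeds, one per fit (default 1:5).
#' @param n_tree trees per forest (default 500).
#' @param train_frac training fraction (default 0.8).
#' @param max_depth maximum tree depth.
#' @return `rf_report`: list with mean `accuracy`, `balanced_accuracy`,
#'   `per_fit` accuracies, `n_direct`, `n_indirect`, `n_mixed_excluded`.
#' @export
predict_direct_indirect <- function(m, target, seeds = 1:5, n_tree = 500L,
                                    train_frac = 0.8, max_depth = 20L) {
  dcol <- paste0("d", target); icol <- paste0("i", target)
  if (!all(c(dcol, icol) %in% colnames(m))) {
    stop("factor ", target, " is not split in this matrix")
  }
  has_d <- m[, dcol] > 0; has_i <- m[, icol] > 0
  mixed <- has_d & has_i
  rows <- which(xor(has_d, has_i))
  y <- as.integer(m[rows, dcol] > 0)  # 1 = direct

  feats <- m[rows, setdiff(colnames(m), c(dcol, icol)), drop = FALSE]
  # collapse other factors' d/i columns: co-binding identity only
  other_split <- sub("^d", "", grep("^d", colnames(feats), value = TRUE))
  other_split <- other_split[paste0("i", other_split) %in% colnames(feats)]
  for (f in other_split) {
    feats[, paste0("d", f)] <-
      feats[, paste0("d", f)] + feats[, paste0("i", f)]
  }
  drop <- paste0("i", other_split)
  feats <- feats[, setdiff(colnames(feats), drop), drop = FALSE]
  colnames(feats) <- sub("^d", "", colnames(feats))

  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n0, n1) < 5) {
    stop("insufficient data: class sizes ", n0, "/", n1,
         " for factor ", target)
  }

  mtry <- max(1L, floor(sqrt(ncol(feats))))
  acc <- bacc <- numeric(length(seeds))
  for (s in seq_along(seeds)) {
    set.seed(as.integer(seeds[s]))
    tr <- unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, floor(length(ix) * train_frac))
    }), use.names = FALSE)
    te <- setdiff(seq_along(y), tr)
    set.seed(as.integer(seeds[s]) + 10000L)
    pred <- rf_predict_cpp(feats[tr, , drop = FALSE], y[tr],
                           feats[te, , drop = FALSE],
                           as.integer(n_tree), mtry, as.integer(max_depth))
    acc[s] <- mean(pred == y[te])
    sens <- mean(pred[y[te] == 1] == 1)
    spec <- mean(pred[y[te] == 0] == 0)
    bacc[s] <- mean(c(sens, spec))
  }
  structure(list(factor = target, accuracy = mean(acc),
                 balanced_accuracy = mean(bacc), per_fit = acc,
                 n_direct = n1, n_indirect = n0,
                 n_mixed_excluded = sum(mixed)),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf(
    "direct/indirect RF for %s: accuracy %.3f (balanced %.3f) over %d fits; %d direct / %d indirect regions (%d mixed excluded)\n",
    x$factor, x$accuracy, x$balanced_accuracy, length(x$per_fit),
    x$n_direct, x$n_indirect, x$n_mixed_excluded))
  invisible(x)
}

#' Correlation between diversification scores and prediction accuracy
#'
#' @param scores numeric diversification scores, or the data frame from
#'   [diversification_scores()].
#' @param accuracies numeric accuracies, or a list of `rf_report`s in the
#'   same factor order.
#' @return Pearson r.
#' @export
diversification_vs_accuracy <- function(scores, accuracies) {
  if (is.data.frame(scores)) scores <- scores$score
  if (is.list(accuracies) && !is.numeric(accuracies)) {
    accuracies <- vapply(accuracies, function(r) r$accuracy, 0)
  }
  if (length(scores) != length(accuracies)) stop("length mismatch")
  if (length(scores) < 2) stop("need >= 2 factors")
  cor(scores, accuracies)
}
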