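# Leave-one-pair-out cross-validation and ROC/AUC scoring of per-cell
# contact probabilities. AUC is the Mann-Whitney rank statistic
# P(score_pos > score_neg) + 0.5 P(tie), which handles the tied scores that
# arise whenever MI values repeat.

#' ROC curve and AUC of contact scores
#'
#' @param scores Numeric vector of per-cell scores (higher = more likely
#'   contact).
#' @param labels Binary vector of the same length; must contain both
#'   classes.
#' @return An `rb_roc`: list with `auc` and `roc_points` (data frame of
#'   `fpr`, `tpr`, one point per distinct score threshold, starting at
#'   (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores)  # average ranks on ties = half credit
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  boundary <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(l)[boundary] / npos)
  fpr <- c(0, cumsum(1L - l)[boundary] / nneg)
  structure(list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr)),
            class = "rb_roc")
}

#' @export
print.rb_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc,
              nrow(x$roc_points) - 1L))
  invisible(x)
}

#' Leave-one-pair-out cross-validation
#'
#' For each labeled instance in turn: fit the CRF on the remaining
#' instances, score every cell of the held-out grid with
#' `Pr(r_ij = 1 | r_Nij, y)` (neighbors conditioned on the TRW-S MAP grid
#' by default, or on the all-zero grid), and compute the AUC against the
#' held-out contacts. Folds whose held-out grid contains a single class are
#' skipped with a warning and reported as `NA`.
#'
#' @param instances List of labeled `rb_instance` objects (>= 2).
#' @param config An `rb_feature_config`.
#' @param control An `rb_training_config`.
#' @param conditioning `"map"` (default) or `"zero"`.
#' @return List with `folds` (data frame: `fold`, `auc`, `n_pos`, `n_cells`),
#'   `mean_auc` (unweighted mean over non-skipped folds) and `fits`
#'   (per-fold `rb_params`).
#' @export
leave_one_out_cv <- function(instances, config, control = training_config(),
                             conditioning = c("map", "zero")) {
  conditioning <- match.arg(conditioning)
  instances <- as_instance_list(instances)
  if (length(instances) < 2L) stop("cross-validation needs at least 2 instances")
  n <- length(instances)
  aucs <- rep(NA_real_, n)
  npos <- integer(n)
  ncells <- integer(n)
  fits <- vector("list", n)
  for (fold in seq_len(n)) {
    held <- instances[[fold]]
    if (is.null(held$r)) stop("all instances must be labeled for CV")
    npos[fold] <- sum(held$r)
    ncells[fold] <- length(held$r)
    fit <- crf_fit(instances[-fold], config, control)
    fits[[fold]] <- fit
    if (npos[fold] == 0L || npos[fold] == ncells[fold]) {
      warning("fold ", fold, " skipped: held-out grid has a single class")
      next
    }
    cond <- if (conditioning == "zero") {
      matrix(0L, nrow(held$m), ncol(held$m))
    } else NULL
    p <- score_grid(fit, config, held, conditioning = cond)
    aucs[fold] <- roc_auc(as.vector(p), as.vector(held$r))$auc
  }
  list(folds = data.frame(fold = seq_len(n), auc = aucs,
                          n_pos = npos, n_cells = ncells),
       mean_auc = mean(aucs, na.rm = TRUE),
       fits = fits)
}
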