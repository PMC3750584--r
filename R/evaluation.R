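# Cross-validation harnesses (LOO, repeated k-fold), error/correlation
# metrics and the EC50-based drug similarity measure.

# One retraining + prediction: train the full pipeline (SFFS target
# selection + TIM) on the training rows of a binarized screen and predict
# the held-out rows.  Retraining per fold avoids leaking the target set.
fit_predict <- function(bin, train_idx, test_idx, max_targets = 10L,
                        discount = 1) {
  dtip <- bin$dtip[train_idx, , drop = FALSE]
  y <- bin$y[train_idx]
  sel <- sffs_select(dtip, y, max_size = max_targets)
  if (length(sel$targets) == 0L) {
    ## nothing separates the drugs; predict the grand mean for everyone
    return(rep(mean(y), length(test_idx)))
  }
  pats <- project_drugs(dtip, sel$targets)
  tim <- build_tim(pats, y, targets = bin$universe[sel$targets],
                   discount = discount,
                   dense = length(sel$targets) <= 16L)
  test_pats <- project_drugs(bin$dtip[test_idx, , drop = FALSE], sel$targets)
  predict(tim, test_pats)
}

cv_report <- function(bin, used, pred, scheme, extra = list()) {
  err <- abs(pred - bin$y[used])
  r <- if (stats::sd(pred) > 0 && stats::sd(bin$y[used]) > 0) {
    stats::cor(pred, bin$y[used])
  } else NA_real_
  structure(c(list(
    table = data.frame(drug = bin$drug[used],
                       error = err,
                       pred_sens = pred,
                       exp_sens = bin$y[used],
                       stringsAsFactors = FALSE),
    mae = mean(err), pearson_r = r, scheme = scheme,
    culture_id = bin$culture_id,
    excluded = bin$drug[bin$excluded]), extra), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation, culture '%s': %d drugs\n",
              x$scheme, x$culture_id, nrow(x$table)))
  cat(sprintf("  MAE = %.3f, Pearson r = %.3f\n", x$mae, x$pearson_r))
  if (length(x$excluded))
    cat("  excluded (no target in window):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of the TIM pipeline
#'
#' For each usable (non-excluded) drug, the full pipeline — SFFS target
#' selection and TIM construction — is retrained on the remaining drugs and
#' the withheld drug's sensitivity is predicted from its inhibition
#' profile.  The per-drug error is `|y - yhat|`; the report carries the
#' mean absolute error and the Pearson correlation between predictions and
#' experiments.
#'
#' @param bin a [binarize_screen()] result (or a compatible list with
#'   `drug`, `y`, `dtip`, `excluded`, `universe`, `culture_id`).
#' @param max_targets maximum target-set cardinality per retraining.
#' @param discount TIM inference discount.
#' @return object of class `cv_report` with a per-drug table
#'   (drug, error, predicted and experimental sensitivity), `mae` and
#'   `pearson_r`.
#' @export
loo_evaluate <- function(bin, max_targets = 10L, discount = 1) {
  used <- which(!bin$excluded)
  if (length(used) < 3L) stop("need at least 3 usable drugs for LOO")
  pred <- vapply(seq_along(used), function(i) {
    fit_predict(bin, used[-i], used[i], max_targets, discount)
  }, numeric(1))
  cv_report(bin, used, pred, "LOO")
}

#' Repeated k-fold cross-validation of the TIM pipeline
#'
#' Usable drugs are partitioned into `k` random folds of near-equal size
#' (within one drug); each fold is predicted by a pipeline retrained on the
#' other folds.  The partition is redrawn `repeats` times; the report
#' carries the mean MAE over repeats and the Pearson correlation pooled
#' over all predictions.  Fully reproducible from `seed`.  With `k` equal
#' to the number of usable drugs and one repeat this reduces exactly to
#' leave-one-out.
#'
#' @inheritParams loo_evaluate
#' @param k number of folds, >= 2.
#' @param repeats number of independent fold partitions.
#' @param seed integer seed for the fold partitions.
#' @return object of class `cv_report`; `mae` is the mean over repeats,
#'   and `mae_by_repeat` holds the per-repeat values.
#' @export
kfold_evaluate <- function(bin, k = 10L, repeats = 5L, seed = 1L,
                           max_targets = 10L, discount = 1) {
  used <- which(!bin$excluded)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(used)) stop("k exceeds the number of usable drugs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maes <- numeric(repeats)
  all_pred <- NULL
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), length(used)))
    pred <- numeric(length(used))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      pred[test] <- fit_predict(bin, used[-test], used[test],
                                max_targets, discount)
    }
    maes[r] <- mean(abs(pred - bin$y[used]))
    all_pred <- c(all_pred, pred)
  }
  all_y <- rep(bin$y[used], repeats)
  rep_last <- cv_report(bin, used, pred,
                        sprintf("%d-fold CV x %d", k, repeats),
                        extra = list(k = k, repeats = repeats, seed = seed,
                                     mae_by_repeat = maes))
  rep_last$mae <- mean(maes)
  rep_last$pearson_r <- if (stats::sd(all_pred) > 0) {
    stats::cor(all_pred, all_y)
  } else NA_real_
  rep_last
}

#' EC50-based similarity between two drugs
#'
#' The similarity of two drugs is the ratio of summed EC50 minima over
#' their shared targets to summed EC50 maxima over the union of their
#' targets (absent interactions count 0):
#' \deqn{\Lambda(D_1, D_2) = \frac{\sum_i \min(E_1(i), E_2(i)) V_1(i) V_2(i)}
#'   {\sum_i \max(E_1(i), E_2(i))}.}
#' Identical profiles score 1; drugs with no overlapping targets score 0.
#'
#' @param ec50_1,ec50_2 named numeric EC50 vectors (nM) of the two drugs.
#' @return similarity in [0,1].
#' @examples
#' drug_similarity(c(A = 2, B = 4), c(A = 2, C = 4))  # 2 / (2+4+4) = 0.2
#' @export
drug_similarity <- function(ec50_1, ec50_2) {
  if (length(ec50_1) == 0L && length(ec50_2) == 0L) {
    warning("both drugs have empty target profiles; similarity defined as 0")
    return(0)
  }
  targets <- union(names(ec50_1), names(ec50_2))
  e1 <- e2 <- rep(0, length(targets))
  names(e1) <- names(e2) <- targets
  e1[names(ec50_1)] <- ec50_1
  e2[names(ec50_2)] <- ec50_2
  shared <- e1 > 0 & e2 > 0
  sum(pmin(e1, e2)[shared]) / sum(pmax(e1, e2))
}

#' Pairwise drug similarity matrix
#'
#' @param profiles named list of per-drug EC50 vectors (as in the
#'   `profiles` element of [read_ec50_panel()]).
#' @return symmetric numeric matrix of similarities with unit diagonal.
#' @export
similarity_matrix <- function(profiles) {
  m <- length(profiles)
  out <- diag(1, m)
  dimnames(out) <- list(names(profiles), names(profiles))
  if (m < 2L) return(out)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      out[i, j] <- out[j, i] <- drug_similarity(profiles[[i]], profiles[[j]])
    }
  }
  out
}
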