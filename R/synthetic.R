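# Random Boolean tumor-survival pathways, synthetic drug libraries and the
# train/test prediction benchmark.

# Random composition of n into k positive parts.
rand_composition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

#' Generate a random block-structured Boolean survival pathway
#'
#' A pathway consists of L blocks in series; block i has a_i parallel
#' lines; line j of block i carries b_j^i targets.  The tumor survives as
#' long as every block has at least one fully uninhibited line, so a drug
#' kills the tumor exactly when it cuts every line of some block.  Active
#' targets are partitioned randomly over blocks and lines (no target
#' appears in two blocks); target identities are drawn from `universe_ids`,
#' allowing the pathway to sit inside a larger universe of decoy targets.
#'
#' @param n_active number of active targets, >= 1.
#' @param max_blocks upper bound on the number of serial blocks L.
#' @param max_lines upper bound on parallel lines per block.
#' @param universe_ids integer ids to draw the active targets from
#'   (default `1:n_active`).
#' @return object of class `pathway_structure`: list of blocks, each a
#'   list of lines, each an integer vector of target ids; plus `n_active`.
#' @export
generate_pathway <- function(n_active, max_blocks = 3L, max_lines = 3L,
                             universe_ids = seq_len(n_active)) {
  stopifnot(n_active >= 1L, length(universe_ids) >= n_active)
  ids <- sample(universe_ids, n_active)
  L <- sample.int(min(max_blocks, n_active), 1L)
  block_sizes <- rand_composition(n_active, L)
  blocks <- vector("list", L)
  pos <- 0L
  for (i in seq_len(L)) {
    sz <- block_sizes[i]
    a <- sample.int(min(max_lines, sz), 1L)
    line_sizes <- rand_composition(sz, a)
    lines <- vector("list", a)
    p <- 0L
    for (j in seq_len(a)) {
      lines[[j]] <- ids[pos + p + seq_len(line_sizes[j])]
      p <- p + line_sizes[j]
    }
    blocks[[i]] <- lines
    pos <- pos + sz
  }
  structure(list(blocks = blocks, n_active = as.integer(n_active)),
            class = "pathway_structure")
}

#' @export
print.pathway_structure <- function(x, ...) {
  cat(sprintf("pathway_structure: %d block(s), %d active targets\n",
              length(x$blocks), x$n_active))
  for (i in seq_along(x$blocks)) {
    lines <- vapply(x$blocks[[i]], function(l)
      paste(l, collapse = ","), character(1))
    cat(sprintf("  block %d: %s\n", i,
                paste(sprintf("{%s}", lines), collapse = " || ")))
  }
  invisible(x)
}

#' Boolean ground-truth sensitivity of an inhibition set
#'
#' A drug is sensitive (1) exactly when, for some block of the pathway, it
#' inhibits at least one target on every parallel line of that block —
#' i.e. it cuts all survival paths through one serial element.
#'
#' @param inhibited integer vector of inhibited target ids (or logical
#'   vector over the universe).
#' @param pathway a [generate_pathway()] structure.
#' @return 0 or 1.
#' @export
boolean_sensitivity <- function(inhibited, pathway) {
  if (is.logical(inhibited)) inhibited <- which(inhibited)
  for (block in pathway$blocks) {
    if (all(vapply(block, function(line)
      any(line %in% inhibited), logical(1)))) return(1)
  }
  0
}

#' Generate a synthetic targeted-drug library
#'
#' Each drug inhibits a Poisson-distributed number of targets (lambda = 3,
#' at least 1, at most the universe size) drawn uniformly from a universe
#' of active plus decoy targets.
#'
#' @param n_drugs library size.
#' @param n_universe total number of targets in the universe.
#' @param lambda mean number of targets per drug.
#' @return logical n_drugs x n_universe inhibition matrix.
#' @export
generate_drug_library <- function(n_drugs = 1000L, n_universe,
                                  lambda = 3) {
  m <- matrix(FALSE, n_drugs, n_universe)
  counts <- pmin(pmax(stats::rpois(n_drugs, lambda), 1L), n_universe)
  for (i in seq_len(n_drugs)) m[i, sample.int(n_universe, counts[i])] <- TRUE
  colnames(m) <- paste0("K", seq_len(n_universe))
  rownames(m) <- sprintf("drug%04d", seq_len(n_drugs))
  m
}

#' Synthetic train/test benchmark of the TIM pipeline
#'
#' For each replicate and each active-target count, a random pathway is
#' embedded in a universe of active plus decoy targets, a drug library is
#' generated, and disjoint training and test panels are drawn.  Boolean
#' ground-truth sensitivities of the training panel feed the full pipeline
#' (SFFS target selection + TIM); TIM predictions on the test panel are
#' thresholded at 0.5 and compared with the Boolean truth.  A coin-flip
#' baseline accuracy is reported alongside.  All randomness flows from the
#' caller's RNG state, so a prior `set.seed()` makes runs reproducible.
#'
#' @param n_active integer vector of active-target counts.
#' @param reps replicate random pathways per count.
#' @param n_train,n_test training/test panel sizes (drawn disjointly).
#' @param library_size drug library size.
#' @param n_decoy decoy (inactive) targets in the universe.
#' @param max_targets SFFS cardinality cap.
#' @param lambda mean targets per library drug.
#' @param verbose print progress per n_active?
#' @return data.frame with one row per `n_active`: mean number of
#'   correctly predicted test drugs, mean accuracy (%), and the coin-flip
#'   baseline accuracy (%).  Per-replicate accuracies are attached as the
#'   `"replicates"` attribute.
#' @export
run_benchmark <- function(n_active = 6:10, reps = 40L, n_train = 60L,
                          n_test = 40L, library_size = 1000L,
                          n_decoy = 10L, max_targets = 12L, lambda = 3,
                          verbose = FALSE) {
  stopifnot(n_train + n_test <= library_size)
  rows <- vector("list", length(n_active))
  rep_acc <- matrix(NA_real_, reps, length(n_active),
                    dimnames = list(NULL, paste0("n", n_active)))
  base_acc <- rep_acc
  for (ai in seq_along(n_active)) {
    na <- n_active[ai]
    nu <- na + n_decoy
    for (r in seq_len(reps)) {
      pathway <- generate_pathway(na, universe_ids = seq_len(nu))
      lib <- generate_drug_library(library_size, nu, lambda)
      idx <- sample.int(library_size, n_train + n_test)
      train <- idx[seq_len(n_train)]
      test <- idx[n_train + seq_len(n_test)]
      y_train <- vapply(train, function(i)
        boolean_sensitivity(lib[i, ], pathway), numeric(1))
      y_test <- vapply(test, function(i)
        boolean_sensitivity(lib[i, ], pathway), numeric(1))
      bin <- list(drug = rownames(lib)[c(train, test)],
                  y = c(y_train, y_test),
                  dtip = lib[c(train, test), , drop = FALSE],
                  excluded = rep(FALSE, n_train + n_test),
                  universe = colnames(lib), culture_id = "synthetic")
      pred <- fit_predict(bin, seq_len(n_train), n_train + seq_len(n_test),
                          max_targets = max_targets)
      rep_acc[r, ai] <- mean((pred >= 0.5) == (y_test == 1))
      base_acc[r, ai] <- mean(sample(c(0, 1), n_test, TRUE) == y_test)
    }
    if (verbose)
      message(sprintf("n_active = %d: mean accuracy %.1f%%",
                      na, 100 * mean(rep_acc[, ai])))
    rows[[ai]] <- data.frame(
      n_active = na,
      correct_prediction = mean(rep_acc[, ai]) * n_test,
      accuracy_pct = 100 * mean(rep_acc[, ai]),
      baseline_pct = 100 * mean(base_acc[, ai]))
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- rep_acc
  out
}
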