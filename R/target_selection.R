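# Target-set scoring (bin-partition error + monotonicity inconsistency
# penalty) and SFFS selection of a minimal relevant target set.

#' Project drug inhibition profiles onto a target set
#'
#' Masks each drug's binary target inhibition profile to the members of a
#' candidate target set and packs the restricted pattern into an integer
#' (bit i-1 = i-th member of `targets`).
#'
#' @param dtip logical drugs x targets matrix.
#' @param targets integer column indices of the target set (<= 30 members).
#' @return integer vector of patterns, one per drug.
#' @export
project_drugs <- function(dtip, targets) {
  k <- length(targets)
  if (k == 0L) return(rep.int(0L, nrow(dtip)))
  if (k > 30L) stop("target sets larger than 30 are not supported")
  as.integer(dtip[, targets, drop = FALSE] %*% bitwShiftL(1L, seq_len(k) - 1L))
}

#' Partition drugs into bins by restricted inhibition pattern
#'
#' @param patterns integer vector of projected patterns.
#' @param y numeric sensitivity scores.
#' @return list with `pattern` (unique patterns), `mean` (per-bin mean
#'   sensitivity), `index` (bin index of each drug).
#' @export
bin_partition <- function(patterns, y) {
  up <- sort(unique(patterns))
  idx <- match(patterns, up)
  means <- vapply(seq_along(up), function(b) mean(y[idx == b]), numeric(1))
  list(pattern = up, mean = means, index = idx)
}

#' Score a target set (bin error plus inconsistency penalty)
#'
#' The score Gamma(T) of a candidate target set is the within-bin absolute
#' deviation of experimental sensitivities from their bin means, plus a
#' penalty term for drug/bin pairs that violate the tumor-promoter rules:
#' a bin whose pattern is a strict subset of a drug's pattern may not have a
#' higher mean than the drug's sensitivity (a superset inhibition cannot be
#' less effective), and a bin whose pattern is a strict superset may not
#' have a lower mean (a subset inhibition cannot be more effective).  Each
#' violating pair contributes `|P(bin) - y(drug)|`.
#'
#' @param patterns integer vector of projected drug patterns.
#' @param y numeric sensitivity scores in [0,1].
#' @param eps tolerance on score comparisons, so float noise never counts
#'   as a violation.
#' @return non-negative numeric score.
#' @examples
#' gamma_score(c(1L, 1L), c(0.2, 0.8))   # one bin, mean 0.5 -> 0.6
#' @export
gamma_score <- function(patterns, y, eps = 1e-9) {
  part <- bin_partition(patterns, y)
  term1 <- sum(abs(y - part$mean[part$index]))
  nb <- length(part$pattern)
  m <- length(patterns)
  # bins x drugs cross comparison
  bp <- matrix(part$pattern, nb, m)
  dp <- matrix(patterns, nb, m, byrow = TRUE)
  both <- matrix(bitwAnd(bp, dp), nb, m)
  pm <- matrix(part$mean, nb, m)
  ym <- matrix(y, nb, m, byrow = TRUE)
  strict <- bp != dp
  viol <- (strict & both == bp & pm > ym + eps) |   # bin subset of drug, rule 1
          (strict & both == dp & pm < ym - eps)     # bin superset of drug, rule 2
  term1 + sum(abs(pm - ym)[viol])
}

#' Greedy pure-forward target selection (baseline)
#'
#' Adds at each step the candidate target that most reduces the score, and
#' stops when no addition strictly improves it.  Serves as a baseline and
#' as a sanity bound for [sffs_select()], which can never do worse.
#'
#' @inheritParams sffs_select
#' @return list with `targets` (integer indices) and `score`.
#' @export
forward_select <- function(dtip, y, candidates = NULL, max_size = 20L,
                           eps = 1e-9) {
  if (is.null(candidates)) candidates <- which(colSums(dtip) > 0L)
  cur <- integer(0)
  cur_score <- gamma_score(project_drugs(dtip, cur), y)
  repeat {
    rem <- setdiff(candidates, cur)
    if (length(rem) == 0L || length(cur) >= max_size) break
    scores <- vapply(rem, function(t)
      gamma_score(project_drugs(dtip, c(cur, t)), y), numeric(1))
    b <- which.min(scores)            # which.min takes the first = lowest index
    if (scores[b] < cur_score - eps) {
      cur <- c(cur, rem[b]); cur_score <- scores[b]
    } else break
  }
  list(targets = sort(cur), score = cur_score)
}

#' Select a minimal relevant target set by sequential floating forward search
#'
#' SFFS alternates a forward step (add the candidate target minimizing the
#' score; ties break toward the lowest target index) with a floating
#' backward step (repeatedly remove the member whose removal scores best,
#' as long as the reduced set beats the best set previously recorded at
#' that smaller cardinality).  The search runs until the cardinality cap
#' `max_size` is reached, the candidate pool is exhausted, or the score
#' hits 0.  The returned set is the best recorded at any cardinality, with
#' score ties broken toward smaller cardinality, and is finally pruned so
#' that no member can be removed without increasing the score (local
#' minimality).
#'
#' @param dtip logical drugs x targets matrix (excluded drugs already
#'   dropped).
#' @param y numeric sensitivity scores, one per drug.
#' @param candidates integer indices of candidate target columns; defaults
#'   to every target hit by at least one drug.
#' @param max_size maximum cardinality of the returned set.
#' @param eps strictness tolerance on score comparisons.
#' @return list with `targets` (sorted integer indices), `score`, and
#'   `bins` (the [bin_partition()] induced by the selected set).
#' @export
sffs_select <- function(dtip, y, candidates = NULL, max_size = 20L,
                        eps = 1e-9) {
  if (is.null(candidates)) candidates <- which(colSums(dtip) > 0L)
  candidates <- sort(candidates)
  score_of <- function(set) gamma_score(project_drugs(dtip, set), y)

  best <- list()   # per-cardinality best: best[[k+1]] = list(score, set)
  note <- function(set, s) {
    k <- length(set) + 1L
    if (k > length(best) || is.null(best[[k]]) || s < best[[k]]$score - eps) {
      best[[k]] <<- list(score = s, set = set)
      TRUE
    } else FALSE
  }
  cur <- integer(0)
  cur_score <- score_of(cur)
  note(cur, cur_score)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 20L * max_size) break
    rem <- setdiff(candidates, cur)
    if (length(rem) == 0L || length(cur) >= max_size) break
    ## forward step: add the candidate minimizing Gamma (ties -> lowest index)
    scores <- vapply(rem, function(t) score_of(c(cur, t)), numeric(1))
    b <- which.min(scores)
    cur <- sort(c(cur, rem[b])); cur_score <- scores[b]
    note(cur, cur_score)
    if (cur_score <= eps) break     # perfect explanation of the screen
    ## floating backward: drop the least useful member while doing so beats
    ## the best set recorded at the smaller cardinality
    while (length(cur) > 1L) {
      drops <- vapply(seq_along(cur), function(i)
        score_of(cur[-i]), numeric(1))
      i <- which.min(drops)
      k <- length(cur)            # candidate lands at cardinality k - 1
      prev_best <- if (k <= length(best) && !is.null(best[[k]]))
        best[[k]]$score else Inf
      if (drops[i] < prev_best - eps) {
        cur <- cur[-i]; cur_score <- drops[i]
        note(cur, cur_score)
      } else break
    }
  }
  ## global best across cardinalities: min score, ties toward smaller set
  recorded <- Filter(Negate(is.null), best)
  scores <- vapply(recorded, `[[`, numeric(1), "score")
  sizes <- vapply(recorded, function(b) length(b$set), integer(1))
  near <- which(scores <= min(scores) + eps)
  winner <- near[which.min(sizes[near])]
  set <- recorded[[winner]]$set
  s <- recorded[[winner]]$score
  ## minimality pruning: drop members whose removal does not increase Gamma
  repeat {
    if (length(set) == 0L) break
    drops <- vapply(seq_along(set), function(i) score_of(set[-i]), numeric(1))
    i <- which.min(drops)
    if (drops[i] <= s + eps) { set <- set[-i]; s <- drops[i] } else break
  }
  set <- sort(set)
  list(targets = set, score = s,
       bins = bin_partition(project_drugs(dtip, set), y))
}
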