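# The Target Inhibition Map: monotone subset/superset interpolation of
# sensitivities for binary target-inhibition combinations.

#' Build a Target Inhibition Map
#'
#' A TIM maps every binary inhibition combination over a selected target set
#' to a predicted sensitivity in [0,1].  Experimentally observed
#' combinations keep their (bin-mean) sensitivities; the all-zeros
#' combination (no treatment) is anchored at 0 and the all-ones combination
#' (every selected target inhibited) at 1 unless experimental entries
#' override them; every other combination is interpolated between its best
#' known subset and its worst known superset (see [infer_sensitivity()]).
#'
#' @param patterns integer vector of known combination patterns (bit i-1 =
#'   i-th target of the set); duplicates are averaged.
#' @param values numeric sensitivities in [0,1] matching `patterns`.
#' @param targets character names of the selected targets (defines nT).
#' @param discount positive inference discount exponent; 1 = linear
#'   interpolation, larger values are more pessimistic about partial
#'   inhibition.
#' @param weights positive per-target relevance weights (default uniform).
#' @param dense materialize the full 2^nT table?  `NA` (default) does so
#'   for nT <= `dense_cap`, otherwise entries are computed on demand.
#' @param dense_cap largest nT for automatic dense materialization.
#' @return object of class `tim`.
#' @examples
#' tim <- build_tim(2L, 0.6, targets = c("A", "B"))  # pattern 10 -> 0.6
#' predict(tim, 0:3)
#' @export
build_tim <- function(patterns, values, targets, discount = 1,
                      weights = NULL, dense = NA, dense_cap = 16L) {
  nT <- length(targets)
  if (nT < 1L) stop("TIM needs at least one target")
  if (nT > 30L) stop("dense TIM limited to 30 targets; project to a smaller set")
  stopifnot(length(patterns) == length(values), discount > 0)
  if (is.null(weights)) weights <- rep(1, nT)
  stopifnot(length(weights) == nT, all(weights > 0))
  if (any(values < 0 | values > 1)) stop("sensitivities must lie in [0,1]")
  if (any(patterns < 0L | patterns >= 2^nT)) stop("pattern out of range for nT targets")
  known <- if (length(patterns)) {
    vapply(split(values, as.integer(patterns)), mean, numeric(1))
  } else numeric(0)
  tim <- structure(list(targets = targets, nT = nT, known = known,
                        discount = discount, weights = weights,
                        table = NULL), class = "tim")
  if (is.na(dense)) dense <- nT <= dense_cap
  if (dense) {
    if (nT > 30L) stop("nT too large for dense mode; use dense = FALSE")
    tim$table <- tim_dense_table(tim)
  }
  tim
}

#' @export
print.tim <- function(x, ...) {
  cat(sprintf("Target Inhibition Map over %d targets (%s)\n", x$nT,
              paste(x$targets, collapse = ", ")))
  cat(sprintf("  %d experimental combination(s), discount n = %g, %s\n",
              length(x$known), x$discount,
              if (is.null(x$table)) "lazy" else "dense table"))
  invisible(x)
}

# Known + boundary entries of a TIM as (pattern, value) vectors.
tim_anchors <- function(tim) {
  pats <- as.integer(names(tim$known))
  vals <- unname(tim$known)
  full <- as.integer(2^tim$nT - 1)
  if (!0L %in% pats) { pats <- c(pats, 0L); vals <- c(vals, 0) }
  if (!full %in% pats) { pats <- c(pats, full); vals <- c(vals, 1) }
  list(pattern = pats, value = vals)
}

#' Bounding subset/superset combinations for a pattern
#'
#' Finds, among the experimental and boundary entries of a TIM, the subset
#' combination of the query with the highest sensitivity (`C_l`, `y_l`) and
#' the superset combination with the lowest sensitivity (`C_u`, `y_u`).
#' Ties break toward the combination closest in Hamming distance to the
#' query (largest subset / smallest superset), then toward the smallest
#' pattern value.  `h` is the Hamming distance between the two bounds and
#' `d` the distance from `C_l` to the query.
#'
#' @param pattern integer inhibition pattern.
#' @param tim a [build_tim()] object.
#' @return list `(C_l, y_l, C_u, y_u, h, d)`.
#' @export
tim_bounds <- function(pattern, tim) {
  a <- tim_anchors(tim)
  pattern <- as.integer(pattern)
  is_sub <- bitwAnd(a$pattern, pattern) == a$pattern
  is_sup <- bitwAnd(a$pattern, pattern) == pattern
  subs <- which(is_sub); sups <- which(is_sup)
  ## lower bound: highest-sensitivity subset; ties -> largest, then smallest id
  yl <- max(a$value[subs])
  cl_cand <- subs[a$value[subs] >= yl - 1e-12]
  sizes <- bit_count(a$pattern[cl_cand])
  cl_cand <- cl_cand[sizes == max(sizes)]
  Cl <- min(a$pattern[cl_cand])
  ## upper bound: lowest-sensitivity superset; ties -> smallest, then smallest id
  yu <- min(a$value[sups])
  cu_cand <- sups[a$value[sups] <= yu + 1e-12]
  sizes <- bit_count(a$pattern[cu_cand])
  cu_cand <- cu_cand[sizes == min(sizes)]
  Cu <- min(a$pattern[cu_cand])
  list(C_l = as.integer(Cl), y_l = yl, C_u = as.integer(Cu), y_u = yu,
       h = bit_count(bitwXor(Cl, Cu)), d = bit_count(bitwXor(Cl, pattern)))
}

# Naive pairwise interpolation between the bounding anchor combinations of
# one pattern (no monotone envelope).
naive_infer <- function(pattern, tim, warn = TRUE) {
  pattern <- as.integer(pattern)
  kn <- tim$known[as.character(pattern)]
  if (!is.na(kn)) return(unname(kn))
  b <- tim_bounds(pattern, tim)
  yl <- b$y_l; yu <- b$y_u
  if (yl > yu + 1e-12) {
    if (warn)
      warning(sprintf(
        "non-monotone experimental entries: subset %s (y=%.3f) exceeds superset %s (y=%.3f); clamping",
        pattern_to_string(b$C_l, tim$nT), yl,
        pattern_to_string(b$C_u, tim$nT), yu))
    yu <- yl
  }
  if (b$h == 0L) return(yl)
  trans <- bit_which(bitwXor(b$C_l, b$C_u), tim$nT)
  added <- bit_which(bitwXor(b$C_l, pattern), tim$nT)
  ratio <- sum(tim$weights[added]) / sum(tim$weights[trans])
  yl + (yu - yl) * ratio^tim$discount
}

#' Predict the sensitivity of one inhibition combination
#'
#' The prediction interpolates between the bounding subset/superset
#' combinations of the query: with `y_l`/`y_u` the sensitivities of the
#' best known subset and worst known superset, `h` the number of
#' transition targets between the bounds and `d` of them added by the
#' query, the pairwise interpolant is
#' \deqn{y_l + (y_u - y_l)\Big(\frac{\sum_{i \in added}\alpha_i}
#'   {\sum_{i \in transition}\alpha_i}\Big)^{n}}
#' where `n` is the inference discount and `alpha` the per-target weights
#' (uniform weights reduce the ratio to `d/h`).  Because different queries
#' can snap to different anchor pairs, the raw interpolant alone is not
#' globally monotone; the returned prediction is its monotone envelope —
#' the maximum of the interpolant over all subsets of the query — which
#' still lies inside `[y_l, y_u]` (upper bounds only tighten on supersets)
#' and therefore also honors the subset/superset rules.  Experimentally
#' observed combinations always return their stored value, so any
#' non-monotonicity present in the data itself stays localized to exact
#' known entries; when the data is inconsistent (`y_l > y_u`) the upper
#' bound is clamped up to `y_l` with a warning naming the offending
#' combinations.
#'
#' @param pattern integer inhibition pattern.
#' @param tim a [build_tim()] object.
#' @param warn warn on clamped non-monotone experimental entries?
#' @return predicted sensitivity in [0,1].
#' @examples
#' tim <- build_tim(integer(0), numeric(0), targets = c("A", "B", "C"))
#' infer_sensitivity(1L, tim)   # 1 of 3 targets inhibited -> 1/3 (n = 1)
#' @export
infer_sensitivity <- function(pattern, tim, warn = TRUE) {
  pattern <- as.integer(pattern)
  if (!is.null(tim$table)) return(tim$table[pattern + 1L])
  kn <- tim$known[as.character(pattern)]
  if (!is.na(kn)) return(unname(kn))
  if (pattern == as.integer(2^tim$nT - 1)) return(1)
  k <- bit_count(pattern)
  if (k > 22L)
    stop("monotone-envelope inference over ", k,
         " inhibited targets is not tractable lazily; build a dense TIM")
  ## enumerate all subsets of the pattern and take the best interpolant
  best <- 0
  s <- pattern
  repeat {
    best <- max(best, naive_infer(s, tim, warn = warn))
    if (s == 0L) break
    s <- bitwAnd(s - 1L, pattern)
  }
  best
}

# Dense table of a TIM: naive interpolants everywhere, then a
# subset-maximum sweep (one pass per bit), with known entries pinned to
# their experimental values afterwards.
tim_dense_table <- function(tim, warn = FALSE) {
  nT <- tim$nT
  tab <- vapply(0L:(2L^nT - 1L), naive_infer, numeric(1), tim = tim,
                warn = warn)
  for (b in seq_len(nT) - 1L) {
    bit <- bitwShiftL(1L, b)
    has <- which(bitwAnd(0L:(2L^nT - 1L), bit) == bit)
    tab[has] <- pmax(tab[has], tab[has - bit])
  }
  kp <- as.integer(names(tim$known))
  tab[kp + 1L] <- unname(tim$known)
  tab
}

#' Predict sensitivities for inhibition patterns or binarized drugs
#'
#' @param object a `tim`.
#' @param patterns integer vector of inhibition patterns over the TIM's
#'   target set.
#' @param warn passed to [infer_sensitivity()].
#' @param ... unused.
#' @return numeric vector of predicted sensitivities.
#' @export
predict.tim <- function(object, patterns, warn = FALSE, ...) {
  vapply(as.integer(patterns), infer_sensitivity, numeric(1),
         tim = object, warn = warn)
}

#' Predict the sensitivity of a binarized drug
#'
#' Projects the drug's full-universe inhibition profile onto the TIM's
#' target set (by name) and evaluates the map.  A drug hitting none of the
#' selected targets lands on the all-zeros side and typically predicts 0.
#'
#' @param dtip logical (or 0/1) vector over the screen universe, named, or
#'   a character vector of inhibited target names.
#' @param tim a `tim` whose `targets` are a subset of the universe names.
#' @param warn passed to [infer_sensitivity()].
#' @return predicted sensitivity in [0,1].
#' @export
predict_drug <- function(dtip, tim, warn = FALSE) {
  hits <- if (is.character(dtip)) dtip else names(dtip)[as.logical(dtip)]
  pattern <- bits_to_pattern(match(intersect(hits, tim$targets), tim$targets))
  infer_sensitivity(pattern, tim, warn = warn)
}

#' Continuous target inhibition profile of a drug at a concentration
#'
#' Logistic dose model: the inhibition of target j at concentration x is
#' `f(j|x) = 1 / (1 + exp(log(ec50_j / x))) = x / (x + ec50_j)`, so each
#' target is exactly half-inhibited at its own EC50.  Targets without a
#' recorded EC50 get 0.
#'
#' @param ec50 named numeric EC50 vector (nM) of the drug.
#' @param x concentration in nM, > 0.
#' @param universe optional character vector of all target names; defaults
#'   to the drug's own targets.
#' @return named numeric vector of inhibition ratios in [0,1].
#' @export
continuous_inhibition <- function(ec50, x, universe = names(ec50)) {
  stopifnot(x > 0)
  z <- rep(0, length(universe))
  names(z) <- universe
  if (length(ec50)) z[names(ec50)] <- x / (x + ec50)
  z
}

#' Combine continuous inhibition profiles of several drugs
#'
#' Independent-complement composition: the joint inhibition of a target is
#' `1 - prod(1 - z_drug)` over the co-applied drugs, i.e. a target escapes
#' only if it escapes every drug independently.
#'
#' @param ... numeric inhibition profiles over the same universe (as from
#'   [continuous_inhibition()]).
#' @return combined inhibition profile.
#' @export
combine_inhibition <- function(...) {
  zs <- list(...)
  out <- 1 - Reduce(`*`, lapply(zs, function(z) 1 - z))
  names(out) <- names(zs[[1]])
  out
}

#' Threshold a continuous inhibition profile to a binary pattern
#'
#' The documented bridge between continuous profiles and the binary TIM:
#' targets inhibited at ratio >= 0.5 count as hit.
#'
#' @param z numeric inhibition profile.
#' @param threshold inhibition ratio cutoff.
#' @return logical vector.
#' @export
threshold_inhibition <- function(z, threshold = 0.5) {
  z >= threshold
}
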