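# Independent brute-force oracles used by the tests.  These deliberately
# use a set-of-indices representation and explicit loops, not the package's
# bitmask machinery, so agreement is a genuine cross-check.

# Target-set score by direct evaluation of the bin error and the
# rule-violation penalty: drugs are lists of inhibited-target index sets.
oracle_gamma <- function(sets, y, eps = 1e-9) {
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
  bins <- unique(keys)
  bin_mean <- vapply(bins, function(b) mean(y[keys == b]), numeric(1))
  term1 <- 0
  for (i in seq_along(sets))
    term1 <- term1 + abs(y[i] - unname(bin_mean[keys[i]]))
  term2 <- 0
  for (i in seq_along(sets)) {
    di <- sort(unname(sets[[i]]))
    for (b in seq_along(bins)) {
      bs <- sort(as.integer(strsplit(bins[b], ",", fixed = TRUE)[[1]]))
      if (identical(bs, di)) next
      sub <- all(bs %in% di)     # bin strict subset of drug
      sup <- all(di %in% bs)     # bin strict superset of drug
      if ((sub && bin_mean[b] > y[i] + eps) ||
          (sup && bin_mean[b] < y[i] - eps)) {
        term2 <- term2 + abs(bin_mean[[b]] - y[i])
      }
    }
  }
  unname(term1 + term2)
}

# Exhaustive minimum of gamma_score over all target subsets.
oracle_best_subset <- function(dtip, y) {
  nt <- ncol(dtip)
  best <- Inf
  for (s in 0:(2^nt - 1)) {
    idx <- which(bitwAnd(s, 2^(seq_len(nt) - 1)) > 0)
    g <- gamma_score(project_drugs(dtip, idx), y)
    if (g < best) best <- g
  }
  best
}

# Straight-line reimplementation of the subset/superset interpolation:
# anchors as list(sets = list of index sets, values), query as index set.
oracle_infer <- function(query, anchor_sets, anchor_values, n, discount = 1) {
  is_subset <- function(a, b) all(a %in% b)
  subs <- which(vapply(anchor_sets, is_subset, logical(1), b = query))
  sups <- which(vapply(anchor_sets, function(s) is_subset(query, s), logical(1)))
  yl <- max(anchor_values[subs])
  yu <- min(anchor_values[sups])
  if (yl > yu) yu <- yl
  cl <- anchor_sets[subs][order(-anchor_values[subs],
                                -lengths(anchor_sets[subs]))][[1]]
  cu <- anchor_sets[sups][order(anchor_values[sups],
                                lengths(anchor_sets[sups]))][[1]]
  h <- length(union(setdiff(cl, cu), setdiff(cu, cl)))
  d <- length(union(setdiff(cl, query), setdiff(query, cl)))
  if (h == 0) return(yl)
  yl + (yu - yl) * (d / h)^discount
}

# Monotone-envelope prediction: maximum of the pairwise interpolant over
# the explicit powerset of the query, with known combinations pinned.
oracle_envelope <- function(query, anchor_sets, anchor_values, n,
                            discount = 1, known_sets = list(),
                            known_values = numeric(0)) {
  key <- function(s) paste(sort(s), collapse = ",")
  kn <- match(key(query), vapply(known_sets, key, character(1)))
  if (!is.na(kn)) return(known_values[kn])
  subsets <- list(integer(0))
  for (t in query) subsets <- c(subsets, lapply(subsets, function(s) c(s, t)))
  base <- vapply(subsets, function(s) {
    kn <- match(key(s), vapply(known_sets, key, character(1)))
    if (!is.na(kn)) return(known_values[kn])
    oracle_infer(s, anchor_sets, anchor_values, n, discount)
  }, numeric(1))
  max(base)
}

# Minimal true points of the monotone indicator 1[value >= theta] over all
# 2^n combinations, by exhaustive enumeration.  The empty combination (no
# treatment) is never a candidate term, so it is excluded up front.
oracle_min_true_points <- function(values, theta, n) {
  true_pats <- setdiff(which(values >= theta) - 1L, 0L)
  minimal <- logical(length(true_pats))
  for (i in seq_along(true_pats)) {
    p <- true_pats[i]
    others <- true_pats[true_pats != p]
    minimal[i] <- !any(bitwAnd(others, p) == others)
  }
  sort(true_pats[minimal])
}

# Path-enumeration ground truth for block pathways: the tumor survives iff
# some source-to-sink path (one line per block, all its targets intact)
# remains unbroken; sensitivity 1 iff every path is broken.
oracle_path_sensitivity <- function(inhibited, pathway) {
  choices <- lapply(pathway$blocks, seq_along)
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    path <- unlist(lapply(seq_along(pathway$blocks), function(i)
      pathway$blocks[[i]][[grid[r, i]]]))
    if (!any(path %in% inhibited)) return(0)   # intact survival path
  }
  1
}

# Per-bit application of the three BN transition rules, independent of the
# precomputed successor table.
oracle_bn_step <- function(state_bits, parents, is_and, mut, drv) {
  n <- length(parents)
  nxt <- integer(n)
  for (j in seq_len(n)) {
    if (mut[j]) { nxt[j] <- 1L; next }
    p <- parents[[j]]
    if (length(p) == 0) { nxt[j] <- 0L; next }
    nxt[j] <- if (is_and[j]) as.integer(all(state_bits[p] == 1)) else
      as.integer(any(state_bits[p] == 1))
  }
  c(nxt, as.integer(any(state_bits[drv] == 1)))   # phenotype last
}

# Random binarized screen for property tests.
rand_screen <- function(nt, m, p_hit = 0.35) {
  dtip <- matrix(stats::runif(m * nt) < p_hit, m, nt)
  empty <- rowSums(dtip) == 0
  if (any(empty)) dtip[cbind(which(empty), sample(nt, sum(empty), TRUE))] <- TRUE
  colnames(dtip) <- paste0("T", seq_len(nt))
  list(dtip = dtip, y = round(stats::runif(m), 2))
}

# Random TIM with c known combinations.
rand_tim <- function(nT, c_known, discount = 1) {
  pats <- sample(0:(2^nT - 1), c_known)
  build_tim(pats, stats::runif(c_known), targets = paste0("T", seq_len(nT)),
            discount = discount, dense = FALSE)
}

# Decode a BN state to the printed convention: target bits then phenotype.
bn_state_string <- function(s, n) {
  paste(c(bitwAnd(bitwShiftR(s, seq_len(n)), 1L), bitwAnd(s, 1L)),
        collapse = "")
}
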