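# Boolean-network dynamics: BN construction from a directional pathway,
# target-inhibition transforms, attractors, the dynamics-derived TIM and
# experiment-design counting formulas.
#
# State encoding: a network over n targets plus one phenotype bit has
# 2^(n+1) states.  Bit 0 (least significant) is the phenotype (1 = tumor),
# bit j (j = 1..n) is the activation state of target j.

#' Build a Boolean network from a directional activation pathway
#'
#' State-transition rules: (a) a target becomes 1 at t+1 when its upstream
#' activators fire — any of them for an OR gate, all of them for an AND
#' gate; (b) a mutated / latently activated target becomes 1 within one
#' step regardless of its inputs; (c) an unmutated target with inactive
#' upstream input (or no upstream at all) becomes 0.  The phenotype bit at
#' t+1 copies the activation of the tumor-driving target(s) at t (OR over
#' drivers).
#'
#' @param targets character vector of target names (defines n and bit
#'   order).
#' @param edges two-column matrix or data.frame of activation edges
#'   (from, to), using target names; may be empty.
#' @param mutated character vector of mutated / latently activated targets.
#' @param drivers character vector of tumor-driving targets.
#' @param gates named character vector, gate type per target ("OR" or
#'   "AND") for targets with several upstream activators; defaults to OR,
#'   the relation most commonly found in curated pathways.
#' @return object of class `boolean_network` with the successor of each of
#'   the 2^(n+1) states precomputed.
#' @export
pathway_to_bn <- function(targets, edges, mutated = character(0),
                          drivers, gates = NULL) {
  n <- length(targets)
  stopifnot(n >= 1L, n <= 16L)
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("edges must have two columns")
  bad <- setdiff(c(edges, mutated, drivers, names(gates)), targets)
  if (length(bad)) stop("unknown target name(s): ", paste(bad, collapse = ", "))
  parents <- lapply(targets, function(t)
    if (length(edges)) match(edges[edges[, 2] == t, 1], targets) else integer(0))
  ## activation graph must be acyclic (feedback is out of scope here)
  indeg <- lengths(parents)
  order_seen <- 0L
  deg <- indeg
  queue <- which(deg == 0L)
  children <- lapply(seq_len(n), function(i)
    which(vapply(parents, function(p) i %in% p, logical(1))))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_seen <- order_seen + 1L
    for (w in children[[v]]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (order_seen < n) stop("activation graph is cyclic; only acyclic pathways are supported")
  is_and <- rep(FALSE, n)
  if (!is.null(gates)) is_and[match(names(gates), targets)] <- toupper(gates) == "AND"
  mut <- targets %in% mutated
  drv <- match(drivers, targets)
  n_states <- 2L^(n + 1L)
  succ <- integer(n_states)
  for (s in 0L:(n_states - 1L)) {
    bits <- bitwAnd(bitwShiftR(s, seq_len(n)), 1L)   # target states
    nxt <- integer(n)
    for (j in seq_len(n)) {
      if (mut[j]) { nxt[j] <- 1L; next }
      p <- parents[[j]]
      if (length(p) == 0L) { nxt[j] <- 0L; next }
      nxt[j] <- if (is_and[j]) as.integer(all(bits[p] == 1L))
                else as.integer(any(bits[p] == 1L))
    }
    phen <- as.integer(any(bits[drv] == 1L))
    succ[s + 1L] <- phen + sum(bitwShiftL(nxt, seq_len(n)))
  }
  structure(list(targets = targets, n = n, successor = succ,
                 mutated = targets[mut], drivers = drivers,
                 inhibited = character(0)),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d targets + phenotype (%d states)\n",
              x$n, 2^(x$n + 1)))
  cat("  mutated:", if (length(x$mutated)) paste(x$mutated, collapse = ", ") else "none",
      "| drivers:", paste(x$drivers, collapse = ", "), "\n")
  if (length(x$inhibited))
    cat("  inhibited:", paste(x$inhibited, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a target-inhibition transform to a Boolean network
#'
#' Every transition i -> j of the untreated system becomes i -> z where z
#' equals j except that all inhibited targets are forced to 0.  The empty
#' inhibition set is the identity transform; applying a transform twice
#' equals applying it once.
#'
#' @param bn a [pathway_to_bn()] network.
#' @param inhibit character vector of inhibited target names (or integer
#'   indices).
#' @return the transformed `boolean_network`.
#' @export
apply_inhibition <- function(bn, inhibit) {
  idx <- if (is.character(inhibit)) match(inhibit, bn$targets) else as.integer(inhibit)
  if (anyNA(idx)) stop("unknown inhibited target(s)")
  if (length(idx) == 0L) return(bn)
  mask <- bitwNot(as.integer(sum(bitwShiftL(1L, idx))))
  bn$successor <- bitwAnd(bn$successor, mask)
  bn$inhibited <- union(bn$inhibited, bn$targets[idx])
  bn
}

#' Attractor reached from a start state
#'
#' Deterministic trajectory iteration: follows successors until a state
#' repeats; the returned attractor is the cycle (a fixed point has length
#' 1).  Any trajectory in a finite deterministic system reaches its cycle
#' within 2^(n+1) steps, which is enforced as a hard stop.
#'
#' @param bn a `boolean_network`.
#' @param start integer start state (default: everything active — all
#'   targets and the tumor bit set).
#' @return list with `cycle` (integer states), `tumorous` (TRUE if any
#'   cycle state has phenotype 1), `steps` taken to enter the cycle.
#' @export
bn_attractor <- function(bn, start = 2L^(bn$n + 1L) - 1L) {
  n_states <- 2L^(bn$n + 1L)
  seen <- integer(0)
  s <- as.integer(start)
  for (step in 0:n_states) {
    pos <- match(s, seen)
    if (!is.na(pos)) {
      cycle <- seen[pos:length(seen)]
      return(list(cycle = cycle,
                  tumorous = any(bitwAnd(cycle, 1L) == 1L),
                  steps = pos - 1L))
    }
    seen <- c(seen, s)
    s <- bn$successor[s + 1L]
  }
  stop("internal error: no cycle within the state-space bound")
}

#' Dynamics-derived Target Inhibition Map of a Boolean network
#'
#' For each of the 2^n target-inhibition combinations, applies the
#' inhibition transform, iterates from the all-active state to the
#' attractor, and scores the combination 1 (effective) when the attractor
#' is tumor-free — for cyclic attractors, tumor-free means no cycle state
#' carries the phenotype bit, a conservative convention.
#'
#' @param bn a `boolean_network` with n <= 16.
#' @return a [build_tim()] object over the network's targets whose known
#'   entries cover all 2^n combinations.
#' @export
tim_from_bn <- function(bn) {
  n <- bn$n
  if (n > 16L) stop("exhaustive dynamics-derived TIM limited to 16 targets")
  pats <- 0L:(2L^n - 1L)
  vals <- vapply(pats, function(p) {
    treated <- apply_inhibition(bn, bit_which(p, n))
    att <- bn_attractor(treated)
    as.numeric(!att$tumorous)
  }, numeric(1))
  build_tim(pats, vals, targets = bn$targets, dense = TRUE)
}

#' Number of distinct dynamic models consistent with a block structure
#'
#' A block structure with L serial blocks and line lengths b_j^i admits at
#' most `L! * prod_ij (b_j^i)!` distinct directional orderings: the serial
#' blocks can be ordered L! ways and each parallel line's targets can be
#' chained in (b_j^i)! ways.
#'
#' @param pathway a [generate_pathway()] structure.
#' @return numeric count.
#' @export
count_models <- function(pathway) {
  b <- unlist(lapply(pathway$blocks, lengths))
  factorial(length(pathway$blocks)) * prod(factorial(b))
}

#' Experiment-design bounds for inferring pathway directionality
#'
#' Bounds on the number of steady-state perturbation experiments needed to
#' orient a block structure: the expected number of experiments to order L
#' serial blocks is `(2L - 1)/3` (0 for a single block); the worst-case
#' and expected-case bounds for orienting the targets within the parallel
#' lines follow the per-block maxima
#' `max(max_j b_j - 2, ceil((sum_j b_j - a)/(a - 1)) - 1)` and their
#' expected-case counterparts `max(max_j (2 b_j - 4)/3,
#' ceil((sum_j (2 b_j - a))/(3 (a - 1))) - 1)`, plus the serial-ordering
#' cost.  Per-block terms are floored at 0 (a negative experiment count is
#' meaningless, e.g. for single-target lines), and the ceiling terms are
#' skipped for single-line blocks.
#'
#' @param pathway a [generate_pathway()] structure.
#' @return object of class `experiment_plan`: list with `L`, `a`, `b`,
#'   `model_count`, `ne_expected` (serial ordering only), `ne_worst_bound`
#'   and `ne_avg_bound`.
#' @export
experiment_bounds <- function(pathway) {
  L <- length(pathway$blocks)
  a <- lengths(pathway$blocks)
  b <- lapply(pathway$blocks, lengths)
  ne_expected <- if (L >= 2L) (2 * L - 1) / 3 else 0
  block_worst <- vapply(seq_len(L), function(i) {
    bi <- b[[i]]
    t1 <- max(bi) - 2
    t2 <- if (a[i] > 1L) ceiling((sum(bi) - a[i]) / (a[i] - 1)) - 1 else -Inf
    max(t1, t2, 0)
  }, numeric(1))
  block_avg <- vapply(seq_len(L), function(i) {
    bi <- b[[i]]
    t1 <- max((2 * bi - 4) / 3)
    t2 <- if (a[i] > 1L) ceiling(sum(2 * bi - a[i]) / (3 * (a[i] - 1))) - 1 else -Inf
    max(t1, t2, 0)
  }, numeric(1))
  structure(list(L = L, a = a, b = b,
                 model_count = count_models(pathway),
                 ne_expected = ne_expected,
                 ne_worst_bound = max(block_worst) + (L - 1),
                 ne_avg_bound = max(block_avg) + ne_expected),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("experiment_plan: L = %d block(s), %s line(s)\n",
              x$L, paste(x$a, collapse = "/")))
  cat(sprintf("  consistent dynamic models: %g\n", x$model_count))
  cat(sprintf("  serial ordering, expected experiments: %.3f\n", x$ne_expected))
  cat(sprintf("  full orientation: worst-case <= %g, expected <= %.3f\n",
              x$ne_worst_bound, x$ne_avg_bound))
  invisible(x)
}

#' Directional Boolean network realizing a block structure
#'
#' Lays the block structure out as one concrete directional pathway: the
#' targets of each line are chained in order; heads of the first block's
#' lines are mutated (latently activated); tails of every line in block i
#' activate the heads of all lines in block i+1 (OR gates); the tails of
#' the last block drive the tumor phenotype.  The dynamics-derived TIM of
#' this network coincides with [boolean_sensitivity()] of the structure.
#'
#' @param pathway a [generate_pathway()] structure.
#' @return a [pathway_to_bn()] network whose targets are named
#'   `K<id>` after the structure's target ids.
#' @export
structure_to_bn <- function(pathway) {
  ids <- unlist(lapply(pathway$blocks, unlist))
  targets <- paste0("K", sort(ids))
  nm <- function(id) paste0("K", id)
  edges <- NULL
  for (block in pathway$blocks) {
    for (line in block) {
      if (length(line) > 1L)
        edges <- rbind(edges, cbind(nm(line[-length(line)]), nm(line[-1])))
    }
  }
  L <- length(pathway$blocks)
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      tails <- vapply(pathway$blocks[[i]], function(l) l[length(l)], ids[1])
      heads <- vapply(pathway$blocks[[i + 1L]], function(l) l[1], ids[1])
      edges <- rbind(edges, as.matrix(expand.grid(nm(tails), nm(heads),
                                                  stringsAsFactors = FALSE)))
    }
  }
  mutated <- nm(vapply(pathway$blocks[[1]], function(l) l[1], ids[1]))
  drivers <- nm(vapply(pathway$blocks[[L]], function(l) l[length(l)], ids[1]))
  pathway_to_bn(targets,
                if (is.null(edges)) matrix(character(0), 0, 2) else edges,
                mutated = mutated, drivers = drivers)
}
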