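# Minimal Boolean equation extraction from a TIM and block-structured
# circuit grouping / DOT rendering.

#' Extract the minimal Boolean equation of effective target combinations
#'
#' Searches combinations of the TIM's targets breadth-first by size, from
#' single targets up to `max_terms` targets, accepting a combination as a
#' term of the Boolean survival equation when its sensitivity meets the
#' binarization threshold (`theta_e` for experimentally observed
#' combinations, `theta_i` for inferred ones).  Because the map is
#' monotone, every superset of an accepted term is also effective, so
#' accepted branches are never expanded: the result is the set of minimal
#' effective combinations.  Experimental combinations of any size whose
#' sensitivity meets `theta_e` are additionally admitted (but not expanded).
#' A term supported only by inference and contradicted by an experimental
#' superset combination below `theta_e` is dropped with a warning.
#'
#' @param tim a [build_tim()] object.
#' @param theta_e binarization threshold for experimental sensitivities.
#' @param theta_i binarization threshold for inferred sensitivities.
#' @param max_terms maximum number of targets per searched combination (M).
#' @return object of class `boolean_equation`: list with `terms` (list of
#'   integer index vectors into `targets`), `targets`, thresholds and cap.
#' @examples
#' tim <- build_tim(3L, 1, targets = c("A", "B", "C"))  # A&B effective
#' minimal_equation(tim, theta_i = 0.6)
#' @export
minimal_equation <- function(tim, theta_e = 0.5, theta_i = 0.5,
                             max_terms = 4L) {
  stopifnot(theta_e >= 0, theta_e <= 1, theta_i >= 0, theta_i <= 1)
  nT <- tim$nT
  max_terms <- min(max_terms, nT)
  known <- as.integer(names(tim$known))
  accepted <- integer(0)        # patterns of accepted terms
  inferred_only <- logical(0)
  covered <- function(p) any(bitwAnd(accepted, p) == accepted)
  for (k in seq_len(max_terms)) {
    combos <- utils::combn(nT, k, bits_to_pattern)
    for (p in combos) {
      if (length(accepted) && covered(p)) next   # cut branches past a term
      exper <- p %in% known
      s <- infer_sensitivity(p, tim, warn = FALSE)
      if (s >= (if (exper) theta_e else theta_i)) {
        accepted <- c(accepted, p)
        inferred_only <- c(inferred_only, !exper)
      }
    }
  }
  ## experimental combinations of any size are admitted regardless of M
  big <- known[bit_count(known) > max_terms]
  for (p in sort(big)) {
    if (tim$known[[as.character(p)]] >= theta_e && !covered(p)) {
      accepted <- c(accepted, p)
      inferred_only <- c(inferred_only, FALSE)
    }
  }
  ## verification against experimental data: an inference-only term whose
  ## experimental superset fails theta_e contradicts rule 1 -> drop it
  if (length(accepted)) {
    low_exp <- known[unname(tim$known) < theta_e]
    keep <- vapply(seq_along(accepted), function(i) {
      if (!inferred_only[i]) return(TRUE)
      p <- accepted[i]
      if (any(bitwAnd(low_exp, p) == p)) {
        warning(sprintf(
          "dropping inferred term %s: contradicted by a sub-threshold experimental superset",
          pattern_to_string(p, nT)))
        FALSE
      } else TRUE
    }, logical(1))
    accepted <- accepted[keep]
  }
  ## minimality filter (also across the late-admitted large terms)
  if (length(accepted) > 1L) {
    minimal <- vapply(seq_along(accepted), function(i) {
      p <- accepted[i]
      !any(bitwAnd(accepted[-i], p) == accepted[-i] & accepted[-i] != p)
    }, logical(1))
    accepted <- accepted[minimal]
  }
  accepted <- sort(accepted)
  structure(list(
    terms = lapply(accepted, bit_which, k = nT),
    targets = tim$targets,
    theta_e = theta_e, theta_i = theta_i, max_terms = max_terms),
    class = "boolean_equation")
}

#' @export
print.boolean_equation <- function(x, ...) {
  if (length(x$terms) == 0L) {
    cat("boolean_equation: empty (no effective combination found)\n")
    return(invisible(x))
  }
  terms <- vapply(x$terms, function(t)
    paste(x$targets[t], collapse = " & "), character(1))
  cat("boolean_equation:", paste0("(", terms, ")", collapse = " | "), "\n")
  invisible(x)
}

# Expand one block (list of lines, each a vector of target indices) into
# the set of terms of its cartesian product, each sorted.
expand_block <- function(lines) {
  grid <- expand.grid(lines, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  apply(grid, 1L, function(r) sort(unique(as.integer(r))), simplify = FALSE)
}

term_key <- function(t) paste(sort(t), collapse = ",")

#' Group the terms of a Boolean equation into circuit blocks
#'
#' Factors the minimal equation into the block structure used by TIM
#' circuit diagrams: each block is a set of parallel lines (AND between
#' lines), each line carries alternative targets (OR within a line), and
#' blocks in series are OR-alternative treatments.  The grouping heuristic
#' repeatedly picks the target shared by the most uncovered terms, factors
#' it into its own line and recurses on the cofactors; terms that fit no
#' factored block become singleton blocks.  The cartesian expansion of each
#' block is checked to reproduce exactly the covered terms, so grouping can
#' never change the equation's semantics.
#'
#' @param eq a [minimal_equation()] result.
#' @return object of class `tim_circuit`: list with `blocks` (each a list
#'   of lines, each line a character vector of target names) and `targets`.
#' @examples
#' eq <- structure(list(terms = list(c(1L, 3L), c(2L, 3L)),
#'                      targets = c("A", "B", "C")),
#'                 class = "boolean_equation")
#' group_blocks(eq)   # one block: line {A,B} AND line {C}
#' @export
group_blocks <- function(eq) {
  terms <- eq$terms
  blocks <- list()
  factor_group <- function(terms) {
    ## returns list(lines) if `terms` is exactly a cartesian product, else NULL
    if (length(terms) == 1L)
      return(lapply(terms[[1]], identity))           # one line per target
    if (all(lengths(terms) == 1L)) {                 # alternatives -> one OR line
      alts <- sort(unique(unlist(terms)))
      if (length(alts) == length(terms)) return(list(alts)) else return(NULL)
    }
    tab <- sort(table(unlist(terms)), decreasing = TRUE)
    t0 <- as.integer(names(tab)[1])
    if (tab[1] < length(terms)) return(NULL)         # no common factor
    cof <- lapply(terms, setdiff, y = t0)
    if (any(lengths(cof) == 0L)) return(NULL)        # {t0} alone can't factor
    sub <- factor_group(cof)
    if (is.null(sub)) return(NULL)
    lines <- c(sub, list(t0))
    got <- vapply(expand_block(lines), term_key, character(1))
    want <- vapply(terms, term_key, character(1))
    if (setequal(got, want) && length(got) == length(terms)) lines else NULL
  }
  remaining <- terms
  while (length(remaining)) {
    tab <- sort(table(unlist(remaining)), decreasing = TRUE)
    t0 <- as.integer(names(tab)[1])
    grp <- Filter(function(t) t0 %in% t, remaining)
    lines <- if (length(grp) > 1L) {
      cof <- lapply(grp, setdiff, y = t0)
      sub <- if (all(lengths(cof) > 0L)) factor_group(cof) else NULL
      if (!is.null(sub)) {
        cand <- c(sub, list(t0))
        got <- vapply(expand_block(cand), term_key, character(1))
        want <- vapply(grp, term_key, character(1))
        if (setequal(got, want) && length(got) == length(grp)) cand else NULL
      } else NULL
    } else NULL
    if (is.null(lines)) {            # fallback: first term as its own block
      grp <- remaining[1]
      lines <- lapply(grp[[1]], identity)
    }
    blocks <- c(blocks, list(lines))
    keys <- vapply(grp, term_key, character(1))
    remaining <- Filter(function(t) !(term_key(t) %in% keys), remaining)
  }
  circuit <- structure(list(
    blocks = lapply(blocks, function(b)
      lapply(b, function(l) eq$targets[sort(as.integer(l))])),
    targets = eq$targets), class = "tim_circuit")
  ## mandatory semantic equivalence check
  expansion <- unlist(lapply(circuit$blocks, function(b)
    lapply(expand_block(lapply(b, function(l) match(l, eq$targets))),
           term_key)), use.names = FALSE)
  if (!setequal(expansion, vapply(terms, term_key, character(1))))
    stop("internal error: block grouping changed the equation semantics")
  circuit
}

#' @export
print.tim_circuit <- function(x, ...) {
  cat(sprintf("tim_circuit: %d block(s)\n", length(x$blocks)))
  for (i in seq_along(x$blocks)) {
    lines <- vapply(x$blocks[[i]], function(l)
      paste(l, collapse = " | "), character(1))
    cat(sprintf("  block %d: %s\n", i,
                paste(sprintf("[%s]", lines), collapse = " & ")))
  }
  invisible(x)
}

#' Render a TIM circuit as DOT graph text
#'
#' Deterministic Graphviz DOT output: blocks are drawn left-to-right as
#' clusters between a source and a sink, lines within a block in parallel.
#' Inhibiting every line of any one block disconnects source from sink,
#' mirroring the treatment semantics of the circuit.
#'
#' @param circuit a [group_blocks()] result.
#' @param name graph name.
#' @return single character string of DOT text.
#' @export
render_circuit <- function(circuit, name = "tim_circuit") {
  out <- c(sprintf("digraph %s {", name),
           "  rankdir=LR;",
           "  node [shape=box, style=rounded];",
           "  start [shape=circle, label=\"\"];",
           "  end [shape=doublecircle, label=\"\"];")
  prev <- "start"
  for (i in seq_along(circuit$blocks)) {
    block <- circuit$blocks[[i]]
    bin <- sprintf("b%d_in", i); bout <- sprintf("b%d_out", i)
    out <- c(out,
             sprintf("  subgraph cluster_%d {", i),
             sprintf("    label=\"block %d\";", i),
             sprintf("    %s [shape=point]; %s [shape=point];", bin, bout))
    for (j in seq_along(block)) {
      node <- sprintf("b%d_l%d", i, j)
      out <- c(out,
               sprintf("    %s [label=\"%s\"];", node,
                       paste(block[[j]], collapse = " | ")),
               sprintf("    %s -> %s; %s -> %s;", bin, node, node, bout))
    }
    out <- c(out, "  }", sprintf("  %s -> %s;", prev, bin))
    prev <- bout
  }
  out <- c(out, sprintf("  %s -> end;", prev), "}")
  paste(out, collapse = "\n")
}
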