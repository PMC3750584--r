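# TIM bounds, interpolation, monotonicity and continuous profiles.

test_that("bounds degenerate correctly on known and empty maps", {
  tim <- build_tim(2L, 0.6, targets = c("A", "B"), dense = FALSE)
  b <- tim_bounds(2L, tim)       # the known combination is its own bounds
  expect_equal(b$y_l, 0.6)
  expect_equal(b$y_u, 0.6)
  expect_equal(b$d, 0L)
  empty <- build_tim(integer(0), numeric(0), targets = c("A", "B", "C"),
                     dense = FALSE)
  b <- tim_bounds(5L, empty)
  expect_equal(b$y_l, 0)
  expect_equal(b$y_u, 1)
  expect_equal(b$h, 3L)
})

test_that("bounds match a brute-force scan over all anchor combinations", {
  set.seed(401)
  for (rep in 1:30) {
    nT <- 5L
    tim <- rand_tim(nT, sample(1:6, 1))
    pats <- as.integer(names(tim$known))
    vals <- unname(tim$known)
    if (!0L %in% pats) { pats <- c(pats, 0L); vals <- c(vals, 0) }
    if (!31L %in% pats) { pats <- c(pats, 31L); vals <- c(vals, 1) }
    for (p in sample(0:31, 8)) {
      b <- tim_bounds(p, tim)
      subs <- pats[bitwAnd(pats, p) == pats]
      sups <- pats[bitwAnd(pats, p) == p]
      expect_equal(b$y_l, max(vals[match(subs, pats)]))
      expect_equal(b$y_u, min(vals[match(sups, pats)]))
      # bound combinations really bracket the query
      expect_identical(bitwAnd(b$C_l, p), b$C_l)
      expect_identical(bitwAnd(b$C_u, p), p)
      expect_lte(b$d, b$h)
    }
  }
})

test_that("interpolation endpoints and the worked example hold", {
  # d = 0 -> y_l, d = h -> y_u by construction; worked case:
  # y_l = 0.2 at {}, y_u = 0.8 at {1,2,3}, query {1}: 0.2 + 0.6 * (1/3)
  tim <- build_tim(c(0L, 7L), c(0.2, 0.8), targets = c("A", "B", "C"),
                   dense = FALSE)
  expect_equal(infer_sensitivity(0L, tim), 0.2)
  expect_equal(infer_sensitivity(7L, tim), 0.8)
  expect_equal(infer_sensitivity(1L, tim), 0.4)
  expect_equal(infer_sensitivity(3L, tim), 0.6)
})

test_that("the 2-target worked map is reproduced", {
  tim <- build_tim(2L, 0.6, targets = c("A", "B"))
  expect_equal(predict(tim, 0:3), c(0, 0.5, 0.6, 1))
})

test_that("uniform weights reduce the weighted form to the naive form", {
  set.seed(402)
  for (rep in 1:200) {
    nT <- sample(3:7, 1)
    pats <- sample(0:(2^nT - 1), sample(1:5, 1))
    vals <- stats::runif(length(pats))
    w <- stats::runif(1, 0.2, 5)          # equal weights, arbitrary scale
    n_disc <- sample(c(0.5, 1, 2), 1)
    t_u <- build_tim(pats, vals, paste0("T", 1:nT), discount = n_disc,
                     dense = FALSE)
    t_w <- build_tim(pats, vals, paste0("T", 1:nT), discount = n_disc,
                     weights = rep(w, nT), dense = FALSE)
    p <- sample(0:(2^nT - 1), 1)
    expect_equal(infer_sensitivity(p, t_u, warn = FALSE),
                 infer_sensitivity(p, t_w, warn = FALSE))
  }
})

test_that("predictions match an independent set-based reimplementation", {
  set.seed(403)
  for (rep in 1:30) {
    nT <- sample(3:6, 1)
    c_known <- sample(1:5, 1)
    pats <- sample(0:(2^nT - 1), c_known)
    vals <- stats::runif(c_known)
    disc <- sample(c(1, 2), 1)
    tim <- build_tim(pats, vals, paste0("T", 1:nT), discount = disc,
                     dense = FALSE)
    anchors_p <- pats
    anchors_v <- vals
    if (!0L %in% anchors_p) { anchors_p <- c(anchors_p, 0L); anchors_v <- c(anchors_v, 0) }
    full <- 2L^nT - 1L
    if (!full %in% anchors_p) { anchors_p <- c(anchors_p, full); anchors_v <- c(anchors_v, 1) }
    anchor_sets <- lapply(anchors_p, function(p) which(bitwAnd(p, 2^(1:nT - 1)) > 0))
    known_sets <- lapply(pats, function(p) which(bitwAnd(p, 2^(1:nT - 1)) > 0))
    for (q in sample(0:full, 6)) {
      qs <- which(bitwAnd(q, 2^(1:nT - 1)) > 0)
      expect_equal(infer_sensitivity(q, tim, warn = FALSE),
                   oracle_envelope(qs, anchor_sets, anchors_v, nT, disc,
                                   known_sets, vals),
                   tolerance = 1e-10)
    }
  }
})

test_that("the map is monotone and bounded on random TIMs", {
  set.seed(404)
  for (rep in 1:60) {
    nT <- sample(3:6, 1)
    c_known <- sample(0:4, 1)
    pats <- if (c_known) sample(0:(2^nT - 1), c_known) else integer(0)
    vals <- stats::runif(c_known)
    # monotone-consistent experimental data: sort values by pattern size
    sizes <- vapply(pats, function(p)
      sum(bitwAnd(p, 2^(1:nT - 1)) > 0), numeric(1))
    vals <- sort(vals)[rank(sizes, ties.method = "first")]
    tim <- build_tim(pats, vals, paste0("T", 1:nT), dense = TRUE)
    tab <- predict(tim, 0:(2^nT - 1))
    expect_true(all(tab >= 0 & tab <= 1))
    expect_equal(tab[1], if (0L %in% pats) unname(tim$known[["0"]]) else 0)
    expect_equal(tab[2^nT], if ((2L^nT - 1L) %in% pats)
      unname(tim$known[[as.character(2L^nT - 1L)]]) else 1)
    for (p in 0:(2^nT - 2)) {
      sups <- which(bitwAnd(0:(2^nT - 1), p) == p) - 1L
      expect_true(all(tab[sups + 1L] >= tab[p + 1L] - 1e-9))
    }
  }
})

test_that("dense and lazy evaluation agree entry by entry", {
  set.seed(405)
  for (rep in 1:10) {
    nT <- 8L
    pats <- sample(0:(2^nT - 1), 6)
    vals <- stats::runif(6)
    dense <- build_tim(pats, vals, paste0("T", 1:nT), dense = TRUE)
    lazy <- build_tim(pats, vals, paste0("T", 1:nT), dense = FALSE)
    qs <- sample(0:(2^nT - 1), 40)
    expect_equal(predict(dense, qs), predict(lazy, qs))
  }
})

test_that("decreasing the discount increases interior predictions", {
  set.seed(406)
  for (rep in 1:20) {
    nT <- 5L
    pats <- sample(0:(2^nT - 1), 3)
    vals <- sort(stats::runif(3))[rank(vapply(pats, function(p)
      sum(bitwAnd(p, 2^(1:nT - 1)) > 0), numeric(1)), ties.method = "first")]
    t1 <- build_tim(pats, vals, paste0("T", 1:nT), discount = 2, dense = FALSE)
    t2 <- build_tim(pats, vals, paste0("T", 1:nT), discount = 0.5, dense = FALSE)
    for (q in sample(0:(2^nT - 1), 10)) {
      expect_lte(infer_sensitivity(q, t1, warn = FALSE),
                 infer_sensitivity(q, t2, warn = FALSE) + 1e-12)
    }
  }
})

test_that("non-monotone experimental data is clamped with a warning", {
  # subset {A} more sensitive than superset {A,B,C}: querying the interior
  # combination {A,B} sees y_l > y_u and clamps upward
  tim <- build_tim(c(1L, 7L), c(0.9, 0.2), targets = c("A", "B", "C"),
                   dense = FALSE)
  expect_warning(v <- infer_sensitivity(3L, tim), "non-monotone")
  expect_equal(v, 0.9)
  # the known entries themselves keep their experimental values
  expect_equal(infer_sensitivity(1L, tim, warn = FALSE), 0.9)
  expect_equal(infer_sensitivity(7L, tim, warn = FALSE), 0.2)
})

test_that("drug prediction projects onto the target set", {
  tim <- build_tim(2L, 0.6, targets = c("B", "C"))
  # drug hits A and C in the universe; projection onto (B,C) = (0,1) = 2
  expect_equal(predict_drug(c(A = TRUE, B = FALSE, C = TRUE), tim), 0.6)
  # drug hitting no selected target lands on the all-zeros boundary
  expect_equal(predict_drug(c(A = TRUE, B = FALSE, C = FALSE), tim), 0)
})

test_that("continuous inhibition follows the logistic dose model", {
  z <- continuous_inhibition(c(A = 100, B = 1000), x = 100,
                             universe = c("A", "B", "C"))
  expect_equal(unname(z["A"]), 0.5)       # half-inhibition at the EC50
  expect_equal(unname(z["C"]), 0)         # no recorded interaction
  expect_lt(continuous_inhibition(c(A = 100), 1e-6)[["A"]], 1e-6)
  expect_gt(continuous_inhibition(c(A = 100), 1e8)[["A"]], 0.999)
  # monotone increasing in concentration
  xs <- c(1, 10, 100, 1000)
  zz <- vapply(xs, function(x) continuous_inhibition(c(A = 100), x)[["A"]],
               numeric(1))
  expect_true(all(diff(zz) > 0))
  # independent-complement combination
  z1 <- continuous_inhibition(c(A = 100, B = 500), 50, c("A", "B"))
  z2 <- continuous_inhibition(c(A = 800), 50, c("A", "B"))
  comb <- combine_inhibition(z1, z2)
  expect_equal(unname(comb["A"]), 1 - (1 - z1[["A"]]) * (1 - z2[["A"]]))
  expect_equal(unname(comb["B"]), z1[["B"]])
  expect_identical(unname(threshold_inhibition(c(0.49, 0.5, 0.51))),
                   c(FALSE, TRUE, TRUE))
})
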