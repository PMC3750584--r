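# Boolean-network construction, inhibition transforms, attractors and the
# experiment-design counting formulas.

# The 3-target reference pathway: K1 and K2 mutated, either activates K3,
# K3 drives the tumor phenotype.
ref_bn <- function() {
  pathway_to_bn(c("K1", "K2", "K3"),
                rbind(c("K1", "K3"), c("K2", "K3")),
                mutated = c("K1", "K2"), drivers = "K3")
}

test_that("the reference pathway walks its published state sequence", {
  bn <- ref_bn()
  # state 0010 (K3 active, phenotype normal): next step turns the
  # phenotype tumorous, K3 off (no upstream support yet), K1/K2 on
  # encoding: bit j holds target Kj, bit 0 the phenotype
  enc <- function(k1, k2, k3, p) p + 2L * k1 + 4L * k2 + 8L * k3
  s <- enc(0, 0, 1, 0)
  s1 <- bn$successor[s + 1L]
  expect_identical(bn_state_string(s1, 3), "1101")   # wait: order K1K2K3 P
  s2 <- bn$successor[s1 + 1L]
  expect_identical(bn_state_string(s2, 3), "1110")
  s3 <- bn$successor[s2 + 1L]
  expect_identical(bn_state_string(s3, 3), "1111")   # full activation locks in
})

test_that("without mutations the all-zeros state is a fixed point", {
  bn <- pathway_to_bn(c("K1", "K2"), rbind(c("K1", "K2")),
                      mutated = character(0), drivers = "K2")
  expect_identical(bn$successor[1L], 0L)
})

test_that("transitions equal a per-bit evaluation of the three rules", {
  set.seed(801)
  for (rep in 1:15) {
    n <- 4L
    targets <- paste0("K", 1:n)
    # random DAG: edges only from lower to higher index
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.4) edges <- rbind(edges, c(targets[i], targets[j]))
    }
    if (is.null(edges)) edges <- matrix(character(0), 0, 2)
    mutated <- sample(targets, sample(0:2, 1))
    drivers <- sample(targets, 1)
    gates <- stats::setNames(sample(c("OR", "AND"), n, TRUE), targets)
    bn <- pathway_to_bn(targets, edges, mutated, drivers, gates)
    parents <- lapply(targets, function(t)
      if (nrow(edges)) match(edges[edges[, 2] == t, 1], targets) else integer(0))
    is_and <- unname(gates[targets] == "AND")
    mut <- targets %in% mutated
    drv <- match(drivers, targets)
    for (s in 0:(2^(n + 1) - 1)) {
      bits <- bitwAnd(bitwShiftR(s, 1:n), 1L)
      want <- oracle_bn_step(bits, parents, is_and, mut, drv)
      got <- bn$successor[s + 1L]
      got_bits <- c(bitwAnd(bitwShiftR(got, 1:n), 1L), bitwAnd(got, 1L))
      expect_identical(got_bits, want)
    }
  }
})

test_that("cyclic activation graphs are rejected", {
  expect_error(pathway_to_bn(c("A", "B"), rbind(c("A", "B"), c("B", "A")),
                             drivers = "B"), "cyclic")
})

test_that("inhibition transform is identity on the empty set and idempotent", {
  bn <- ref_bn()
  expect_identical(apply_inhibition(bn, character(0))$successor,
                   bn$successor)
  once <- apply_inhibition(bn, "K3")
  twice <- apply_inhibition(once, "K3")
  expect_identical(once$successor, twice$successor)
})

test_that("reference attractors under K3 and K2 inhibition are reproduced", {
  bn <- ref_bn()
  a3 <- bn_attractor(apply_inhibition(bn, "K3"))
  expect_length(a3$cycle, 1L)
  expect_identical(bn_state_string(a3$cycle, 3), "1100")
  expect_false(a3$tumorous)
  a2 <- bn_attractor(apply_inhibition(bn, "K2"))
  expect_identical(bn_state_string(a2$cycle, 3), "1011")
  expect_true(a2$tumorous)
})

test_that("the dynamics-derived map flags exactly the effective inhibitions", {
  tim <- tim_from_bn(ref_bn())
  # patterns over (K1,K2,K3): bit1=K1, bit2=K2, bit3=K3
  eff <- predict(tim, 0:7)
  expect_equal(eff[[1]], 0)                       # no inhibition
  expect_equal(eff[[2]], 0)                       # K1 alone
  expect_equal(eff[[3]], 0)                       # K2 alone
  expect_equal(eff[[4]], 1)                       # K1+K2
  expect_equal(eff[[5]], 1)                       # K3 alone
  expect_true(all(eff[c(6, 7, 8)] == 1))          # supersets of K3
})

test_that("dynamics TIM equals the static Boolean sensitivity on block structures", {
  set.seed(802)
  for (rep in 1:12) {
    p <- generate_pathway(sample(2:6, 1))
    bn <- structure_to_bn(p)
    n <- bn$n
    ids <- sort(unlist(p$blocks))
    tim <- tim_from_bn(bn)
    for (pat in 0:(2^n - 1)) {
      inhibited <- ids[which(bitwAnd(pat, 2^(1:n - 1)) > 0)]
      expect_equal(infer_sensitivity(pat, tim),
                   boolean_sensitivity(inhibited, p))
    }
  }
})

test_that("inhibiting everything clears the tumor when a target drives it", {
  set.seed(803)
  for (rep in 1:10) {
    p <- generate_pathway(sample(2:5, 1))
    bn <- structure_to_bn(p)
    all_inh <- apply_inhibition(bn, bn$targets)
    expect_false(bn_attractor(all_inh)$tumorous)
  }
})

test_that("model counting matches the closed form and small enumerations", {
  p1 <- structure(list(blocks = list(list(1L)), n_active = 1L),
                  class = "pathway_structure")
  expect_equal(count_models(p1), 1)
  p2 <- structure(list(blocks = list(list(c(1L, 2L)), list(c(3L, 4L))),
                       n_active = 4L), class = "pathway_structure")
  expect_equal(count_models(p2), 8)   # 2! * 2! * 2!
  # enumeration oracle: orderings of blocks x per-line target chains
  set.seed(804)
  for (rep in 1:10) {
    p <- generate_pathway(sample(2:6, 1))
    L <- length(p$blocks)
    b <- unlist(lapply(p$blocks, lengths))
    n_enum <- nrow(expand.grid(c(list(seq_len(factorial(L))),
                                 lapply(b, function(x) seq_len(factorial(x))))))
    expect_equal(count_models(p), n_enum)
  }
})

test_that("experiment bounds match worked cases and dominance", {
  # two serial blocks: expected serial-ordering experiments = (2*2-1)/3 = 1
  p2 <- structure(list(blocks = list(list(1L), list(2L)), n_active = 2L),
                  class = "pathway_structure")
  plan <- experiment_bounds(p2)
  expect_equal(plan$ne_expected, 1)
  # a single block costs nothing in serial ordering
  p1 <- structure(list(blocks = list(list(1L, 2L)), n_active = 2L),
                  class = "pathway_structure")
  expect_equal(experiment_bounds(p1)$ne_expected, 0)
  # worst-case bound dominates the expected-case bound
  set.seed(805)
  for (rep in 1:200) {
    p <- generate_pathway(sample(2:10, 1), max_blocks = 4, max_lines = 4)
    plan <- experiment_bounds(p)
    expect_gte(plan$ne_worst_bound, plan$ne_avg_bound - 1e-9)
    expect_gte(plan$ne_worst_bound, 0)
    expect_gte(plan$ne_avg_bound, 0)
    expect_gte(plan$model_count, 1)
  }
})
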