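test_that("shannon entropy matches direct evaluation", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), 1)  # zeros skipped
  expect_error(shannon_entropy(c(0.6, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
  # bounded by log2 of the support size
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(sample(2:10, 1)); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(sum(p > 0)) + 1e-12)
  }
})

test_that("species richness counts entries above the threshold", {
  expect_equal(species_richness(numeric(3)), 0)
  expect_equal(species_richness(c(0.9, 0.1, 0)), 2)
  expect_equal(species_richness(c(0.99, 0.0099, 0.0001), 1e-3), 2)
  expect_error(species_richness(c(-0.1, 1.1)), "nonnegative")
})

test_that("epistasis scores follow their definitions and are symmetric", {
  expect_equal(epistasis_yield(0.3, 0.3, 0.3), 0)
  expect_equal(epistasis_yield(0.13, 0, 0), 0.13)
  expect_equal(epistasis_yield(0.1, 0.4, 0.2), -0.2)

  expect_equal(epistasis_richness(3, 3, 2), 0)
  expect_equal(epistasis_richness(5, 3, 2), 2)
  expect_equal(epistasis_richness(1, 3, 2), -2)

  expect_equal(epistasis_shannon(1, 1, 0.5), 0)
  expect_equal(epistasis_shannon(1, 0, 0), 1)
  expect_equal(epistasis_shannon(0, 2, 1), -2)

  set.seed(2)
  for (i in 1:25) {
    v <- stats::runif(3, 0, 5)
    expect_equal(epistasis_yield(v[1], v[2], v[3]),
                 epistasis_yield(v[1], v[3], v[2]))
    expect_equal(epistasis_richness(v[1], v[2], v[3]),
                 epistasis_richness(v[1], v[3], v[2]))
    expect_equal(epistasis_shannon(v[1], v[2], v[3]),
                 epistasis_shannon(v[1], v[3], v[2]))
    # E_S bounded: observed minus expectation never exceeds observed
    expect_lte(epistasis_richness(v[1], v[2], v[3]), v[1])
  }
  expect_error(epistasis_yield(1, -1, 0), ">= 0")
})

test_that("epistasis over a scheme produces one record per edge", {
  sch <- scheme32()
  meas <- data.frame(env_id = sch$environments$env_id, yield = 0.3)
  recs <- epistasis_over_tree(sch, meas, "yield")
  expect_equal(nrow(recs), 31)  # 16 + 8 + 4 + 2 + 1 composites
  expect_true(all(recs$E == 0))  # identical measurements are exactly additive

  meas$richness <- 4
  expect_true(all(epistasis_over_tree(sch, meas, "richness")$E == 0))

  # exact additivity on a single edge
  s2 <- build_hierarchical_scheme(resource_set(c("a", "b"), 1:2))
  m <- data.frame(env_id = c("1-1", "1-2", "2-1"), yield = c(0.2, 0.4, 0.3))
  expect_equal(epistasis_over_tree(s2, m, "yield")$E, 0)
})

test_that("no-growth environments contribute zero diversity", {
  s2 <- build_hierarchical_scheme(resource_set(c("a", "b"), 1:2))
  m <- data.frame(env_id = c("1-1", "1-2", "2-1"),
                  yield = c(0.02, 0.4, 0.3),
                  richness = c(5, 2, 3), shannon = c(2, 1, 1.2),
                  growth_flag = c(FALSE, TRUE, TRUE))
  # richness of the no-growth constituent treated as 0 -> expected = max(0, 2)
  expect_equal(epistasis_over_tree(s2, m, "richness")$E, 3 - 2)
  expect_equal(epistasis_over_tree(s2, m, "shannon")$E, 1.2 - 1)
  # yield kept as measured by default, zeroed on request
  expect_equal(epistasis_over_tree(s2, m, "yield")$E, 0.3 - (0.02 + 0.4) / 2)
  expect_equal(epistasis_over_tree(s2, m, "yield", no_growth_yield = "zero")$E,
               0.3 - (0 + 0.4) / 2)
})

test_that("missing measurements are explicit gaps or structural errors", {
  s2 <- build_hierarchical_scheme(resource_set(c("a", "b"), 1:2))
  # composite unmeasured -> NA record, not a silent drop
  m <- data.frame(env_id = c("1-1", "1-2"), yield = c(0.2, 0.4))
  recs <- epistasis_over_tree(s2, m, "yield")
  expect_equal(nrow(recs), 1)
  expect_true(is.na(recs$E))
  expect_equal(recs$expected, 0.3)
  # constituent unmeasured -> structural error naming the composite
  m2 <- data.frame(env_id = c("1-1", "2-1"), yield = c(0.2, 0.3))
  expect_error(epistasis_over_tree(s2, m2, "yield"), "2-1")
})

test_that("outcome classification matches the rule definitions", {
  expect_equal(classify_outcome(c("x"), c("x", "y"), c("x", "z"))$label, "I")
  expect_equal(classify_outcome(c("x"), c("y"), c("x", "y"))$label, "II")
  expect_equal(classify_outcome(c("x", "y", "z"), c("x"), c("x"))$label, "III")
  expect_equal(classify_outcome(c("x", "y"), c("x", "z"), c("y"))$label, "IV")
  # all-empty sets: vacuous union
  expect_equal(classify_outcome(character(0), character(0),
                                character(0))$label, "II")
  # richness tie: either survivor set qualifies as Type III
  expect_equal(classify_outcome(c("x", "y"), c("y", "z"), c("y", "z"))$label,
               "III")
})

test_that("classification is exhaustive and mutually exclusive (enumerated)", {
  # independent brute-force oracle over all subset triples of a 3-taxon
  # universe (the 4-taxon exhaustive sweep lives with the acceptance checks)
  universe <- c("a", "b", "c")
  subsets <- lapply(0:7, function(m) universe[bitwAnd(m, c(1, 2, 4)) != 0])
  oracle <- function(A, B, AB) {
    conds <- c(
      I = length(setdiff(AB, union(A, B))) > 0,
      II = setequal(AB, union(A, B)),
      III = (length(A) <= length(B) && setequal(AB, A)) ||
            (length(B) <= length(A) && setequal(AB, B)),
      IV = TRUE)
    names(which(conds))[1]
  }
  for (A in subsets) for (B in subsets) for (AB in subsets) {
    got <- classify_outcome(A, B, AB)$label
    expect_identical(got, oracle(A, B, AB))
  }
})

test_that("type II/III imply the expected sign of richness epistasis", {
  set.seed(3)
  universe <- sprintf("t%d", 1:6)
  for (i in 1:200) {
    A <- sample(universe, sample(0:6, 1))
    B <- sample(universe, sample(0:6, 1))
    AB <- sample(universe, sample(0:6, 1))
    lab <- classify_outcome(A, B, AB)$label
    es <- epistasis_richness(length(AB), length(A), length(B))
    if (lab == "II" && length(intersect(A, B)) == 0)
      expect_equal(es, min(length(A), length(B)))
    if (lab == "III") expect_lte(es, 0)
  }
})

test_that("distribution statistics handle identity, shifts and pairing", {
  # identical distributions: no significance either way
  E <- c(0.1, -0.2, 0.3, 0)
  s <- distribution_stats(E, baseline = E, alternative = "less")
  expect_equal(s$p_baseline, 0.5)
  expect_true(s$paired)

  z <- distribution_stats(rep(0, 5))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)

  # planted shift of -0.5 with sd 0.1, n = 31: overwhelming one-sided evidence
  set.seed(4)
  shifted <- stats::rnorm(31, -0.5, 0.1)
  s2 <- distribution_stats(shifted, alternative = "less")
  expect_lt(s2$p_zero, 1e-3)

  # pairing by composite id uses the common names
  E1 <- stats::setNames(stats::rnorm(10), sprintf("e%d", 1:10))
  E2 <- stats::setNames(E1 + 0.2, sprintf("e%d", 1:10))
  sp <- distribution_stats(E1, baseline = E2, alternative = "less")
  expect_true(sp$paired)
  expect_lt(sp$p_baseline, 1e-6)

  expect_error(distribution_stats(0.3), "at least two")
})
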