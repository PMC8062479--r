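test_that("MAD outlier filter matches direct evaluation of the Z-score", {
  # constant replicates: MAD = 0 guard, nothing removed
  f <- mad_outlier_filter(c(0.3, 0.3, 0.3))
  expect_equal(f$removed_idx, integer(0))
  expect_equal(f$kept, c(0.3, 0.3, 0.3))

  # (1, 2, 9): median 2, MAD 1, M(9) = 0.6745 * 7 = 4.72 > 3.5
  f2 <- mad_outlier_filter(c(1, 2, 9))
  expect_equal(f2$removed_idx, 3L)
  expect_equal(f2$z[3], 0.6745 * 7, tolerance = 1e-12)
  expect_equal(f2$kept, c(1, 2))

  expect_error(mad_outlier_filter(0.5), "at least two")
})

test_that("MAD filter is invariant under affine rescaling", {
  set.seed(5)
  for (i in 1:20) {
    x <- c(stats::rnorm(4), stats::rnorm(1, 8))
    a <- stats::runif(1, 0.5, 3); b <- stats::rnorm(1)
    expect_identical(mad_outlier_filter(x)$removed_idx,
                     mad_outlier_filter(a * x + b)$removed_idx)
  }
})

test_that("growth calls combine blank correction, t-test and OD threshold", {
  mk <- function(corrected, ctrl = c(0.00, 0.01, -0.01), blank = 0.04) {
    plate_table(data.frame(environment_id = "e1", replicate = seq_along(corrected),
                           od_raw = blank + corrected),
                blank_od = blank, negative_controls = blank + ctrl)
  }
  # raw equals blank everywhere: zero yield, no growth
  r0 <- correct_and_call_growth(mk(c(0, 0, 0), ctrl = c(0, 0, 0)))
  expect_equal(r0$yield, 0)
  expect_false(r0$growth_flag)

  # clear growth: corrected ~0.30 vs controls ~0
  r1 <- correct_and_call_growth(mk(c(0.30, 0.31, 0.29)))
  expect_true(r1$growth_flag)
  expect_equal(r1$yield, 0.30)
  expect_lt(r1$p_growth, 0.05)

  # significant but below the 0.05 OD floor: threshold overrides the test
  r2 <- correct_and_call_growth(mk(c(0.040, 0.041, 0.039)))
  expect_lt(r2$p_growth, 0.05)
  expect_false(r2$growth_flag)

  # evaporation control shifts the correction
  pl <- mk(c(0.30, 0.31, 0.29))
  pl$evap_control_od <- c(0.02, 0.02, 0.02)
  r3 <- correct_and_call_growth(pl)
  expect_equal(r3$yield, 0.28)
})

test_that("outliers are removed before the growth call and are logged", {
  pl <- plate_table(data.frame(environment_id = "e1", replicate = 1:4,
                               od_raw = 0.04 + c(0.30, 0.31, 0.29, 0.90)),
                    blank_od = 0.04,
                    negative_controls = c(0.04, 0.05, 0.03))
  r <- correct_and_call_growth(pl)
  expect_equal(r$n_removed, 1L)
  expect_equal(r$n_used, 3L)
  expect_equal(r$yield, 0.30)
})

test_that("plate tables round-trip through the delimited dialect", {
  pl <- plate_table(data.frame(environment_id = rep(c("a", "b"), each = 3),
                               replicate = rep(1:3, 2),
                               od_raw = c(0.31, 0.32, 0.30, 0.11, 0.12, 0.10)),
                    blank_od = 0.041,
                    negative_controls = c(0.042, 0.043),
                    evap_control_od = 0.012)
  for (sep in c("\t", ",")) {
    tf <- tempfile()
    write_plate_table(pl, tf, sep = sep)
    back <- read_plate_table(tf)
    expect_identical(back$data, pl$data)
    expect_identical(back$blank_od, pl$blank_od)
    expect_identical(back$negative_controls, pl$negative_controls)
    expect_identical(back$evap_control_od, pl$evap_control_od)
  }
})

test_that("abundance tables normalize, track unassigned reads and round-trip", {
  m <- matrix(c(60, 30, 10,
                20, 70, 10,
                1,  1,  0), nrow = 3, byrow = FALSE,
              dimnames = list(c("sp1", "sp2", "Unassigned"),
                              c("e1|r1", "e1|r2", "e2|r1")))
  meta <- data.frame(sample_id = colnames(m),
                     environment_id = c("e1", "e1", "e2"),
                     replicate = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  tab <- abundance_table(m, meta)
  expect_equal(unname(colSums(tab$abund)), rep(1, 3))
  expect_equal(unname(tab$unassigned), c(10 / 100, 10 / 100, 0))
  expect_false("Unassigned" %in% rownames(tab$abund))
  expect_equal(tab$abund["sp1", "e1|r1"], 60 / 90)

  tf <- tempfile()
  write_abundance_table(tab, tf)
  back <- read_abundance_table(tf)
  expect_equal(back$abund, tab$abund)
  expect_identical(back$meta, tab$meta)
})

test_that("replicate averaging renormalizes per environment", {
  m <- matrix(c(1, 0, 0, 1, 0.6, 0.4, 0.5, 0.5, 0.7, 0.3), nrow = 2,
              dimnames = list(c("sp1", "sp2"),
                              c("e1|r1", "e1|r2", "e2|r1", "e2|r2", "e2|r3")))
  meta <- data.frame(sample_id = colnames(m),
                     environment_id = c("e1", "e1", "e2", "e2", "e2"),
                     replicate = c(1L, 2L, 1L, 2L, 3L), stringsAsFactors = FALSE)
  avg <- average_replicates(abundance_table(m, meta))
  expect_equal(avg[, "e1"], c(sp1 = 0.5, sp2 = 0.5))
  expect_equal(avg[, "e2"], c(sp1 = 0.6, sp2 = 0.4))
  expect_equal(unname(colSums(avg)), c(1, 1))
})

test_that("survivor sets apply the presence threshold after averaging", {
  comp <- matrix(c(0.999, 0.0005, 0.0005, 0.2, 0.3, 0.5), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("e1", "e2")))
  s <- survivor_sets(comp, threshold = 1e-3)
  expect_equal(s$e1, "a")
  expect_setequal(s$e2, c("a", "b", "c"))
})

test_that("UPGMA clustering matches a hand-rolled agglomeration oracle", {
  # four composition vectors with distinct taxon rank orders
  comp <- matrix(c(0.50, 0.30, 0.15, 0.05,
                   0.30, 0.50, 0.15, 0.05,
                   0.10, 0.20, 0.30, 0.40,
                   0.25, 0.05, 0.50, 0.20), nrow = 4,
                 dimnames = list(c("sp1", "sp2", "sp3", "sp4"),
                                 c("e1", "e2", "e3", "e4")))
  cl <- cluster_environments(comp)

  # oracle: UPGMA on the same Euclidean distances, agglomerated by hand
  rho <- stats::cor(comp, method = "spearman")
  d <- as.matrix(stats::dist(rho))
  clusters <- as.list(colnames(comp))
  heights <- numeric(0)
  cdist <- function(c1, c2) mean(d[c1, c2])
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- cdist(clusters[[i]], clusters[[j]])
      if (h < bh) { bh <- h; best <- c(j, i) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(cl$hclust$height), sort(heights))

  # identical compositions merge first
  comp2 <- cbind(comp, e5 = comp[, "e1"])
  cl2 <- cluster_environments(comp2)
  first <- cl2$hclust$merge[1, ]
  expect_setequal(cl2$hclust$labels[-first], c("e1", "e5"))
  expect_equal(cl2$hclust$height[1], 0)

  # permutation invariance of merge heights
  perm <- comp[, c(3, 1, 4, 2)]
  expect_equal(sort(cluster_environments(perm)$hclust$height),
               sort(cl$hclust$height))

  # constant composition vector is dropped with a warning
  comp3 <- cbind(comp, flat = rep(0.25, 4))
  expect_warning(cl3 <- cluster_environments(comp3), "flat")
  expect_false("flat" %in% cl3$hclust$labels)

  # newick export is readable and preserves the leaves
  tf <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, colnames(comp))
})

test_that("OD/CFU conversion is linear and invertible", {
  expect_equal(cfu_od_convert(0.3, "od_to_cfu"), 2.4e8)
  expect_equal(cfu_od_convert(0, "od_to_cfu"), 0)
  x <- c(0.01, 0.3, 1.2)
  expect_equal(cfu_od_convert(cfu_od_convert(x, "od_to_cfu"), "cfu_to_od"), x,
               tolerance = 1e-12)
  expect_error(cfu_od_convert(-1), ">= 0")
})
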