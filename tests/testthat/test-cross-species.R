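test_that("nearest anchor distance handles the printed pairing examples", {
  anchors <- data.frame(symbol = c("Sluc29", "Sluc22"), chrom = "10",
                        pos_cM = c(4, 61))
  # the proximal chromosome 10 pair sits 2 cM apart
  expect_equal(nearest_anchor_distance("10", 2, anchors), 2)
  expect_equal(nearest_anchor_distance("10", 61, anchors), 0)
  expect_true(is.na(nearest_anchor_distance("11", 2, anchors)))
})

test_that("hit probability is a clipped, merged window measure", {
  tested <- region_set("1", 0, 100)
  one <- data.frame(symbol = "a", chrom = "1", pos_cM = 50)
  expect_equal(hit_probability(one, 5, tested), 0.10)
  # two anchors 4 cM apart: windows merge, no double counting
  two <- data.frame(symbol = c("a", "b"), chrom = "1", pos_cM = c(48, 52))
  expect_equal(hit_probability(two, 5, tested), 0.14)
  # windows covering everything
  expect_equal(hit_probability(one, 60, tested), 1.0)
  # monotone non-decreasing in w
  ws <- seq(0.5, 30, length.out = 15)
  p <- vapply(ws, function(w) hit_probability(two, w, tested), 0)
  expect_true(all(diff(p) >= -1e-12))
  expect_error(hit_probability(one, 5, region_set()), "empty tested")
})

test_that("binomial tail handles degenerate and enumerable cases", {
  tested <- region_set("1", 0, 100)
  anchors <- data.frame(symbol = "a", chrom = "1", pos_cM = 50)
  # p0 = 1: every placement is a hit, tail p is 1
  q <- data.frame(symbol = c("q1", "q2"), chrom = "1", pos_cM = c(10, 90))
  pt <- binomial_proximity_test(q, anchors, tested, w = 60, nperm = 0)
  expect_equal(pt$p0, 1)
  expect_equal(pt$p.value, 1)
  # n = 2, p0 = 0.5, observed 1 hit: P(X >= 1) = 0.75 by enumeration
  pt2 <- binomial_proximity_test(
    data.frame(symbol = c("q1", "q2"), chrom = "1", pos_cM = c(30, 90)),
    anchors, tested, w = 25, nperm = 0)
  expect_equal(pt2$p0, 0.5)
  expect_equal(pt2$n_hit, 1L)
  expect_equal(pt2$p.value, 0.75)
  expect_error(binomial_proximity_test(q[0, ], anchors, tested), "no query")
  # non-informative queries are rejected
  out <- data.frame(symbol = "q", chrom = "2", pos_cM = 10)
  expect_error(binomial_proximity_test(out, anchors, tested),
               "not informative")
})

test_that("binomial and permutation p agree under the uniform null", {
  tested <- region_set(c("1", "2"), c(0, 0), c(120, 80))
  anchors <- data.frame(symbol = paste0("a", 1:6),
                        chrom = c("1", "1", "1", "2", "2", "2"),
                        pos_cM = c(15, 60, 100, 10, 40, 70))
  q <- simulate_locus_placement(tested, n_fixed = 10, seed = 41)
  pt <- binomial_proximity_test(q, anchors, tested, w = 5, nperm = 4000,
                                seed = 42)
  se <- sqrt(pt$p.value * (1 - pt$p.value) / 4000)
  expect_lt(abs(pt$p.value - pt$p.perm), 4 * se + 0.01)
})

test_that("the curated human-locus set reproduces the published proximity result", {
  q <- fig6_loci()
  hq <- q[q$species == "human" & q$trait == "colon" &
            q$informative == "yes", ]
  expect_equal(nrow(hq), 11L)
  pt <- binomial_proximity_test(hq, sluc_anchors(), ocb_tested(), w = 7,
                                nperm = 0)
  expect_equal(pt$n_hit, 9L)
  # the nine linked loci lie on average 3.3 cM from their anchor
  expect_equal(pt$mean_hit_distance, 3.3, tolerance = 1e-8)
  expect_lt(pt$p.value, 0.05)
})

test_that("rat loci show the published 5/7 pairing at 2-8 cM", {
  q <- fig6_loci()
  rq <- q[q$species == "rat" & q$informative == "yes", ]
  expect_equal(nrow(rq), 7L)
  pt <- binomial_proximity_test(rq, sluc_anchors(), ocb_tested(), w = 8,
                                nperm = 0)
  expect_equal(pt$n_hit, 5L)
  d <- pt$distances[is.finite(pt$distances) & pt$distances <= 8]
  expect_true(all(d >= 2 & d <= 8))
})

test_that("single-linkage clusters assemble and flag tight lung/colon pairs", {
  loci <- data.frame(
    symbol = c("Scc14", "Sluc29", "h6q23-25", "far"),
    species = c("mouse", "mouse", "human", "mouse"),
    trait = c("colon", "lung", "colon", "colon"),
    chrom = c("10", "10", "10", "10"),
    pos_cM = c(2, 4, 1.5, 40))
  cl <- assemble_clusters(loci, threshold = 10)
  expect_equal(nrow(cl), 1L)  # the singleton at 40 cM is not emitted
  expect_equal(cl$n_members, 3L)
  expect_true(cl$mixed_trait)
  expect_true(cl$tight_pair)
  expect_equal(cl$species, "human/mouse")

  expect_equal(nrow(assemble_clusters(loci[0, ])), 0L)
  two <- loci[c(1, 4), ]
  expect_equal(nrow(assemble_clusters(two, threshold = 10)), 0L)
})

test_that("cluster assembly on the curated locus set is chain-consistent", {
  loci <- rbind(
    fig6_loci()[fig6_loci()$informative == "yes",
                c("symbol", "species", "trait", "chrom", "pos_cM")],
    sluc_anchors()[, c("symbol", "species", "trait", "chrom", "pos_cM")])
  cl <- assemble_clusters(loci, threshold = 10)
  expect_gt(nrow(cl), 10)
  expect_true(all(cl$span >= 0))
  members <- attr(cl, "members")
  for (m in members) {
    gaps <- diff(sort(m$pos_cM))
    expect_true(all(gaps <= 10))  # single linkage: consecutive gaps bounded
  }
  # every mixed cluster really contains both traits
  for (i in seq_len(nrow(cl))) {
    expect_equal(cl$mixed_trait[i],
                 all(c("colon", "lung") %in% members[[i]]$trait))
  }
})
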