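test_that("single-marker ANOVA equals the textbook F on a balanced toy table", {
  toy <- data.frame(
    id = sprintf("m%02d", 1:9),
    sex = "F",
    mk = rep(c("cc", "cs", "ss"), each = 3),
    tumor_number = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
    stringsAsFactors = FALSE
  )
  res <- single_marker_anova(toy, "mk", trait = "number",
                             covariates = NULL, transform = "identity")
  F_oracle <- oneway_F_oracle(list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7)))
  expect_equal(F_oracle, 13)  # frozen hand computation
  expect_equal(res$F, F_oracle)
  expect_equal(res$df, c(2, 6))
  # balanced one-factor design: LS means equal the raw group means
  expect_equal(res$ls_means$lsmean, c(2, 3, 6))
})

test_that("a constant phenotype gives F = 0, p = 1", {
  toy <- data.frame(sex = rep(c("F", "M"), 6),
                    mk = rep(c("cc", "cs", "ss"), 4),
                    tumor_number = 5)
  res <- single_marker_anova(toy, "mk", trait = "number",
                             transform = "identity")
  expect_equal(res$F, 0)
  expect_equal(res$p.value, 1)
})

test_that("a monomorphic marker is flagged and excluded", {
  toy <- data.frame(sex = rep(c("F", "M"), 6), mk = "cc",
                    tumor_number = rnorm(12, 10))
  expect_warning(res <- single_marker_anova(toy, "mk", "number"),
                 "monomorphic")
  expect_true(res$monomorphic)
  expect_true(is.na(res$F))
})

test_that("null single-marker p-values are approximately uniform", {
  gm <- two_marker_map(10)
  g <- simulate_f2(gm, n = 120, seed = 21)
  p <- vapply(1:400, function(r) {
    d <- simulate_phenotypes(g, seed = 100 + r)
    single_marker_anova(d, "mA", "number")$p.value
  }, 0)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("allele direction uses a strict 30% threshold", {
  expect_equal(allele_direction(c(cc = 10, ss = 13))$label, "none")
  d <- allele_direction(c(cc = 10, ss = 14))
  expect_equal(d$label, "susceptible")
  expect_equal(d$percent, 40)
  expect_equal(allele_direction(c(cc = 10, ss = 6))$label, "resistant")
  expect_warning(d0 <- allele_direction(c(cc = 0, ss = 5)), "zero")
  expect_equal(d0$label, "none")
})

test_that("a susceptible donor allele is called susceptible from the scan", {
  # regime of the mapped cross: s alleles raise tumor load
  gm <- two_marker_map(40)
  d <- simulate_cross(gm, n = 400, seed = 22,
                      qtls = list(qtl_spec("mA", additive = 0.5,
                                           trait = "load")))
  sc <- qtl_scan(d, "load", interactions = FALSE, sex_interactions = FALSE)
  expect_true("mA" %in% sc$direction$term)
  expect_equal(sc$direction$label[sc$direction$term == "mA"], "susceptible")
})

test_that("genome-wide correction obeys its limits and monotonicity", {
  expect_equal(genomewide_correct(0, C = 21, G_morgans = 3.29), 0)
  p <- c(1e-6, 1e-4, 1e-2, 0.5)
  expect_equal(genomewide_correct(p, C = 1, G_morgans = 0), p)
  gw <- genomewide_correct(p, C = 21, G_morgans = 3.29, rho = 1.5)
  expect_true(all(diff(gw) >= 0))  # non-decreasing (clamped at 1)
  expect_true(all(diff(gw[gw < 1]) > 0))
  expect_true(all(gw >= p))
  expect_true(all(gw <= 1))
})

test_that("genome-wide correction matches a permutation oracle on a sparse scan", {
  # five unlinked markers: the correction reduces to Bonferroni over C = 5,
  # which permutation of the phenotype must reproduce
  gm <- genome_map(data.frame(marker = paste0("m", 1:5),
                              chrom = as.character(1:5), pos_cM = 20))
  d <- simulate_cross(gm, n = 226, seed = 23)
  null_max <- qtl_permutation_null(d, "number", nperm = 1000, seed = 24)
  # observed statistic near the genome-wide 5% point of the null
  F_obs <- quantile(null_max, 0.95)
  p_nom <- pf(F_obs, 2, 223, lower.tail = FALSE)
  gw_formula <- genomewide_correct(p_nom, C = 5, G_morgans = 0, df = 2)
  gw_perm <- mean(null_max >= F_obs)
  se <- sqrt(gw_perm * (1 - gw_perm) / 1000)
  expect_lt(abs(gw_formula - gw_perm), 4 * se + 0.01)
})

test_that("the full scan recovers a planted additive QTL", {
  gm <- synthetic_map()
  seg <- synthetic_regions()
  d <- simulate_cross(gm, seg, n = 226, seed = 25,
                      qtls = list(qtl_spec("D5Mit68", additive = 0.4)))
  sc <- qtl_scan(d, "number")
  tt <- sc$terms
  expect_true("D5Mit68" %in% tt$term[tt$kind == "marker"])
  p_qtl <- tt$p_genomewide[tt$term == "D5Mit68"]
  expect_lt(p_qtl, 0.05)
  # no other main effect beats the planted marker
  others <- tt$p_genomewide[tt$kind == "marker" & tt$term != "D5Mit68"]
  expect_true(all(others > p_qtl))
})

test_that("a pure epistatic pair is retained as an interaction term", {
  gm <- synthetic_map()
  seg <- synthetic_regions()
  d <- simulate_cross(gm, seg, n = 226, seed = 27,
                      interactions = list(
                        interaction_spec("D8Mit17", "D18Mit17",
                                         effect = 0.6)))
  sc <- qtl_scan(d, "number", ls_means = "none", profile = FALSE)
  expect_true(any(sc$terms$term %in%
                    c("D8Mit17:D18Mit17", "D18Mit17:D8Mit17")))
})

test_that("elimination respects alpha, marginality, and is idempotent", {
  gm <- synthetic_map()
  d <- simulate_cross(gm, n = 226, seed = 27)
  sc <- qtl_scan(d, "number", ls_means = "none", profile = FALSE)
  tt <- sc$terms
  ints <- tt$term[tt$kind %in% c("marker:marker", "marker:sex")]
  protected <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
  free <- tt$term[!(tt$term %in% protected) & tt$kind != "sex"]
  # every droppable retained term is significant at alpha
  expect_true(all(tt$p_nominal[tt$term %in% c(free, ints)] <= 0.05))
  # genome-wide p never below nominal
  expect_true(all(tt$p_genomewide >= tt$p_nominal - 1e-12, na.rm = TRUE))
  # dropped terms were all above alpha when dropped
  expect_true(all(sc$dropped$p > 0.05))
})

test_that("scan results are deterministic given the data", {
  gm <- two_marker_map(40)
  d <- simulate_cross(gm, n = 120, seed = 28)
  s1 <- qtl_scan(d, "number", ls_means = "none", profile = FALSE)
  s2 <- qtl_scan(d, "number", ls_means = "none", profile = FALSE)
  expect_identical(s1$terms, s2$terms)
})

test_that("detection frequency rises with effect size", {
  gm <- synthetic_map()
  seg <- synthetic_regions()
  det <- vapply(c(0, 0.2, 0.4), function(eff) {
    hits <- vapply(1:12, function(r) {
      d <- simulate_cross(gm, seg, n = 226, seed = 500 + r,
                          qtls = if (eff > 0)
                            list(qtl_spec("D9Mit254", additive = eff))
                          else list())
      sc <- qtl_scan(d, "number", ls_means = "none", profile = FALSE,
                     interactions = FALSE, sex_interactions = FALSE)
      tt <- sc$terms
      "D9Mit254" %in% tt$term &&
        isTRUE(tt$p_genomewide[tt$term == "D9Mit254"] < 0.05)
    }, logical(1))
    mean(hits)
  }, 0)
  expect_true(det[1] <= det[2] && det[2] <= det[3])
  expect_lt(det[1], 0.3)
  expect_gt(det[3], 0.5)
})
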