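test_that("region_set validates and orders intervals", {
  rs <- region_set(c("2", "1"), c(5, 32.8), c(41.4, 41))
  expect_s3_class(rs, "region_set")
  expect_equal(rs$chrom, c("1", "2"))
  expect_equal(region_total_length(rs), (41 - 32.8) + (41.4 - 5))

  expect_error(region_set("1", 10, 5), "start > end")
  expect_error(region_set("1", -1, 5), "negative")
  expect_error(region_set(c("1", "1"), c(0, 5), c(10, 15)), "overlap")
  # merge = TRUE unions instead
  m <- region_set(c("1", "1"), c(0, 5), c(10, 15), merge = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end, 15)
})

test_that("region_intersect matches the printed per-chromosome examples", {
  expect_equal(
    as.data.frame(region_intersect(region_set("1", 81.6, 127),
                                   region_set("1", 81.6, 127))),
    data.frame(chrom = "1", start = 81.6, end = 127))
  expect_equal(
    as.data.frame(region_intersect(region_set("1", 32.8, 41),
                                   region_set("1", 0, 59))),
    data.frame(chrom = "1", start = 32.8, end = 41))
  expect_equal(nrow(region_intersect(region_set("1", 0, 10),
                                     region_set("1", 20, 30))), 0L)
})

test_that("region_intersect is commutative, idempotent and bounded", {
  set.seed(11)
  for (i in 1:20) {
    mk <- function() {
      ch <- sample(c("1", "2", "3"), 4, replace = TRUE)
      st <- runif(4, 0, 80)
      region_set(ch, st, st + runif(4, 0, 30), merge = TRUE)
    }
    a <- mk(); b <- mk()
    ab <- region_intersect(a, b)
    ba <- region_intersect(b, a)
    expect_equal(as.data.frame(ab), as.data.frame(ba))
    expect_equal(as.data.frame(region_intersect(a, a)), as.data.frame(a))
    expect_lte(region_total_length(ab),
               min(region_total_length(a), region_total_length(b)) + 1e-9)
  }
})

test_that("locate_locus is boundary-inclusive", {
  ov <- region_set("4", 56.6, 62.3)
  expect_equal(locate_locus("4", 62.3, ov)$start, 56.6)  # exact endpoint
  expect_null(locate_locus("4", 67, ov))
  expect_null(locate_locus("4", 60, region_set()))
})

test_that("the packaged region table parses to the published locus counts", {
  rt <- table1()
  expect_equal(sum(rt$loci$trait == "colon"), 9L)
  expect_equal(sum(rt$loci$trait == "lung"), 15L)
  # Sluc5 position is the 100 cM calling position
  expect_equal(rt$loci$pos_cM[rt$loci$symbol == "Sluc5"], 100)
})

test_that("overlap regions reproduce the published 23-region set", {
  rt <- table1()
  ov <- overlap_regions(rt)
  expect_equal(nrow(ov), 23L)
  # printed total is 430 (rounded); the exact sum of the printed columns
  expect_equal(region_total_length(ov), 433.7, tolerance = 1e-8)
  # every colon locus and all lung loci except Sluc6 fall inside an overlap
  in_overlap <- function(l) {
    vapply(seq_len(nrow(l)), function(i) {
      !is.null(locate_locus(l$chrom[i], l$pos_cM[i], ov))
    }, logical(1))
  }
  colon <- loci_by_trait(rt, "colon")
  lung <- loci_by_trait(rt, "lung")
  expect_true(all(in_overlap(colon)))
  expect_equal(sum(in_overlap(lung)), 14L)
  expect_equal(lung$symbol[!in_overlap(lung)], "Sluc6")
})

test_that("global intersection differs from the paired overlap only by boundary slivers", {
  rt <- table1()
  glob <- region_intersect(rt$regions$colon, rt$regions$lung)
  paired <- overlap_regions(rt)
  expect_equal(nrow(glob), 25L)
  extra <- setdiff(
    sprintf("%s:%g-%g", glob$chrom, glob$start, glob$end),
    sprintf("%s:%g-%g", paired$chrom, paired$start, paired$end))
  expect_setequal(extra, c("2:45-47.5", "6:62.5-63.6"))
})

test_that("region tables round-trip field-for-field and reject bad rows", {
  rt <- table1()
  tmp <- tempfile(fileext = ".csv")
  write_region_table(rt, tmp)
  rt2 <- read_region_table(tmp)
  expect_equal(rt2$table, rt$table)
  expect_equal(rt2$loci, rt$loci)

  bad <- rt$table[1:2, ]
  bad$trait[2] <- "liver"
  f <- tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_region_table(f), "row 2.*liver")
  bad2 <- rt$table[1:2, ]
  bad2$region_start_cM[1] <- "50"
  bad2$region_end_cM[1] <- "40"
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_region_table(f), "row 1")
})

test_that("an empty region table yields empty region sets and no loci", {
  f <- tempfile(fileext = ".csv")
  writeLines(paste("chrom,trait,region_start_cM,region_end_cM,locus_symbol,",
                   "locus_cM,species,source", sep = ""), f)
  rt <- read_region_table(f)
  expect_equal(nrow(rt$regions$colon), 0L)
  expect_equal(nrow(rt$regions$lung), 0L)
  expect_equal(nrow(rt$loci), 0L)
})

test_that("genome_map validates marker and chromosome constraints", {
  expect_error(genome_map(data.frame(marker = c("a", "a"), chrom = "1",
                                     pos_cM = c(1, 2))), "duplicated")
  expect_error(
    genome_map(data.frame(marker = "a", chrom = "1", pos_cM = 200),
               chromosomes = data.frame(chrom = "1", length_cM = 100)),
    "beyond")
  gm <- synthetic_map()
  expect_equal(nrow(gm$markers), 23L)
  expect_true(all(gm$markers$pos_cM <=
    gm$chromosomes$length_cM[match(gm$markers$chrom, gm$chromosomes$chrom)]))
})
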