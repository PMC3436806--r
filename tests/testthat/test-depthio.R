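test_that("BED regions parse in file order with defaulted ids", {
  bed <- c("chr1\t100\t200\tR1", "chr1\t300\t400", "chr2\t0\t50\tR3\t0.42")
  regions <- load_regions(bed, gc_col = 5L)
  expect_equal(nrow(regions), 3L)
  expect_equal(regions$region_id, c("R1", "chr1:300-400", "R3"))
  expect_equal(regions$start, c(100L, 300L, 0L))
  expect_equal(regions$gc_fraction, c(NA, NA, 0.42))
})

test_that("malformed BED lines are rejected with their line number", {
  expect_error(load_regions("chr1\t200\t100"), "line 1.*start >= end")
  expect_error(load_regions(c("chr1\t1\t2", "chr1\tx\t300")),
               "line 2.*non-integer")
  expect_error(load_regions("chr1\t100"), "fewer than 3")
  expect_error(load_regions(c("chr1\t1\t2\tA", "chr1\t5\t9\tA")), "duplicate")
})

test_that("per-base depth from alignments piles reads up correctly", {
  region <- region_row("chr1", 100L, 150L)
  # one 90-bp read fully covering the 50-bp region
  sam1 <- write_test_sam(data.frame(qname = "r1", rname = "chr1",
                                    pos = 61L, len = 90L))
  expect_equal(per_base_depth(sam1, region), rep(1L, 50L))
  # no reads overlapping the region
  sam2 <- write_test_sam(data.frame(qname = "r1", rname = "chr1",
                                    pos = 500L, len = 90L))
  expect_equal(per_base_depth(sam2, region), rep(0L, 50L))
  # two reads covering only the first 10 bases
  sam3 <- write_test_sam(data.frame(qname = c("r1", "r2"),
                                    rname = "chr1", pos = c(91L, 81L),
                                    len = c(20L, 30L)))
  expect_equal(per_base_depth(sam3, region), c(rep(2L, 10L), rep(0L, 40L)))
  expect_error(per_base_depth(sam1, region_row("chrX", 0L, 10L)),
               "chrX")
})

test_that("depth tables address regions and absent positions are zero", {
  tab <- make_depth_table("chr1", c(10L, 11L, 14L),
                          matrix(c(3L, 4L, 5L, 6L, 7L, 8L), 3, 2,
                                 dimnames = list(NULL, c("s1", "s2"))))
  d <- depth_from_table(tab, region_row("chr1", 10L, 15L))
  expect_equal(dim(d), c(5L, 2L))
  expect_equal(d[, "s1"], c(3L, 4L, 0L, 0L, 5L))
  expect_error(depth_from_table(tab, region_row("chr9", 0L, 5L)), "chr9")
})

test_that("sample mean depth is total depth over the capture footprint", {
  regions <- rbind(region_row("chr1", 0L, 4L, "A"),
                   region_row("chr1", 10L, 14L, "B"))
  tab <- make_depth_table("chr1", c(0:3, 10:13),
                          matrix(c(rep(10L, 4), rep(20L, 4),
                                   rep(15L, 8)), 8, 2,
                                 dimnames = list(NULL, c("s1", "s2"))))
  md <- sample_mean_depth(tab, regions)
  expect_equal(unname(md["s1"]), 15)
  expect_equal(unname(md["s2"]), 15)
  tab$s1 <- 0L
  expect_error(sample_mean_depth(tab, regions), "zero total depth: s1")
})

test_that("normalization divides by sample mean and ignores raw scale", {
  region <- region_row("chr1", 0L, 3L)
  depth <- matrix(c(30L, 0L, 15L), 3, 1, dimnames = list(NULL, "s1"))
  nm <- build_normalized_matrix(region, depth, c(s1 = 15))
  expect_equal(nm$values[, 1], c(2, 0, 1))
  # scaling a sample's raw depths by c > 0 leaves its column unchanged
  for (c_scale in c(2, 7)) {
    nm2 <- build_normalized_matrix(region, depth * c_scale,
                                   c(s1 = 15 * c_scale))
    expect_equal(nm2$values, nm$values)
  }
  expect_error(build_normalized_matrix(region_row("chr1", 5L, 5L),
                                       depth[0, , drop = FALSE], c(s1 = 1)),
               "length 0")
})

test_that("region GC counts unambiguous bases only", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test chromosome", "ACGTGGCCANNT"), fa)
  expect_equal(region_gc(region_row("chr1", 0L, 4L), fa), 0.5)
  expect_equal(region_gc(region_row("chr1", 4L, 8L), fa), 1.0)
  expect_equal(region_gc(region_row("chr1", 8L, 12L), fa), 0.0)
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "NNNN"), fa2)
  expect_true(is.na(region_gc(region_row("chr1", 0L, 4L), fa2)))
  expect_error(region_gc(region_row("chr2", 0L, 2L), fa), "chr2")
})

test_that("normalized matrices round-trip through TSV exactly", {
  region <- region_row("chr1", 0L, 5L)
  depth <- matrix(rpois(15, 20), 5, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  nm <- build_normalized_matrix(region, depth, c(a = 3, b = 7, c = 13))
  path <- tempfile(fileext = ".tsv")
  write_normalized_matrix(nm, path)
  back <- read_normalized_matrix(path)
  expect_identical(back$sample_order, nm$sample_order)
  expect_identical(unname(back$values), unname(nm$values))
})
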