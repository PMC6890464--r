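test_that("BED round-trip preserves half-open coordinates, ids and order", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200\tpk2", "chr1\t10\t20\tpk1", "chr1\t5\t15\tpk0"),
             path)
  s <- read_bed(path)
  expect_s3_class(s, "interval_set")
  expect_equal(s$chrom, c("chr1", "chr1", "chr2"))   # re-sorted
  expect_equal(s$start, c(5, 10, 100))
  expect_equal(s$id, c("pk0", "pk1", "pk2"))

  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, out)
  expect_equal(read_bed(out), s, ignore_attr = TRUE)
})

test_that("BED reading generates ids, accepts empty files, rejects bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", path)
  expect_equal(read_bed(path)$id, "chr1:10-20")

  writeLines(character(0), path)
  expect_equal(nrow(read_bed(path)), 0L)

  writeLines(c("chr1\t10\t20", "chr1\t30"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t20\t10", path)
  expect_error(read_bed(path), "end <= start")
})

test_that("interval_set enforces its invariants", {
  expect_error(interval_set("chr1", 10, 10), "end > start")
  expect_error(interval_set("chr1", -1, 10), ">= 0")
  expect_error(interval_set(c("chr1", "chr1"), c(1, 5), c(4, 9),
                            id = c("a", "a")), "unique")
  expect_error(interval_set("chr1", 10, 2e7, genome = c(chr1 = 1e7)),
               "exceed")
})

test_that("merge handles overlap, book-ended intervals, and gaps", {
  s <- interval_set(c("chr1", "chr1"), c(10, 15), c(20, 30))
  m <- merge_intervals(s)
  expect_equal(m$start, 10)
  expect_equal(m$end, 30)

  s <- interval_set(c("chr1", "chr1"), c(10, 20), c(20, 25))
  expect_equal(nrow(merge_intervals(s)), 1L)  # book-ended at gap 0

  s <- interval_set(c("chr1", "chr1"), c(10, 25), c(20, 30))
  expect_equal(nrow(merge_intervals(s)), 2L)
  expect_equal(nrow(merge_intervals(s, gap = 5)), 1L)
})

test_that("merge equals the covered-base oracle and is idempotent", {
  set.seed(101)
  for (rep in 1:3) {
    s <- random_intervals(1000)
    m <- merge_intervals(s)
    expect_equal(iv_df(m), oracle_merge(s))
    expect_equal(iv_df(merge_intervals(m)), iv_df(m))
    g <- sample(1:50, 1)
    expect_equal(iv_df(merge_intervals(s, gap = g)), oracle_merge(s, gap = g))
  }
})

test_that("length filter keeps exactly max_len and drops longer", {
  s <- interval_set(c("chr1", "chr1", "chr1"), c(0, 10000, 30000),
                    c(5000, 15001, 30100))
  f <- filter_by_length(s, 5000)
  expect_equal(f$end - f$start, c(5000, 100))
  expect_equal(nrow(filter_by_length(interval_set(), 5000)), 0L)
})

test_that("exclusion removal is half-open and matches the all-pairs oracle", {
  tgt <- interval_set("chr1", 10, 20)
  expect_equal(nrow(remove_overlapping(tgt, interval_set("chr1", 19, 25))), 0L)
  expect_equal(nrow(remove_overlapping(tgt, interval_set("chr1", 20, 30))), 1L)

  set.seed(7)
  a <- random_intervals(800)
  b <- random_intervals(300)
  kept <- remove_overlapping(a, b)
  expect_equal(sort(kept$id), sort(a$id[!oracle_overlaps_any(a, b)]))

  # removing nothing / removing against itself
  expect_equal(nrow(remove_overlapping(a, interval_set())), nrow(a))
  expect_equal(nrow(remove_overlapping(a, a)), 0L)
})

test_that("expansion pads, clips at zero and at chromosome ends", {
  s <- interval_set(c("chr1", "chr1"), c(1000, 100), c(1500, 200),
                    genome = c(chr1 = 2000))
  e <- expand_intervals(s, 500)
  expect_equal(e$start, c(0, 500))
  expect_equal(e$end, c(700, 2000))
  expect_true(all(expand_intervals(random_intervals(200), 1000)$start >= 0))
  expect_equal(expand_intervals(s, 0), s)
})

test_that("nearest TSS distances match the all-pairs oracle with its tie rule", {
  regions <- interval_set("chr1", c(100, 5000), c(200, 5100),
                          id = c("r1", "r2"))
  tss <- interval_set("chr1", c(150, 1300), c(151, 1301), id = c("gA", "gB"))
  nt <- nearest_tss(regions, tss)
  expect_equal(nt$distance[nt$region_id == "r1"], 0)
  expect_equal(nt$gene_id[nt$region_id == "r1"], "gA")
  expect_equal(nt$distance[nt$region_id == "r2"], 5000 - 1300 - 1)

  # equidistant: smaller coordinate wins
  regions <- interval_set("chr1", 1000, 1100, id = "r")
  tss <- interval_set("chr1", c(900, 1199), c(901, 1200), id = c("L", "R"))
  # L gap: 1000-900-1 = 99 ; R gap: 1199-1100 = 99
  nt <- nearest_tss(regions, tss)
  expect_equal(nt$gene_id, "L")

  set.seed(13)
  regions <- random_intervals(500)
  pos <- sample.int(1e5, 300) - 1
  tss <- interval_set(sample(c("chrA", "chrB"), 300, TRUE), pos, pos + 1,
                      id = sprintf("g%03d", 1:300))
  nt <- nearest_tss(regions, tss)
  o <- oracle_nearest(regions[match(nt$region_id, regions$id), ], tss)
  expect_equal(nt$distance, o[, 1])

  # chromosome missing from the annotation
  regions <- interval_set(c("chrA", "chrZ"), c(0, 0), c(10, 10),
                          id = c("a", "z"))
  tss <- interval_set("chrA", 5, 6, id = "g")
  expect_warning(nt <- nearest_tss(regions, tss), "absent")
  expect_true(is.na(nt$distance[nt$region_id == "z"]))
})

test_that("proximity classification splits at the threshold", {
  d <- data.frame(region_id = c("a", "b", "c", "d"),
                  distance = c(1000, 1001, 0, NA))
  cls <- classify_proximity(d)
  expect_equal(cls$class, c("proximal", "distal", "proximal", "unassigned"))
})

test_that("overlap fraction matches the pairwise oracle and its bounds", {
  a <- interval_set("chr1", c(0, 100), c(50, 150), id = c("x", "y"))
  expect_equal(overlap_fraction(a, a), 1.0)
  expect_equal(overlap_fraction(a, interval_set("chr2", 0, 50)), 0.0)
  expect_error(overlap_fraction(interval_set(), a), "empty")

  set.seed(23)
  a <- random_intervals(600)
  b <- random_intervals(200)
  expect_equal(overlap_fraction(a, b), mean(oracle_overlaps_any(a, b)))
})
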