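test_that("chromosome-sizes parsing preserves order and rejects bad input", {
  f <- withr::local_tempfile()
  writeLines(c("chrA\t10000", "chrB\t5000"), f)
  gm <- read_chrom_sizes(f)
  expect_equal(gm$chrom, c("chrA", "chrB"))
  expect_equal(gm$length, c(10000, 5000))

  writeLines(c("chrA\t10000", "chrA\t9000"), f)
  expect_error(read_chrom_sizes(f), "duplicate")
  writeLines("chrA\t0", f)
  expect_error(read_chrom_sizes(f), "positive")
  writeLines("chrA\t12.5", f)
  expect_error(read_chrom_sizes(f), "integer")
  writeLines(character(0), f)
  expect_error(read_chrom_sizes(f), "empty")
})

test_that("bedGraph reading expands multi-bin lines and zero-fills", {
  gm <- genome_model("chrA", 600)
  f <- withr::local_tempfile()
  writeLines("chrA\t0\t400\t3.0", f)
  tr <- read_bedgraph(f, gm, 200)
  expect_equal(tr$values$chrA, c(3, 3, 0))

  writeLines("chrA\t100\t300\t1.0", f)
  expect_error(read_bedgraph(f, gm, 200), "grid")
  writeLines("chrA\t0\t800\t1.0", f)
  expect_error(read_bedgraph(f, gm, 200), "bounds")
  writeLines("chrX\t0\t200\t1.0", f)
  expect_error(read_bedgraph(f, gm, 200), "unknown")

  file.create(f)
  writeLines(character(0), f)
  expect_equal(read_bedgraph(f, gm, 200)$values$chrA, c(0, 0, 0))
})

test_that("bedGraph covering a partial final bin is accepted", {
  gm <- genome_model("chrA", 500)   # bins: [0,200) [200,400) [400,500)
  f <- withr::local_tempfile()
  writeLines(c("chrA\t0\t200\t1", "chrA\t400\t500\t7"), f)
  tr <- read_bedgraph(f, gm, 200)
  expect_equal(tr$values$chrA, c(1, 0, 7))
})

test_that("bedGraph writing run-length merges and round-trips", {
  gm <- genome_model("chrA", 600)
  tr <- binned_track(gm, 200, list(chrA = c(3, 3, 0)))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f, merge_equal = TRUE)
  expect_equal(readLines(f), c("chrA\t0\t400\t3", "chrA\t400\t600\t0"))
  write_bedgraph(binned_track(genome_model("chrA", 400), 200,
                              list(chrA = c(1, 2))), f, merge_equal = FALSE)
  expect_equal(readLines(f), c("chrA\t0\t200\t1", "chrA\t200\t400\t2"))

  set.seed(42)
  gm2 <- genome_model(c("chrA", "chrB"), c(4100, 2000))
  for (merge in c(TRUE, FALSE)) {
    t0 <- rand_track(gm2, 200, function(n) round(rnorm(n), 3))
    write_bedgraph(t0, f, merge_equal = merge)
    t1 <- read_bedgraph(f, gm2, 200)
    expect_equal(t1$values, t0$values)
  }
})

test_that("BED reading/writing is 0-based half-open and round-trip stable", {
  gm <- genome_model(c("chrA", "chrB"), c(10000, 5000))
  f <- withr::local_tempfile()
  writeLines("chrA\t0\t200\tp1", f)
  gr <- read_bed(f, gm)
  expect_equal(GenomicRanges::start(gr), 1)
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(S4Vectors::mcols(gr)$name, "p1")

  writeLines("chrA\t200\t200", f)
  expect_error(read_bed(f, gm), "interval")
  writeLines("chrZ\t0\t100", f)
  expect_error(read_bed(f, gm), "unknown")

  set.seed(7)
  r <- rand_regions(gm, 25)
  S4Vectors::mcols(r)$name <- paste0("r", seq_along(r))
  S4Vectors::mcols(r)$score <- round(runif(25), 4)
  GenomicRanges::strand(r) <- sample(c("+", "-", "*"), 25, replace = TRUE)
  write_bed(r, f)
  r2 <- read_bed(f, gm)
  expect_equal(bed0(r2), bed0(r))
  expect_equal(S4Vectors::mcols(r2)$name, S4Vectors::mcols(r)$name)
  expect_equal(S4Vectors::mcols(r2)$score, S4Vectors::mcols(r)$score)
  expect_equal(as.character(GenomicRanges::strand(r2)),
               as.character(GenomicRanges::strand(r)))
})

test_that("repeat BED dialects populate class and subfamily", {
  gm <- genome_model("chrA", 10000)
  f <- withr::local_tempfile()
  writeLines(c("chrA\t0\t300\tAluY\t.\t+\tSINE/Alu",
               "chrA\t400\t700\tSAR\t.\t-\tSatellite",
               "chrA\t800\t900\tX\t.\t+\tDNA?/hAT?"), f)
  rep1 <- read_repeat_bed(f, gm, dialect = "slash")
  expect_equal(S4Vectors::mcols(rep1)$repeat_class,
               c("SINE", "Satellite", "DNA?"))
  expect_equal(S4Vectors::mcols(rep1)$repeat_subfamily,
               c("Alu", "Satellite", "hAT?"))

  writeLines("chrA\t0\t300\tAluY\t.\t+\tSINE\tAlu", f)
  rep2 <- read_repeat_bed(f, gm, dialect = "columns")
  expect_equal(S4Vectors::mcols(rep2)$repeat_name, "AluY")
  expect_equal(S4Vectors::mcols(rep2)$repeat_class, "SINE")
  expect_equal(S4Vectors::mcols(rep2)$repeat_subfamily, "Alu")

  writeLines("chrA\t0\t300\tAluY\t.\t+", f)
  expect_error(read_repeat_bed(f, gm, dialect = "slash"), "class")

  # round trip through the columns dialect
  write_repeat_bed(rep1, f)
  rep3 <- read_repeat_bed(f, gm, dialect = "columns")
  expect_equal(bed0(rep3), bed0(rep1))
  expect_equal(S4Vectors::mcols(rep3)$repeat_subfamily,
               S4Vectors::mcols(rep1)$repeat_subfamily)
})

test_that("promoters are strand-aware, clipped, deduplicated and sorted", {
  gm <- genome_model(c("chrA", "chrB"), c(9000, 5000))
  plus <- gr0("chrA", 5000, 8000, "+")
  minus <- gr0("chrA", 5000, 8000, "-")
  expect_equal(bed0(extract_promoters(plus, gm)),
               data.frame(chrom = "chrA", start = 4000, end = 6000))
  expect_equal(bed0(extract_promoters(minus, gm)),
               data.frame(chrom = "chrA", start = 7000, end = 9000))

  # duplicates removed; two '+' genes sharing a TSS give one promoter
  two <- c(gr0("chrA", 5000, 8000, "+"), gr0("chrA", 5000, 6000, "+"))
  expect_length(extract_promoters(two, gm), 1)

  # clipping at chromosome start and end
  edge <- c(gr0("chrA", 300, 2000, "+"), gr0("chrA", 8500, 8800, "-"))
  prom <- extract_promoters(edge, gm)
  expect_equal(bed0(prom),
               data.frame(chrom = "chrA", start = c(0, 7800),
                          end = c(1300, 9000)))

  expect_error(extract_promoters(gr0("chrA", 10, 20, "*"), gm), "unstranded")

  # duplicate-free and sorted on random input
  set.seed(11)
  g <- rand_regions(gm, 40, 500, 2000)
  GenomicRanges::strand(g) <- sample(c("+", "-"), 40, replace = TRUE)
  p <- extract_promoters(g, gm)
  key <- paste(bed0(p)$chrom, bed0(p)$start, bed0(p)$end)
  expect_false(any(duplicated(key)))
  expect_false(S4Vectors::is.unsorted(p))
  full <- GenomicRanges::width(p) == 2000
  tss_inside <- TRUE  # clipped promoters only at ends
  expect_true(all(full | bed0(p)$start == 0 |
                    bed0(p)$end == chrom_length(gm, bed0(p)$chrom)))
})
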