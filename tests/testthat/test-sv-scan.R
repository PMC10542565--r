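sam_header <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:V\tLN:20900000")
sam_line <- function(pos, cigar, flag = 0, tags = NULL) {
  paste(c(sprintf("r1\t%d\tV\t%d\t60\t%s\t*\t0\t0\t*\t*", flag, pos, cigar),
          tags), collapse = "\t")
}

test_that("CIGAR clip arithmetic matches hand-computed cases", {
  f <- parse_alignments(c(sam_header, sam_line(100, "100M")), min_clip = 20)
  expect_identical(c(f$left_clip, f$right_clip), c(0L, 0L))
  expect_false(f$is_clipped)
  expect_identical(f$read_length, 100L)

  f <- parse_alignments(c(sam_header, sam_line(100, "35S65M")), min_clip = 20)
  expect_identical(f$left_clip, 35L)
  expect_true(f$is_clipped)
  f40 <- parse_alignments(c(sam_header, sam_line(100, "35S65M")), min_clip = 40)
  expect_false(f40$is_clipped)

  f <- parse_alignments(c(sam_header, sam_line(100, "10S80M10S")), min_clip = 10)
  expect_identical(c(f$left_clip, f$right_clip), c(10L, 10L))
  # hard clips count as terminal clips and extend the query length
  f <- parse_alignments(c(sam_header, sam_line(100, "15H85M")), min_clip = 15)
  expect_identical(f$left_clip, 15L)
  expect_identical(f$read_length, 100L)
  # deletions consume reference, not query
  f <- parse_alignments(c(sam_header, sam_line(100, "50M5D50M")), min_clip = 20)
  expect_identical(f$read_length, 100L)
  expect_false(f$is_clipped)
})

test_that("chimeric reads are recognized by SA tag or supplementary flag", {
  f <- parse_alignments(c(sam_header,
                          sam_line(100, "50S50M", tags = "SA:Z:V,1,+,50M,60,0;")))
  expect_true(f$is_chimeric)
  f <- parse_alignments(c(sam_header, sam_line(100, "100M", flag = 2048)))
  expect_true(f$is_chimeric)
  f <- parse_alignments(c(sam_header, sam_line(100, "100M")))
  expect_false(f$is_chimeric)
})

test_that("unmapped and secondary records are skipped; bad input errors carry line numbers", {
  expect_message(
    f <- parse_alignments(c(sam_header,
                            sam_line(100, "*", flag = 4),
                            sam_line(200, "100M"),
                            sam_line(300, "100M", flag = 256))),
    "1 unmapped")
  expect_identical(nrow(f), 1L)
  expect_identical(f$pos, 200L)
  expect_error(parse_alignments(c(sam_header, sam_line(100, "10Q90M"))),
               "CIGAR.*line 3")
  expect_error(parse_alignments(c(sam_header, "r1\t0\tV\t100")),
               "line 3.*11 fields")
  expect_error(parse_alignments(c(sam_header, sam_line(100, "100M")),
                                min_clip = 0), ">= 1")
})

test_that("window counts conserve totals and tile the map", {
  map <- small_map(P = 10500)
  set.seed(81)
  feats <- data.frame(chrom = "I", pos = sample.int(10500, 300, replace = TRUE),
                      read_length = 100L, left_clip = 0L, right_clip = 0L,
                      is_clipped = runif(300) < 0.2,
                      is_chimeric = runif(300) < 0.1)
  wc <- window_counts(feats, 1000, map)
  expect_identical(nrow(wc), 11L)  # ceiling(10500/1000)
  expect_identical(wc$start, as.integer(seq(1, 10001, by = 1000)))
  expect_identical(wc$end[11], 10501L)
  expect_identical(sum(wc$n_reads), 300L)
  expect_identical(sum(wc$n_clipped), sum(feats$is_clipped))
  expect_identical(sum(wc$n_chimeric), sum(feats$is_chimeric))
  # empty input -> all-zero tiling
  wc0 <- window_counts(feats[0, ], 1000, map)
  expect_identical(sum(wc0$n_reads), 0L)
  expect_identical(nrow(wc0), 11L)
  # 30 clipped features at one position land in exactly one window
  f30 <- data.frame(chrom = "I", pos = 4321L, read_length = 100L,
                    left_clip = 25L, right_clip = 0L, is_clipped = TRUE,
                    is_chimeric = FALSE)[rep(1, 30), ]
  wc30 <- window_counts(f30, 1000, map)
  expect_identical(wc30$n_clipped[wc30$start == 4001], 30L)
  expect_identical(sum(wc30$n_clipped), 30L)
})

test_that("window p-values are monotone in the pooled count and flags behave at the limits", {
  map <- small_map(P = 5000)
  base <- data.frame(chrom = "I", start = seq(1, 4001, 1000),
                     end = c(seq(1001, 4001, 1000), 5001),
                     n_reads = 200L, n_clipped = c(0L, 1L, 3L, 10L, 30L),
                     n_chimeric = 0L)
  fl <- flag_windows(base, alpha = 0.05, background = 0.01)
  expect_true(all(diff(fl$p_value) <= 0))
  expect_true(all(fl$p_value >= 0 & fl$p_value <= 1))
  # alpha -> 1 limit: every window with signal and finite p is flagged
  fl1 <- flag_windows(base, alpha = 1, background = 0.01)
  expect_identical(fl1$flagged, base$n_clipped + base$n_chimeric > 0)
  # all-zero coverage: warning, no flags
  zero <- base; zero$n_reads <- 0L; zero$n_clipped <- 0L
  expect_warning(flz <- flag_windows(zero), "no covered windows|no clipped")
  expect_false(any(flz$flagged))
  expect_error(flag_windows(base, alpha = 0), "alpha")
})

test_that("the scan is deterministic and exports BED in 0-based half-open coordinates", {
  map <- small_map(P = 50000, chrom = "V")
  aln <- simulate_breakpoint_alignments(depth = 30, read_length = 100,
                                        region = list(chrom = "V", start = 1,
                                                      end = 50000),
                                        breakpoint_pos = 25500,
                                        clip_fraction = 0.5,
                                        chimera_fraction = 0.2,
                                        background_clip_rate = 0.01, seed = 82)
  run1 <- flag_windows(window_counts(as_clip_features(aln, 20), 1000, map))
  run2 <- flag_windows(window_counts(as_clip_features(aln, 20), 1000, map))
  expect_identical(run1, run2)
  bpw <- run1[run1$start == 25001, ]
  expect_true(bpw$flagged)
  bed <- tempfile(fileext = ".bed")
  write_scan_results(run1, bed_path = bed)
  btab <- read.delim(bed, header = FALSE)
  expect_true(25000 %in% btab$V2)  # 1-based window [25001, 26001) -> BED 25000
  expect_true(all(btab$V3 - btab$V2 == 1000))
})
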