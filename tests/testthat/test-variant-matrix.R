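test_that("VCF parsing handles headers, annotation dialects, and multiallelics", {
  hdr <- c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  expect_identical(nrow(parse_vcf(hdr)), 0L)

  v <- parse_vcf(c(hdr, "V\t20064174\t.\tT\tC\t.\t.\tANN=C|missense_variant|ttx-1"))
  expect_identical(v$chrom, "V")
  expect_identical(v$pos, 20064174L)
  expect_identical(v$ref, "T")
  expect_identical(v$alt, "C")
  expect_identical(v$gene, "ttx-1")
  expect_identical(v$effect, "missense")

  # SnpEff-style 4-field ANN puts the gene in field 4
  v4 <- parse_vcf(c(hdr, "I\t100\t.\tA\tG\t.\t.\tANN=G|stop_gained|HIGH|abc-1"))
  expect_identical(v4$gene, "abc-1")
  expect_identical(v4$effect, "nonsense")

  # multiallelic rows split, ANN entries matched per allele
  vm <- parse_vcf(c(hdr, paste0("II\t500\t.\tA\tC,T\t.\t.\t",
                                "ANN=C|missense_variant|MOD|g1,T|synonymous_variant|LOW|g2")))
  expect_identical(nrow(vm), 2L)
  expect_identical(vm$alt, c("C", "T"))
  expect_identical(vm$effect, c("missense", "synonymous"))
  expect_identical(vm$gene, c("g1", "g2"))

  # EFF= and plain EFFECT=/GENE= dialects
  ve <- parse_vcf(c(hdr, "III\t9\t.\tG\tA\t.\t.\tEFF=frameshift_variant(HIGH|x|y|indl-1)"))
  expect_identical(ve$effect, "indel")
  expect_identical(ve$gene, "indl-1")
  vp <- parse_vcf(c(hdr, "X\t7\t.\tC\tG\t.\t.\tEFFECT=intron_variant;GENE=nc-9"))
  expect_identical(vp$effect, "noncoding")
  expect_identical(vp$gene, "nc-9")

  # unknown token -> noncoding with a warning; no annotation -> noncoding
  expect_warning(vu <- parse_vcf(c(hdr, "I\t5\t.\tA\tT\t.\t.\tANN=T|mystery_token|g")),
                 "unknown effect token")
  expect_identical(vu$effect, "noncoding")
  expect_identical(parse_vcf(c(hdr, "I\t5\t.\tA\tT\t.\t.\t."))$effect, "noncoding")
})

test_that("malformed VCF lines are rejected with their line number", {
  hdr <- c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  expect_error(parse_vcf(c(hdr, "I\t10\t.\tA")), "line 3.*8 tab-separated")
  expect_error(parse_vcf(c(hdr, "I\tten\t.\tA\tG\t.\t.\t.")), "line 3.*POS")
  expect_error(parse_vcf(c(hdr, "I\t10\t.\tA\tA\t.\t.\t.")), "REF equals ALT")
})

test_that("VCF write -> parse round trip is the identity on random records", {
  set.seed(51)
  rec <- random_records(100)
  f <- tempfile(fileext = ".vcf")
  write_vcf(rec, f, strain = "RIL001")
  back <- parse_vcf(f)
  expect_identical(back, rec)
  # independent reader agrees on the fixed columns
  w <- vcfR::read.vcfR(f, verbose = FALSE)
  fx <- vcfR::getFIX(w)
  expect_identical(unname(fx[, "CHROM"]), rec$chrom)
  expect_identical(as.integer(fx[, "POS"]), rec$pos)
  expect_identical(unname(fx[, "REF"]), rec$ref)
  expect_identical(unname(fx[, "ALT"]), rec$alt)
})

test_that("filter_coding keeps exactly the coding records, in order", {
  set.seed(52)
  rec <- random_records(40)
  kept <- filter_coding(rec)
  # enumeration oracle
  want <- which(rec$effect %in% c("missense", "nonsense", "indel"))
  expect_identical(as.integer(rownames(kept)), want)
  expect_identical(kept$pos, rec$pos[want])
  allnc <- rec[rec$effect == "noncoding", ]
  expect_identical(nrow(filter_coding(allnc)), 0L)
  # the packaged table is all-coding and therefore unchanged
  fx <- table1_fixture()
  expect_identical(nrow(filter_coding(fx$variants)), 13L)
  expect_identical(sum(fx$variants$effect == "missense"), 12L)
  expect_identical(sum(fx$variants$effect == "indel"), 1L)
})

test_that("presence matrix cells follow strain call sets", {
  v1 <- variant_records("I", 10, "A", "G", gene = "g1", effect = "missense")
  m1 <- build_presence_matrix(list(s1 = v1))
  expect_identical(dim(m1$cells), c(1L, 1L))
  expect_true(m1$cells[1, 1])

  set.seed(53)
  rec <- random_records(30)
  sets <- list(sA = rec[sample(30, 12), ], sB = rec[sample(30, 20), ],
               sC = rec[0, ])
  m <- build_presence_matrix(sets)
  for (s in names(sets)) {
    expect_identical(sum(m$cells[, s]),
                     length(unique(variant_key(sets[[s]]))))
  }
  # permutation invariance up to declared column order
  m_perm <- build_presence_matrix(sets[c("sC", "sA", "sB")])
  ord <- match(m$variants$key, m_perm$variants$key)
  expect_identical(m_perm$cells[ord, colnames(m$cells)], m$cells)

  expect_error(build_presence_matrix(setNames(list(v1, v1), c("x", "x"))),
               "duplicate strain")
  expect_error(build_presence_matrix(list()), "at least one")
})

test_that("matrix TSV round trip is the identity", {
  set.seed(54)
  rec <- random_records(25)
  m <- build_presence_matrix(list(a = rec[1:15, ], b = rec[10:25, ]))
  f <- tempfile(fileext = ".tsv")
  write_presence_tsv(m, f)
  back <- read_presence_tsv(f)
  expect_identical(back$strains, m$strains)
  expect_identical(back$cells, m$cells)
  expect_equal(back$variants, m$variants, ignore_attr = TRUE)
})

test_that("the packaged table is transcribed faithfully", {
  m <- table1_fixture()
  expect_identical(nrow(m$variants), 13L)
  expect_identical(m$strains,
                   c("N2", "CC1", "PY12237", "PY12265", "PY12270", "PY12272"))
  # reference columns are all-absent
  expect_true(all(!m$cells[, "N2"]))
  expect_true(all(!m$cells[, "CC1"]))
  # efn-4 is the only variant carried by PY12272
  efn <- m$variants$gene == "efn-4"
  expect_identical(unname(m$cells[efn, ]),
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(m$variants$key[efn], "IV:565523:A:G")
  # every row is present in PY12237 and absent from PY12265
  expect_true(all(m$cells[, "PY12237"]))
  expect_true(all(!m$cells[, "PY12265"]))
  # the causal-locus row
  ttx <- m$variants[m$variants$gene == "ttx-1", ]
  expect_identical(ttx$key, "V:20064174:T:C")
  expect_identical(ttx$effect, "missense")
})
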