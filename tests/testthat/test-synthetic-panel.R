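test_that("a homozygote transmits its haplotype unchanged", {
  map <- small_map()
  hom <- strain_genotype("P", founder_haplotype(map, "A"),
                         founder_haplotype(map, "A"))
  gam <- simulate_gamete(hom, map, seed = 1)
  probe <- c(1, 1234, 5e5, 999999, 1e6)
  expect_identical(hap_origin_at(gam, "I", probe), rep("A", 5))
  off <- self_cross(hom, map, seed = 2)
  expect_identical(hap_origin_at(off$hap_a, "I", probe), rep("A", 5))
  expect_identical(hap_origin_at(off$hap_b, "I", probe), rep("A", 5))
})

test_that("F1 gametes transmit either allele fairly at a marker", {
  set.seed(21)
  map <- small_map()
  f1 <- f1_of(map)
  n <- 2000
  hits <- vapply(seq_len(n), function(i)
    hap_origin_at(simulate_gamete(f1, map), "I", 5e5) == "A", logical(1))
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("recombinant fraction follows the Haldane map function", {
  set.seed(22)
  map <- small_map(G = 100)
  f1 <- f1_of(map)
  d <- 0.5  # Morgans
  m1 <- genetic_to_physical(map, "I", 25)
  m2 <- genetic_to_physical(map, "I", 25 + 100 * d)
  n <- 2000
  rec <- vapply(seq_len(n), function(i) {
    g <- simulate_gamete(f1, map)
    hap_origin_at(g, "I", m1) != hap_origin_at(g, "I", m2)
  }, logical(1))
  r <- (1 - exp(-2 * d)) / 2
  expect_lt(abs(mean(rec) - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("obligate crossover model yields exactly one exchange per gamete", {
  set.seed(23)
  map <- small_map(G = 1)  # tiny genetic length: Haldane would rarely cross
  f1 <- f1_of(map)
  n_seg <- vapply(seq_len(50), function(i) {
    g <- simulate_gamete(f1, map, xo_model = "obligate")
    length(g$segments[["I"]]$start)
  }, integer(1))
  expect_true(all(n_seg == 2))  # one crossover -> two parental blocks
})

test_that("selfing a single-locus heterozygote matches the Punnett square", {
  set.seed(24)
  map <- small_map(G = 0.001)  # effectively a single locus
  f1 <- f1_of(map)
  n <- 2000
  het <- vapply(seq_len(n), function(i)
    is_het_at(self_cross(f1, map), "I", 5e5), logical(1))
  # 2 of the 4 equally likely gamete pairs are heterozygous
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("marker heterozygosity decays as (1/2)^g under selfing", {
  set.seed(25)
  map <- small_map()
  f1 <- f1_of(map)
  n <- 400
  gs <- c(1, 4)
  het <- matrix(NA, n, length(gs))
  for (i in seq_len(n)) {
    cur <- f1
    for (gen in 1:max(gs)) {
      cur <- self_cross(cur, map)
      k <- match(gen, gs)
      if (!is.na(k)) het[i, k] <- is_het_at(cur, "I", 5e5)
    }
  }
  for (k in seq_along(gs)) {
    p0 <- 0.5^gs[k]
    expect_lt(abs(mean(het[, k]) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("a zero mutation rate leaves every allele parental", {
  map <- small_map()
  pa <- founder_parent("A", variant_records("I", 1e5, "A", "G",
                                            gene = "pa-1", effect = "missense"),
                       map)
  pb <- founder_parent("B", variant_records("I", 9e5, "C", "T",
                                            gene = "pb-1", effect = "missense"),
                       map)
  panel <- generate_ril_panel(pa, pb, n_lines = 5, g_generations = 3,
                              de_novo_rate = 0, map = map, seed = 31)
  expect_length(panel$lines, 5)
  expect_identical(nrow(panel$truth), 0L)
  for (ln in names(panel$lines)) {
    g <- panel$lines[[ln]]
    for (h in list(g$hap_a, g$hap_b)) {
      expect_true(all(h$segments[["I"]]$origin %in% c("A", "B")))
      expect_identical(nrow(h$variants), 0L)
    }
    sv <- strain_variants(panel, ln)
    expect_true(all(startsWith(sv$source, "parental_")))
  }
})

test_that("de novo events accrue at the Poisson rate and settle into the three fates", {
  set.seed(32)
  map <- small_map()
  pa <- founder_parent("A", map = map)
  pb <- founder_parent("B", map = map)
  rate <- 0.3; g <- 9; n <- 300
  panel <- generate_ril_panel(pa, pb, n_lines = n, g_generations = g,
                              de_novo_rate = rate, map = map)
  counts <- table(factor(panel$truth$line, levels = names(panel$lines)))
  mu <- rate * 2 * g  # two transmitted gametes per generation
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n))
  expect_true(all(panel$truth$zygosity %in% c("het", "hom_alt", "lost")))
  fr <- prop.table(table(panel$truth$zygosity))
  expect_equal(sum(fr), 1)
  # de novo positions never collide with parental variant positions
  expect_false(any(panel$truth$pos %in% c(pa$variants$pos, pb$variants$pos)))
})

test_that("identical seeds give byte-identical panels", {
  map <- small_map()
  pa <- founder_parent("A", map = map)
  pb <- founder_parent("B", map = map)
  p1 <- generate_ril_panel(pa, pb, n_lines = 4, g_generations = 3,
                           de_novo_rate = 0.3, map = map, seed = 77)
  p2 <- generate_ril_panel(pa, pb, n_lines = 4, g_generations = 3,
                           de_novo_rate = 0.3, map = map, seed = 77)
  expect_identical(p1, p2)
})

test_that("panel parameter validation", {
  map <- small_map()
  pa <- founder_parent("A", map = map)
  pb <- founder_parent("B", map = map)
  expect_error(generate_ril_panel(pa, pb, n_lines = 0, map = map), ">= 1")
  expect_error(generate_ril_panel(pa, pb, g_generations = 0, map = map), ">= 1")
  expect_error(generate_ril_panel(pa, pa, map = map), "distinct")
})

test_that("phenotypes equal a direct genotype lookup, including a double-defect line", {
  map <- build_map(data.frame(chrom = c("I", "II"),
                              physical_length = c(1e6, 1e6),
                              genetic_length = c(50, 50)))
  pa <- founder_parent("A", map = map)
  pb <- founder_parent("B", map = map)
  planted <- variant_records(c("I", "II"), c(5e5, 5e5), c("A", "C"),
                             c("G", "T"), gene = c("loc1", "loc2"),
                             effect = "missense")
  panel <- generate_ril_panel(pa, pb, n_lines = 40, g_generations = 9,
                              de_novo_rate = 0, map = map, planted = planted,
                              seed = 41)
  cm <- c(planted_1 = "circling", planted_2 = "thermotaxis")
  phen <- simulate_phenotypes(panel, cm, penetrance = 1)
  # brute-force oracle straight from the truth table
  for (i in seq_len(nrow(phen))) {
    tr <- panel$truth[panel$truth$line == phen$strain[i], ]
    want <- unname(cm[tr$id[tr$zygosity == "hom_alt"]])
    expect_identical(phen$phenotype[i], paste(want, collapse = ";"))
    expect_identical(phen$indeterminate[i], any(tr$zygosity == "het"))
  }
  # both-loci-homozygous lines carry both labels
  both <- phen$phenotype == "circling;thermotaxis"
  hom1 <- panel$truth$line[panel$truth$id == "planted_1" &
                             panel$truth$zygosity == "hom_alt"]
  hom2 <- panel$truth$line[panel$truth$id == "planted_2" &
                             panel$truth$zygosity == "hom_alt"]
  expect_setequal(phen$strain[both], intersect(hom1, hom2))

  expect_true(all(simulate_phenotypes(panel, character())$phenotype == ""))
  expect_error(simulate_phenotypes(panel, c(nope = "x")), "absent from panel")
})
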