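# shared fixtures, all built in code

small_map <- function(P = 1e6, G = 50, chrom = "I") {
  build_map(data.frame(chrom = chrom, physical_length = P, genetic_length = G))
}

f1_of <- function(map, a = "A", b = "B") {
  strain_genotype("F1", founder_haplotype(map, a), founder_haplotype(map, b))
}

# n random variant records spread over a map, covering all effect classes
random_records <- function(n, map = build_map()) {
  bases <- c("A", "C", "G", "T")
  ci <- sample.int(nrow(map), n, replace = TRUE)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    w <- sample(1:3, 1)
    ref[i] <- paste(sample(bases, w, replace = TRUE), collapse = "")
    repeat {
      alt[i] <- paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
      if (alt[i] != ref[i]) break
    }
  }
  variant_records(
    chrom = map$chrom[ci],
    pos = vapply(ci, function(j) sample.int(map$physical_length[j], 1L), numeric(1)),
    ref = ref, alt = alt,
    gene = ifelse(runif(n) < 0.2, "", sprintf("gene-%d", seq_len(n))),
    effect = sample(c("missense", "nonsense", "indel", "synonymous", "noncoding"),
                    n, replace = TRUE))
}

# straight-line track builder (t in seconds, points as matrix cols x, y)
track_from_points <- function(x, y, plate = default_plate()) {
  tr <- data.frame(t = seq_along(x) - 1, x = x, y = y)
  attr(tr, "plate") <- plate
  class(tr) <- c("worm_track", "data.frame")
  tr
}
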