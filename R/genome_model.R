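# Genome coordinate system: genetic <-> physical maps, variants, haplotypes.
# Coordinates are 1-based and inclusive (VCF convention); windows elsewhere
# in the package are half-open [start, end).

EFFECT_CLASSES <- c("missense", "nonsense", "indel", "synonymous", "noncoding")
CODING_EFFECTS <- c("missense", "nonsense", "indel")

#' Build a genetic map
#'
#' A genetic map is the shared coordinate system of the package: an ordered
#' set of chromosomes, each with a physical length in bp and a genetic length
#' in centiMorgans. Conversion between the two scales is linear
#' (see [genetic_to_physical()]).
#'
#' @param spec A data.frame with columns `chrom`, `physical_length` (bp,
#'   integer >= 1) and `genetic_length` (cM, > 0), one row per chromosome.
#'   `NULL` (default) gives a six-chromosome map named I, II, III, IV, V, X
#'   with physical lengths 15.1, 15.3, 13.8, 17.5, 20.9, 17.7 Mb and 50 cM
#'   each -- configurable approximations to the *C. elegans* genome, not
#'   measured values.
#' @return An object of class `genetic_map` (a validated data.frame).
#' @examples
#' map <- build_map()
#' map$physical_length[map$chrom == "V"]
#' @export
build_map <- function(spec = NULL) {
  if (is.null(spec)) {
    spec <- data.frame(
      chrom = c("I", "II", "III", "IV", "V", "X"),
      physical_length = c(15.1e6, 15.3e6, 13.8e6, 17.5e6, 20.9e6, 17.7e6),
      genetic_length = rep(50, 6)
    )
  }
  if (is.list(spec) && !is.data.frame(spec)) {
    spec <- do.call(rbind, lapply(spec, function(x) {
      data.frame(chrom = x$chrom, physical_length = x$physical_length,
                 genetic_length = x$genetic_length)
    }))
  }
  if (!is.data.frame(spec) || nrow(spec) == 0) {
    stop("map spec must be a non-empty data.frame of chromosome descriptors")
  }
  need <- c("chrom", "physical_length", "genetic_length")
  if (!all(need %in% names(spec))) {
    stop("map spec needs columns: ", paste(need, collapse = ", "))
  }
  spec$chrom <- as.character(spec$chrom)
  spec$physical_length <- as.numeric(spec$physical_length)
  spec$genetic_length <- as.numeric(spec$genetic_length)
  dup <- spec$chrom[duplicated(spec$chrom)]
  if (length(dup)) stop("duplicate chromosome name(s): ", paste(unique(dup), collapse = ", "))
  bad <- spec$chrom[is.na(spec$physical_length) | spec$physical_length < 1 |
                      is.na(spec$genetic_length) | spec$genetic_length <= 0]
  if (length(bad)) stop("non-positive length for chromosome(s): ", paste(bad, collapse = ", "))
  spec$physical_length <- round(spec$physical_length)
  rownames(spec) <- NULL
  structure(spec[, need], class = c("genetic_map", "data.frame"))
}

#' Read a genetic map from a plain-text spec
#'
#' One chromosome per line: `name  physical_length_bp  genetic_length_cM`,
#' whitespace-separated; lines starting with `#` are ignored.
#'
#' @param path Path to the text file.
#' @return A `genetic_map`.
#' @export
read_map_spec <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("chrom", "physical_length", "genetic_length"),
                           colClasses = c("character", "numeric", "numeric"))
  build_map(tab)
}

map_chrom_row <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  i
}

# round half away from zero (documented rounding rule for map conversion)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert genetic to physical coordinates (and back)
#'
#' Conversion is linear per chromosome: 0 cM maps to bp 1 and the full
#' genetic length maps to the physical length. `genetic_to_physical()` rounds
#' half away from zero to the nearest bp; `physical_to_genetic()` is exact,
#' so a physical -> genetic -> physical round trip recovers the input bp.
#'
#' @param map A [build_map()] object.
#' @param chrom Chromosome name (scalar).
#' @param g Genetic position(s) in cM, within `[0, genetic_length]`.
#' @param p Physical position(s) in bp, within `[1, physical_length]`.
#' @return Physical positions in bp (integer) or genetic positions in cM.
#' @export
genetic_to_physical <- function(map, chrom, g) {
  i <- map_chrom_row(map, chrom)
  P <- map$physical_length[i]; G <- map$genetic_length[i]
  if (any(is.na(g) | g < 0 | g > G)) {
    stop("genetic position out of range [0, ", G, "] on ", chrom)
  }
  as.integer(round_half_up(1 + g / G * (P - 1)))
}

#' @rdname genetic_to_physical
#' @export
physical_to_genetic <- function(map, chrom, p) {
  i <- map_chrom_row(map, chrom)
  P <- map$physical_length[i]; G <- map$genetic_length[i]
  if (any(is.na(p) | p < 1 | p > P)) {
    stop("physical position out of range [1, ", P, "] on ", chrom)
  }
  (p - 1) / (P - 1) * G
}

#' Construct variant records
#'
#' A variant record is one sequence variant: chromosome, 1-based position,
#' reference and alternate allele strings, an optional gene label, and an
#' effect class from the closed set missense / nonsense / indel /
#' synonymous / noncoding.
#'
#' @param chrom,pos,ref,alt,gene,effect Parallel vectors (recycled where
#'   scalar). `ref` must differ from `alt` row-wise.
#' @return A data.frame with one row per variant.
#' @export
variant_records <- function(chrom, pos, ref, alt, gene = "", effect) {
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  gene = as.character(gene), effect = as.character(effect),
                  stringsAsFactors = FALSE)
  if (any(is.na(v$pos) | v$pos < 1)) stop("variant pos must be a 1-based integer")
  if (any(v$ref == v$alt)) stop("ref allele must differ from alt allele")
  bad <- setdiff(unique(v$effect), EFFECT_CLASSES)
  if (length(bad)) {
    stop("effect must be one of {", paste(EFFECT_CLASSES, collapse = ", "),
         "}; got: ", paste(bad, collapse = ", "))
  }
  v
}

empty_variants <- function(with_id = FALSE) {
  v <- data.frame(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(), effect = character(),
                  stringsAsFactors = FALSE)
  if (with_id) v$id <- character()
  v
}

validate_variants <- function(v, map) {
  i <- map_chrom_row(map, v$chrom)
  out <- v$pos > map$physical_length[i]
  if (any(out)) {
    stop("variant position beyond chromosome end: ",
         paste(paste0(v$chrom[out], ":", v$pos[out]), collapse = ", "))
  }
  invisible(v)
}

#' Variant identity key
#'
#' Variants are keyed by `chrom:pos:ref:alt`; the key is the row identity in
#' presence/absence matrices.
#'
#' @param v A variant data.frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

## -- haplotypes and strain genotypes ---------------------------------------

new_haplotype <- function(segments, variants = empty_variants(with_id = TRUE)) {
  structure(list(segments = segments, variants = variants), class = "haplotype")
}

#' Founder haplotype of uniform parental origin
#'
#' A haplotype is a mosaic of parental segments tiling every chromosome of
#' the map, plus the set of de novo variants carried on it. Segments are
#' stored per chromosome as parallel `start` / `end` / `origin` vectors.
#' A founder haplotype is a single segment per chromosome, all of one
#' origin.
#'
#' @param map A `genetic_map`.
#' @param origin Parent label.
#' @return A `haplotype` object.
#' @export
founder_haplotype <- function(map, origin) {
  segs <- lapply(seq_len(nrow(map)), function(i) {
    list(start = 1L, end = as.integer(map$physical_length[i]),
         origin = origin)
  })
  names(segs) <- map$chrom
  new_haplotype(segs)
}

#' @export
print.haplotype <- function(x, ...) {
  nseg <- sum(vapply(x$segments, function(s) length(s$start), integer(1)))
  cat("<haplotype>", length(x$segments), "chromosomes,", nseg, "segments,",
      nrow(x$variants), "de novo variant(s)\n")
  invisible(x)
}

#' Parental origin at a position
#'
#' @param hap A `haplotype`.
#' @param chrom Chromosome name.
#' @param pos Physical position(s), bp.
#' @return Character vector of origin labels.
#' @export
hap_origin_at <- function(hap, chrom, pos) {
  s <- hap$segments[[chrom]]
  if (is.null(s)) stop("haplotype has no chromosome ", chrom)
  s$origin[findInterval(pos, s$start)]
}

validate_haplotype <- function(hap, map, parents = NULL) {
  for (i in seq_len(nrow(map))) {
    s <- hap$segments[[map$chrom[i]]]
    if (is.null(s)) stop("missing segments for chromosome ", map$chrom[i])
    n <- length(s$start)
    if (s$start[1] != 1L || s$end[n] != map$physical_length[i] ||
        (n > 1 && any(s$start[-1] != s$end[-n] + 1L))) {
      stop("segments do not tile chromosome ", map$chrom[i])
    }
    if (!is.null(parents) && !all(s$origin %in% parents)) {
      stop("segment origin outside declared parents on ", map$chrom[i])
    }
  }
  invisible(hap)
}

#' Diploid strain genotype
#'
#' @param name Strain name.
#' @param hap_a,hap_b The two haplotypes, defined over the same map.
#' @return A `strain_genotype` object.
#' @export
strain_genotype <- function(name, hap_a, hap_b) {
  stopifnot(inherits(hap_a, "haplotype"), inherits(hap_b, "haplotype"))
  structure(list(name = name, hap_a = hap_a, hap_b = hap_b),
            class = "strain_genotype")
}

#' @export
print.strain_genotype <- function(x, ...) {
  cat("<strain_genotype>", x$name, "\n")
  invisible(x)
}

#' Is a genotype heterozygous (by parental origin) at a position?
#'
#' @param g A `strain_genotype`.
#' @param chrom,pos Marker location.
#' @return Logical.
#' @export
is_het_at <- function(g, chrom, pos) {
  hap_origin_at(g$hap_a, chrom, pos) != hap_origin_at(g$hap_b, chrom, pos)
}
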