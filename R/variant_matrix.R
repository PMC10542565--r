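# Variant-call ingestion and the strains x variants presence/absence matrix.
# The VCF reader handles the v4.2 subset this pipeline consumes (8 fixed
# columns, one record per ALT allele) with effect annotations in ANN=, EFF=
# or plain EFFECT=/GENE= INFO keys; a transcription of the published
# six-strain coding-variant table ships as a packaged fixture.

# SnpEff-style annotation tokens -> the closed effect set
map_effect_token <- function(token) {
  if (is.na(token) || token == "" || token == ".") return("noncoding")
  t <- tolower(token)
  if (grepl("missense|start_lost|stop_lost|initiator_codon", t)) return("missense")
  if (grepl("stop_gained|nonsense", t)) return("nonsense")
  if (grepl("frameshift|inframe|insertion|deletion|indel|duplication", t)) return("indel")
  if (grepl("synonymous|stop_retained", t)) return("synonymous")
  known_noncoding <- c("intron", "intergenic", "upstream", "downstream",
                       "utr", "prime", "non_coding", "noncoding", "splice",
                       "regulatory", "intragenic")
  if (any(vapply(known_noncoding, grepl, logical(1), x = t))) return("noncoding")
  warning("unknown effect token '", token, "' mapped to noncoding", call. = FALSE)
  "noncoding"
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}

# effect + gene for one ALT allele from an INFO string
parse_info_effect <- function(info, alt) {
  ann <- info_field(info, "ANN")
  if (!is.na(ann)) {
    entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
    hit <- entries[vapply(entries, function(s)
      identical(strsplit(s, "|", fixed = TRUE)[[1]][1], alt), logical(1))]
    entry <- if (length(hit)) hit[1] else entries[1]
    fs <- strsplit(entry, "|", fixed = TRUE)[[1]]
    token <- if (length(fs) >= 2) fs[2] else NA_character_
    gene <- if (length(fs) >= 4) fs[4] else if (length(fs) >= 3) fs[3] else ""
    if (is.na(gene) || gene == ".") gene <- ""
    return(list(effect = map_effect_token(token), gene = gene))
  }
  eff <- info_field(info, "EFF")
  if (!is.na(eff)) {
    entry <- strsplit(eff, ",", fixed = TRUE)[[1]][1]
    token <- sub("\\(.*$", "", entry)
    inner <- sub("^[^(]*\\(", "", sub("\\)$", "", entry))
    fs <- strsplit(inner, "|", fixed = TRUE)[[1]]
    gene <- if (length(fs) >= 4 && fs[4] != ".") fs[4] else ""
    return(list(effect = map_effect_token(token), gene = gene))
  }
  token <- info_field(info, "EFFECT")
  gene <- info_field(info, "GENE")
  if (!is.na(token)) {
    return(list(effect = map_effect_token(token),
                gene = if (is.na(gene)) "" else gene))
  }
  list(effect = "noncoding", gene = "")
}

#' Parse a VCF v4.2 subset into variant records
#'
#' Reads the eight fixed columns (CHROM POS ID REF ALT QUAL FILTER INFO);
#' multi-allelic rows are split into one record per ALT allele. The effect
#' class and gene label are taken from a SnpEff-style `ANN=` entry matching
#' the allele (first entry as fallback), an `EFF=` entry, or plain
#' `EFFECT=`/`GENE=` keys; unknown effect tokens map to `noncoding` with a
#' warning, never a hard failure.
#'
#' @param input A file path, or a character vector of VCF lines.
#' @return A [variant_records()] data.frame, in input order.
#' @export
parse_vcf <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input)
  } else {
    input
  }
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop("malformed VCF line ", ln, ": expected 8 tab-separated fields, got ",
           length(f))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF line ", ln, ": POS is not an integer")
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (identical(alt, f[4])) {
        stop("malformed VCF line ", ln, ": REF equals ALT")
      }
      eg <- parse_info_effect(f[8], alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[1], pos = pos, ref = f[4], alt = alt, gene = eg$gene,
        effect = eg$effect, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_variants())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

effect_to_token <- c(missense = "missense_variant", nonsense = "stop_gained",
                     indel = "frameshift_variant",
                     synonymous = "synonymous_variant",
                     noncoding = "intergenic_region")

#' Write variant records as a VCF v4.2 subset
#'
#' Emits a header plus one body row per record with the effect encoded as a
#' SnpEff-style `ANN=<alt>|<token>|.|<gene>` INFO entry; [parse_vcf()]
#' recovers the records exactly.
#'
#' @param records A [variant_records()] data.frame.
#' @param path Output path.
#' @param strain Optional strain name recorded as a `##strain=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, strain = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Impact | Gene_Name'\">")
  if (!is.null(strain)) hdr <- c(hdr, paste0("##strain=", strain))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(records)) {
    gene <- ifelse(records$gene == "", ".", records$gene)
    info <- sprintf("ANN=%s|%s|.|%s", records$alt,
                    effect_to_token[records$effect], gene)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", records$chrom, records$pos,
                    records$ref, records$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Keep protein-coding variants
#'
#' Order-preserving subset of records whose effect is missense, nonsense or
#' indel -- the "variants in protein-coding sequences" a segregation filter
#' examines first.
#'
#' @param records A variant data.frame.
#' @return The coding subset, in input order.
#' @export
filter_coding <- function(records) {
  records[records$effect %in% CODING_EFFECTS, , drop = FALSE]
}

#' Build a strains x variants presence/absence matrix
#'
#' Rows are the union of variant keys (`chrom:pos:ref:alt`) across strains,
#' in first-appearance order; a cell is `TRUE` iff that strain's call set
#' contains the key. Presence is binary: zygosity is deliberately collapsed,
#' matching how shared-variant tables are reported.
#'
#' @param per_strain Named list: strain name -> variant data.frame.
#' @return A `presence_matrix`: list with `variants` (data.frame incl.
#'   `key`), `strains`, and a logical `cells` matrix (variants x strains).
#' @export
build_presence_matrix <- function(per_strain) {
  if (!length(per_strain)) stop("at least one strain is required")
  strains <- names(per_strain)
  if (is.null(strains) || any(strains == "")) stop("per_strain must be a named list")
  if (anyDuplicated(strains)) {
    stop("duplicate strain name(s): ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  }
  keysets <- lapply(per_strain, function(v) unique(variant_key(v)))
  meta <- do.call(rbind, lapply(per_strain, function(v)
    v[, c("chrom", "pos", "ref", "alt", "gene", "effect"), drop = FALSE]))
  keys_all <- unlist(lapply(per_strain, variant_key), use.names = FALSE)
  first <- !duplicated(keys_all)
  variants <- meta[first, , drop = FALSE]
  variants$key <- keys_all[first]
  rownames(variants) <- NULL
  cells <- vapply(strains, function(s) variants$key %in% keysets[[s]],
                  logical(nrow(variants)))
  cells <- matrix(cells, nrow = nrow(variants), ncol = length(strains),
                  dimnames = list(variants$key, strains))
  structure(list(variants = variants, strains = strains, cells = cells),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix>", nrow(x$variants), "variants x", length(x$strains),
      "strains\n")
  if (nrow(x$variants)) {
    df <- cbind(x$variants[, c("gene", "key", "effect")],
                as.data.frame(x$cells + 0L))
    print(utils::head(df, 20), row.names = FALSE)
    if (nrow(df) > 20) cat("... (", nrow(df) - 20, " more rows)\n", sep = "")
  }
  invisible(x)
}

# row subset preserving structure
subset_matrix_rows <- function(m, idx) {
  structure(list(variants = m$variants[idx, , drop = FALSE],
                 strains = m$strains,
                 cells = m$cells[idx, , drop = FALSE]),
            class = "presence_matrix")
}

#' Write / read a presence matrix as TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`, then one `0/1`
#' column per strain. The write -> read round trip is the identity.
#'
#' @param m A `presence_matrix`.
#' @param path File path.
#' @return `write_presence_tsv()`: `path`, invisibly; `read_presence_tsv()`:
#'   a `presence_matrix`.
#' @export
write_presence_tsv <- function(m, path) {
  df <- cbind(m$variants[, c("chrom", "pos", "ref", "alt", "gene", "effect")],
              as.data.frame(m$cells + 0L, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  meta_cols <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  if (!all(meta_cols %in% names(df))) {
    stop("presence TSV must have columns: ", paste(meta_cols, collapse = ", "))
  }
  strains <- setdiff(names(df), meta_cols)
  if (!length(strains)) stop("presence TSV has no strain columns")
  variants <- df[, meta_cols, drop = FALSE]
  variants$pos <- as.integer(variants$pos)
  variants$gene[is.na(variants$gene)] <- ""
  variants$key <- variant_key(variants)
  cells <- as.matrix(df[, strains, drop = FALSE]) == "1"
  dimnames(cells) <- list(variants$key, strains)
  structure(list(variants = variants, strains = strains, cells = cells),
            class = "presence_matrix")
}

#' The published six-strain coding-variant table, as a packaged fixture
#'
#' A transcription of the published summary of presence or absence of
#' protein-coding variants in the examined strains: 13 variants (12
#' missense and 1 indel, including the *ttx-1* T-to-C change at
#' V:20064174) x 6 strains (N2, CC1, PY12237, PY12265, PY12270, PY12272).
#' The reference N2 and CC1 columns are all-absent as printed.
#'
#' @return A `presence_matrix`.
#' @examples
#' m <- table1_fixture()
#' nrow(m$variants)  # 13
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_presence.tsv", package = "rilseg",
                      mustWork = TRUE)
  read_presence_tsv(path)
}
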