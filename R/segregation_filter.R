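# Phenotype-conditioned segregation filtering: boolean pattern matching over
# the presence/absence matrix, and the three-hypothesis candidate report
# used to nominate causal variants.

#' Define a phenotype-conditioned presence pattern
#'
#' @param name Pattern label.
#' @param present_in Strains the variant must be present in.
#' @param absent_in Strains the variant must be absent from. Must not
#'   overlap `present_in`.
#' @return A `phenotype_pattern` object.
#' @export
phenotype_pattern <- function(name, present_in, absent_in = character()) {
  present_in <- unique(as.character(present_in))
  absent_in <- unique(as.character(absent_in))
  both <- intersect(present_in, absent_in)
  if (length(both)) {
    stop("strain(s) in both present_in and absent_in: ",
         paste(both, collapse = ", "))
  }
  structure(list(name = name, present_in = present_in, absent_in = absent_in),
            class = "phenotype_pattern")
}

#' @export
print.phenotype_pattern <- function(x, ...) {
  cat("<phenotype_pattern>", x$name,
      "\n  present in:", paste(x$present_in, collapse = ", "),
      "\n  absent in: ", paste(x$absent_in, collapse = ", "), "\n")
  invisible(x)
}

#' Match a presence pattern against a matrix
#'
#' Returns the variants whose cell is `TRUE` for every strain in
#' `present_in` and `FALSE` for every strain in `absent_in`, in matrix row
#' order. This is the core boolean inference: no scoring or ranking is
#' applied.
#'
#' @param m A `presence_matrix`.
#' @param pattern A [phenotype_pattern()].
#' @return The matching rows of `m$variants`.
#' @examples
#' m <- table1_fixture()
#' # variants consistent with causing the thermotaxis defect alone
#' pattern_match(m, phenotype_pattern("ttx-only",
#'   present_in = c("PY12237", "PY12272"),
#'   absent_in = c("PY12270", "PY12265")))
#' @export
pattern_match <- function(m, pattern) {
  unknown <- setdiff(c(pattern$present_in, pattern$absent_in), m$strains)
  if (length(unknown)) {
    stop("pattern names strain(s) not in the matrix: ",
         paste(unknown, collapse = ", "))
  }
  ok <- rep(TRUE, nrow(m$variants))
  for (s in pattern$present_in) ok <- ok & m$cells[, s]
  for (s in pattern$absent_in) ok <- ok & !m$cells[, s]
  m$variants[ok, , drop = FALSE]
}

#' Phenotype classes for a set of strains
#'
#' @param strain Strain names.
#' @param labels `;`-separated phenotype labels per strain (`""` =
#'   wild-type).
#' @param role One of `line`, `parent_a`, `parent_b` per strain.
#' @param indeterminate Logical: phenotype could not be scored (e.g. the
#'   line still segregates it); such strains are left unconstrained.
#' @return A data.frame of classes.
#' @export
phenotype_classes <- function(strain, labels, role = "line",
                              indeterminate = FALSE) {
  data.frame(strain = as.character(strain), labels = as.character(labels),
             role = rep_len(as.character(role), length(strain)),
             indeterminate = rep_len(as.logical(indeterminate), length(strain)),
             stringsAsFactors = FALSE)
}

#' Phenotype classes of the six published strains
#'
#' N2 and CC1 are the wild-type parents; PY12237 shows both the circling
#' and the thermotaxis defect, PY12270 circling only (its circling precludes
#' scoring thermotaxis directly), PY12272 the thermotaxis defect only, and
#' PY12265 neither.
#'
#' @return A [phenotype_classes()] data.frame.
#' @export
study_phenotype_classes <- function() {
  phenotype_classes(
    strain = c("N2", "CC1", "PY12237", "PY12265", "PY12270", "PY12272"),
    labels = c("", "", "circling;thermotaxis", "", "circling", "thermotaxis"),
    role = c("parent_a", "parent_b", "line", "line", "line", "line"))
}

#' Read phenotype classes from a TSV
#'
#' Two required columns (`strain`, `labels`, the latter `;`-separated) and
#' optional `role` / `indeterminate` columns.
#'
#' @param path File path.
#' @return A [phenotype_classes()] data.frame.
#' @export
read_phenotype_classes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("strain", "labels") %in% names(df))) {
    stop("phenotype class TSV needs 'strain' and 'labels' columns")
  }
  df$labels[is.na(df$labels)] <- ""
  phenotype_classes(df$strain, df$labels,
                    role = if ("role" %in% names(df)) df$role else "line",
                    indeterminate = if ("indeterminate" %in% names(df))
                      as.logical(df$indeterminate) else FALSE)
}

split_labels <- function(labels) {
  lapply(strsplit(labels, ";", fixed = TRUE), function(x) trimws(x[x != ""]))
}

matrix_fingerprint <- function(m) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_presence_tsv(m, tf)
  unname(tools::md5sum(tf))
}

#' Build and evaluate the candidate-variant hypotheses
#'
#' Encodes the boolean reasoning used to nominate causal variants from a
#' presence matrix and the strains' phenotype classes. For every phenotype
#' label `L` a hypothesis pattern is evaluated: the variant must be present
#' in every strain labeled `L` and absent from every informative strain that
#' is not -- except strains whose phenotype for `L` is masked by another
#' label (by default circling masks the thermotaxis readout, so
#' circling-only strains are left unconstrained when testing the
#' thermotaxis hypothesis). A third, parental-masking hypothesis asks for
#' variants shared between the `parent_b` founder and all defective lines
#' but absent from wild-type lines -- the case of a parental allele whose
#' effect is masked in the parent's own background.
#'
#' Strains flagged `indeterminate` are never constrained. Noncoding and
#' synonymous rows are dropped unless `include_noncoding = TRUE`.
#'
#' @param m A `presence_matrix`. Every matrix strain must appear in
#'   `classes`.
#' @param classes A [phenotype_classes()] data.frame.
#' @param masks Named character vector: `masks[L]` is the label that masks
#'   the readout of `L`.
#' @param include_noncoding Keep noncoding/synonymous matrix rows.
#' @return A `candidate_report`: per hypothesis the pattern, its candidate
#'   variants, a status (`ok` / `undefined`), and a note; plus the matrix
#'   fingerprint for provenance.
#' @examples
#' candidate_report(table1_fixture(), study_phenotype_classes())
#' @export
candidate_report <- function(m, classes, masks = c(thermotaxis = "circling"),
                             include_noncoding = FALSE) {
  missing_cls <- setdiff(m$strains, classes$strain)
  if (length(missing_cls)) {
    stop("strain(s) without a phenotype class: ",
         paste(missing_cls, collapse = ", "))
  }
  cl <- classes[match(m$strains, classes$strain), , drop = FALSE]
  labs <- split_labels(cl$labels)
  informative <- !cl$indeterminate
  mm <- if (include_noncoding) m else {
    subset_matrix_rows(m, m$variants$effect %in% CODING_EFFECTS)
  }
  label_set <- sort(unique(unlist(labs)))
  hyps <- list()

  for (L in label_set) {
    has <- vapply(labs, function(x) L %in% x, logical(1))
    maskL <- if (L %in% names(masks)) masks[[L]] else NA_character_
    masked <- if (is.na(maskL)) rep(FALSE, length(labs)) else
      vapply(labs, function(x) maskL %in% x, logical(1))
    pat <- phenotype_pattern(
      name = L,
      present_in = m$strains[has],
      absent_in = m$strains[!has & informative & !masked])
    note <- if (!is.na(maskL) && any(masked & !has)) {
      paste0("strains left unconstrained (", maskL, " masks the ", L,
             " readout): ", paste(m$strains[masked & !has], collapse = ", "))
    } else ""
    hyps[[L]] <- list(name = L, status = "ok", pattern = pat,
                      candidates = pattern_match(mm, pat), note = note)
  }
  if (!length(label_set)) {
    hyps[["none"]] <- list(
      name = "none", status = "undefined", pattern = NULL,
      candidates = mm$variants[0, , drop = FALSE],
      note = "no phenotype-defective strain: label hypotheses are undefined")
  }

  pb <- intersect(cl$strain[cl$role == "parent_b"], m$strains)
  pa <- intersect(cl$strain[cl$role == "parent_a"], m$strains)
  defective <- m$strains[lengths(labs) > 0]
  wild_lines <- m$strains[lengths(labs) == 0 & informative &
                            cl$role == "line"]
  if (length(pb) && length(defective)) {
    pat <- phenotype_pattern("parental_masking",
                             present_in = c(pb, defective),
                             absent_in = c(wild_lines, pa))
    hyps[["parental_masking"]] <- list(
      name = "parental_masking", status = "ok", pattern = pat,
      candidates = pattern_match(mm, pat),
      note = paste0("parental allele masked in the ", pb[1], " background"))
  } else {
    hyps[["parental_masking"]] <- list(
      name = "parental_masking", status = "undefined", pattern = NULL,
      candidates = mm$variants[0, , drop = FALSE],
      note = if (!length(pb)) "no parent_b strain in the matrix"
             else "no defective strain")
  }

  structure(list(hypotheses = hyps, classes = classes,
                 matrix_fingerprint = matrix_fingerprint(m),
                 include_noncoding = include_noncoding),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate variant report (matrix md5 ", x$matrix_fingerprint, ")\n",
      sep = "")
  for (h in x$hypotheses) {
    cat("\nHypothesis '", h$name, "' [", h$status, "]\n", sep = "")
    if (!is.null(h$pattern)) {
      cat("  present in:", paste(h$pattern$present_in, collapse = ", "), "\n")
      cat("  absent in: ", paste(h$pattern$absent_in, collapse = ", "), "\n")
    }
    if (nzchar(h$note)) cat("  note:", h$note, "\n")
    if (h$status == "ok") {
      if (nrow(h$candidates)) {
        cat("  candidates (", nrow(h$candidates), "):\n", sep = "")
        print(h$candidates[, c("gene", "key", "effect")], row.names = FALSE)
      } else {
        cat("  candidates: none\n")
      }
    }
  }
  invisible(x)
}

#' Write a candidate report as TSV plus a text summary
#'
#' @param report A [candidate_report()].
#' @param tsv_path Output TSV (hypothesis, key, gene, effect).
#' @param txt_path Optional human-readable summary path.
#' @return `tsv_path`, invisibly.
#' @export
write_candidate_report <- function(report, tsv_path, txt_path = NULL) {
  rows <- do.call(rbind, lapply(report$hypotheses, function(h) {
    if (!nrow(h$candidates)) return(NULL)
    data.frame(hypothesis = h$name, key = h$candidates$key,
               gene = h$candidates$gene, effect = h$candidates$effect,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(hypothesis = character(), key = character(),
                       gene = character(), effect = character())
  }
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con)
    print(report)
    sink()
    close(con)
  }
  invisible(tsv_path)
}
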