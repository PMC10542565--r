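# Breakpoint-signature scan: count soft-clipped and chimeric reads per
# genomic window and flag windows enriched over the genome-wide background
# with a one-sided Poisson test + Benjamini-Hochberg correction.

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

cigar_runs <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(lens = lens, ops = ops)
}

# query length incl. hard clips; terminal S/H runs as clips
cigar_features <- function(cigar) {
  r <- cigar_runs(cigar)
  qlen <- sum(r$lens[r$ops %in% c("M", "I", "S", "H", "=", "X")])
  nr <- length(r$ops)
  left <- if (r$ops[1] %in% c("S", "H")) r$lens[1] else 0L
  right <- if (nr > 1 && r$ops[nr] %in% c("S", "H")) r$lens[nr] else 0L
  c(qlen, left, right)
}

#' Parse SAM text into clip/chimera features
#'
#' Consumes a SAM subset (FLAG, RNAME, POS, CIGAR, optional `SA:Z` tag).
#' One feature record is produced per alignment line; unmapped reads
#' (FLAG 0x4) are skipped with their count reported in a message, and
#' secondary alignments (0x100) are skipped. A record is `is_clipped` iff a
#' terminal soft/hard-clip CIGAR run is at least `min_clip` bp, and
#' `is_chimeric` iff it carries an `SA:Z` tag or the supplementary flag
#' (0x800).
#'
#' @param input A file path or character vector of SAM lines.
#' @param min_clip Minimum terminal clip length, bp (default 20).
#' @return A data.frame: `chrom`, `pos`, `read_length`, `left_clip`,
#'   `right_clip`, `is_clipped`, `is_chimeric`.
#' @export
parse_alignments <- function(input, min_clip = 20L) {
  if (min_clip < 1) stop("min_clip must be >= 1")
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input)
  } else {
    input
  }
  body_idx <- which(!startsWith(lines, "@") & lines != "")
  n_unmapped <- 0L
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      stop("malformed SAM line ", ln, ": expected >= 11 fields, got ", length(f))
    }
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("malformed SAM line ", ln, ": FLAG is not an integer")
    if (bitwAnd(flag, 4L) > 0L) { n_unmapped <- n_unmapped + 1L; next }
    if (bitwAnd(flag, 256L) > 0L) next
    cigar <- f[6]
    if (cigar == "*" || !grepl(CIGAR_RE, cigar)) {
      stop("unparsable CIGAR '", cigar, "' at SAM line ", ln)
    }
    cf <- cigar_features(cigar)
    chim <- bitwAnd(flag, 2048L) > 0L || any(startsWith(f[-(1:11)], "SA:Z:"))
    rows[[k]] <- data.frame(chrom = f[3], pos = as.integer(f[4]),
                            read_length = cf[1], left_clip = cf[2],
                            right_clip = cf[3], is_chimeric = chim,
                            stringsAsFactors = FALSE)
  }
  if (n_unmapped > 0L) message("skipped ", n_unmapped, " unmapped read(s)")
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(), pos = integer(), read_length = integer(),
               left_clip = integer(), right_clip = integer(),
               is_chimeric = logical(), stringsAsFactors = FALSE)
  }
  out$is_clipped <- pmax(out$left_clip, out$right_clip) >= min_clip
  rownames(out) <- NULL
  out[, c("chrom", "pos", "read_length", "left_clip", "right_clip",
          "is_clipped", "is_chimeric")]
}

#' Derive clip features from simulated alignments
#'
#' Applies the same `min_clip` rule as [parse_alignments()] directly to a
#' [simulate_breakpoint_alignments()] table, avoiding a SAM round trip.
#'
#' @param aln A `sim_alignments` data.frame.
#' @param min_clip Minimum terminal clip length, bp.
#' @return A feature data.frame as from [parse_alignments()].
#' @export
as_clip_features <- function(aln, min_clip = 20L) {
  out <- as.data.frame(aln)
  out$is_clipped <- pmax(out$left_clip, out$right_clip) >= min_clip
  out[, c("chrom", "pos", "read_length", "left_clip", "right_clip",
          "is_clipped", "is_chimeric")]
}

#' Count clip/chimera features per genomic window
#'
#' Windows of `window_size` bp tile every chromosome of the map, half-open
#' `[start, end)` in 1-based coordinates; each feature is assigned to the
#' window containing its leftmost mapped base, so totals are conserved.
#'
#' @param features Output of [parse_alignments()] or [as_clip_features()].
#' @param window_size Window size, bp (default 1000, the scale of the
#'   clipped/chimeric read cluster expected upstream of a breakpoint).
#' @param map A `genetic_map`.
#' @return A `clip_windows` data.frame: `chrom`, `start`, `end`, `n_reads`,
#'   `n_clipped`, `n_chimeric`.
#' @export
window_counts <- function(features, window_size = 1000L, map = build_map()) {
  if (window_size < 1) stop("window_size must be >= 1")
  window_size <- as.integer(window_size)
  unknown <- setdiff(unique(features$chrom), map$chrom)
  if (length(unknown)) {
    warning("dropping features on chromosome(s) not in the map: ",
            paste(unknown, collapse = ", "))
    features <- features[features$chrom %in% map$chrom, , drop = FALSE]
  }
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    ch <- map$chrom[i]
    P <- as.integer(map$physical_length[i])
    nw <- as.integer(ceiling(P / window_size))
    f <- features[features$chrom == ch, , drop = FALSE]
    bad <- f$pos < 1L | f$pos > P
    if (any(bad)) {
      warning(sum(bad), " feature(s) outside chromosome ", ch, " dropped")
      f <- f[!bad, , drop = FALSE]
    }
    idx <- (f$pos - 1L) %/% window_size + 1L
    start <- (seq_len(nw) - 1L) * window_size + 1L
    out[[i]] <- data.frame(
      chrom = ch, start = start, end = pmin(start + window_size, P + 1L),
      n_reads = tabulate(idx, nw),
      n_clipped = tabulate(idx[f$is_clipped], nw),
      n_chimeric = tabulate(idx[f$is_chimeric], nw),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("clip_windows", "data.frame")
  res
}

#' Flag windows enriched for clipped/chimeric reads
#'
#' For each window the pooled signature count `n_clipped + n_chimeric` is
#' tested against a Poisson expectation of `background * n_reads` (one-sided
#' upper tail); `background` defaults to the genome-wide signature rate of
#' the input. P-values are Benjamini-Hochberg adjusted across covered
#' windows and a window is flagged iff its adjusted p-value is at most
#' `alpha` and it carries at least one signature read. The threshold rule --
#' what counts as "a large number" of clipped/chimeric reads -- is a design
#' decision of this package, exposed through `alpha` and `background`.
#'
#' @param stats A `clip_windows` data.frame from [window_counts()].
#' @param alpha FDR threshold in (0, 1]; default 0.05. At `alpha = 1` every
#'   window carrying at least one signature read is flagged.
#' @param background Optional per-read signature rate; `NULL` estimates it
#'   from the data.
#' @return `stats` with `p_value`, `p_adj` and `flagged` columns.
#' @export
flag_windows <- function(stats, alpha = 0.05, background = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  x <- stats$n_clipped + stats$n_chimeric
  total_reads <- sum(stats$n_reads)
  if (total_reads == 0) {
    warning("no covered windows: nothing to flag")
    stats$p_value <- 1
    stats$p_adj <- 1
    stats$flagged <- FALSE
    return(stats)
  }
  if (is.null(background)) background <- sum(x) / total_reads
  covered <- stats$n_reads > 0
  p <- rep(1, nrow(stats))
  lambda <- background * stats$n_reads[covered]
  p[covered] <- stats::ppois(x[covered] - 1L, lambda, lower.tail = FALSE)
  padj <- rep(1, nrow(stats))
  padj[covered] <- stats::p.adjust(p[covered], method = "BH")
  stats$p_value <- p
  stats$p_adj <- padj
  stats$flagged <- padj <= alpha & x > 0
  if (!any(stats$flagged) && sum(x) == 0) {
    warning("no clipped or chimeric reads observed")
  }
  stats
}

#' Write flagged windows as BED and the full table as TSV
#'
#' BED rows are 0-based half-open, per BED convention.
#'
#' @param stats Output of [flag_windows()].
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the flagged subset.
#' @export
write_scan_results <- function(stats, bed_path = NULL, tsv_path = NULL) {
  fl <- stats[stats$flagged, , drop = FALSE]
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = fl$chrom, start = fl$start - 1L,
                      end = fl$end - 1L,
                      name = sprintf("clip_window_%d", seq_len(nrow(fl))),
                      score = round(-10 * log10(pmax(fl$p_adj, 1e-30))))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(stats, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fl)
}
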