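# Synthetic alignments around a planted structural-variant breakpoint, and a
# SAM-text writer for them. Read sequences are not modeled (SEQ/QUAL are
# "*"); only the mapping geometry that the clip/chimera scan consumes.

#' Simulate read alignments around a planted breakpoint
#'
#' Reads are placed uniformly over the region at the requested mean depth.
#' A read spanning `breakpoint_pos` is soft-clipped at the breakpoint with
#' probability `clip_fraction` -- anchored on the left or the right of the
#' break with equal probability, the unanchored part becoming the clip --
#' and flagged chimeric (split alignment) with probability
#' `chimera_fraction`. All other reads are clipped with probability
#' `background_clip_rate` at a uniform offset, emulating the genome-wide
#' noise floor of clip artifacts.
#'
#' @param depth Mean read depth per position; default 30 (a typical
#'   whole-genome sequencing design).
#' @param read_length Read length, bp; default 100.
#' @param region List or vector with `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @param breakpoint_pos Breakpoint position, inside the region, or `NULL`
#'   for pure background.
#' @param clip_fraction,chimera_fraction Probabilities in `[0, 1]` applied
#'   to breakpoint-spanning reads.
#' @param background_clip_rate Clip probability for non-breakpoint reads.
#' @param seed Optional integer seed.
#' @return A `sim_alignments` data.frame: `chrom`, `pos` (1-based leftmost
#'   mapped base), `read_length`, `left_clip`, `right_clip`, `is_chimeric`.
#' @export
simulate_breakpoint_alignments <- function(depth = 30, read_length = 100L,
                                           region, breakpoint_pos = NULL,
                                           clip_fraction = 0,
                                           chimera_fraction = 0,
                                           background_clip_rate = 0,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region <- as.list(region)
  chrom <- as.character(region$chrom)
  start <- as.integer(region$start)
  end <- as.integer(region$end)
  read_length <- as.integer(read_length)
  if (is.na(start) || is.na(end) || end - start + 1L < read_length) {
    stop("region must be at least one read length long")
  }
  for (f in c(clip_fraction, chimera_fraction, background_clip_rate)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  bp <- NULL
  if (!is.null(breakpoint_pos)) {
    bp <- as.integer(breakpoint_pos)
    if (bp <= start || bp >= end) {
      stop("breakpoint_pos must lie strictly inside the region")
    }
  }
  span <- end - start + 1L
  n <- as.integer(round(depth * span / read_length))
  pos <- start + sample.int(span - read_length + 1L, n, replace = TRUE) - 1L
  left_clip <- integer(n)
  right_clip <- integer(n)
  chimeric <- logical(n)

  spanning <- if (is.null(bp)) rep(FALSE, n) else pos <= bp & pos + read_length - 1L > bp
  if (any(spanning)) {
    idx <- which(spanning)
    do_clip <- stats::runif(length(idx)) < clip_fraction
    anchor_left <- stats::runif(length(idx)) < 0.5
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (do_clip[k]) {
        if (anchor_left[k]) {
          # aligned part ends at the breakpoint; 3' side clipped
          right_clip[i] <- pos[i] + read_length - 1L - bp
        } else {
          # aligned part starts just past the breakpoint; 5' side clipped
          left_clip[i] <- bp - pos[i] + 1L
          pos[i] <- bp + 1L
        }
      }
    }
    chimeric[idx] <- stats::runif(length(idx)) < chimera_fraction
  }
  if (background_clip_rate > 0) {
    bg <- which(!spanning & left_clip == 0L & right_clip == 0L)
    do_bg <- bg[stats::runif(length(bg)) < background_clip_rate]
    if (length(do_bg)) {
      len <- sample.int(read_length - 1L, length(do_bg), replace = TRUE)
      side_left <- stats::runif(length(do_bg)) < 0.5
      left_clip[do_bg[side_left]] <- len[side_left]
      right_clip[do_bg[!side_left]] <- len[!side_left]
    }
  }
  structure(data.frame(chrom = chrom, pos = pos, read_length = read_length,
                       left_clip = left_clip, right_clip = right_clip,
                       is_chimeric = chimeric, stringsAsFactors = FALSE),
            class = c("sim_alignments", "data.frame"))
}

#' Write simulated alignments as SAM text
#'
#' Emits a minimal, valid SAM file: `@HD`/`@SQ` header from the map,
#' soft-clip CIGARs (`<l>S<m>M<r>S`), `SEQ`/`QUAL` as `*`, and an `SA:Z`
#' tag on chimeric reads pointing at a nominal supplementary locus.
#'
#' @param aln A `sim_alignments` data.frame.
#' @param map A `genetic_map` providing reference names and lengths.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, map, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", map$chrom, as.integer(map$physical_length)))
  ord <- order(match(aln$chrom, map$chrom), aln$pos)
  aln <- aln[ord, , drop = FALSE]
  m <- aln$read_length - aln$left_clip - aln$right_clip
  cig <- paste0(ifelse(aln$left_clip > 0L, paste0(aln$left_clip, "S"), ""),
                m, "M",
                ifelse(aln$right_clip > 0L, paste0(aln$right_clip, "S"), ""))
  sa <- ifelse(aln$is_chimeric,
               sprintf("\tSA:Z:%s,%d,+,%dM,60,0;", aln$chrom,
                       pmax(1L, aln$pos - 10000L), m),
               "")
  body <- sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
                  seq_len(nrow(aln)), aln$chrom, aln$pos, cig, sa)
  writeLines(c(hdr, body), path)
  invisible(path)
}
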