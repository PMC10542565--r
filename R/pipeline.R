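# Pipeline orchestration: a single seeded config drives simulate -> filter
# -> svscan -> behavior, with a JSON manifest per run. The default config
# reproduces the study design in silico: a 30-line selfing panel from a
# cross of a reference-like and a divergent founder, one causal variant
# planted on an F1 haplotype, ~30x alignments around an upstream breakpoint,
# and 1 Hz gradient-plate tracks.

#' Default run configuration
#'
#' All tunables of the pipeline in one hierarchical list; [load_config()]
#' merges a YAML file over these defaults. Every random stage derives its
#' own seed stream from the single root `seed`.
#'
#' @param seed Root integer seed.
#' @return A nested list of parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    map = NULL,  # NULL = build_map() default
    panel = list(n_lines = 30L, g_generations = 9L, de_novo_rate = 0.3,
                 xo_model = "haldane"),
    causal = list(chrom = "V", pos = 20064174L, ref = "T", alt = "C",
                  gene = "ttx-1", effect = "missense", label = "defective",
                  penetrance = 1.0),
    scan = list(window = 1000L, min_clip = 20L, alpha = 0.05, depth = 30,
                read_length = 100L, clip_fraction = 0.5,
                chimera_fraction = 0.2, background_clip_rate = 0.01,
                breakpoint_offset = -500L, region_halfwidth = 25000L),
    behavior = list(speed_min = 0.02, angle_band = 45, steepness = 0.5,
                    n_tracks = 15L, n_steps = 2100L, step_length = 0.025,
                    drift_wild = 0.7, drift_defective = 0.5)
  )
}

#' Load a YAML config over the defaults
#'
#' @param path YAML file path (may specify any subset of keys).
#' @return The merged config list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# one derived sub-seed per named stage, all below 2^31
derive_stage_seeds <- function(seed) {
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max - 1L, 5L),
           c("panel", "phenotype", "sv", "tracks", "misc"))
}

#' Default divergent-founder variant set
#'
#' The variant catalog of the divergent parent relative to the reference
#' parent: eight homozygous missense variants spread over the genome (three
#' of them on chromosome V, at increasing linkage distance from the default
#' planted causal locus) and four noncoding variants. The density mirrors
#' the low coding divergence of a laboratory-derived strain pair.
#'
#' @param map A `genetic_map`.
#' @return A [variant_records()] data.frame.
#' @export
default_parent_variants <- function(map = build_map()) {
  v <- variant_records(
    chrom = c("I", "II", "III", "IV", "V", "V", "V", "X",
              "I", "III", "IV", "X"),
    pos = c(4200000L, 9600000L, 11000000L, 1900000L, 6800000L, 14000000L,
            19200000L, 8200000L, 10000000L, 2200000L, 12000000L, 15000000L),
    ref = c("G", "C", "A", "T", "C", "A", "G", "C", "T", "G", "A", "C"),
    alt = c("A", "T", "G", "C", "T", "C", "A", "T", "A", "T", "G", "G"),
    gene = c(sprintf("pcv-%d", 1:8), sprintf("ncv-%d", 1:4)),
    effect = c(rep("missense", 8), rep("noncoding", 4)))
  validate_variants(v, map)
  v
}

study_causal_variant <- function(cfg) {
  variant_records(chrom = cfg$causal$chrom, pos = cfg$causal$pos,
                  ref = cfg$causal$ref, alt = cfg$causal$alt,
                  gene = cfg$causal$gene, effect = cfg$causal$effect)
}

#' Simulate the default in-silico study panel
#'
#' Crosses a reference-like founder ("N2", no variants) with a divergent
#' founder ("CC1", [default_parent_variants()]), plants the configured
#' causal variant on the divergent F1 haplotype, propagates the panel by
#' selfing, and scores phenotypes at the configured penetrance.
#'
#' @param config A [default_config()] list.
#' @return List: `panel` (a `ril_panel`), `phenotypes`
#'   (from [simulate_phenotypes()]), `causal_key` (the planted variant's
#'   `chrom:pos:ref:alt` key), `seeds`.
#' @export
simulate_study <- function(config = default_config()) {
  seeds <- derive_stage_seeds(config$seed)
  map <- if (is.null(config$map)) build_map() else build_map(config$map)
  parent_a <- founder_parent("N2", map = map)
  parent_b <- founder_parent("CC1", default_parent_variants(map), map = map)
  causal <- study_causal_variant(config)
  panel <- generate_ril_panel(parent_a, parent_b,
                              n_lines = config$panel$n_lines,
                              g_generations = config$panel$g_generations,
                              de_novo_rate = config$panel$de_novo_rate,
                              map = map, planted = causal, planted_hap = "b",
                              seed = seeds[["panel"]],
                              xo_model = config$panel$xo_model)
  phen <- simulate_phenotypes(panel,
                              causal_map = setNames(config$causal$label, "planted_1"),
                              penetrance = config$causal$penetrance,
                              seed = seeds[["phenotype"]])
  list(panel = panel, phenotypes = phen, causal_key = variant_key(causal),
       seeds = seeds)
}

#' Candidate recovery on a simulated panel
#'
#' Runs the full inference loop on one simulated study: build the coding
#' presence matrix over a chosen number of informative lines (lines whose
#' phenotype is determinate, sampled to include both phenotype classes),
#' evaluate the segregation filter, and report whether the planted causal
#' variant is among the candidates and how many candidates survive.
#'
#' @param seed Integer seed for this replicate.
#' @param n_informative Number of informative lines to condition on; `NULL`
#'   uses all of them.
#' @param config Base configuration (seed is overridden by `seed`).
#' @return List: `recovered` (logical), `n_candidates`, `candidates`
#'   (data.frame), `n_labeled`, `n_lines_used`.
#' @export
simulate_recovery_study <- function(seed, n_informative = NULL,
                                    config = default_config()) {
  config$seed <- as.integer(seed)
  recover_candidates(simulate_study(config), n_informative, config)
}

#' Evaluate the segregation filter on a simulated study
#'
#' The evaluation half of [simulate_recovery_study()], usable on a
#' precomputed [simulate_study()] result so several conditioning set sizes
#' can be compared on the same panel.
#'
#' @param study Output of [simulate_study()].
#' @param n_informative See [simulate_recovery_study()].
#' @param config The configuration the study was generated with.
#' @return As [simulate_recovery_study()].
#' @export
recover_candidates <- function(study, n_informative = NULL,
                               config = default_config()) {
  st <- study
  phen <- st$phenotypes
  lab <- phen$strain[!phen$indeterminate & phen$phenotype != ""]
  wt <- phen$strain[!phen$indeterminate & phen$phenotype == ""]
  if (!length(lab) || !length(wt)) {
    stop("panel has no informative line in one phenotype class; ",
         "cannot condition the filter")
  }
  if (is.null(n_informative)) {
    use <- c(lab, wt)
  } else {
    k <- as.integer(n_informative)
    k_lab <- min(length(lab), ceiling(k / 2))
    k_wt <- k - k_lab
    if (k_wt > length(wt)) {
      k_wt <- length(wt)
      k_lab <- min(length(lab), k - k_wt)
    }
    if (k_lab < 1L || k_wt < 1L || k_lab + k_wt < k) {
      stop("not enough informative lines for n_informative = ", k)
    }
    use <- c(lab[seq_len(k_lab)], wt[seq_len(k_wt)])
  }
  per_strain <- lapply(setNames(use, use), function(s)
    filter_coding(strain_variants(st$panel, s)))
  m <- build_presence_matrix(per_strain)
  classes <- phenotype_classes(phen$strain, phen$phenotype,
                               indeterminate = phen$indeterminate)
  classes <- classes[classes$strain %in% use, , drop = FALSE]
  rep <- candidate_report(m, classes, masks = character())
  cand <- rep$hypotheses[[config$causal$label]]$candidates
  list(recovered = st$causal_key %in% cand$key, n_candidates = nrow(cand),
       candidates = cand, n_labeled = length(intersect(use, lab)),
       n_lines_used = length(use))
}

## -- stage runners ----------------------------------------------------------

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the simulation stage
#'
#' Writes every input the downstream stages consume: one VCF per line, the
#' panel truth and phenotype TSVs, a SAM of alignments around the planted
#' breakpoint (placed `breakpoint_offset` bp from the causal position), one
#' track CSV per line and animal, and a JSON manifest with stage seeds,
#' parameters and file checksums.
#'
#' @param config A [default_config()] list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly: list with the panel, phenotypes, and file paths.
#' @export
run_simulate <- function(config = default_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  for (d in c("vcf", "tracks")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  st <- simulate_study(config)
  panel <- st$panel; phen <- st$phenotypes; seeds <- st$seeds
  map <- panel$map

  log_stage("simulate", "panel of ", length(panel$lines), " lines")
  vcf_paths <- character(0)
  for (ln in names(panel$lines)) {
    p <- file.path(outdir, "vcf", paste0(ln, ".vcf"))
    write_vcf(strain_variants(panel, ln), p, strain = ln)
    vcf_paths <- c(vcf_paths, p)
  }
  truth_path <- file.path(outdir, "panel_truth.tsv")
  utils::write.table(panel$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phen_path <- file.path(outdir, "phenotypes.tsv")
  utils::write.table(
    data.frame(strain = phen$strain, labels = phen$phenotype, role = "line",
               indeterminate = phen$indeterminate),
    phen_path, sep = "\t", quote = FALSE, row.names = FALSE)

  sc <- config$scan
  bp <- config$causal$pos + sc$breakpoint_offset
  aln <- simulate_breakpoint_alignments(
    depth = sc$depth, read_length = sc$read_length,
    region = list(chrom = config$causal$chrom,
                  start = max(1L, bp - sc$region_halfwidth),
                  end = bp + sc$region_halfwidth),
    breakpoint_pos = bp, clip_fraction = sc$clip_fraction,
    chimera_fraction = sc$chimera_fraction,
    background_clip_rate = sc$background_clip_rate, seed = seeds[["sv"]])
  sam_path <- file.path(outdir, "breakpoint.sam")
  write_sam(aln, map, sam_path)
  log_stage("simulate", "wrote ", nrow(aln), " alignments around ",
            config$causal$chrom, ":", bp)

  bh <- config$behavior
  plate <- default_plate(steepness = bh$steepness)
  set.seed(seeds[["tracks"]])
  track_paths <- character(0)
  defective <- phen$strain[phen$phenotype != ""]
  for (ln in names(panel$lines)) {
    drift <- if (ln %in% defective) bh$drift_defective else bh$drift_wild
    for (k in seq_len(bh$n_tracks)) {
      tr <- simulate_track(drift, n_steps = bh$n_steps,
                           step_length = bh$step_length, plate = plate)
      p <- file.path(outdir, "tracks", sprintf("%s_%02d.csv", ln, k))
      write_track_csv(tr, p)
      track_paths <- c(track_paths, p)
    }
  }
  log_stage("simulate", "wrote ", length(track_paths), " track CSV(s)")

  files <- c(vcf_paths, truth_path, phen_path, sam_path, track_paths)
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   params = config,
                   files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(panel = panel, phenotypes = phen, vcf = vcf_paths,
                 truth = truth_path, phenotype_tsv = phen_path,
                 sam = sam_path, tracks = track_paths,
                 manifest = manifest_path))
}

vcf_strain_name <- function(path) {
  hdr <- grep("^##strain=", readLines(path, n = 50L), value = TRUE)
  if (length(hdr)) sub("^##strain=", "", hdr[1])
  else sub("\\.vcf$", "", basename(path))
}

#' Run the segregation-filter stage
#'
#' Parses per-strain VCFs, reduces to protein-coding variants, builds the
#' presence matrix, and evaluates the candidate hypotheses against the
#' phenotype classes.
#'
#' @param config A config list.
#' @param vcf_paths Character vector of per-strain VCF paths (>= 1).
#' @param phenotype_tsv Phenotype class TSV (see
#'   [read_phenotype_classes()]).
#' @param outdir Output directory for `candidates.tsv` / `candidates.txt`;
#'   `NULL` skips writing.
#' @param include_noncoding Keep noncoding rows in the matrix.
#' @return The [candidate_report()].
#' @export
run_filter <- function(config, vcf_paths, phenotype_tsv, outdir = NULL,
                       include_noncoding = FALSE) {
  if (!length(vcf_paths)) stop("no VCF inputs given")
  classes <- read_phenotype_classes(phenotype_tsv)
  per_strain <- list()
  for (p in vcf_paths) {
    per_strain[[vcf_strain_name(p)]] <- parse_vcf(p)
  }
  missing_cls <- setdiff(names(per_strain), classes$strain)
  if (length(missing_cls)) {
    stop("strain(s) in VCFs but not in the phenotype table: ",
         paste(missing_cls, collapse = ", "))
  }
  m <- build_presence_matrix(per_strain)
  rep <- candidate_report(m, classes, include_noncoding = include_noncoding)
  log_stage("filter", nrow(m$variants), " variants x ", length(m$strains),
            " strains")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_report(rep, file.path(outdir, "candidates.tsv"),
                           file.path(outdir, "candidates.txt"))
  }
  rep
}

#' Run the structural-variant scan stage
#'
#' @param config A config list (uses `scan$min_clip`, `scan$window`,
#'   `scan$alpha`).
#' @param sam_path SAM input.
#' @param outdir Output directory for `flagged.bed` / `windows.tsv`; `NULL`
#'   skips writing.
#' @param map A `genetic_map`.
#' @return The flagged window table from [flag_windows()].
#' @export
run_svscan <- function(config, sam_path, outdir = NULL, map = build_map()) {
  feats <- parse_alignments(sam_path, min_clip = config$scan$min_clip)
  stats <- flag_windows(window_counts(feats, config$scan$window, map),
                        alpha = config$scan$alpha)
  log_stage("svscan", sum(stats$flagged), " window(s) flagged")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_scan_results(stats, file.path(outdir, "flagged.bed"),
                       file.path(outdir, "windows.tsv"))
  }
  stats
}

#' Run the behavior stage
#'
#' Reads track CSVs, computes the thermotaxis bias per track, and
#' aggregates by strain (tracks are grouped by the file-name prefix before
#' the final underscore).
#'
#' @param config A config list (uses `behavior$speed_min`,
#'   `behavior$angle_band`).
#' @param track_paths Track CSV paths.
#' @param outdir Output directory for `bias_per_track.tsv` /
#'   `bias_by_strain.tsv`; `NULL` skips writing.
#' @return List: `per_track` and `by_strain` data.frames.
#' @export
run_behavior <- function(config, track_paths, outdir = NULL) {
  if (!length(track_paths)) stop("no track inputs given")
  rows <- lapply(track_paths, function(p) {
    tr <- read_track_csv(p)
    b <- thermotaxis_bias(tr, speed_min = config$behavior$speed_min,
                          angle_band = config$behavior$angle_band)
    strain <- sub("_[^_]*$", "", sub("\\.csv$", "", basename(p)))
    data.frame(file = basename(p), strain = strain, bias = b$bias,
               t_toward_cold = b$t_toward_cold,
               t_toward_warm = b$t_toward_warm, t_neutral = b$t_neutral,
               stringsAsFactors = FALSE)
  })
  per_track <- do.call(rbind, rows)
  rownames(per_track) <- NULL
  agg <- split(per_track$bias, per_track$strain)
  by_strain <- data.frame(
    strain = names(agg),
    n_tracks = vapply(agg, length, integer(1)),
    mean_bias = vapply(agg, mean, numeric(1)),
    sem_bias = vapply(agg, function(b)
      if (length(b) > 1) stats::sd(b) / sqrt(length(b)) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(by_strain) <- NULL
  log_stage("behavior", nrow(per_track), " track(s), ", nrow(by_strain),
            " strain(s)")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(per_track, file.path(outdir, "bias_per_track.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(by_strain, file.path(outdir, "bias_by_strain.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(per_track = per_track, by_strain = by_strain)
}

#' Reproduce the published candidate inference from the packaged table
#'
#' Runs [candidate_report()] on [table1_fixture()] with
#' [study_phenotype_classes()] and prints the result: the circling
#' hypothesis yields the 12 variants shared by the two circling strains
#' (among them the *ttx-1* missense change), the thermotaxis-only
#' hypothesis yields exactly the *efn-4* variant, and the parental-masking
#' hypothesis yields nothing.
#'
#' @param outdir Optional directory for `candidates.tsv` / `candidates.txt`.
#' @param quiet Suppress printing.
#' @return The [candidate_report()], invisibly.
#' @export
reproduce_table1 <- function(outdir = NULL, quiet = FALSE) {
  rep <- candidate_report(table1_fixture(), study_phenotype_classes())
  if (!quiet) print(rep)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_report(rep, file.path(outdir, "candidates.tsv"),
                           file.path(outdir, "candidates.txt"))
  }
  invisible(rep)
}
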