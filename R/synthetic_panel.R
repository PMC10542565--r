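# RIL panel simulator: meiosis under a Poisson-crossover model, repeated
# self-fertilization with single-individual transfer, de novo mutation, and
# phenotype assignment from planted causal variants.

rbind_variants <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (!length(lst)) return(empty_variants(with_id = TRUE))
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Simulate one gamete (meiotic product) of a diploid genotype
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' genetic length in Morgans (Haldane model, no interference) or exactly one
#' (`xo_model = "obligate"`, approximating the near-complete crossover
#' interference of *C. elegans*). Crossover positions are uniform in genetic
#' distance; the starting haplotype is chosen fairly. De novo variants
#' carried on a parental haplotype are transmitted with the segment that
#' carries them.
#'
#' @param genotype A [strain_genotype()].
#' @param map The `genetic_map` the genotype is defined over.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param xo_model `"haldane"` (default) or `"obligate"`.
#' @return A `haplotype`.
#' @export
simulate_gamete <- function(genotype, map, seed = NULL,
                            xo_model = c("haldane", "obligate")) {
  xo_model <- match.arg(xo_model)
  if (!is.null(seed)) set.seed(seed)
  segs <- vector("list", nrow(map))
  names(segs) <- map$chrom
  iv <- vector("list", nrow(map))
  names(iv) <- map$chrom
  for (i in seq_len(nrow(map))) {
    chrom <- map$chrom[i]
    P <- as.integer(map$physical_length[i])
    G <- map$genetic_length[i]
    n_xo <- if (xo_model == "haldane") stats::rpois(1L, G / 100) else 1L
    if (n_xo > 0L && P > 1L) {
      xo_g <- sort(stats::runif(n_xo, 0, G))
      xo_p <- as.integer(round_half_up(1 + xo_g / G * (P - 1)))
      xo_p <- unique(pmin(pmax(xo_p, 1L), P - 1L))
    } else {
      xo_p <- integer(0)
    }
    starts <- c(1L, xo_p + 1L)
    ends <- c(xo_p, P)
    first <- sample(c("a", "b"), 1L)
    src <- rep_len(c(first, setdiff(c("a", "b"), first)), length(starts))
    ha <- genotype$hap_a$segments[[chrom]]
    hb <- genotype$hap_b$segments[[chrom]]
    # vector-level interval clipping: data.frame churn here dominates panel
    # simulation cost, so one data.frame is built per chromosome at the end
    acc_s <- vector("list", length(starts))
    acc_e <- vector("list", length(starts))
    acc_o <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      h <- if (src[k] == "a") ha else hb
      keep <- which(h$end >= starts[k] & h$start <= ends[k])
      acc_s[[k]] <- pmax(h$start[keep], starts[k])
      acc_e[[k]] <- pmin(h$end[keep], ends[k])
      acc_o[[k]] <- h$origin[keep]
    }
    s <- unlist(acc_s, use.names = FALSE)
    e <- unlist(acc_e, use.names = FALSE)
    o <- unlist(acc_o, use.names = FALSE)
    r <- rle(o)
    idx_end <- cumsum(r$lengths)
    idx_start <- c(1L, head(idx_end, -1L) + 1L)
    segs[[chrom]] <- list(start = s[idx_start], end = e[idx_end],
                          origin = r$values)
    iv[[chrom]] <- list(starts = starts, src = src)
  }
  vs <- vector("list", 2L)
  for (h in c("a", "b")) {
    v <- genotype[[paste0("hap_", h)]]$variants
    if (nrow(v)) {
      keep <- vapply(seq_len(nrow(v)), function(j) {
        z <- iv[[v$chrom[j]]]
        z$src[findInterval(v$pos[j], z$starts)] == h
      }, logical(1))
      vs[[if (h == "a") 1L else 2L]] <- v[keep, , drop = FALSE]
    }
  }
  new_haplotype(segs, rbind_variants(vs))
}

#' Self-fertilize a genotype for one generation
#'
#' The offspring is the union of two independent gametes drawn from the same
#' parent -- the single-individual-transfer regime of RIL propagation in a
#' selfing hermaphrodite. Expected marker-wise heterozygosity halves each
#' generation.
#'
#' @inheritParams simulate_gamete
#' @param name Offspring name (defaults to the parent's).
#' @return A `strain_genotype`.
#' @export
self_cross <- function(genotype, map, seed = NULL,
                       xo_model = c("haldane", "obligate"), name = genotype$name) {
  xo_model <- match.arg(xo_model)
  if (!is.null(seed)) set.seed(seed)
  strain_genotype(name,
                  simulate_gamete(genotype, map, xo_model = xo_model),
                  simulate_gamete(genotype, map, xo_model = xo_model))
}

#' Declare a founder parent
#'
#' A founder parent is a fully homozygous strain: a name plus the set of
#' variants (relative to the reference) fixed in its genome. Parental
#' variants are carried by descent: a derived line carries a parental
#' variant wherever a haplotype segment of that parent's origin covers the
#' variant position.
#'
#' @param name Parent strain label.
#' @param variants A [variant_records()] data.frame (possibly empty).
#' @param map The `genetic_map` (used for validation).
#' @return A `ril_parent` object.
#' @export
founder_parent <- function(name, variants = empty_variants(), map = build_map()) {
  if (nrow(variants)) validate_variants(variants, map)
  structure(list(name = name, variants = variants), class = "ril_parent")
}

EFFECT_PROBS <- c(noncoding = 0.70, synonymous = 0.10, missense = 0.15,
                  nonsense = 0.02, indel = 0.03)

draw_de_novo <- function(n, map, occupied, line, gen, counter) {
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    repeat {
      ci <- sample.int(nrow(map), 1L, prob = map$physical_length)
      chrom <- map$chrom[ci]
      pos <- sample.int(as.integer(map$physical_length[ci]), 1L)
      if (!pos %in% occupied[[chrom]]) break
    }
    occupied[[chrom]] <- c(occupied[[chrom]], pos)
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    eff <- sample(names(EFFECT_PROBS), 1L, prob = EFFECT_PROBS)
    id <- sprintf("dn_%s_g%d_%d", line, gen, counter + k)
    rows[[k]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            gene = sprintf("novel_%s", id), effect = eff,
                            id = id, stringsAsFactors = FALSE)
  }
  list(variants = rbind_variants(rows), occupied = occupied)
}

#' Generate a panel of recombinant inbred lines by selfing
#'
#' Starting from the F1 of a cross between two homozygous founder parents,
#' each line is an independent lineage propagated by single-individual
#' transfer: at every generation one offspring is formed from two gametes of
#' the current individual. Generations count selfing steps from the F1
#' (F2 = 1); the published panel design -- F2 founders selfed for a further
#' 8 generations -- corresponds to `g_generations = 9`. De novo mutation
#' events are drawn Poisson(`de_novo_rate`) per transmitted gamete per
#' generation, placed uniformly on the physical map, and tracked to their
#' final zygosity (`het`, `hom_alt`, or `lost`) in the returned truth table.
#' Variants in `planted` are placed on one F1 haplotype (generation 0) and
#' segregate through every line -- the "spontaneous causal variant"
#' scenario.
#'
#' @param parent_a,parent_b [founder_parent()] objects with distinct names.
#' @param n_lines Number of independent lines (>= 1); default 30.
#' @param g_generations Selfing generations from the F1 (>= 1); default 9.
#' @param de_novo_rate Expected de novo mutations per transmitted gamete per
#'   generation; default 0.3.
#' @param map A `genetic_map`.
#' @param planted Optional [variant_records()] data.frame of causal variants
#'   planted on the F1 haplotype named by `planted_hap`.
#' @param planted_hap `"a"` or `"b"`: which F1 haplotype carries `planted`.
#' @param seed Optional integer seed.
#' @param xo_model Crossover model, see [simulate_gamete()].
#' @return A `ril_panel`: list with `lines` (named list of
#'   [strain_genotype()]), `truth` (data.frame: line, id, chrom, pos, ref,
#'   alt, gene, effect, generation, planted, zygosity), `parents`, `map`,
#'   and `params`.
#' @export
generate_ril_panel <- function(parent_a, parent_b, n_lines = 30L,
                               g_generations = 9L, de_novo_rate = 0.3,
                               map = build_map(), planted = NULL,
                               planted_hap = c("b", "a"), seed = NULL,
                               xo_model = c("haldane", "obligate")) {
  xo_model <- match.arg(xo_model)
  planted_hap <- match.arg(planted_hap)
  if (n_lines < 1L || g_generations < 1L) {
    stop("n_lines and g_generations must both be >= 1")
  }
  if (de_novo_rate < 0) stop("de_novo_rate must be >= 0")
  if (identical(parent_a$name, parent_b$name)) stop("parents must have distinct names")
  if (!is.null(seed)) set.seed(seed)

  planted_v <- empty_variants(with_id = TRUE)
  if (!is.null(planted) && nrow(planted)) {
    validate_variants(planted, map)
    planted_v <- planted
    planted_v$id <- sprintf("planted_%d", seq_len(nrow(planted)))
  }
  f1_a <- founder_haplotype(map, parent_a$name)
  f1_b <- founder_haplotype(map, parent_b$name)
  if (nrow(planted_v)) {
    if (planted_hap == "a") f1_a$variants <- planted_v else f1_b$variants <- planted_v
  }
  f1 <- strain_genotype("F1", f1_a, f1_b)

  occupied0 <- lapply(setNames(map$chrom, map$chrom), function(ch) {
    c(parent_a$variants$pos[parent_a$variants$chrom == ch],
      parent_b$variants$pos[parent_b$variants$chrom == ch],
      planted_v$pos[planted_v$chrom == ch])
  })

  lines <- vector("list", n_lines)
  names(lines) <- sprintf("RIL%03d", seq_len(n_lines))
  truth_rows <- list()

  for (li in seq_len(n_lines)) {
    ln <- names(lines)[li]
    cur <- f1
    occupied <- occupied0
    counter <- 0L
    events <- list()
    for (gen in seq_len(g_generations)) {
      gam <- list(simulate_gamete(cur, map, xo_model = xo_model),
                  simulate_gamete(cur, map, xo_model = xo_model))
      if (de_novo_rate > 0) {
        for (gi in 1:2) {
          n_mut <- stats::rpois(1L, de_novo_rate)
          if (n_mut > 0L) {
            dn <- draw_de_novo(n_mut, map, occupied, ln, gen, counter)
            occupied <- dn$occupied
            counter <- counter + n_mut
            ev <- dn$variants
            ev$generation <- gen
            events[[length(events) + 1L]] <- ev
            gam[[gi]]$variants <- rbind_variants(list(gam[[gi]]$variants, dn$variants))
          }
        }
      }
      cur <- strain_genotype(ln, gam[[1L]], gam[[2L]])
    }
    lines[[li]] <- cur

    ids_a <- cur$hap_a$variants$id
    ids_b <- cur$hap_b$variants$id
    zyg_of <- function(id) {
      ina <- id %in% ids_a; inb <- id %in% ids_b
      ifelse(ina & inb, "hom_alt", ifelse(ina | inb, "het", "lost"))
    }
    ev <- rbind_variants(events)
    if (nrow(ev)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        line = ln, id = ev$id, chrom = ev$chrom, pos = ev$pos, ref = ev$ref,
        alt = ev$alt, gene = ev$gene, effect = ev$effect,
        generation = ev$generation, planted = FALSE,
        zygosity = zyg_of(ev$id), stringsAsFactors = FALSE)
    }
    if (nrow(planted_v)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        line = ln, id = planted_v$id, chrom = planted_v$chrom,
        pos = planted_v$pos, ref = planted_v$ref, alt = planted_v$alt,
        gene = planted_v$gene, effect = planted_v$effect, generation = 0L,
        planted = TRUE, zygosity = zyg_of(planted_v$id), stringsAsFactors = FALSE)
    }
  }

  truth <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows); rownames(out) <- NULL; out
  } else {
    data.frame(line = character(), id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               gene = character(), effect = character(), generation = integer(),
               planted = logical(), zygosity = character(), stringsAsFactors = FALSE)
  }

  structure(list(lines = lines, truth = truth,
                 parents = list(a = parent_a, b = parent_b), map = map,
                 params = list(n_lines = n_lines, g_generations = g_generations,
                               de_novo_rate = de_novo_rate, xo_model = xo_model)),
            class = "ril_panel")
}

#' @export
print.ril_panel <- function(x, ...) {
  cat("<ril_panel>", length(x$lines), "lines,", x$params$g_generations,
      "selfing generations,", nrow(x$truth), "tracked de novo record(s)\n")
  invisible(x)
}

#' Variant calls carried by one line of a panel
#'
#' Returns the variant set a sequencing + calling pipeline would report for
#' the line: parental variants covered by a segment of the corresponding
#' origin on either haplotype, plus de novo variants not lost from the
#' lineage. Presence is binary; zygosity is retained only in the panel truth
#' table.
#'
#' @param panel A `ril_panel`.
#' @param line Line name (an element of `names(panel$lines)`).
#' @return A variant data.frame with an additional `source` column
#'   (`parental_<name>` or `de_novo`).
#' @export
strain_variants <- function(panel, line) {
  g <- panel$lines[[line]]
  if (is.null(g)) stop("unknown line: ", line)
  out <- list()
  for (p in panel$parents) {
    pv <- p$variants
    if (nrow(pv)) {
      present <- vapply(seq_len(nrow(pv)), function(j) {
        hap_origin_at(g$hap_a, pv$chrom[j], pv$pos[j]) == p$name ||
          hap_origin_at(g$hap_b, pv$chrom[j], pv$pos[j]) == p$name
      }, logical(1))
      if (any(present)) {
        sub <- pv[present, , drop = FALSE]
        sub$id <- variant_key(sub)
        sub$source <- paste0("parental_", p$name)
        out[[length(out) + 1L]] <- sub
      }
    }
  }
  dn <- rbind_variants(list(g$hap_a$variants, g$hap_b$variants))
  if (nrow(dn)) {
    dn <- dn[!duplicated(dn$id), , drop = FALSE]
    dn$source <- "de_novo"
    out[[length(out) + 1L]] <- dn
  }
  if (!length(out)) {
    v <- empty_variants(with_id = TRUE); v$source <- character(); return(v)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, panel$map$chrom), res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign phenotypes from causal variants
#'
#' A line is labeled with a phenotype iff it is homozygous for the mapped
#' causal variant, with the stated penetrance. Lines heterozygous for a
#' causal variant still segregate the phenotype on the plate and are flagged
#' `indeterminate`: downstream segregation filters leave them unconstrained
#' rather than scoring them wild-type.
#'
#' @param panel A `ril_panel`.
#' @param causal_map Named character vector: names are variant ids from
#'   `panel$truth` (e.g. `"planted_1"`), values are phenotype labels.
#' @param penetrance Probability a homozygous line expresses the label;
#'   default 1.
#' @param seed Optional integer seed (used only when `penetrance < 1`).
#' @return data.frame with columns `strain`, `phenotype` (`;`-joined labels,
#'   `""` = wild-type) and `indeterminate`.
#' @export
simulate_phenotypes <- function(panel, causal_map = character(), penetrance = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(causal_map)) {
    missing_ids <- setdiff(names(causal_map), panel$truth$id)
    if (length(missing_ids)) {
      stop("causal variant(s) absent from panel truth: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  strains <- names(panel$lines)
  phen <- character(length(strains))
  indet <- logical(length(strains))
  for (i in seq_along(strains)) {
    labels <- character(0)
    if (length(causal_map)) {
      tr <- panel$truth[panel$truth$line == strains[i] &
                          panel$truth$id %in% names(causal_map), , drop = FALSE]
      for (j in seq_len(nrow(tr))) {
        if (tr$zygosity[j] == "hom_alt") {
          if (stats::runif(1) <= penetrance) {
            labels <- c(labels, unname(causal_map[[tr$id[j]]]))
          }
        } else if (tr$zygosity[j] == "het") {
          indet[i] <- TRUE
        }
      }
    }
    phen[i] <- paste(unique(labels), collapse = ";")
  }
  data.frame(strain = strains, phenotype = phen, indeterminate = indet,
             stringsAsFactors = FALSE)
}
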