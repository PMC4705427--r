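# Synthetic fixtures with planted, recorded ground truth. Every generator is
# a pure function of (parameters, seed): the RNG state of the caller is left
# untouched, and the same call reproduces byte-identical outputs.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

write_manifest <- function(dir, name, params) {
  yaml::write_yaml(params, file.path(dir, paste0(name, "_manifest.yaml")))
}

#' Generate a synthetic gene annotation with promoters
#'
#' Places non-overlapping gene bodies with random strand on a small genome
#' and derives a strand-aware promoter window around each TSS. Stands in for
#' a reference annotation plus promoter database in pipeline tests.
#'
#' @param n_genes Number of genes (>= 1).
#' @param genome_size Length of each chromosome in bp.
#' @param seed Integer RNG seed; the same seed reproduces identical output.
#' @param chroms Chromosome names over which genes are distributed evenly.
#' @param gene_length Two-element range of gene-body lengths (bp).
#' @param promoter_window `c(upstream, downstream)` extent of the promoter
#'   around the TSS in bp, applied strand-aware (default 1000 bp upstream,
#'   200 bp downstream).
#' @param dir Optional directory: writes `annotation.tsv`, `promoters.bed`,
#'   `chrom.sizes` and a YAML manifest.
#' @return A list with `genes` (data.frame: gene_id, chrom, start, end,
#'   strand, tss; 0-based half-open, `tss` a 0-based position), `promoters`
#'   (`GRanges` named by gene), `chrom_sizes`, and `params`.
#' @export
generate_annotation <- function(n_genes, genome_size, seed,
                                chroms = c("chr1", "chr2"),
                                gene_length = c(2000, 10000),
                                promoter_window = c(1000, 200),
                                dir = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  with_seed(seed, {
    per_chrom <- table(rep(chroms, length.out = n_genes))
    rows <- list()
    gi <- 0L
    for (ch in names(per_chrom)) {
      k <- as.integer(per_chrom[[ch]])
      lens <- sample(gene_length[1]:gene_length[2], k, replace = TRUE)
      free <- genome_size - sum(lens)
      if (free < k + 1) {
        stop("genome too small to place ", k, " genes of total length ",
             sum(lens), " on ", ch, " (", genome_size, " bp)")
      }
      cuts <- sort(stats::runif(k, 0, free))
      gaps <- diff(c(0, cuts))
      starts <- cumsum(gaps) + c(0, cumsum(lens))[seq_len(k)]
      starts <- as.integer(floor(starts))
      strands <- sample(c("+", "-"), k, replace = TRUE)
      rows[[ch]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi + seq_len(k)),
        chrom = ch, start = starts, end = starts + lens,
        strand = strands, stringsAsFactors = FALSE)
      gi <- gi + k
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    up <- promoter_window[1]; down <- promoter_window[2]
    prom_start <- ifelse(genes$strand == "+", genes$tss - up,
                         genes$tss - down + 1L)
    prom_end <- ifelse(genes$strand == "+", genes$tss + down,
                       genes$tss + up + 1L)
    prom_start <- pmax(prom_start, 0L)
    promoters <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(prom_start + 1L, prom_end))
    S4Vectors::mcols(promoters)$name <- genes$gene_id
    chrom_sizes <- stats::setNames(rep(as.integer(genome_size),
                                       length(chroms)), chroms)
    params <- list(generator = "generate_annotation", n_genes = n_genes,
                   genome_size = genome_size, seed = seed, chroms = chroms,
                   gene_length = gene_length,
                   promoter_window = promoter_window)
    out <- list(genes = genes, promoters = promoters,
                chrom_sizes = chrom_sizes, params = params)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_annotation(genes, file.path(dir, "annotation.tsv"))
      write_bed(promoters, file.path(dir, "promoters.bed"))
      utils::write.table(data.frame(names(chrom_sizes), chrom_sizes),
                         file.path(dir, "chrom.sizes"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      write_manifest(dir, "annotation", params)
    }
    out
  })
}

#' Generate a two-condition, three-assay binding experiment
#'
#' Plants non-overlapping regions carrying one of three response classes and
#' samples read pileups consistent with them. Group I regions gain both
#' transcription-factor (TF) and histone (H3K27ac) signal on induction,
#' Group II gain TF signal only, Group III are unchanged. Read counts per
#' region are Poisson around the planted means; reads are fixed-length
#' intervals placed uniformly within their region.
#'
#' @param n_regions_per_group Named counts `c(I=, II=, III=)`.
#' @param depth Baseline mean reads per region per assay in the uninduced
#'   condition; induced means are `depth * fold`.
#' @param fold_pu1,fold_h3k27ac Planted induction fold changes (> 1).
#' @param seed Integer RNG seed.
#' @param genome_size,chroms Genome to place regions on.
#' @param region_width Range of region widths (bp).
#' @param read_length Read length (bp).
#' @param peak_call_min Planted mean at or above which a region is emitted
#'   as a called peak in that assay/condition.
#' @param hist_abs_min Absolute induced histone read floor the downstream
#'   classifier will apply; if `depth * fold_h3k27ac` falls below it the
#'   planted Group I regions cannot satisfy the classifier and the function
#'   warns and flags the truth record.
#' @param cebpa_bound_frac Named fractions of each group's regions also
#'   bound by the co-factor CEBPA (condition-invariant means).
#' @param background Background-read multiplier. Each assay's two
#'   libraries are padded with uniformly placed background reads up to
#'   `(1 + background) * max(planted condition totals)`, emulating real
#'   ChIP libraries, which are mostly background and sequenced to
#'   comparable depth in both conditions. Without this padding, a global
#'   gain in planted signal would inflate the induced library size and the
#'   per-million normalisation would cancel the planted fold changes.
#' @param annotation Optional result of [generate_annotation()]; when given
#'   with `placement = "group_biased"`, Group III regions are placed inside
#'   promoter windows and Groups I/II in gene-free intergenic space,
#'   emulating the enhancer bias of induced binding.
#' @param placement `"random"` or `"group_biased"`.
#' @param dir Optional output directory for BED/TSV fixtures + manifest.
#' @return A list: `regions` (`GRanges` with `region_id`), `peaks` (nested
#'   list `[assay][condition]` of `GRanges`), `reads` (list
#'   `<assay>_<condition>` of read `GRanges`), `truth` (data.frame with
#'   planted group and means per region), `library_sizes`, `params`.
#' @export
generate_binding_experiment <- function(n_regions_per_group = c(I = 150, II = 300, III = 250),
                                        depth = 50,
                                        fold_pu1 = 8, fold_h3k27ac = 8,
                                        seed = 1,
                                        genome_size = 5e6,
                                        chroms = c("chr1", "chr2"),
                                        region_width = c(200, 800),
                                        read_length = 50,
                                        peak_call_min = 10,
                                        hist_abs_min = 50,
                                        cebpa_bound_frac = c(I = 0.5, II = 0.25, III = 0.5),
                                        background = 1,
                                        annotation = NULL,
                                        placement = c("random", "group_biased"),
                                        dir = NULL) {
  placement <- match.arg(placement)
  stopifnot(all(c("I", "II", "III") %in% names(n_regions_per_group)))
  if (fold_pu1 < 1 || fold_h3k27ac < 1) stop("folds must be >= 1")
  infeasible <- depth * fold_h3k27ac < hist_abs_min
  if (infeasible) {
    warning("expected induced histone count (", depth * fold_h3k27ac,
            ") is below the absolute floor (", hist_abs_min,
            "); planted Group I regions will not be recoverable")
  }
  with_seed(seed, {
    n_tot <- sum(n_regions_per_group)
    groups <- rep(c("I", "II", "III"), times = n_regions_per_group[c("I", "II", "III")])
    widths <- sample(region_width[1]:region_width[2], n_tot, replace = TRUE)

    if (placement == "group_biased") {
      if (is.null(annotation)) stop("group_biased placement needs an annotation")
      regions <- place_biased(groups, widths, annotation)
      chroms <- union(chroms, GenomeInfoDb::seqlevels(regions))
    } else {
      regions <- place_random(n_tot, widths, genome_size, chroms)
    }
    GenomeInfoDb::seqlevels(regions) <- chroms
    S4Vectors::mcols(regions)$region_id <- sprintf("region_%05d", seq_len(n_tot))

    mean_tf_minus <- rep(depth, n_tot)
    mean_tf_plus <- ifelse(groups %in% c("I", "II"), depth * fold_pu1, depth)
    mean_hist_minus <- rep(depth, n_tot)
    mean_hist_plus <- ifelse(groups == "I", depth * fold_h3k27ac, depth)
    cebpa_bound <- stats::runif(n_tot) < cebpa_bound_frac[groups]
    mean_cebpa <- ifelse(cebpa_bound, depth, 0)

    means <- list(
      pu1 = list(minus = mean_tf_minus, plus = mean_tf_plus),
      cebpa = list(minus = mean_cebpa, plus = mean_cebpa),
      h3k27ac = list(minus = mean_hist_minus, plus = mean_hist_plus))

    reads <- list()
    library_sizes <- list()
    peaks <- list()
    for (assay in names(means)) {
      peaks[[assay]] <- list()
      planted <- list()
      for (cond in c("minus", "plus")) {
        mu <- means[[assay]][[cond]]
        counts <- stats::rpois(n_tot, mu)
        rd <- sample_reads(regions, counts, read_length)
        GenomeInfoDb::seqlevels(rd) <- chroms
        planted[[cond]] <- rd
        peaks[[assay]][[cond]] <- regions[mu >= peak_call_min]
      }
      target_lib <- ceiling((1 + background) *
                              max(vapply(planted, length, integer(1))))
      for (cond in c("minus", "plus")) {
        n_bg <- target_lib - length(planted[[cond]])
        bg <- sample_background_reads(n_bg, regions, chroms, genome_size,
                                      read_length)
        rd <- sort_peaks(base::c(planted[[cond]], bg))
        reads[[paste0(assay, "_", cond)]] <- rd
        library_sizes[[paste0(assay, "_", cond)]] <- length(rd)
      }
    }

    # the truth label reflects what is actually planted: degenerate folds
    # (e.g. fold_pu1 = 1) collapse the requested groups accordingly
    tf_up <- mean_tf_plus > mean_tf_minus
    hist_up <- mean_hist_plus > mean_hist_minus
    truth <- data.frame(
      region_id = S4Vectors::mcols(regions)$region_id,
      group = ifelse(tf_up & hist_up, "I", ifelse(tf_up, "II", "III")),
      requested_group = groups,
      mean_tf_minus = mean_tf_minus, mean_tf_plus = mean_tf_plus,
      mean_hist_minus = mean_hist_minus, mean_hist_plus = mean_hist_plus,
      cebpa_bound = cebpa_bound,
      stringsAsFactors = FALSE)
    attr(truth, "infeasible") <- infeasible

    params <- list(generator = "generate_binding_experiment",
                   n_regions_per_group = as.list(n_regions_per_group),
                   depth = depth, fold_pu1 = fold_pu1,
                   fold_h3k27ac = fold_h3k27ac, seed = seed,
                   genome_size = genome_size, chroms = chroms,
                   region_width = region_width, read_length = read_length,
                   peak_call_min = peak_call_min,
                   hist_abs_min = hist_abs_min, placement = placement,
                   infeasible = infeasible)
    out <- list(regions = regions, peaks = peaks, reads = reads,
                truth = truth, library_sizes = library_sizes,
                params = params)
    if (!is.null(dir)) write_binding_fixture(out, dir)
    out
  })
}

place_random <- function(n, widths, genome_size, chroms) {
  per_chrom <- table(rep(chroms, length.out = n))
  chrom_v <- character(n)
  start_v <- integer(n)
  i <- 0L
  for (ch in names(per_chrom)) {
    k <- as.integer(per_chrom[[ch]])
    w <- widths[i + seq_len(k)]
    free <- genome_size - sum(w)
    if (free < k + 1) stop("genome too small for the requested regions")
    cuts <- sort(stats::runif(k, 0, free))
    starts <- as.integer(floor(cuts + c(0, cumsum(w))[seq_len(k)]))
    chrom_v[i + seq_len(k)] <- ch
    start_v[i + seq_len(k)] <- starts
    i <- i + k
  }
  # region order stays aligned with the planted group order
  GenomicRanges::GRanges(chrom_v, IRanges::IRanges(start_v + 1L,
                                                   start_v + widths))
}

# Group-coherent placement. Intergenic gaps are assigned cyclic roles
# (I-host, spacer, II-host, spacer, III-marker, spacer): Group I regions go
# into I-host gaps, Group II into II-host gaps, and Group III regions sit
# in the promoters of genes flanking III-marker gaps (which host nothing).
# The spacer gaps keep the flank genes of the three roles disjoint, so a
# gene is linked to regions of (essentially) one group only — emulating
# the group coherence of real enhancer neighbourhoods and giving the
# downstream group-versus-group expression contrast something to detect.
place_biased <- function(groups, widths, annotation) {
  genes <- annotation$genes
  proms <- annotation$promoters
  gene_gr <- annotation_to_granges(genes)
  occupied <- GenomicRanges::reduce(c(GenomicRanges::granges(gene_gr),
                                      GenomicRanges::granges(proms)),
                                    ignore.strand = TRUE)
  gaps_gr <- GenomicRanges::gaps(occupied)
  gaps_gr <- gaps_gr[as.character(BiocGenerics::strand(gaps_gr)) == "*"]
  gaps_gr <- sort_peaks(gaps_gr[BiocGenerics::width(gaps_gr) >
                                  max(widths) + 200])
  if (length(gaps_gr) == 0) stop("annotation leaves no intergenic space")
  roles <- rep(c("I", "spacer", "II", "spacer", "IIImark", "spacer"),
               length.out = length(gaps_gr))

  # promoters eligible for Group III: the gene's footprint (body +
  # promoter) must not flank an I/II-host gap — otherwise that gene would
  # also collect intergenic Group I/II links — and the promoter must
  # overlap no other promoter (each hosts one disjoint region)
  host_flank <- GenomicRanges::resize(
    gaps_gr[roles %in% c("I", "II")],
    BiocGenerics::width(gaps_gr[roles %in% c("I", "II")]) + 2L,
    fix = "center")
  foot <- GenomicRanges::punion(GenomicRanges::granges(gene_gr),
                                GenomicRanges::granges(proms),
                                fill.gap = TRUE, ignore.strand = TRUE)
  near_host <- GenomicRanges::countOverlaps(foot, host_flank,
                                            ignore.strand = TRUE) > 0
  disjoint <- GenomicRanges::countOverlaps(proms, proms,
                                           ignore.strand = TRUE) == 1
  iii_proms <- proms[!near_host & disjoint]
  if (sum(groups == "III") > length(iii_proms)) {
    stop("more Group III regions requested than eligible promoters (",
         length(iii_proms), "); enlarge the annotation")
  }

  host_gaps <- list(I = which(roles == "I"), II = which(roles == "II"))
  gap_cursor <- BiocGenerics::start(gaps_gr) + 100L
  rr <- list(I = 0L, II = 0L)   # round-robin position per host role
  chroms <- character(length(groups))
  starts <- integer(length(groups))
  prom_i <- 0L
  for (j in seq_along(groups)) {
    w <- widths[j]
    if (groups[j] == "III") {
      # wholly inside one promoter window so the gene assignment is forced
      prom_i <- prom_i + 1L
      p <- iii_proms[prom_i]
      w <- min(w, BiocGenerics::width(p))
      widths[j] <- w
      mid <- (BiocGenerics::start(p) + BiocGenerics::end(p)) %/% 2L
      s <- max(BiocGenerics::start(p),
               min(mid - w %/% 2L, BiocGenerics::end(p) - w + 1L))
      chroms[j] <- as.character(GenomicRanges::seqnames(p))
      starts[j] <- s
    } else {
      hosts <- host_gaps[[groups[j]]]
      placed <- FALSE
      for (try in seq_along(hosts)) {
        rr[[groups[j]]] <- rr[[groups[j]]] %% length(hosts) + 1L
        gi <- hosts[rr[[groups[j]]]]
        g <- gaps_gr[gi]
        if (gap_cursor[gi] + w - 1L <= BiocGenerics::end(g) - 100L) {
          chroms[j] <- as.character(GenomicRanges::seqnames(g))
          starts[j] <- gap_cursor[gi]
          gap_cursor[gi] <- gap_cursor[gi] + w + 100L
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("intergenic space exhausted while placing Group ",
                        groups[j], " regions")
    }
  }
  out <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts,
                                                         width = widths))
  if (length(GenomicRanges::reduce(out, ignore.strand = TRUE)) != length(out)) {
    stop("internal error: biased placement produced overlapping regions")
  }
  out
}

# background reads are placed in the complement of the planted regions
# (width-weighted over the inter-region gaps) so that they pad the library
# size without perturbing the planted per-region means
sample_background_reads <- function(n, regions, chroms, genome_size,
                                    read_length) {
  if (n <= 0) {
    return(GenomicRanges::GRanges(
      seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms)))
  }
  genome <- GenomicRanges::GRanges(chroms,
                                   IRanges::IRanges(1L, genome_size))
  gaps <- GenomicRanges::setdiff(genome,
                                 GenomicRanges::reduce(
                                   GenomicRanges::granges(regions),
                                   ignore.strand = TRUE),
                                 ignore.strand = TRUE)
  room <- BiocGenerics::width(gaps) - read_length + 1L
  gaps <- gaps[room > 0]
  room <- room[room > 0]
  gi <- sample.int(length(gaps), n, replace = TRUE, prob = room)
  offset <- as.integer(floor(stats::runif(n) * room[gi]))
  starts <- BiocGenerics::start(gaps)[gi] + offset
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gaps))[gi],
                         IRanges::IRanges(starts, width = read_length))
}

sample_reads <- function(regions, counts, read_length) {
  n <- sum(counts)
  if (n == 0) return(GenomicRanges::GRanges())
  idx <- rep(seq_along(regions), counts)
  rs <- BiocGenerics::start(regions)[idx]
  re <- BiocGenerics::end(regions)[idx]
  span <- pmax(re - read_length + 1L - rs, 0L)
  starts <- rs + as.integer(floor(stats::runif(n) * (span + 1L)))
  GenomicRanges::GRanges(GenomicRanges::seqnames(regions)[idx],
                         IRanges::IRanges(starts, width = read_length))
}

#' Match planted regions to merged-region identifiers
#'
#' After the two-condition peak merge, merged regions carry fresh
#' coordinate-sorted ids; this maps each planted region to the merged
#' region covering it so truth labels can be compared with downstream
#' classifications.
#'
#' @param planted `GRanges` of generator regions (in truth order).
#' @param merged Merged `GRanges` with a `region_id` column.
#' @return Character vector of merged `region_id`s, one per planted
#'   region; errors if the mapping is not one-to-one.
#' @export
match_planted_regions <- function(planted, merged) {
  hits <- GenomicRanges::findOverlaps(planted, merged,
                                      ignore.strand = TRUE)
  if (length(hits) != length(planted) ||
      anyDuplicated(S4Vectors::queryHits(hits))) {
    stop("planted regions do not map one-to-one onto merged regions")
  }
  S4Vectors::mcols(merged)$region_id[S4Vectors::subjectHits(hits)]
}

write_binding_fixture <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (assay in names(x$peaks)) {
    for (cond in names(x$peaks[[assay]])) {
      write_bed(x$peaks[[assay]][[cond]],
                file.path(dir, sprintf("peaks_%s_%s.bed", assay, cond)))
    }
  }
  for (nm in names(x$reads)) {
    write_bed(x$reads[[nm]], file.path(dir, sprintf("reads_%s.bed", nm)))
  }
  utils::write.table(x$truth, file.path(dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(dir, "binding", x$params)
  invisible(dir)
}

#' Generate a two-condition expression matrix with planted up-regulation
#'
#' Gaussian log2 intensities with per-gene baselines; a chosen subset of
#' genes is shifted up by `effect_log2fc` in the induced condition.
#'
#' @param n_genes Number of genes/probes.
#' @param n_samples_per_condition Replicates per condition (>= 2).
#' @param n_up_genes Number of planted up-regulated genes.
#' @param effect_log2fc Planted shift on the log2 scale.
#' @param noise_sd Residual standard deviation (log2 scale).
#' @param seed Integer RNG seed.
#' @param gene_ids Optional gene identifiers (length `n_genes`); defaults to
#'   `gene_0001`... so the matrix can share ids with a generated annotation.
#' @param up_gene_ids Optional explicit set of genes to up-regulate
#'   (subset of `gene_ids`); overrides the random choice of `n_up_genes`.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param dir Optional output directory (expression TSV, design TSV, truth
#'   TSV, manifest).
#' @return List: `expr` (genes x samples matrix, log2 scale), `design`
#'   (data.frame sample_id, condition in `minus`/`plus`), `truth`
#'   (`de_gene_ids`), `params`.
#' @export
generate_expression_matrix <- function(n_genes = 2000,
                                       n_samples_per_condition = 3,
                                       n_up_genes = 100,
                                       effect_log2fc = 1,
                                       noise_sd = 0.1,
                                       seed = 1,
                                       gene_ids = NULL,
                                       up_gene_ids = NULL,
                                       baseline_mean = 8, baseline_sd = 1,
                                       dir = NULL) {
  if (n_up_genes > n_genes) stop("n_up_genes must be <= n_genes")
  if (n_samples_per_condition < 2) stop("need >= 2 samples per condition")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  with_seed(seed, {
    n_s <- n_samples_per_condition
    cond <- rep(c("minus", "plus"), each = n_s)
    samples <- paste0(cond, "_", rep(seq_len(n_s), 2))
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    expr <- matrix(stats::rnorm(n_genes * 2 * n_s, 0, noise_sd),
                   nrow = n_genes) + base
    up_idx <- if (!is.null(up_gene_ids)) {
      stopifnot(all(up_gene_ids %in% gene_ids))
      match(up_gene_ids, gene_ids)
    } else if (n_up_genes > 0 && effect_log2fc != 0) {
      sample.int(n_genes, n_up_genes)
    } else integer(0)
    if (effect_log2fc == 0) up_idx <- integer(0)
    expr[up_idx, cond == "plus"] <- expr[up_idx, cond == "plus"] + effect_log2fc
    dimnames(expr) <- list(gene_ids, samples)
    design <- data.frame(sample_id = samples, condition = cond,
                         stringsAsFactors = FALSE)
    truth <- list(de_gene_ids = sort(gene_ids[up_idx]))
    params <- list(generator = "generate_expression_matrix",
                   n_genes = n_genes,
                   n_samples_per_condition = n_samples_per_condition,
                   n_up_genes = n_up_genes, effect_log2fc = effect_log2fc,
                   noise_sd = noise_sd, seed = seed)
    out <- list(expr = expr, design = design, truth = truth, params = params)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_expression(expr, file.path(dir, "expression.tsv"))
      utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(truth$de_gene_ids, file.path(dir, "truth_up_genes.txt"))
      write_manifest(dir, "expression", params)
    }
    out
  })
}

#' Generate a labelled expression cohort with planted cluster structure
#'
#' Emulates an annotated expression compendium (cell-type atlas or patient
#' cohort): each planted cluster has a distinct mean profile over the
#' signature genes, scaled by `separation`; categorical sample labels (e.g.
#' karyotype) are drawn per cluster from `label_table`.
#'
#' @param n_samples Total samples.
#' @param n_clusters Planted clusters (>= 2); sizes as equal as possible.
#' @param signature_genes Character vector of informative gene ids.
#' @param separation Scale of between-cluster centroid distance relative to
#'   unit centroid draws; 0 plants no structure.
#' @param label_table Optional matrix/data.frame of label proportions,
#'   `n_clusters` rows x label values as columns (rows normalised to 1).
#' @param seed Integer RNG seed.
#' @param n_background_genes Uninformative genes added to the matrix.
#' @param noise_sd Residual standard deviation.
#' @param marker_gene Optional name of an extra marker row (e.g. the
#'   inducing factor itself) whose per-cluster means are `marker_means`.
#' @param marker_means Numeric, one mean per cluster, for `marker_gene`.
#' @param label_name Metadata column name for the categorical label.
#' @param dir Optional output directory (expression, metadata, truth TSVs,
#'   manifest).
#' @return List: `expr`, `metadata` (sample_id + label column), `truth`
#'   (`cluster_labels` named by sample), `params`.
#' @export
generate_labeled_cohort <- function(n_samples = 60, n_clusters = 3,
                                    signature_genes = sprintf("sig_%03d", 1:50),
                                    separation = 2,
                                    label_table = NULL,
                                    seed = 1,
                                    n_background_genes = 200,
                                    noise_sd = 1,
                                    marker_gene = NULL,
                                    marker_means = NULL,
                                    label_name = "karyotype",
                                    dir = NULL) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (separation < 0) stop("separation must be >= 0")
  with_seed(seed, {
    cl <- rep(seq_len(n_clusters), length.out = n_samples)
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    n_sig <- length(signature_genes)
    centroids <- matrix(stats::rnorm(n_sig * n_clusters), nrow = n_sig) *
      separation
    sig_expr <- centroids[, cl, drop = FALSE] +
      matrix(stats::rnorm(n_sig * n_samples, 0, noise_sd), nrow = n_sig) + 8
    rownames(sig_expr) <- signature_genes
    bg <- matrix(stats::rnorm(n_background_genes * n_samples, 8, noise_sd),
                 nrow = n_background_genes)
    rownames(bg) <- sprintf("bg_%04d", seq_len(n_background_genes))
    expr <- rbind(sig_expr, bg)
    if (!is.null(marker_gene)) {
      if (is.null(marker_means)) marker_means <- seq_len(n_clusters)
      stopifnot(length(marker_means) == n_clusters)
      mk <- marker_means[cl] + stats::rnorm(n_samples, 0, noise_sd)
      expr <- rbind(expr, matrix(mk, nrow = 1,
                                 dimnames = list(marker_gene, NULL)))
    }
    colnames(expr) <- samples
    if (is.null(label_table)) {
      label_table <- diag(n_clusters)
      colnames(label_table) <- sprintf("type_%d", seq_len(n_clusters))
    }
    label_table <- as.matrix(label_table)
    stopifnot(nrow(label_table) == n_clusters)
    if (is.null(colnames(label_table))) {
      colnames(label_table) <- sprintf("%s_%d", label_name,
                                       seq_len(ncol(label_table)))
    }
    probs <- label_table / rowSums(label_table)
    labels <- vapply(cl, function(k) {
      sample(colnames(probs), 1, prob = probs[k, ])
    }, character(1))
    metadata <- data.frame(sample_id = samples, labels,
                           stringsAsFactors = FALSE)
    names(metadata)[2] <- label_name
    truth <- list(cluster_labels = stats::setNames(cl, samples))
    params <- list(generator = "generate_labeled_cohort",
                   n_samples = n_samples, n_clusters = n_clusters,
                   n_signature_genes = n_sig, separation = separation,
                   seed = seed, n_background_genes = n_background_genes,
                   noise_sd = noise_sd, label_name = label_name)
    out <- list(expr = expr, metadata = metadata, truth = truth,
                params = params)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_expression(expr, file.path(dir, "cohort_expression.tsv"))
      utils::write.table(metadata, file.path(dir, "cohort_metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = samples, cluster = cl),
        file.path(dir, "truth_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(dir, "cohort", params)
    }
    out
  })
}

#' Write / read an expression matrix as TSV (genes x samples)
#'
#' @param expr Numeric matrix with gene ids as rownames.
#' @param path Output path.
#' @return `path` invisibly (`write_expression`); numeric matrix
#'   (`read_expression`).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, start, end, strand, tss
#' (0-based half-open body coordinates, 0-based TSS position).
#'
#' @param genes Annotation data.frame.
#' @param path File path.
#' @return `path` invisibly (`write_annotation`); data.frame
#'   (`read_annotation`).
#' @export
write_annotation <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Convert an annotation data.frame to gene-body GRanges
#'
#' @param genes Annotation data.frame (0-based half-open coordinates).
#' @return `GRanges` with `gene_id` metadata and strand.
#' @export
annotation_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  gr
}
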