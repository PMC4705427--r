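# Region-to-gene assignment, in strict precedence:
#   1. region overlaps a promoter window  -> promoter (that gene)
#   2. region overlaps a gene body        -> intragenic (all such genes)
#   3. otherwise                          -> intergenic: nearest gene on
#      each genomic side, kept iff edge-to-edge distance <= max_dist
#   4. no gene within reach               -> unassigned
# Promoters are checked before gene bodies because a promoter can lie
# inside another gene's body.

#' Assign regions to genes
#'
#' @param regions `GRanges` with a `region_id` metadata column.
#' @param genes Gene annotation data.frame (0-based half-open `start`/`end`,
#'   `strand`, `gene_id`; see [generate_annotation()]).
#' @param promoters Promoter `GRanges` with gene ids in the `name` column.
#' @param max_dist Maximum edge-to-edge distance for intergenic assignment
#'   (bp, inclusive; default 50000).
#' @return A data.frame with one row per (region, assigned gene) — or one
#'   row with `gene_id = NA` for unassigned regions — and columns
#'   `region_id`, `category` (promoter/intragenic/intergenic/unassigned),
#'   `gene_id`, `distance` (bp; 0 for promoter/intragenic).
#' @export
assign_regions <- function(regions, genes, promoters, max_dist = 50000) {
  rid <- S4Vectors::mcols(regions)$region_id
  if (is.null(rid)) rid <- sprintf("region_%05d", seq_along(regions))
  gene_gr <- annotation_to_granges(genes)

  known_chroms <- unique(c(genes$chrom,
                           as.character(GenomicRanges::seqnames(promoters))))
  reg_chrom <- as.character(GenomicRanges::seqnames(regions))
  if (any(!reg_chrom %in% known_chroms)) {
    warning("regions on chromosomes absent from the annotation are left ",
            "unassigned: ",
            paste(unique(reg_chrom[!reg_chrom %in% known_chroms]),
                  collapse = ", "))
  }

  prom_hits <- GenomicRanges::findOverlaps(regions, promoters,
                                           ignore.strand = TRUE)
  body_hits <- GenomicRanges::findOverlaps(regions, gene_gr,
                                           ignore.strand = TRUE)
  in_prom <- unique(S4Vectors::queryHits(prom_hits))
  in_body <- setdiff(unique(S4Vectors::queryHits(body_hits)), in_prom)

  # per-chromosome gene edges (0-based) for the intergenic nearest search
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)

  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    if (i %in% in_prom) {
      gid <- unique(S4Vectors::mcols(promoters)$name[
        S4Vectors::subjectHits(prom_hits)[S4Vectors::queryHits(prom_hits) == i]])
      rows[[i]] <- data.frame(region_id = rid[i], category = "promoter",
                              gene_id = gid, distance = 0,
                              stringsAsFactors = FALSE)
    } else if (i %in% in_body) {
      gid <- unique(genes$gene_id[
        S4Vectors::subjectHits(body_hits)[S4Vectors::queryHits(body_hits) == i]])
      rows[[i]] <- data.frame(region_id = rid[i], category = "intragenic",
                              gene_id = gid, distance = 0,
                              stringsAsFactors = FALSE)
    } else {
      gi <- by_chrom[[reg_chrom[i]]]
      hit_gid <- character(0); hit_d <- numeric(0)
      if (length(gi) > 0) {
        rs0 <- BiocGenerics::start(regions)[i] - 1L
        re0 <- BiocGenerics::end(regions)[i]
        left <- gi[genes$end[gi] <= rs0]
        right <- gi[genes$start[gi] >= re0]
        if (length(left) > 0) {
          d <- rs0 - genes$end[left]
          keep <- left[d == min(d)]
          if (min(d) <= max_dist) {
            hit_gid <- c(hit_gid, genes$gene_id[keep])
            hit_d <- c(hit_d, rep(min(d), length(keep)))
          }
        }
        if (length(right) > 0) {
          d <- genes$start[right] - re0
          keep <- right[d == min(d)]
          if (min(d) <= max_dist) {
            hit_gid <- c(hit_gid, genes$gene_id[keep])
            hit_d <- c(hit_d, rep(min(d), length(keep)))
          }
        }
      }
      if (length(hit_gid) > 0) {
        rows[[i]] <- data.frame(region_id = rid[i], category = "intergenic",
                                gene_id = hit_gid, distance = hit_d,
                                stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- data.frame(region_id = rid[i], category = "unassigned",
                                gene_id = NA_character_, distance = NA_real_,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic-distribution summary per region group
#'
#' For each group, the fraction of regions falling in each assignment
#' category, plus the composite intragenic + intergenic fraction (the
#' enhancer-bias statistic). Fractions are over regions with a genomic
#' category; unassigned regions are counted separately.
#'
#' @param assignments Result of [assign_regions()].
#' @param groups Result of [classify_regions()] (needs `region_id`,
#'   `group`).
#' @return A data.frame, one row per group: `n`, category fractions,
#'   `composite_intra_intergenic` (percent), `n_unassigned`.
#' @export
distribution_summary <- function(assignments, groups) {
  cat_per_region <- assignments[!duplicated(assignments$region_id),
                                c("region_id", "category")]
  m <- merge(cat_per_region, groups[, c("region_id", "group")],
             by = "region_id")
  res <- lapply(split(m, m$group), function(d) {
    assigned <- d$category != "unassigned"
    n_cat <- sum(assigned)
    frac <- function(cat) if (n_cat == 0) NA_real_ else
      sum(d$category == cat) / n_cat
    data.frame(group = d$group[1], n = nrow(d),
               frac_promoter = frac("promoter"),
               frac_intragenic = frac("intragenic"),
               frac_intergenic = frac("intergenic"),
               composite_intra_intergenic =
                 round(100 * (frac("intragenic") + frac("intergenic")), 1),
               n_unassigned = sum(!assigned),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene set linked to a region group
#'
#' @param assignments Result of [assign_regions()].
#' @param groups Result of [classify_regions()].
#' @param group Group label (`"I"`, `"II"`, `"III"`).
#' @return Sorted character vector of unique gene ids assigned to any
#'   region in the group.
#' @export
genes_for_group <- function(assignments, groups, group) {
  rids <- groups$region_id[groups$group == group]
  gids <- assignments$gene_id[assignments$region_id %in% rids]
  sort(unique(gids[!is.na(gids)]))
}
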