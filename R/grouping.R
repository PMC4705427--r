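# Classification of merged regions into functional groups from TF and
# histone fold changes:
#   Group I   — TF fold-up AND histone fold-up AND absolute histone floor
#   Group II  — TF fold-up, remaining
#   Group III — TF fold change inside the no-change band
# Everything else is left unclassified; the three groups never exhaust the
# region set because regions between the band and the fold threshold belong
# to no group.

#' Thresholds for region group classification
#'
#' @param fc_tf_min Minimum TF fold increase for Groups I/II (default 4).
#' @param fc_hist_min Minimum histone fold increase for Group I (default 4).
#' @param hist_abs_min Absolute floor on the induced-condition raw histone
#'   read count for Group I (default 50 reads).
#' @param no_change_band Symmetric fold band defining "no change" (Group
#'   III): `max(fc, 1/fc) <= no_change_band` (default 2).
#' @param pseudocount Added to both conditions' normalised scores before
#'   ratios (default 1 on the normalised scale).
#' @return A validated list of class `group_thresholds`.
#' @export
group_thresholds <- function(fc_tf_min = 4, fc_hist_min = 4,
                             hist_abs_min = 50, no_change_band = 2,
                             pseudocount = 1) {
  th <- list(fc_tf_min = fc_tf_min, fc_hist_min = fc_hist_min,
             hist_abs_min = hist_abs_min, no_change_band = no_change_band,
             pseudocount = pseudocount)
  if (any(unlist(th) <= 0)) stop("all thresholds must be > 0")
  if (no_change_band >= fc_tf_min) {
    stop("no_change_band must be below fc_tf_min, otherwise Group III ",
         "overlaps Group II")
  }
  structure(th, class = "group_thresholds")
}

#' Pseudocounted fold change between conditions
#'
#' @param norm_minus,norm_plus Non-negative normalised scores for the
#'   uninduced and induced condition.
#' @param pseudocount Positive stabiliser added to both (default 1).
#' @return `(norm_plus + pseudocount) / (norm_minus + pseudocount)`;
#'   strictly positive and finite, 1 when both scores are zero.
#' @export
fold_change <- function(norm_minus, norm_plus, pseudocount = 1) {
  stopifnot(pseudocount > 0, all(norm_minus >= 0), all(norm_plus >= 0))
  (norm_plus + pseudocount) / (norm_minus + pseudocount)
}

#' Classify regions into Groups I/II/III
#'
#' Applies the three-criterion cascade on the coverage matrix: Group I =
#' TF fold change >= `fc_tf_min` and histone fold change >= `fc_hist_min`
#' and raw induced histone count >= `hist_abs_min`; Group II = remaining
#' regions with TF fold change >= `fc_tf_min`; Group III = regions whose TF
#' fold change lies within the symmetric no-change band. Remaining regions
#' are `unclassified`. The groups are mutually exclusive by construction.
#'
#' @param cov Coverage matrix from [coverage_matrix()].
#' @param assay_tf,assay_hist Assay name prefixes of the TF and histone
#'   columns (e.g. `"pu1"`, `"h3k27ac"`).
#' @param thresholds A [group_thresholds()] object.
#' @param conditions Condition suffixes, uninduced first.
#' @return A data.frame (`region_id`, `tf_fc`, `hist_fc`,
#'   `hist_induced_raw`, `group`) with a `sizes` attribute holding the
#'   group size table.
#' @export
classify_regions <- function(cov, assay_tf = "pu1", assay_hist = "h3k27ac",
                             thresholds = group_thresholds(),
                             conditions = c("minus", "plus")) {
  need <- c(paste0("norm_", assay_tf, "_", conditions),
            paste0("norm_", assay_hist, "_", conditions),
            paste0("raw_", assay_hist, "_", conditions[2]))
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols) > 0) {
    stop("coverage matrix lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  pc <- thresholds$pseudocount
  tf_fc <- fold_change(cov[[paste0("norm_", assay_tf, "_", conditions[1])]],
                       cov[[paste0("norm_", assay_tf, "_", conditions[2])]],
                       pc)
  hist_fc <- fold_change(cov[[paste0("norm_", assay_hist, "_", conditions[1])]],
                         cov[[paste0("norm_", assay_hist, "_", conditions[2])]],
                         pc)
  hist_raw <- cov[[paste0("raw_", assay_hist, "_", conditions[2])]]

  group <- rep("unclassified", nrow(cov))
  is_tf_up <- tf_fc >= thresholds$fc_tf_min
  is_i <- is_tf_up & hist_fc >= thresholds$fc_hist_min &
    hist_raw >= thresholds$hist_abs_min
  is_ii <- is_tf_up & !is_i
  is_iii <- !is_tf_up & pmax(tf_fc, 1 / tf_fc) <= thresholds$no_change_band
  group[is_iii] <- "III"
  group[is_ii] <- "II"
  group[is_i] <- "I"

  out <- data.frame(region_id = cov$region_id, tf_fc = tf_fc,
                    hist_fc = hist_fc, hist_induced_raw = hist_raw,
                    group = group, stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(factor(group,
                                     levels = c("I", "II", "III",
                                                "unclassified")))
  attr(out, "thresholds") <- thresholds
  out
}

#' Global two-condition binding summary for one assay
#'
#' Counts called peaks per condition, partitions the merged regions by
#' which condition(s) contributed (shared / gained / lost), and reports the
#' arithmetic mean of the pseudocounted per-region fold changes.
#'
#' @param cov Coverage matrix whose `regions` carried `in_a`/`in_b`
#'   contribution flags (pass the merged `GRanges` as `regions`).
#' @param regions The merged `GRanges` from [merge_two_condition_peaks()]
#'   (condition a = uninduced, b = induced).
#' @param assay Assay column prefix to summarise.
#' @param n_peaks_minus,n_peaks_plus Peak counts of the original input peak
#'   sets (pre-merge); defaults to the contribution-flag counts.
#' @param pseudocount Stabiliser for the fold changes.
#' @param conditions Condition suffixes, uninduced first.
#' @return A list: peak counts per condition, `n_new`, `n_lost`,
#'   `n_shared` over merged regions, and `mean_fold_increase`.
#' @export
global_binding_summary <- function(cov, regions, assay = "pu1",
                                   n_peaks_minus = NULL,
                                   n_peaks_plus = NULL,
                                   pseudocount = 1,
                                   conditions = c("minus", "plus")) {
  mc <- S4Vectors::mcols(regions)
  if (is.null(mc$in_a) || is.null(mc$in_b)) {
    stop("regions must carry in_a/in_b contribution flags from ",
         "merge_two_condition_peaks()")
  }
  fc <- fold_change(cov[[paste0("norm_", assay, "_", conditions[1])]],
                    cov[[paste0("norm_", assay, "_", conditions[2])]],
                    pseudocount)
  list(
    n_peaks_minus = if (is.null(n_peaks_minus)) sum(mc$in_a) else n_peaks_minus,
    n_peaks_plus = if (is.null(n_peaks_plus)) sum(mc$in_b) else n_peaks_plus,
    n_new = sum(!mc$in_a & mc$in_b),
    n_lost = sum(mc$in_a & !mc$in_b),
    n_shared = sum(mc$in_a & mc$in_b),
    mean_fold_increase = mean(fc))
}

#' Correlation between TF and histone log2 fold changes
#'
#' Pearson product-moment correlation of the two per-region log2 fold
#' change vectors over the (TF-bound) regions, with the usual t-based
#' p-value.
#'
#' @param cov Coverage matrix.
#' @param assay_tf,assay_hist Assay column prefixes.
#' @param pseudocount Stabiliser for the fold changes.
#' @param conditions Condition suffixes, uninduced first.
#' @return List with `r`, `p_value`, `n`; `r` is `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
tf_histone_correlation <- function(cov, assay_tf = "pu1",
                                   assay_hist = "h3k27ac",
                                   pseudocount = 1,
                                   conditions = c("minus", "plus")) {
  if (nrow(cov) < 3) stop("need at least 3 regions for a correlation")
  ltf <- log2(fold_change(cov[[paste0("norm_", assay_tf, "_", conditions[1])]],
                          cov[[paste0("norm_", assay_tf, "_", conditions[2])]],
                          pseudocount))
  lh <- log2(fold_change(cov[[paste0("norm_", assay_hist, "_", conditions[1])]],
                         cov[[paste0("norm_", assay_hist, "_", conditions[2])]],
                         pseudocount))
  if (stats::sd(ltf) == 0 || stats::sd(lh) == 0) {
    warning("zero-variance fold-change vector; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(cov)))
  }
  ct <- stats::cor.test(ltf, lh, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(cov))
}
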