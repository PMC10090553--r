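# Phenotype-score stratification of cell lines and group comparison.
# Lines at or above the score cutoff are HI ("SCN score >= 1.1" is the
# reference convention); group comparisons use the Mann-Whitney rank-sum
# test.

#' Partition cell lines into HI/LO by phenotype-score cutoff
#'
#' A line is HI iff its score is greater than or equal to the cutoff,
#' otherwise LO; the partition is exhaustive and exclusive over the
#' annotation.
#'
#' @param annotation Data.frame with `cell_line` (unique) and `scn_score`
#'   (finite numeric) columns.
#' @param cutoff Finite score cutoff (the conventional value is 1.1).
#' @return A list of class `"scn_partition"`: `hi` and `lo` (cell-line id
#'   vectors, annotation order), `cutoff`, `n_hi`, `n_lo`.
#' @export
classify_scn <- function(annotation, cutoff = 1.1) {
  if (!nrow(annotation)) stop_validation("annotation is empty")
  check_scalar_number(cutoff, "cutoff")
  if (anyDuplicated(annotation$cell_line)) {
    stop_integrity("duplicate cell-line identifiers in annotation")
  }
  bad <- !is.finite(annotation$scn_score)
  if (any(bad)) {
    stop_validation("non-finite SCN score for line(s): ",
                    paste(annotation$cell_line[bad], collapse = ", "))
  }
  hi <- annotation$scn_score >= cutoff
  structure(list(hi = annotation$cell_line[hi],
                 lo = annotation$cell_line[!hi],
                 cutoff = cutoff,
                 n_hi = sum(hi), n_lo = sum(!hi)),
            class = "scn_partition")
}

#' @export
print.scn_partition <- function(x, ...) {
  cat("SCN partition at cutoff ", x$cutoff, ": ", x$n_hi, " HI, ",
      x$n_lo, " LO\n", sep = "")
  invisible(x)
}

#' Fraction of a lineage's lines at or above a cutoff
#'
#' Quantifies how well a candidate cutoff captures a reference lineage (for
#' example, the fraction of small-cell lung cancer lines scoring at or above
#' 1.1), which is how the cutoff is justified from data.
#'
#' @param annotation Data.frame with `cell_line`, `scn_score`, `lineage`.
#' @param lineage Lineage label to assess.
#' @param cutoff Score cutoff.
#' @return A list: `fraction_above`, `n_above`, `n_total`.
#' @export
cutoff_support <- function(annotation, lineage, cutoff = 1.1) {
  sel <- annotation$lineage == lineage
  if (!any(sel)) stop_validation("no lines carry lineage label: ", lineage)
  scores <- annotation$scn_score[sel]
  n_above <- sum(scores >= cutoff)
  list(fraction_above = n_above / length(scores),
       n_above = n_above, n_total = length(scores))
}

#' Compare a per-line quantity between HI and LO groups by rank sum
#'
#' Two-sided Mann-Whitney U with midrank handling of ties. The null
#' distribution is enumerated exactly when both groups have at most
#' `exact_max` non-missing values and there are no ties; otherwise the
#' normal approximation with tie correction is used (via
#' [stats::wilcox.test()]). U is reported for the HI group
#' (`U = sum of HI midranks - n_hi (n_hi + 1) / 2`).
#'
#' @param values Named numeric vector: cell line -> value; missing values
#'   dropped per line.
#' @param partition An `"scn_partition"` from [classify_scn()].
#' @param exact_max Largest group size for which the exact null is used
#'   (default 8).
#' @return A list: `U`, `p_two_sided`, `median_hi`, `median_lo`, `n_hi`,
#'   `n_lo`, `method`.
#' @export
rank_sum_compare <- function(values, partition, exact_max = 8L) {
  stopifnot(inherits(partition, "scn_partition"))
  v_hi <- values[names(values) %in% partition$hi]
  v_lo <- values[names(values) %in% partition$lo]
  v_hi <- v_hi[is.finite(v_hi)]
  v_lo <- v_lo[is.finite(v_lo)]
  if (!length(v_hi) || !length(v_lo)) {
    stop_validation("each group needs at least one non-missing value")
  }
  n1 <- length(v_hi); n2 <- length(v_lo)
  r <- rank(c(v_hi, v_lo))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(v_hi, v_lo)) > 0L
  exact <- !ties && n1 <= exact_max && n2 <= exact_max
  if (length(unique(c(v_hi, v_lo))) == 1L) {
    p <- 1  # every observation tied: no evidence either way
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(v_hi, v_lo, exact = exact, correct = !exact)
    )
    p <- min(1, wt$p.value)
    if (is.nan(p)) p <- 1
  }
  list(U = u, p_two_sided = p,
       median_hi = stats::median(v_hi), median_lo = stats::median(v_lo),
       n_hi = n1, n_lo = n2,
       method = if (exact) "exact" else "normal approximation")
}
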