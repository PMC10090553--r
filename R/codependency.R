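# Anchored co-dependency screening: correlate every gene's dependency
# profile against an anchor gene within a cell-line group, then apply the
# candidate funnel (significance, top-K positive rank, transcription-factor
# membership, cross-group exclusion).

#' Pearson correlation with a t-distribution p-value
#'
#' Product-moment correlation on pairwise-complete entries with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @param min_n Minimum number of complete pairs (default 3).
#' @return A list: `r`, `p_two_sided`, `n`.
#' @export
pearson_with_p <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) {
    stop_validation("fewer than ", min_n, " complete pairs (", n, ")")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_validation("correlation undefined: constant vector on complete pairs")
  }
  r <- stats::cor(x, y)
  list(r = r, p_two_sided = .cor_p(r, n), n = n)
}

#' Spearman correlation with a t-approximation p-value
#'
#' Pearson correlation of midranks over the pairwise-complete entries, with
#' the same t-transform p-value as [pearson_with_p()] applied to rho.
#'
#' @inheritParams pearson_with_p
#' @return A list: `rho`, `p_two_sided`, `n`.
#' @export
spearman_with_p <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  res <- pearson_with_p(rank(x[ok]), rank(y[ok]), min_n = min_n)
  list(rho = res$r, p_two_sided = res$p_two_sided, n = res$n)
}

# Two-sided p for a correlation r at sample size n via the t-transform.
# Vectorized over r and n; returns NA where n < 3 or |r| is NA.
.cor_p <- function(r, n) {
  df <- n - 2
  t <- abs(r) * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(t, df, lower.tail = FALSE)
  p[df < 1] <- NA_real_
  pmin(p, 1)
}

#' Screen all genes for co-dependency with an anchor within a line group
#'
#' For every non-anchor gene, correlates its dependency profile with the
#' anchor's over the given cell lines (Pearson and Spearman,
#' pairwise-complete). Genes with fewer than `min_n` complete pairs against
#' the anchor, or constant on those pairs, are excluded with a logged
#' reason. Among genes with `pearson_p < alpha` and `pearson_r > 0`,
#' `rank_positive` numbers them 1..K by descending `pearson_r` (ties broken
#' by smaller p, then symbol). A Benjamini-Hochberg column `pearson_q` is
#' emitted for transparency; it does not gate anything.
#'
#' @param dep Genes-by-lines dependency matrix (lower = more dependent).
#' @param anchor Anchor gene symbol (must be a row of `dep`).
#' @param lines Cell-line identifiers defining the group; subset of
#'   `colnames(dep)`.
#' @param alpha Significance level for the positive ranking (default 0.05).
#' @param min_n Minimum pairwise-complete lines per gene (default 10).
#' @return Data.frame (gene, pearson_r, pearson_p, pearson_q, spearman_rho,
#'   spearman_p, n_used, rank_positive) sorted by descending `pearson_r`;
#'   excluded genes with reasons in `attr(, "excluded")`.
#' @export
screen_codependency <- function(dep, anchor, lines = colnames(dep),
                                alpha = 0.05, min_n = 10L) {
  validate_matrix_table(dep)
  anchor <- canonicalize_symbols(anchor)
  if (!anchor %in% rownames(dep)) {
    stop_validation("anchor gene not in dependency matrix: ", anchor)
  }
  missing_lines <- setdiff(lines, colnames(dep))
  if (length(missing_lines)) {
    stop_validation("lines absent from dependency matrix: ",
                    paste(utils::head(missing_lines, 5), collapse = ", "))
  }
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  min_n <- check_count(min_n, "min_n", min = 3L)

  sub <- dep[, lines, drop = FALSE]
  a <- sub[anchor, ]
  others <- setdiff(rownames(sub), anchor)
  x <- t(sub[others, , drop = FALSE])  # lines x genes

  n_used <- colSums(!is.na(x) & !is.na(a))
  r <- suppressWarnings(as.vector(
    stats::cor(x, a, use = "pairwise.complete.obs")))
  rho <- suppressWarnings(as.vector(
    stats::cor(x, a, use = "pairwise.complete.obs", method = "spearman")))

  reason <- rep(NA_character_, length(others))
  reason[n_used < min_n] <- "n_below_min"
  reason[is.na(reason) & (is.na(r) | is.na(rho))] <- "constant_profile"
  keep <- is.na(reason)

  res <- data.frame(
    gene = others[keep],
    pearson_r = r[keep],
    pearson_p = .cor_p(r[keep], n_used[keep]),
    spearman_rho = rho[keep],
    spearman_p = .cor_p(rho[keep], n_used[keep]),
    n_used = n_used[keep],
    stringsAsFactors = FALSE
  )
  res$pearson_q <- stats::p.adjust(res$pearson_p, method = "BH")

  res$rank_positive <- rep(NA_integer_, nrow(res))
  pos <- which(res$pearson_p < alpha & res$pearson_r > 0)
  if (length(pos)) {
    o <- pos[order(-res$pearson_r[pos], res$pearson_p[pos], res$gene[pos])]
    res$rank_positive[o] <- seq_along(o)
  }
  res <- res[order(-res$pearson_r, res$pearson_p, res$gene), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- data.frame(gene = others[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  attr(res, "anchor") <- anchor
  attr(res, "alpha") <- alpha
  res
}

#' Apply the candidate funnel to HI and LO screen tables
#'
#' A gene is a candidate iff it is significantly positively correlated with
#' the anchor in the HI group (`pearson_p < alpha`), ranks within the top
#' `top_k` positively correlated genes there, is a transcription factor, and
#' is NOT also a significant positive co-dependency in the LO group. The
#' stage at which each transcription factor fell out is recorded so the
#' funnel can be audited.
#'
#' @param hi,lo Screen tables from [screen_codependency()] for the HI and LO
#'   groups (same anchor).
#' @param tf_list Character vector of transcription-factor symbols.
#' @param top_k Rank cutoff within the positive correlates (default 100).
#' @param alpha Significance level (default 0.05; applied to both groups).
#' @return A list of class `"candidate_report"`: `candidates` (symbols,
#'   HI-rank order) and `provenance` (data.frame per transcription factor
#'   present in the HI table: r/p in both groups, rank, stage survived or
#'   failed).
#' @export
candidate_filter <- function(hi, lo, tf_list, top_k = 100L, alpha = 0.05) {
  if (!length(tf_list)) stop_validation("tf_list is empty")
  tf_list <- canonicalize_symbols(tf_list)
  top_k <- check_count(top_k, "top_k")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)

  tf_in <- tf_list[tf_list %in% hi$gene]
  ih <- match(tf_in, hi$gene)
  il <- match(tf_in, lo$gene)

  sig_hi <- !is.na(hi$pearson_p[ih]) & hi$pearson_p[ih] < alpha &
    hi$pearson_r[ih] > 0
  in_top <- !is.na(hi$rank_positive[ih]) & hi$rank_positive[ih] <= top_k
  lo_r <- lo$pearson_r[il]
  lo_p <- lo$pearson_p[il]
  sig_lo_pos <- !is.na(lo_p) & lo_p < alpha & !is.na(lo_r) & lo_r > 0

  stage <- ifelse(!sig_hi, "failed_hi_significance",
           ifelse(!in_top, "failed_rank",
           ifelse(sig_lo_pos, "excluded_lo_codependency", "candidate")))

  prov <- data.frame(
    gene = tf_in,
    hi_r = hi$pearson_r[ih], hi_p = hi$pearson_p[ih],
    hi_rank = hi$rank_positive[ih],
    lo_r = lo_r, lo_p = lo_p,
    tf = rep(TRUE, length(tf_in)),
    stage = stage,
    stringsAsFactors = FALSE
  )
  cand <- prov$gene[prov$stage == "candidate"]
  cand <- cand[order(prov$hi_rank[match(cand, prov$gene)])]
  structure(list(candidates = cand, provenance = prov,
                 top_k = top_k, alpha = alpha),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report:", length(x$candidates), "candidate(s)")
  if (length(x$candidates)) cat(":", paste(x$candidates, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Compare one gene's anchor correlation across two screens
#'
#' Used to check that an RNAi-based screen and a CRISPR-based screen tell
#' the same story for a candidate.
#'
#' @param screen_a,screen_b Screen tables from [screen_codependency()].
#' @param gene Gene symbol present in both tables.
#' @return A list: `r_a`, `r_b`, `agree_sign`.
#' @export
codependency_concordance <- function(screen_a, screen_b, gene) {
  gene <- canonicalize_symbols(gene)
  ia <- match(gene, screen_a$gene)
  ib <- match(gene, screen_b$gene)
  if (is.na(ia) || is.na(ib)) {
    stop_validation("gene not present in both screen tables: ", gene)
  }
  r_a <- screen_a$pearson_r[ia]
  r_b <- screen_b$pearson_r[ib]
  list(r_a = r_a, r_b = r_b, agree_sign = sign(r_a) == sign(r_b))
}
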