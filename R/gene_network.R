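# Per-cohort anchor-centred correlation gene networks, signature
# extraction at a coefficient cutoff, cross-state congruence, and
# differential-network ranking between two disease states.
#
# A "gene network" here is, for one anchor gene in one cohort, the vector of
# its expression-correlation coefficients with every other gene across that
# cohort's samples. Networks are computed anchor-wise (one row of the
# correlation matrix at a time); the full all-pairs matrix is only
# materialized on request for small instances.

#' Build the correlation network of one anchor gene in one cohort
#'
#' Correlates every gene's expression with the anchor's over all cohort
#' samples. Genes constant within the cohort have undefined correlation and
#' are dropped with a logged reason; the anchor maps to 1.
#'
#' @param expr Genes-by-samples expression matrix (assumed pre-normalized,
#'   log scale); at least 3 samples.
#' @param anchor Anchor gene symbol, a row of `expr`, non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param cohort Optional cohort label recorded on the result.
#' @return A list of class `"gene_network"`: `anchor`, `cohort`, `method`,
#'   `coefficients` (named numeric, anchor included at 1), `dropped`
#'   (data.frame gene/reason).
#' @export
build_network <- function(expr, anchor, method = c("pearson", "spearman"),
                          cohort = NA_character_) {
  validate_matrix_table(expr)
  method <- match.arg(method)
  anchor <- canonicalize_symbols(anchor)
  if (!anchor %in% rownames(expr)) {
    stop_validation("anchor gene not in expression matrix: ", anchor)
  }
  if (ncol(expr) < 3L) stop_validation("need at least 3 samples")
  a <- expr[anchor, ]
  if (stats::var(a, na.rm = TRUE) == 0) {
    stop_validation("anchor gene is constant in this cohort: ", anchor)
  }
  r <- suppressWarnings(as.vector(
    stats::cor(t(expr), a, use = "pairwise.complete.obs", method = method)))
  names(r) <- rownames(expr)
  r[anchor] <- 1
  dropped_genes <- names(r)[is.na(r)]
  dropped <- data.frame(gene = dropped_genes,
                        reason = rep("constant_or_insufficient",
                                     length(dropped_genes)),
                        stringsAsFactors = FALSE)
  structure(list(anchor = anchor, cohort = cohort, method = method,
                 coefficients = r[!is.na(r)], dropped = dropped),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network for anchor ", x$anchor,
      if (!is.na(x$cohort)) paste0(" in cohort ", x$cohort), ": ",
      length(x$coefficients), " genes (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Full all-pairs correlation matrix of a cohort
#'
#' Convenience for small instances and brute-force checks; for genome-scale
#' matrices use anchor-wise [build_network()] instead.
#'
#' @inheritParams build_network
#' @return Symmetric genes-by-genes correlation matrix.
#' @export
full_correlation_matrix <- function(expr, method = c("pearson", "spearman")) {
  validate_matrix_table(expr)
  method <- match.arg(method)
  suppressWarnings(
    stats::cor(t(expr), use = "pairwise.complete.obs", method = method))
}

#' Extract a multi-anchor network signature at a coefficient cutoff
#'
#' Members are the genes whose coefficient is strictly above the cutoff in
#' EVERY anchor network ("above 0.7" is the reference convention, signed,
#' strict). Anchors themselves are excluded from the membership.
#'
#' @param networks A list of `"gene_network"` objects from the same cohort
#'   (one per anchor).
#' @param cutoff Coefficient cutoff in (-1, 1); default 0.7.
#' @return A list of class `"network_signature"`: `anchors`, `cohort`,
#'   `cutoff`, `members` (sorted symbols).
#' @export
extract_signature <- function(networks, cutoff = 0.7) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  if (!length(networks)) stop_validation("need at least one anchor network")
  stopifnot(all(vapply(networks, inherits, TRUE, "gene_network")))
  if (!is.finite(cutoff) || cutoff <= -1 || cutoff >= 1) {
    stop_validation("cutoff must lie in (-1, 1)")
  }
  cohorts <- unique(vapply(networks, `[[`, "", "cohort"))
  if (length(cohorts) > 1L) {
    stop_validation("all networks must come from the same cohort, got: ",
                    paste(cohorts, collapse = ", "))
  }
  anchors <- vapply(networks, `[[`, "", "anchor")
  member_sets <- lapply(networks, function(net) {
    names(net$coefficients)[net$coefficients > cutoff]
  })
  members <- Reduce(intersect, member_sets)
  members <- sort(setdiff(members, anchors))
  structure(list(anchors = anchors, cohort = cohorts, cutoff = cutoff,
                 members = members),
            class = "network_signature")
}

#' @export
print.network_signature <- function(x, ...) {
  cat("network_signature (anchors ", paste(x$anchors, collapse = "+"),
      ", cutoff ", x$cutoff, "): ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Assess a signature's congruence in the other disease state
#'
#' For each anchor, takes the signature members (defined in one cohort) and
#' asks what fraction of them fall below the cutoff in the other cohort's
#' anchor network, together with a five-number summary of those coefficients
#' (the violin plot reduced to numbers). A high fraction means the
#' co-expression context around the anchor has dissolved in the other state.
#'
#' @param signature A `"network_signature"`.
#' @param other_networks List of `"gene_network"` objects for the same
#'   anchors in the other cohort (matched by anchor symbol).
#' @return Data.frame, one row per anchor: anchor, n_members, n_scored,
#'   fraction_below, min, q1, median, q3, max.
#' @export
cross_state_assessment <- function(signature, other_networks) {
  stopifnot(inherits(signature, "network_signature"))
  if (inherits(other_networks, "gene_network")) {
    other_networks <- list(other_networks)
  }
  other_anchors <- vapply(other_networks, `[[`, "", "anchor")
  rows <- lapply(signature$anchors, function(anc) {
    idx <- match(anc, other_anchors)
    if (is.na(idx)) {
      stop_validation("no other-cohort network for anchor: ", anc)
    }
    net <- other_networks[[idx]]
    coefs <- net$coefficients[intersect(signature$members,
                                        names(net$coefficients))]
    if (!length(coefs)) {
      stop_validation("signature members absent from other-cohort network ",
                      "for anchor: ", anc)
    }
    q <- stats::quantile(coefs, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(anchor = anc,
               n_members = length(signature$members),
               n_scored = length(coefs),
               fraction_below = mean(coefs < signature$cutoff),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential network profile between two cohorts
#'
#' Per gene present in both anchor networks, `delta` is the coefficient in
#' cohort B minus that in cohort A (for the reference use, NEPC minus ADCA),
#' so positive values mark genes more associated with the anchor in B.
#' Genes are densely ranked by descending delta, ties broken by symbol.
#'
#' @param net_b,net_a `"gene_network"` objects for the same anchor in the
#'   two cohorts (B is the state of interest, A the comparator).
#' @return Data.frame of class `"differential_profile"` (gene, r_b, r_a,
#'   delta, rank), sorted by rank; `attr(, "anchor")` and
#'   `attr(, "n_common")` record the anchor and common-gene count.
#' @export
differential_profile <- function(net_b, net_a) {
  stopifnot(inherits(net_b, "gene_network"), inherits(net_a, "gene_network"))
  if (net_b$anchor != net_a$anchor) {
    stop_validation("anchor mismatch: ", net_b$anchor, " vs ", net_a$anchor)
  }
  common <- intersect(names(net_b$coefficients), names(net_a$coefficients))
  common <- setdiff(common, net_b$anchor)
  if (length(common) < 2L) {
    stop_validation("fewer than 2 genes common to both networks")
  }
  delta <- net_b$coefficients[common] - net_a$coefficients[common]
  o <- order(-delta, common)
  df <- data.frame(gene = common[o],
                   r_b = unname(net_b$coefficients[common][o]),
                   r_a = unname(net_a$coefficients[common][o]),
                   delta = unname(delta[o]),
                   stringsAsFactors = FALSE)
  # dense rank over distinct delta values, descending
  df$rank <- cumsum(c(TRUE, diff(df$delta) != 0))
  rownames(df) <- NULL
  class(df) <- c("differential_profile", "data.frame")
  attr(df, "anchor") <- net_b$anchor
  attr(df, "n_common") <- length(common)
  df
}

#' Count gene-set members among the extremes of a differential profile
#'
#' Reports how many members of a gene set (e.g. apoptosis regulators) sit in
#' the `top_n` highest-delta and `top_n` lowest-delta genes of the profile.
#'
#' @param profile A `"differential_profile"`.
#' @param gene_set Character vector of symbols.
#' @param top_n Extreme size (the reference analysis uses 1,000); at most
#'   half the profile.
#' @return A list: `count_top`, `count_bottom`, `members_top`,
#'   `members_bottom`.
#' @export
annotate_extremes <- function(profile, gene_set, top_n = 1000L) {
  top_n <- check_count(top_n, "top_n")
  n <- nrow(profile)
  if (top_n > n / 2) {
    stop_validation("top_n (", top_n, ") exceeds half the profiled genes (",
                    n, ")")
  }
  gene_set <- canonicalize_symbols(gene_set)
  top <- profile$gene[seq_len(top_n)]
  bottom <- profile$gene[seq.int(n - top_n + 1L, n)]
  members_top <- intersect(top, gene_set)
  members_bottom <- intersect(bottom, gene_set)
  list(count_top = length(members_top),
       count_bottom = length(members_bottom),
       members_top = members_top,
       members_bottom = members_bottom)
}
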