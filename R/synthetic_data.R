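# Synthetic-data generators with planted, recorded ground truth. Every
# generator is a pure function of (parameters, seed): the caller's RNG state
# is never consulted or modified. Gaussian constructions are used throughout
# because Pearson correlation is the pipeline's instrument and the
# bivariate/equicorrelated normal gives exact expected correlations.

#' Construct a planted co-dependency truth table
#'
#' Records, per gene, the correlation its dependency profile is to have with
#' the anchor gene's profile within the HI and LO phenotype groups, and
#' whether the gene is flagged as a transcription factor. The anchor's
#' self-correlation is fixed at 1 in both groups.
#'
#' @param anchor Anchor gene symbol.
#' @param genes Character vector of gene symbols (the anchor is added if
#'   absent).
#' @param rho_hi,rho_lo Numeric vectors in `[-1, 1]`, recycled to
#'   `length(genes)`: planted correlation with the anchor in each group.
#' @param tf Logical vector, recycled: transcription-factor flag per gene.
#' @return A data.frame (gene, rho_hi, rho_lo, tf) with the anchor symbol in
#'   `attr(, "anchor")`.
#' @export
dependency_truth <- function(anchor, genes, rho_hi = 0, rho_lo = 0,
                             tf = FALSE) {
  anchor <- canonicalize_symbols(anchor)
  genes <- canonicalize_symbols(genes)
  if (anyDuplicated(genes)) stop_integrity("duplicate genes in truth")
  n <- length(genes)
  rho_hi <- rep_len(as.numeric(rho_hi), n)
  rho_lo <- rep_len(as.numeric(rho_lo), n)
  tf <- rep_len(as.logical(tf), n)
  if (any(abs(c(rho_hi, rho_lo)) > 1, na.rm = TRUE)) {
    stop_validation("planted correlations must lie in [-1, 1]")
  }
  truth <- data.frame(gene = genes, rho_hi = rho_hi, rho_lo = rho_lo,
                      tf = tf, stringsAsFactors = FALSE)
  if (!anchor %in% truth$gene) {
    truth <- rbind(data.frame(gene = anchor, rho_hi = 1, rho_lo = 1,
                              tf = FALSE), truth)
  }
  truth$rho_hi[truth$gene == anchor] <- 1
  truth$rho_lo[truth$gene == anchor] <- 1
  attr(truth, "anchor") <- anchor
  truth
}

#' Construct a planted two-cohort block-correlation truth
#'
#' Assigns each gene to exactly one correlation block per cohort and fixes a
#' within-block target correlation; genes in different blocks are
#' uncorrelated by construction. Block 0 denotes a singleton (independent)
#' gene.
#'
#' @param genes Character vector of gene symbols.
#' @param block_a,block_b Integer vectors, recycled: block id per gene in
#'   cohorts A and B (0 = no block).
#' @param rho_a,rho_b Named numeric vectors giving the within-block target
#'   correlation for each nonzero block id (names are block ids as strings).
#' @param anchors Character vector of anchor gene symbols.
#' @return A list of class `"network_truth"`.
#' @export
network_truth <- function(genes, block_a = 0L, block_b = 0L,
                          rho_a = numeric(0), rho_b = numeric(0),
                          anchors = character(0)) {
  genes <- canonicalize_symbols(genes)
  if (anyDuplicated(genes)) stop_integrity("duplicate genes in truth")
  n <- length(genes)
  tr <- list(
    genes = genes,
    block = list(A = rep_len(as.integer(block_a), n),
                 B = rep_len(as.integer(block_b), n)),
    rho = list(A = rho_a, B = rho_b),
    anchors = canonicalize_symbols(anchors)
  )
  for (co in c("A", "B")) {
    ids <- unique(tr$block[[co]][tr$block[[co]] != 0L])
    missing_rho <- setdiff(as.character(ids), names(tr$rho[[co]]))
    if (length(missing_rho)) {
      stop_validation("no target correlation given for cohort ", co,
                      " block(s): ", paste(missing_rho, collapse = ", "))
    }
    for (id in ids) {
      k <- sum(tr$block[[co]] == id)
      rho <- tr$rho[[co]][[as.character(id)]]
      if (rho >= 1 || rho <= -1) {
        stop_validation("block correlation must lie in (-1, 1)")
      }
      if (k > 1L && rho < -1 / (k - 1L)) {
        stop_validation("block correlation ", rho, " infeasible (not positive",
                        " semi-definite) for block of size ", k)
      }
    }
  }
  structure(tr, class = "network_truth")
}

#' Generate a synthetic SCN-score annotation
#'
#' Draws phenotype scores for two groups of cell lines from Gaussian
#' distributions centred above and below an intended classification cutoff.
#' The generating group of every line is recorded in `truth_group`, so
#' downstream classification accuracy can be measured.
#'
#' @param n_hi,n_lo Number of high- and low-scoring lines.
#' @param hi_center,lo_center Means of the two score distributions.
#' @param spread Standard deviation of both distributions.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param cutoff Intended classification cutoff (default 1.1); a warning is
#'   issued if the centres are within one `spread` of it.
#' @param hi_lineage,lo_lineage Lineage labels assigned to the two groups.
#' @return A data.frame (cell_line, scn_score, lineage, truth_group).
#' @export
gen_scn_annotation <- function(n_hi, n_lo, hi_center, lo_center, spread, seed,
                               cutoff = 1.1, hi_lineage = "SCLC",
                               lo_lineage = "OTHER") {
  n_hi <- check_count(n_hi, "n_hi")
  n_lo <- check_count(n_lo, "n_lo")
  check_scalar_number(spread, "spread", lower = .Machine$double.eps)
  check_scalar_number(hi_center, "hi_center")
  check_scalar_number(lo_center, "lo_center")
  if (hi_center < cutoff + spread || lo_center > cutoff - spread) {
    warning("group centres are within one spread of the cutoff ", cutoff,
            "; HI/LO scores will overlap the boundary")
  }
  scores <- with_seed(seed, c(stats::rnorm(n_hi, hi_center, spread),
                              stats::rnorm(n_lo, lo_center, spread)))
  n <- n_hi + n_lo
  data.frame(
    cell_line = sprintf("LINE%04d", seq_len(n)),
    scn_score = scores,
    lineage = c(rep(hi_lineage, n_hi), rep(lo_lineage, n_lo)),
    truth_group = c(rep("HI", n_hi), rep("LO", n_lo)),
    stringsAsFactors = FALSE
  )
}

#' Generate a dependency-score matrix with planted anchor co-dependencies
#'
#' Within each phenotype group the anchor profile is a standard normal draw
#' across that group's cell lines, and each gene's profile is
#' `rho * anchor + sqrt(1 - rho^2) * noise` with independent unit-normal
#' noise, so the expected Pearson correlation with the anchor equals the
#' planted `rho` exactly. The two groups are generated independently, which
#' lets a gene be strongly co-dependent with the anchor in one group and
#' uncorrelated in the other. Scores are then scaled by `score_sd`
#' (correlations are scale-invariant, so planted values are unaffected) and
#' cells are deleted completely at random at `missing_rate`.
#'
#' @param truth A [dependency_truth()] table.
#' @param annotation An annotation with `cell_line` and `truth_group`
#'   columns, e.g. from [gen_scn_annotation()].
#' @param score_sd Marginal standard deviation of the simulated scores.
#' @param missing_rate Fraction of cells set to missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Numeric genes-by-lines matrix; the truth table is attached as
#'   `attr(, "truth")` and the anchor as `attr(, "anchor")`.
#' @export
gen_dependency_matrix <- function(truth, annotation, score_sd = 1,
                                  missing_rate = 0, seed = 1L) {
  anchor <- attr(truth, "anchor")
  if (is.null(anchor)) stop_validation("truth must carry an anchor attribute")
  if (!nrow(annotation)) stop_validation("annotation is empty")
  check_scalar_number(score_sd, "score_sd", lower = .Machine$double.eps)
  check_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  if (missing_rate >= 1) stop_validation("missing_rate must be < 1")
  if (any(abs(c(truth$rho_hi, truth$rho_lo)) > 1)) {
    stop_validation("planted correlations must lie in [-1, 1]")
  }

  genes <- truth$gene
  m <- with_seed(seed, {
    cols <- lapply(c("HI", "LO"), function(grp) {
      lines <- annotation$cell_line[annotation$truth_group == grp]
      n <- length(lines)
      if (!n) return(NULL)
      rho <- if (grp == "HI") truth$rho_hi else truth$rho_lo
      x <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes))
      block <- rho %o% x + sqrt(pmax(0, 1 - rho^2)) * eps
      block[genes == anchor, ] <- x
      colnames(block) <- lines
      block
    })
    out <- do.call(cbind, cols) * score_sd
    rownames(out) <- genes
    out <- out[, annotation$cell_line, drop = FALSE]
    if (missing_rate > 0) {
      drop <- stats::runif(length(out)) < missing_rate
      out[drop] <- NA_real_
    }
    out
  })
  attr(m, "truth") <- truth
  attr(m, "anchor") <- anchor
  m
}

#' Generate a cohort expression matrix with planted correlation blocks
#'
#' Genes sharing a block are drawn from an equicorrelated multivariate
#' normal at the block's target correlation; genes in different blocks (and
#' block-0 singletons) are independent. Expression values are scaled by
#' `expr_sd` (scale does not affect correlations).
#'
#' @param truth A [network_truth()] object.
#' @param cohort `"A"` or `"B"`: which cohort's block structure to realise.
#' @param n_samples Number of samples (columns); at least 3.
#' @param expr_sd Marginal standard deviation of the simulated expression.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for sample identifiers.
#' @return Numeric genes-by-samples matrix with the truth attached as
#'   `attr(, "truth")`.
#' @export
gen_cohort_expression <- function(truth, cohort = c("A", "B"), n_samples,
                                  expr_sd = 1, seed = 1L,
                                  sample_prefix = NULL) {
  stopifnot(inherits(truth, "network_truth"))
  cohort <- match.arg(cohort)
  n_samples <- check_count(n_samples, "n_samples", min = 3L)
  check_scalar_number(expr_sd, "expr_sd", lower = .Machine$double.eps)
  if (is.null(sample_prefix)) sample_prefix <- paste0(cohort, "_S")

  genes <- truth$genes
  block <- truth$block[[cohort]]
  rho <- truth$rho[[cohort]]
  m <- with_seed(seed, {
    out <- matrix(stats::rnorm(length(genes) * n_samples),
                  nrow = length(genes))
    for (id in unique(block[block != 0L])) {
      idx <- which(block == id)
      k <- length(idx)
      if (k < 2L) next
      r <- rho[[as.character(id)]]
      sigma <- matrix(r, k, k)
      diag(sigma) <- 1
      out[idx, ] <- t(MASS::mvrnorm(n_samples, mu = rep(0, k), Sigma = sigma))
    }
    out
  }) * expr_sd
  dimnames(m) <- list(genes, sprintf("%s%03d", sample_prefix,
                                     seq_len(n_samples)))
  attr(m, "truth") <- truth
  attr(m, "cohort") <- cohort
  m
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Enriched sets are sampled from the top of a score profile (the pool is
#' the highest-scoring `4 * set_size` genes, at least a tenth of the
#' universe), null sets uniformly from all genes, so downstream preranked
#' enrichment has recoverable positives with recorded truth.
#'
#' @param profile_truth Named numeric vector: gene -> score defining "top".
#' @param n_sets Total number of sets.
#' @param set_size Members per set; must be below the universe size.
#' @param n_enriched Number of sets drawn from the top pool (may be 0).
#' @param seed Integer seed.
#' @return A `"gene_set_collection"`; `attr(, "truth")` is a data.frame
#'   (set, enriched).
#' @export
gen_gene_sets <- function(profile_truth, n_sets, set_size, n_enriched, seed) {
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  n_enriched <- check_count(n_enriched, "n_enriched", min = 0L)
  if (n_enriched > n_sets) stop_validation("n_enriched must be <= n_sets")
  genes <- names(profile_truth)
  if (is.null(genes) || !length(genes)) {
    stop_validation("profile_truth must be a named score vector")
  }
  if (set_size >= length(genes)) {
    stop_validation("set_size must be below the gene-universe size")
  }
  pool_n <- min(length(genes),
                max(4L * set_size, ceiling(length(genes) / 10)))
  top_pool <- genes[order(profile_truth, decreasing = TRUE)][seq_len(pool_n)]

  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      if (i <= n_enriched) sample(top_pool, set_size)
      else sample(genes, set_size)
    })
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  coll <- gene_set_collection(
    sets,
    stats::setNames(ifelse(seq_len(n_sets) <= n_enriched,
                           "planted_enriched", "null"), names(sets))
  )
  attr(coll, "truth") <- data.frame(
    set = names(sets),
    enriched = seq_len(n_sets) <= n_enriched,
    stringsAsFactors = FALSE
  )
  coll
}
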