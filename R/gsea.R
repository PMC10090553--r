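# Preranked gene-set enrichment from scratch: weighted Kolmogorov-Smirnov
# style running-sum enrichment score, gene-label permutation null,
# normalized enrichment scores, and the sign-stratified FDR of the classic
# GSEA procedure. Nothing here calls an external GSEA implementation.

#' Order a score vector into a ranked profile
#'
#' Sorts genes by descending score; ties are broken by lexicographic symbol
#' so the ranking is deterministic.
#'
#' @param scores Named numeric vector (gene -> score), e.g. the `delta`
#'   column of a differential profile.
#' @return Named numeric vector sorted for use with [enrichment_score()] and
#'   [gsea_preranked()].
#' @export
ranked_profile <- function(scores) {
  genes <- names(scores)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop_validation("scores must be named with unique gene symbols")
  }
  if (any(!is.finite(scores))) stop_validation("scores must be finite")
  scores[order(-scores, genes)]
}

# Running-sum enrichment score from sorted hit positions.
# pos: strictly increasing positions of the set's hits in the ranked list;
# w: the |score|^p weight at each hit; N: profile length.
# Increments at hit i by w_i / sum(w); decrements at each miss by
# 1/(N - k). ES is the extremum of larger magnitude (positive extremum
# attained just after a hit, negative just before one). If all hit weights
# are zero the hits are weighted equally (unweighted semantics).
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  if (k == 0L || k >= N) {
    stop_validation("gene set must hit some but not all of the profile")
  }
  W <- sum(w)
  if (W == 0) w <- rep(1, k) else w <- w
  W <- sum(w)
  cw <- cumsum(w) / W
  miss_step <- (pos - seq_len(k)) / (N - k)
  tops <- cw - miss_step          # value just after each hit
  bottoms <- c(0, cw[-k]) - miss_step  # value just before each hit
  i_top <- which.max(tops)
  i_bot <- which.min(bottoms)
  # exact magnitude ties (possible with the unweighted statistic) resolve
  # to the positive extremum; the 1e-9 pad keeps the choice stable against
  # floating-point accumulation order
  if (tops[i_top] >= -bottoms[i_bot] - 1e-9) {
    list(es = unname(tops[i_top]), extremum_hit = i_top, positive = TRUE)
  } else {
    list(es = unname(bottoms[i_bot]), extremum_hit = i_bot, positive = FALSE)
  }
}

#' Weighted running-sum enrichment score of a gene set in a ranked profile
#'
#' Walks the ranked profile; at each set member ("hit") the running sum
#' rises by that gene's `|score|^weight_p` (normalized so the hits sum to
#' 1), at each non-member it falls by `1/(N - n_hits)`. The enrichment
#' score is the extremum of the walk with the larger magnitude. The leading
#' edge is the set members at or before the extremum for positive ES, and
#' at or after it for negative ES.
#'
#' @param profile Ranked profile from [ranked_profile()] (named, descending).
#' @param gene_set Character vector of member symbols.
#' @param weight_p Weighting exponent on `|score|` (default 1, classic
#'   weighted GSEA; 0 gives the unweighted statistic).
#' @return A list: `es`, `n_hits`, `extremum_rank` (profile position of the
#'   extremum), `leading_edge` (symbols in profile order).
#' @export
enrichment_score <- function(profile, gene_set, weight_p = 1) {
  check_scalar_number(weight_p, "weight_p", lower = 0)
  N <- length(profile)
  genes <- names(profile)
  pos <- sort(match(unique(canonicalize_symbols(gene_set)), genes))
  pos <- pos[!is.na(pos)]
  k <- length(pos)
  if (k == 0L || k >= N) {
    stop_validation("gene set must hit some but not all of the profile (",
                    k, " of ", N, " hit)")
  }
  w <- abs(profile[pos])^weight_p
  res <- .es_from_positions(pos, w, N)
  le_idx <- if (res$positive) pos[seq_len(res$extremum_hit)]
            else pos[seq.int(res$extremum_hit, k)]
  list(es = res$es, n_hits = k,
       extremum_rank = pos[res$extremum_hit],
       leading_edge = genes[le_idx])
}

#' Preranked gene-set enrichment with permutation null and FDR
#'
#' For every gene set with an in-profile hit count inside
#' `[min_hits, max_hits]`, computes the observed enrichment score, a
#' gene-label permutation null (random same-size draws from the profile;
#' nulls are shared across sets of equal size, which leaves the null
#' distribution unchanged and makes the run fast and deterministic), the
#' one-tailed nominal p with +1 smoothing, the normalized enrichment score
#' (ES divided by the mean null ES magnitude of matching sign), and the
#' sign-stratified FDR q of the classic GSEA procedure. A plain
#' Benjamini-Hochberg q on the nominal p-values is also reported for
#' cross-checking.
#'
#' @param profile Named numeric score vector (sorted internally via
#'   [ranked_profile()]); at least 10 genes.
#' @param sets A `"gene_set_collection"` or named list of symbol vectors.
#' @param weight_p Weighting exponent (default 1).
#' @param n_perm Number of permutations per set size (default 1000, minimum
#'   100).
#' @param seed Integer seed for the permutation draws.
#' @param min_hits,max_hits Hit-count bounds for a set to be scored
#'   (defaults 5 and 500).
#' @return Data.frame, one row per scored set: set, es, nes, p_nominal,
#'   fdr_q, bh_q, n_hits, leading_edge (comma-joined). Sets excluded by the
#'   hit bounds are listed in `attr(, "excluded")`.
#' @export
gsea_preranked <- function(profile, sets, weight_p = 1, n_perm = 1000L,
                           seed = 1L, min_hits = 5L, max_hits = 500L) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (!is.list(sets) || is.null(names(sets))) {
    stop_validation("sets must be a gene_set_collection or named list")
  }
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  min_hits <- check_count(min_hits, "min_hits")
  max_hits <- check_count(max_hits, "max_hits", min = min_hits)
  profile <- ranked_profile(profile)
  N <- length(profile)
  if (N < 10L) stop_validation("profile must contain at least 10 genes")
  genes <- names(profile)

  hit_pos <- lapply(sets, function(s) {
    p <- match(unique(canonicalize_symbols(s)), genes)
    sort(p[!is.na(p)])
  })
  n_hits <- lengths(hit_pos)
  keep <- n_hits >= min_hits & n_hits <= max_hits & n_hits < N
  if (!any(keep)) {
    warning("no gene set has a hit count within [", min_hits, ", ",
            max_hits, "]")
    out <- data.frame(set = character(0), es = numeric(0), nes = numeric(0),
                      p_nominal = numeric(0), fdr_q = numeric(0),
                      bh_q = numeric(0), n_hits = integer(0),
                      leading_edge = character(0), stringsAsFactors = FALSE)
    attr(out, "excluded") <- names(sets)
    return(out)
  }

  obs <- lapply(names(sets)[keep], function(nm) {
    enrichment_score(profile, sets[[nm]], weight_p)
  })
  es_obs <- vapply(obs, `[[`, 0, "es")

  # Shared permutation null per distinct set size, in sorted-size order so
  # the draw sequence is a pure function of the seed.
  sizes <- sort(unique(n_hits[keep]))
  null_es <- with_seed(seed, {
    out <- lapply(sizes, function(k) {
      vapply(seq_len(n_perm), function(i) {
        pos <- sort(sample.int(N, k))
        .es_from_positions(pos, abs(profile[pos])^weight_p, N)$es
      }, 0)
    })
    names(out) <- as.character(sizes)
    out
  })

  size_key <- as.character(n_hits[keep])
  p_nom <- numeric(sum(keep))
  nes <- numeric(sum(keep))
  null_nes_all <- vector("list", sum(keep))
  for (i in seq_along(es_obs)) {
    nulls <- null_es[[size_key[i]]]
    pos_mean <- mean(nulls[nulls >= 0])
    neg_mean <- mean(abs(nulls[nulls < 0]))
    if (es_obs[i] >= 0) {
      same <- nulls[nulls >= 0]
      p_nom[i] <- (1 + sum(same >= es_obs[i])) / (1 + length(same))
      nes[i] <- if (is.finite(pos_mean) && pos_mean > 0)
        es_obs[i] / pos_mean else NA_real_
    } else {
      same <- nulls[nulls < 0]
      p_nom[i] <- (1 + sum(same <= es_obs[i])) / (1 + length(same))
      nes[i] <- if (is.finite(neg_mean) && neg_mean > 0)
        es_obs[i] / neg_mean else NA_real_
    }
    nn <- nulls
    nn[nulls >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      nulls[nulls >= 0] / pos_mean else NA_real_
    nn[nulls < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      nulls[nulls < 0] / neg_mean else NA_real_
    null_nes_all[[i]] <- nn
  }
  all_null_nes <- unlist(null_nes_all, use.names = FALSE)
  all_null_nes <- all_null_nes[is.finite(all_null_nes)]

  fdr_q <- vapply(seq_along(nes), function(i) {
    v <- nes[i]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num_den <- sum(all_null_nes >= 0)
      num <- if (num_den) sum(all_null_nes >= v) / num_den else 1
      obs_den <- sum(nes >= 0, na.rm = TRUE)
      den <- if (obs_den) sum(nes >= v, na.rm = TRUE) / obs_den else 1
    } else {
      num_den <- sum(all_null_nes < 0)
      num <- if (num_den) sum(all_null_nes <= v) / num_den else 1
      obs_den <- sum(nes < 0, na.rm = TRUE)
      den <- if (obs_den) sum(nes <= v, na.rm = TRUE) / obs_den else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)

  out <- data.frame(
    set = names(sets)[keep],
    es = es_obs,
    nes = nes,
    p_nominal = p_nom,
    fdr_q = fdr_q,
    bh_q = stats::p.adjust(p_nom, method = "BH"),
    n_hits = n_hits[keep],
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$nes, out$p_nominal, out$set), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- names(sets)[!keep]
  attr(out, "n_perm") <- n_perm
  attr(out, "weight_p") <- weight_p
  out
}
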