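## Round-over-round enrichment, candidate ranking, GC-binned amplification
## bias, diversity gain/loss between amplification arms, and convergence.

#' Round-over-round enrichment rate
#'
#' The ratio of a sequence's prevalence in the later round to its prevalence
#' in the earlier round. A sequence absent from the earlier round would have
#' an infinite raw ratio, so the pseudocount is applied to both numerator and
#' denominator in that case only: `(count_next + p) / p`. When both counts
#' are zero the rate is undefined (`NA`).
#'
#' @param count_prev,count_next non-negative counts (vectorised).
#' @param pseudocount positive value used only when `count_prev == 0`
#'   (default 0.5).
#' @return numeric vector of rates (full precision; tables conventionally
#'   print them rounded to one decimal).
#' @export
enrichment_rate <- function(count_prev, count_next, pseudocount = 0.5) {
  stopifnot(pseudocount > 0, all(count_prev >= 0), all(count_next >= 0))
  n <- max(length(count_prev), length(count_next))
  count_prev <- rep_len(count_prev, n)
  count_next <- rep_len(count_next, n)
  rate <- ifelse(count_prev > 0, count_next / count_prev,
                 (count_next + pseudocount) / pseudocount)
  rate[count_prev == 0 & count_next == 0] <- NA_real_
  rate
}

#' GC content of DNA strings
#'
#' @param x character vector of sequences.
#' @return numeric fraction of G+C in `[0, 1]` per sequence.
#' @export
gc_content <- function(x) {
  as.numeric(Biostrings::letterFrequency(Biostrings::DNAStringSet(x), "GC",
                                         as.prob = TRUE))
}

#' Enrichment records across consecutive rounds
#'
#' Builds the per-sequence prevalence trajectory and one enrichment rate per
#' consecutive round transition. By default rates are raw-count ratios; with
#' `normalize = TRUE` counts are first scaled to reads-per-million within
#' each pool (for pools of unequal depth).
#'
#' @param combined combined census (see [combine_censuses()]).
#' @param round_pools character vector of pool_id column names in round
#'   order.
#' @param normalize scale to reads-per-million before taking ratios.
#' @param pseudocount see [enrichment_rate()].
#' @return data.frame: `sequence`, the count columns, `gc`, and one
#'   `rate_<from>_<to>` column per transition. The final transition's rate is
#'   repeated in `enrichment` and the final round's count in `prevalence`
#'   (the two default ranking keys).
#' @export
enrichment_table <- function(combined, round_pools, normalize = FALSE,
                             pseudocount = 0.5) {
  stopifnot(length(round_pools) >= 2,
            all(round_pools %in% names(combined)))
  out <- combined[c("sequence", round_pools)]
  out$gc <- gc_content(out$sequence)
  mat <- as.matrix(combined[round_pools])
  if (normalize) {
    depth <- colSums(mat)
    mat <- sweep(mat, 2L, depth / 1e6, "/")
  }
  for (j in seq_len(length(round_pools) - 1L)) {
    out[[paste0("rate_", round_pools[j], "_", round_pools[j + 1L])]] <-
      enrichment_rate(mat[, j], mat[, j + 1L], pseudocount)
  }
  nt <- length(round_pools)
  out$prevalence <- combined[[round_pools[nt]]]
  out$enrichment <-
    out[[paste0("rate_", round_pools[nt - 1L], "_", round_pools[nt])]]
  out
}

#' Rank candidate sequences by prevalence, enrichment, or both
#'
#' `"prevalence"` ranks by final-round copy number, `"enrichment"` by the
#' final round-over-round rate. `"combined"` ranks each sequence by the worse
#' (numerically larger) of its two individual ranks, so a top candidate must
#' rank high on both axes; ties are broken by prevalence, then sequence.
#' `NA` rates rank last.
#'
#' @param records data.frame with `prevalence` and `enrichment` columns
#'   (see [enrichment_table()]).
#' @param mode `"prevalence"`, `"enrichment"` or `"combined"`.
#' @return `records` reordered best-first, with `rank_prevalence`,
#'   `rank_enrichment` and `rank` columns added.
#' @export
rank_candidates <- function(records,
                            mode = c("combined", "prevalence", "enrichment")) {
  mode <- match.arg(mode)
  stopifnot(nrow(records) >= 1)
  enr <- records$enrichment
  enr[is.na(enr)] <- -Inf
  records$rank_prevalence <- rank(-records$prevalence, ties.method = "min")
  records$rank_enrichment <- rank(-enr, ties.method = "min")
  key <- switch(mode,
                prevalence = records$rank_prevalence,
                enrichment = records$rank_enrichment,
                combined = pmax(records$rank_prevalence,
                                records$rank_enrichment))
  ord <- order(key, -records$prevalence, records$sequence)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Mean enrichment rate per GC-content bin, for two amplification arms
#'
#' Pools sequences by the GC content of their random region and reports the
#' arithmetic mean enrichment rate per bin in each arm — the standard view of
#' GC-dependent PCR bias (uniform across bins for emulsion PCR, decreasing
#' with GC for open PCR). Default bins are deciles of the observed GC values
#' pooled over both arms; pass explicit `breaks` to fix the bin edges.
#'
#' @param records_a,records_b data.frames with `sequence`, `gc`,
#'   `enrichment` columns (see [enrichment_table()]), one per arm.
#' @param bins number of quantile bins when `breaks` is NULL (default 10).
#' @param breaks optional explicit GC bin edges.
#' @return data.frame: `bin`, `gc_lo`, `gc_hi`, `n_a`, `mean_rate_a`,
#'   `n_b`, `mean_rate_b` (empty bins report `NA` means).
#' @export
gc_binned_enrichment <- function(records_a, records_b, bins = 10L,
                                 breaks = NULL) {
  gc_all <- c(records_a$gc, records_b$gc)
  if (is.null(breaks)) {
    breaks <- unique(quantile(gc_all, probs = seq(0, 1, length.out = bins + 1),
                              na.rm = TRUE))
    if (length(breaks) < 2) breaks <- c(breaks, breaks + 1e-9)
  }
  cut_arm <- function(rec)
    cut(rec$gc, breaks = breaks, include.lowest = TRUE)
  ba <- cut_arm(records_a); bb <- cut_arm(records_b)
  lv <- levels(ba)
  mean_in <- function(rates, f, level) {
    x <- rates[!is.na(f) & f == level & !is.na(rates)]
    if (length(x)) mean(x) else NA_real_
  }
  data.frame(
    bin = seq_along(lv),
    gc_lo = breaks[-length(breaks)],
    gc_hi = breaks[-1],
    n_a = as.integer(table(ba)[lv]),
    mean_rate_a = vapply(lv, function(l)
      mean_in(records_a$enrichment, ba, l), numeric(1)),
    n_b = as.integer(table(bb)[lv]),
    mean_rate_b = vapply(lv, function(l)
      mean_in(records_b$enrichment, bb, l), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Diversity gain/loss between an earlier and a later pool
#'
#' Set algebra on census keys: how many of the earlier pool's unique
#' sequences fail to reappear later (`n_lost`), how many later sequences are
#' new (`n_new`), and the net diversity change as a fraction of the earlier
#' pool. The `low_abundance` component restricts the loss accounting to
#' earlier-pool sequences with copy number at or below the cutoff — rare
#' sequences are the first casualties of a biased amplification step.
#'
#' @param census_prior,census_later `pool_census` objects (or named count
#'   vectors).
#' @param low_abundance_cutoff prior-count cutoff for the restricted
#'   accounting (default 100).
#' @return list with `overall` (data.frame `n_prior`, `n_lost`, `n_new`,
#'   `net_change_fraction`) and `low_abundance` (data.frame `n_prior`,
#'   `n_lost`, `n_recovered`, `lost_fraction`).
#' @export
diversity_accounting <- function(census_prior, census_later,
                                 low_abundance_cutoff = 100L) {
  cp <- if (inherits(census_prior, "pool_census")) census_prior$counts
        else census_prior
  cl <- if (inherits(census_later, "pool_census")) census_later$counts
        else census_later
  if (length(cp) && length(cl) &&
      length(unique(nchar(c(names(cp)[1], names(cl)[1])))) != 1)
    stop("censuses do not share a region length")
  prior <- names(cp); later <- names(cl)
  n_prior <- length(prior)
  lost <- setdiff(prior, later)
  new <- setdiff(later, prior)
  low <- prior[cp <= low_abundance_cutoff]
  low_lost <- intersect(low, lost)
  list(
    overall = data.frame(
      n_prior = n_prior, n_lost = length(lost), n_new = length(new),
      net_change_fraction =
        if (n_prior) (length(new) - length(lost)) / n_prior else NA_real_),
    low_abundance = data.frame(
      n_prior = length(low), n_lost = length(low_lost),
      n_recovered = length(low) - length(low_lost),
      lost_fraction =
        if (length(low)) length(low_lost) / length(low) else NA_real_))
}

#' Convergence report across selection rounds
#'
#' A selection converges when competition between enriched families starts
#' eliminating whole clusters: the number of distinct clusters drops while
#' the surviving clusters keep growing. This flags the first round where
#' `n_clusters` decreases from the previous round while the mean members per
#' cluster increases.
#'
#' @param cluster_stats data.frame with `round`, `n_clusters`,
#'   `mean_members_per_cluster` (see [round_composition()]).
#' @return the input ordered by round with a logical `convergence_flag`
#'   column, plus attribute `converged_round` (NA if never flagged).
#' @export
convergence_report <- function(cluster_stats) {
  stopifnot(nrow(cluster_stats) >= 2,
            all(c("round", "n_clusters", "mean_members_per_cluster") %in%
                  names(cluster_stats)))
  cs <- cluster_stats[order(cluster_stats$round), , drop = FALSE]
  d_n <- c(NA, diff(cs$n_clusters))
  d_m <- c(NA, diff(cs$mean_members_per_cluster))
  cs$convergence_flag <- !is.na(d_n) & d_n < 0 & !is.na(d_m) & d_m > 0
  attr(cs, "converged_round") <-
    if (any(cs$convergence_flag)) cs$round[which(cs$convergence_flag)[1]]
    else NA_integer_
  rownames(cs) <- NULL
  cs
}
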