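## Reference-pool specificity screening: ten-fold pattern rule, pH-adjusted
## electrostatic-binder exclusion, cross-species calls.

#' Classify a sequence's target-vs-control distribution pattern
#'
#' The ten-fold rule on pseudocounted prevalence ratios: with
#' `r = (count_target + p) / (count_control + p)`, a sequence is
#' `target_specific` when `r >= fold`, `control_preferential` when
#' `r <= 1/fold`, and `shared` otherwise. The rule is antisymmetric in its
#' two pools: swapping target and control swaps the two extreme patterns and
#' leaves `shared` fixed.
#'
#' @param count_target,count_control non-negative counts (vectorised; they
#'   should be depth-comparable — see [normalize_depth()]).
#' @param fold fold-change boundary (> 1, default 10).
#' @param pseudocount added to both counts (default 0.5).
#' @return character vector: `target_specific`, `shared`, or
#'   `control_preferential`.
#' @export
classify_pattern <- function(count_target, count_control, fold = 10,
                             pseudocount = 0.5) {
  stopifnot(fold > 1, all(count_target >= 0), all(count_control >= 0))
  r <- (count_target + pseudocount) / (count_control + pseudocount)
  ifelse(r >= fold, "target_specific",
         ifelse(r <= 1 / fold, "control_preferential", "shared"))
}

#' Flag electrostatic (charge-driven) binders via a pH-adjusted control
#'
#' When the control protein is assayed in a buffer adjusted so that its net
#' charge turns positive, sequences that bind through electrostatic rather
#' than specific interactions become strongly enriched on it. A sequence is
#' flagged (for exclusion from candidate lists) when its prevalence on the
#' adjusted control exceeds its prevalence on the normal control
#' `fold`-times, after pseudocounting.
#'
#' @param count_control_normal,count_control_adjusted non-negative counts.
#' @param fold flag boundary (default 10).
#' @param pseudocount added to both counts (default 0.5).
#' @return logical vector, `TRUE` = flagged for exclusion.
#' @export
electrostatic_filter <- function(count_control_normal, count_control_adjusted,
                                 fold = 10, pseudocount = 0.5) {
  stopifnot(all(count_control_normal >= 0), all(count_control_adjusted >= 0))
  (count_control_adjusted + pseudocount) /
    (count_control_normal + pseudocount) >= fold
}

#' Call cross-species (cross-reactive) candidates
#'
#' A sequence is cross-species when it is `target_specific` against the
#' control in BOTH target pools (e.g. the human receptor and its murine
#' ortholog) and its prevalences in the two target pools are within a
#' `similarity` fold-change of each other ("enriched equally well").
#'
#' @param count_target_a,count_target_b,count_control non-negative counts
#'   (vectorised).
#' @param fold ten-fold rule boundary vs the control (default 10).
#' @param pseudocount added to counts in all ratios (default 0.5).
#' @param similarity maximum fold-difference between the two target
#'   prevalences (default 3).
#' @return data.frame: `pattern_a`, `pattern_b` (each vs control),
#'   `cross_species` logical.
#' @export
cross_species_call <- function(count_target_a, count_target_b, count_control,
                               fold = 10, pseudocount = 0.5, similarity = 3) {
  pa <- classify_pattern(count_target_a, count_control, fold, pseudocount)
  pb <- classify_pattern(count_target_b, count_control, fold, pseudocount)
  ra <- count_target_a + pseudocount
  rb <- count_target_b + pseudocount
  similar <- pmax(ra, rb) / pmin(ra, rb) <= similarity
  data.frame(pattern_a = pa, pattern_b = pb,
             cross_species = pa == "target_specific" &
               pb == "target_specific" & similar,
             stringsAsFactors = FALSE)
}

#' Scale pool counts to a common depth when depths are unequal
#'
#' Prevalences from pools of very different sequencing depth are not
#' directly comparable. When the deepest and shallowest pool differ by more
#' than `max_ratio` (default 2), every pool's counts are rescaled to the mean
#' depth; otherwise raw counts are returned unchanged.
#'
#' @param counts named list of non-negative count vectors, one per pool,
#'   all the same length.
#' @param max_ratio depth ratio above which normalization kicks in.
#' @return list of (possibly rescaled) count vectors, with attribute
#'   `normalized` (logical).
#' @export
normalize_depth <- function(counts, max_ratio = 2) {
  depth <- vapply(counts, sum, numeric(1))
  normalized <- length(depth) > 1 && min(depth) > 0 &&
    max(depth) / min(depth) > max_ratio
  if (normalized) {
    target <- mean(depth)
    counts <- lapply(seq_along(counts),
                     function(j) counts[[j]] * target / depth[j])
    names(counts) <- names(depth)
  }
  structure(counts, normalized = normalized)
}

#' Specificity table across target, control and ortholog pools
#'
#' For every sequence in the combined census, classifies the
#' target-vs-control distribution pattern, applies the electrostatic filter
#' when a pH-adjusted control pool is configured, evaluates the pattern
#' against every configured control (a sequence is excluded if flagged or
#' control-preferential against ANY of them), and makes the cross-species
#' call when an ortholog pool is configured. Counts are depth-normalized
#' first via [normalize_depth()].
#'
#' @param combined combined census.
#' @param target pool_id of the target pool.
#' @param control pool_id of the primary control (carrier) pool.
#' @param adjusted optional pool_id of the pH-adjusted control pool.
#' @param ortholog optional pool_id of the species-ortholog target pool.
#' @param extra_controls optional character vector of additional control
#'   pool_ids.
#' @param fold,pseudocount,similarity see [classify_pattern()] and
#'   [cross_species_call()].
#' @return data.frame: `sequence`, per-pool counts, `pattern`,
#'   `electrostatic_flag`, `excluded`, and (with an ortholog)
#'   `pattern_ortholog`, `cross_species`.
#' @export
specificity_table <- function(combined, target, control, adjusted = NULL,
                              ortholog = NULL, extra_controls = NULL,
                              fold = 10, pseudocount = 0.5, similarity = 3) {
  pools <- c(target, control, adjusted, ortholog, extra_controls)
  stopifnot(all(pools %in% names(combined)))
  raw <- lapply(pools, function(p) combined[[p]])
  names(raw) <- pools
  cnt <- normalize_depth(raw)
  out <- data.frame(sequence = combined$sequence, stringsAsFactors = FALSE)
  for (p in pools) out[[p]] <- combined[[p]]
  out$pattern <- classify_pattern(cnt[[target]], cnt[[control]],
                                  fold, pseudocount)
  out$electrostatic_flag <-
    if (!is.null(adjusted))
      electrostatic_filter(cnt[[control]], cnt[[adjusted]], fold, pseudocount)
    else FALSE
  excluded <- out$pattern == "control_preferential" | out$electrostatic_flag
  for (p in extra_controls) {
    excluded <- excluded |
      classify_pattern(cnt[[target]], cnt[[p]], fold, pseudocount) ==
        "control_preferential"
  }
  out$excluded <- excluded
  if (!is.null(ortholog)) {
    cs <- cross_species_call(cnt[[target]], cnt[[ortholog]], cnt[[control]],
                             fold, pseudocount, similarity)
    out$pattern_ortholog <- cs$pattern_b
    out$cross_species <- cs$cross_species
  }
  out
}
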