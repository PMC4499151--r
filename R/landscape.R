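## Within-cluster mutational landscape: cluster substitution rate,
## per-position attribution, high/low flags, candidate variant nomination.

#' Cluster-average substitution rate
#'
#' The total copy number of all derivative sequences in a cluster (every
#' member except the founder), divided by the founder's copy number and by
#' the random-region length: `sigma = sum(derivative copies) /
#' (founder_count * L)`. It estimates the per-position rate at which
#' PCR-mutagenesis variants of the founder accumulate through selection.
#'
#' @param members data.frame of one cluster's members with columns
#'   `sequence`, `is_founder` and a count column (see [cluster_members()]).
#' @param pool name of the count column to use (e.g. a pool_id); defaults to
#'   `"total"`.
#' @return `sigma`, or `NA` when the founder is absent from the pool.
#' @export
substitution_rate <- function(members, pool = "total") {
  stopifnot(pool %in% names(members), sum(members$is_founder) == 1)
  counts <- members[[pool]]
  founder_count <- counts[members$is_founder]
  if (founder_count <= 0) return(NA_real_)
  L <- nchar(members$sequence[members$is_founder])
  sum(counts[!members$is_founder]) / (founder_count * L)
}

## Positions and bases of the single difference between founder and a
## same-length Hamming-1 variant; NA row when the variant is not that.
single_substitution <- function(founder, variants) {
  Lf <- nchar(founder)
  out <- data.frame(position = rep(NA_integer_, length(variants)),
                    ref = rep(NA_character_, length(variants)),
                    alt = rep(NA_character_, length(variants)),
                    stringsAsFactors = FALSE)
  if (!length(variants)) return(out)
  same_len <- nchar(variants) == Lf
  if (!any(same_len)) return(out)
  fm <- strsplit(founder, "")[[1]]
  for (i in which(same_len)) {
    vm <- strsplit(variants[i], "")[[1]]
    diffs <- which(vm != fm)
    if (length(diffs) == 1L) {
      out$position[i] <- diffs
      out$ref[i] <- fm[diffs]
      out$alt[i] <- vm[diffs]
    }
  }
  out
}

#' Per-position mutational landscape of a cluster
#'
#' Attributes every single-substitution variant's copies to its position and
#' alternative base. Variants at edit distance 2-3 from the founder and
#' indel variants are tallied in an `other` class: they contribute to the
#' cluster substitution rate but not to per-position attribution. Under a
#' uniform mutagenesis model the expected copy total at each position is
#' `founder_count * sigma`; a position is flagged `high` when its observed
#' total is at least `high_fold` times that expectation, `low` when at most
#' `low_fold` times it, `normal` otherwise. A one-sided Poisson tail
#' probability (mean = expected) is reported alongside the fold flags as a
#' rough significance guide.
#'
#' @param members one cluster's members (see [cluster_members()]).
#' @param pool count column to profile (default `"total"`).
#' @param high_fold,low_fold flag boundaries (defaults 3 and 1/3).
#' @return object of class `landscape_table`: list with `cluster_id`,
#'   `founder`, `L`, `founder_count`, `sigma`, `other_copies` (multi-edit /
#'   indel derivative copies), `expected_per_position`, `variants`
#'   (data.frame of attributed single-substitution variants) and
#'   `per_position` (data.frame over positions `1..L`: `position`, `ref`,
#'   copy totals per alternative base `A`/`C`/`G`/`T`, `total_copies`,
#'   `n_distinct_variants`, `expected`, `flag`, `p_high`, `p_low`).
#' @export
position_profile <- function(members, pool = "total",
                             high_fold = 3, low_fold = 1 / 3) {
  stopifnot(sum(members$is_founder) == 1)
  founder <- members$sequence[members$is_founder]
  founder_count <- members[[pool]][members$is_founder]
  L <- nchar(founder)
  sigma <- substitution_rate(members, pool)
  deriv <- members[!members$is_founder, , drop = FALSE]
  deriv <- deriv[deriv[[pool]] > 0, , drop = FALSE]
  sub <- single_substitution(founder, deriv$sequence)
  is_single <- !is.na(sub$position)
  variants <- data.frame(sequence = deriv$sequence[is_single],
                         position = sub$position[is_single],
                         ref = sub$ref[is_single],
                         alt = sub$alt[is_single],
                         copies = deriv[[pool]][is_single],
                         stringsAsFactors = FALSE)
  other_copies <- sum(deriv[[pool]][!is_single])
  bases <- c("A", "C", "G", "T")
  per_pos <- data.frame(position = seq_len(L),
                        ref = strsplit(founder, "")[[1]],
                        stringsAsFactors = FALSE)
  for (b in bases) {
    v <- numeric(L)
    hit <- variants$alt == b
    if (any(hit)) {
      agg <- tapply(variants$copies[hit], variants$position[hit], sum)
      v[as.integer(names(agg))] <- agg
    }
    v[per_pos$ref == b] <- NA        # founder base, not a substitution
    per_pos[[b]] <- v
  }
  mat <- as.matrix(per_pos[bases])
  per_pos$total_copies <- rowSums(mat, na.rm = TRUE)
  per_pos$n_distinct_variants <- rowSums(mat > 0, na.rm = TRUE)
  expected <- if (is.na(sigma)) NA_real_ else founder_count * sigma
  per_pos$expected <- expected
  per_pos$flag <- if (is.na(expected) || expected == 0) {
    ifelse(per_pos$total_copies > 0, "high", "normal")
  } else {
    ifelse(per_pos$total_copies >= high_fold * expected, "high",
           ifelse(per_pos$total_copies <= low_fold * expected, "low",
                  "normal"))
  }
  per_pos$p_high <- ppois(per_pos$total_copies - 1, expected,
                          lower.tail = FALSE)
  per_pos$p_low <- ppois(per_pos$total_copies, expected)
  structure(list(cluster_id = if ("cluster_id" %in% names(members))
                   members$cluster_id[1] else NA_character_,
                 founder = founder, L = L, founder_count = founder_count,
                 sigma = sigma, other_copies = other_copies,
                 expected_per_position = expected,
                 variants = variants, per_position = per_pos),
            class = "landscape_table")
}

#' @export
print.landscape_table <- function(x, ...) {
  cat("landscape_table for cluster ", x$cluster_id, " (founder count ",
      x$founder_count, ", L = ", x$L, ")\n", sep = "")
  cat("  sigma = ", format(x$sigma, digits = 4),
      ", expected copies/position = ",
      format(x$expected_per_position, digits = 4), "\n", sep = "")
  flags <- x$per_position$flag
  cat("  positions flagged high: ",
      paste(x$per_position$position[flags == "high"], collapse = ", "),
      "\n  positions flagged low:  ",
      paste(x$per_position$position[flags == "low"], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Nominate cluster variants for affinity testing
#'
#' Returns the single-substitution variants sitting at `high`-flagged
#' positions, ranked by copy number. Variants at positions where all three
#' alternative bases occur, each at roughly the average per-variant rate
#' (within `high_fold`/`low_fold` of `expected/3`), are down-ranked below
#' the rest: a position that tolerates every substitution equally is more
#' likely mutable-neutral than affinity-improving, whereas a single
#' dominant substitution suggests a genuine gain.
#'
#' @param table a `landscape_table` from [position_profile()].
#' @param high_fold,low_fold the fold boundaries used for the flags.
#' @return data.frame of candidate variants: `sequence`, `position`, `ref`,
#'   `alt`, `copies`, `down_ranked`; best candidate first. Zero rows when no
#'   position is flagged high.
#' @export
candidate_variants <- function(table, high_fold = 3, low_fold = 1 / 3) {
  stopifnot(inherits(table, "landscape_table"))
  pp <- table$per_position
  high_pos <- pp$position[pp$flag == "high"]
  v <- table$variants[table$variants$position %in% high_pos, , drop = FALSE]
  if (!nrow(v)) {
    v$down_ranked <- logical(0)
    return(v)
  }
  exp_var <- table$expected_per_position / 3   # per alternative base
  uniform_pos <- vapply(unique(v$position), function(p) {
    row <- pp[pp$position == p, , drop = FALSE]
    if (row$n_distinct_variants != 3L) return(FALSE)
    copies <- unlist(row[c("A", "C", "G", "T")])
    copies <- copies[!is.na(copies)]
    all(copies >= low_fold * exp_var & copies <= high_fold * exp_var)
  }, logical(1))
  v$down_ranked <- v$position %in% unique(v$position)[uniform_pos]
  v <- v[order(v$down_ranked, -v$copies, v$sequence), , drop = FALSE]
  rownames(v) <- NULL
  v
}
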