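## Per-pool prevalence censuses and bystander / true-aptamer classification.

#' Build a prevalence census for one pool
#'
#' Counts every unique random-region sequence in a pool. The census is a hash
#' of sequence to copy number ("prevalence") and is deterministic regardless
#' of read order.
#'
#' @param regions character vector of random-region sequences (all the same
#'   length).
#' @param pool_id pool identifier.
#' @return an object of class `pool_census`: list with `pool_id`, `counts`
#'   (named integer vector, descending count then lexicographic), and
#'   `total_reads`.
#' @export
build_census <- function(regions, pool_id) {
  regions <- as.character(regions)
  if (length(regions)) {
    len <- nchar(regions)
    if (length(unique(len)) != 1)
      stop("mixed region lengths in pool '", pool_id, "': first offender ",
           regions[which(len != len[1])[1]])
  }
  tab <- table(regions)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  structure(list(pool_id = as.character(pool_id), counts = counts,
                 total_reads = length(regions)),
            class = "pool_census")
}

#' @export
print.pool_census <- function(x, ...) {
  cat("pool_census '", x$pool_id, "': ", length(x$counts),
      " unique sequences, ", x$total_reads, " reads\n", sep = "")
  invisible(x)
}

#' Combine per-pool censuses into a wide sequence-by-pool count table
#'
#' @param censuses list of `pool_census` objects (or a single one).
#' @return data.frame with columns `sequence`, one count column per pool_id,
#'   and `total`; rows ordered by descending total then sequence.
#' @export
combine_censuses <- function(censuses) {
  if (inherits(censuses, "pool_census")) censuses <- list(censuses)
  stopifnot(length(censuses) >= 1)
  ids <- vapply(censuses, function(cn) cn$pool_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate pool_ids in censuses")
  lens <- unlist(lapply(censuses, function(cn) unique(nchar(names(cn$counts)))))
  if (length(unique(lens)) > 1)
    stop("censuses do not share a region length")
  seqs <- sort(unique(unlist(lapply(censuses, function(cn) names(cn$counts)))))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (cn in censuses) {
    v <- integer(length(seqs))
    idx <- match(names(cn$counts), seqs)
    v[idx] <- unname(cn$counts)
    out[[cn$pool_id]] <- v
  }
  out$total <- as.integer(rowSums(out[, ids, drop = FALSE]))
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_ids") <- ids
  out
}

pool_ids_of <- function(combined) {
  ids <- attr(combined, "pool_ids")
  if (is.null(ids)) ids <- setdiff(names(combined),
                                   c("sequence", "total"))
  ids
}

#' Classify sequences as bystander, unclustered or clustered
#'
#' A bystander is a sequence seen exactly once in the entire dataset (one
#' copy, one pool); everything else is a true aptamer, either because it is
#' present in multiple copies or because it recurs in different pools. Among
#' true aptamers, a sequence is `clustered` when a clustering assigns it to a
#' family of two or more members, `unclustered` otherwise (including members
#' of singleton clusters).
#'
#' @param combined combined census from [combine_censuses()].
#' @param clusters optional clustering from [cluster_pool()].
#' @return data.frame `sequence`, `total`, `status`
#'   (`bystander`/`unclustered`/`clustered`), `cluster_id` (NA unless
#'   clustered).
#' @export
classify_sequences <- function(combined, clusters = NULL) {
  status <- ifelse(combined$total == 1L, "bystander", "unclustered")
  cluster_id <- rep(NA_character_, nrow(combined))
  if (!is.null(clusters) && nrow(clusters)) {
    size <- table(clusters$cluster_id)
    multi <- clusters[clusters$cluster_id %in%
                        names(size)[size >= 2], , drop = FALSE]
    idx <- match(combined$sequence, multi$sequence)
    hit <- !is.na(idx) & status != "bystander"
    status[hit] <- "clustered"
    cluster_id[hit] <- multi$cluster_id[idx[hit]]
  }
  data.frame(sequence = combined$sequence, total = combined$total,
             status = status, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}

#' Per-round pool composition and cluster convergence statistics
#'
#' For each selection round, computes the fractions of unique sequences that
#' are bystanders, unclustered true aptamers, and clustered true aptamers
#' (fractions over unique sequences present in that round, so they sum to 1),
#' plus the number of clusters with at least one member present in the round
#' and the mean number of present members per such cluster.
#'
#' @param combined combined census.
#' @param statuses output of [classify_sequences()].
#' @param pools pool sheet restricted to the pools/rounds of interest; one
#'   pool per round.
#' @param clusters optional clustering (needed for cluster statistics).
#' @return data.frame with one row per round: `round`, `pool_id`, `n_unique`,
#'   `frac_bystander`, `frac_unclustered`, `frac_clustered`, `n_clusters`,
#'   `mean_members_per_cluster`.
#' @export
round_composition <- function(combined, statuses, pools, clusters = NULL) {
  stopifnot(nrow(pools) >= 1)
  pools <- pools[order(pools$round), , drop = FALSE]
  st <- statuses$status[match(combined$sequence, statuses$sequence)]
  cl <- rep(NA_character_, nrow(combined))
  if (!is.null(clusters)) {
    ## singleton "clusters" are unclustered sequences, not families
    size <- table(clusters$cluster_id)
    real <- clusters[clusters$cluster_id %in% names(size)[size >= 2], ,
                     drop = FALSE]
    cl <- real$cluster_id[match(combined$sequence, real$sequence)]
  }
  out <- lapply(seq_len(nrow(pools)), function(j) {
    pid <- pools$pool_id[j]
    present <- combined[[pid]] > 0
    n <- sum(present)
    frac <- function(s) if (n) sum(st[present] == s) / n else NA_real_
    cl_present <- cl[present & !is.na(cl)]
    ncl <- length(unique(cl_present))
    data.frame(round = pools$round[j], pool_id = pid, n_unique = n,
               frac_bystander = frac("bystander"),
               frac_unclustered = frac("unclustered"),
               frac_clustered = frac("clustered"),
               n_clusters = ncl,
               mean_members_per_cluster =
                 if (ncl) length(cl_present) / ncl else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a census (or combined census) as TSV
#'
#' @param x a `pool_census` or combined census data.frame.
#' @param path output path.
#' @export
write_census <- function(x, path) {
  if (inherits(x, "pool_census"))
    x <- data.frame(sequence = names(x$counts), count = unname(x$counts),
                    stringsAsFactors = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
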