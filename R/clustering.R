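## Greedy founder-first clustering of related sequences: k-mer profile
## prefilter, exact Levenshtein confirmation.

#' Unit-cost edit (Levenshtein) distance
#'
#' Substitutions, insertions and deletions each cost 1. Vectorised over the
#' longer argument.
#'
#' @param a,b character vectors of sequences (recycled).
#' @return integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  d <- adist(a, b)
  if (length(a) == 1L || length(b) == 1L) as.integer(d) else as.integer(diag(d))
}

kmer_profiles <- function(seqs, k = 4L) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = k)
}

#' Euclidean k-mer profile distance
#'
#' Distance between the k-mer count vectors of two sequences. Identical
#' sequences have distance 0; a single edit changes at most `k` k-mers in
#' each sequence, so sequences within edit distance `e` have k-mer profile
#' L1 distance at most `2*k*e`, and Euclidean distance at most the same.
#' That bound is what makes the profile a sound prefilter for edit-distance
#' neighbourhoods.
#'
#' @param a,b single DNA strings with `nchar >= k`.
#' @param k k-mer length (default 4).
#' @return non-negative numeric distance.
#' @export
kmer_distance <- function(a, b, k = 4L) {
  stopifnot(nchar(a) >= k, nchar(b) >= k)
  p <- kmer_profiles(c(a, b), k)
  sqrt(sum((p[1, ] - p[2, ])^2))
}

#' Cluster a census around abundant founders
#'
#' Greedy founder-first clustering: sequences are processed in decreasing
#' total copy number (ties broken lexicographically); each still-unassigned
#' sequence seeds a cluster and collects every unassigned sequence within
#' `max_dist` edits of it. Candidate members are prefiltered by k-mer profile
#' distance (threshold `2*k*max_dist`, which by the bound in
#' [kmer_distance()] can never exclude a true neighbour) and then confirmed
#' by exact edit distance. Membership is measured to the founder, not
#' transitively, matching the founder-plus-variants view of a
#' PCR-mutagenesis family. The result is a partition: each input sequence
#' belongs to exactly one cluster (possibly a singleton).
#'
#' @param census combined census data.frame (see [combine_censuses()]), or
#'   any data.frame with columns `sequence` and `total` (per-pool count
#'   columns are carried through).
#' @param max_dist maximum edit distance from founder (default 3).
#' @param k k-mer length for the prefilter (default 4).
#' @param use_prefilter disable to force all-pairs edit distances (for
#'   validation; results must be identical).
#' @return data.frame with columns `cluster_id`, `sequence`, `is_founder`,
#'   `edit_distance`, plus the count columns of `census`; ordered by cluster
#'   then descending count.
#' @export
cluster_pool <- function(census, max_dist = 3L, k = 4L, use_prefilter = TRUE) {
  stopifnot(nrow(census) >= 1, all(c("sequence", "total") %in% names(census)))
  ord <- order(-census$total, census$sequence)
  census <- census[ord, , drop = FALSE]
  seqs <- census$sequence
  n <- length(seqs)
  ## Two sound prefilter stages (neither can exclude a true neighbour at
  ## edit distance <= max_dist):
  ##  - base composition: one edit changes the A/C/G/T count vector by at
  ##    most 2 in L1, so neighbours satisfy L1 <= 2*max_dist;
  ##  - k-mer profile: one edit changes at most k k-mers in each sequence,
  ##    so neighbours satisfy Euclidean <= L1 <= 2*k*max_dist.
  comp <- if (use_prefilter) kmer_profiles(seqs, 1L) else NULL
  prof <- if (use_prefilter) kmer_profiles(seqs, k) else NULL
  thr1 <- 2 * max_dist
  thr2 <- (2 * k * max_dist)^2            # squared Euclidean threshold
  cluster_of <- integer(n)                # 0 = unassigned
  dist_to_founder <- integer(n)
  n_clusters <- 0L
  for (i in seq_len(n)) {
    if (cluster_of[i] != 0L) next
    n_clusters <- n_clusters + 1L
    cluster_of[i] <- n_clusters
    dist_to_founder[i] <- 0L
    open <- which(cluster_of == 0L)
    if (!length(open)) next
    if (use_prefilter) {
      d1 <- abs(comp[open, 1L] - comp[i, 1L]) +
        abs(comp[open, 2L] - comp[i, 2L]) +
        abs(comp[open, 3L] - comp[i, 3L]) +
        abs(comp[open, 4L] - comp[i, 4L])
      open <- open[d1 <= thr1]
      if (!length(open)) next
      d2 <- rowSums(sweep(prof[open, , drop = FALSE], 2L, prof[i, ])^2)
      open <- open[d2 <= thr2]
      if (!length(open)) next
    }
    ed <- as.integer(adist(seqs[i], seqs[open]))
    hit <- ed <= max_dist
    cluster_of[open[hit]] <- n_clusters
    dist_to_founder[open[hit]] <- ed[hit]
  }
  id_width <- max(4L, nchar(n_clusters))
  out <- data.frame(
    cluster_id = sprintf(paste0("C%0", id_width, "d"), cluster_of),
    sequence = seqs,
    is_founder = dist_to_founder == 0L & !duplicated(cluster_of),
    edit_distance = dist_to_founder,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(census), "sequence")
  out[extra] <- census[extra]
  out <- out[order(out$cluster_id, -out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Members of one cluster
#'
#' @param clusters clustering result from [cluster_pool()].
#' @param cluster_id cluster to extract; defaults to the cluster of the most
#'   abundant founder.
#' @return data.frame of the cluster's rows, founder first.
#' @export
cluster_members <- function(clusters, cluster_id = NULL) {
  if (is.null(cluster_id)) {
    f <- clusters[clusters$is_founder, , drop = FALSE]
    cluster_id <- f$cluster_id[which.max(f$total)]
  }
  m <- clusters[clusters$cluster_id == cluster_id, , drop = FALSE]
  m[order(!m$is_founder, -m$total, m$sequence), , drop = FALSE]
}
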