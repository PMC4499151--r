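## Independent oracles and fixture builders shared across the suite.

## Textbook dynamic-programming Levenshtein distance, written directly from
## the recurrence; deliberately independent of the package's edit_distance().
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1L, m + 1L]
}

## Brute-force greedy founder-first clustering: identical rule to
## cluster_pool but with a full all-pairs distance matrix and no prefilter.
brute_force_cluster <- function(census, max_dist = 3L) {
  ord <- order(-census$total, census$sequence)
  seqs <- census$sequence[ord]
  dmat <- adist(seqs)
  n <- length(seqs)
  founder_of <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(founder_of[i])) next
    members <- which(is.na(founder_of) & dmat[i, ] <= max_dist)
    founder_of[members] <- seqs[i]
  }
  setNames(founder_of, seqs)
}

random_dna <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

## Mutate a sequence with `n_sub` substitutions and optionally one indel.
mutate_seq <- function(seq, n_sub, indel = FALSE) {
  L <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  pos <- sample.int(L, n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  if (indel) {
    if (runif(1) < 0.5) s <- s[-sample.int(length(s), 1)]
    else {
      at <- sample.int(length(s), 1)
      s <- append(s, sample(c("A", "C", "G", "T"), 1), after = at)
    }
  }
  paste(s, collapse = "")
}

## Random clustering instance: planted mutant families around founders.
make_instance <- function(n_founders, L = 40L, max_variants = 6L) {
  founders <- random_dna(n_founders, L)
  rows <- lapply(seq_along(founders), function(i) {
    fcount <- sample(50:5000, 1)
    nv <- sample(0:max_variants, 1)
    vseqs <- character(0)
    if (nv > 0)
      vseqs <- vapply(seq_len(nv), function(j)
        mutate_seq(founders[i], sample(1:3, 1), indel = runif(1) < 0.2),
        character(1))
    data.frame(sequence = c(founders[i], vseqs),
               total = c(fcount, sample(1:40, length(vseqs), replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  inst <- do.call(rbind, rows)
  inst <- inst[!duplicated(inst$sequence), , drop = FALSE]
  inst
}

## Small simulated campaign shared by tests that only need "a campaign";
## built once per test session.
small_sim_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_species = 400L, pool_cap = 1e5,
             reads_per_pool = 1e4, ...)
}

.helper_env <- new.env(parent = emptyenv())
helper_campaign <- function() {
  if (is.null(.helper_env$camp))
    .helper_env$camp <- simulate_campaign(small_sim_config())
  .helper_env$camp
}

## Table of representative IL-10RA sequences bundled with the package.
il10 <- il10ra_example()
il10_core <- il10[il10$category == "core", ]
il10_j <- il10[il10$cluster_id == "J" & il10$category %in% c("core", "variant"), ]
j_founder <- il10$sequence[il10$sequence_id == "411"]
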