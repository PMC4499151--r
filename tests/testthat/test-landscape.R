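## Cluster substitution rate, per-position attribution, variant nomination.

## one founder with single-substitution variants, arbitrary counts
make_cluster <- function(founder, variants, counts, founder_count) {
  data.frame(sequence = c(founder, variants),
             is_founder = c(TRUE, rep(FALSE, length(variants))),
             total = c(founder_count, counts),
             cluster_id = "C1", stringsAsFactors = FALSE)
}

j_members <- function(pool = c("r4", "r5")) {
  pool <- match.arg(pool)
  m <- data.frame(sequence = il10_j$sequence,
                  is_founder = il10_j$sequence == j_founder,
                  cluster_id = "J", stringsAsFactors = FALSE)
  m$total <- if (pool == "r5") il10_j$r5 else il10_j$r4
  m
}

test_that("substitution rate follows the founder-normalized formula", {
  L <- 40L
  founder <- paste(rep("ACGT", 10), collapse = "")
  v1 <- sub("^A", "G", founder)
  v2 <- sub("T$", "C", founder)
  m <- make_cluster(founder, c(v1, v2), c(300L, 100L), 10000L)
  expect_equal(substitution_rate(m), 400 / (10000 * 40))   # = 0.001
  ## no derivatives -> rate 0; founder absent -> undefined
  expect_equal(substitution_rate(make_cluster(founder, character(0),
                                              integer(0), 10L)), 0)
  m0 <- m; m0$total[m0$is_founder] <- 0L
  expect_true(is.na(substitution_rate(m0)))
})

test_that("cluster-J round-5 substitution rate matches hand arithmetic", {
  m <- j_members("r5")
  expect_equal(substitution_rate(m), 142 / (6311 * 40))
  expect_equal(substitution_rate(m), 142 / 252440)
})

test_that("sigma is invariant under uniform scaling of counts", {
  m <- j_members("r5")
  m2 <- m; m2$total <- m2$total * 7L
  expect_equal(substitution_rate(m2), substitution_rate(m))
})

test_that("position profile attributes variants and flags extremes", {
  pr <- position_profile(j_members("r5"))
  pp <- pr$per_position
  expect_equal(pr$founder_count, 6311L)
  expect_equal(pr$sigma, 142 / 252440)
  expect_equal(pr$expected_per_position, 142 / 40)
  ## per-position copies: A1G 47, G7T 25, A19T 2, C28T 17, G30T 46, A39G 5
  expect_equal(pp$total_copies[c(1, 7, 19, 28, 30, 39)],
               c(47, 25, 2, 17, 46, 5))
  expect_equal(sum(pp$total_copies) + pr$other_copies, 142)
  ## against the uniform expectation 3.55, the four showcased abundant
  ## variants sit above the 3x fold; the two rare ones do not reach the
  ## 1/3 fold on this representative subset
  expect_equal(pp$flag[c(1, 7, 28, 30)], rep("high", 4))
  expect_equal(pp$flag[c(19, 39)], rep("normal", 2))
  ## substitution identities land on the right alternative base
  expect_equal(pp$G[1], 47)
  expect_equal(pp$T[30], 46)
  expect_equal(pp$n_distinct_variants[1], 1L)
  ## untouched positions carry zero copies and a Poisson-low tail
  expect_equal(pp$total_copies[2], 0)
  expect_lt(pp$p_low[2], 0.05)
})

test_that("a uniformly mutated synthetic cluster is all-normal", {
  founder <- paste(rep("ACGT", 10), collapse = "")
  fb <- strsplit(founder, "")[[1]]
  variants <- unlist(lapply(1:40, function(p) {
    vapply(setdiff(c("A", "C", "G", "T"), fb[p]), function(b) {
      s <- fb; s[p] <- b; paste(s, collapse = "")
    }, character(1))
  }))
  m <- make_cluster(founder, variants, rep(4L, length(variants)), 5000L)
  pr <- position_profile(m)
  expect_equal(unique(pr$per_position$flag), "normal")
  expect_equal(unique(pr$per_position$n_distinct_variants), 3L)
  ## conservation: all copies attributed, none in the `other` class
  expect_equal(sum(pr$per_position$total_copies), 120 * 4)
  expect_equal(pr$other_copies, 0)
})

test_that("multi-edit variants count toward sigma but not positions", {
  founder <- paste(rep("ACGT", 10), collapse = "")
  v1 <- sub("^A", "G", founder)                    # single substitution
  v2 <- sub("^ACGTA", "GTGTC", founder)            # multiple differences
  m <- make_cluster(founder, c(v1, v2), c(10L, 6L), 1000L)
  pr <- position_profile(m)
  expect_equal(pr$sigma, 16 / (1000 * 40))
  expect_equal(sum(pr$per_position$total_copies), 10)
  expect_equal(pr$other_copies, 6)
})

test_that("flags are monotone in observed copies", {
  founder <- paste(rep("ACGT", 10), collapse = "")
  v1 <- sub("^A", "G", founder)
  v2 <- sub("T$", "C", founder)
  lvl <- c(low = 1L, normal = 2L, high = 3L)
  prev <- 0L
  for (n in c(0L, 1L, 3L, 10L, 40L, 200L)) {
    m <- make_cluster(founder, c(v1, v2), c(n, 30L), 5000L)
    f <- position_profile(m)$per_position$flag[1]
    expect_gte(lvl[f], prev)
    prev <- lvl[f]
  }
})

test_that("candidate ranking puts the dominant high-position variant first", {
  cv <- candidate_variants(position_profile(j_members("r5")))
  expect_equal(cv$sequence[1],
               il10$sequence[il10$sequence_id == "411-J-A1G"])
  expect_true(all(cv$position %in% c(1, 7, 28, 30)))
  expect_equal(cv$copies, sort(cv$copies, decreasing = TRUE))
  ## no high positions -> empty nomination
  founder <- paste(rep("ACGT", 10), collapse = "")
  m <- make_cluster(founder, sub("^A", "G", founder), 3L, 1000L)
  pr <- position_profile(m)
  pr$per_position$flag[] <- "normal"
  expect_equal(nrow(candidate_variants(pr)), 0L)
})

test_that("a planted high-fitness variant is flagged in simulation", {
  camp <- helper_campaign()
  comb <- combine_censuses(campaign_censuses(camp))
  cl <- cluster_pool(comb[comb$total >= 2, ])
  pl <- camp$planted
  fcid <- cl$cluster_id[cl$sequence == pl$founder]
  expect_length(fcid, 1)
  mem <- cluster_members(cl, fcid)
  expect_equal(mem$sequence[mem$is_founder], pl$founder)
  last <- paste0("R", max(camp$pool_sheet$round))
  pr <- position_profile(mem, pool = last)
  expect_equal(pr$per_position$flag[pl$position], "high")
  cv <- candidate_variants(pr)
  expect_true(pl$sequence %in% head(cv$sequence, 3))
})
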