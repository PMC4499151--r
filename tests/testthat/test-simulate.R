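## Generative model: binding isotherm, PCR bias and mutagenesis,
## sequencing, campaign reproducibility.

test_that("binding probability follows the Langmuir isotherm", {
  expect_equal(binding_probability(10, 10), 0.5)        # midpoint kd == T
  expect_equal(binding_probability(10, 10, carrier = 0.1), 0.6)
  expect_lt(binding_probability(1e9, 10), 1e-6)         # kd -> Inf limit
  expect_equal(binding_probability(0.1, 10, carrier = 0.9), 1)  # capped
})

test_that("retained counts are binomial around the closed-form mean", {
  set.seed(17)
  counts <- rep(1e5L, 6)
  kd <- c(2, 10, 50, 200, 1000, 1e5)
  got <- simulate_binding(counts, kd, target_conc = 10)
  p <- binding_probability(kd, 10)
  expect_true(all(got <= counts))
  expect_true(all(abs(got - counts * p) <= 3 * sqrt(counts * p * (1 - p)) + 1))
})

test_that("mutation-free emulsion PCR amplifies evenly, creating nothing", {
  set.seed(23)
  pool <- data.frame(sequence = random_dna(20, 40),
                     count = rep(1000L, 20), stringsAsFactors = FALSE)
  res <- simulate_pcr(pool, "emulsion", cycles = 5, mu = 0, cap = 1e7)
  expect_setequal(res$pool$sequence, pool$sequence)
  expect_equal(sum(res$events$n_events), 0L)
  expected <- 1000 * amplification_factor(0.5, "emulsion", 5)
  expect_true(all(abs(res$pool$count - expected) < 6 * sqrt(expected)))
})

test_that("open PCR favours low-GC sequences as the closed form predicts", {
  f_low <- amplification_factor(0.25, "open")
  f_high <- amplification_factor(0.75, "open")
  expect_gt(f_low, f_high)
  ## calibration: a GC-0.2 sequence gains ~3x over the emulsion arm
  expect_equal(amplification_factor(0.2, "open") /
                 amplification_factor(0.2, "emulsion"), 3, tolerance = 0.02)
  ## and stochastic amplification reproduces the ordering
  set.seed(29)
  pool <- data.frame(
    sequence = c(paste(rep(c("A", "T", "A", "G"), 10), collapse = ""),
                 paste(rep(c("G", "C", "G", "A"), 10), collapse = "")),
    count = c(2000L, 2000L), stringsAsFactors = FALSE)
  res <- simulate_pcr(pool, "open", cycles = 8, mu = 0, cap = 1e9)
  expect_gt(res$pool$count[res$pool$sequence == pool$sequence[1]],
            res$pool$count[res$pool$sequence == pool$sequence[2]])
})

test_that("mutation events are uniform over positions", {
  set.seed(31)
  pool <- data.frame(sequence = random_dna(1, 40), count = 500L,
                     stringsAsFactors = FALSE)
  res <- simulate_pcr(pool, "emulsion", cycles = 20, mu = 1e-3, cap = 1e5)
  ev <- res$events
  expect_gt(sum(ev$n_events), 500)           # mutagenesis actually happened
  chi <- suppressWarnings(chisq.test(ev$n_events))
  expect_gt(chi$p.value, 0.01)
  ## derivative species exist and are near their parents
  mut <- res$pool$sequence[res$pool$is_new]
  expect_gt(length(mut), 10)
  expect_true(all(edit_distance(pool$sequence, head(mut, 20)) >= 1))
})

test_that("sequencing samples the pool composition without replacement", {
  spec <- pool_sheet("P1", 1, "t", "AAAACCCC", "ACGTACGT", "TTGGCCAA", 12)
  pool <- data.frame(sequence = c("ACGTACGTACGA", "GGGGTTTTCCCC"),
                     count = c(9000L, 1000L), stringsAsFactors = FALSE)
  ## zero reads -> empty output
  sq0 <- simulate_sequencing(pool, 0, spec)
  expect_length(sq0$reads, 0)
  ## single species -> all reads identical
  sq1 <- simulate_sequencing(pool[1, ], 50, spec)
  expect_equal(length(unique(sq1$reads)), 1L)
  expect_equal(unname(sq1$reads[1]),
               paste0("AAAACCCC", "ACGTACGT", "ACGTACGTACGA", "TTGGCCAA"))
  ## draws stay within 3 sigma of the hypergeometric expectation
  set.seed(37)
  for (i in 1:5) {
    sq <- simulate_sequencing(pool, 2000, spec)
    x <- sq$census_true$count[sq$census_true$sequence == pool$sequence[2]]
    mu <- 2000 * 0.1
    sd3 <- 3 * sqrt(2000 * 0.1 * 0.9 * (10000 - 2000) / 9999)
    expect_true(abs(x - mu) <= sd3)
  }
  ## requested depth beyond the pool size sequences it exhaustively
  sqx <- simulate_sequencing(pool, 1e6, spec)
  expect_equal(sum(sqx$census_true$count), 10000L)
  expect_equal(setNames(sqx$census_true$count, sqx$census_true$sequence),
               setNames(pool$count, pool$sequence))
})

test_that("campaigns are exactly reproducible from their seed", {
  c1 <- simulate_campaign(small_sim_config(seed = 7L))
  c2 <- simulate_campaign(small_sim_config(seed = 7L))
  expect_identical(c1$pools, c2$pools)
  expect_identical(c1$species, c2$species)
  c3 <- simulate_campaign(small_sim_config(seed = 8L))
  expect_false(identical(c1$pools, c3$pools))
})

test_that("high-affinity species out-enrich nonbinders across rounds", {
  wins <- 0L
  for (seed in 1:5) {
    camp <- simulate_campaign(small_sim_config(seed = seed))
    cens <- campaign_censuses(camp)
    comb <- combine_censuses(cens[c("R1", "R2")])
    et <- enrichment_table(comb, c("R1", "R2"))
    sp <- camp$species
    idx <- match(et$sequence, sp$sequence)
    ok <- !is.na(idx) & comb$R1 > 0 & !sp$carrier_binder[idx] &
      !sp$charge_binder[idx]
    cls <- sp$class[idx]
    m_high <- mean(et$enrichment[ok & cls == "high"], na.rm = TRUE)
    m_non <- mean(et$enrichment[ok & cls == "nonbinder"], na.rm = TRUE)
    wins <- wins + (m_high > m_non)
  }
  expect_gte(wins, 4L)
})

test_that("binding never creates molecules and conserves species", {
  camp <- helper_campaign()
  final <- camp$final_composition
  expect_true(all(final$count >= 1))
  expect_true(all(nchar(final$sequence) %in%
                    (camp$config$region_length + c(-3:3))))
})
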