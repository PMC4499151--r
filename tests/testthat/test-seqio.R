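## Barcode demultiplexing and random-region extraction.

barcodes3 <- c("AAAACCCC", "GGGGTTTT", "CCCCGGGG")   # pairwise Hamming 8

make_pools <- function(barcodes, L = 12L) {
  pool_sheet(pool_id = paste0("P", seq_along(barcodes)),
             round = seq_along(barcodes), target = "t",
             barcode = barcodes,
             flank5 = "ACGTACGT", flank3 = "TTGGCCAA",
             region_length = L)
}

test_that("pool sheet validation rejects bad specifications", {
  expect_error(pool_sheet("a", 1, "t", "ACGN", "A", "C", 10), "ACGT")
  expect_error(pool_sheet(c("a", "a"), 1, "t", c("AAAA", "CCCC"),
                          "A", "C", 10), "unique")
  expect_error(pool_sheet("a", 1, "t", "AAAA", "A", "C", 0), "region_length")
})

test_that("demultiplex assigns exact matches and respects tolerance", {
  pools <- make_pools(barcodes3)
  reads <- paste0(c("AAAACCCC", "GGGGTTTT", "TTTTTTTT"), "ACGTACGTNNNN")
  dm <- demultiplex(reads, pools, max_mismatches = 0L)
  expect_equal(dm$assignment, c("P1", "P2", "unassigned"))
  ## a read 2+ mismatches from every barcode stays unassigned at tolerance 1
  far <- paste0("AAGGCCCC", "ACGTACGTNNNN")   # 2 from P1, >2 from others
  dm2 <- demultiplex(far, pools, max_mismatches = 1L)
  expect_equal(dm2$assignment, "unassigned")
})

test_that("ambiguous barcode sets are rejected before processing", {
  pools <- make_pools(c("AAAACCCC", "AAAACCCA", "GGGGTTTT"))
  expect_error(demultiplex("AAAACCCCACGTACGT", pools, max_mismatches = 1L),
               "ambiguous")
})

test_that("reads are conserved across pools plus unassigned", {
  pools <- make_pools(barcodes3)
  set.seed(11)
  reads <- paste0(sample(c(barcodes3, "TTTTTTTT"), 200, replace = TRUE),
                  random_dna(200, 20))
  dm <- demultiplex(reads, pools, max_mismatches = 0L)
  expect_equal(sum(lengths(dm$reads)), length(reads))
})

test_that("single barcode errors are fully recovered at tolerance 1", {
  pools <- make_pools(barcodes3)
  set.seed(7)
  truth <- sample(pools$pool_id, 1000, replace = TRUE)
  bcs <- pools$barcode[match(truth, pools$pool_id)]
  reads <- vapply(bcs, function(b) {
    p <- sample.int(8, 1)
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(b, p, p)), 1)
    paste0(b, "ACGTACGT", paste(rep("A", 12), collapse = ""), "TTGGCCAA")
  }, character(1), USE.NAMES = FALSE)
  dm <- demultiplex(reads, pools, max_mismatches = 1L)
  expect_equal(dm$assignment, truth)
})

test_that("extract_region recovers the region and tallies rejections", {
  spec <- make_pools(barcodes3)[1, ]
  region <- paste(rep("A", 12), collapse = "")
  good <- paste0("AAAACCCC", spec$flank5, region, spec$flank3)
  ex <- extract_region(good, spec)
  expect_equal(ex$regions, region)
  ## one substitution in flank5, still within tolerance
  sub5 <- good
  substr(sub5, 9, 9) <- "T"
  expect_equal(extract_region(sub5, spec, max_flank_mismatches = 1L)$regions,
               region)
  ## wrong region length -> tallied rejection
  short <- paste0("AAAACCCC", spec$flank5, substr(region, 1, 11), spec$flank3)
  ex3 <- extract_region(short, spec)
  expect_length(ex3$regions, 0)
  expect_equal(ex3$tally$count[ex3$tally$reason == "bad_region_length"], 1L)
  ## N inside the region -> rejected with its own reason
  nread <- paste0("AAAACCCC", spec$flank5, "AANAAAAAAAAA", spec$flank3)
  ex4 <- extract_region(nread, spec)
  expect_equal(ex4$tally$count[ex4$tally$reason == "ambiguous_base"], 1L)
})

test_that("extraction is idempotent when re-embedding the region", {
  spec <- make_pools(barcodes3)[1, ]
  set.seed(3)
  regions <- random_dna(25, 12)
  reads <- paste0("AAAACCCC", spec$flank5, regions, spec$flank3)
  ex <- extract_region(reads, spec)
  expect_equal(ex$regions, regions)
  reembedded <- paste0(spec$flank5, ex$regions, spec$flank3)
  expect_equal(extract_region(reembedded, spec)$regions, regions)
})

test_that("reverse-orientation pools are handled by reverse complement", {
  spec <- make_pools(barcodes3)[1, ]
  spec$orientation <- "rev"
  region <- "ACGTACGTACGT"
  fwd <- paste0("AAAACCCC", spec$flank5, region, spec$flank3)
  read <- revcomp(fwd)
  dm <- demultiplex(read, spec, max_mismatches = 0L)
  expect_equal(dm$assignment, "P1")
  expect_equal(extract_region(read, spec)$regions, region)
})

test_that("error-free simulator reads demultiplex and extract perfectly", {
  dir <- file.path(tempdir(), "aptrace-demux-check")
  camp2 <- simulate_campaign(small_sim_config(), out_dir = dir)
  reads <- read_reads(file.path(dir, "reads.fastq"))
  pools <- read_pool_sheet(file.path(dir, "pools.tsv"))
  dm <- demux_extract(reads, pools)
  expect_equal(dm$n_unassigned, 0L)
  ## every read assigned to the pool encoded in its (ground truth) name
  truth_pool <- sub("\\|.*$", "", names(reads))
  got <- demultiplex(reads, pools)$assignment
  expect_equal(got, truth_pool)
  ## extracted censuses match the simulator's true sampled counts exactly
  for (p in pools$pool_id) {
    cen <- build_census(dm$regions[[p]], p)
    truth <- camp2$pools[[p]]
    expect_equal(cen$counts[order(names(cen$counts))],
                 setNames(truth$count, truth$sequence)[order(truth$sequence)],
                 ignore_attr = TRUE)
  }
  unlink(dir, recursive = TRUE)
})
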