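## Reading multiplexed selection-round reads, barcode demultiplexing and
## random-region extraction.

#' Construct a pool specification table
#'
#' Each sequenced pool (one selection round, one target arm) is described by
#' a row: its barcode, the constant flanks surrounding the random region, the
#' random-region length, and where on the read the barcode sits. The layout
#' mirrors the common SELEX library design `barcode + flank5 + N-region +
#' flank3`, with the barcode at a fixed offset from the read start.
#'
#' @param pool_id character, unique pool identifiers.
#' @param round integer selection-round index (>= 0).
#' @param target character target label (e.g. `"hIL10RA"`, `"hIgG"`,
#'   `"hIgG_pH_adjusted"`, `"mIL10RA"`).
#' @param barcode,flank5,flank3 DNA strings (`ACGT` only; `U` is converted
#'   to `T` on input elsewhere, not here).
#' @param region_length integer length of the random region (40 for an N40
#'   library, 20 for an N20 library).
#' @param barcode_offset 0-based offset of the barcode on the read
#'   (default 0, i.e. the read starts with the barcode).
#' @param orientation `"fwd"` or `"rev"`; reads of `"rev"` pools are
#'   reverse-complemented before barcode and flank matching.
#' @return A `data.frame` with one row per pool, validated.
#' @export
pool_sheet <- function(pool_id, round, target, barcode, flank5, flank3,
                       region_length, barcode_offset = 0L,
                       orientation = "fwd") {
  ps <- data.frame(pool_id = as.character(pool_id),
                   round = as.integer(round),
                   target = as.character(target),
                   barcode = toupper(as.character(barcode)),
                   flank5 = toupper(as.character(flank5)),
                   flank3 = toupper(as.character(flank3)),
                   region_length = as.integer(region_length),
                   barcode_offset = as.integer(barcode_offset),
                   orientation = as.character(orientation),
                   stringsAsFactors = FALSE)
  validate_pool_sheet(ps)
  ps
}

#' Read a pool sheet from a delimited file
#'
#' Expects a tab-delimited table with the columns of [pool_sheet()];
#' `barcode_offset` and `orientation` are optional and default to 0 / "fwd".
#'
#' @param path file path.
#' @return validated pool sheet `data.frame`.
#' @export
read_pool_sheet <- function(path) {
  ps <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("pool_id", "round", "target", "barcode", "flank5", "flank3",
                "region_length")
  missing <- setdiff(required, names(ps))
  if (length(missing))
    stop("pool sheet is missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(ps$barcode_offset)) ps$barcode_offset <- "0"
  if (is.null(ps$orientation)) ps$orientation <- "fwd"
  pool_sheet(ps$pool_id, as.integer(ps$round), ps$target, ps$barcode,
             ps$flank5, ps$flank3, as.integer(ps$region_length),
             as.integer(ps$barcode_offset), ps$orientation)
}

validate_pool_sheet <- function(ps) {
  stopifnot(is.data.frame(ps), nrow(ps) >= 1)
  if (anyDuplicated(ps$pool_id))
    stop("pool_ids must be unique within a run")
  for (col in c("barcode", "flank5", "flank3")) {
    bad <- grepl("[^ACGT]", ps[[col]])
    if (any(bad))
      stop(col, " must contain only ACGT (offending pool: ",
           ps$pool_id[which(bad)[1]], ")")
  }
  if (any(ps$region_length <= 0)) stop("region_length must be > 0")
  if (any(ps$round < 0)) stop("round must be >= 0")
  if (any(ps$barcode_offset < 0)) stop("barcode_offset must be >= 0")
  if (!all(ps$orientation %in% c("fwd", "rev")))
    stop("orientation must be 'fwd' or 'rev'")
  if (length(unique(nchar(ps$barcode))) != 1)
    stop("all barcodes must have the same length")
  invisible(ps)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' Format is inferred from the file extension (`.fastq`/`.fq` vs
#' `.fasta`/`.fa`/`.fna`, optionally `.gz`); gzip is handled transparently.
#' `U` is normalised to `T` so RNA-derived reads and DNA libraries share one
#' alphabet.
#'
#' @param path path to the reads file.
#' @return character vector of read sequences (names = read ids).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq"
         else "fasta"
  ss <- Biostrings::readBStringSet(path, format = fmt)
  reads <- toupper(chartr("Uu", "Tt", as.character(ss)))
  names(reads) <- sub("\\s.*$", "", names(ss))
  reads
}

## Hamming mismatches between each read's barcode window and one barcode.
## Vectorised over reads; reads too short for the window get Inf.
barcode_mismatches <- function(reads, barcode, offset) {
  w <- nchar(barcode)
  window <- substr(reads, offset + 1L, offset + w)
  mm <- rep(0, length(reads))
  bc <- strsplit(barcode, "")[[1]]
  for (i in seq_len(w)) mm <- mm + (substr(window, i, i) != bc[i])
  mm[nchar(window) < w] <- Inf
  mm
}

#' Assign reads to pools by barcode
#'
#' Each read is compared to every pool's barcode at that pool's declared
#' offset (after reverse-complementing for `"rev"` pools) and assigned to the
#' unique best match within `max_mismatches`; ties and out-of-tolerance reads
#' go to `"unassigned"`. Before any read is touched the barcode set is checked
#' for ambiguity: every pair of barcodes must differ at more than
#' `2 * max_mismatches` positions, otherwise a single read could be within
#' tolerance of two pools.
#'
#' @param reads character vector of read sequences (see [read_reads()]).
#' @param pools pool sheet (see [pool_sheet()]).
#' @param max_mismatches maximum barcode mismatches tolerated (default 0).
#' @return list with `assignment` (character vector, a `pool_id` or
#'   `"unassigned"` per read) and `reads` (named list of read vectors, one
#'   per pool plus `unassigned`).
#' @export
demultiplex <- function(reads, pools, max_mismatches = 0L) {
  validate_pool_sheet(pools)
  bcs <- pools$barcode
  if (nrow(pools) > 1) {
    pd <- adist(bcs)          # equal lengths, so Levenshtein == Hamming here
    diag(pd) <- Inf
    if (min(pd) <= 2 * max_mismatches)
      stop("ambiguous barcode set: minimum pairwise barcode distance ",
           min(pd), " is not > 2 * max_mismatches (", 2 * max_mismatches, ")")
  }
  rc <- NULL
  if (any(pools$orientation == "rev")) rc <- revcomp(reads)
  mm <- matrix(Inf, nrow = length(reads), ncol = nrow(pools))
  for (j in seq_len(nrow(pools))) {
    rr <- if (pools$orientation[j] == "rev") rc else reads
    mm[, j] <- barcode_mismatches(rr, bcs[j], pools$barcode_offset[j])
  }
  assignment <- rep("unassigned", length(reads))
  if (length(reads)) {
    best <- apply(mm, 1L, min)
    hit <- best <= max_mismatches
    n_best <- rowSums(mm == best)
    ok <- hit & n_best == 1L
    assignment[ok] <- pools$pool_id[apply(mm[ok, , drop = FALSE], 1L,
                                          which.min)]
  }
  out <- lapply(pools$pool_id, function(p) reads[assignment == p])
  names(out) <- pools$pool_id
  out$unassigned <- reads[assignment == "unassigned"]
  list(assignment = assignment, reads = out)
}

#' Extract the random region between constant flanks
#'
#' Locates `flank5` and `flank3` on each read (allowing up to
#' `max_flank_mismatches` substitutions in each flank), and returns the
#' enclosed subsequence when it has exactly `region_length` bases, all of
#' them `ACGT`. Reads of `"rev"` pools are reverse-complemented first.
#' Rejections are tallied by reason: `flank5_not_found`, `flank3_not_found`,
#' `bad_region_length`, `ambiguous_base`.
#'
#' @param reads character vector of reads belonging to one pool.
#' @param spec one row of a pool sheet.
#' @param max_flank_mismatches substitutions tolerated within each flank
#'   (default 2).
#' @return list with `regions` (character vector of accepted random regions),
#'   `accepted` (logical per input read), and `tally` (data.frame reason /
#'   count including the `accepted` row).
#' @export
extract_region <- function(reads, spec, max_flank_mismatches = 2L) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  L <- spec$region_length
  if (spec$orientation == "rev") reads <- revcomp(reads)
  reasons <- rep(NA_character_, length(reads))
  regions <- rep(NA_character_, length(reads))
  if (length(reads)) {
    subj <- Biostrings::DNAStringSet(reads)
    m5 <- Biostrings::vmatchPattern(spec$flank5, subj,
                                    max.mismatch = max_flank_mismatches)
    m3 <- Biostrings::vmatchPattern(spec$flank3, subj,
                                    max.mismatch = max_flank_mismatches)
    e5 <- Biostrings::endIndex(m5)
    s3 <- Biostrings::startIndex(m3)
    for (i in seq_along(reads)) {
      if (is.null(e5[[i]]) || length(e5[[i]]) == 0) {
        reasons[i] <- "flank5_not_found"; next
      }
      if (is.null(s3[[i]]) || length(s3[[i]]) == 0) {
        reasons[i] <- "flank3_not_found"; next
      }
      gap <- outer(s3[[i]], e5[[i]], "-") - 1L   # enclosed region lengths
      hit <- which(gap == L, arr.ind = TRUE)
      if (nrow(hit) == 0) { reasons[i] <- "bad_region_length"; next }
      start <- e5[[i]][hit[1, 2]] + 1L
      region <- substr(reads[i], start, start + L - 1L)
      if (grepl("[^ACGT]", region)) { reasons[i] <- "ambiguous_base"; next }
      regions[i] <- region
    }
  }
  accepted <- !is.na(regions)
  tally <- as.data.frame(table(
    reason = factor(ifelse(accepted, "accepted", reasons),
                    levels = c("accepted", "flank5_not_found",
                               "flank3_not_found", "bad_region_length",
                               "ambiguous_base"))),
    responseName = "count", stringsAsFactors = FALSE)
  list(regions = regions[accepted], accepted = accepted, tally = tally)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Demultiplex and extract regions for every pool
#'
#' Convenience wrapper chaining [demultiplex()] and [extract_region()].
#'
#' @inheritParams demultiplex
#' @inheritParams extract_region
#' @return list with `regions` (named list of region vectors per pool),
#'   `tallies` (named list of rejection tallies), `n_unassigned`.
#' @export
demux_extract <- function(reads, pools, max_mismatches = 0L,
                          max_flank_mismatches = 2L) {
  dm <- demultiplex(reads, pools, max_mismatches)
  regions <- vector("list", nrow(pools))
  tallies <- vector("list", nrow(pools))
  names(regions) <- names(tallies) <- pools$pool_id
  for (j in seq_len(nrow(pools))) {
    ex <- extract_region(dm$reads[[pools$pool_id[j]]], pools[j, , drop = FALSE],
                         max_flank_mismatches)
    regions[[j]] <- ex$regions
    tallies[[j]] <- ex$tally
  }
  list(regions = regions, tallies = tallies,
       n_unassigned = length(dm$reads$unassigned))
}
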