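## Generative SELEX simulator: Langmuir binding, emulsion/open PCR with
## GC-dependent efficiency and per-cycle mutagenesis, multinomial
## sequencing, and multi-round campaigns with parallel arms and reference
## pools. Every run is fully determined by its seed and carries ground
## truth for validating the analysis pipeline.

#' Simulation configuration
#'
#' Returns the default configuration for [simulate_campaign()], with any
#' field overridden by name. The defaults describe a scaled-down five-round
#' selection of an N40 RNA library against a bead-bound Fc-fusion target:
#' a log-uniform starting abundance distribution, a Langmuir binding step
#' whose target concentration declines 25% per round, 25 PCR cycles per
#' round (emulsion by default, with an open-PCR arm branching at round 2),
#' Taq-like mutagenesis, and multinomial sequencing of every bound pool.
#'
#' Key fields (units in brackets):
#' \describe{
#' \item{region_length}{random-region length (default 40).}
#' \item{n_species}{initial unique species (default 400).}
#' \item{init_copies_log10}{range of log10 initial copies, drawn
#'   log-uniformly (default c(1, 4)).}
#' \item{class_probs}{named probabilities for affinity classes
#'   high/medium/low/nonbinder.}
#' \item{kd_high, kd_medium, kd_low}{Kd ranges per class [nM]; the high
#'   class stays below 20 nM, the conventional high-affinity cutoff.}
#' \item{kd_nonbinder}{Kd assigned to nonbinders [nM].}
#' \item{carrier_frac, kd_carrier}{fraction of species that bind the bead
#'   carrier, and their carrier Kd range [nM].}
#' \item{charge_frac, kd_charge}{fraction of electrostatic (charge) binders
#'   and their Kd range on the pH-adjusted control [nM].}
#' \item{cross_frac}{fraction of high-affinity species that are
#'   cross-reactive with the ortholog target.}
#' \item{ortholog_kd_jitter}{multiplicative range applied to the target Kd
#'   to obtain a cross-reactive species' ortholog Kd.}
#' \item{background_retention}{kd-independent retention probability per
#'   molecule (bead/wash background).}
#' \item{target_conc0, target_decay}{initial target concentration [nM] and
#'   its per-round multiplier (0.75 = reduce by 25% each round).}
#' \item{rounds}{number of selection rounds (default 5).}
#' \item{pcr_mode, pcr_cycles, e_base}{amplification mode of the main line,
#'   cycles per round, and per-cycle duplication probability at GC 0.5.}
#' \item{mu}{per-base per-cycle mutation probability (default 1e-4).}
#' \item{gc_slope}{open-PCR efficiency penalty per unit GC above 0.5; the
#'   default 0.27 makes a GC-0.2 sequence amplify about 3-fold more than
#'   the emulsion arm over 25 cycles.}
#' \item{pool_cap}{molecule cap per pool; pools exceeding it are thinned
#'   (the aliquot taken forward), keeping per-cycle sampling tractable.}
#' \item{reads_per_pool}{sequencing reads per pool (default 5e4).}
#' \item{arm_branch_round}{round whose bound pool is amplified by both
#'   emulsion and open PCR for the arm comparison (NA disables).}
#' \item{parallel_targets}{run the final binding round in parallel against
#'   target, control, pH-adjusted control and ortholog pools.}
#' \item{mutant_kd_meanlog, mutant_kd_sdlog}{lognormal multiplicative Kd
#'   penalty for newly arisen mutants (mostly deleterious).}
#' \item{plant_variant, planted_kd_factor}{plant one high-fitness single
#'   substitution of the best binder (Kd multiplied by the factor).}
#' \item{seq_error_rate}{uniform per-base sequencing substitution rate
#'   (default 0).}
#' \item{seed}{mandatory RNG seed.}
#' }
#'
#' @param ... overrides by field name.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    region_length = 40L,
    n_species = 3000L,
    init_copies_log10 = c(1, 4),
    gc_prob_range = c(0.1, 0.9),
    class_probs = c(high = 0.03, medium = 0.12, low = 0.35, nonbinder = 0.50),
    kd_high = c(2, 20), kd_medium = c(20, 200), kd_low = c(200, 1000),
    kd_nonbinder = 1e5,
    carrier_frac = 0.05, kd_carrier = c(2, 20),
    charge_frac = 0.05, kd_charge = c(0.5, 5),
    cross_frac = 0.25, ortholog_kd_jitter = c(0.7, 1.4),
    background_retention = 5e-4,
    target_conc0 = 5, target_decay = 0.75,
    rounds = 5L,
    pcr_mode = "emulsion", pcr_cycles = 25L, e_base = 0.8,
    mu = 5e-5, gc_slope = 0.27, pool_cap = 1e6,
    reads_per_pool = 1e5,
    arm_branch_round = 2L,
    parallel_targets = TRUE,
    mutant_kd_meanlog = log(2), mutant_kd_sdlog = 0.7,
    plant_variant = TRUE, planted_kd_factor = 0.2,
    planted_init_copies = 20L,
    seq_error_rate = 0,
    target_label = "hIL10RA", ortholog_label = "mIL10RA",
    control_label = "hIgG", adjusted_label = "hIgG_pH_adjusted",
    flank5 = "TCTCGATCTCAGCGAGTCGTCG",
    flank3 = "CCCATCCCTCTTCCTCTCTCCC",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$mu >= 0, cfg$mu <= 1, cfg$e_base > 0, cfg$e_base < 1,
            cfg$rounds >= 1, !is.null(cfg$seed))
  structure(cfg, class = "sim_config")
}

## Barcodes with pairwise Hamming distance >= 4: two length-4 homopolymer
## blocks per barcode.
sim_barcodes <- function(n) {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(b, b, function(x, y)
    paste0(strrep(x, 4), strrep(y, 4))))
  if (n > length(all)) stop("too many pools for built-in barcode set")
  all[seq_len(n)]
}

#' Probability that a molecule is retained in a binding step
#'
#' Single-site Langmuir isotherm plus additive carrier and background
#' terms, capped at 1: `p = T/(T + kd) + carrier + background`.
#'
#' @param kd dissociation constant(s) [nM].
#' @param target_conc free target concentration [nM].
#' @param carrier additive carrier-binding probability (default 0).
#' @param background additive kd-independent retention (default 0).
#' @return retention probabilities in `[0, 1]`.
#' @export
binding_probability <- function(kd, target_conc, carrier = 0,
                                background = 0) {
  pmin(target_conc / (target_conc + kd) + carrier + background, 1)
}

#' Simulate one binding-selection step
#'
#' Each molecule of each species is retained independently with the
#' probability from [binding_probability()], so retained counts are
#' binomial with expectation `count * p`.
#'
#' @param counts non-negative molecule counts per species.
#' @param kd per-species Kd [nM].
#' @param target_conc target concentration [nM].
#' @param carrier,background see [binding_probability()].
#' @return integer-valued vector of retained counts (`<= counts`).
#' @export
simulate_binding <- function(counts, kd, target_conc, carrier = 0,
                             background = 0) {
  p <- binding_probability(kd, target_conc, carrier, background)
  rbinom(length(counts), counts, p)
}

## Per-cycle duplication probability as a function of GC content.
pcr_efficiency <- function(gc, mode, e_base, gc_slope) {
  eff <- if (mode == "emulsion") rep(e_base, length(gc))
         else e_base - gc_slope * (gc - 0.5)
  pmin(pmax(eff, 0.01), 0.99)
}

#' Expected amplification factor after a PCR run
#'
#' Closed form `(1 + efficiency)^cycles` with the GC-dependent efficiency
#' of [simulate_pcr()]. In emulsion mode the factor is GC-independent; in
#' open mode low-GC sequences amplify more. With the defaults, a GC-0.2
#' sequence in open mode gains about 3-fold over the emulsion arm across
#' 25 cycles, while a GC-0.8 sequence falls about 3-fold behind.
#'
#' @param gc GC content(s) in `[0, 1]`.
#' @param mode `"emulsion"` or `"open"`.
#' @param cycles number of cycles.
#' @param e_base per-cycle duplication probability at GC 0.5.
#' @param gc_slope open-mode efficiency slope.
#' @return expected fold-amplification per input molecule.
#' @export
amplification_factor <- function(gc, mode = c("emulsion", "open"),
                                 cycles = 25L, e_base = 0.8,
                                 gc_slope = 0.27) {
  mode <- match.arg(mode)
  (1 + pcr_efficiency(gc, mode, e_base, gc_slope))^cycles
}

#' Simulate PCR amplification with mutagenesis
#'
#' Runs `cycles` cycles over a species pool. Each molecule duplicates with
#' the (GC-dependent in open mode) per-cycle efficiency; each newly
#' synthesised molecule acquires a mutation with probability
#' `1 - (1 - mu)^L`, creating a derivative species at a uniformly chosen
#' position with a uniformly chosen alternative base. New species inherit
#' every annotation column of their parent row. When the pool exceeds
#' `cap` molecules it is binomially thinned back to `cap` (the aliquot
#' carried forward), which preserves relative expectations.
#'
#' @param pool data.frame with at least `sequence` and `count` columns;
#'   extra columns are carried through and inherited by mutants.
#' @param mode `"emulsion"` or `"open"`.
#' @param cycles,mu,gc_slope,e_base see [sim_config()].
#' @param cap molecule cap (default 2e5).
#' @return list with `pool` (amplified pool, zero-count rows dropped,
#'   mutants marked by the logical `is_new` column) and `events`
#'   (data.frame `position`, `n_events` of raw mutation events).
#' @export
simulate_pcr <- function(pool, mode = c("emulsion", "open"), cycles = 25L,
                         mu = 5e-5, gc_slope = 0.27, e_base = 0.8,
                         cap = 2e5) {
  mode <- match.arg(mode)
  stopifnot(cycles >= 1, all(pool$count >= 0))
  L <- nchar(pool$sequence[1])
  bases <- c("A", "C", "G", "T")
  original <- pool$sequence
  pool$gc <- gc_content(pool$sequence)
  p_mut <- 1 - (1 - mu)^L
  ev_pos <- integer(L)
  for (cyc in seq_len(cycles)) {
    eff <- pcr_efficiency(pool$gc, mode, e_base, gc_slope)
    new <- rbinom(nrow(pool), pool$count, eff)
    n_mut <- if (p_mut > 0) rbinom(nrow(pool), new, p_mut) else
      integer(nrow(pool))
    pool$count <- pool$count + new - n_mut
    total_mut <- sum(n_mut)
    if (total_mut > 0) {
      parent <- rep(which(n_mut > 0), n_mut[n_mut > 0])
      pos <- sample.int(L, total_mut, replace = TRUE)
      ev_pos <- ev_pos + tabulate(pos, nbins = L)
      ref <- substr(pool$sequence[parent], pos, pos)
      ref_idx <- match(ref, bases)
      alt_idx <- ((ref_idx - 1L + sample.int(3L, total_mut,
                                             replace = TRUE)) %% 4L) + 1L
      mseq <- pool$sequence[parent]
      substr(mseq, pos, pos) <- bases[alt_idx]
      agg <- tapply(rep(1L, total_mut), mseq, sum)
      mseqs <- names(agg)
      hit <- match(mseqs, pool$sequence)
      known <- !is.na(hit)
      if (any(known))
        pool$count[hit[known]] <- pool$count[hit[known]] +
          as.integer(agg[known])
      if (any(!known)) {
        first_parent <- parent[match(mseqs[!known], mseq)]
        rows <- pool[first_parent, , drop = FALSE]
        rows$sequence <- mseqs[!known]
        rows$count <- as.integer(agg[!known])
        rows$gc <- gc_content(rows$sequence)
        pool <- rbind(pool, rows)
      }
    }
    total <- sum(pool$count)
    if (total > cap) {
      pool$count <- rbinom(nrow(pool), pool$count, cap / total)
      pool <- pool[pool$count > 0, , drop = FALSE]
    }
  }
  pool <- pool[pool$count > 0, , drop = FALSE]
  pool$gc <- NULL
  pool$is_new <- !(pool$sequence %in% original)
  rownames(pool) <- NULL
  list(pool = pool,
       events = data.frame(position = seq_len(L), n_events = ev_pos))
}

## Multivariate hypergeometric draw: k molecules sampled without
## replacement from species counts.
rmvhyper <- function(counts, k) {
  total <- sum(counts)
  stopifnot(k <= total)
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (k == 0) break
    total <- total - counts[i]
    out[i] <- rhyper(1, counts[i], total, k)
    k <- k - out[i]
  }
  out
}

#' Simulate sequencing of a pool
#'
#' Draws `min(n_reads, pool size)` molecules without replacement from the
#' pool composition and emits each as a read
#' `barcode + flank5 + region + flank3` with the pool's barcode. Sampling
#' without replacement keeps read counts proportional to molecule counts
#' even for small bound pools (a recovered pool smaller than the requested
#' depth is simply sequenced exhaustively), so prevalences remain
#' comparable across pools after depth normalization.
#'
#' @param pool data.frame with `sequence` (region) and `count`.
#' @param n_reads requested number of reads.
#' @param spec one pool-sheet row (see [pool_sheet()]).
#' @param error_rate optional uniform per-base substitution error applied
#'   to the emitted reads (default 0).
#' @return list with `reads` (named character vector; names are
#'   `<pool_id>|<serial>`), and `census_true` (data.frame `sequence`,
#'   `count` of sampled region copies, zero rows dropped).
#' @export
simulate_sequencing <- function(pool, n_reads, spec, error_rate = 0) {
  stopifnot(nrow(pool) >= 1)
  if (n_reads == 0)
    return(list(reads = character(0),
                census_true = data.frame(sequence = character(0),
                                         count = integer(0))))
  draw <- rmvhyper(pool$count, min(n_reads, sum(pool$count)))
  keep <- draw > 0
  regions <- rep(pool$sequence[keep], draw[keep])
  reads <- paste0(spec$barcode, spec$flank5, regions, spec$flank3)
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    W <- nchar(reads[1])
    n_err <- rbinom(length(reads), W, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(W, n_err[i])
      old <- match(substring(reads[i], pos, pos), bases)
      new <- ((old - 1L + sample.int(3L, n_err[i], replace = TRUE)) %% 4L) + 1L
      for (j in seq_along(pos))
        substr(reads[i], pos[j], pos[j]) <- bases[new[j]]
    }
  }
  names(reads) <- paste0(spec$pool_id, "|", seq_along(reads))
  census <- data.frame(sequence = pool$sequence[keep],
                       count = draw[keep], stringsAsFactors = FALSE)
  census <- census[order(-census$count, census$sequence), , drop = FALSE]
  rownames(census) <- NULL
  list(reads = reads, census_true = census)
}

## Random region sequences with per-species GC propensity drawn from
## gc_prob_range, giving the pool a broad GC spread.
random_regions <- function(n, L, gc_prob_range) {
  gcp <- runif(n, gc_prob_range[1], gc_prob_range[2])
  vapply(gcp, function(p) {
    is_gc <- runif(L) < p
    b <- ifelse(is_gc, sample(c("G", "C"), L, replace = TRUE),
                sample(c("A", "T"), L, replace = TRUE))
    paste(b, collapse = "")
  }, character(1))
}

init_species <- function(cfg) {
  n <- cfg$n_species
  seqs <- unique(random_regions(n, cfg$region_length, cfg$gc_prob_range))
  while (length(seqs) < n)
    seqs <- unique(c(seqs, random_regions(n - length(seqs),
                                          cfg$region_length,
                                          cfg$gc_prob_range)))
  cls <- sample(names(cfg$class_probs), n, replace = TRUE,
                prob = cfg$class_probs)
  kd <- numeric(n)
  kd[cls == "high"] <- runif(sum(cls == "high"), cfg$kd_high[1],
                             cfg$kd_high[2])
  kd[cls == "medium"] <- runif(sum(cls == "medium"), cfg$kd_medium[1],
                               cfg$kd_medium[2])
  kd[cls == "low"] <- runif(sum(cls == "low"), cfg$kd_low[1], cfg$kd_low[2])
  kd[cls == "nonbinder"] <- cfg$kd_nonbinder
  carrier <- runif(n) < cfg$carrier_frac
  kd_carrier <- ifelse(carrier,
                       runif(n, cfg$kd_carrier[1], cfg$kd_carrier[2]), Inf)
  ## charge binders bind the control only under charge-flipped (adjusted)
  ## conditions; a species that also binds the carrier normally belongs to
  ## the carrier class, so the two mechanisms are disjoint
  charge <- runif(n) < cfg$charge_frac & !carrier
  kd_charge <- ifelse(charge,
                      runif(n, cfg$kd_charge[1], cfg$kd_charge[2]), Inf)
  ## epitope conservation is independent of affinity: any binder class can
  ## be cross-reactive with the ortholog target
  cross <- cls != "nonbinder" & runif(n) < cfg$cross_frac
  kd_ortholog <- ifelse(cross,
                        kd * runif(n, cfg$ortholog_kd_jitter[1],
                                   cfg$ortholog_kd_jitter[2]),
                        cfg$kd_nonbinder)
  counts <- as.integer(round(10^runif(n, cfg$init_copies_log10[1],
                                      cfg$init_copies_log10[2])))
  data.frame(sequence = seqs, count = counts, species_id = seq_len(n),
             class = cls, kd_target = kd, kd_ortholog = kd_ortholog,
             kd_carrier = kd_carrier, kd_charge = kd_charge,
             carrier_binder = carrier, charge_binder = charge,
             cross_reactive = cross, origin = "initial",
             stringsAsFactors = FALSE)
}

## Retention probabilities of a pool against one pool type.
pool_retention <- function(pool, type, target_conc, cfg) {
  bg <- cfg$background_retention
  carrier_term <- binding_probability(pool$kd_carrier, target_conc)
  p <- switch(type,
    target = binding_probability(pool$kd_target, target_conc,
                                 carrier_term, bg),
    ortholog = binding_probability(pool$kd_ortholog, target_conc,
                                   carrier_term, bg),
    control = pmin(carrier_term + bg, 1),
    adjusted = pmin(carrier_term +
                      binding_probability(pool$kd_charge, target_conc) + bg,
                    1),
    stop("unknown pool type: ", type))
  p
}

bind_pool <- function(pool, type, target_conc, cfg) {
  p <- pool_retention(pool, type, target_conc, cfg)
  pool$count <- rbinom(nrow(pool), pool$count, p)
  pool[pool$count > 0, , drop = FALSE]
}

## Apply Kd inheritance penalties to mutants that arose in a PCR step, and
## the planted-variant override.
annotate_mutants <- function(pool, cfg, planted) {
  new <- which(pool$is_new)
  if (length(new)) {
    pen <- exp(rnorm(length(new), cfg$mutant_kd_meanlog, cfg$mutant_kd_sdlog))
    pool$kd_target[new] <- pool$kd_target[new] * pen
    pool$kd_ortholog[new] <- pool$kd_ortholog[new] * pen
    pool$origin[new] <- "mutant"
    if (!is.null(planted)) {
      hit <- new[pool$sequence[new] == planted$sequence]
      if (length(hit))
        pool$kd_target[hit] <- planted$kd_target
    }
  }
  pool$is_new <- NULL
  pool
}

#' Simulate a full SELEX campaign
#'
#' Chains binding, amplification (with mutagenesis) and sequencing across
#' rounds. The bound fraction of every round is sequenced (pools `R1` ...
#' `R<rounds>`); at `arm_branch_round` the bound pool is additionally
#' amplified by open PCR and carried through one more binding round,
#' sequenced as `R<r+1>_oPCR` (the emulsion-amplified `R<r+1>` is its
#' paired arm); at the final round parallel aliquots are bound to the
#' control, pH-adjusted control and ortholog pools. Runs are exactly
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory: writes `reads.fastq` (all pools
#'   combined, shuffled), `pools.tsv` (pool sheet), and
#'   `species_truth.tsv` (per-species ground truth: class, Kds, flags).
#' @return object of class `selex_campaign`: list with `config`, `species`
#'   (initial ground-truth table), `planted` (planted variant info or NULL),
#'   `pool_sheet`, `pools` (named list of true sampled-read censuses,
#'   data.frames `sequence`/`count`), `final_composition` (pre-sequencing
#'   molecule table of the last main-line pool) and `files`.
#' @export
simulate_campaign <- function(config = sim_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  species <- init_species(cfg)
  planted <- NULL
  pool <- species
  if (cfg$plant_variant) {
    cand <- species[species$class == "high" & !species$carrier_binder &
                      !species$charge_binder, , drop = FALSE]
    ## prefer a founder in the upper half of the high-affinity Kd range:
    ## an improvement of a 2 nM binder is invisible once the Langmuir
    ## term saturates, whereas a 10 nM founder leaves room for its
    ## variant to expand
    mid <- cand[cand$kd_target >= mean(cfg$kd_high), , drop = FALSE]
    if (nrow(mid)) cand <- mid
    if (nrow(cand)) {
      founder <- cand[which.max(cand$count), , drop = FALSE]
      pos <- sample.int(cfg$region_length, 1)
      bases <- c("A", "C", "G", "T")
      ref <- substr(founder$sequence, pos, pos)
      alt <- sample(setdiff(bases, ref), 1)
      pseq <- founder$sequence
      substr(pseq, pos, pos) <- alt
      planted <- list(sequence = pseq, founder = founder$sequence,
                      position = pos, ref = ref, alt = alt,
                      kd_target = founder$kd_target * cfg$planted_kd_factor)
      ## seeded at trace copies: stands for an early PCR-mutagenesis event,
      ## giving the beneficial variant the whole campaign to expand
      prow <- founder
      prow$sequence <- pseq
      prow$count <- cfg$planted_init_copies
      prow$kd_target <- planted$kd_target
      prow$origin <- "planted"
      pool <- rbind(pool, prow)
    }
  }
  pools <- list()
  sheet_rows <- list()
  all_reads <- list()
  barcodes <- sim_barcodes(min(16L, cfg$rounds + 5L))
  bc_i <- 0L
  next_barcode <- function() {
    bc_i <<- bc_i + 1L
    barcodes[bc_i]
  }
  add_pool <- function(bound, pool_id, round, target) {
    spec <- pool_sheet(pool_id, round, target, next_barcode(),
                       cfg$flank5, cfg$flank3, cfg$region_length)
    sq <- simulate_sequencing(bound[c("sequence", "count")],
                              cfg$reads_per_pool, spec, cfg$seq_error_rate)
    pools[[pool_id]] <<- sq$census_true
    sheet_rows[[pool_id]] <<- spec
    all_reads[[pool_id]] <<- sq$reads
  }
  amplify <- function(bound, mode) {
    res <- simulate_pcr(bound, mode, cfg$pcr_cycles, cfg$mu, cfg$gc_slope,
                        cfg$e_base, cfg$pool_cap)
    annotate_mutants(res$pool, cfg, planted)
  }
  final_composition <- NULL
  for (r in seq_len(cfg$rounds)) {
    target_conc <- cfg$target_conc0 * cfg$target_decay^(r - 1)
    is_final <- r == cfg$rounds
    bound <- bind_pool(pool, "target", target_conc, cfg)
    if (nrow(bound) == 0) stop("selection collapsed: empty bound pool")
    add_pool(bound, paste0("R", r), r, cfg$target_label)
    if (is_final && cfg$parallel_targets) {
      for (pt in list(list("control", cfg$control_label, "hIgG"),
                      list("adjusted", cfg$adjusted_label, "hIgG_pH"),
                      list("ortholog", cfg$ortholog_label, "ortholog"))) {
        pbound <- bind_pool(pool, pt[[1]], target_conc, cfg)
        if (nrow(pbound))
          add_pool(pbound, paste0("R", r, "_", pt[[3]]), r, pt[[2]])
      }
    }
    if (!is.na(cfg$arm_branch_round) && r == cfg$arm_branch_round &&
        !is_final) {
      opcr <- amplify(bound, "open")
      obound <- bind_pool(opcr, "target",
                          cfg$target_conc0 * cfg$target_decay^r, cfg)
      if (nrow(obound))
        add_pool(obound, paste0("R", r + 1L, "_oPCR"), r + 1L,
                 cfg$target_label)
    }
    if (is_final) {
      final_composition <- bound
    } else {
      pool <- amplify(bound, cfg$pcr_mode)
    }
  }
  sheet <- do.call(rbind, sheet_rows)
  rownames(sheet) <- NULL
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    reads <- unlist(unname(all_reads))
    reads <- reads[sample.int(length(reads))]   # shuffle pools together
    fq <- file.path(out_dir, "reads.fastq")
    writeLines(as.vector(rbind(paste0("@", names(reads)), reads, "+",
                               strrep("I", nchar(reads)))), fq)
    ps <- file.path(out_dir, "pools.tsv")
    write.table(sheet, ps, sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- file.path(out_dir, "species_truth.tsv")
    truth <- species
    truth$planted_variant <- if (is.null(planted)) FALSE
                             else truth$sequence == planted$founder
    write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(reads = fq, pools = ps, truth = tr)
  }
  structure(list(config = cfg, species = species, planted = planted,
                 pool_sheet = sheet, pools = pools,
                 final_composition = final_composition, files = files),
            class = "selex_campaign")
}

#' @export
print.selex_campaign <- function(x, ...) {
  cat("selex_campaign: ", x$config$rounds, " rounds, ",
      nrow(x$species), " initial species, pools: ",
      paste(names(x$pools), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' True read-count censuses of a simulated campaign
#'
#' Converts the simulator's per-pool sampled-read tables into
#' [build_census()]-compatible `pool_census` objects (bypassing FASTQ
#' round-tripping).
#'
#' @param campaign a `selex_campaign`.
#' @return named list of `pool_census` objects.
#' @export
campaign_censuses <- function(campaign) {
  out <- lapply(names(campaign$pools), function(p) {
    cen <- campaign$pools[[p]]
    build_census(rep(cen$sequence, cen$count), p)
  })
  names(out) <- names(campaign$pools)
  out
}
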