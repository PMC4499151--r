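## End-to-end orchestration: demux -> census -> cluster -> dynamics ->
## specificity -> landscape -> report, with TSV checkpoints per stage.

#' Pipeline parameters
#'
#' All tunables of the analysis stages, with the module defaults.
#'
#' @param max_barcode_mismatches barcode mismatches tolerated in demux.
#' @param max_flank_mismatches flank mismatches tolerated in region
#'   extraction.
#' @param max_dist cluster membership edit-distance bound.
#' @param kmer_k k-mer length of the clustering prefilter.
#' @param pseudocount pseudocount for enrichment and specificity ratios.
#' @param fold ten-fold specificity boundary.
#' @param similarity cross-species prevalence similarity bound.
#' @param high_fold,low_fold landscape flag boundaries.
#' @param n_top_clusters clusters profiled by the landscape stage.
#' @param shortlist_size rows in the candidate shortlist.
#' @param target_label,control_label,adjusted_label,ortholog_label pool
#'   target labels used to locate the specificity pools.
#' @return named list of parameters.
#' @export
pipeline_params <- function(max_barcode_mismatches = 0L,
                            max_flank_mismatches = 2L,
                            max_dist = 3L, kmer_k = 4L,
                            pseudocount = 0.5, fold = 10, similarity = 3,
                            high_fold = 3, low_fold = 1 / 3,
                            n_top_clusters = 5L, shortlist_size = 50L,
                            target_label = "hIL10RA",
                            control_label = "hIgG",
                            adjusted_label = "hIgG_pH_adjusted",
                            ortholog_label = "mIL10RA") {
  as.list(environment())
}

#' Load a pipeline run configuration from YAML
#'
#' The file may contain `input_dir`, `out_dir`, and a `params` mapping with
#' any field of [pipeline_params()].
#'
#' @param path YAML file path.
#' @return list with `input_dir`, `out_dir`, `params`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  cfg <- yaml::read_yaml(path)
  params <- do.call(pipeline_params, cfg$params %||% list())
  list(input_dir = cfg$input_dir, out_dir = cfg$out_dir, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Expects `input_dir` to contain a reads file (`reads.fastq`, optionally
#' `.fastq.gz`, or `.fasta`) and a pool sheet `pools.tsv`
#' (see [read_pool_sheet()]). Stages run in order with TSV checkpoints in
#' `out_dir`; a stage failure halts the run naming the stage, keeping the
#' artifacts already written. Rerunning on identical inputs reproduces the
#' artifacts byte for byte: no stage uses randomness.
#'
#' The main selection line is taken to be the pools whose target equals
#' `params$target_label` and whose pool_id contains no underscore
#' (arm and reference pools are suffixed, e.g. `R3_oPCR`, `R5_hIgG`).
#'
#' @param input_dir directory of inputs (or a YAML config path, see
#'   [load_run_config()]).
#' @param out_dir directory for artifacts (created).
#' @param params [pipeline_params()].
#' @return invisible list with every stage table, the artifact paths, and
#'   `report` / `shortlist`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         params = pipeline_params()) {
  if (length(input_dir) == 1 && grepl("\\.ya?ml$", input_dir)) {
    cfg <- load_run_config(input_dir)
    return(run_pipeline(cfg$input_dir, out_dir %||% cfg$out_dir, cfg$params))
  }
  stage("validate", {
    if (is.null(out_dir)) stop("out_dir is required")
    if (!dir.exists(input_dir)) stop("input_dir not found: ", input_dir)
    reads_file <- Filter(file.exists, file.path(input_dir,
      c("reads.fastq", "reads.fastq.gz", "reads.fasta", "reads.fasta.gz")))
    if (!length(reads_file)) stop("no reads file in ", input_dir)
    reads_file <- reads_file[1]
    sheet_file <- file.path(input_dir, "pools.tsv")
    if (!file.exists(sheet_file)) stop("no pools.tsv in ", input_dir)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pools <- stage("pool_sheet", read_pool_sheet(sheet_file))
  reads <- stage("read_reads", read_reads(reads_file))

  dm <- stage("demux_extract",
              demux_extract(reads, pools, params$max_barcode_mismatches,
                            params$max_flank_mismatches))
  tallies <- do.call(rbind, lapply(names(dm$tallies), function(p)
    cbind(pool_id = p, dm$tallies[[p]])))
  write_tsv(tallies, out_dir, "extraction_tally.tsv")

  censuses <- stage("census", lapply(pools$pool_id, function(p)
    build_census(dm$regions[[p]], p)))
  combined <- stage("census", combine_censuses(censuses))
  write_tsv(combined, out_dir, "census.tsv")

  ## bystanders (single copy in the whole dataset) cannot seed or join a
  ## PCR-mutagenesis family by definition; cluster the true aptamers
  clusters <- stage("clustering", {
    ta <- combined[combined$total >= 2L, , drop = FALSE]
    if (nrow(ta)) cluster_pool(ta, params$max_dist, params$kmer_k) else NULL
  })
  if (!is.null(clusters)) write_tsv(clusters, out_dir, "clusters.tsv")

  statuses <- stage("classify", classify_sequences(combined, clusters))
  write_tsv(statuses, out_dir, "statuses.tsv")

  main <- pools[pools$target == params$target_label &
                  !grepl("_", pools$pool_id), , drop = FALSE]
  main <- main[order(main$round), , drop = FALSE]

  composition <- stage("round_composition",
                       round_composition(combined, statuses, main, clusters))
  convergence <- stage("convergence", if (nrow(composition) >= 2)
    convergence_report(composition[c("round", "n_clusters",
                                     "mean_members_per_cluster")])
    else NULL)
  write_tsv(composition, out_dir, "round_composition.tsv")
  if (!is.null(convergence)) write_tsv(convergence, out_dir,
                                       "convergence.tsv")

  enrich <- stage("dynamics", if (nrow(main) >= 2)
    enrichment_table(combined, main$pool_id, pseudocount = params$pseudocount)
    else NULL)
  if (!is.null(enrich)) write_tsv(enrich, out_dir, "enrichment.tsv")

  final_round <- max(pools$round)
  find_pool <- function(label) {
    p <- pools$pool_id[pools$round == final_round & pools$target == label]
    if (length(p)) p[1] else NULL
  }
  spec_tab <- stage("specificity", {
    target_pool <- find_pool(params$target_label)
    control_pool <- find_pool(params$control_label)
    if (!is.null(target_pool) && !is.null(control_pool))
      specificity_table(combined, target_pool, control_pool,
                        adjusted = find_pool(params$adjusted_label),
                        ortholog = find_pool(params$ortholog_label),
                        fold = params$fold,
                        pseudocount = params$pseudocount,
                        similarity = params$similarity)
    else NULL
  })
  if (!is.null(spec_tab)) write_tsv(spec_tab, out_dir, "specificity.tsv")

  landscapes <- stage("landscape", {
    if (is.null(clusters)) list() else {
      founders <- clusters[clusters$is_founder, , drop = FALSE]
      sizes <- table(clusters$cluster_id)
      founders <- founders[sizes[founders$cluster_id] >= 2, , drop = FALSE]
      founders <- founders[order(-founders$total), , drop = FALSE]
      top <- head(founders$cluster_id, params$n_top_clusters)
      out <- lapply(top, function(cid)
        position_profile(cluster_members(clusters, cid),
                         pool = "total", high_fold = params$high_fold,
                         low_fold = params$low_fold))
      names(out) <- top
      out
    }
  })
  for (cid in names(landscapes))
    write_tsv(landscapes[[cid]]$per_position, out_dir,
              paste0("landscape_", cid, ".tsv"))
  variant_cand <- do.call(rbind, lapply(names(landscapes), function(cid) {
    v <- candidate_variants(landscapes[[cid]], params$high_fold,
                            params$low_fold)
    if (nrow(v)) cbind(cluster_id = cid, v) else NULL
  }))
  if (!is.null(variant_cand))
    write_tsv(variant_cand, out_dir, "variant_candidates.tsv")

  report <- stage("report", {
    if (is.null(enrich)) stop("need at least two main-line rounds")
    rep <- rank_candidates(enrich, "combined")
    rep$status <- statuses$status[match(rep$sequence, statuses$sequence)]
    rep$cluster_id <-
      statuses$cluster_id[match(rep$sequence, statuses$sequence)]
    if (!is.null(spec_tab)) {
      idx <- match(rep$sequence, spec_tab$sequence)
      rep$pattern <- spec_tab$pattern[idx]
      rep$electrostatic_flag <- spec_tab$electrostatic_flag[idx]
      rep$excluded <- spec_tab$excluded[idx]
      if (!is.null(spec_tab$cross_species))
        rep$cross_species <- spec_tab$cross_species[idx]
    }
    rep
  })
  write_tsv(report, out_dir, "report.tsv")
  shortlist <- report
  if (!is.null(shortlist$pattern))
    shortlist <- shortlist[shortlist$pattern == "target_specific" &
                             !shortlist$excluded, , drop = FALSE]
  shortlist <- head(shortlist[shortlist$status != "bystander", , drop = FALSE],
                    params$shortlist_size)
  write_tsv(shortlist, out_dir, "shortlist.tsv")

  invisible(list(pools = pools, combined = combined, clusters = clusters,
                 statuses = statuses, composition = composition,
                 convergence = convergence, enrichment = enrich,
                 specificity = spec_tab, landscapes = landscapes,
                 variant_candidates = variant_cand,
                 report = report, shortlist = shortlist,
                 out_dir = out_dir))
}
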