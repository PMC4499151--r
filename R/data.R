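#' Bundled example: representative aptamers from an IL-10RA selection
#'
#' A small published set of representative N40 aptamer sequences from a
#' five-round selection against the human IL-10 receptor alpha chain:
#' the core (founder) sequences of the major clusters with their round-4
#' and round-5 prevalences, the printed enrichment rates and measured
#' binding affinities, the single-substitution variants of cluster J, and
#' example unclustered and bystander sequences. Used in the worked
#' examples and as a real-data fixture for the enrichment, clustering and
#' landscape operations.
#'
#' @return data.frame with columns `cluster_id`, `sequence_id`, `sequence`
#'   (N40 random region), `r4`, `r5` (prevalences), `rate_printed`
#'   (published round-4 to round-5 enrichment rate, one decimal), `kd_nM`
#'   (measured Kd as printed, including `>500` and `n.d.`), `category`
#'   (`core`, `variant`, `unclustered`, `bystander`).
#' @export
il10ra_example <- function() {
  path <- system.file("extdata", "il10ra_representatives.tsv",
                      package = "aptrace", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(rate_printed = "numeric", r4 = "integer",
                            r5 = "integer"))
}
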