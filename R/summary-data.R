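#' Published questionnaire summary statistics
#'
#' The printed t statistics, sample sizes, Bayes factors and effect
#' sizes of the two questionnaire comparisons of the source experiments:
#' simulated-hallucination video versus unaltered control video (paired,
#' n = 12), versus psilocybin administration (independent, 12 vs 15),
#' and the two Experiment-2 subjective ratings (paired, n = 21). Only
#' the t statistics and sample sizes are inputs to recomputation; the
#' printed `bf10_printed` / `d_printed` columns are carried for
#' comparison.
#'
#' @return Data frame with columns `comparison` (`control`,
#'   `psilocybin`, `exp2`), `dimension`, `design`, `n1`, `n2`, `t`,
#'   `bf10_printed`, `d_printed`.
#' @export
ascq_summary_stats <- function() {
  read.csv(system.file("extdata", "ascq_summary_stats.csv",
                       package = "deepdreamr"),
           stringsAsFactors = FALSE)
}
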