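#' Run the full target-network analysis for a miRNA cohort
#'
#' End-to-end convenience wrapper: miTG filtering and ID mapping
#' ([build_target_sets()]), seed matching and one-hop network extraction
#' ([extract_cohort()]), canonical-network scoring and ranking
#' ([enrich_cohort()]), top-k totalization ([totalize_topk()]) and the
#' large-network report ([large_network_report()]).
#'
#' @param graph a [knowledge_graph()].
#' @param library a [canonical_library()].
#' @param predictions prediction table (see [read_predictions()]).
#' @param idmap ID-mapping table (see [read_idmap()]).
#' @param cutoff miTG reliability cutoff (default 20).
#' @param mode network-search mode, `"connector"` or `"full"`.
#' @param k top-k depth for totalization (default 3).
#' @param min_targets strict threshold for the large-network report
#'   (default 100).
#' @return list with `target_sets`, `networks`, `results`, `summary`,
#'   `report`, and `attrition` (stage counts of the cohort).
#' @export
run_target_network_analysis <- function(graph, library, predictions, idmap,
                                        cutoff = 20,
                                        mode = c("connector", "full"),
                                        k = 3, min_targets = 100) {
  mode <- match.arg(mode)
  target_sets <- build_target_sets(predictions, idmap, cutoff = cutoff)
  networks <- extract_cohort(target_sets, graph, mode = mode)
  results <- enrich_cohort(networks, library, graph)
  summary <- totalize_topk(results, k = k)
  report <- large_network_report(target_sets, networks, results,
                                 min_targets = min_targets)
  n_reliable <- sum(lengths(filter_targets(predictions, cutoff)) > 0)
  attrition <- c(examined = length(unique(predictions$mirna)),
                 reliable = n_reliable,
                 mapped = length(target_sets),
                 networked = length(networks))
  list(target_sets = target_sets, networks = networks, results = results,
       summary = summary, report = report, attrition = attrition)
}
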