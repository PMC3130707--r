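#' Totalize top-k canonical networks across a miRNA cohort
#'
#' For each category independently, counts how often each canonical network
#' appears among any miRNA's k best-ranked results. The percentage
#' denominator is the number of top-k slots actually filled in that category
#' (miRNAs scored against fewer than k canonicals contribute fewer slots),
#' and is exposed in the output rather than guessed.
#'
#' @param results cohort result table from [enrich_cohort()].
#' @param k number of top ranks to count per miRNA and category (default 3).
#' @return data frame with columns `category`, `canonical_name`, `n`
#'   (appearances), `n_slots` (filled slots in the category), `pct`
#'   (`100 * n / n_slots`), sorted by count within category.
#' @export
totalize_topk <- function(results, k = 3) {
  stopifnot(k >= 1)
  top <- results[results$rank <= k, , drop = FALSE]
  if (nrow(top) == 0L) {
    return(data.frame(category = character(), canonical_name = character(),
                      n = integer(), n_slots = integer(), pct = numeric()))
  }
  out <- lapply(split(top, top$category), function(block) {
    tab <- sort(table(block$canonical_name), decreasing = TRUE)
    data.frame(category = block$category[1],
               canonical_name = names(tab),
               n = as.integer(tab),
               n_slots = nrow(block),
               pct = 100 * as.integer(tab) / nrow(block),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Report the large-scale miRNA target networks
#'
#' Restricts the cohort to miRNAs whose mapped target count is strictly
#' greater than `min_targets` and tabulates, per miRNA: the number of mapped
#' targets, the number of molecules in the extracted network, and the
#' top-ranked pathway, disease and pathological event with their integer
#' scores and p-values.
#'
#' @param target_sets named list from [build_target_sets()].
#' @param networks named list from [extract_cohort()].
#' @param results cohort result table from [enrich_cohort()].
#' @param min_targets strict lower bound on mapped target count (default
#'   100; a miRNA with exactly `min_targets` targets is excluded).
#' @return data frame with one row per qualifying miRNA, ordered by name.
#' @export
large_network_report <- function(target_sets, networks, results,
                                 min_targets = 100) {
  keep <- names(networks)[vapply(names(networks), function(m) {
    target_sets[[m]]$n_mapped > min_targets
  }, logical(1))]
  keep <- sort(keep)
  cols <- c(pathway = "pathway", disease = "disease",
            pathological_event = "event")
  rows <- lapply(keep, function(m) {
    row <- data.frame(mirna = m,
                      n_targets = target_sets[[m]]$n_mapped,
                      n_molecules = networks[[m]]$v_mol,
                      stringsAsFactors = FALSE)
    for (cat in names(cols)) {
      hit <- results[results$mirna == m & results$category == cat &
                       results$rank == 1, , drop = FALSE]
      pfx <- cols[[cat]]
      row[[paste0("top_", pfx)]] <-
        if (nrow(hit)) hit$canonical_name else NA_character_
      row[[paste0(pfx, "_score")]] <-
        if (nrow(hit)) round_half_up(hit$score) else NA_real_
      row[[paste0(pfx, "_p")]] <- if (nrow(hit)) hit$p_value else NA_real_
    }
    row
  })
  if (length(rows) == 0L) {
    return(data.frame(mirna = character(), n_targets = integer(),
                      n_molecules = integer(),
                      top_pathway = character(), pathway_score = numeric(),
                      pathway_p = numeric(),
                      top_disease = character(), disease_score = numeric(),
                      disease_p = numeric(),
                      top_event = character(), event_score = numeric(),
                      event_p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Bar chart of the cumulative top-k totalization
#'
#' One horizontal-bar panel per category showing the `top_n` canonical
#' networks by cumulative top-k count. All numbers live in the
#' [totalize_topk()] table; the chart is a rendering of that table only.
#'
#' @param summary data frame from [totalize_topk()].
#' @param top_n bars per category panel (default 10).
#' @param file optional output path (any device [ggplot2::ggsave()]
#'   supports); when `NULL` the plot object is returned unrendered.
#' @return the ggplot object, invisibly when written to file.
#' @export
render_summary_chart <- function(summary, top_n = 10, file = NULL) {
  shown <- do.call(rbind, lapply(split(summary, summary$category),
                                 utils::head, n = top_n))
  shown$category <- factor(shown$category, levels = CANONICAL_CATEGORIES)
  p <- ggplot2::ggplot(shown,
                       ggplot2::aes(x = .data$n,
                                    y = stats::reorder(.data$canonical_name,
                                                       .data$n))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free",
                        drop = FALSE) +
    ggplot2::labs(x = "appearances in top-k lists", y = NULL,
                  caption = "empty panels: no canonical network scored in that category") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 10, height = 4)
    return(invisible(p))
  }
  p
}
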