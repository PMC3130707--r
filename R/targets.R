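#' Read per-miRNA target predictions
#'
#' Expected TSV columns: `mirna`, `gene`, `mitg_score`. The miTG score is the
#' prediction program's reliability score for a miRNA-target interaction
#' (weighted over conserved and non-conserved recognition elements); higher
#' means a more reliable target.
#'
#' @param file path to a TSV with a header row.
#' @return data frame with columns `mirna`, `gene` (character) and
#'   `mitg_score` (numeric, non-negative).
#' @export
read_predictions <- function(file) {
  df <- utils::read.delim(file, colClasses = "character")
  stopifnot(all(c("mirna", "gene", "mitg_score") %in% names(df)))
  df$mitg_score <- as.numeric(df$mitg_score)
  if (anyNA(df$mitg_score) || any(df$mitg_score < 0)) {
    stop("mitg_score must be numeric and non-negative")
  }
  df[, c("mirna", "gene", "mitg_score")]
}

#' Read a gene ID-mapping table
#'
#' Many-to-many mapping from source gene identifiers (e.g. Ensembl-style) to
#' canonical gene identifiers (Entrez-style). Source ids without an
#' annotation are simply absent from the table; the pipeline drops them.
#'
#' @param file path to a TSV with columns `source_id`, `canonical_id`.
#' @return data frame with character columns `source_id`, `canonical_id`.
#' @export
read_idmap <- function(file) {
  df <- utils::read.delim(file, colClasses = "character")
  stopifnot(all(c("source_id", "canonical_id") %in% names(df)))
  if (any(!nzchar(df$canonical_id) | is.na(df$canonical_id))) {
    stop("idmap contains empty canonical_id entries")
  }
  unique(df[, c("source_id", "canonical_id")])
}

#' Filter predictions by miTG score
#'
#' Retains exactly the predictions whose score is greater than or equal to
#' the cutoff (inclusive boundary: a score of exactly 20 passes the default
#' filter). Grouping by miRNA preserves the input gene order, then
#' deduplicates genes within each miRNA.
#'
#' @param predictions data frame as returned by [read_predictions()].
#' @param cutoff non-negative reliability cutoff; default 20, the value
#'   separating high-precision predictions from the rest.
#' @return named list, one character vector of retained gene ids per miRNA
#'   (possibly empty; empty input yields an empty list).
#' @export
filter_targets <- function(predictions, cutoff = 20) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  keep <- predictions[predictions$mitg_score >= cutoff, , drop = FALSE]
  mirnas <- unique(predictions$mirna)
  out <- lapply(mirnas, function(m) {
    unique(keep$gene[keep$mirna == m])
  })
  stats::setNames(out, mirnas)
}

#' Map source gene ids to canonical gene ids
#'
#' Returns the union of all images of the input ids under the (possibly
#' many-to-many) mapping, deduplicated. Ids absent from the map — the
#' non-annotated ones — are silently dropped; their count is reported with a
#' message.
#'
#' @param genes character vector of source gene ids.
#' @param idmap data frame as returned by [read_idmap()].
#' @return character vector of canonical gene ids, deduplicated, ordered by
#'   first appearance.
#' @export
map_ids <- function(genes, idmap) {
  genes <- as.character(genes)
  n_dropped <- sum(!genes %in% idmap$source_id)
  if (n_dropped > 0) {
    message("map_ids: dropped ", n_dropped, " unannotated id(s)")
  }
  hits <- idmap[idmap$source_id %in% genes, , drop = FALSE]
  # order by position of the source id in the input, then map order
  hits <- hits[order(match(hits$source_id, genes)), , drop = FALSE]
  unique(hits$canonical_id)
}

#' Assemble per-miRNA target sets
#'
#' Composes the miTG filter with ID mapping for every miRNA in the
#' prediction table, keeping attrition bookkeeping per miRNA: `n_input`
#' prediction rows, `n_filtered` unique genes passing the score cutoff,
#' `n_mapped` canonical gene ids after mapping. miRNAs whose mapped set is
#' empty are excluded from the result (they cannot seed a network search)
#' and reported with a message; their names are kept in the `excluded`
#' attribute.
#'
#' @inheritParams filter_targets
#' @inheritParams map_ids
#' @return named list of `target_set` objects (fields `mirna`, `genes`,
#'   `n_input`, `n_filtered`, `n_mapped`) with attribute `excluded`.
#' @export
build_target_sets <- function(predictions, idmap, cutoff = 20) {
  filtered <- filter_targets(predictions, cutoff)
  sets <- list()
  excluded <- character()
  for (m in names(filtered)) {
    genes <- suppressMessages(map_ids(filtered[[m]], idmap))
    ts <- structure(
      list(mirna = m, genes = genes,
           n_input = sum(predictions$mirna == m),
           n_filtered = length(filtered[[m]]),
           n_mapped = length(genes)),
      class = "target_set"
    )
    if (length(genes) == 0L) {
      excluded <- c(excluded, m)
    } else {
      sets[[m]] <- ts
    }
  }
  if (length(excluded)) {
    message("build_target_sets: excluded ", length(excluded),
            " miRNA(s) with no usable targets: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  }
  attr(sets, "excluded") <- excluded
  sets
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$mirna, ": ", x$n_mapped, " mapped genes (",
      x$n_input, " predictions -> ", x$n_filtered, " filtered)\n", sep = "")
  invisible(x)
}

#' Cohort attrition summary
#'
#' Given ordered stage counts of a miRNA cohort (e.g. miRNAs examined,
#' miRNAs with any predicted target, miRNAs with reliable targets, miRNAs
#' with an extracted network), reports each stage as a percentage of the
#' first.
#'
#' @param counts named numeric vector of non-increasing stage counts.
#' @return data frame with columns `stage`, `n`, `pct` (percent of the
#'   first stage).
#' @export
#' @examples
#' attrition_summary(c(examined = 1223, predicted = 532,
#'                     reliable = 273, networked = 232))
attrition_summary <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 1, all(counts >= 0),
            !is.null(names(counts)))
  if (any(diff(counts) > 0)) {
    stop("stage counts must be non-increasing")
  }
  data.frame(stage = names(counts), n = as.numeric(counts),
             pct = 100 * as.numeric(counts) / counts[[1]],
             row.names = NULL)
}
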