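#' Match target genes onto knowledge-graph molecules
#'
#' The starting points of the neighboring network search are the molecules
#' whose canonical gene id appears in the target set. Target genes without a
#' corresponding molecule are counted and reported with a message.
#'
#' @param targets a `target_set` (from [build_target_sets()]) or a character
#'   vector of canonical gene ids.
#' @param graph a [knowledge_graph()].
#' @return character vector of seed molecule ids (possibly empty).
#' @export
match_seeds <- function(targets, graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  genes <- if (inherits(targets, "target_set")) targets$genes
           else as.character(targets)
  seeds <- graph$molecules$id[!is.na(graph$molecules$gene_id) &
                                graph$molecules$gene_id %in% genes]
  n_unmatched <- sum(!genes %in% graph$molecules$gene_id)
  if (n_unmatched > 0) {
    message("match_seeds: ", n_unmatched,
            " target gene(s) not in the knowledge graph")
  }
  seeds
}

#' One-hop neighboring network search
#'
#' Expands a set of seed molecules over the knowledge graph within one
#' interaction hop, over all five relation kinds, ignoring edge direction
#' for adjacency. Two expansion modes:
#'
#' * `connector` (default): a non-seed molecule joins the network only if it
#'   is adjacent to at least two distinct seeds — the minimal set of
#'   intervening molecules needed to connect starting points.
#' * `full`: any molecule adjacent to at least one seed joins.
#'
#' The extracted network's edges are all graph relations with both endpoints
#' inside the node set. The result supplies the V of the overlap statistic
#' as `v_mol` (molecule count) and `v_molrel` (molecules plus relations).
#'
#' @param graph a [knowledge_graph()].
#' @param seeds character vector of seed molecule ids; every seed must exist
#'   in the graph (apply [match_seeds()] first).
#' @param mode `"connector"` or `"full"`.
#' @param mirna optional miRNA label carried along for reporting.
#' @return object of class `extracted_network` with fields `mirna`,
#'   `seed_molecules`, `nodes`, `edges`, `v_mol`, `v_molrel`.
#' @export
#' @examples
#' mol <- data.frame(id = c("A", "B", "C", "D"))
#' rel <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
#'                   kind = "direct_activation")
#' g <- knowledge_graph(mol, rel)
#' net <- neighboring_search(g, c("A", "C"), mode = "connector")
#' sort(net$nodes)  # A B C
neighboring_search <- function(graph, seeds,
                               mode = c("connector", "full"),
                               mirna = NA_character_) {
  stopifnot(inherits(graph, "knowledge_graph"))
  mode <- match.arg(mode)
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, graph$molecules$id)
  if (length(missing)) {
    stop("seed molecule(s) not in graph: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }

  rel <- graph$relations
  # undirected incidence: each relation seen from both ends
  from <- c(rel$source, rel$target)
  to <- c(rel$target, rel$source)
  is_seed_end <- from %in% seeds
  cand <- to[is_seed_end]
  cand_src <- from[is_seed_end]
  keep <- !(cand %in% seeds)
  cand <- cand[keep]
  cand_src <- cand_src[keep]
  if (length(cand)) {
    pair <- !duplicated(paste(cand, cand_src, sep = "\r"))
    n_seed_neighbors <- table(cand[pair])
    need <- if (mode == "connector") 2L else 1L
    added <- names(n_seed_neighbors)[n_seed_neighbors >= need]
  } else {
    added <- character()
  }

  nodes <- union(seeds, added)
  in_nodes <- rel$source %in% nodes & rel$target %in% nodes
  edges <- rel[in_nodes, , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(mirna = mirna, seed_molecules = seeds, nodes = nodes,
         edges = edges, v_mol = length(nodes),
         v_molrel = length(nodes) + nrow(edges)),
    class = "extracted_network"
  )
}

#' @export
print.extracted_network <- function(x, ...) {
  cat("<extracted_network>",
      if (!is.na(x$mirna)) paste0(" ", x$mirna) else "", ": ",
      length(x$seed_molecules), " seeds -> ", x$v_mol, " molecules, ",
      nrow(x$edges), " relations\n", sep = "")
  invisible(x)
}

#' Extract networks for a whole cohort of target sets
#'
#' Runs [match_seeds()] and [neighboring_search()] for every target set.
#' miRNAs whose seeds do not match any graph molecule are dropped (with a
#' message) — mirroring the attrition between miRNAs with reliable targets
#' and miRNAs with an extractable network.
#'
#' @param target_sets named list from [build_target_sets()].
#' @inheritParams neighboring_search
#' @return named list of `extracted_network`s with attribute `no_network`
#'   (miRNAs without matched seeds).
#' @export
extract_cohort <- function(target_sets, graph,
                           mode = c("connector", "full")) {
  mode <- match.arg(mode)
  out <- list()
  dropped <- character()
  for (m in names(target_sets)) {
    seeds <- suppressMessages(match_seeds(target_sets[[m]], graph))
    if (length(seeds) == 0L) {
      dropped <- c(dropped, m)
    } else {
      out[[m]] <- neighboring_search(graph, seeds, mode = mode, mirna = m)
    }
  }
  if (length(dropped)) {
    message("extract_cohort: no network for ", length(dropped), " miRNA(s)")
  }
  attr(out, "no_network") <- dropped
  out
}
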