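#' Relation kinds recognised by the knowledgebase
#'
#' The five interaction types a curated molecular-interaction knowledgebase
#' distinguishes: direct activation/inactivation, transcriptional
#' activation/repression, and complex formation. Complex formation is the
#' only undirected kind; its endpoint pair is stored in canonical (sorted)
#' order so that (a, b) and (b, a) denote the same relation.
#'
#' @format Character vector of length 5.
#' @export
RELATION_KINDS <- c(
  "direct_activation",
  "direct_inactivation",
  "transcriptional_activation",
  "transcriptional_repression",
  "complex_formation"
)

UNDIRECTED_KINDS <- "complex_formation"

#' Canonical-network categories
#' @format Character vector of length 3.
#' @export
CANONICAL_CATEGORIES <- c("pathway", "disease", "pathological_event")

#' Unique key for a set of relations
#'
#' Undirected kinds are order-normalised so the key is orientation-free.
#'
#' @param source,target molecule ids
#' @param kind relation kind, one of [RELATION_KINDS]
#' @return character vector of keys
#' @export
relation_key <- function(source, kind, target) {
  undirected <- kind %in% UNDIRECTED_KINDS
  swap <- undirected & source > target
  s <- ifelse(swap, target, source)
  t <- ifelse(swap, source, target)
  paste(s, kind, t, sep = "\t")
}

normalize_relations <- function(relations) {
  undirected <- relations$kind %in% UNDIRECTED_KINDS
  swap <- undirected & relations$source > relations$target
  if (any(swap)) {
    tmp <- relations$source[swap]
    relations$source[swap] <- relations$target[swap]
    relations$target[swap] <- tmp
  }
  relations$directed <- !(relations$kind %in% UNDIRECTED_KINDS)
  relations$key <- paste(relations$source, relations$kind, relations$target,
                         sep = "\t")
  relations
}

#' Construct a molecular-interaction knowledge graph
#'
#' The knowledge graph is the interaction universe the pipeline searches and
#' scores against: a molecule table (nodes, optionally carrying a canonical
#' gene identifier used to match target genes) and a typed relation table
#' (edges). It supplies the universe size T of the overlap statistic:
#' `n_molecules` for molecule-only scoring, `n_molecules + n_relations` for
#' molecule-plus-relation scoring.
#'
#' @param molecules data frame with columns `id` (unique), optional `name`
#'   (defaults to `id`) and optional `gene_id` (canonical gene identifier;
#'   `NA`/empty for molecules without one; each non-missing value may occur
#'   at most once, one node per gene).
#' @param relations data frame with columns `source`, `target`, `kind`
#'   (one of [RELATION_KINDS]); may be `NULL` or empty for an edgeless graph.
#'   Duplicate relations (same source, kind, target after orientation
#'   normalisation) are collapsed with a warning. Self-loops are rejected
#'   unless `allow_self_loops = TRUE`.
#' @param allow_self_loops logical, default `FALSE`.
#' @return object of class `knowledge_graph` with elements `molecules`,
#'   `relations` (with `directed` and `key` columns), `n_molecules`,
#'   `n_relations`.
#' @export
#' @examples
#' mol <- data.frame(id = c("A", "B", "C"), gene_id = c("1", "2", NA))
#' rel <- data.frame(source = c("A", "B"), target = c("B", "C"),
#'                   kind = c("direct_activation", "complex_formation"))
#' g <- knowledge_graph(mol, rel)
#' g$n_molecules
knowledge_graph <- function(molecules, relations = NULL,
                            allow_self_loops = FALSE) {
  stopifnot(is.data.frame(molecules), "id" %in% names(molecules))
  molecules$id <- as.character(molecules$id)
  if (is.null(molecules$name)) molecules$name <- molecules$id
  molecules$name <- as.character(molecules$name)
  if (is.null(molecules$gene_id)) molecules$gene_id <- NA_character_
  molecules$gene_id <- as.character(molecules$gene_id)
  molecules$gene_id[!is.na(molecules$gene_id) &
                      !nzchar(molecules$gene_id)] <- NA_character_
  molecules <- molecules[, c("id", "name", "gene_id")]

  if (anyDuplicated(molecules$id)) {
    stop("duplicate molecule id(s): ",
         paste(unique(molecules$id[duplicated(molecules$id)]), collapse = ", "))
  }
  gid <- molecules$gene_id[!is.na(molecules$gene_id)]
  if (anyDuplicated(gid)) {
    stop("gene_id mapped to more than one molecule: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }

  if (is.null(relations) || nrow(as.data.frame(relations)) == 0L) {
    relations <- data.frame(source = character(), target = character(),
                            kind = character(), stringsAsFactors = FALSE)
  }
  relations <- as.data.frame(relations)
  stopifnot(all(c("source", "target", "kind") %in% names(relations)))
  relations$source <- as.character(relations$source)
  relations$target <- as.character(relations$target)
  relations$kind <- as.character(relations$kind)

  bad_kind <- !(relations$kind %in% RELATION_KINDS)
  if (any(bad_kind)) {
    stop("unknown relation kind in row(s) ",
         paste(which(bad_kind), collapse = ", "), ": ",
         paste(unique(relations$kind[bad_kind]), collapse = ", "))
  }
  dangling <- !(relations$source %in% molecules$id) |
    !(relations$target %in% molecules$id)
  if (any(dangling)) {
    stop("relation endpoint not in molecule table, row(s) ",
         paste(which(dangling), collapse = ", "))
  }
  loops <- relations$source == relations$target
  if (any(loops) && !allow_self_loops) {
    stop("self-loop relation(s) in row(s) ",
         paste(which(loops), collapse = ", "),
         " (set allow_self_loops = TRUE to keep them)")
  }

  relations <- normalize_relations(relations)
  dup <- duplicated(relations$key)
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate relation(s)")
    relations <- relations[!dup, , drop = FALSE]
  }
  rownames(relations) <- NULL
  rownames(molecules) <- NULL

  structure(
    list(molecules = molecules,
         relations = relations[, c("source", "target", "kind", "directed",
                                   "key")],
         n_molecules = nrow(molecules),
         n_relations = nrow(relations)),
    class = "knowledge_graph"
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> ", x$n_molecules, " molecules, ",
      x$n_relations, " relations\n", sep = "")
  if (x$n_relations > 0) {
    tab <- table(x$relations$kind)
    cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a knowledge graph from node and edge TSV tables
#'
#' Native tabular format: a molecule table with columns `id`, `name`,
#' `gene_id` (empty allowed) and a relation table with columns `source`,
#' `target`, `kind` (a `directed` column, if present, is ignored: direction
#' is a property of the kind).
#'
#' @param molecule_file,relation_file paths to TSV files with header rows.
#' @inheritParams knowledge_graph
#' @return a [knowledge_graph()]
#' @export
read_knowledgebase <- function(molecule_file, relation_file,
                               allow_self_loops = FALSE) {
  mol <- utils::read.delim(molecule_file, colClasses = "character",
                           na.strings = c("NA", ""))
  rel <- utils::read.delim(relation_file, colClasses = "character")
  knowledge_graph(mol, rel, allow_self_loops = allow_self_loops)
}

#' Write a knowledge graph back to node and edge TSV tables
#' @param graph a [knowledge_graph()]
#' @param molecule_file,relation_file output paths
#' @return invisibly, the graph
#' @export
write_knowledgebase <- function(graph, molecule_file, relation_file) {
  stopifnot(inherits(graph, "knowledge_graph"))
  utils::write.table(graph$molecules, molecule_file, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  rel <- graph$relations[, c("source", "target", "kind")]
  rel$directed <- as.integer(graph$relations$directed)
  utils::write.table(rel, relation_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(graph)
}

#' Export relations in SIF dialect
#'
#' One line per relation: `source<TAB>kind<TAB>target`. SIF carries no
#' molecule attributes; round-tripping through [read_sif()] preserves the
#' multiset of (source, kind, target) triples (undirected pairs
#' order-normalised) but needs the molecule table to restore names and gene
#' ids.
#'
#' @param graph a [knowledge_graph()] or an `extracted_network` (whose
#'   edges are then exported)
#' @param file output path or connection
#' @return invisibly, the SIF lines
#' @export
write_sif <- function(graph, file) {
  rel <- if (inherits(graph, "extracted_network")) graph$edges
         else if (inherits(graph, "knowledge_graph")) graph$relations
         else stop("write_sif: need a knowledge_graph or extracted_network")
  lines <- with(rel, paste(source, kind, target, sep = "\t"))
  writeLines(lines, file)
  invisible(lines)
}

#' Import a SIF interaction file
#'
#' @param file path or connection to a 3-column SIF file.
#' @param molecules optional molecule table (as for [knowledge_graph()]);
#'   when `NULL`, molecules are inferred from the relation endpoints with no
#'   names or gene ids.
#' @return a [knowledge_graph()]
#' @export
read_sif <- function(file, molecules = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    parts <- matrix(character(), ncol = 3)
  } else {
    split <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(split) != 3L)) {
      stop("malformed SIF line(s): ",
           paste(which(lengths(split) != 3L), collapse = ", "))
    }
    parts <- do.call(rbind, split)
  }
  rel <- data.frame(source = parts[, 1], kind = parts[, 2],
                    target = parts[, 3], stringsAsFactors = FALSE)
  if (is.null(molecules)) {
    molecules <- data.frame(id = unique(c(rel$source, rel$target)),
                            stringsAsFactors = FALSE)
  }
  knowledge_graph(molecules, rel[, c("source", "target", "kind")])
}

#' Construct a canonical reference network
#'
#' A named, categorised reference subnetwork (pathway, disease, or
#' pathological event) used as the comparison standard: it supplies the C of
#' the overlap statistic. Pathways are scored on molecules plus relations;
#' diseases and pathological events on molecules alone.
#'
#' @param name unique label.
#' @param category one of [CANONICAL_CATEGORIES].
#' @param molecules character vector of member molecule ids.
#' @param relations optional data frame (`source`, `kind`, `target`) or list
#'   of 3-element `[source, kind, target]` triples; endpoints must be members.
#' @return object of class `canonical_network` with `relation_keys`
#'   precomputed for overlap counting.
#' @export
canonical_network <- function(name, category, molecules, relations = NULL) {
  category <- match.arg(category, CANONICAL_CATEGORIES)
  molecules <- unique(as.character(molecules))
  if (is.null(relations)) {
    relations <- data.frame(source = character(), kind = character(),
                            target = character(), stringsAsFactors = FALSE)
  } else if (!is.data.frame(relations)) {
    if (length(relations) == 0L) {
      relations <- data.frame(source = character(), kind = character(),
                              target = character(), stringsAsFactors = FALSE)
    } else {
      relations <- as.data.frame(do.call(rbind, lapply(relations, unlist)),
                                 stringsAsFactors = FALSE)
      names(relations) <- c("source", "kind", "target")
    }
  }
  relations$source <- as.character(relations$source)
  relations$kind <- as.character(relations$kind)
  relations$target <- as.character(relations$target)
  bad <- !(relations$source %in% molecules) |
    !(relations$target %in% molecules)
  if (any(bad)) {
    stop("canonical network '", name, "': relation endpoint(s) outside the ",
         "member molecule set in row(s) ", paste(which(bad), collapse = ", "))
  }
  keys <- unique(relation_key(relations$source, relations$kind,
                              relations$target))
  structure(
    list(name = as.character(name), category = category,
         molecules = molecules, relations = relations,
         relation_keys = keys,
         n_molecules = length(molecules), n_relations = length(keys)),
    class = "canonical_network"
  )
}

#' Bundle canonical networks into a library
#'
#' @param networks list of [canonical_network()] objects; names must be
#'   unique across the whole library.
#' @return object of class `canonical_library`.
#' @export
canonical_library <- function(networks) {
  stopifnot(all(vapply(networks, inherits, logical(1), "canonical_network")))
  nms <- vapply(networks, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicated canonical network name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(networks) <- nms
  structure(list(networks = networks), class = "canonical_library")
}

#' @export
print.canonical_library <- function(x, ...) {
  tab <- library_categories(x)
  cat("<canonical_library> ", length(x$networks), " networks (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-category network counts of a library
#' @param library a [canonical_library()]
#' @return named integer vector over [CANONICAL_CATEGORIES]
#' @export
library_categories <- function(library) {
  cats <- vapply(library$networks, `[[`, character(1), "category")
  tab <- table(factor(cats, levels = CANONICAL_CATEGORIES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset a library by category
#' @inheritParams library_categories
#' @param category one of [CANONICAL_CATEGORIES]
#' @return list of [canonical_network()]s
#' @export
networks_by_category <- function(library, category) {
  category <- match.arg(category, CANONICAL_CATEGORIES)
  Filter(function(n) n$category == category, library$networks)
}

#' Read a canonical-network library from JSON
#'
#' The library is a JSON array of objects
#' `{name, category, molecules: [...], relations: [[source, kind, target], ...]}`.
#' Every member molecule and relation must exist in `graph`.
#'
#' @param file path to a JSON file.
#' @param graph the parent [knowledge_graph()] the members must resolve in.
#' @return a [canonical_library()]; per-category counts are reported with a
#'   message.
#' @export
read_canonical_library <- function(file, graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  networks <- lapply(raw, function(entry) {
    cn <- canonical_network(entry$name, entry$category,
                            unlist(entry$molecules), entry$relations)
    validate_canonical(cn, graph)
    cn
  })
  lib <- canonical_library(networks)
  tab <- library_categories(lib)
  message("canonical library: ",
          paste(names(tab), tab, sep = "=", collapse = ", "))
  lib
}

validate_canonical <- function(network, graph) {
  missing_mol <- setdiff(network$molecules, graph$molecules$id)
  if (length(missing_mol)) {
    stop("canonical network '", network$name, "': member molecule(s) not in ",
         "knowledge graph: ", paste(utils::head(missing_mol, 5),
                                    collapse = ", "))
  }
  missing_rel <- setdiff(network$relation_keys, graph$relations$key)
  if (length(missing_rel)) {
    stop("canonical network '", network$name, "': ", length(missing_rel),
         " member relation(s) not in knowledge graph")
  }
  invisible(network)
}

#' Write a canonical-network library to JSON
#' @param library a [canonical_library()]
#' @param file output path
#' @return invisibly, the library
#' @export
write_canonical_library <- function(library, file) {
  stopifnot(inherits(library, "canonical_library"))
  entries <- lapply(unname(library$networks), function(n) {
    list(name = n$name, category = n$category,
         molecules = as.list(n$molecules),
         relations = lapply(seq_len(nrow(n$relations)), function(i) {
           list(n$relations$source[i], n$relations$kind[i],
                n$relations$target[i])
         }))
  })
  jsonlite::write_json(entries, file, auto_unbox = TRUE, pretty = FALSE)
  invisible(library)
}
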