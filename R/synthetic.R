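#' Configuration for the synthetic data generator
#'
#' Defaults emulate the curated-knowledgebase setting the pipeline targets
#' at one-tenth scale: ~1,570 molecules carrying ~12,300 typed relations
#' (mean degree ~15.7, matching the full-scale ratio of 123,000 relations
#' over 15,700 molecules), a canonical library of 43 pathways, 88 diseases
#' and 21 pathological events, and per-miRNA target lists of 100-500
#' predictions with miTG scores straddling the reliability cutoff of 20.
#'
#' @param n_molecules,n_relations knowledgebase size. `n_relations` must be
#'   achievable as a simple undirected pair set.
#' @param relation_kind_mixture probability vector over [RELATION_KINDS]
#'   (must sum to 1).
#' @param n_pathways,n_diseases,n_events canonical-library category counts.
#' @param canonical_size_range inclusive (min, max) member molecules per
#'   canonical network.
#' @param n_mirnas number of miRNAs to emit predictions for.
#' @param targets_per_mirna_range inclusive (min, max) prediction rows per
#'   miRNA.
#' @param mitg_meanlog,mitg_sdlog log-normal location/scale of the miTG
#'   score distribution; the default median of 20 puts mass on both sides
#'   of the reliability cutoff. Scores are drawn independently of canonical
#'   membership so filtering and enrichment stay statistically separable.
#' @param planted_network name of the canonical network enriched among
#'   targets, or `"random"` to draw one pathway uniformly per generator
#'   call (recorded in the ledger).
#' @param rho fraction of each miRNA's targets drawn from the planted
#'   network's member genes (0 = pure background).
#' @param unmapped_fraction share of used gene ids absent from the emitted
#'   ID map (emulating non-annotated ids dropped at conversion).
#' @param seed integer RNG seed; identical configs give identical outputs.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 1570,
                             n_relations = 12300,
                             relation_kind_mixture = c(
                               direct_activation = 0.30,
                               direct_inactivation = 0.15,
                               transcriptional_activation = 0.20,
                               transcriptional_repression = 0.15,
                               complex_formation = 0.20),
                             n_pathways = 43,
                             n_diseases = 88,
                             n_events = 21,
                             canonical_size_range = c(20, 80),
                             n_mirnas = 20,
                             targets_per_mirna_range = c(100, 500),
                             mitg_meanlog = log(20),
                             mitg_sdlog = 0.6,
                             planted_network = "random",
                             rho = 0.5,
                             unmapped_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_molecules = as.integer(n_molecules),
              n_relations = as.integer(n_relations),
              relation_kind_mixture = relation_kind_mixture,
              n_pathways = as.integer(n_pathways),
              n_diseases = as.integer(n_diseases),
              n_events = as.integer(n_events),
              canonical_size_range = as.integer(canonical_size_range),
              n_mirnas = as.integer(n_mirnas),
              targets_per_mirna_range = as.integer(targets_per_mirna_range),
              mitg_meanlog = mitg_meanlog, mitg_sdlog = mitg_sdlog,
              planted_network = planted_network, rho = rho,
              unmapped_fraction = unmapped_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_molecules > 0, n_relations > 0, n_pathways > 0,
              n_diseases >= 0, n_events >= 0, n_mirnas > 0,
              length(canonical_size_range) == 2,
              canonical_size_range[1] >= 1,
              canonical_size_range[1] <= canonical_size_range[2],
              canonical_size_range[2] <= n_molecules,
              length(targets_per_mirna_range) == 2,
              targets_per_mirna_range[1] >= 1,
              targets_per_mirna_range[1] <= targets_per_mirna_range[2],
              rho >= 0, rho <= 1,
              unmapped_fraction >= 0, unmapped_fraction <= 1,
              mitg_sdlog > 0, seed >= 0, seed < 2^31 - 10)
    stopifnot(setequal(names(relation_kind_mixture), RELATION_KINDS),
              abs(sum(relation_kind_mixture) - 1) < 1e-8,
              all(relation_kind_mixture >= 0))
    if (n_relations > n_molecules * (n_molecules - 1) / 2) {
      stop("infeasible config: n_relations exceeds the number of ",
           "unordered molecule pairs")
    }
  })
  structure(cfg, class = "generator_config")
}

#' Generate a scale-free synthetic knowledgebase
#'
#' Builds a preferential-attachment graph (heavy-tailed degree, emulating
#' the hub structure of curated molecular networks) with exactly
#' `n_relations` simple undirected pairs, then assigns each pair a relation
#' kind drawn from the configured mixture. Roughly 90% of molecules carry a
#' canonical gene id; the rest stand in for small molecules and complexes
#' that no target gene can match. Deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @return a [knowledge_graph()].
#' @export
generate_knowledgebase <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_molecules
  n_rel <- config$n_relations
  m <- max(1L, floor(n_rel / n))
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- pair_id(el[, 1], el[, 2])
  if (length(seen) > n_rel) {
    keep <- sort(sample.int(length(seen), n_rel))
    el <- el[keep, , drop = FALSE]
    seen <- seen[keep]
  }
  deg <- igraph::degree(g)
  while (nrow(el) < n_rel) {
    need <- n_rel - nrow(el)
    a <- sample.int(n, 2 * need, replace = TRUE, prob = deg + 1)
    b <- sample.int(n, 2 * need, replace = TRUE, prob = deg + 1)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    ids <- pair_id(a, b)
    fresh <- !(ids %in% seen) & !duplicated(ids)
    a <- a[fresh][seq_len(min(need, sum(fresh)))]
    b <- b[fresh][seq_len(min(need, sum(fresh)))]
    if (length(a)) {
      el <- rbind(el, cbind(a, b))
      seen <- c(seen, pair_id(a, b))
    }
  }

  ids <- sprintf("MOL%05d", seq_len(n))
  gene_id <- sprintf("%d", 1000L + seq_len(n))
  no_gene <- sample.int(n, round(0.1 * n))
  gene_id[no_gene] <- NA_character_
  molecules <- data.frame(id = ids, name = sprintf("molecule_%d", seq_len(n)),
                          gene_id = gene_id, stringsAsFactors = FALSE)
  kinds <- sample(RELATION_KINDS, nrow(el), replace = TRUE,
                  prob = config$relation_kind_mixture[RELATION_KINDS])
  relations <- data.frame(source = ids[el[, 1]], target = ids[el[, 2]],
                          kind = kinds, stringsAsFactors = FALSE)
  knowledge_graph(molecules, relations)
}

# draw one integer uniformly from an inclusive range; safe when the range
# is a single value (unlike sample(seq(lo, hi), 1))
draw_from_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

# classic snowball sample: each frontier node contributes at most
# `branch` randomly chosen neighbours per wave; bounding the branching
# keeps samples from collapsing onto the hub core of a scale-free graph
snowball_sample <- function(adj, anchor, size, branch = 3L) {
  members <- anchor
  frontier <- anchor
  while (length(members) < size && length(frontier)) {
    nxt <- unlist(lapply(adj[frontier], function(nb) {
      if (length(nb) > branch) sample(nb, branch) else nb
    }), use.names = FALSE)
    nxt <- setdiff(unique(nxt), members)
    if (!length(nxt)) break
    if (length(members) + length(nxt) > size) {
      nxt <- nxt[seq_len(size - length(members))]
    }
    members <- c(members, nxt)
    frontier <- nxt
  }
  members
}

#' Generate a canonical-network library over a knowledge graph
#'
#' Each canonical network is a connectivity-biased node sample: a snowball
#' expansion from a random anchor up to a size drawn uniformly from the
#' configured range, together with all induced relations. Networks may
#' overlap one another, as real pathway libraries do. Deterministic under
#' the config seed.
#'
#' @param graph a [knowledge_graph()].
#' @param config a [generator_config()].
#' @return a [canonical_library()] with networks named
#'   `pathway_001`, ..., `disease_001`, ..., `event_001`, ...
#' @export
generate_canonical_library <- function(graph, config) {
  stopifnot(inherits(graph, "knowledge_graph"),
            inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  rel <- graph$relations
  adj <- split(c(rel$target, rel$source), c(rel$source, rel$target))
  ids <- graph$molecules$id
  counts <- c(pathway = config$n_pathways, disease = config$n_diseases,
              pathological_event = config$n_events)
  prefix <- c(pathway = "pathway", disease = "disease",
              pathological_event = "event")
  networks <- list()
  for (cat in names(counts)) {
    for (i in seq_len(counts[[cat]])) {
      size <- draw_from_range(config$canonical_size_range)
      anchor <- sample(ids, 1)
      members <- snowball_sample(adj, anchor, size)
      in_net <- rel$source %in% members & rel$target %in% members
      networks[[length(networks) + 1L]] <- canonical_network(
        name = sprintf("%s_%03d", prefix[[cat]], i),
        category = cat, molecules = members,
        relations = rel[in_net, c("source", "kind", "target"), drop = FALSE]
      )
    }
  }
  canonical_library(networks)
}

#' Generate per-miRNA target predictions with planted enrichment
#'
#' For each miRNA, a fraction `rho` of its target genes is drawn (without
#' replacement, capped at the member count) from the planted canonical
#' network's member genes and the rest uniformly from the remaining gene
#' universe of the graph. miTG scores are log-normal draws independent of
#' membership. A single set of "non-annotated" gene ids — a fraction
#' `unmapped_fraction` of all used genes — is withheld from the emitted ID
#' map. The ledger records the ground truth per miRNA (planted counts, and
#' expected sizes after the score-20 filter and the ID map), so tests can
#' reconcile pipeline bookkeeping against the generator.
#'
#' @param graph a [knowledge_graph()].
#' @param library a [canonical_library()] containing the planted network.
#' @param config a [generator_config()].
#' @return list with elements `predictions` (data frame `mirna`, `gene`,
#'   `mitg_score`; `gene` holds source-style ids), `idmap` (data frame
#'   `source_id`, `canonical_id`), and `ledger` (list: `planted_network`,
#'   `rho`, `unmapped_genes`, and per-miRNA rows with `n_rows`, `n_planted`,
#'   `n_filtered20`, `n_mapped20`, `n_planted_mapped20`).
#' @export
generate_targets <- function(graph, library, config) {
  stopifnot(inherits(graph, "knowledge_graph"),
            inherits(library, "canonical_library"),
            inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  planted_name <- config$planted_network
  if (identical(planted_name, "random")) {
    pw <- names(networks_by_category(library, "pathway"))
    planted_name <- sample(pw, 1)
  }
  planted <- library$networks[[planted_name]]
  if (is.null(planted)) {
    stop("planted network '", planted_name, "' not found in library")
  }
  mol <- graph$molecules
  gene_of <- stats::setNames(mol$gene_id, mol$id)
  member_genes <- unname(gene_of[planted$molecules])
  member_genes <- member_genes[!is.na(member_genes)]
  all_genes <- mol$gene_id[!is.na(mol$gene_id)]
  source_of <- stats::setNames(sprintf("ENSG%08d", as.integer(all_genes)),
                               all_genes)

  rows <- vector("list", config$n_mirnas)
  per_mirna <- vector("list", config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    mirna <- sprintf("syn-miR-%03d", i)
    n_t <- draw_from_range(config$targets_per_mirna_range)
    # planted quota rho*n_t (capped by the member pool); background quota
    # (1-rho)*n_t drawn uniformly from the genes not already drawn, so
    # rho = 1 yields member genes only and rho = 0 is uniform over the
    # whole gene universe (planted membership carries no signal)
    n_pl <- min(round(config$rho * n_t), length(member_genes))
    pl <- if (n_pl > 0) sample(member_genes, n_pl) else character()
    pool <- setdiff(all_genes, pl)
    n_bg <- min(n_t - round(config$rho * n_t), length(pool))
    bg <- if (n_bg > 0) sample(pool, n_bg) else character()
    genes <- c(pl, bg)
    scores <- stats::rlnorm(length(genes), config$mitg_meanlog,
                            config$mitg_sdlog)
    rows[[i]] <- data.frame(mirna = mirna, gene = unname(source_of[genes]),
                            mitg_score = scores, canonical_gene = genes,
                            planted = genes %in% member_genes,
                            stringsAsFactors = FALSE)
    per_mirna[[i]] <- mirna
  }
  pred_full <- do.call(rbind, rows)

  used <- unique(pred_full$canonical_gene)
  n_unmapped <- round(config$unmapped_fraction * length(used))
  unmapped <- if (n_unmapped > 0) sample(used, n_unmapped) else character()
  mapped <- setdiff(used, unmapped)
  idmap <- data.frame(source_id = unname(source_of[mapped]),
                      canonical_id = mapped, stringsAsFactors = FALSE)

  ledger_rows <- lapply(rows, function(df) {
    pass <- df$mitg_score >= 20
    ok_map <- pass & !(df$canonical_gene %in% unmapped)
    list(mirna = df$mirna[1],
         n_rows = nrow(df),
         n_planted = sum(df$planted),
         n_filtered20 = sum(pass),
         n_mapped20 = sum(ok_map),
         n_planted_mapped20 = sum(ok_map & df$planted))
  })
  list(predictions = pred_full[, c("mirna", "gene", "mitg_score")],
       idmap = idmap,
       ledger = list(planted_network = planted_name, rho = config$rho,
                     unmapped_genes = unmapped, mirnas = ledger_rows))
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_knowledgebase()], [generate_canonical_library()] and
#' [generate_targets()] under one config and optionally writes the same
#' file formats the readers consume: `nodes.tsv`, `edges.tsv`,
#' `library.json`, `targets.tsv`, `idmap.tsv`, `ledger.json`.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory (created if missing).
#' @return list with `graph`, `library`, `predictions`, `idmap`, `ledger`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  graph <- generate_knowledgebase(config)
  library <- generate_canonical_library(graph, config)
  targets <- generate_targets(graph, library, config)
  out <- list(graph = graph, library = library,
              predictions = targets$predictions, idmap = targets$idmap,
              ledger = targets$ledger)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_knowledgebase(graph, file.path(dir, "nodes.tsv"),
                        file.path(dir, "edges.tsv"))
    write_canonical_library(library, file.path(dir, "library.json"))
    utils::write.table(targets$predictions, file.path(dir, "targets.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(targets$idmap, file.path(dir, "idmap.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(targets$ledger, file.path(dir, "ledger.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
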