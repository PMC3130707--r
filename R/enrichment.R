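#' Floor of the reportable p-value
#'
#' The smallest positive normalised double, 2^-1022 (~2.23e-308). P-values
#' at or below the floor are reported as the floor, which caps the overlap
#' score at exactly 1022.
#' @export
P_FLOOR <- 2^-1022

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap of at least `O` between an extracted
#' network of size `V` and a canonical network of size `C` drawn from a
#' universe of `T_total` elements: `P(X >= O)` for
#' `X ~ Hypergeometric(T_total, C, V)`. Computed in log space so scores
#' remain finite and exact down to the reporting floor even for universes of
#' ~1e5 elements.
#'
#' @param O overlap count, `0 <= O <= min(V, C)`.
#' @param V extracted-side element count (`<= T_total`).
#' @param C canonical-side element count (`<= T_total`).
#' @param T_total universe element count.
#' @param log.p return the natural-log probability instead.
#' @return the tail probability (or its natural log). Vectorised.
#' @export
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # choose(5,5)/choose(10,5) = 1/252
hypergeom_tail <- function(O, V, C, T_total, log.p = FALSE) {
  ok <- is.finite(O) & is.finite(V) & is.finite(C) & is.finite(T_total) &
    O >= 0 & V >= 0 & C >= 0 & O <= pmin(V, C) & V <= T_total & C <= T_total
  if (!all(ok)) {
    stop("hypergeom_tail: bounds violated (need 0 <= O <= min(V, C), ",
         "V <= T, C <= T)")
  }
  stats::phyper(O - 1, C, T_total - C, V, lower.tail = FALSE, log.p = log.p)
}

#' Overlap-significance score transform
#'
#' Maps a p-value to the reported network score: `-log2(max(p, 2^-1022))`.
#' The floor at the smallest normalised double makes 1022 the exact score
#' ceiling, attained whenever `p <= 2^-1022`. Scores are kept at full
#' precision; reports round half-up to the nearest integer (see
#' [round_half_up()]).
#'
#' @param p_value numeric vector in (0, 1].
#' @return numeric vector of scores between 0 and 1022.
#' @export
#' @examples
#' round_half_up(score_transform(2.69e-179))  # 593
score_transform <- function(p_value) {
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1)) {
    stop("score_transform: p-values must lie in (0, 1]")
  }
  pmin(1022, -log2(pmax(p_value, P_FLOOR)))
}

# score from a natural-log p-value without leaving log space
score_from_log_p <- function(log_p) {
  pmin(1022, -log_p / log(2))
}

#' Half-up rounding to the nearest integer
#'
#' Report-display rounding for scores: .5 always rounds up (unlike base
#' `round()`'s round-half-even).
#' @param x numeric vector
#' @return numeric vector of integers
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Count the overlap between an extracted and a canonical network
#'
#' Two counting modes mirror the two scoring universes:
#' * `mol`: overlapping molecules alone — `O = |nodes ∩ members|`,
#'   `V = v_mol`, `C` = member molecule count. Used for disease and
#'   pathological-event networks.
#' * `molrel`: molecules plus relations — the molecule overlap plus the
#'   number of extracted relations present in the canonical network with
#'   identical endpoints and kind; `V = v_molrel`, `C` = member molecules +
#'   member relations. Used for pathway networks.
#'
#' @param extracted an `extracted_network` from [neighboring_search()].
#' @param canonical a [canonical_network()].
#' @param mode `"mol"` or `"molrel"`; defaults to `"molrel"` for pathways
#'   and `"mol"` otherwise.
#' @return named numeric vector `c(O, V, C)`.
#' @export
count_overlap <- function(extracted, canonical, mode = NULL) {
  stopifnot(inherits(extracted, "extracted_network"),
            inherits(canonical, "canonical_network"))
  if (is.null(mode)) {
    mode <- if (canonical$category == "pathway") "molrel" else "mol"
  }
  mode <- match.arg(mode, c("mol", "molrel"))
  o_mol <- length(intersect(extracted$nodes, canonical$molecules))
  if (mode == "mol") {
    c(O = o_mol, V = extracted$v_mol, C = canonical$n_molecules)
  } else {
    o_rel <- sum(extracted$edges$key %in% canonical$relation_keys)
    c(O = o_mol + o_rel, V = extracted$v_molrel,
      C = canonical$n_molecules + canonical$n_relations)
  }
}

#' Score an extracted network against a canonical library
#'
#' Every canonical network is scored with its category's overlap mode and
#' universe: pathways on molecules plus relations with
#' `T = n_molecules + n_relations`; diseases and pathological events on
#' molecules alone with `T = n_molecules`. Within each category, results are
#' ranked by p-value ascending, ties broken by overlap `O` descending and
#' then name; exact ties (identical p and O) are reported with a message.
#'
#' @param extracted an `extracted_network`.
#' @param library a [canonical_library()].
#' @param graph the [knowledge_graph()] supplying the universe counts.
#' @return data frame with one row per canonical network: `mirna`,
#'   `category`, `canonical_name`, `O`, `V`, `C`, `T`, `p_value` (floored at
#'   [P_FLOOR]), `score` (full precision), `rank` (within category).
#' @export
rank_canonicals <- function(extracted, library, graph) {
  stopifnot(inherits(extracted, "extracted_network"),
            inherits(library, "canonical_library"),
            inherits(graph, "knowledge_graph"))
  nets <- library$networks
  if (length(nets) == 0L) {
    return(empty_results())
  }
  rows <- lapply(nets, function(cn) {
    is_pw <- cn$category == "pathway"
    ovc <- count_overlap(extracted, cn, mode = if (is_pw) "molrel" else "mol")
    T_total <- if (is_pw) graph$n_molecules + graph$n_relations
               else graph$n_molecules
    log_p <- hypergeom_tail(ovc[["O"]], ovc[["V"]], ovc[["C"]], T_total,
                            log.p = TRUE)
    data.frame(mirna = extracted$mirna, category = cn$category,
               canonical_name = cn$name,
               O = ovc[["O"]], V = ovc[["V"]], C = ovc[["C"]], T = T_total,
               log_p = log_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$p_value <- pmax(exp(res$log_p), P_FLOOR)
  res$score <- score_from_log_p(res$log_p)

  out <- lapply(split(res, res$category), function(block) {
    ord <- order(block$log_p, -block$O, block$canonical_name)
    block <- block[ord, , drop = FALSE]
    ties <- duplicated(block[, c("log_p", "O")])
    if (any(ties)) {
      message("rank_canonicals: ", sum(ties), " exact tie(s) in category '",
              block$category[1], "' broken by name")
    }
    block$rank <- seq_len(nrow(block))
    block
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$log_p <- NULL
  rownames(res) <- NULL
  res[, c("mirna", "category", "canonical_name", "O", "V", "C", "T",
          "p_value", "score", "rank")]
}

empty_results <- function() {
  data.frame(mirna = character(), category = character(),
             canonical_name = character(), O = numeric(), V = numeric(),
             C = numeric(), T = numeric(), p_value = numeric(),
             score = numeric(), rank = integer(), stringsAsFactors = FALSE)
}

#' Score a whole cohort of extracted networks
#'
#' @param networks named list from [extract_cohort()].
#' @inheritParams rank_canonicals
#' @return row-bound data frame of [rank_canonicals()] results.
#' @export
enrich_cohort <- function(networks, library, graph) {
  if (length(networks) == 0L) {
    return(empty_results())
  }
  res <- lapply(networks, rank_canonicals, library = library, graph = graph)
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
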