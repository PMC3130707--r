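# small in-code fixtures shared across test files

# A -> B -> C -> D chain, every molecule carrying a gene id
path_graph <- function() {
  knowledge_graph(
    data.frame(id = c("A", "B", "C", "D"), gene_id = c("1", "2", "3", "4")),
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               kind = "direct_activation")
  )
}

# random scale-free graph at test scale, via the synthetic generator
random_graph <- function(n = 50, m = 150, seed = 1) {
  generate_knowledgebase(generator_config(n_molecules = n, n_relations = m,
                                          canonical_size_range = c(5, 10),
                                          seed = seed))
}

# independent oracle: hypergeometric upper tail as a direct combinatorial
# sum over overlap values, exact in double precision for T <= 25
hyper_tail_sum <- function(O, V, C, T_total) {
  k <- seq(O, min(V, C))
  sum(choose(C, k) * choose(T_total - C, V - k)) / choose(T_total, V)
}

# independent oracle: literal enumeration of all size-V draws (tiny T only)
hyper_tail_enum <- function(O, V, C, T_total) {
  draws <- utils::combn(T_total, V)
  marked <- seq_len(C) # first C elements are the marked ones
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= O)
  mean(hits)
}

# closed-neighborhood oracle for the one-hop full search
closed_neighborhood <- function(graph, seeds) {
  rel <- graph$relations
  nb <- c(rel$target[rel$source %in% seeds], rel$source[rel$target %in% seeds])
  union(seeds, nb)
}
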