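test_that("a typed graph is built, counted and validated", {
  g <- knowledge_graph(
    data.frame(id = c("A", "B", "C")),
    data.frame(source = c("A", "B"), target = c("B", "C"),
               kind = c("direct_activation", "complex_formation"))
  )
  expect_equal(g$n_molecules, 3)
  expect_equal(g$n_relations, 2)
  # universe counts for the two scoring modes are consistent
  expect_equal(g$n_molecules + g$n_relations, 5)
  expect_false(g$relations$directed[g$relations$kind == "complex_formation"])

  # empty relation table gives a valid edgeless graph
  g0 <- knowledge_graph(data.frame(id = c("A", "B")))
  expect_equal(g0$n_relations, 0)
  expect_equal(g0$n_molecules, 2)
})

test_that("undirected relations are order-normalised and duplicates collapse", {
  rel <- data.frame(source = c("B", "A"), target = c("A", "B"),
                    kind = "complex_formation")
  expect_warning(
    g <- knowledge_graph(data.frame(id = c("A", "B")), rel),
    "duplicate"
  )
  expect_equal(g$n_relations, 1)
  expect_equal(g$relations$source, "A") # canonical order

  # directed duplicates collapse too, opposite directions do not
  rel2 <- data.frame(source = c("A", "A", "B"), target = c("B", "B", "A"),
                     kind = "direct_activation")
  expect_warning(g2 <- knowledge_graph(data.frame(id = c("A", "B")), rel2))
  expect_equal(g2$n_relations, 2)
})

test_that("malformed inputs fail with the offending row named", {
  mol <- data.frame(id = c("A", "B"))
  expect_error(
    knowledge_graph(mol, data.frame(source = "A", target = "Z",
                                    kind = "direct_activation")),
    "row\\(s\\) 1"
  )
  expect_error(
    knowledge_graph(mol, data.frame(source = "A", target = "B",
                                    kind = "phosphorylation")),
    "unknown relation kind"
  )
  expect_error(
    knowledge_graph(mol, data.frame(source = "A", target = "A",
                                    kind = "direct_activation")),
    "self-loop"
  )
  expect_error(knowledge_graph(data.frame(id = c("A", "A"))), "duplicate")
  expect_error(
    knowledge_graph(data.frame(id = c("A", "B"), gene_id = c("7", "7"))),
    "gene_id"
  )
})

test_that("node/edge TSV and SIF writers round-trip the graph", {
  g <- path_graph()
  nodes <- tempfile(fileext = ".tsv"); edges <- tempfile(fileext = ".tsv")
  write_knowledgebase(g, nodes, edges)
  g2 <- read_knowledgebase(nodes, edges)
  expect_equal(g2$molecules, g$molecules)
  expect_equal(g2$relations, g$relations)

  sif <- tempfile(fileext = ".sif")
  write_sif(g, sif)
  expect_length(readLines(sif), 3)
  g3 <- read_sif(sif, molecules = g$molecules)
  expect_setequal(g3$relations$key, g$relations$key)

  # edgeless graph writes an empty SIF body
  g0 <- knowledge_graph(data.frame(id = "A"))
  write_sif(g0, sif)
  expect_length(readLines(sif), 0)
})

test_that("SIF round-trip preserves relation triples for random graphs", {
  for (seed in 1:5) {
    g <- random_graph(40, 100, seed = seed)
    sif <- tempfile(fileext = ".sif")
    write_sif(g, sif)
    g2 <- read_sif(sif, molecules = g$molecules)
    expect_setequal(g2$relations$key, g$relations$key)
    expect_equal(g2$n_relations, g$n_relations)
    expect_equal(g2$molecules, g$molecules)
  }
})

test_that("canonical networks validate membership and categories", {
  cn <- canonical_network("wnt", "pathway", c("A", "B"),
                          data.frame(source = "A", kind = "direct_activation",
                                     target = "B"))
  expect_equal(cn$n_molecules, 2)
  expect_equal(cn$n_relations, 1)
  expect_error(
    canonical_network("bad", "pathway", c("A", "B"),
                      data.frame(source = "A", kind = "direct_activation",
                                 target = "Z")),
    "outside the member"
  )
  expect_error(canonical_network("x", "drug_response", "A"))
})

test_that("a canonical library reads from JSON with category counts", {
  g <- random_graph(20, 40, seed = 3)
  rel1 <- g$relations[1, c("source", "kind", "target")]
  nets <- list(
    canonical_network("p1", "pathway",
                      unique(c(rel1$source, rel1$target)), rel1),
    canonical_network("p2", "pathway", g$molecules$id[1:5]),
    canonical_network("d1", "disease", g$molecules$id[3:8])
  )
  lib <- canonical_library(nets)
  expect_equal(unname(library_categories(lib)), c(2L, 1L, 0L))

  f <- tempfile(fileext = ".json")
  write_canonical_library(lib, f)
  lib2 <- suppressMessages(read_canonical_library(f, g))
  expect_equal(library_categories(lib2), library_categories(lib))
  expect_setequal(lib2$networks$p1$relation_keys, nets[[1]]$relation_keys)

  # duplicated names and members outside the graph are hard errors
  expect_error(canonical_library(nets[c(1, 1)]), "duplicated")
  nets_bad <- c(nets[1:2], list(canonical_network("d2", "disease", "NOPE")))
  write_canonical_library(canonical_library(nets_bad), f)
  expect_error(suppressMessages(read_canonical_library(f, g)),
               "not in\\s+knowledge graph|not in knowledge graph")
})

test_that("a tenth-scale generated library loads without error", {
  cfg <- generator_config(n_molecules = 400, n_relations = 3000,
                          n_pathways = 43, n_diseases = 88, n_events = 21,
                          canonical_size_range = c(10, 30), seed = 5)
  g <- generate_knowledgebase(cfg)
  lib <- generate_canonical_library(g, cfg)
  f <- tempfile(fileext = ".json")
  write_canonical_library(lib, f)
  lib2 <- suppressMessages(read_canonical_library(f, g))
  expect_equal(unname(library_categories(lib2)), c(43L, 88L, 21L))
})
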