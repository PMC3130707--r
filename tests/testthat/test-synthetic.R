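small_cfg <- function(...) {
  generator_config(n_molecules = 300, n_relations = 2400,
                   n_pathways = 6, n_diseases = 6, n_events = 3,
                   canonical_size_range = c(20, 40), n_mirnas = 4,
                   targets_per_mirna_range = c(60, 120), ...)
}

test_that("identical configs give identical datasets and files", {
  cfg <- small_cfg(seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$graph$relations, d2$graph$relations)
  expect_identical(d1$predictions, d2$predictions)
  expect_identical(d1$idmap, d2$idmap)
  expect_identical(d1$ledger, d2$ledger)

  dir1 <- tempfile(); dir2 <- tempfile()
  generate_dataset(cfg, dir1); generate_dataset(cfg, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- generate_dataset(small_cfg(seed = 8))
  expect_false(identical(d1$predictions, d3$predictions))
})

test_that("generated knowledgebase honours the configured sizes", {
  cfg <- small_cfg(seed = 3)
  g <- generate_knowledgebase(cfg)
  expect_equal(g$n_molecules, 300)
  expect_equal(g$n_relations, 2400)
  expect_error(generator_config(n_molecules = 10, n_relations = 100,
                                canonical_size_range = c(2, 5)),
               "infeasible")
})

test_that("relation kinds follow the mixture within multinomial bounds", {
  cfg <- small_cfg(seed = 5)
  g <- generate_knowledgebase(cfg)
  n <- g$n_relations
  p <- cfg$relation_kind_mixture
  obs <- table(factor(g$relations$kind, levels = RELATION_KINDS))
  for (k in RELATION_KINDS) {
    sigma <- sqrt(n * p[[k]] * (1 - p[[k]]))
    expect_lt(abs(obs[[k]] - n * p[[k]]), 3 * sigma)
  }
})

test_that("the degree distribution is heavy-tailed", {
  exceeds <- vapply(1:20, function(s) {
    cfg <- generator_config(n_molecules = 500, n_relations = 4000, seed = s)
    g <- generate_knowledgebase(cfg)
    deg <- table(c(g$relations$source, g$relations$target))
    max(deg) > 5 * mean(deg)
  }, logical(1))
  expect_true(all(exceeds))
})

test_that("canonical libraries match config counts, sizes and closure", {
  cfg <- small_cfg(seed = 9)
  g <- generate_knowledgebase(cfg)
  lib <- generate_canonical_library(g, cfg)
  expect_equal(unname(library_categories(lib)), c(6L, 6L, 3L))
  sizes <- vapply(lib$networks, `[[`, numeric(1), "n_molecules")
  expect_true(mean(sizes) >= cfg$canonical_size_range[1] &&
                mean(sizes) <= cfg$canonical_size_range[2])
  for (cn in lib$networks) {
    expect_true(all(cn$molecules %in% g$molecules$id))
    expect_true(all(cn$relations$source %in% cn$molecules))
    expect_true(all(cn$relations$target %in% cn$molecules))
    expect_true(all(cn$relation_keys %in% g$relations$key))
  }
})

test_that("the ledger reconciles with a direct recount of emitted rows", {
  cfg <- small_cfg(seed = 13, rho = 0.4, unmapped_fraction = 0.15)
  d <- generate_dataset(cfg)
  pred <- d$predictions
  mapped_sources <- d$idmap$source_id
  for (row in d$ledger$mirnas) {
    mine <- pred[pred$mirna == row$mirna, ]
    expect_equal(nrow(mine), row$n_rows)
    expect_equal(sum(mine$mitg_score >= 20), row$n_filtered20)
    expect_equal(sum(mine$mitg_score >= 20 & mine$gene %in% mapped_sources),
                 row$n_mapped20)
  }
})

test_that("rho = 1 with full mapping plants every usable target", {
  cfg <- small_cfg(seed = 17, rho = 1, unmapped_fraction = 0,
                   planted_network = "pathway_002")
  d <- generate_dataset(cfg)
  planted <- d$library$networks$pathway_002
  gene_of <- setNames(d$graph$molecules$gene_id, d$graph$molecules$id)
  member_genes <- gene_of[planted$molecules]
  sets <- suppressMessages(build_target_sets(d$predictions, d$idmap))
  for (ts in sets) {
    expect_true(all(ts$genes %in% member_genes))
  }
})

test_that("rho = 0 leaves the planted overlap indistinguishable from a control", {
  o_planted <- numeric(0); o_control <- numeric(0)
  for (s in 1:50) {
    cfg <- generator_config(n_molecules = 250, n_relations = 1800,
                            n_pathways = 6, n_diseases = 2, n_events = 2,
                            canonical_size_range = c(30, 30), n_mirnas = 1,
                            targets_per_mirna_range = c(60, 60),
                            rho = 0, planted_network = "pathway_001",
                            seed = 3000 + s)
    d <- generate_dataset(cfg)
    res <- suppressMessages(run_target_network_analysis(
      d$graph, d$library, d$predictions, d$idmap))
    r <- res$results[res$results$category == "pathway", ]
    # control pathway generated identically, never planted
    o_planted <- c(o_planted, r$O[r$canonical_name == "pathway_001"])
    o_control <- c(o_control, r$O[r$canonical_name == "pathway_002"])
  }
  p <- stats::wilcox.test(o_planted, o_control, exact = FALSE)$p.value
  expect_gt(p, 0.01)
})
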