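test_that("hypergeometric tail matches closed forms and handles O = 0", {
  expect_equal(hypergeom_tail(0, 6, 10, 20), 1) # whole sample space
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / 252) # choose(5,5)/choose(10,5)
  expect_equal(hypergeom_tail(5, 6, 10, 20), hyper_tail_sum(5, 6, 10, 20),
               tolerance = 1e-12)
})

test_that("hypergeometric tail agrees with literal draw enumeration", {
  cases <- list(c(2, 3, 4, 8), c(3, 5, 5, 10), c(1, 4, 6, 12),
                c(4, 4, 4, 9), c(0, 3, 3, 7), c(2, 6, 3, 11))
  for (x in cases) {
    expect_equal(hypergeom_tail(x[1], x[2], x[3], x[4]),
                 hyper_tail_enum(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
  }
})

test_that("the tail probability decreases as the overlap grows", {
  p <- hypergeom_tail(0:10, 10, 15, 40)
  expect_true(all(diff(p) < 0))
  expect_error(hypergeom_tail(6, 5, 10, 20), "bounds")
  expect_error(hypergeom_tail(2, 5, 30, 20), "bounds")
})

test_that("log-space evaluation survives large universes without underflow", {
  lp <- hypergeom_tail(900, 1000, 5000, 120000, log.p = TRUE)
  expect_true(is.finite(lp))
  expect_true(lp < log(1e-320)) # far below double range, still finite in logs
  expect_equal(pmin(1022, -lp / log(2)), 1022)
})

test_that("the score transform reproduces printed anchor values", {
  expect_equal(round_half_up(score_transform(2.69e-179)), 593)
  expect_equal(score_transform(1), 0)
  expect_equal(score_transform(2.23e-308), -log2(2.23e-308))
  expect_equal(round_half_up(score_transform(2.23e-308)), 1022)
  expect_error(score_transform(0), "p-values")
  expect_error(score_transform(-1e-5), "p-values")
  expect_error(score_transform(1.5), "p-values")
})

test_that("the score ceiling of 1022 is attained exactly at the floor", {
  expect_identical(score_transform(P_FLOOR), 1022)
  expect_identical(score_transform(P_FLOOR / 4), 1022) # subnormal p
  expect_lt(score_transform(P_FLOOR * 2), 1022)
})

test_that("half-up rounding rounds .5 upward", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.4, 2.6)), c(1, 2, 2, 3))
})

test_that("overlap counting distinguishes molecule and relation modes", {
  g <- knowledge_graph(
    data.frame(id = c("A", "B", "C", "D")),
    data.frame(source = "A", target = "B", kind = "direct_activation")
  )
  net <- neighboring_search(g, c("A", "B", "C"), mode = "connector")
  dis <- canonical_network("d", "disease", c("B", "C", "D"))
  expect_equal(count_overlap(net, dis, "mol"), c(O = 2, V = 3, C = 3))

  # identical extracted and canonical pathway: O = V = C
  pw <- canonical_network("p", "pathway", c("A", "B"),
                          data.frame(source = "A",
                                     kind = "direct_activation",
                                     target = "B"))
  net2 <- neighboring_search(g, c("A", "B"), mode = "connector")
  ovc <- count_overlap(net2, pw, "molrel")
  expect_equal(unname(ovc[["O"]]), unname(ovc[["V"]]))
  expect_equal(unname(ovc[["V"]]), unname(ovc[["C"]]))
})

test_that("overlap equals a brute-force intersection on random instances", {
  g <- random_graph(30, 80, seed = 13)
  set.seed(13)
  seeds <- sample(g$molecules$id, 8)
  net <- neighboring_search(g, seeds, mode = "full")
  members <- sample(g$molecules$id, 12)
  in_net <- g$relations$source %in% members & g$relations$target %in% members
  cn <- canonical_network("p", "pathway", members,
                          g$relations[in_net, c("source", "kind", "target")])
  ovc <- count_overlap(net, cn, "molrel")
  expect_equal(unname(ovc[["O"]]),
               sum(net$nodes %in% members) +
                 sum(net$edges$key %in% cn$relation_keys))
  expect_equal(unname(count_overlap(net, cn, "mol")[["O"]]),
               length(intersect(net$nodes, members)))
})

test_that("ranking uses the category-specific universe and finds dominance", {
  g <- random_graph(40, 120, seed = 17)
  set.seed(17)
  seeds <- sample(g$molecules$id, 6)
  net <- neighboring_search(g, seeds, mode = "connector", mirna = "m")
  in_net <- g$relations$source %in% net$nodes & g$relations$target %in% net$nodes
  dominant <- canonical_network("contains_all", "pathway", net$nodes,
                                g$relations[in_net,
                                            c("source", "kind", "target")])
  others <- lapply(1:3, function(i) {
    set.seed(100 + i)
    canonical_network(paste0("p", i), "pathway", sample(g$molecules$id, 10))
  })
  dis <- canonical_network("d1", "disease", sample(g$molecules$id, 10))
  lib <- canonical_library(c(list(dominant), others, list(dis)))
  res <- rank_canonicals(net, lib, g)
  expect_equal(res$canonical_name[res$category == "pathway" & res$rank == 1],
               "contains_all")
  # universe differs by category
  expect_true(all(res$T[res$category == "pathway"] ==
                    g$n_molecules + g$n_relations))
  expect_true(all(res$T[res$category == "disease"] == g$n_molecules))
  # reported p never leaves (0, 1] and score matches it
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$score, -log2(res$p_value), tolerance = 1e-9)
})

test_that("exact ties rank lexicographically and are flagged", {
  g <- knowledge_graph(data.frame(id = LETTERS[1:6]),
                       data.frame(source = "A", target = "B",
                                  kind = "direct_activation"))
  net <- neighboring_search(g, c("A", "B"), mode = "connector", mirna = "m")
  lib <- canonical_library(list(
    canonical_network("zeta", "disease", c("A", "C")),
    canonical_network("alpha", "disease", c("B", "D"))
  ))
  expect_message(res <- rank_canonicals(net, lib, g), "tie")
  expect_equal(res$canonical_name[res$rank == 1], "alpha")
  expect_equal(res$p_value[1], res$p_value[2])
})
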