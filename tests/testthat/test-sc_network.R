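test_that("type profiles are column means per annotated type", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 2,
                dimnames = list(c("G1", "G2"), paste0("c", 1:4)))
  ann <- data.frame(cell = paste0("c", 1:4),
                    cell_type = c("A", "A", "B", "B"))
  prof <- type_profiles(mat, ann)
  expect_equal(prof$means["G1", "A"], mean(c(1, 3)))
  expect_equal(prof$means["G2", "B"], mean(c(6, 8)))
  expect_equal(unname(prof$n_cells), c(2L, 2L))
  expect_error(type_profiles(mat, ann[1:3, ]), "unannotated")
})

test_that("constant genes are never called high", {
  set.seed(1)
  mat <- rbind(FLAT = rep(5, 60), VAR = rnbinom(60, mu = 2, size = 2))
  colnames(mat) <- paste0("c", 1:60)
  ann <- data.frame(cell = colnames(mat),
                    cell_type = rep(c("A", "B", "C"), each = 20))
  for (scope in c("pooled", "pooled_all", "per_type")) {
    calls <- call_high(mat, ann, k = 3, scope = scope)
    expect_false(any(calls$calls[, "FLAT"]))
  }
})

test_that("high calls are invariant under global rescaling", {
  set.seed(2)
  mat <- matrix(rnbinom(300, mu = 3, size = 2), nrow = 5,
                dimnames = list(paste0("G", 1:5), paste0("c", 1:60)))
  mat[1, 41:60] <- mat[1, 41:60] + 60
  ann <- data.frame(cell = colnames(mat),
                    cell_type = rep(c("A", "B", "C"), each = 20))
  base <- call_high(mat, ann, k = 3)
  scaled <- call_high(mat * 17.3, ann, k = 3)
  expect_identical(base$calls, scaled$calls)
})

test_that("lowering k never removes a call", {
  set.seed(3)
  for (rep in 1:5) {
    mat <- matrix(rnbinom(400, mu = 2, size = 1), nrow = 8,
                  dimnames = list(paste0("G", 1:8), paste0("c", 1:50)))
    mat[1:2, 1:10] <- mat[1:2, 1:10] + 30
    ann <- data.frame(cell = colnames(mat),
                      cell_type = rep(c("A", "B", "C", "D", "E"), each = 10))
    c3 <- call_high(mat, ann, k = 3)$calls
    c2 <- call_high(mat, ann, k = 2)$calls
    c1 <- call_high(mat, ann, k = 1)$calls
    expect_true(all(c2[c3]))
    expect_true(all(c1[c2]))
  }
})

test_that("the per-type-statistic variant can never fire at k = 3 with 7 types", {
  # largest standardized deviation among T values is (T-1)/sqrt(T)
  expect_lt(6 / sqrt(7), 3)
  set.seed(4)
  for (rep in 1:10) {
    mat <- matrix(rlnorm(7 * 40 * 12, meanlog = sample(0:4, 1)), nrow = 12,
                  dimnames = list(paste0("G", 1:12), paste0("c", 1:280)))
    ann <- data.frame(cell = colnames(mat),
                      cell_type = rep(paste0("T", 1:7), each = 40))
    calls <- call_high(mat, ann, k = 3, scope = "per_type")
    expect_equal(sum(calls$calls), 0L)
    # empirical check of the analytic bound on the standardized deviations
    prof <- type_profiles(mat, ann)
    z <- apply(prof$means, 1, function(v) max((v - mean(v)) / sd(v)))
    expect_true(all(z <= 6 / sqrt(7) + 1e-12))
  }
})

test_that("a self-including pooled reference stays silent on a balanced
           planted design while the default recovers it", {
  edges <- data.frame(sender = "T1", receiver = "T2",
                      ligand = "LG001", receptor = "RC001", elevation = 20)
  spec <- single_cell_spec(setNames(rep(200, 7), paste0("T", 1:7)),
                           c("LG001", "RC001", "G3", "G4"),
                           mu = 1, size = 2, planted_edges = edges, seed = 51)
  sim <- simulate_single_cells(spec)
  silent <- call_high(sim$counts, sim$annotations, k = 3, scope = "pooled_all")
  expect_equal(sum(silent$calls), 0L)
  active <- call_high(sim$counts, sim$annotations, k = 3)
  expect_true(active$calls["T1", "LG001"])
  expect_true(active$calls["T2", "RC001"])
  expect_equal(sum(active$calls), 2L)
})

test_that("network construction emits one directed edge per high L/R type pair", {
  db <- db_from_pairs(c("L1", "L2"), c("R1", "R2"))
  calls <- matrix(FALSE, nrow = 3, ncol = 4,
                  dimnames = list(c("A", "B", "C"), c("L1", "R1", "L2", "R2")))
  expect_equal(nrow(build_network(manual_calls(calls), db)), 0L)
  calls["A", "L1"] <- TRUE
  calls["B", "R1"] <- TRUE
  edges <- build_network(manual_calls(calls), db)
  expect_equal(edges, data.frame(sender = "A", receiver = "B",
                                 ligand = "L1", receptor = "R1"))
  # autocrine: same type on both sides
  calls["A", "R1"] <- TRUE
  edges2 <- build_network(manual_calls(calls), db)
  expect_true(any(edges2$sender == "A" & edges2$receiver == "A"))
  expect_equal(nrow(edges2), 2L)
})

test_that("edge counts form a sender x receiver integer matrix", {
  edges <- data.frame(sender = c("A", "A", "A", "B"),
                      receiver = c("B", "B", "B", "A"),
                      ligand = "L", receptor = "R")
  m <- edge_counts(edges)
  expect_equal(m["A", "B"], 3L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(sum(m), nrow(edges))
  empty <- edge_counts(edges[0, ], types = c("A", "B"))
  expect_true(all(empty == 0L))
})

test_that("exclusiveness scores match their closed forms", {
  means <- matrix(1, nrow = 2, ncol = 7,
                  dimnames = list(c("UNIF", "SOLO"), paste0("T", 1:7)))
  means["SOLO", ] <- c(5, 0, 0, 0, 0, 0, 0)
  prof <- structure(list(means = means, n_cells = rep(10L, 7)),
                    class = "cell_type_profiles")
  for (t in paste0("T", 1:7)) expect_equal(exclusiveness(prof, t, "UNIF"), 1)
  expect_equal(exclusiveness(prof, "T1", "SOLO"), 7)
  expect_equal(exclusiveness(prof, "T2", "SOLO"), 0)
  means["SOLO", ] <- 0
  prof$means <- means
  expect_warning(sc <- exclusiveness(prof, "T1", "SOLO"), "zero mean")
  expect_true(is.na(sc))
})

test_that("edge ranking keeps the top fraction by geometric-mean score", {
  means <- matrix(1, nrow = 4, ncol = 4,
                  dimnames = list(c("L1", "R1", "L2", "R2"),
                                  c("A", "B", "C", "D")))
  means["L1", "A"] <- 49; means["L1", c("B", "C", "D")] <- 1
  means["R1", "B"] <- 49; means["R1", c("A", "C", "D")] <- 1
  prof <- structure(list(means = means, n_cells = rep(10L, 4)),
                    class = "cell_type_profiles")
  edges <- data.frame(sender = c("A", "C"), receiver = c("B", "D"),
                      ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  top <- rank_edges(edges, prof, top_fraction = 0.5)
  expect_equal(nrow(top), 1L)
  expect_equal(top$ligand, "L1")
  # a single edge is always kept: ceiling(0.02 * 1) = 1
  single <- rank_edges(edges[1, ], prof, top_fraction = 0.02)
  expect_equal(nrow(single), 1L)

  # 100 edges with constructed scores: agree with a brute-force sort
  set.seed(6)
  g <- sprintf("GG%02d", 1:100)
  means_big <- matrix(rlnorm(200), nrow = 100, ncol = 2,
                      dimnames = list(g, c("A", "B")))
  prof_big <- structure(list(means = means_big, n_cells = c(10L, 10L)),
                        class = "cell_type_profiles")
  edges_big <- data.frame(sender = "A", receiver = "B",
                          ligand = g, receptor = rev(g))
  top2 <- rank_edges(edges_big, prof_big, top_fraction = 0.02)
  score <- sqrt(
    (means_big[edges_big$ligand, "A"] / rowMeans(means_big)[edges_big$ligand]) *
    (means_big[edges_big$receptor, "B"] / rowMeans(means_big)[edges_big$receptor]))
  expect_equal(nrow(top2), 2L)
  expect_setequal(top2$ligand, edges_big$ligand[order(-score)][1:2])
})

test_that("focal-type filtering keeps autocrine edges and drops the rest", {
  edges <- data.frame(sender = c("A", "B", "C", "C"),
                      receiver = c("B", "C", "C", "A"),
                      ligand = "L", receptor = "R")
  kept <- filter_involving(edges, "C")
  expect_equal(nrow(kept), 3L)
  expect_true(any(kept$sender == "C" & kept$receiver == "C"))
  expect_equal(nrow(filter_involving(edges, "ZZ")), 0L)
})

test_that("GraphML export round-trips through igraph", {
  edges <- data.frame(sender = c("A", "B"), receiver = c("B", "B"),
                      ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                      score = c(2.0, 1.0))
  path <- tempfile(fileext = ".graphml")
  export_graphml(edges, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::edge_attr(g, "ligand"), c("L1", "L2"))
})

test_that("planted edges are recovered exactly from simulated cells", {
  planted <- data.frame(
    sender = c("Mel", "CAF", "Endo", "Tcell", "Mel"),
    receiver = c("CAF", "Mel", "Mel", "Mel", "Mel"),
    ligand = c("ANGPT1", "CCL21", "L1CAM", "NCAM1", "MDK"),
    receptor = c("TEK", "CCBP2", "CNTN1", "GFRA1", "GPC2"),
    elevation = 20)
  db <- demo_db()
  genes <- unique(c(db$pairs$ligand, db$pairs$receptor))
  types <- setNames(rep(200, 7),
                    c("Mel", "CAF", "Endo", "Tcell", "Bcell", "Macro", "NK"))
  sim <- simulate_single_cells(single_cell_spec(types, genes, mu = 1, size = 2,
                                                planted_edges = planted,
                                                seed = 61))
  calls <- call_high(sim$counts, sim$annotations, k = 3)
  edges <- build_network(calls, db)
  key <- function(d) paste(d$sender, d$receiver, d$ligand, d$receptor)
  expect_setequal(key(edges), key(planted))
  m <- edge_counts(edges, types = names(types))
  expect_equal(sum(m), 5L)
  expect_equal(m["Mel", "CAF"], 1L)
})
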