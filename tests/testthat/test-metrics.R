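test_that("Jaccard similarity on edge sets behaves as a similarity", {
  a <- cascade_from_dag("A", data.frame(src = c("A", "A", "B"),
                                        tgt = c("B", "C", "D")))
  expect_equal(jaccard_similarity(a, a), 1)
  b <- cascade_from_dag("X", data.frame(src = "X", tgt = "Y"))
  expect_equal(jaccard_similarity(a, b), 0)
  # {e1,e2,e3} vs {e2,e3,e4} -> 2/4
  c1 <- cascade_from_dag("A", data.frame(src = c("A", "A", "B"),
                                         tgt = c("B", "C", "D")))
  c2 <- cascade_from_dag("A", data.frame(src = c("A", "B", "C"),
                                         tgt = c("C", "D", "E")))
  expect_equal(jaccard_similarity(c1, c2), 0.5)
  expect_equal(jaccard_similarity(c2, c1), 0.5)   # symmetric
  e0 <- cascade_from_dag("A", data.frame(src = character(0),
                                         tgt = character(0)))
  expect_error(jaccard_similarity(e0, e0), "empty")
})

test_that("cascade dendrogram merges by similarity with chosen linkage", {
  a <- cascade_from_dag("u", data.frame(src = c("u", "u"),
                                        tgt = c("x", "y")))
  b <- cascade_from_dag("v", data.frame(src = c("v", "u"),
                                        tgt = c("x", "x")))   # shares u->x
  d <- cascade_from_dag("w", data.frame(src = "w", tgt = "z"))
  a2 <- cascade_from_dag("t", a$dag)                           # identical
  dend <- cascade_dendrogram(cascade_collection(a, a2, d))
  # the identical pair merges first at height 0
  expect_equal(dend$hclust$height[1], 0)
  first <- dend$hclust$merge[1, ]
  expect_setequal(dend$hclust$labels[-first], c("u", "t"))

  # hand agglomeration for three distinct cascades, average linkage:
  # J(a,b) = 1/3, J(a,d) = 0, J(b,d) = 0 -> a,b merge at 2/3, then d at 1
  dend2 <- cascade_dendrogram(cascade_collection(a, b, d), "average")
  expect_equal(dend2$hclust$height, c(2 / 3, 1), tolerance = 1e-12)
  expect_error(cascade_dendrogram(cascade_collection(a, b), "ward"))

  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend2, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, c("u", "v", "w"))
})

test_that("source distance and influence match BFS / reachability oracles", {
  chain <- cascade_from_dag("A", data.frame(src = c("A", "B", "C"),
                                            tgt = c("B", "C", "D")))
  expect_equal(unname(source_distance(chain)[c("A", "B", "C", "D")]),
               0:3)
  expect_equal(unname(influence(chain)[c("A", "B", "C", "D")]),
               c(4, 3, 2, 1))

  diamond <- cascade_from_dag("A", data.frame(src = c("A", "A", "B", "C"),
                                              tgt = c("B", "C", "D", "D")))
  expect_equal(source_distance(diamond)[["D"]], 2)
  expect_equal(influence(diamond)[["D"]], 1)   # terminal reaches only itself

  for (seed in 1:8) {
    cas <- rand_dag_cascade(9, 0.4, seed = 700 + seed)
    g <- igraph::graph_from_data_frame(
      cas$dag, vertices = unique(c(cas$sources, cas$dag$src, cas$dag$tgt)))
    bfs <- igraph::distances(g, v = cas$sources, mode = "out", weights = NA)
    sd_pkg <- source_distance(cas)
    for (v in colnames(bfs))
      expect_equal(sd_pkg[[v]],
                   if (is.finite(bfs[1, v])) as.integer(bfs[1, v])
                   else NA_integer_)
    reach <- igraph::distances(g, mode = "out", weights = NA)
    inf_pkg <- influence(cas)
    for (v in rownames(reach))
      expect_equal(inf_pkg[[v]], sum(is.finite(reach[v, ])))
  }
})

test_that("path classification partitions paths and matches enumeration", {
  cls_all <- function(x, cl) stats::setNames(rep(cl, length(x)), x)
  chain <- cascade_from_dag("A", data.frame(src = c("A", "B"),
                                            tgt = c("B", "C")))
  res <- classify_paths(chain, cls_all(c("A", "B", "C"), "cortical"))
  expect_equal(res$C, 1); expect_equal(res$total, 1)

  cs <- cascade_from_dag("A", data.frame(src = "A", tgt = "B"))
  res <- classify_paths(cs, c(A = "cortical", B = "subcortical"))
  expect_equal(res$CS, 1)

  csc <- cascade_from_dag("A", data.frame(src = c("A", "B"),
                                          tgt = c("B", "C")))
  res <- classify_paths(csc, c(A = "cortical", B = "subcortical",
                               C = "cortical"))
  expect_equal(res$CSC_plus, 1)

  expect_error(classify_paths(chain, c(A = "cortical", B = "cortical")),
               "unclassified")

  for (seed in 1:10) {
    cas <- rand_dag_cascade(9, 0.45, seed = 900 + seed)
    withr::with_seed(seed, {
      cl <- stats::setNames(sample(c("cortical", "subcortical"),
                                   length(cas$nodes), replace = TRUE),
                            cas$nodes)
    })
    cl[cas$sources] <- "cortical"
    got <- classify_paths(cas, cl)
    want <- oracle_classify(cas, cl)
    expect_equal(got[c("C", "CS", "CSC_plus", "residual", "total")],
                 want, info = paste("seed", seed))
    expect_equal(got$C + got$CS + got$CSC_plus + got$residual, got$total)
  }
})

test_that("volume fraction is a plain weighted share", {
  con <- rand_connectome(10, 0.3, seed = 5)
  con$nodes$volume_mm3 <- seq(1, 10)
  expect_equal(volume_fraction(con$nodes$acronym, con), 1)
  expect_equal(volume_fraction(c("N01", "N03"), con), (1 + 3) / 55)
  expect_error(volume_fraction("ZZZ", con), "not in connectome")
  # equal volumes: fraction = count share
  con$nodes$volume_mm3 <- 2
  expect_equal(volume_fraction(con$nodes$acronym[1:4], con), 4 / 10)
})
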