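test_that("kNN graph on collinear points is the path graph", {
  X <- rbind(x = c(0, 1, 2), y = c(0, 0, 0))
  colnames(X) <- c("a", "b", "c")
  adj <- embedAndKnn(X, nNeighbors = 2)
  expect_true(adj["a", "b"] && adj["b", "c"])
  expect_false(adj["a", "c"])
  expect_identical(adj, t(adj))
  # embedding on all components preserves distances
  set.seed(41)
  M <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("i", 1:5)))
  emb <- prcomp(t(M))$x
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(t(M))),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(embedAndKnn(matrix(0, 3, 4,
                                  dimnames = list(NULL, letters[1:4]))),
               "degenerate")
})

test_that("partition connectivity is observed-over-expected, clipped", {
  ids <- paste0("i", 1:9)
  labels <- setNames(rep(c("A", "B", "C"), each = 3), ids)
  adj <- matrix(FALSE, 9, 9, dimnames = list(ids, ids))
  link <- function(a, b) adj[a, b] <<- adj[b, a] <<- TRUE
  link("i1", "i4"); link("i2", "i5")      # A-B twice
  link("i6", "i7")                        # B-C once
  pg <- partitionConnectivity(adj, labels)
  w <- confidence(pg)
  # E = 3 inter edges over 3 equal-size pairs: expected 1 each
  expect_equal(w["A", "B"], 1)            # 2/1 clipped at 1
  expect_equal(w["B", "C"], 1)            # 1/1
  expect_equal(w["A", "C"], 0)            # no edge -> 0
  expect_equal(unname(diag(w)), rep(0, 3))
  expect_error(partitionConnectivity(adj, labels, nodes = c("A", "B", "C",
                                                            "D")),
               "empty")
  # fully separated blobs: all cross-confidences zero
  adj0 <- matrix(FALSE, 9, 9, dimnames = list(ids, ids))
  adj0[1:3, 1:3] <- adj0[4:6, 4:6] <- adj0[7:9, 7:9] <- TRUE
  diag(adj0) <- FALSE
  expect_true(all(confidence(partitionConnectivity(adj0, labels)) == 0))
})

test_that("pruning removes everything at or below twice the NCI-AD ceiling", {
  nodes <- c("NCI_Typical", "MCI_Typical", "AD_HH")
  stageMap <- setNames(c("NCI", "MCI", "AD"), nodes)
  w <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2   # md_na
  pg <- PartitionGraph(nodes, w)
  pr <- pruneGraph(pg, stageMap)
  expect_equal(attr(pr, "mdNA"), 0.2)
  e <- graphEdges(pr)
  expect_equal(nrow(e), 2)
  expect_false(any(e$from == "NCI_Typical" & e$to == "AD_HH"))
  # all-equal confidences prune to nothing
  weq <- matrix(0.4, 3, 3); diag(weq) <- 0
  dimnames(weq) <- list(nodes, nodes)
  expect_equal(nrow(graphEdges(pruneGraph(PartitionGraph(nodes, weq),
                                          stageMap))), 0)
  # random graphs never keep a direct NCI-AD edge when md_na > 0
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(0, 3, 3); m[upper.tri(m)] <- runif(3)
    m <- m + t(m); dimnames(m) <- list(nodes, nodes)
    pr2 <- pruneGraph(PartitionGraph(nodes, m), stageMap)
    if (attr(pr2, "mdNA") > 0)
      expect_equal(confidence(pr2)["NCI_Typical", "AD_HH"], 0)
  }
})

test_that("graph intersection is commutative, idempotent and minimal", {
  nodes <- letters[1:4]
  mk <- function(...) {
    w <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    for (e in list(...)) w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
    PartitionGraph(nodes, w)
  }
  A <- mk(list("a", "b", 0.8), list("b", "c", 0.6), list("c", "d", 0.4))
  B <- mk(list("a", "b", 0.5), list("c", "d", 0.9), list("a", "d", 0.7))
  AB <- intersectGraphs(A, B)
  e <- graphEdges(AB)
  expect_equal(nrow(e), 2)
  expect_equal(confidence(AB)["a", "b"], 0.5)  # min of the two
  expect_equal(confidence(AB)["c", "d"], 0.4)
  expect_equal(confidence(intersectGraphs(B, A)), confidence(AB))
  expect_equal(confidence(intersectGraphs(A, A)), confidence(A))
  expect_equal(nrow(graphEdges(intersectGraphs(
    mk(list("a", "b", 1)), mk(list("c", "d", 1))))), 0)
  expect_error(intersectGraphs(A, PartitionGraph("x", matrix(0, 1, 1))),
               "node sets")
})

test_that("orientation follows the clinical stage order", {
  nodes <- c("NCI_MCI", "MCI_NCI", "AD_HH", "AD_HH_MCI")
  stageMap <- setNames(c("NCI", "MCI", "AD", "AD"), nodes)
  w <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  w["NCI_MCI", "MCI_NCI"] <- w["MCI_NCI", "NCI_MCI"] <- 0.9
  w["AD_HH", "AD_HH_MCI"] <- w["AD_HH_MCI", "AD_HH"] <- 0.8
  w["MCI_NCI", "AD_HH"] <- w["AD_HH", "MCI_NCI"] <- 0.7
  pg <- PartitionGraph(nodes, w)
  e <- orientGraph(pg, stageMap)
  cross <- e[e$from == "NCI_MCI", ]
  expect_equal(cross$to, "MCI_NCI")   # NCI -> MCI
  expect_true(cross$directed)
  same <- e[e$from %in% c("AD_HH", "AD_HH_MCI") &
            e$to %in% c("AD_HH", "AD_HH_MCI"), ]
  expect_false(same$directed)
  expect_equal(orientGraph(pg, stageMap), orientGraph(pg, stageMap))
})

test_that("planted chains put higher confidence on adjacent substages", {
  ch <- simulateChainCohort(seed = 2)
  adj <- embedAndKnn(ch$X[ch$setA, ], nNeighbors = 2)
  pg <- partitionConnectivity(adj, ch$labels)
  w <- confidence(pg)[rownames(ch$chain), colnames(ch$chain)]
  expect_gt(mean(w[ch$chain > 0]), mean(w[ch$chain == 0 &
                                          upper.tri(ch$chain)]))
})
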