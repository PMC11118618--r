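fake_results2 <- function(records) {
  # records: list of c(phenotype, domain, metabolite, subpathway, superpathway)
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(phenotype = r[1], domain = r[2], metabolite = r[3],
               subpathway = r[4], superpathway = r[5], model = "Model1",
               effect = 0, test_df = 1L, p_raw = 0.001, p_fdr = 0.01,
               significant = TRUE, stringsAsFactors = FALSE)))
  class(df) <- c("association_table", "data.frame")
  df
}

test_that("incidence consolidation sums weights and ORs the binary matrix", {
  res <- fake_results2(list(
    c("p1", "HR", "m1", "subA", "Lipid"),
    c("p2", "HR", "m1", "subA", "Lipid"),      # same domain+subpathway cell
    c("p3", "SDB", "m2", "subB", "Lipid")))
  inc <- build_incidence(res, "domain", "subpathway")
  expect_equal(inc$weights["HR", "subA"], 2L)
  expect_equal(inc$binary["HR", "subA"], 1L)
  expect_equal(sum(inc$weights), 3)            # conservation
  expect_equal(inc$binary, (inc$weights > 0) * 1L)
  # phenotype x metabolite level keeps cells at weight 1
  incp <- build_incidence(res, "phenotype", "metabolite")
  expect_true(all(incp$weights <= 1))
  expect_equal(sum(incp$weights), 3)
  # no significant rows -> empty pruned network
  res0 <- res; res0$significant <- FALSE
  expect_equal(nrow(build_incidence(res0, "domain", "subpathway")$weights), 0)
})

test_that("degree statistics match hand counts", {
  B <- matrix(1, 2, 3)                         # complete bipartite 2x3
  inc <- structure(list(binary = B, weights = B), class = "bipartite_incidence")
  ds <- degree_stats(inc)
  expect_equal(ds$links_per_node, 6 / 5)
  expect_equal(ds$mean_shared_partners_rows, 3)
  expect_equal(ds$mean_shared_partners_cols, 2)
  # perfect matching: no shared partners
  inc2 <- structure(list(binary = diag(3), weights = diag(3)),
                    class = "bipartite_incidence")
  expect_equal(degree_stats(inc2)$mean_shared_partners_rows, 0)
  # single edge
  inc3 <- structure(list(binary = matrix(1, 1, 1), weights = matrix(1, 1, 1)),
                    class = "bipartite_incidence")
  expect_equal(degree_stats(inc3)$links_per_node, 1 / 2)
})

test_that("cluster coefficient is links over possible links", {
  expect_equal(cluster_coefficient(matrix(1, 2, 3)), 1)
  B <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  expect_equal(cluster_coefficient(B), 0.5)
  expect_equal(cluster_coefficient(matrix(0, 2, 2)), 0)
  expect_error(cluster_coefficient(matrix(0, 0, 0)), "empty")
})

test_that("NODF is 100 on a staircase, 0 on a permutation, and permutation-invariant", {
  stair <- matrix(0, 4, 4)
  stair[upper.tri(stair, diag = TRUE)] <- 1    # fills 4,3,2,1 nested
  expect_equal(nestedness_nodf(stair), 100)
  expect_equal(nodf_oracle(stair), 100)
  anti <- diag(4)[4:1, ]
  expect_equal(nestedness_nodf(anti), 0)
  set.seed(5)
  for (i in 1:10) {
    B <- matrix(rbinom(30, 1, 0.5), 5, 6)
    B <- B[rowSums(B) > 0, colSums(B) > 0, drop = FALSE]
    if (nrow(B) < 2 || ncol(B) < 2) next
    v <- nestedness_nodf(B)
    expect_equal(v, nodf_oracle(B), tolerance = 1e-12)
    # invariant under simultaneous row/column shuffles
    pr <- sample(nrow(B)); pc <- sample(ncol(B))
    expect_equal(nestedness_nodf(B[pr, pc]), v, tolerance = 1e-12)
  }
})

test_that("weighted nestedness scores staircases 1, constants 0, scale-free", {
  # staircase support; each sparser row/column strictly dominated cellwise
  W <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (j >= i) W[i, j] <- (5 - i) + j
  expect_equal(weighted_nestedness(W), 1)
  expect_equal(weighted_nestedness(matrix(5, 3, 3)), 0)
  expect_equal(weighted_nestedness(W * 3), weighted_nestedness(W))
  expect_error(weighted_nestedness(matrix(-1, 2, 2)), "nonnegative")
})

test_that("Barber modularity matches hand and brute-force evaluations", {
  # two disconnected 2x2 complete blocks with unit weights
  W <- matrix(0, 4, 4)
  W[1:2, 1:2] <- 1
  W[3:4, 3:4] <- 1
  rownames(W) <- paste0("r", 1:4); colnames(W) <- paste0("c", 1:4)
  mod <- bipartite_modularity(W, n_restarts = 10, seed = 2)
  expect_equal(mod$Q, 0.5, tolerance = 1e-12)
  p <- mod$partition
  expect_equal(p[["R:r1"]], p[["C:c1"]])
  expect_false(p[["R:r1"]] == p[["R:r3"]])
  # complete bipartite uniform: no partition beats the single module (Q=0)
  Wc <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bipartite_modularity(Wc, 10, 3)$Q, 0, tolerance = 1e-12)
  for (labels in all_partitions(4)) {
    expect_lte(barber_Q(Wc, labels), 1e-12)
  }
})

test_that("modularity heuristic matches exhaustive search on small networks", {
  set.seed(77)
  for (case in 1:50) {
    R <- sample(2:4, 1)
    C <- sample(2:min(3, 7 - R), 1)
    W <- matrix(rpois(R * C, 0.8), R, C)
    if (sum(W) == 0) W[sample(R, 1), sample(C, 1)] <- 1
    dimnames(W) <- list(paste0("r", 1:R), paste0("c", 1:C))
    best <- max(vapply(all_partitions(R + C), function(l) barber_Q(W, l), 0))
    got <- bipartite_modularity(W, n_restarts = 25, seed = case)$Q
    expect_equal(got, best, tolerance = 1e-10)
  }
})

test_that("layout is seed-deterministic and separates components", {
  res <- fake_results2(list(
    c("p1", "HR", "m1", "subA", "Lipid"),
    c("p1", "HR", "m2", "subB", "Lipid"),
    c("p2", "SDB", "m3", "subC", "Lipid"),
    c("p2", "SDB", "m4", "subD", "Lipid")))
  inc <- build_incidence(res, "domain", "subpathway")
  l1 <- fr_layout(inc, iterations = 150, seed = 4)
  l2 <- fr_layout(inc, iterations = 150, seed = 4)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))
  # two disconnected components end far apart over several seeds
  comp <- ifelse(l1$node %in% c("R:HR", "C:subA", "C:subB"), 1, 2)
  seps <- vapply(1:10, function(s) {
    l <- fr_layout(inc, iterations = 150, seed = s)
    c1 <- colMeans(l[comp == 1, c("x", "y")])
    c2 <- colMeans(l[comp == 2, c("x", "y")])
    cent_d <- sqrt(sum((c1 - c2)^2))
    rad <- mean(vapply(seq_len(nrow(l)), function(i) {
      cc <- if (comp[i] == 1) c1 else c2
      sqrt(sum((l[i, c("x", "y")] - cc)^2))
    }, 0))
    cent_d > rad
  }, TRUE)
  expect_gte(mean(seps), 0.9)
  # a lone node sits at the origin
  res1 <- fake_results2(list(c("p1", "HR", "m1", "subA", "Lipid")))
  inc1 <- build_incidence(res1, "domain", "subpathway")
  # 1 row + 1 col = 2 nodes; prune to a single-node case manually
  single <- structure(list(binary = matrix(1, 1, 0,
                             dimnames = list("HR", NULL)),
                           weights = matrix(1, 1, 0,
                             dimnames = list("HR", NULL))),
                      class = "bipartite_incidence")
  lay <- fr_layout(single, seed = 1)
  expect_equal(c(lay$x, lay$y), c(0, 0))
})

test_that("metrics are invariant to label permutations", {
  set.seed(9)
  W <- matrix(rpois(20, 1.2), 4, 5,
              dimnames = list(paste0("r", 1:4), paste0("c", 1:5)))
  W <- W[rowSums(W) > 0, colSums(W) > 0, drop = FALSE]
  inc <- structure(list(binary = (W > 0) * 1L, weights = W),
                   class = "bipartite_incidence")
  m1 <- network_metrics(inc, n_restarts = 15, seed = 1)
  pr <- sample(nrow(W)); pc <- sample(ncol(W))
  W2 <- W[pr, pc]
  inc2 <- structure(list(binary = (W2 > 0) * 1L, weights = W2),
                    class = "bipartite_incidence")
  m2 <- network_metrics(inc2, n_restarts = 15, seed = 1)
  for (f in c("links", "links_per_node", "cluster_coefficient", "nodf",
              "weighted_nestedness", "modularity_Q")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-9, label = f)
  }
})
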