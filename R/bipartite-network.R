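#' Build the significance bipartite incidence matrix
#'
#' Links row entities (phenotypes, or domains after consolidation) to column
#' entities (metabolites, or sub/superpathways) through the Model-1
#' significant associations. The weight matrix counts significant
#' (phenotype, metabolite) records per cell; consolidation to coarser levels
#' sums the weights, and the binary matrix is its positivity indicator.
#' All-zero rows and columns are pruned.
#'
#' @param results an `association_table` with significance flags.
#' @param row_level `"phenotype"` or `"domain"`.
#' @param col_level `"metabolite"`, `"subpathway"` or `"superpathway"`.
#' @return An object of class `bipartite_incidence`: list with `binary`,
#'   `weights`, `row_level`, `col_level`.
#' @export
build_incidence <- function(results, row_level = c("domain", "phenotype"),
                            col_level = c("subpathway", "metabolite",
                                          "superpathway")) {
  row_level <- match.arg(row_level)
  col_level <- match.arg(col_level)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    w <- matrix(0L, 0, 0)
    return(structure(list(binary = w, weights = w, row_level = row_level,
                          col_level = col_level),
                     class = "bipartite_incidence"))
  }
  rl <- factor(sig[[row_level]])
  cl <- factor(sig[[col_level]])
  w <- table(rl, cl)
  w <- matrix(as.integer(w), nrow(w), ncol(w),
              dimnames = dimnames(w))
  w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  structure(list(binary = (w > 0) * 1L, weights = w,
                 row_level = row_level, col_level = col_level),
            class = "bipartite_incidence")
}

#' Degree-based summary statistics of a bipartite network
#'
#' @param inc a `bipartite_incidence`.
#' @return List with `links` (realized binary links), `links_per_node`
#'   (links / (rows + cols)), `connected_rows`, `connected_cols`,
#'   `mean_shared_partners_rows` (average over unordered row pairs of the
#'   number of common column neighbors) and `mean_shared_partners_cols`.
#' @export
degree_stats <- function(inc) {
  B <- inc$binary
  if (length(B) == 0) stop("empty network")
  L <- sum(B)
  R <- nrow(B); C <- ncol(B)
  shared <- function(M) {       # mean co-neighbors over unordered row pairs
    if (nrow(M) < 2) return(NA_real_)
    cp <- tcrossprod(M)
    mean(cp[upper.tri(cp)])
  }
  list(links = L, links_per_node = L / (R + C),
       connected_rows = sum(rowSums(B) > 0),
       connected_cols = sum(colSums(B) > 0),
       mean_shared_partners_rows = shared(B),
       mean_shared_partners_cols = shared(t(B)))
}

#' Connectance-style cluster coefficient
#'
#' Number of realized links divided by the number of possible links,
#' `L / (R * C)`.
#'
#' @param inc a `bipartite_incidence` (or a plain binary matrix).
#' @return A number in `[0, 1]`.
#' @export
cluster_coefficient <- function(inc) {
  B <- if (inherits(inc, "bipartite_incidence")) inc$binary else inc
  if (length(B) == 0 || nrow(B) == 0 || ncol(B) == 0)
    stop("cluster coefficient undefined for an empty matrix")
  sum(B > 0) / (nrow(B) * ncol(B))
}

#' NODF nestedness of a binary matrix
#'
#' For every ordered pair of rows whose marginal totals strictly decrease,
#' the paired overlap is the percentage of the sparser row's links also
#' present in the denser row (pairs with equal or increasing totals
#' contribute 0); same over columns. NODF averages all row and column pair
#' contributions. 100 = perfectly nested, 0 = no nested structure. The
#' complementary orientation `100 - NODF` (0 = highly nested) is reported by
#' [network_metrics()] alongside.
#'
#' @param B binary matrix without all-zero rows or columns.
#' @return NODF in `[0, 100]`.
#' @export
nestedness_nodf <- function(B) {
  B <- (as.matrix(B) > 0) * 1
  if (nrow(B) < 2 && ncol(B) < 2)
    stop("nestedness undefined for a degenerate matrix")
  if (any(rowSums(B) == 0) || any(colSums(B) == 0))
    stop("prune all-zero rows/columns before computing nestedness")
  pair_sum <- function(M) {
    f <- rowSums(M)
    n <- nrow(M)
    if (n < 2) return(c(0, 0))
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hi <- if (f[i] >= f[j]) i else j
        lo <- if (f[i] >= f[j]) j else i
        if (f[hi] > f[lo])
          tot <- tot + 100 * sum(M[hi, ] * M[lo, ]) / f[lo]
      }
    }
    c(tot, n * (n - 1) / 2)
  }
  rs <- pair_sum(B)
  cs <- pair_sum(t(B))
  (rs[1] + cs[1]) / (rs[2] + cs[2])
}

#' Weighted nestedness of a nonnegative weight matrix
#'
#' Rank-based weighted analogue of NODF on the `[0, 1]` scale: an ordered
#' pair of rows qualifies when the busier row's marginal total is strictly
#' larger; its contribution is the fraction of the sparser row's nonzero
#' cells whose weights are strictly smaller than the corresponding cells of
#' the busier row. The score is the total contribution divided by its
#' maximum (the number of pairs), so a strictly nested weight staircase
#' scores 1 and a constant positive matrix scores 0. Invariant to scaling
#' all weights by a positive constant.
#'
#' @param W nonnegative weight matrix.
#' @return A number in `[0, 1]`.
#' @export
weighted_nestedness <- function(W) {
  W <- as.matrix(W)
  if (length(W) == 0) stop("empty weight matrix")
  if (any(W < 0)) stop("weights must be nonnegative")
  pair_sum <- function(M) {
    f <- rowSums(M)
    n <- nrow(M)
    if (n < 2) return(c(0, 0))
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hi <- if (f[i] >= f[j]) i else j
        lo <- if (f[i] >= f[j]) j else i
        if (f[hi] > f[lo]) {
          nz <- M[lo, ] > 0
          if (any(nz))
            tot <- tot + sum(M[lo, nz] < M[hi, nz]) / sum(nz)
        }
      }
    }
    c(tot, n * (n - 1) / 2)
  }
  rs <- pair_sum(W)
  cs <- pair_sum(t(W))
  denom <- rs[2] + cs[2]
  if (denom == 0) stop("weighted nestedness undefined for a 1x1 matrix")
  (rs[1] + cs[1]) / denom
}

#' Barber bipartite modularity
#'
#' Maximizes `Q = (1/W) * sum_ij (A_ij - k_i d_j / W) * [g(row i) = g(col j)]`
#' over joint module assignments of rows and columns by a seeded
#' label-switching heuristic: starting from random labels (and once from
#' singletons), nodes are repeatedly moved to the module that most increases
#' Q until no move helps; the best of `n_restarts` runs is returned. The
#' single-module partition has Q = 0 by construction, so the reported Q is
#' never negative.
#'
#' @param W nonnegative weight matrix with positive total.
#' @param n_restarts number of random restarts (default 20).
#' @param seed integer seed for the restarts.
#' @return List with `Q` and `partition` (named module id per node; row
#'   nodes prefixed `R:`, column nodes `C:`).
#' @export
bipartite_modularity <- function(W, n_restarts = 20, seed = 1) {
  W <- as.matrix(W)
  tot <- sum(W)
  if (tot <= 0) stop("total weight must be positive")
  R <- nrow(W); C <- ncol(W)
  k <- rowSums(W); d <- colSums(W)
  B <- W - outer(k, d) / tot            # modularity surplus matrix
  n <- R + C
  set.seed(seed)
  eval_q <- function(gr, gc) {
    q <- 0
    for (g in unique(gr)) {
      jc <- gc == g
      if (any(jc)) q <- q + sum(B[gr == g, jc, drop = FALSE])
    }
    q / tot
  }
  refine <- function(gr, gc) {
    repeat {
      improved <- FALSE
      for (i in seq_len(R)) {
        # gain of putting row i in module g: sum of B[i, cols in g];
        # an empty (fresh) module has gain 0
        gains <- tapply(B[i, ], gc, sum)
        best <- names(gains)[which.max(gains)]
        best_gain <- max(gains)
        if (best_gain < 0) { best <- paste0("solo_r", i); best_gain <- 0 }
        if (!identical(best, gr[i]) &&
            best_gain > sum(B[i, gc == gr[i]]) + 1e-12) {
          gr[i] <- best; improved <- TRUE
        }
      }
      for (j in seq_len(C)) {
        gains <- tapply(B[, j], gr, sum)
        best <- names(gains)[which.max(gains)]
        best_gain <- max(gains)
        if (best_gain < 0) { best <- paste0("solo_c", j); best_gain <- 0 }
        if (!identical(best, gc[j]) &&
            best_gain > sum(B[gr == gc[j], j]) + 1e-12) {
          gc[j] <- best; improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(gr = gr, gc = gc, Q = eval_q(gr, gc))
  }
  best <- NULL
  inits <- c(list(list(gr = paste0("m", seq_len(R)),
                       gc = paste0("m", R + seq_len(C))),
                  list(gr = rep("m1", R), gc = rep("m1", C))),
             lapply(seq_len(max(0, n_restarts - 2)), function(s) {
               lab <- paste0("m", sample(min(n, 6), n, replace = TRUE))
               list(gr = lab[seq_len(R)], gc = lab[R + seq_len(C)])
             }))
  for (init in inits) {
    res <- refine(init$gr, init$gc)
    if (is.null(best) || res$Q > best$Q) best <- res
  }
  part <- c(stats::setNames(best$gr, paste0("R:", rownames(W))),
            stats::setNames(best$gc, paste0("C:", colnames(W))))
  # relabel modules consecutively
  part <- stats::setNames(paste0("m", as.integer(factor(part,
                                                        levels = unique(part)))),
                          names(part))
  list(Q = best$Q, partition = part)
}

#' Fruchterman-Reingold force-directed layout
#'
#' Classic spring-embedder on the bipartite graph's nodes (rows and columns
#' together): repulsion `k^2 / d` between all pairs, attraction `d^2 / k`
#' along binary edges, displacement capped by a linearly cooling
#' temperature. Deterministic given the seed; a single node is placed at the
#' origin.
#'
#' @param inc a `bipartite_incidence`.
#' @param iterations number of cooling steps (default 200).
#' @param seed integer seed for the initial placement.
#' @return data.frame: node, type (`row`/`col`), x, y.
#' @export
fr_layout <- function(inc, iterations = 200, seed = 1) {
  B <- inc$binary
  R <- nrow(B); C <- ncol(B)
  n <- R + C
  if (n == 0) stop("empty network")
  nodes <- c(if (R > 0) paste0("R:", rownames(B)),
             if (C > 0) paste0("C:", colnames(B)))
  type <- c(rep("row", R), rep("col", C))
  if (n == 1)
    return(data.frame(node = nodes, type = type, x = 0, y = 0,
                      stringsAsFactors = FALSE))
  edges <- which(B > 0, arr.ind = TRUE)
  ei <- edges[, 1]; ej <- R + edges[, 2]
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n, -0.5, 0.5), n, 2)
  k <- sqrt(1 / n)
  t0 <- 0.1
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (v in seq_len(n)) {
      delta <- sweep(pos, 2, pos[v, ])     # others minus v
      dist <- sqrt(rowSums(delta^2))
      dist[v] <- Inf
      dist <- pmax(dist, 1e-9)
      rep_f <- k^2 / dist^2                # magnitude/d of k^2/d
      disp[v, ] <- -colSums(delta * rep_f)
    }
    if (length(ei)) {
      dvec <- pos[ej, , drop = FALSE] - pos[ei, , drop = FALSE]
      dist <- pmax(sqrt(rowSums(dvec^2)), 1e-9)
      att <- dist / k                      # (d^2/k)/d
      fa <- dvec * att
      for (e in seq_along(ei)) {
        disp[ei[e], ] <- disp[ei[e], ] + fa[e, ]
        disp[ej[e], ] <- disp[ej[e], ] - fa[e, ]
      }
    }
    temp <- t0 * (1 - it / iterations) + 1e-4
    mag <- pmax(sqrt(rowSums(disp^2)), 1e-9)
    step <- pmin(mag, temp) / mag
    pos <- pos + disp * step
  }
  data.frame(node = nodes, type = type, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}

#' All structural metrics of a bipartite network
#'
#' @param inc a `bipartite_incidence`.
#' @param n_restarts,seed passed to [bipartite_modularity()].
#' @return List: `links`, `links_per_node`, `connected_rows`,
#'   `connected_cols`, `cluster_coefficient`, `nodf` (100 = nested),
#'   `nestedness` (paper orientation, `100 - nodf`, 0 = highly nested),
#'   `weighted_nestedness` (1 = nested), `modularity_Q`,
#'   `mean_shared_partners_rows`, `mean_shared_partners_cols`.
#' @export
network_metrics <- function(inc, n_restarts = 20, seed = 1) {
  ds <- degree_stats(inc)
  nodf <- tryCatch(nestedness_nodf(inc$binary), error = function(e) NA_real_)
  wn <- tryCatch(weighted_nestedness(inc$weights),
                 error = function(e) NA_real_)
  mod <- bipartite_modularity(inc$weights, n_restarts, seed)
  c(ds, list(cluster_coefficient = cluster_coefficient(inc),
             nodf = nodf, nestedness = 100 - nodf,
             weighted_nestedness = wn, modularity_Q = mod$Q))
}

#' Network metrics per superpathway subset
#'
#' Restricts the consolidated domain x subpathway network to the subpathways
#' of each superpathway in turn (plus the full network under `"All"`) and
#' computes [network_metrics()] on each, mirroring a per-superpathway
#' structural breakdown.
#'
#' @param results an `association_table`.
#' @param annotation metabolite annotation table.
#' @param n_restarts,seed passed through.
#' @return Named list of metric lists.
#' @export
network_report <- function(results, annotation, n_restarts = 20, seed = 1) {
  inc <- build_incidence(results, "domain", "subpathway")
  sub2super <- unique(annotation[, c("subpathway", "superpathway")])
  out <- list(All = network_metrics(inc, n_restarts, seed))
  for (sp in sort(unique(sub2super$superpathway))) {
    subs <- sub2super$subpathway[sub2super$superpathway == sp]
    keep <- colnames(inc$weights) %in% subs
    if (!any(keep)) next
    w <- inc$weights[, keep, drop = FALSE]
    w <- w[rowSums(w) > 0, , drop = FALSE]
    if (nrow(w) == 0) next
    sub_inc <- structure(list(binary = (w > 0) * 1L, weights = w,
                              row_level = inc$row_level,
                              col_level = inc$col_level),
                         class = "bipartite_incidence")
    out[[sp]] <- network_metrics(sub_inc, n_restarts, seed)
  }
  out
}

#' Write network artifacts as delimited text
#'
#' Writes `edges.tsv` (row, col, weight), `nodes.tsv` (id, type, degree,
#' module, x, y) and `metrics.json` under `dir`.
#'
#' @param inc a `bipartite_incidence`.
#' @param dir output directory.
#' @param n_restarts,seed,iterations layout/modularity knobs.
#' @return Invisibly, the directory.
#' @export
write_network <- function(inc, dir, n_restarts = 20, seed = 1,
                          iterations = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- inc$weights
  edges <- which(W > 0, arr.ind = TRUE)
  edge_df <- data.frame(row = rownames(W)[edges[, 1]],
                        col = colnames(W)[edges[, 2]],
                        weight = W[edges], stringsAsFactors = FALSE)
  utils::write.table(edge_df, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  lay <- fr_layout(inc, iterations = iterations, seed = seed)
  mod <- bipartite_modularity(W, n_restarts, seed)
  deg <- c(rowSums(inc$binary), colSums(inc$binary))
  nodes <- data.frame(node = lay$node, type = lay$type,
                      degree = as.integer(deg),
                      module = mod$partition[lay$node],
                      x = lay$x, y = lay$y, stringsAsFactors = FALSE)
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(network_metrics(inc, n_restarts, seed),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
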