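#' Per-phenotype counts of significant metabolites
#'
#' Counts, for every phenotype, the metabolites flagged significant
#' (Model 1, FDR < alpha) and the percentage of all tested metabolites,
#' plus median and range of the counts within each domain.
#'
#' @param results an `association_table` from [run_scan()].
#' @return List with `per_phenotype` (phenotype, domain, n_significant,
#'   pct_significant) and `per_domain` (domain, median, min, max of the
#'   per-phenotype counts).
#' @export
count_table <- function(results) {
  n_met <- length(unique(results$metabolite))
  phen <- unique(results[, c("phenotype", "domain")])
  sig <- results[results$significant, , drop = FALSE]
  counts <- vapply(phen$phenotype, function(ph)
    length(unique(sig$metabolite[sig$phenotype == ph])), 0L)
  per_phenotype <- data.frame(
    phenotype = phen$phenotype, domain = phen$domain,
    n_significant = counts,
    pct_significant = if (n_met > 0) 100 * counts / n_met else 0,
    row.names = NULL, stringsAsFactors = FALSE)
  per_domain <- do.call(rbind, lapply(split(per_phenotype,
                                            per_phenotype$domain),
    function(d) data.frame(domain = d$domain[1],
                           median_significant = stats::median(d$n_significant),
                           min_significant = min(d$n_significant),
                           max_significant = max(d$n_significant))))
  rownames(per_domain) <- NULL
  list(per_phenotype = per_phenotype, per_domain = per_domain)
}

#' Top-connected metabolites
#'
#' Ranks metabolites by the number of distinct phenotypes they are
#' significantly associated with (Model 1) and returns the top fraction of
#' the metabolites that have at least one association. Ties are broken
#' lexicographically by metabolite identifier for reproducibility.
#'
#' @param results an `association_table`.
#' @param fraction fraction of connected metabolites to keep, in (0, 1];
#'   default 0.10 (the "top 10%" convention).
#' @return data.frame: metabolite, n_phenotypes, then one count column per
#'   domain present.
#' @export
top_connected <- function(results, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(metabolite = character(), n_phenotypes = integer()))
  pairs <- unique(sig[, c("metabolite", "phenotype", "domain")])
  counts <- tapply(pairs$phenotype, pairs$metabolite,
                   function(x) length(unique(x)))
  ord <- order(-counts, names(counts))
  n_keep <- ceiling(fraction * length(counts))
  top <- names(counts)[ord][seq_len(n_keep)]
  out <- data.frame(metabolite = top,
                    n_phenotypes = as.integer(counts[top]),
                    stringsAsFactors = FALSE)
  for (dm in sort(unique(pairs$domain))) {
    out[[dm]] <- vapply(top, function(m)
      sum(pairs$metabolite == m & pairs$domain == dm), 0L)
  }
  rownames(out) <- NULL
  out
}

#' Dice similarity coefficient of two significance sets
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|)`: 1 when the two sets coincide,
#' 0 when they are disjoint. Undefined (error) when both sets are empty.
#'
#' @param x,y character vectors of metabolite identifiers (duplicates are
#'   collapsed).
#' @return A number in `[0, 1]`.
#' @examples
#' dice(c("a", "b", "c"), c("b", "c", "d", "e", "f"))
#' @export
dice <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 && length(y) == 0)
    stop("Dice coefficient undefined for two empty sets")
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

#' Pairwise Dice similarity matrix
#'
#' Builds the significance set of each phenotype (or each domain, as the
#' union of its phenotypes' sets) and returns the symmetric matrix of
#' pairwise Dice coefficients with unit diagonal. Pairs where both sets are
#' empty get `NA` and a warning rather than an error.
#'
#' @param results an `association_table`.
#' @param level `"domain"` (default) or `"phenotype"`.
#' @return A symmetric numeric matrix with owner labels.
#' @export
dsc_matrix <- function(results, level = c("domain", "phenotype")) {
  level <- match.arg(level)
  sig <- results[results$significant, , drop = FALSE]
  owners <- sort(unique(results[[level]]))
  if (length(owners) < 2) stop("need at least two ", level, "s")
  sets <- lapply(owners, function(o)
    unique(sig$metabolite[sig[[level]] == o]))
  names(sets) <- owners
  k <- length(owners)
  out <- matrix(1, k, k, dimnames = list(owners, owners))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- tryCatch(dice(sets[[i]], sets[[j]]), error = function(e) {
        warning("both ", owners[i], " and ", owners[j],
                " have empty significance sets; DSC set to NA")
        NA_real_
      })
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}
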