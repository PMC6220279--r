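#' Two-sided Fisher exact p for a 2x2 overlap table
#'
#' Point-probability convention: the sum of probabilities of all tables
#' (at fixed margins) whose hypergeometric point probability does not
#' exceed that of the observed table.
#'
#' @param overlap genes in both the list and the set.
#' @param list_size,set_size,universe list, set and universe sizes.
#' @return two-sided p value.
#' @export
fisher_overlap_p <- function(overlap, list_size, set_size, universe) {
  lo <- max(0, list_size + set_size - universe)
  hi <- min(list_size, set_size)
  support <- lo:hi
  pr <- stats::dhyper(support, set_size, universe - set_size, list_size)
  p_obs <- pr[support == overlap]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Cell-type enrichment of a DEG list against marker gene sets
#'
#' For each specificity-thresholded marker set, builds the 2x2 overlap
#' table against the differentially-expressed-gene (DEG) list over an
#' explicit gene universe, computes the two-sided Fisher exact p, applies
#' Benjamini-Hochberg correction across sets, and (when directions are
#' supplied) the fraction of overlapping DEGs that are down-regulated.
#'
#' @param degs character vector of DEG ids, or a data frame with columns
#'   `gene` and `log2fc` (directions enable the down-fraction).
#' @param sets named list of gene-id vectors (the marker collection).
#' @param universe character vector of all genes tested.
#' @param alpha significance threshold on the BH q value.
#' @return an `enrichment_table` data frame, one row per set, sorted by q:
#'   set, set_size, overlap, p, q, significant, frac_down.
#' @export
fisher_enrichment <- function(degs, sets, universe, alpha = 0.05) {
  if (is.data.frame(degs)) {
    genes <- degs$gene; l2fc <- degs$log2fc
  } else {
    genes <- degs; l2fc <- NULL
  }
  bad <- setdiff(genes, universe)
  if (length(bad))
    stop(sprintf("DEG outside universe: %s", bad[1]))
  bad_set <- names(sets)[vapply(sets, function(s) length(setdiff(s, universe)) > 0, TRUE)]
  if (length(bad_set))
    stop(sprintf("set '%s' contains genes outside the universe", bad_set[1]))
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  N <- length(universe)
  nl <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(genes, s)
    k <- length(ov)
    p <- fisher_overlap_p(k, nl, length(s), N)
    fd <- if (!is.null(l2fc) && k > 0) mean(l2fc[match(ov, genes)] < 0) else NA_real_
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               frac_down = fd, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_correct(tab$p)
  tab$significant <- tab$q < alpha
  tab <- tab[order(tab$q, tab$p), c("set", "set_size", "overlap", "p", "q",
                                    "significant", "frac_down")]
  rownames(tab) <- NULL
  structure(tab, class = c("enrichment_table", "data.frame"))
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' @param p vector of p values in `[0, 1]`.
#' @return q values (monotone, elementwise >= p).
#' @export
bh_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Direction decomposition of enrichment overlaps
#'
#' Recomputes each set's fraction of overlapping DEGs that are
#' down-regulated (log2 fold change < 0); sets with zero overlap get an
#' absent (`NA`) fraction rather than a number.
#'
#' @param tab an `enrichment_table`.
#' @param degs data frame with `gene` and `log2fc`.
#' @param sets the gene-set collection used to build `tab`.
#' @return `tab` with the `frac_down` column (re)populated.
#' @export
direction_decomposition <- function(tab, degs, sets) {
  stopifnot(all(c("gene", "log2fc") %in% names(degs)))
  tab$frac_down <- vapply(tab$set, function(nm) {
    ov <- intersect(degs$gene, sets[[nm]])
    if (length(ov) == 0) return(NA_real_)
    mean(degs$log2fc[match(ov, degs$gene)] < 0)
  }, 0)
  tab
}

#' Contrast mean marker fold changes between two cell-type classes
#'
#' Treats markers (not animals) as the sampling units: reports each
#' class's mean log2 fold change, their difference, and pooled/Welch
#' two-sample t tests across markers.
#'
#' @param panel data frame with columns `gene`, `log2fc`, `class`.
#' @param class_a,class_b the two classes to contrast.
#' @return list with `mean_a`, `mean_b`, `difference`, `test`
#'   (a `group_test` table).
#' @export
marker_contrast <- function(panel, class_a, class_b) {
  a <- panel$log2fc[panel$class == class_a]
  b <- panel$log2fc[panel$class == class_b]
  if (length(a) < 2 || length(b) < 2)
    stop("both classes need at least 2 markers")
  tt <- two_sample_test(a, b)
  list(mean_a = mean(a), mean_b = mean(b), difference = mean(a) - mean(b),
       test = tt)
}
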