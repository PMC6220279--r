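#' Generate a DEG table and marker gene-set collection with known overlap
#'
#' Fabricates a gene universe, a panel of pairwise-disjoint cell-type
#' marker sets, and a differentially-expressed-gene list whose overlap
#' with named sets is enriched (or depleted) by a controlled factor and
#' whose overlapping members carry a controlled down-regulation bias
#' (e.g. 100 percent down-regulated among the overlaps of a
#' medium-spiny-neuron set). Unnamed sets overlap at the hypergeometric
#' expectation.
#'
#' @param universe_size number of genes in the universe.
#' @param n_sets number of marker sets (default 27, the breadth of a
#'   typical cell-type panel).
#' @param set_size genes per set (scalar or vector).
#' @param n_deg size of the DEG list.
#' @param enrich named list: per set, `list(fold =, frac_down =)` giving
#'   the overlap enrichment factor over the hypergeometric mean and the
#'   down-regulated fraction among overlaps.
#' @param frac_down_background down fraction among non-overlap DEGs.
#' @param seed RNG seed.
#' @return list with `degs` (gene, log2fc, pvalue), `sets` (named list),
#'   `universe` (character vector).
#' @export
make_deg_table <- function(universe_size = 15000, n_sets = 27,
                           set_size = 300, n_deg = 500,
                           enrich = list(), frac_down_background = 0.5,
                           seed = 1L) {
  with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(universe_size))
    set_size <- rep(set_size, length.out = n_sets)
    if (sum(set_size) > universe_size)
      stop("sets exceed the universe; shrink or overlap them")
    pool <- sample(universe, sum(set_size))
    sets <- split(pool, rep(seq_len(n_sets), set_size))
    names(sets) <- sprintf("celltype_%02d", seq_len(n_sets))
    bad <- setdiff(names(enrich), names(sets))
    if (length(bad)) stop(sprintf("depletion profile names unknown set '%s'", bad[1]))

    deg <- character(0)
    down <- logical(0)
    for (nm in names(enrich)) {
      e <- enrich[[nm]]
      k <- round((e$fold %||% 1) * n_deg * length(sets[[nm]]) / universe_size)
      if (k > length(sets[[nm]]))
        stop(sprintf("requested overlap %d exceeds size of set '%s'", k, nm))
      pick <- sample(sets[[nm]], k)
      deg <- c(deg, pick)
      down <- c(down, stats::runif(k) < (e$frac_down %||% 0.5))
    }
    rest <- setdiff(universe, unlist(sets[names(enrich)]))
    n_rest <- n_deg - length(deg)
    if (n_rest < 0) stop("enrichment profile exceeds the DEG list size")
    pick <- sample(rest, n_rest)
    deg <- c(deg, pick)
    down <- c(down, stats::runif(n_rest) < frac_down_background)

    mag <- stats::rlnorm(n_deg, log(0.8), 0.4)
    degs <- data.frame(gene = deg,
                       log2fc = ifelse(down, -mag, mag),
                       pvalue = stats::runif(n_deg, 0, 0.05),
                       stringsAsFactors = FALSE)
    list(degs = degs, sets = sets, universe = universe)
  })
}

#' Generate a qPCR plate with standards and known fold changes
#'
#' Simulates Cq values from the standard-curve model
#' `Cq = intercept - log10(quantity) / log10(1 + efficiency)` plus
#' Gaussian cycle noise. Each biological sample carries a shared loading
#' factor (removed downstream by reference-gene normalization); mutant
#' samples scale target-gene quantities by the true fold change.
#' Standards are serial dilutions of a pooled quantity of 1.
#'
#' @param genes character vector of target genes.
#' @param reference_genes character vector of reference genes (fold
#'   change fixed at 1).
#' @param n_wt,n_mut samples per genotype group.
#' @param fold_change named true mutant/wild-type fold changes per target
#'   gene (default 1).
#' @param efficiency amplification efficiency per gene in (0.7, 1.1]
#'   (scalar or named).
#' @param intercept Cq at quantity 1 (scalar or named).
#' @param dilutions relative quantities of the standard series
#'   (>= 3 points; default five ten-fold dilutions).
#' @param noise_sd Gaussian Cq noise (cycles).
#' @param bio_cv biological between-sample CV of true quantities.
#' @param loading_sd log2 SD of the per-sample loading factor.
#' @param stage age-stage label stored with the samples.
#' @param seed RNG seed.
#' @return data frame: sample, group, stage, gene, Cq, is_standard,
#'   dilution.
#' @export
make_qpcr_plate <- function(genes, reference_genes = paste0("ref", 1:4),
                            n_wt = 6, n_mut = 6, fold_change = numeric(),
                            efficiency = 1.0, intercept = 22,
                            dilutions = 10^-(0:4), noise_sd = 0.2,
                            bio_cv = 0.15, loading_sd = 0.25,
                            stage = "P56", seed = 1L) {
  all_genes <- c(genes, reference_genes)
  eff <- if (length(efficiency) == 1) stats::setNames(rep(efficiency, length(all_genes)), all_genes) else efficiency
  if (any(eff <= 0.7 | eff > 1.1)) stop("efficiencies must lie in (0.7, 1.1]")
  if (length(dilutions) < 3) stop("need >= 3 dilution points")
  icpt <- if (length(intercept) == 1) stats::setNames(rep(intercept, length(all_genes)), all_genes) else intercept
  slope <- -1 / log10(1 + eff)

  with_seed(seed, {
    n <- n_wt + n_mut
    grp <- rep(c("WT", "MUT"), c(n_wt, n_mut))
    ids <- sprintf("s%02d", seq_len(n))
    loading <- 2^stats::rnorm(n, 0, loading_sd)
    rows <- list()
    for (gi in seq_along(all_genes)) {
      g <- all_genes[gi]
      fc <- if (g %in% names(fold_change)) fold_change[[g]] else 1
      q_true <- rlnorm_mean_cv(n, 1, max(bio_cv, 1e-9)) *
        ifelse(grp == "MUT", fc, 1) * loading
      cq <- icpt[[g]] + slope[[g]] * log10(q_true) +
        stats::rnorm(n, 0, noise_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = ids, group = grp, stage = stage, gene = g,
                   Cq = cq, is_standard = FALSE, dilution = NA_real_,
                   stringsAsFactors = FALSE)
      cq_std <- icpt[[g]] + slope[[g]] * log10(dilutions) +
        stats::rnorm(length(dilutions), 0, noise_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = sprintf("std%d", seq_along(dilutions)),
                   group = "standard", stage = stage, gene = g,
                   Cq = cq_std, is_standard = TRUE, dilution = dilutions,
                   stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
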