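#' Fit a qPCR standard curve for one gene
#'
#' Least-squares line of Cq against log10(relative quantity) over the
#' dilution series; amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope) - 1`. A non-monotone dilution response or a
#' non-negative slope flags the curve as rejected.
#'
#' @param plate qPCR table as produced by [make_qpcr_plate()].
#' @param gene gene to fit.
#' @return a `standard_curve` list: gene, slope, intercept, r_squared,
#'   efficiency, ok (logical), reason.
#' @export
fit_standard_curve <- function(plate, gene) {
  std <- plate[plate$is_standard & plate$gene == gene, ]
  if (nrow(std) < 3) stop("need >= 3 dilution points")
  x <- log10(std$dilution)
  if (diff(range(x)) < 2) stop("dilution series must span >= 2 log10 units")
  fit <- stats::lm(std$Cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  icpt <- unname(stats::coef(fit)[1])
  ss_tot <- sum((std$Cq - mean(std$Cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  ord <- order(x)
  mono <- all(diff(std$Cq[ord]) < 0)
  ok <- slope < 0 && mono
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  structure(list(gene = gene, slope = slope, intercept = icpt,
                 r_squared = r2, efficiency = eff, ok = ok,
                 reason = if (ok) NA_character_ else "non-monotone or non-negative slope"),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve for %s: slope %.3f, R^2 %.4f, efficiency %.3f%s\n",
              x$gene, x$slope, x$r_squared, x$efficiency,
              if (x$ok) "" else " [REJECTED]"))
  invisible(x)
}

#' Back-calculate relative quantities from standard curves
#'
#' @param plate qPCR table.
#' @param curves optional named list of pre-fit `standard_curve`s.
#' @return data frame of unknowns with a `quantity` column
#'   (`10^((Cq - intercept)/slope)`).
#' @export
quantify_samples <- function(plate, curves = NULL) {
  genes <- unique(plate$gene)
  if (is.null(curves))
    curves <- stats::setNames(lapply(genes, fit_standard_curve, plate = plate), genes)
  unk <- plate[!plate$is_standard, ]
  unk$quantity <- vapply(seq_len(nrow(unk)), function(i) {
    cv <- curves[[unk$gene[i]]]
    10^((unk$Cq[i] - cv$intercept) / cv$slope)
  }, 0)
  attr(unk, "curves") <- curves
  unk
}

#' Rank reference-gene stability and select the best pair
#'
#' Model-based stability in the NormFinder spirit, on log2 quantities
#' with the per-sample loading effect removed (each sample centered by
#' its mean over the candidate genes): a gene's stability combines its
#' intergroup bias (variance of group means) and its average intragroup
#' variance; smaller is more stable. The best pair minimizes the
#' stability of the pairwise-averaged log signal, which lets opposite
#' group biases cancel.
#'
#' @param quantities data frame with `sample`, `group`, `gene`,
#'   `quantity` for the candidate reference genes.
#' @param candidates candidate gene names (>= 3).
#' @return list with `ranking` (gene, stability, ordered most stable
#'   first) and `best_pair` (character vector of 2).
#' @export
stability_rank <- function(quantities, candidates) {
  stopifnot(length(candidates) >= 3)
  q <- quantities[quantities$gene %in% candidates, ]
  if (length(unique(q$group)) < 2) stop("need >= 2 groups")
  m <- stats::xtabs(log2(quantity) ~ sample + gene, data = q)
  m <- as.matrix(unclass(m))[, candidates, drop = FALSE]
  grp <- q$group[match(rownames(m), q$sample)]
  m <- m - rowMeans(m) # remove sample loading

  gene_stability <- function(v) {
    gm <- tapply(v, grp, mean)
    gv <- tapply(v, grp, stats::var)
    sqrt(stats::var(gm) + mean(gv))
  }
  stab <- apply(m, 2, gene_stability)
  ranking <- data.frame(gene = candidates[order(stab)],
                        stability = sort(stab), stringsAsFactors = FALSE)
  prs <- utils::combn(candidates, 2)
  pair_stab <- apply(prs, 2, function(pr)
    gene_stability(rowMeans(m[, pr, drop = FALSE])))
  best <- prs[, which.min(pair_stab)]
  list(ranking = ranking, best_pair = best,
       pair_stability = stats::setNames(pair_stab,
                                        apply(prs, 2, paste, collapse = "+")))
}

#' Normalize quantities and contrast genotype groups
#'
#' Divides each sample's quantities by the geometric mean of the selected
#' reference pair (making results invariant to per-sample loading), then
#' reports per-gene group fold change on normalized group means,
#' `log2FC = log2(mean_mut / mean_wt)`, gated by Shapiro-Wilk and paired
#' with pooled and Welch t tests on log2 quantities.
#'
#' @param quantities data frame from [quantify_samples()].
#' @param reference_pair the two normalizer genes.
#' @param genes target genes to report (defaults to all non-reference).
#' @return data frame: gene, stage, log2fc, p_pooled, p_welch,
#'   shapiro_pass.
#' @export
normalize_and_contrast <- function(quantities, reference_pair,
                                   genes = NULL) {
  q <- quantities
  refs <- q[q$gene %in% reference_pair, ]
  nf <- tapply(refs$quantity, refs$sample, function(v) exp(mean(log(v))))
  miss <- setdiff(unique(q$sample), names(nf)[!is.na(nf)])
  if (length(miss)) {
    message(sprintf("dropping sample(s) without reference measurements: %s",
                    paste(miss, collapse = ", ")))
    q <- q[!q$sample %in% miss, ]
  }
  q$norm <- q$quantity / as.numeric(nf[q$sample])
  genes <- genes %||% setdiff(unique(q$gene), reference_pair)
  out <- lapply(genes, function(g) {
    d <- q[q$gene == g, ]
    by_stage <- split(d, d$stage)
    do.call(rbind, lapply(names(by_stage), function(st) {
      ds <- by_stage[[st]]
      wt <- ds$norm[ds$group == "WT"]; mut <- ds$norm[ds$group == "MUT"]
      tt <- two_sample_test(log2(mut), log2(wt))
      gate <- normality_gate(c(log2(wt) - mean(log2(wt)),
                               log2(mut) - mean(log2(mut))))
      data.frame(gene = g, stage = st,
                 log2fc = log2(mean(mut) / mean(wt)),
                 p_pooled = tt$p[tt$kind == "pooled"],
                 p_welch = tt$p[tt$kind == "welch"],
                 shapiro_pass = isTRUE(gate$pass),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
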