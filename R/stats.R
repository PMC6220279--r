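#' Shapiro-Wilk normality gate
#'
#' Wraps the Shapiro-Wilk test as the pre-test applied before two-sample
#' comparisons; the gate passes when p > 0.05. Constant samples have an
#' undefined W and fail the gate with a reason.
#'
#' @param x numeric sample (3 <= n <= 5000).
#' @param alpha gate level (default 0.05).
#' @return list with `W`, `p`, `pass`, `reason`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3)
    return(list(W = NA_real_, p = NA_real_, pass = FALSE, reason = "n < 3"))
  if (stats::sd(x) == 0)
    return(list(W = NA_real_, p = NA_real_, pass = FALSE,
                reason = "constant sample: W undefined"))
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value,
       pass = sw$p.value > alpha, reason = NA_character_)
}

#' Two-sample t tests from raw data or printed summary statistics
#'
#' Computes the pooled-variance (Student) and Welch two-sample t tests
#' either from raw samples or directly from `(mean, SD, n)` summaries, so
#' that comparisons printed in a publication table can be reproduced
#' exactly. The raw-data path computes the summaries and delegates to the
#' summary path, making the two routes identical by construction.
#'
#' @param x,y raw samples, or `NULL` when summaries are given.
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @return a `group_test` data frame with one row per variant
#'   (`pooled`, `welch`): t, df, p (two-sided) and the summaries used.
#' @export
two_sample_test <- function(x = NULL, y = NULL,
                            mean1 = NULL, sd1 = NULL, n1 = NULL,
                            mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    stopifnot(!is.null(y), length(x) >= 2, length(y) >= 2)
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  d <- mean1 - mean2
  res <- lapply(c("pooled", "welch"), function(kind) {
    if (kind == "pooled") {
      sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
      se <- sqrt(v1 + v2)
      df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else NA_real_
    }
    if (se == 0) { # degenerate: both groups constant
      t <- if (d == 0) 0 else sign(d) * Inf
      p <- if (d == 0) 1 else 0
    } else {
      t <- d / se
      p <- 2 * stats::pt(-abs(t), df)
    }
    data.frame(kind = kind, t = t, df = df, p = p,
               mean1 = mean1, sd1 = sd1, n1 = n1,
               mean2 = mean2, sd2 = sd2, n2 = n2,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), class = c("group_test", "data.frame"))
}

#' Two-way ANOVA with genotype and layer factors
#'
#' Fits `value ~ genotype * layer` with type-II sums of squares, reports
#' F and p for both main effects and the interaction, Tukey HSD pairwise
#' comparisons, and Bonferroni-adjusted within-layer genotype t tests
#' (the two post hoc conventions are labeled, not conflated).
#'
#' @param value numeric response.
#' @param genotype,layer factors (>= 2 levels each).
#' @return an `anova_result` list: `effects` (term, df, F, p),
#'   `tukey` (Tukey HSD table), `within_layer` (per-layer genotype
#'   contrast with Bonferroni-adjusted p).
#' @export
two_way_anova <- function(value, genotype, layer) {
  genotype <- factor(genotype); layer <- factor(layer)
  stopifnot(nlevels(genotype) >= 2, nlevels(layer) >= 2)
  dat <- data.frame(value = value, genotype = genotype, layer = layer)
  cell_n <- table(dat$genotype, dat$layer)
  form <- if (any(cell_n < 2)) {
    warning("empty or singleton cells: interaction term dropped")
    value ~ genotype + layer
  } else value ~ genotype * layer
  fit <- stats::lm(form, data = dat)
  a2 <- car::Anova(fit, type = "II")
  keep <- rownames(a2) != "Residuals"
  effects <- data.frame(term = rownames(a2)[keep],
                        df = a2$Df[keep],
                        F = a2$`F value`[keep],
                        p = a2$`Pr(>F)`[keep],
                        stringsAsFactors = FALSE)
  tukey <- stats::TukeyHSD(stats::aov(form, data = dat))
  wl <- do.call(rbind, lapply(levels(layer), function(l) {
    d <- dat[dat$layer == l, ]
    if (nlevels(droplevels(d$genotype)) < 2) return(NULL)
    g <- split(d$value, droplevels(d$genotype))
    tt <- two_sample_test(g[[1]], g[[2]])
    data.frame(layer = l, t = tt$t[1], df = tt$df[1], p = tt$p[1],
               stringsAsFactors = FALSE)
  }))
  wl$p_bonferroni <- pmin(1, wl$p * nrow(wl))
  structure(list(effects = effects, tukey = tukey, within_layer = wl),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (type II):\n")
  print(x$effects, row.names = FALSE)
  cat("Within-layer genotype contrasts (Bonferroni):\n")
  print(x$within_layer, row.names = FALSE)
  invisible(x)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param x numeric matrix or data frame, observations in rows.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   columns produce `NA` entries and a warning (never a silent 0).
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 observations")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning(sprintf("zero-variance column(s): %s",
                    paste(colnames(x)[which(sds == 0)], collapse = ", ")))
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
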