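#' Gundersen-Jensen error prediction for systematic sampling
#'
#' Predicted coefficient of error of a systematic-uniform-random sample
#' from the ordered sequence of section measurements, using the
#' transitive-methods combination `3A - 4B + C` with
#' `A = sum(a_i^2)`, `B = sum(a_i a_{i+1})`, `C = sum(a_i a_{i+2})` and
#' denominator 240 (smoothness class m = 1) or 12 (m = 0).
#'
#' @param a ordered sequence of sampled section values (areas or counts).
#' @param m smoothness class, 0 or 1 (default 1).
#' @return CE of the sum of the sequence (dimensionless).
#' @export
ce_surs <- function(a, m = 1) {
  n <- length(a)
  if (n < 3 || sum(a) == 0) return(NA_real_)
  A <- sum(a * a)
  B <- sum(a[-n] * a[-1])
  C <- sum(a[seq_len(n - 2)] * a[-(1:2)])
  denom <- if (m == 1) 240 else 12
  v <- max(0, (3 * A - 4 * B + C) / denom)
  sqrt(v) / sum(a)
}

# Cavalieri CE on the sampled area sequence (>= 3 sections needed)
cavalieri_ce <- function(areas) ce_surs(areas, m = 1)

# count CE: Poisson (nucleolus-noise) term plus the SURS term of the
# section-wise Q- sequence
count_ce <- function(q_sec) {
  sq <- sum(q_sec)
  if (sq == 0) return(NA_real_)
  surs <- ce_surs(q_sec, m = 1)
  if (is.na(surs)) surs <- 0
  sqrt(1 / sq + surs^2)
}

#' Predicted CE of a stereological estimate
#' @param estimate a `stereo_estimate`.
#' @return the predicted coefficient of error.
#' @export
precision <- function(estimate) {
  stopifnot(inherits(estimate, "stereo_estimate"))
  estimate$ce
}

#' Group-level precision summary
#'
#' Assembles the between-animal summary of a set of per-animal estimates:
#' mean, SD, CV = SD/mean, the mean squared predicted CE and the ratio
#' `CE^2/CV^2` — the share of observed group variance attributable to the
#' sampling itself (well below 1 in a healthy design).
#'
#' @param estimates list of `stereo_estimate`s, or a numeric vector of
#'   estimates with `ces` supplied separately.
#' @param ces optional numeric vector of per-animal CEs.
#' @return a one-row data frame: n, mean, sd, cv, mean_ce2, ce2_cv2.
#' @export
group_precision <- function(estimates, ces = NULL) {
  if (is.list(estimates) && inherits(estimates[[1]], "stereo_estimate")) {
    ces <- vapply(estimates, `[[`, 0, "ce")
    estimates <- vapply(estimates, `[[`, 0, "estimate")
  }
  n <- length(estimates)
  m <- mean(estimates)
  s <- stats::sd(estimates)
  cv <- if (m > 0) s / m else NA_real_
  mce2 <- if (is.null(ces)) NA_real_ else mean(ces^2, na.rm = TRUE)
  ratio <- if (!is.na(cv) && cv > 0) mce2 / cv^2 else NA_real_
  data.frame(n = n, mean = m, sd = s, cv = cv,
             mean_ce2 = mce2, ce2_cv2 = ratio)
}
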