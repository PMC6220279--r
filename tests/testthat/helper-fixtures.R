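# Printed group summaries of the emulated study (mean, SD, n), re-entered
# as fixture inputs for the summary-statistic test path.
table2 <- list(
  cpu_volume  = list(wt = c(mean = 10.90, sd = 0.70, n = 7),
                     mut = c(mean = 9.70, sd = 0.59, n = 6)),
  cpu_neurons = list(wt = c(mean = 666016, sd = 90787, n = 7),
                     mut = c(mean = 527479, sd = 84378, n = 6)),
  acc_pv      = list(wt = c(mean = 9481, sd = 1639, n = 8),
                     mut = c(mean = 6294, sd = 1536, n = 6)),
  acc_vva     = list(wt = c(mean = 9837, sd = 1600, n = 8),
                     mut = c(mean = 7206, sd = 1334, n = 6)),
  acc_pv_vva  = list(wt = c(mean = 9375, sd = 1633, n = 8),
                     mut = c(mean = 6157, sd = 1556, n = 6)))

summary_test <- function(row) {
  two_sample_test(mean1 = row$wt[["mean"]], sd1 = row$wt[["sd"]], n1 = row$wt[["n"]],
                  mean2 = row$mut[["mean"]], sd2 = row$mut[["sd"]], n2 = row$mut[["n"]])
}

# small sphere phantom reused across tests: radius 1000 um, 50 um voxels
sphere_phantom <- function(r_um = 1000, voxel = 50) {
  make_phantom(list(region_shape("ball", "ellipsoid", center = c(0, 0, 0),
                                 semiaxes = rep(r_um, 3))), voxel)
}

# exact hypergeometric point probability from binomial coefficients only
# (independent of dhyper): P(X = x) for overlap x
hyper_point <- function(x, set, universe, list_size) {
  exp(lchoose(set, x) + lchoose(universe - set, list_size - x) -
        lchoose(universe, list_size))
}

# brute-force two-sided Fisher p by enumeration over the whole support
enum_fisher_p <- function(overlap, list_size, set_size, universe) {
  support <- max(0, list_size + set_size - universe):min(list_size, set_size)
  pr <- vapply(support, hyper_point, 0, set = set_size, universe = universe,
               list_size = list_size)
  sum(pr[pr <= pr[support == overlap] * (1 + 1e-7)])
}

# literal step-up Benjamini-Hochberg, written independently of p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
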