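#' Regional volumetry over a label volume
#'
#' Tabulates voxel-counting volumes per region and hemisphere (split by a
#' plane perpendicular to axis 1 at `midplane_um`), and rolls regions up
#' to their structures via the label hierarchy.
#'
#' @param vol a `label_volume`.
#' @param midplane_um hemisphere plane position along axis 1 (micrometres);
#'   `NULL` skips the hemisphere split.
#' @return a `region_volume_table` data frame: region, level
#'   (`region`/`structure`), hemisphere (`left`/`right`/`both`),
#'   volume_mm3.
#' @export
region_volumes <- function(vol, midplane_um = NULL) {
  vx <- prod(vol$voxel_size) / 1e9
  labs <- vol$label_map
  xs <- (seq_len(dim(vol$grid)[1]) - 0.5) * vol$voxel_size[1]
  rows <- list()
  for (r in names(labs)) {
    mask <- vol$grid == labs[[r]]
    per_x <- apply(mask, 1, sum)
    tot <- sum(per_x) * vx
    rows[[length(rows) + 1L]] <- data.frame(
      region = r, level = "region", hemisphere = "both",
      volume_mm3 = tot, stringsAsFactors = FALSE)
    if (!is.null(midplane_um)) {
      left <- sum(per_x[xs < midplane_um]) * vx
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, level = "region", hemisphere = c("left", "right"),
        volume_mm3 = c(left, tot - left), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # structure roll-ups
  if (!is.null(vol$hierarchy)) {
    h <- vol$hierarchy
    for (s in unique(h$structure)) {
      members <- h$region[h$structure == s]
      for (hemi in unique(tab$hemisphere)) {
        v <- sum(tab$volume_mm3[tab$region %in% members & tab$hemisphere == hemi])
        tab <- rbind(tab, data.frame(region = s, level = "structure",
                                     hemisphere = hemi, volume_mm3 = v,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  structure(tab, class = c("region_volume_table", "data.frame"))
}

#' Percent volume change between genotype groups
#'
#' For each region, the change is
#' `100 * (mean_mut - mean_wt) / mean_wt` (reductions negative, the
#' wild-type mean in the denominator), paired with pooled and Welch
#' two-sample tests.
#'
#' @param tab data frame with columns `animal`, `genotype`
#'   (`"WT"`/`"MUT"`), `region`, `volume_mm3`.
#' @return data frame: region, mean_wt, mean_mut, pct_change, p_pooled,
#'   p_welch.
#' @export
percent_change <- function(tab) {
  out <- lapply(unique(tab$region), function(r) {
    d <- tab[tab$region == r, ]
    wt <- d$volume_mm3[d$genotype == "WT"]
    mut <- d$volume_mm3[d$genotype == "MUT"]
    if (length(wt) == 0 || length(mut) == 0) stop("both groups must be non-empty")
    if (mean(wt) == 0) {
      return(data.frame(region = r, mean_wt = 0, mean_mut = mean(mut),
                        pct_change = NA_real_, p_pooled = NA_real_,
                        p_welch = NA_real_, flag = "zero WT mean"))
    }
    tt <- two_sample_test(mut, wt)
    data.frame(region = r, mean_wt = mean(wt), mean_mut = mean(mut),
               pct_change = 100 * (mean(mut) - mean(wt)) / mean(wt),
               p_pooled = tt$p[tt$kind == "pooled"],
               p_welch = tt$p[tt$kind == "welch"],
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Region-by-region volume correlation matrix
#'
#' Pearson correlations of regional volumes across animals, pooling both
#' genotypes by default (a per-genotype matrix is available via `group`).
#'
#' @param tab data frame as in [percent_change()].
#' @param group optional genotype to restrict to.
#' @return symmetric correlation matrix (regions x regions).
#' @export
volume_correlations <- function(tab, group = NULL) {
  if (!is.null(group)) tab <- tab[tab$genotype == group, ]
  m <- stats::xtabs(volume_mm3 ~ animal + region, data = tab)
  m <- as.matrix(unclass(m))
  if (nrow(m) < 3) stop("need at least 3 animals")
  pearson_matrix(m)
}
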