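#' Group summary in the style of a stereology results table
#'
#' Assembles per-genotype mean, SD, CV, mean predicted CE^2, the ratio
#' CE^2/CV^2, and pooled plus Welch p values between genotypes, from
#' per-animal estimates.
#'
#' @param est data frame with columns `animal`, `genotype`, `estimate`
#'   and optionally `ce`.
#' @param label row label for the measured quantity.
#' @return one-row-per-quantity data frame with WT and MUT summary
#'   columns and the two p values.
#' @export
summarize_groups <- function(est, label = "quantity") {
  stopifnot(all(c("genotype", "estimate") %in% names(est)))
  gp <- function(g) {
    d <- est[est$genotype == g, ]
    if (nrow(d) < 2)
      return(data.frame(n = nrow(d), mean = mean(d$estimate), sd = NA_real_,
                        cv = NA_real_, mean_ce2 = NA_real_, ce2_cv2 = NA_real_))
    group_precision(d$estimate, ces = if ("ce" %in% names(d)) d$ce else NULL)
  }
  wt <- gp("WT"); mut <- gp("MUT")
  p_pooled <- p_welch <- NA_real_
  if (wt$n >= 2 && mut$n >= 2) {
    tt <- two_sample_test(est$estimate[est$genotype == "WT"],
                          est$estimate[est$genotype == "MUT"])
    p_pooled <- tt$p[tt$kind == "pooled"]
    p_welch <- tt$p[tt$kind == "welch"]
  }
  data.frame(quantity = label,
             wt_n = wt$n, wt_mean = wt$mean, wt_sd = wt$sd, wt_cv = wt$cv,
             wt_ce2_cv2 = wt$ce2_cv2,
             mut_n = mut$n, mut_mean = mut$mean, mut_sd = mut$sd,
             mut_cv = mut$cv, mut_ce2_cv2 = mut$ce2_cv2,
             p_pooled = p_pooled, p_welch = p_welch,
             stringsAsFactors = FALSE)
}

#' Default study-replica configuration
#'
#' A demo-sized configuration that exercises the full chain: a bilateral
#' volumetry cohort, a stereology arm (Cavalieri volume + optical
#' fractionator on a caudate-putamen phantom), a laminar density-count
#' arm, DEG enrichment and a qPCR panel. Cell totals are scaled down from
#' study scale so the demo completes quickly; the acceptance analyses use
#' study-scale phantoms.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    volumetry = list(n_wt = 9, n_mut = 10, cv = 0.06,
                     effects = c("Caudate Nucleus/Putamen" = -0.10,
                                 "Amygdala" = -0.05)),
    stereology = list(n_wt = 7, n_mut = 6, volume_mm3 = 10.90,
                      volume_cv = 0.06, volume_effect = -0.11,
                      neurons = 66602, neuron_cv = 0.15,
                      neuron_effect = -0.21,
                      design = list(period = 6, step = c(400, 400),
                                    frame = c(50, 40), z_window = c(5, 15)),
                      thickness_um = 40),
    acc = list(n_wt = 8, n_mut = 6, cells = 9481, cv = 0.17,
               layer_profile = c("I-III" = 0.45, "V" = 0.40, "VI" = 0.15),
               layer_effect = c("V" = -0.45),
               effect = -0.10,
               layout = c("I-III" = 3, "V" = 3, "VI" = 1)),
    enrichment = list(universe = 12000, n_sets = 27, set_size = 250,
                      n_deg = 400,
                      enrich = list(celltype_01 = list(fold = 6, frac_down = 1),
                                    celltype_02 = list(fold = 4, frac_down = 1))),
    qpcr = list(genes = c("Cck", "Vip", "Pvalb"),
                fold_change = c(Cck = 0.6), n_wt = 7, n_mut = 7,
                efficiency = 0.95, noise_sd = 0.2)
  ), class = "run_config")
}

#' Run the full study replica and write paper-shaped reports
#'
#' Orchestrates phantom-cohort generation, regional volumetry with
#' percent change and correlations, the stereology arm (Cavalieri +
#' fractionator with CE accounting), the laminar disector-density arm
#' with a genotype-by-layer ANOVA, DEG enrichment, and the qPCR panel;
#' writes one TSV per report plus a JSON manifest. Deterministic under a
#' fixed configuration seed.
#'
#' @param config a [default_config()]-shaped list.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list of the report data frames.
#' @export
run_study <- function(config = default_config(), outdir = tempfile("study")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  reports <- list()

  # -- volumetry arm ------------------------------------------------------
  tmpl <- brain_template()
  cs <- cohort_spec(config$volumetry$n_wt, config$volumetry$n_mut,
                    volume_effect = config$volumetry$effects,
                    volume_cv = config$volumetry$cv, seed = seed)
  co <- make_cohort(cs, tmpl)
  vt <- do.call(rbind, lapply(seq_len(nrow(co$animals)), function(i) {
    ph <- animal_phantom(co, i)
    rv <- region_volumes(ph$volume, midplane_um = tmpl$midplane_um)
    rv <- rv[rv$hemisphere == "both", ]
    data.frame(animal = i, genotype = co$animals$genotype[i],
               region = rv$region, level = rv$level,
               volume_mm3 = rv$volume_mm3, stringsAsFactors = FALSE)
  }))
  reports$volumetry <- percent_change(vt[vt$level == "region", ])
  write_tsv(reports$volumetry, file.path(outdir, "volumetry.tsv"))
  cm <- volume_correlations(vt[vt$level == "region", ])
  write_tsv(data.frame(region = rownames(cm), cm, check.names = FALSE),
            file.path(outdir, "volume_correlations.tsv"))
  reports$correlations <- cm

  # -- stereology arm -----------------------------------------------------
  sg <- config$stereology
  tmpl2 <- cpu_template(sg$volume_mm3)
  cs2 <- cohort_spec(sg$n_wt, sg$n_mut,
                     volume_effect = c(CPu = sg$volume_effect),
                     volume_cv = sg$volume_cv,
                     count_mean = sg$neurons, count_cv = sg$neuron_cv,
                     count_effect = sg$neuron_effect,
                     count_region = "CPu", seed = seed + 1L)
  co2 <- make_cohort(cs2, tmpl2)
  design <- do.call(sampling_design, sg$design)
  st <- do.call(rbind, lapply(seq_len(nrow(co2$animals)), function(i) {
    ph <- animal_phantom(co2, i)
    cells <- animal_cells(co2, i, ph)
    ser <- section_phantom(ph$volume, cells, sg$thickness_um,
                           seed = seed + 100L + i)
    cav <- cavalieri_volume(ser, "CPu", design, seed = seed + 200L + i)
    fr <- fractionator_count(ser, design, seed = seed + 300L + i)
    data.frame(animal = i, genotype = co2$animals$genotype[i],
               kind = c("volume", "number"),
               estimate = c(cav$estimate, fr$estimate),
               ce = c(cav$ce, fr$ce), stringsAsFactors = FALSE)
  }))
  write_tsv(st, file.path(outdir, "stereology_estimates.tsv"))
  reports$stereology <- rbind(
    summarize_groups(st[st$kind == "volume", ], "CPu volume (mm^3)"),
    summarize_groups(st[st$kind == "number", ], "CPu neurons"))
  write_tsv(reports$stereology, file.path(outdir, "stereology_summary.tsv"))

  # -- laminar density arm ------------------------------------------------
  ac <- config$acc
  tmpl3 <- acc_template()
  cs3 <- cohort_spec(ac$n_wt, ac$n_mut, volume_cv = 0.06,
                     count_mean = ac$cells, count_cv = ac$cv,
                     count_effect = ac$effect,
                     layer_profile = ac$layer_profile,
                     layer_effect = ac$layer_effect,
                     count_region = "aCC", seed = seed + 2L)
  co3 <- make_cohort(cs3, tmpl3)
  lw <- tmpl3$layer_widths
  acc_rows <- do.call(rbind, lapply(seq_len(nrow(co3$animals)), function(i) {
    ph <- animal_phantom(co3, i)
    cells <- animal_cells(co3, i, ph)
    ser <- section_phantom(ph$volume, cells, 40, seed = seed + 400L + i)
    v_ref <- voxel_volume_mm3(ph$volume, "aCC")
    stacks <- sample_stacks(ser, "aCC", ac$layout, lw,
                            seed = seed + 500L + i)
    ly <- layerwise_counts(stacks, v_ref * lw)
    data.frame(animal = i, genotype = co3$animals$genotype[i],
               layer = ly$layer, estimate = ly$estimate,
               stringsAsFactors = FALSE)
  }))
  write_tsv(acc_rows, file.path(outdir, "acc_layer_estimates.tsv"))
  an <- two_way_anova(acc_rows$estimate, acc_rows$genotype, acc_rows$layer)
  reports$acc_anova <- an$effects
  write_tsv(an$effects, file.path(outdir, "acc_anova.tsv"))
  write_tsv(an$within_layer, file.path(outdir, "acc_within_layer.tsv"))

  # -- enrichment arm -----------------------------------------------------
  en <- config$enrichment
  dg <- make_deg_table(en$universe, en$n_sets, en$set_size, en$n_deg,
                       enrich = en$enrich, seed = seed + 3L)
  reports$enrichment <- fisher_enrichment(dg$degs, dg$sets, dg$universe)
  write_tsv(reports$enrichment, file.path(outdir, "enrichment.tsv"))

  # -- qPCR arm -----------------------------------------------------------
  qp <- config$qpcr
  plate <- make_qpcr_plate(qp$genes, n_wt = qp$n_wt, n_mut = qp$n_mut,
                           fold_change = qp$fold_change,
                           efficiency = qp$efficiency,
                           noise_sd = qp$noise_sd, seed = seed + 4L)
  qs <- quantify_samples(plate)
  sr <- stability_rank(qs, paste0("ref", 1:4))
  reports$qpcr <- normalize_and_contrast(qs, sr$best_pair, genes = qp$genes)
  write_tsv(reports$qpcr, file.path(outdir, "qpcr_log2fc.tsv"))

  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("stereophantom")),
                   outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}
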