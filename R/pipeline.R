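## Study orchestration: cohort generation -> three attenuation maps per
## patient -> one simulated acquisition -> three OSEM reconstructions ->
## difference/delineation metrics -> TOST equivalence report.

#' Configuration of a full study run
#'
#' Bundles every module's parameters, validated up front. Blocks:
#' `phantom` (a [phantom_spec()]), `cohort` (n_patients / n_primary /
#' n_nodal), `maps` (calibration curve, MRAC class LACs, water fill,
#' air-vs-tissue cut, synthetic-CT error knobs), `geometry`
#' (a [scan_geometry()]), `recon` (a [recon_settings()]), `acquisition`
#' (count_scale, Poisson noise on/off), `metrics` (external-contour
#' threshold, GTV fraction, bone HU threshold and minimum component,
#' histogram bins/range) and `stats` (baseline uncertainty, allowed
#' increase, base alpha, number of tests).
#'
#' @param phantom a [phantom_spec()].
#' @param n_patients,n_primary,n_nodal cohort composition (defaults 10/9/5).
#' @param curve a [calibration_curve()].
#' @param mrac_lacs named class LACs (cm^-1).
#' @param water_lac,air_cut map-preparation parameters (cm^-1).
#' @param sct_bone_hu_bias,sct_bone_shift_mm synthetic-CT error knobs
#'   (defaults -30 HU, 0 mm: a small bone-density under-estimate).
#' @param geometry a [scan_geometry()].
#' @param recon a [recon_settings()].
#' @param count_scale,noise acquisition scale and Poisson noise switch.
#' @param external_threshold external-contour SUV threshold (default 0.05).
#' @param gtv_fraction GTV threshold fraction of SUVmax (default 0.4).
#' @param bone_hu_threshold,bone_min_component bone-ROI parameters.
#' @param hist_range,hist_bins difference-histogram range (%) and bin count.
#' @param delta_petct,allowed_increase,base_alpha,n_tests equivalence
#'   parameters (defaults 12%, 0.5%, 0.05, 8).
#' @param seed master seed; per-patient sub-seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       n_patients = 10L, n_primary = 9L, n_nodal = 5L,
                       curve = default_calibration_curve(),
                       mrac_lacs = default_mrac_lacs(),
                       water_lac = 0.096, air_cut = 0.02,
                       sct_bone_hu_bias = -30, sct_bone_shift_mm = 0,
                       geometry = scan_geometry(),
                       recon = recon_settings(),
                       count_scale = 100, noise = TRUE,
                       external_threshold = 0.05, gtv_fraction = 0.4,
                       bone_hu_threshold = 200, bone_min_component = 50L,
                       hist_range = c(-100, 100), hist_bins = 400L,
                       delta_petct = 12, allowed_increase = 0.5,
                       base_alpha = 0.05, n_tests = 8L,
                       seed = 1L) {
  validate_phantom_spec(phantom)
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(geometry, "scan_geometry"),
            inherits(recon, "recon_settings"))
  if (geometry$n_angles %% recon$subsets != 0)
    stop("recon subsets must divide the geometry's n_angles", call. = FALSE)
  if (n_patients <= 0) stop("n_patients must be > 0", call. = FALSE)
  if (count_scale <= 0) stop("count_scale must be > 0", call. = FALSE)
  if (external_threshold <= 0 || gtv_fraction <= 0 || gtv_fraction > 1)
    stop("invalid metric thresholds", call. = FALSE)
  if (delta_petct <= 0 || allowed_increase <= 0 || n_tests < 2)
    stop("invalid statistics block", call. = FALSE)
  structure(list(
    phantom = phantom,
    cohort = list(n_patients = as.integer(n_patients),
                  n_primary = as.integer(n_primary),
                  n_nodal = as.integer(n_nodal)),
    maps = list(curve = curve, mrac_lacs = mrac_lacs, water_lac = water_lac,
                air_cut = air_cut, sct_bone_hu_bias = sct_bone_hu_bias,
                sct_bone_shift_mm = sct_bone_shift_mm),
    geometry = geometry, recon = recon,
    acquisition = list(count_scale = count_scale, noise = isTRUE(noise)),
    metrics = list(external_threshold = external_threshold,
                   gtv_fraction = gtv_fraction,
                   bone_hu_threshold = bone_hu_threshold,
                   bone_min_component = as.integer(bone_min_component),
                   hist_range = hist_range, hist_bins = as.integer(hist_bins)),
    stats = list(delta_petct = delta_petct,
                 allowed_increase = allowed_increase,
                 base_alpha = base_alpha, n_tests = as.integer(n_tests)),
    seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any block or field omitted from the file keeps its [run_config()]
#' default. The `phantom`, `curve`, `geometry` and `recon` blocks accept
#' the corresponding constructor arguments as nested maps.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$curve))
    args$curve <- calibration_curve(y$curve$breakpoints, y$curve$lac_values)
  if (!is.null(y$geometry)) args$geometry <- do.call(scan_geometry, y$geometry)
  if (!is.null(y$recon)) args$recon <- do.call(recon_settings, y$recon)
  if (!is.null(y$mrac_lacs)) args$mrac_lacs <- unlist(y$mrac_lacs)
  scalars <- setdiff(names(y), c("phantom", "curve", "geometry", "recon",
                                 "mrac_lacs"))
  args <- c(args, y[scalars])
  do.call(run_config, args)
}

## Reconstruct one patient's three SUV images from one simulated scan.
reconstruct_patient <- function(patient, config, base_seed) {
  maps <- patient_attenuation_maps(
    patient, curve = config$maps$curve, mrac_lacs = config$maps$mrac_lacs,
    sct_bone_hu_bias = config$maps$sct_bone_hu_bias,
    sct_bone_shift_mm = config$maps$sct_bone_shift_mm,
    water_lac = config$maps$water_lac, air_cut = config$maps$air_cut,
    sct_seed = child_seed(base_seed, 2L))
  sino <- simulate_scan(patient$activity_truth, maps$CTAC, config$geometry,
                        count_scale = config$acquisition$count_scale,
                        noise = config$acquisition$noise,
                        seed = child_seed(base_seed, 3L))
  suv <- lapply(names(maps), function(prov) {
    rec <- osem_reconstruct(sino, maps[[prov]], config$geometry, config$recon)
    rec <- postfilter(rec, config$recon$postfilter_fwhm_mm,
                      patient$voxel_spacing)
    to_suv(rec, config$acquisition$count_scale, patient$weight_kg,
           patient$injected_dose_MBq, provenance = prov,
           patient_id = patient$patient_id,
           voxel_spacing = patient$voxel_spacing)
  })
  names(suv) <- names(maps)
  list(maps = maps, sinogram = sino, suv = suv)
}

## Difference/delineation metrics for one reconstructed patient.
evaluate_patient <- function(patient, suv, config) {
  m <- config$metrics
  contour <- external_contour(suv$CTAC, m$external_threshold)
  bmask <- withCallingHandlers(
    bone_mask(patient$hu_volume, m$bone_hu_threshold, m$bone_min_component),
    warning = function(w) invokeRestart("muffleWarning"))
  n_ext <- sum(contour)
  diffs <- list(); bone_diffs <- list()
  for (prov in c("sCTAC", "MRAC")) {
    diffs[[prov]] <- percent_diff_map(suv[[prov]], suv$CTAC, contour)
    if (any(bmask & contour)) {
      bd <- percent_diff_map(suv[[prov]], suv$CTAC, bmask & contour)
      ## bone-histogram fractions are expressed relative to the whole
      ## external contour, so both histograms share one y-axis unit
      bd$n_contour <- n_ext
      bone_diffs[[prov]] <- bd
    }
  }
  gtv <- lapply(patient$manual_volumes, function(mv)
    gtv_metrics(suv, mv$mask, kind = mv$kind,
                spacing = patient$voxel_spacing, fraction = m$gtv_fraction))
  list(contour = contour, bone_mask = bmask, diffs = diffs,
       bone_diffs = bone_diffs, gtv = gtv,
       bone_empty = !any(bmask & contour))
}

#' Run the full attenuation-correction evaluation study
#'
#' Generates the seeded cohort, builds the three prepared attenuation maps
#' per patient, simulates one attenuated acquisition per patient with the
#' CTAC map as physical truth, reconstructs it once per map (identical
#' data, geometry and settings — only the attenuation factors differ),
#' computes whole-image and bone-region SUV difference histograms and
#' per-lesion delineation/SUV metrics, and tests the 2 provenances x 2 GTV
#' kinds x 2 SUV metrics for equivalence with paired TOST at the
#' quadrature-derived margin and the corrected significance level. Fully
#' deterministic for a fixed `(config, seed)`.
#'
#' @param config a [run_config()].
#' @param keep_images keep the per-patient SUV volumes in the report
#'   (memory-heavy; default FALSE).
#' @param progress print per-patient progress messages.
#' @return Object of class `petmr_study`; see [render_tables()],
#'   `print()`, `summary()` and `plot()` methods.
#' @export
run_study <- function(config = run_config(), keep_images = FALSE,
                      progress = interactive()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$phantom, config$cohort$n_patients,
                            config$cohort$n_primary, config$cohort$n_nodal,
                            seed = config$seed)
  per_patient <- vector("list", length(cohort))
  images <- if (keep_images) vector("list", length(cohort)) else NULL
  warnings <- character(0)
  for (i in seq_along(cohort)) {
    pat <- cohort[[i]]
    base_seed <- child_seed(config$seed, i)
    res <- tryCatch({
      rec <- reconstruct_patient(pat, config, base_seed)
      ev <- evaluate_patient(pat, rec$suv, config)
      if (ev$bone_empty)
        warnings <- c(warnings, sprintf("%s: empty bone mask", pat$patient_id))
      if (keep_images) images[[i]] <- rec$suv
      ev
    }, error = function(e)
      stop(sprintf("patient %s failed at simulation/evaluation: %s",
                   pat$patient_id, conditionMessage(e)), call. = FALSE))
    per_patient[[i]] <- c(list(patient_id = pat$patient_id,
                               seed = base_seed), res)
    if (isTRUE(progress))
      message(sprintf("[%s] reconstructed and evaluated (%d/%d)",
                      pat$patient_id, i, length(cohort)))
  }
  names(per_patient) <- vapply(cohort, `[[`, "", "patient_id")
  report <- assemble_report(per_patient, config, warnings = warnings)
  report$images <- images
  report
}

## Aggregate per-patient evaluation results into the cohort report:
## difference histograms, mean differences, the per-lesion table and the
## eight TOST rows. Shared by run_study() and the staged CLI.
assemble_report <- function(per_patient, config, warnings = character(0)) {
  for (id in names(per_patient))
    if (is.null(per_patient[[id]]$patient_id))
      per_patient[[id]]$patient_id <- id
  ## cohort difference histograms and mean differences
  hist_whole <- list(); hist_bone <- list()
  mean_whole <- c(); mean_bone <- c()
  for (prov in c("sCTAC", "MRAC")) {
    dm <- lapply(per_patient, function(p) p$diffs[[prov]])
    hist_whole[[prov]] <- bin_histogram(dm, config$metrics$hist_range,
                                        config$metrics$hist_bins)
    mean_whole[prov] <- mean(vapply(dm, function(d) mean(d$values), 0))
    bm <- Filter(Negate(is.null),
                 lapply(per_patient, function(p) p$bone_diffs[[prov]]))
    if (length(bm)) {
      hist_bone[[prov]] <- bin_histogram(bm, config$metrics$hist_range,
                                         config$metrics$hist_bins)
      mean_bone[prov] <- mean(vapply(bm, function(d) mean(d$values), 0))
    } else mean_bone[prov] <- NA_real_
  }

  ## per-lesion table
  gtv_table <- do.call(rbind, lapply(per_patient, function(p) {
    if (!length(p$gtv)) return(NULL)
    do.call(rbind, lapply(p$gtv, function(g) {
      cbind(patient_id = p$patient_id, g$comparisons,
            suv_max_ctac = g$suv_max[["CTAC"]],
            suv_mean_ctac = g$suv_mean[["CTAC"]])
    }))
  }))
  rownames(gtv_table) <- NULL

  ## equivalence tests
  margin <- derive_margin(config$stats$delta_petct,
                          config$stats$allowed_increase)
  alpha <- corrected_alpha(config$stats$n_tests, config$stats$base_alpha)
  rows <- list()
  for (prov in c("sCTAC", "MRAC")) for (kind in c("primary", "nodal"))
    for (metric in c("suv_max_pct_diff", "suv_mean_pct_diff")) {
      d <- gtv_table[gtv_table$provenance == prov & gtv_table$kind == kind,
                     metric]
      lbl <- sprintf("%s %s %s", prov, kind,
                     if (metric == "suv_max_pct_diff") "SUVmax" else "SUVmean")
      if (length(d) >= 2) {
        r <- withCallingHandlers(
          tost_paired(d, margin, alpha_corrected = as.numeric(alpha),
                      comparison = lbl),
          warning = function(w) {
            warnings <<- c(warnings, sprintf("%s: %s", lbl,
                                             conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        rows[[lbl]] <- data.frame(
          provenance = prov, kind = kind,
          metric = if (metric == "suv_max_pct_diff") "SUVmax" else "SUVmean",
          n = r$n, mean_diff = r$mean_diff, se_diff = r$se_diff,
          margin = r$margin, p_value = r$p_value,
          alpha_corrected = r$alpha_corrected, equivalent = r$equivalent,
          stringsAsFactors = FALSE)
      } else {
        rows[[lbl]] <- data.frame(
          provenance = prov, kind = kind,
          metric = if (metric == "suv_max_pct_diff") "SUVmax" else "SUVmean",
          n = length(d), mean_diff = if (length(d)) mean(d) else NA_real_,
          se_diff = NA_real_, margin = margin, p_value = NA_real_,
          alpha_corrected = as.numeric(alpha), equivalent = NA,
          stringsAsFactors = FALSE)
        warnings <- c(warnings, sprintf("%s: fewer than 2 paired GTVs", lbl))
      }
    }
  equivalence <- do.call(rbind, rows)
  rownames(equivalence) <- NULL

  structure(list(
    config = config, config_hash = hash_config(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("petmrac")),
    n_patients = length(per_patient),
    per_patient = per_patient, images = NULL,
    hist_whole = hist_whole, hist_bone = hist_bone,
    mean_whole_pct = mean_whole, mean_bone_pct = mean_bone,
    gtv_table = gtv_table, equivalence = equivalence,
    margin = margin, alpha_corrected = as.numeric(alpha),
    alpha_reported = attr(alpha, "reported"),
    warnings = warnings), class = "petmr_study")
}

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.petmr_study <- function(x, ...) {
  cat(sprintf("<petmr_study>  %d patients, seed %d, config %s\n",
              x$n_patients, x$seed, substr(x$config_hash, 1, 8)))
  cat(sprintf("  whole-image mean SUV difference: sCTAC %+.2f%%, MRAC %+.2f%%\n",
              x$mean_whole_pct["sCTAC"], x$mean_whole_pct["MRAC"]))
  cat(sprintf("  bone-region mean SUV difference: sCTAC %+.2f%%, MRAC %+.2f%%\n",
              x$mean_bone_pct["sCTAC"], x$mean_bone_pct["MRAC"]))
  cat(sprintf("  equivalence margin %.2f%%, corrected alpha %.3f (%.5f)\n",
              x$margin, x$alpha_reported, x$alpha_corrected))
  eq <- x$equivalence
  for (i in seq_len(nrow(eq)))
    cat(sprintf("  %-6s %-7s %-7s n=%2d  mean %+5.2f%%  p=%s  %s\n",
                eq$provenance[i], eq$kind[i], eq$metric[i], eq$n[i],
                eq$mean_diff[i],
                ifelse(is.na(eq$p_value[i]), "NA",
                       sprintf("%.3f", eq$p_value[i])),
                ifelse(is.na(eq$equivalent[i]), "(untestable)",
                       ifelse(eq$equivalent[i], "EQUIVALENT",
                              "not equivalent"))))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Summarise delineation metrics per GTV kind and method
#'
#' @param object a `petmr_study`.
#' @param ... unused.
#' @return Data frame: mean, SE, min, max for DSC, DTA mean/max and volume
#'   difference per (kind, provenance); printed together with the
#'   equivalence table.
#' @export
summary.petmr_study <- function(object, ...) {
  g <- object$gtv_table
  agg <- function(v) c(mean = mean(v), se = if (length(v) > 1)
    sd(v) / sqrt(length(v)) else 0, min = min(v), max = max(v))
  out <- list()
  for (kind in unique(g$kind)) for (prov in c("MRAC", "sCTAC")) {
    sub <- g[g$kind == kind & g$provenance == prov, ]
    if (!nrow(sub)) next
    for (metric in c("dsc", "dta_mean_mm", "dta_max_mm", "volume_pct_diff")) {
      out[[length(out) + 1]] <- data.frame(
        kind = kind, provenance = prov, metric = metric, n = nrow(sub),
        t(agg(sub[[metric]])), stringsAsFactors = FALSE)
    }
  }
  delin <- do.call(rbind, out)
  res <- list(delineation = delin, equivalence = object$equivalence,
              mean_whole_pct = object$mean_whole_pct,
              mean_bone_pct = object$mean_bone_pct)
  class(res) <- "summary.petmr_study"
  res
}

#' @export
print.summary.petmr_study <- function(x, ...) {
  cat("Delineation metrics (mean / SE / min / max):\n")
  print(x$delineation, digits = 3, row.names = FALSE)
  cat("\nEquivalence tests:\n")
  print(x$equivalence, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot the cohort SUV-difference histograms
#'
#' Mean per-bin voxel fraction across patients with a +-1 SE band, for the
#' sCTAC and MRAC whole-image (or bone-region) difference distributions.
#'
#' @param x a `petmr_study`.
#' @param region "whole" or "bone".
#' @param xlim x-axis limits (%).
#' @param ... passed to [graphics::plot()].
#' @export
plot.petmr_study <- function(x, region = c("whole", "bone"),
                             xlim = c(-40, 40), ...) {
  region <- match.arg(region)
  hists <- if (region == "whole") x$hist_whole else x$hist_bone
  if (!length(hists)) stop("no histograms for region ", region, call. = FALSE)
  cols <- c(sCTAC = "forestgreen", MRAC = "steelblue")
  ymax <- max(vapply(hists, function(h) max(h$mean_per_bin + h$se_per_bin), 0))
  graphics::plot(NULL, xlim = xlim, ylim = c(0, ymax * 1.05),
                 xlab = "SUV difference to CTAC [%]",
                 ylab = "voxels [% of external contour]",
                 main = sprintf("%s-image SUV differences", region), ...)
  for (prov in names(hists)) {
    h <- hists[[prov]]
    graphics::polygon(c(h$bin_mid, rev(h$bin_mid)),
                      c(h$mean_per_bin + h$se_per_bin,
                        rev(pmax(h$mean_per_bin - h$se_per_bin, 0))),
                      col = grDevices::adjustcolor(cols[prov], 0.25),
                      border = NA)
    graphics::lines(h$bin_mid, h$mean_per_bin, col = cols[prov], lwd = 2)
  }
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", legend = names(hists), col = cols[names(hists)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Write the study report as CSV tables, JSON and a text summary
#'
#' Writes `equivalence.csv` (one row per comparison), `gtv_metrics.csv`
#' (one row per lesion per evaluated provenance), `delineation_summary.csv`
#' (mean/SE/min/max per metric, kind and method), `histogram_whole.csv` and
#' `histogram_bone.csv` (bin centre, mean and SE per provenance),
#' `report.json` (scalars and tables) and `summary.txt`.
#'
#' @param report a `petmr_study`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
render_tables <- function(report, outdir) {
  stopifnot(inherits(report, "petmr_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- summary(report)
  write.csv(report$equivalence, file.path(outdir, "equivalence.csv"),
            row.names = FALSE)
  write.csv(report$gtv_table, file.path(outdir, "gtv_metrics.csv"),
            row.names = FALSE)
  write.csv(s$delineation, file.path(outdir, "delineation_summary.csv"),
            row.names = FALSE)
  hist_df <- function(hists) do.call(rbind, lapply(names(hists), function(p) {
    h <- hists[[p]]
    data.frame(provenance = p, bin_mid = h$bin_mid,
               mean_pct = h$mean_per_bin, se_pct = h$se_per_bin)
  }))
  write.csv(hist_df(report$hist_whole),
            file.path(outdir, "histogram_whole.csv"), row.names = FALSE)
  if (length(report$hist_bone))
    write.csv(hist_df(report$hist_bone),
              file.path(outdir, "histogram_bone.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    seed = report$seed, config_hash = report$config_hash,
    package_version = report$package_version,
    n_patients = report$n_patients, margin_pct = report$margin,
    alpha_corrected = report$alpha_corrected,
    mean_whole_pct = as.list(report$mean_whole_pct),
    mean_bone_pct = as.list(report$mean_bone_pct),
    equivalence = report$equivalence, warnings = report$warnings),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  con <- file(file.path(outdir, "summary.txt"), "w")
  sink(con); print(report); cat("\n"); print(s); sink()
  close(con)
  invisible(outdir)
}
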