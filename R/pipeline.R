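#' Axial angular difference
#'
#' Smallest difference between two orientations on the axial (period-180)
#' circle, in degrees: `axialDiff(175, 5)` is 10, and the maximum possible
#' difference is 90.
#'
#' @param a,b angles in degrees.
#' @return Non-negative difference in `[0, 90]`.
#' @export
axialDiff <- function(a, b) {
  d <- abs(((a - b) %% 180))
  pmin(d, 180 - d)
}

#' Cross-modality comparison of alignment metrics
#'
#' Joins per-location alignment from the three branches -- PRS (amplitude
#' `A` and angle `beta_PRS`), discrete fiber images (index `S` and mean
#' axis), and the continuum model (`alpha`, equivalent `S`, `beta_model`)
#' -- into a comparison table.  Each modality's magnitude is normalized by
#' its own within-sample maximum (`gamma = A/A_max`, `alpha/alpha_max`,
#' `S/S_max`), and angles are compared on the axial circle.
#'
#' @param prs data.frame from [summarizeAlignment()] (or NULL).
#' @param image data.frame with columns `location`, `S`, `mean_axis_deg`
#'   (or NULL).
#' @param model `regions` data.frame from [alignmentMap()] (or NULL).
#' @return List of class `ComparisonTable`: `gamma` (location x modality),
#'   `angles` (location x modality, degrees), `S` (raw alignment indices
#'   where a modality provides one), and `long` (tidy rows).
#' @export
compareModalities <- function(prs = NULL, image = NULL, model = NULL) {
  rows <- list()
  if (!is.null(prs))
    rows$PRS <- data.frame(location = prs$location, modality = "PRS",
                           gamma = prs$A_mean / max(prs$A_mean),
                           angle_deg = prs$beta_prs_deg,
                           extra = prs$A_mean, S = NA_real_)
  if (!is.null(image))
    rows$image <- data.frame(location = image$location, modality = "image",
                             gamma = image$S / max(image$S),
                             angle_deg = image$mean_axis_deg,
                             extra = image$S, S = image$S)
  if (!is.null(model))
    rows$model <- data.frame(location = model$location, modality = "model",
                             gamma = model$alpha / max(model$alpha),
                             angle_deg = model$beta_model_deg,
                             extra = model$alpha, S = model$S_equiv)
  if (length(rows) < 2)
    stop("need at least two modalities to compare")
  long <- do.call(rbind, rows)
  locs <- Reduce(intersect, lapply(rows, function(r) r$location))
  if (!length(locs)) stop("no overlapping locations across modalities")
  wide <- function(col) {
    out <- data.frame(location = locs)
    for (m in names(rows)) {
      r <- rows[[m]]
      out[[m]] <- r[[col]][match(locs, r$location)]
    }
    out
  }
  structure(list(gamma = wide("gamma"), angles = wide("angle_deg"),
                 S = wide("S"), long = long),
            class = "ComparisonTable")
}

#' Run the full three-branch pipeline from a configuration
#'
#' Configuration-driven orchestration: a YAML file (or equivalent list)
#' describes the PRS, image and model branches; each present branch is
#' executed (synthetic generation, preprocessing, PCA projection and sine
#' fits; fiber-table statistics; FE contraction, strain fitting and
#' kinematic alignment), intermediate artifacts are written to `outDir`,
#' and the cross-modality [compareModalities()] tables are produced.  A
#' `run_log.txt` records the seed and configuration for reproducibility:
#' rerunning with the same config and seed reproduces every artifact.
#'
#' Config schema (all branches optional, at least two needed for the
#' comparison):
#' \preformatted{
#' seed: 1
#' prs:
#'   locations: {CE: {phase_deg: 75, m: 0.45}, ME: {...}, MC: {...}}
#'   noise_sd: 1
#'   preprocess: {baseline_order: 11, sg_polyorder: 3, sg_window: 11,
#'                crop_lo: 1400, crop_hi: 1800}
#' image:
#'   locations: {CE: {n: 150, mean_deg: 129.1, sd_deg: 25}, ...}
#' model:
#'   element_size: 0.1
#'   target_area_shrinkage: 0.6   # or eps_s: 0.6
#' }
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param outDir output directory for artifacts.
#' @return Invisibly, a list with the branch results and the
#'   `ComparisonTable`.
#' @export
runPipeline <- function(config, outDir = tempfile("fiberalign_run_")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1
  prs_sum <- image_sum <- model_reg <- NULL

  if (!is.null(cfg$prs)) {
    pc <- cfg$prs$preprocess
    pcfg <- preprocessConfig(
      baselineOrder = pc$baseline_order %||% 11,
      sgPolyorder = pc$sg_polyorder %||% 3,
      sgWindow = pc$sg_window %||% 11,
      cropLo = pc$crop_lo %||% 1400, cropHi = pc$crop_hi %||% 1800)
    noise <- cfg$prs$noise_sd %||% 1
    ref_model <- spectrumModel(noiseSd = noise, phaseDeg = 90)
    loading <- deriveLoading(preprocessSpectra(
      genReferenceSet(ref_model, seed = seed), pcfg))
    scores <- list()
    for (loc in names(cfg$prs$locations)) {
      lc <- cfg$prs$locations[[loc]]
      m <- spectrumModel(noiseSd = noise,
                         phaseDeg = lc$phase_deg %||% 90)
      m$bands$m[m$bands$m > 0] <- lc$m %||% 0.5
      set <- genAcquisitionSet(m, location = loc,
                               phaseJitterSd = lc$phase_jitter_sd %||% 0,
                               seed = seed + match(loc,
                                 names(cfg$prs$locations)))
      pp <- preprocessSpectra(set, pcfg)
      scores[[loc]] <- projectPC1(pp, loading)
    }
    prs_scores <- do.call(rbind, scores)
    prs_sum <- summarizeAlignment(prs_scores)
    write.csv(prs_sum, file.path(outDir, "prs_alignment.csv"),
              row.names = FALSE)
  }

  if (!is.null(cfg$image)) {
    rows <- lapply(names(cfg$image$locations), function(loc) {
      lc <- cfg$image$locations[[loc]]
      fs <- if (!is.null(lc$table)) readFiberTable(lc$table)
            else genFiberAngles(lc$n %||% 150, lc$mean_deg %||% 90,
                                lc$sd_deg %||% 30,
                                seed = seed + 100 +
                                  match(loc, names(cfg$image$locations)))
      ai <- alignmentIndex(fs)
      data.frame(location = loc, S = ai$S,
                 mean_axis_deg = ai$mean_axis_deg,
                 theta_sd_deg = ai$theta_sd_deg, n_fibers = ai$n_fibers)
    })
    image_sum <- do.call(rbind, rows)
    write.csv(image_sum, file.path(outDir, "image_alignment.csv"),
              row.names = FALSE)
  }

  if (!is.null(cfg$model)) {
    mc <- cfg$model
    geo <- tissueGeometry(elementSize = mc$element_size %||% 0.1)
    mesh <- buildMesh(geo)
    mat <- tissueMaterial(E = mc$E %||% 700, nu = mc$nu %||% 0.4)
    if (!is.null(mc$target_area_shrinkage)) {
      fit <- fitShrinkageStrain(mc$target_area_shrinkage, mesh, mat,
                                grid = seq(0, mc$eps_max %||% 0.7,
                                           by = mc$eps_step %||% 0.05))
      field <- fit$field
      write.csv(fit$sweep, file.path(outDir, "shrinkage_sweep.csv"),
                row.names = FALSE)
    } else {
      field <- solveContraction(mesh, mat, mc$eps_s %||% 0.6)
    }
    map <- alignmentMap(mesh, field)
    model_reg <- map$regions
    writeAlignmentMap(map, file.path(outDir, "alignment_map.csv"))
    write.csv(model_reg, file.path(outDir, "model_regions.csv"),
              row.names = FALSE)
    writeVTK(mesh, field, file.path(outDir, "displacement.vtk"))
  }

  cmp <- NULL
  nbranch <- sum(!vapply(list(prs_sum, image_sum, model_reg), is.null,
                         logical(1)))
  if (nbranch >= 2) {
    cmp <- compareModalities(prs = prs_sum, image = image_sum,
                             model = model_reg)
    write.csv(cmp$gamma, file.path(outDir, "comparison_gamma.csv"),
              row.names = FALSE)
    write.csv(cmp$angles, file.path(outDir, "comparison_angles.csv"),
              row.names = FALSE)
    write.csv(cmp$S, file.path(outDir, "comparison_S.csv"),
              row.names = FALSE)
  }
  writeLines(c(sprintf("seed: %s", seed),
               sprintf("time: %s", format(Sys.time())),
               "config:", yaml::as.yaml(cfg)),
             file.path(outDir, "run_log.txt"))
  invisible(list(prs = prs_sum, image = image_sum, model = model_reg,
                 comparison = cmp, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
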