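#' Configuration of a pipeline run
#'
#' @param input_root Directory holding `subject_*/<condition>/` NIfTI sets
#'   (see [simulate_cohort()] for the layout).
#' @param output_root Directory for per-subject artifacts and cohort
#'   tables.
#' @param template_condition Condition used as the template (reference)
#'   position; all motion is reported as displacement of template voxels.
#' @param conditions Moving conditions to register against the template.
#' @param registration Named list of solver settings: `alpha`, `beta`,
#'   `levels`, `max_iter`, `tol_rel`, `smoothing_sigma`, `rigid_levels`,
#'   `crop_margin_vox`.
#' @param allow_partial Keep going when individual subjects fail
#'   (quarantining them) instead of aborting the cohort.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(input_root, output_root = file.path(input_root, "out"),
                       template_condition = "reference",
                       conditions = c("internal", "external"),
                       registration = list(), allow_partial = FALSE,
                       seed = 1) {
  reg <- utils::modifyList(list(alpha = 1.0, beta = 0.1, levels = 3,
                                max_iter = 50, tol_rel = 1e-4,
                                smoothing_sigma = 1, rigid_levels = 3,
                                crop_margin_vox = 6), registration)
  structure(list(input_root = input_root, output_root = output_root,
                 template_condition = template_condition,
                 conditions = conditions, registration = reg,
                 allow_partial = allow_partial, seed = seed),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [save_config()] or by hand.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

subject_file <- function(config, subject_id, condition, name) {
  p <- file.path(config$input_root, subject_id, condition, name)
  if (!file.exists(p)) stop("missing input file: ", p)
  p
}

load_subject_set <- function(config, subject_id, condition) {
  list(volume = load_volume(subject_file(config, subject_id, condition,
                                         "volume.nii.gz")),
       tibia = load_mask(subject_file(config, subject_id, condition,
                                      "tibia.nii.gz"), "tibia"),
       MM = load_mask(subject_file(config, subject_id, condition,
                                   "meniscus_medial.nii.gz"),
                      "meniscus_medial"),
       LM = load_mask(subject_file(config, subject_id, condition,
                                   "meniscus_lateral.nii.gz"),
                      "meniscus_lateral"))
}

subject_laterality <- function(config, subject_id) {
  p <- file.path(config$input_root, subject_id, "meta.yaml")
  if (file.exists(p)) {
    lat <- yaml::read_yaml(p)$laterality
    if (!is.null(lat)) return(lat)
  }
  "right"
}

# crop a grid to the bounding box of a logical array plus a margin
crop_box <- function(arr, margin, dims) {
  idx <- which(arr, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(dims, apply(idx, 2, max) + margin)
  # keep at least 8 voxels per axis so the multilevel pyramid is usable
  for (ax in 1:3) {
    while (hi[ax] - lo[ax] + 1L < 8L && (lo[ax] > 1L || hi[ax] < dims[ax])) {
      if (lo[ax] > 1L) lo[ax] <- lo[ax] - 1L
      if (hi[ax] - lo[ax] + 1L < 8L && hi[ax] < dims[ax]) hi[ax] <- hi[ax] + 1L
    }
  }
  list(lo = lo, hi = hi)
}

crop_volume <- function(vol, box) {
  sub <- vol$data[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                  box$lo[3]:box$hi[3], drop = FALSE]
  new_origin <- as.numeric(voxel_to_world(vol, matrix(box$lo - 1L, 1)))
  if (inherits(vol, "label_mask"))
    label_mask(sub, vol$spacing, new_origin, vol$orientation,
               label_name = vol$label_name)
  else
    knee_volume(sub, vol$spacing, new_origin, vol$orientation)
}

#' Run the full pipeline for one subject
#'
#' Stage order is fixed: (1) rigid registration of each moving position to
#' the template, restricted to the tibia (providing the common
#' tibia-anchored frame); (2) resampling of the moving masks into that
#' frame; (3) deformable registration of the menisci (both menisci in one
#' field, on a grid cropped to the meniscus neighbourhood); (4) cropping of
#' the field with the template meniscus masks; (5) arc-length partition and
#' (6) projection onto the PCA-derived anatomical axes.  All artifacts
#' (rigid parameters, deformation fields, segment labels, objective traces,
#' motion CSV) are persisted under `output_root/subject_id`; a rerun with
#' the same config reproduces the CSV bit-for-bit.
#'
#' @param config A [run_config()].
#' @param subject_id Subject directory name, e.g. `"subject_01"`.
#' @return Data.frame of per-segment motions (one row per condition x
#'   meniscus x segment).
#' @export
run_subject <- function(config, subject_id) {
  reg <- config$registration
  lat <- subject_laterality(config, subject_id)
  tpl <- load_subject_set(config, subject_id, config$template_condition)
  outdir <- file.path(config$output_root, subject_id)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  axes <- anatomical_axes(tpl$MM, tpl$LM, lat)
  labels <- list(MM = partition_arch(tpl$MM, axes),
                 LM = partition_arch(tpl$LM, axes))
  seg_img <- knee_volume(labels$MM$data + labels$LM$data, tpl$MM$spacing,
                         tpl$MM$origin, tpl$MM$orientation)
  save_volume(as_segment_nifti(seg_img),
              file.path(outdir, "segment_labels.nii.gz"))

  tpl_union <- label_mask(pmin(tpl$MM$data + tpl$LM$data, 1),
                          tpl$MM$spacing, tpl$MM$origin, tpl$MM$orientation,
                          label_name = "menisci")
  weights <- objective_weights(alpha = reg$alpha, beta = reg$beta)
  sched <- multilevel_schedule(n_levels = reg$levels,
                               max_iter_per_level = reg$max_iter,
                               tol_rel = reg$tol_rel,
                               smoothing_sigma = reg$smoothing_sigma)

  rows <- list()
  for (cond in config$conditions) {
    mov <- load_subject_set(config, subject_id, cond)
    rig <- register_rigid(tpl$volume, mov$volume, tpl$tibia,
                          levels = reg$rigid_levels)
    yaml::write_yaml(list(angles = rig$angles, translation = rig$translation,
                          center = rig$center,
                          objective = as.list(attr(rig, "objective"))),
                     file.path(outdir, paste0("rigid_", cond, ".yaml")))

    mov_mm <- resample(mov$MM, rig, "nearest", grid = tpl$volume)
    mov_lm <- resample(mov$LM, rig, "nearest", grid = tpl$volume)
    mov_union <- label_mask(pmin(mov_mm$data + mov_lm$data, 1),
                            tpl$MM$spacing, tpl$MM$origin,
                            tpl$MM$orientation, label_name = "menisci")

    box <- crop_box(tpl_union$data > 0.5 | mov_union$data > 0.5,
                    reg$crop_margin_vox, dim(tpl_union$data))
    tpl_c <- crop_volume(tpl_union, box)
    mov_c <- crop_volume(mov_union, box)
    pairs <- list(list(template = crop_volume(tpl$MM, box),
                       moving = crop_volume(mov_mm, box)),
                  list(template = crop_volume(tpl$LM, box),
                       moving = crop_volume(mov_lm, box)))
    pairs <- Filter(function(p) sum(p$template$data) > 0 &&
                      sum(p$moving$data) > 0, pairs)
    init <- if (length(pairs)) init_field_from_centroids(pairs) else NULL
    fld_c <- register_deformable(tpl_c, mov_c, weights, sched, init = init)

    # embed the cropped field into the full template grid (zero outside)
    u_full <- matrix(0, prod(dim(tpl_union$data)), 3)
    full_idx <- array(seq_len(prod(dim(tpl_union$data))),
                      dim(tpl_union$data))[box$lo[1]:box$hi[1],
                                           box$lo[2]:box$hi[2],
                                           box$lo[3]:box$hi[3]]
    u_full[as.vector(full_idx), ] <- field_matrix(fld_c)
    fld <- deformation_field(u_full, tpl$volume)
    save_field(fld, file.path(outdir, paste0("field_", cond, ".nii.gz")))
    utils::write.csv(attr(fld_c, "trace"),
                     file.path(outdir, paste0("trace_", cond, ".csv")),
                     row.names = FALSE)

    for (m in c("MM", "LM")) {
      sm <- segment_motion(fld, labels[[m]], axes, meniscus_id = m)
      sm$subject <- subject_id; sm$laterality <- lat; sm$condition <- cond
      rows[[length(rows) + 1]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("subject", "laterality", "condition", "meniscus", "segment",
                 "avg_mm", "ml_mm", "ap_mm", "n_voxels")]
  rownames(out) <- NULL
  utils::write.csv(out, file.path(outdir, "motion.csv"), row.names = FALSE)
  out
}

as_segment_nifti <- function(vol) {
  label_mask_like <- knee_volume(vol$data, vol$spacing, vol$origin,
                                 vol$orientation)
  class(label_mask_like) <- c("label_mask", "knee_volume")
  label_mask_like$label_name <- "segments (1=AH, 2=IH, 3=PH)"
  label_mask_like
}

#' Run the full pipeline for a cohort
#'
#' Processes every `subject_*` directory under the input root (order does
#' not affect any output), aggregates per-segment motions, computes the
#' cohort summary and the paired Wilcoxon comparison grid, and writes
#' `motions.csv`, `summary.csv`, `comparisons.csv` and a Markdown report
#' with per-segment motion-vector figures.
#'
#' @param config A [run_config()].
#' @return List of class `cohort_result`: `motions`, `summary`, `tests`,
#'   `failed` (quarantined subject ids), `output_root`.
#' @export
run_cohort <- function(config) {
  subjects <- sort(basename(list.dirs(config$input_root, recursive = FALSE)))
  subjects <- grep("^subject_", subjects, value = TRUE)
  if (length(subjects) < 2L) stop("need at least 2 subjects under ",
                                  config$input_root)
  motions <- list(); failed <- character()
  for (sid in subjects) {
    res <- tryCatch(run_subject(config, sid), error = function(e) e)
    if (inherits(res, "error")) {
      if (!config$allow_partial)
        stop("subject ", sid, " failed: ", conditionMessage(res))
      warning("quarantined ", sid, ": ", conditionMessage(res))
      failed <- c(failed, sid)
    } else motions[[sid]] <- res
  }
  if (length(motions) < 2L) stop("fewer than 2 subjects completed")
  motions <- do.call(rbind, motions)
  rownames(motions) <- NULL
  summ <- summarize_cohort(motions)
  tests <- compare_conditions(motions, conditions = config$conditions)
  dir.create(config$output_root, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(motions, file.path(config$output_root, "motions.csv"),
                   row.names = FALSE)
  utils::write.csv(summ, file.path(config$output_root, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(tests, file.path(config$output_root, "comparisons.csv"),
                   row.names = FALSE)
  out <- structure(list(motions = motions, summary = summ, tests = tests,
                        failed = failed, output_root = config$output_root),
                   class = "cohort_result")
  write_report(out, config)
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>", length(unique(x$motions$subject)), "subjects,",
      nrow(x$tests), "comparisons\n")
  whole <- x$summary[x$summary$segment == "whole", ]
  print(whole, row.names = FALSE)
  invisible(x)
}

#' Per-segment motion-vector plot
#'
#' Draws the cohort-mean (ML, AP) motion vector of each segment for both
#' menisci in one condition, in the anatomical plane (positive ML =
#' lateral, positive AP = posterior).
#'
#' @param summary A [summarize_cohort()] result.
#' @param condition Condition to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_segment_vectors <- function(summary, condition, ...) {
  sub <- summary[summary$condition == condition & summary$segment != "whole", ]
  lim <- max(abs(c(sub$mean)), 1) * 1.2
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "ML (mm, + lateral)", ylab = "AP (mm, + posterior)",
                 main = paste("Segment motion vectors,", condition), ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  cols <- c(AH = "goldenrod", IH = "firebrick", PH = "navy")
  off <- c(MM = -0.25, LM = 0.25)
  for (men in c("MM", "LM")) for (seg in c("AH", "IH", "PH")) {
    ml <- sub$mean[sub$meniscus == men & sub$segment == seg &
                     sub$measure == "ml"]
    ap <- sub$mean[sub$meniscus == men & sub$segment == seg &
                     sub$measure == "ap"]
    if (!length(ml)) next
    graphics::arrows(off[[men]], 0, off[[men]] + ml, ap, col = cols[[seg]],
                     lwd = 2, length = 0.08)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

write_report <- function(result, config) {
  outdir <- config$output_root
  figs <- character()
  if (capabilities("png")) {
    for (cond in config$conditions) {
      f <- file.path(outdir, paste0("vectors_", cond, ".png"))
      grDevices::png(f, width = 800, height = 800, res = 120)
      plot_segment_vectors(result$summary, cond)
      grDevices::dev.off()
      figs <- c(figs, basename(f))
    }
  }
  fmt_summary <- function(cond) {
    sub <- result$summary[result$summary$condition == cond, ]
    wide <- stats::reshape(sub[, c("meniscus", "segment", "measure", "mean", "sd")],
                           idvar = c("meniscus", "segment"),
                           timevar = "measure", direction = "wide")
    hdr <- "| meniscus | segment | Avg (SD) | ML (SD) | AP (SD) |\n|---|---|---|---|---|"
    rows <- apply(wide, 1, function(r)
      sprintf("| %s | %s | %.2f (%.2f) | %.2f (%.2f) | %.2f (%.2f) |",
              r[["meniscus"]], r[["segment"]],
              as.numeric(r[["mean.avg"]]), as.numeric(r[["sd.avg"]]),
              as.numeric(r[["mean.ml"]]), as.numeric(r[["sd.ml"]]),
              as.numeric(r[["mean.ap"]]), as.numeric(r[["sd.ap"]])))
    paste(c(hdr, rows), collapse = "\n")
  }
  lines <- c(
    "# Meniscal motion cohort report", "",
    sprintf("Subjects analysed: %d (quarantined: %s)",
            length(unique(result$motions$subject)),
            if (length(result$failed)) paste(result$failed, collapse = ", ")
            else "none"), "",
    "Positive ML = lateral movement, positive AP = posterior movement (mm).",
    "")
  for (cond in config$conditions)
    lines <- c(lines, sprintf("## Meniscus movements, %s rotation", cond), "",
               fmt_summary(cond), "")
  lines <- c(lines, "## Wilcoxon signed-rank comparisons",
             "", "No adjustment for multiple testing (exploratory analysis).", "",
             "| comparison | segment | measure | W | p |", "|---|---|---|---|---|",
             apply(result$tests, 1, function(r)
               sprintf("| %s | %s | %s | %s | %.4g |", r[["comparison"]],
                       r[["segment"]], r[["measure"]], r[["W"]],
                       as.numeric(r[["p_value"]]))),
             "")
  if (length(figs))
    lines <- c(lines, "## Figures", "",
               sprintf("![segment vectors](%s)", figs), "")
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(file.path(outdir, "report.md"))
}
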