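#' Specification of a simulated cohort
#'
#' Defines the generating distributions of a phantom cohort: per-condition,
#' per-meniscus mean and SD of the in-plane meniscal translation expressed
#' in anatomical components (`ml`, positive = lateral; `ap`, positive =
#' posterior), plus tibial rotation and whole-knee repositioning noise.
#' The default generating means reproduce the published whole-meniscus
#' pattern for internal/external tibial rotation under load: under internal
#' rotation the LM glides posterior-medially and the MM slightly
#' anterior-laterally; under external rotation the roles reverse — i.e. MM
#' and LM move in opposite AP directions in both conditions.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Named list per condition; each entry is a list with
#'   `MM` and `LM` (each `list(ml = c(mean, sd), ap = c(mean, sd))` in mm)
#'   and `rotation_deg = c(mean, sd)` for the tibial in-plane rotation.
#' @param rigid_angle_sd_deg,rigid_trans_sd_mm SD of the random whole-knee
#'   repositioning between scans.
#' @param phantom A [phantom_spec()]; the default uses a coarser 1.2 x 1.2
#'   x 1.0 mm grid with anatomically spaced menisci so a full cohort runs
#'   at desk scale.
#' @param window_width Per-meniscus window ramp length (mm), see
#'   [ground_truth_motion()].
#' @param seed Base RNG seed for the cohort.
#' @export
cohort_spec <- function(n_subjects = 10,
                        conditions = list(
                          internal = list(
                            MM = list(ml = c(0.14, 0.45), ap = c(-1.66, 0.99)),
                            LM = list(ml = c(-1.19, 0.71), ap = c(4.32, 1.15)),
                            rotation_deg = c(10, 2)),
                          external = list(
                            MM = list(ml = c(1.91, 0.89), ap = c(5.70, 1.49)),
                            LM = list(ml = c(-0.22, 0.58), ap = c(-3.51, 1.83)),
                            rotation_deg = c(-10, 2))),
                        rigid_angle_sd_deg = 1, rigid_trans_sd_mm = 1.5,
                        phantom = cohort_phantom_spec(),
                        window_width = 18, seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  for (cond in conditions) for (m in c("MM", "LM")) for (cmp in c("ml", "ap"))
    if (cond[[m]][[cmp]][2] < 0) stop("SDs must be non-negative")
  if (rigid_angle_sd_deg < 0 || rigid_trans_sd_mm < 0)
    stop("SDs must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions,
                 rigid_angle_sd_deg = rigid_angle_sd_deg,
                 rigid_trans_sd_mm = rigid_trans_sd_mm,
                 phantom = phantom, window_width = window_width,
                 seed = seed),
            class = "cohort_spec")
}

#' Phantom geometry used for cohort simulations
#'
#' A coarser, wider-field variant of [phantom_spec()] (1.2 x 1.2 x 1.0 mm,
#' 115 x 115 x 40 mm field of view) with menisci separated as on a real
#' tibial plateau, keeping a 20-subject-scan cohort tractable on one CPU.
#' @param laterality `"right"` or `"left"`.
#' @export
cohort_phantom_spec <- function(laterality = "right") {
  phantom_spec(shape = c(96, 96, 40), spacing = c(1.2, 1.2, 1.0),
               laterality = laterality,
               tibia_radius = 38, tibia_height = 8, plateau_z = -4,
               menisci = list(
                 MM = list(center_offset = 24, r_inner = 6.5, r_outer = 13,
                           span_deg = 300, thickness = 4),
                 LM = list(center_offset = 24, r_inner = 6, r_outer = 12,
                           span_deg = 250, thickness = 4)))
}

#' Simulate a phantom cohort with known ground truth
#'
#' Draws per-subject motion parameters from the generating distributions of
#' a [cohort_spec()], renders template (reference) and per-condition moving
#' images with [make_phantom()] / [apply_motion()], writes them in the
#' pipeline's input layout, and returns the analytic ground-truth segment
#' motions.
#'
#' Layout per subject: `subject_<id>/<condition>/{volume.nii.gz,
#' tibia.nii.gz, meniscus_medial.nii.gz, meniscus_lateral.nii.gz}` plus
#' `truth_field.nii.gz`, `truth_motion.yaml` for moving conditions and a
#' top-level `meta.yaml` naming the laterality.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Directory to write the cohort into.
#' @param write_truth_fields Also write dense truth fields (larger files).
#' @return List: `truth` (tidy data.frame of ground-truth per-segment
#'   motions: subject, laterality, condition, meniscus, segment, avg_mm,
#'   ml_mm, ap_mm, n_voxels), `draws` (per-subject drawn parameters),
#'   `dir`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = tempfile("cohort_"),
                            write_truth_fields = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  truth <- list(); draws <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("subject_%02d", s)
    laterality <- if (s %% 2 == 1) "right" else "left"
    pspec <- spec$phantom
    pspec$laterality <- laterality
    noise_seed <- sample.int(2^30, 1)
    ph <- make_phantom(pspec, seed = noise_seed)

    # anatomical axes of this subject's template, for the anatomical ->
    # world conversion of the generating draws
    side <- if (laterality == "right") 1 else -1
    lat_dir <- c(side, 0, 0)   # lateral in world (RAS)
    post_dir <- c(0, -1, 0)    # posterior in world

    sdir <- file.path(out_dir, sid)
    dir.create(file.path(sdir, "reference"), recursive = TRUE,
               showWarnings = FALSE)
    yaml::write_yaml(list(subject = sid, laterality = laterality),
                     file.path(sdir, "meta.yaml"))
    write_set <- function(set, cdir) {
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      save_volume(set$volume, file.path(cdir, "volume.nii.gz"))
      save_volume(set$tibia, file.path(cdir, "tibia.nii.gz"))
      save_volume(set$MM, file.path(cdir, "meniscus_medial.nii.gz"))
      save_volume(set$LM, file.path(cdir, "meniscus_lateral.nii.gz"))
    }
    write_set(ph, file.path(sdir, "reference"))

    # template segmentation -> axes + segment labels (shared by conditions)
    axes <- anatomical_axes(ph$MM, ph$LM, laterality)
    labels <- list(MM = partition_arch(ph$MM, axes),
                   LM = partition_arch(ph$LM, axes))

    for (cname in names(spec$conditions)) {
      cnd <- spec$conditions[[cname]]
      tr <- list()
      for (m in c("MM", "LM")) {
        ml <- stats::rnorm(1, cnd[[m]]$ml[1], cnd[[m]]$ml[2])
        ap <- stats::rnorm(1, cnd[[m]]$ap[1], cnd[[m]]$ap[2])
        tr[[m]] <- ml * lat_dir + ap * post_dir
      }
      rot <- stats::rnorm(1, cnd$rotation_deg[1], cnd$rotation_deg[2])
      grigid <- rigid_transform(
        angles = stats::rnorm(3, 0, spec$rigid_angle_sd_deg * pi / 180),
        translation = stats::rnorm(3, 0, spec$rigid_trans_sd_mm))
      # extreme tail draws can violate the smooth-invertibility bound of
      # the motion model; redraw that condition's translations (rare)
      for (try in 1:20) {
        motion <- tryCatch(
          ground_truth_motion(global_rigid = grigid,
                              tibial_rotation_deg = rot,
                              meniscus_translation = tr,
                              window_width = spec$window_width),
          error = function(e) NULL)
        if (!is.null(motion)) break
        for (m in c("MM", "LM")) {
          ml <- stats::rnorm(1, cnd[[m]]$ml[1], cnd[[m]]$ml[2])
          ap <- stats::rnorm(1, cnd[[m]]$ap[1], cnd[[m]]$ap[2])
          tr[[m]] <- ml * lat_dir + ap * post_dir
        }
      }
      if (is.null(motion))
        stop("could not draw an invertible motion for ", sid, "/", cname)
      moved <- apply_motion(ph, motion)
      cdir <- file.path(sdir, cname)
      write_set(moved, cdir)
      if (write_truth_fields)
        save_field(moved$truth_field, file.path(cdir, "truth_field.nii.gz"))
      yaml::write_yaml(list(
        condition = cname,
        tibial_rotation_deg = rot,
        global_rigid = list(angles = grigid$angles,
                            translation = grigid$translation),
        meniscus_translation = lapply(tr, as.numeric)),
        file.path(cdir, "truth_motion.yaml"))

      gt <- ground_truth_segment_motion(ph, motion, labels, axes)
      gt$subject <- sid; gt$laterality <- laterality; gt$condition <- cname
      truth[[length(truth) + 1]] <- gt
      draws[[paste(sid, cname)]] <- list(translation = tr, rotation = rot)
    }
  }
  truth <- do.call(rbind, truth)
  truth <- truth[, c("subject", "laterality", "condition", "meniscus",
                     "segment", "avg_mm", "ml_mm", "ap_mm", "n_voxels")]
  rownames(truth) <- NULL
  list(truth = truth, draws = draws, dir = out_dir)
}
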