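#' Reproducible end-to-end pipeline
#'
#' Binds the stages into one seeded run: scene synthesis, detector training,
#' whole-image detection, morphometry and group statistics, with every
#' output written under one directory together with the verbatim
#' configuration and a manifest of seeds and file hashes. Re-running with
#' the same configuration and seed reproduces all CSV/JSON outputs
#' bit-for-bit.
#'
#' @name pipeline
NULL

#' Build and validate a pipeline configuration
#'
#' @param config a named list, or a path to a YAML file with the same
#'   structure. Recognised sections (all optional, defaults shown by
#'   [default_pipeline_config()]): `seed`; `scenes` (`n_per_group`,
#'   `vesicle_preset_wt/ko`, `morpho_preset_wt/ko`, `n_train_scenes`,
#'   `image_format`); `train` (`n_patches_stage1/2`, `stage2_patch_px`,
#'   `max_epoch_stage1/2`, `patience`, `lr`); `morpho`
#'   (`gap_threshold_um`, `n_samples`, `exclusion_deg`); `stats` (`eps_nm`,
#'   `min_pts`, `min_count`, `hull`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_pipeline_config()
  for (sec in names(config)) {
    if (!sec %in% names(cfg))
      stop("pipeline config: unknown section or field '", sec, "'")
    if (is.list(cfg[[sec]])) {
      for (f in names(config[[sec]])) {
        if (!f %in% names(cfg[[sec]]))
          stop("pipeline config: unknown field '", sec, ".", f, "'")
        cfg[[sec]][[f]] <- config[[sec]][[f]]
      }
    } else cfg[[sec]] <- config[[sec]]
  }
  stopifnot(cfg$scenes$n_per_group >= 1, cfg$scenes$n_train_scenes >= 1,
            cfg$train$n_patches_stage1 >= 10, cfg$train$n_patches_stage2 >= 10,
            cfg$morpho$gap_threshold_um > 0, cfg$stats$eps_nm > 0,
            cfg$stats$min_pts >= 1, cfg$stats$min_count >= 1)
  # stage configs are validated now, before any stage runs
  train_config(1, max_epoch = cfg$train$max_epoch_stage1,
               patience = cfg$train$patience, lr = cfg$train$lr, seed = cfg$seed)
  train_config(2, max_epoch = cfg$train$max_epoch_stage2,
               patience = cfg$train$patience, lr = cfg$train$lr, seed = cfg$seed)
  stopifnot(cfg$stats$hull %in% c("largest_cluster", "all_points"),
            cfg$scenes$image_format %in% c("png", "tiff"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       scenes = list(n_per_group = 8L, n_train_scenes = 8L,
                     vesicle_preset_wt = "wt_vesicle",
                     vesicle_preset_ko = "ko_vesicle",
                     morpho_preset_wt = "wt_morpho",
                     morpho_preset_ko = "ko_morpho",
                     image_format = "png"),
       train = list(n_patches_stage1 = 2000L, n_patches_stage2 = 1200L,
                    stage2_patch_px = 16L, max_epoch_stage1 = 500L,
                    max_epoch_stage2 = 1000L, patience = 20L, lr = 2e-3),
       morpho = list(gap_threshold_um = 0.25, n_samples = 720L,
                     exclusion_deg = 20),
       stats = list(eps_nm = 200, min_pts = 3L, min_count = 3L,
                    hull = "largest_cluster"))
}

#' Run the pipeline
#'
#' Stages run in order `synth`, `train`, `detect`, `morpho`, `stats`; a
#' prefix of stages can be skipped when their outputs already exist in
#' `out_dir` (e.g. `stages = c("detect", "morpho", "stats")` reuses scenes
#' and model). Missing inputs for a requested stage raise an error naming
#' the absent artifact.
#'
#' @param config a `pipeline_config` (or list / YAML path accepted by
#'   [pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param stages character vector, contiguous suffix of the stage order.
#' @param quiet suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("synth", "train", "detect", "morpho", "stats"),
                         quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  order_all <- c("synth", "train", "detect", "morpho", "stats")
  stopifnot(all(stages %in% order_all))
  stages <- order_all[order_all %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  ext <- if (cfg$scenes$image_format == "png") "png" else "tif"

  scene_dir <- file.path(out_dir, "scenes")
  model_path <- file.path(out_dir, "model_bundle.json")
  det_path <- file.path(out_dir, "detections.json")

  groups <- c("wt", "ko")
  scene_name <- function(kind, grp, i) sprintf("%s_%s_%02d", kind, grp, i)
  n <- cfg$scenes$n_per_group

  if ("synth" %in% stages) {
    say("synth: %d vesicle + %d morphometry scenes per group", n, n)
    dir.create(scene_dir, showWarnings = FALSE)
    for (grp in groups) {
      vp <- cfg$scenes[[paste0("vesicle_preset_", grp)]]
      mp <- cfg$scenes[[paste0("morpho_preset_", grp)]]
      for (i in seq_len(n)) {
        sseed <- cfg$seed * 1000 + i + (if (grp == "ko") 500L else 0L)
        sc <- synthesize_scene(scene_params(preset = vp, seed = sseed))
        base <- file.path(scene_dir, scene_name("vesicle", grp, i))
        write_image(sc$image, paste0(base, ".", ext))
        write_scene_truth(sc$truth, paste0(base, ".json"))
        sm <- synthesize_scene(scene_params(preset = mp, seed = sseed + 250L),
                               render = FALSE)
        write_scene_truth(sm$truth, file.path(scene_dir, paste0(
          scene_name("morpho", grp, i), ".json")))
      }
    }
    for (i in seq_len(cfg$scenes$n_train_scenes)) {
      sc <- synthesize_scene(scene_params(preset = "train_vesicle",
                                          seed = cfg$seed * 1000 + 900L + i))
      base <- file.path(scene_dir, sprintf("train_%02d", i))
      write_image(sc$image, paste0(base, ".", ext))
      write_scene_truth(sc$truth, paste0(base, ".json"))
    }
  }

  read_scene <- function(base) {
    img_path <- paste0(base, ".", ext)
    if (!file.exists(img_path) || !file.exists(paste0(base, ".json")))
      stop("missing stage input: scene artifact '", base, "'")
    list(image = read_image(img_path), truth = read_scene_truth(paste0(base, ".json")))
  }

  if ("train" %in% stages) {
    say("train: stage-1 and stage-2 networks")
    tscenes <- lapply(seq_len(cfg$scenes$n_train_scenes), function(i)
      read_scene(file.path(scene_dir, sprintf("train_%02d", i))))
    ds1 <- make_patch_dataset(tscenes, n_patches = cfg$train$n_patches_stage1,
                              mode = "classify", seed = cfg$seed + 11L)
    ds2 <- make_patch_dataset(tscenes, patch_px = cfg$train$stage2_patch_px,
                              n_patches = cfg$train$n_patches_stage2,
                              mode = "segment", seed = cfg$seed + 22L)
    bundle <- train_stage(ds1, train_config(
      1, max_epoch = cfg$train$max_epoch_stage1, patience = cfg$train$patience,
      lr = cfg$train$lr, seed = cfg$seed), verbose = !quiet)
    bundle <- train_stage(ds2, train_config(
      2, max_epoch = cfg$train$max_epoch_stage2, patience = cfg$train$patience,
      lr = cfg$train$lr, seed = cfg$seed), bundle = bundle, verbose = !quiet)
    write_model_bundle(bundle, model_path)
    say("train: stage1 val acc %.4f, stage2 val acc %.4f",
        bundle$training_report$stage1$validation_accuracy,
        bundle$training_report$stage2$validation_accuracy)
  }

  if ("detect" %in% stages) {
    if (!file.exists(model_path))
      stop("missing stage input: model bundle '", model_path, "'")
    bundle <- read_model_bundle(model_path)
    say("detect: scanning %d scenes", 2L * n)
    dets <- list()
    for (grp in groups) for (i in seq_len(n)) {
      nm <- scene_name("vesicle", grp, i)
      sc <- read_scene(file.path(scene_dir, nm))
      dets[[nm]] <- detect_vesicles(bundle, sc$image)
    }
    write_detections(dets, det_path)
  }

  if ("morpho" %in% stages) {
    say("morpho: measuring %d neurons", 2L * n)
    rows <- list(); flags <- list()
    for (grp in groups) {
      truths <- lapply(seq_len(n), function(i) {
        p <- file.path(scene_dir, paste0(scene_name("morpho", grp, i), ".json"))
        if (!file.exists(p)) stop("missing stage input: annotation '", p, "'")
        read_scene_truth(p)
      })
      tb <- morphometry_table(truths,
                              ids = sprintf("%s_%02d", grp, seq_len(n)),
                              threshold_um = cfg$morpho$gap_threshold_um,
                              n_samples = cfg$morpho$n_samples,
                              exclusion_deg = cfg$morpho$exclusion_deg)
      tb$group <- grp
      rows[[grp]] <- tb
    }
    morpho <- do.call(rbind, rows)
    rownames(morpho) <- NULL
    write_table_csv(morpho, file.path(out_dir, "morphometry.csv"))
    cmp <- morpho_comparisons(morpho)
    write_table_csv(cmp, file.path(out_dir, "morphometry_comparisons.csv"))
  }

  if ("stats" %in% stages) {
    if (!file.exists(det_path))
      stop("missing stage input: detections '", det_path, "'")
    dets <- read_detections(det_path)
    say("stats: %d cells", length(dets))
    nmv <- vapply(names(dets), function(nm)
      read_scene_truth(file.path(scene_dir, paste0(nm, ".json")))$nm_per_px,
      numeric(1))
    profs <- do.call(rbind, lapply(names(dets), function(nm)
      cell_profile(dets[[nm]], cell_id = nm,
                   group = if (grepl("_wt_", nm)) "wt" else "ko",
                   min_count = cfg$stats$min_count, eps_nm = cfg$stats$eps_nm,
                   min_pts = cfg$stats$min_pts, nm_per_px = nmv[[nm]],
                   hull = cfg$stats$hull)))
    write_table_csv(profs, file.path(out_dir, "cell_profiles.csv"))
    write_table_csv(summarize_groups(profs), file.path(out_dir, "group_summary.csv"))
    cmp <- density_comparisons(profs)
    write_table_csv(cmp, file.path(out_dir, "density_comparisons.csv"))
  }

  write_manifest(cfg, out_dir)
  invisible(out_dir)
}

#' Group comparisons for the morphometry table
#'
#' Chi-square on the distant-glia flags, KS on the pooled three-gap
#' measurements, and unpaired t tests on diameter, area and circularity.
#'
#' @param morpho a [morphometry_table()] with a `group` column (two groups).
#' @return data.frame of `group_comparison` rows plus a `measure` column.
#' @export
morpho_comparisons <- function(morpho) {
  gs <- unique(morpho$group)
  stopifnot(length(gs) == 2)
  a <- morpho[morpho$group == gs[1], ]; b <- morpho[morpho$group == gs[2], ]
  gaps <- function(d) c(d$gap1_um, d$gap2_um, d$gap3_um)
  tab <- rbind(table(factor(a$gap_flag, levels = 0:1)),
               table(factor(b$gap_flag, levels = 0:1)))
  out <- list()
  out$gap_flag <- tryCatch(chi_square_2x2(tab),
                           error = function(e) NULL) # degenerate margin
  out$gap_distance <- ks_two_sample(gaps(a), gaps(b))
  for (m in c("diameter_um", "area_um2", "circularity"))
    out[[m]] <- t_test_groups(a[[m]], b[[m]])
  keep <- !vapply(out, is.null, logical(1))
  cmp <- do.call(rbind, out[keep])
  cmp$measure <- names(out)[keep]
  rownames(cmp) <- NULL
  cmp
}

#' Group comparisons for cell vesicle profiles
#'
#' Chi-square on the proportion of cells with detectable vesicles and KS on
#' the per-cell densities (cells with defined density only).
#'
#' @param profiles rows from [cell_profile()] with a two-level `group`.
#' @return data.frame of `group_comparison` rows plus a `measure` column.
#' @export
density_comparisons <- function(profiles) {
  gs <- unique(profiles$group)
  stopifnot(length(gs) == 2)
  a <- profiles[profiles$group == gs[1], ]; b <- profiles[profiles$group == gs[2], ]
  tab <- rbind(c(sum(!a$detectable), sum(a$detectable)),
               c(sum(!b$detectable), sum(b$detectable)))
  out <- list()
  out$prop_detectable <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
  da <- a$density_per_um2[!is.na(a$density_per_um2)]
  db <- b$density_per_um2[!is.na(b$density_per_um2)]
  if (length(da) && length(db)) out$density <- ks_two_sample(da, db)
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) { # degenerate margins and no defined densities
    cmp <- group_comparison("none", NA_real_, 1, c(nrow(a), nrow(b)), "")[0, ]
    cmp$measure <- character(0)
    return(cmp)
  }
  cmp <- do.call(rbind, out[keep])
  cmp$measure <- names(out)[keep]
  rownames(cmp) <- NULL
  cmp
}

# Manifest: config digest plus md5 of every CSV/JSON artifact (regenerable
# outputs only; no timestamps, so reruns are bit-identical).
write_manifest <- function(cfg, out_dir) {
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE,
               pattern = "\\.(csv|json|yaml|png|tif)$"),
    "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  obj <- list(format = "temquant_manifest_v1",
              package_version = as.character(utils::packageVersion("temquant")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = cfg$seed,
              config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
              files = hashes)
  jsonlite::write_json(obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
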