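#' Reading and writing images, annotations, detections and models
#'
#' Images are 8/16-bit grayscale PNG or TIFF. Scene truth, detections and
#' model bundles are JSON. All pixel coordinates on disk are 0-based (x, y)
#' with x = column, y = row, and every artifact records its nm-per-pixel
#' scale. JSON/CSV artifacts round-trip losslessly.
#'
#' @name io
NULL

#' @rdname io
#' @param img numeric matrix in [0, 1].
#' @param path output path; format from the extension (.png, .tif/.tiff).
#' @param bits bit depth (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  img <- pmin(pmax(unclass(img), 0), 1)
  attr(img, "nm_per_px") <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path) # writePNG stores doubles as 8-bit
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' @rdname io
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a scene's ground truth as JSON
#'
#' Contours are vertex lists; vesicles are stored as centre + radius plus a
#' run-length-encoded binary mask.
#'
#' @param truth a `scene_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_truth <- function(truth, path) {
  enc_contour <- function(m) list(x = m[, 1], y = m[, 2])
  ves <- lapply(seq_len(truth$vesicle_count), function(i) {
    mk <- truth$vesicle_masks[[i]]
    r <- rle(as.integer(mk$mask))
    list(center = truth$vesicle_centers[i, ],
         radius_px = truth$vesicle_radii_px[i],
         mask = list(offset = mk$offset, nrow = nrow(mk$mask),
                     ncol = ncol(mk$mask),
                     rle_lengths = r$lengths, rle_values = r$values))
  })
  obj <- list(format = "temquant_scene_truth_v1",
              image_size_px = truth$image_size_px,
              nm_per_px = truth$nm_per_px,
              center_px = truth$center_px,
              cytoplasm_area_um2 = truth$cytoplasm_area_um2,
              neuron_contour = enc_contour(truth$neuron_contour),
              sgc_inner_contour = enc_contour(truth$sgc_inner_contour),
              sgc_outer_contour = enc_contour(truth$sgc_outer_contour),
              gap_sectors = truth$gap_sectors,
              vesicles = ves)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene-truth JSON annotation
#'
#' @param path JSON path.
#' @return A `scene_truth` (without the generating `params`).
#' @export
read_scene_truth <- function(path) {
  obj <- tryCatch(suppressWarnings(jsonlite::read_json(path, simplifyVector = FALSE)),
                  error = function(e)
                    stop("corrupt annotation JSON '", path, "': ",
                         conditionMessage(e)))
  for (f in c("image_size_px", "nm_per_px", "neuron_contour",
              "sgc_inner_contour", "sgc_outer_contour"))
    if (is.null(obj[[f]]))
      stop("corrupt annotation JSON '", path, "': missing field '", f, "'")
  dec_contour <- function(l) cbind(unlist(l$x), unlist(l$y))
  ves <- obj$vesicles
  n <- if (is.null(ves)) 0L else length(ves)
  centers <- if (n) do.call(rbind, lapply(ves, function(v) unlist(v$center)))
             else matrix(numeric(0), 0, 2)
  masks <- lapply(ves, function(v) {
    m <- v$mask
    r <- inverse.rle(list(lengths = unlist(m$rle_lengths),
                          values = unlist(m$rle_values)))
    list(offset = unlist(m$offset),
         mask = matrix(as.logical(r), m$nrow, m$ncol))
  })
  gs <- lapply(obj$gap_sectors, function(s) s)
  structure(list(neuron_contour = dec_contour(obj$neuron_contour),
                 sgc_inner_contour = dec_contour(obj$sgc_inner_contour),
                 sgc_outer_contour = dec_contour(obj$sgc_outer_contour),
                 gap_sectors = gs,
                 vesicle_centers = centers,
                 vesicle_radii_px = if (n)
                   vapply(ves, function(v) v$radius_px, numeric(1))
                 else numeric(0),
                 vesicle_masks = masks,
                 vesicle_count = n,
                 cytoplasm_area_um2 = obj$cytoplasm_area_um2,
                 nm_per_px = obj$nm_per_px,
                 image_size_px = unlist(obj$image_size_px),
                 center_px = unlist(obj$center_px)),
            class = "scene_truth")
}

#' Write/read detections JSON
#'
#' One entry per image: image name, nm-per-px, and the instance table
#' (centroid, diameter, score, RLE mask).
#'
#' @param detections named list of [segment_vesicles()] results.
#' @param path JSON path.
#' @return `path` / the named list of data.frames.
#' @export
write_detections <- function(detections, path) {
  obj <- lapply(names(detections), function(nm) {
    d <- detections[[nm]]
    masks <- attr(d, "masks")
    list(image = nm,
         instances = lapply(seq_len(nrow(d)), function(i) {
           r <- rle(as.integer(masks[[i]]$mask))
           list(centroid_px = c(d$x_px[i], d$y_px[i]),
                area_px = d$area_px[i],
                diameter_nm = d$diameter_nm[i], score = d$score[i],
                rle_mask = list(offset = masks[[i]]$offset,
                                nrow = nrow(masks[[i]]$mask),
                                ncol = ncol(masks[[i]]$mask),
                                rle_lengths = r$lengths, rle_values = r$values))
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(obj, function(e) {
    ins <- e$instances
    d <- data.frame(
      x_px = vapply(ins, function(i) i$centroid_px[[1]], numeric(1)),
      y_px = vapply(ins, function(i) i$centroid_px[[2]], numeric(1)),
      area_px = vapply(ins, function(i) i$area_px, numeric(1)),
      diameter_nm = vapply(ins, function(i) i$diameter_nm, numeric(1)),
      score = vapply(ins, function(i) i$score, numeric(1)))
    attr(d, "masks") <- lapply(ins, function(i) {
      v <- inverse.rle(list(lengths = unlist(i$rle_mask$rle_lengths),
                            values = unlist(i$rle_mask$rle_values)))
      list(offset = unlist(i$rle_mask$offset),
           mask = matrix(as.logical(v), i$rle_mask$nrow, i$rle_mask$ncol))
    })
    d
  })
  names(out) <- vapply(obj, function(e) e$image, character(1))
  out
}

#' Serialize / load a trained model bundle
#'
#' A single JSON file holding the manifest (configs, seeds, training
#' reports) and the network weights at full precision.
#'
#' @param bundle a `model_bundle`.
#' @param path JSON path.
#' @return `path` / the restored `model_bundle`.
#' @export
write_model_bundle <- function(bundle, path) {
  enc_net <- function(net) {
    if (is.null(net)) return(NULL)
    list(input_hw = net$input_hw,
         layers = lapply(net$layers, function(l) {
           o <- list(type = l$type)
           if (!is.null(l$W)) {
             o$c_in <- l$c_in; o$c_out <- l$c_out
             o$W <- as.vector(l$W); o$W_dim <- dim(l$W); o$b <- l$b
           }
           o
         }))
  }
  rep_enc <- function(r) if (is.null(r)) NULL else
    list(per_epoch = r$per_epoch, validation_accuracy = r$validation_accuracy,
         best_epoch = r$best_epoch, seed = r$seed)
  obj <- list(format = "temquant_model_bundle_v1",
              patch_px = bundle$patch_px, nm_per_px = bundle$nm_per_px,
              class_semantics = bundle$class_semantics,
              config = bundle$config,
              training_report = lapply(bundle$training_report, rep_enc),
              stage1 = enc_net(bundle$stage1), stage2 = enc_net(bundle$stage2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_net <- function(n) {
    if (is.null(n) || !length(n)) return(NULL)
    layers <- lapply(seq_len(nrow(n$layers)), function(i) {
      l <- as.list(n$layers[i, ])
      o <- list(type = l$type)
      if (!is.na(l$c_in)) {
        o$c_in <- l$c_in; o$c_out <- l$c_out
        o$W <- matrix(unlist(l$W), l$W_dim[[1]][1], l$W_dim[[1]][2])
        o$b <- unlist(l$b)
      }
      o
    })
    structure(list(layers = layers, input_hw = unlist(n$input_hw)),
              class = "cnn_net")
  }
  rep_dec <- function(r) if (is.null(r)) NULL else
    list(per_epoch = r$per_epoch, validation_accuracy = r$validation_accuracy,
         best_epoch = r$best_epoch, seed = r$seed)
  structure(list(stage1 = dec_net(obj$stage1), stage2 = dec_net(obj$stage2),
                 patch_px = obj$patch_px, nm_per_px = obj$nm_per_px,
                 class_semantics = obj$class_semantics,
                 training_report = lapply(obj$training_report, rep_dec),
                 config = obj$config),
            class = "model_bundle")
}

#' Write a data.frame as CSV (round-trip safe)
#'
#' @param df data.frame; @param path output path.
#' @param df,path see description.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
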