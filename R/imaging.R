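#' Circular region-of-interest specifications
#'
#' One row per optode disk. Coordinates are 0-based pixel indices with the
#' origin at the top-left corner, x rightward and y downward; a pixel
#' belongs to the ROI when its centre lies strictly inside the circle.
#'
#' @param disk_id character vector of disk identifiers.
#' @param center_x,center_y circle centres in pixels (0-based).
#' @param radius circle radii in pixels, >= 3.
#' @return data.frame of class \code{roi_layout}.
#' @export
roi_layout <- function(disk_id, center_x, center_y, radius) {
  n <- length(disk_id)
  center_x <- rep_len(center_x, n)
  center_y <- rep_len(center_y, n)
  radius <- rep_len(radius, n)
  if (any(radius < 3)) stop("ROI radius must be >= 3 px")
  if (anyDuplicated(disk_id)) stop("duplicate disk_id in ROI layout")
  structure(data.frame(disk_id = as.character(disk_id),
                       center_x = center_x, center_y = center_y,
                       radius = radius, stringsAsFactors = FALSE),
            class = c("roi_layout", "data.frame"))
}

#' Read an ROI layout from CSV or YAML
#'
#' Expected fields: \code{disk_id}, \code{center_x}, \code{center_y},
#' \code{radius}.
#'
#' @param path file path (.csv, .yml or .yaml).
#' @return An \code{\link{roi_layout}}.
#' @export
read_roi_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    do.call(rbind, lapply(y, function(e)
      data.frame(disk_id = e$disk_id, center_x = e$center_x,
                 center_y = e$center_y, radius = e$radius,
                 stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  roi_layout(df$disk_id, df$center_x, df$center_y, df$radius)
}

#' @rdname read_roi_layout
#' @param rois an \code{\link{roi_layout}} to write.
#' @export
write_roi_layout <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

roi_pixel_mask <- function(roi, width, height) {
  # bounding box first; pixel centres at integer coordinates (0-based)
  xs <- max(0, floor(roi$center_x - roi$radius)):
    min(width - 1, ceiling(roi$center_x + roi$radius))
  ys <- max(0, floor(roi$center_y - roi$radius)):
    min(height - 1, ceiling(roi$center_y + roi$radius))
  g <- expand.grid(x = xs, y = ys)
  inside <- (g$x - roi$center_x)^2 + (g$y - roi$center_y)^2 < roi$radius^2
  g[inside, , drop = FALSE]
}

check_roi_bounds <- function(roi, width, height) {
  if (roi$center_x - roi$radius < -0.5 || roi$center_y - roi$radius < -0.5 ||
      roi$center_x + roi$radius > width - 0.5 ||
      roi$center_y + roi$radius > height - 0.5)
    stop("ROI for disk '", roi$disk_id, "' extends outside the image")
}

#' Extract per-disk red/green ratio samples from one RGB frame
#'
#' Computes the arithmetic mean of the red and green channels over the
#' pixels of each circular ROI and both ratiometric responses: the
#' reference-normalised difference ratio (red - green)/green and the simple
#' ratio red/green. The two are linked by the identity
#' \code{ratio_larsen == ratio_simple - 1}. The fraction of ROI pixels at
#' the sensor's full-scale value is recorded and a QC flag raised when it
#' exceeds \code{saturation_threshold}.
#'
#' @param image numeric array \code{[height, width, >=3]} in digital
#'   numbers (0 .. 2^bit_depth - 1), e.g. from \code{\link{read_frame}}.
#' @param rois an \code{\link{roi_layout}}.
#' @param time_min frame time in minutes from experiment start.
#' @param bit_depth 8 or 16; defines the full-scale digital number.
#' @param saturation_threshold maximum tolerated fraction of full-scale
#'   pixels before the sample fails QC (default 0.01).
#' @return data.frame with one row per disk: \code{disk_id},
#'   \code{time_min}, \code{mean_red}, \code{mean_green}, \code{n_pixels},
#'   \code{ratio_larsen}, \code{ratio_simple}, \code{saturated_fraction},
#'   \code{qc_pass}.
#' @export
extract_roi_ratios <- function(image, rois, time_min = NA_real_,
                               bit_depth = 8,
                               saturation_threshold = 0.01) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] >= 3)
  stopifnot(inherits(rois, "data.frame"))
  height <- dim(image)[1]; width <- dim(image)[2]
  full_scale <- 2^bit_depth - 1
  out <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    check_roi_bounds(roi, width, height)
    px <- roi_pixel_mask(roi, width, height)
    idx_r <- cbind(px$y + 1L, px$x + 1L, 1L)
    idx_g <- cbind(px$y + 1L, px$x + 1L, 2L)
    red <- image[idx_r]; green <- image[idx_g]
    mean_red <- mean(red); mean_green <- mean(green)
    sat_frac <- mean(red >= full_scale | green >= full_scale)
    if (mean_green <= 0) {
      warning("disk '", roi$disk_id, "': mean green intensity is zero; ",
              "ratios undefined")
      rl <- NA_real_; rs <- NA_real_; qc <- FALSE
    } else {
      rs <- mean_red / mean_green
      rl <- rs - 1
      qc <- sat_frac < saturation_threshold
    }
    data.frame(disk_id = roi$disk_id, time_min = time_min,
               mean_red = mean_red, mean_green = mean_green,
               n_pixels = nrow(px), ratio_larsen = rl, ratio_simple = rs,
               saturated_fraction = sat_frac, qc_pass = qc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a synthetic optode frame
#'
#' Forward model of the imaging physics used as the testable counterpart of
#' extraction: the green (reference) channel is oxygen-insensitive and set
#' to \code{green_level} inside each disk, while the red (sensing) channel
#' is quenched so that the chosen ratio definition reproduces the
#' Stern-Volmer response exactly before noise. I.i.d. Gaussian pixel noise
#' is then added to every channel and the image clipped to the
#' representable range. Background is black. Identical seeds yield
#' identical images.
#'
#' @param layout an \code{\link{roi_layout}}.
#' @param truth named numeric vector or list, disk_id -> % air saturation.
#' @param cals named list, disk_id -> \code{\link{calibration_curve}}.
#' @param width,height image size in pixels.
#' @param green_level reference-channel digital number inside disks.
#' @param noise_sd Gaussian noise standard deviation in digital numbers.
#' @param bit_depth 8 or 16.
#' @param seed optional integer seed for the noise.
#' @return numeric array \code{[height, width, 3]} in digital numbers.
#' @export
render_synthetic_frame <- function(layout, truth, cals,
                                   width = 160, height = 120,
                                   green_level = 100, noise_sd = 0,
                                   bit_depth = 8, seed = NULL) {
  stopifnot(inherits(layout, "data.frame"))
  full_scale <- 2^bit_depth - 1
  missing_cal <- setdiff(layout$disk_id, names(cals))
  missing_truth <- setdiff(layout$disk_id, names(truth))
  if (length(missing_cal))
    stop("no calibration for disk(s): ", paste(missing_cal, collapse = ", "))
  if (length(missing_truth))
    stop("no truth entry for disk(s): ",
         paste(missing_truth, collapse = ", "))

  img <- array(0, dim = c(height, width, 3))
  for (i in seq_len(nrow(layout))) {
    roi <- layout[i, ]
    check_roi_bounds(roi, width, height)
    cal <- cals[[roi$disk_id]]
    C <- as.numeric(truth[[roi$disk_id]])
    R <- stern_volmer_forward(C, cal)
    red_level <- if (cal$ratio_def == "larsen") green_level * (R + 1)
                 else green_level * R
    if (red_level > full_scale)
      stop("disk '", roi$disk_id, "': required red level ",
           round(red_level, 1), " DN exceeds full scale ", full_scale,
           "; lower green_level")
    px <- roi_pixel_mask(roi, width, height)
    img[cbind(px$y + 1L, px$x + 1L, 1L)] <- red_level
    img[cbind(px$y + 1L, px$x + 1L, 2L)] <- green_level
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  pmin(pmax(img, 0), full_scale)
}

#' Read and write image frames
#'
#' Frames are stored as PNG (8-bit) or TIFF (8- or 16-bit) RGB images.
#' In memory they are numeric arrays \code{[height, width, channel]} in
#' digital numbers on the 0 .. 2^bit_depth - 1 scale.
#'
#' @param path image file (.png, .tif, .tiff).
#' @param bit_depth 8 or 16.
#' @return \code{read_frame} returns the DN array; \code{write_frame}
#'   returns \code{path} invisibly.
#' @export
read_frame <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  full_scale <- 2^bit_depth - 1
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  arr * full_scale
}

#' @rdname read_frame
#' @param image DN array to write.
#' @export
write_frame <- function(image, path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  full_scale <- 2^bit_depth - 1
  scaled <- pmin(pmax(image / full_scale, 0), 1)
  # quantize to the storage grid so read_frame round-trips the DN values
  if (ext == "png") {
    if (bit_depth != 8)
      stop("PNG frames are written 8-bit; use TIFF for 16-bit frames")
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a frame manifest
#'
#' CSV with columns \code{time_min} and \code{path} (paths relative to the
#' manifest's directory unless absolute). Times must be strictly
#' increasing.
#'
#' @param path manifest CSV.
#' @return data.frame with \code{time_min} and absolute \code{path}.
#' @export
read_frame_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "path") %in% names(df)))
    stop("frame manifest needs columns time_min and path")
  if (nrow(df) && any(diff(df$time_min) <= 0))
    stop("manifest times must be strictly increasing")
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  data.frame(time_min = df$time_min, path = abs, stringsAsFactors = FALSE)
}

#' Build per-disk oxygen time series from ratio samples
#'
#' Joins extracted ratio samples to the calibration registry and inverts
#' each disk's Stern-Volmer response. Samples that failed QC are carried
#' through with a missing concentration rather than dropped.
#'
#' @param samples data.frame of ratio samples from
#'   \code{\link{extract_roi_ratios}} (rows from several frames can be
#'   concatenated).
#' @param cal_registry named list, disk_id -> \code{calibration_curve}.
#' @param ratio_def which measured ratio to invert; must match the
#'   registry's calibrations.
#' @return data.frame with columns \code{disk_id}, \code{time_min},
#'   \code{ratio}, \code{conc_pct_sat}, \code{qc_pass}.
#' @export
build_timeseries <- function(samples, cal_registry,
                             ratio_def = c("larsen", "simple")) {
  ratio_def <- match.arg(ratio_def)
  if (is.null(samples) || nrow(samples) == 0)
    return(data.frame(disk_id = character(), time_min = numeric(),
                      ratio = numeric(), conc_pct_sat = numeric(),
                      qc_pass = logical(), stringsAsFactors = FALSE))
  missing <- setdiff(unique(samples$disk_id), names(cal_registry))
  if (length(missing))
    stop("no calibration registered for disk(s): ",
         paste(missing, collapse = ", "))
  ratio_col <- if (ratio_def == "larsen") "ratio_larsen" else "ratio_simple"
  out <- lapply(split(samples, samples$disk_id), function(sub) {
    cal <- cal_registry[[sub$disk_id[1]]]
    if (cal$ratio_def != ratio_def)
      warning("disk '", sub$disk_id[1], "': calibration uses ",
              cal$ratio_def, " ratio but ", ratio_def, " was requested")
    ratio <- sub[[ratio_col]]
    ok <- sub$qc_pass & is.finite(ratio)
    conc <- rep(NA_real_, nrow(sub))
    if (any(ok))
      conc[ok] <- suppressWarnings(invert_calibration(ratio[ok], cal))
    data.frame(disk_id = sub$disk_id, time_min = sub$time_min,
               ratio = ratio, conc_pct_sat = conc, qc_pass = sub$qc_pass,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$disk_id, res$time_min), ]
}
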