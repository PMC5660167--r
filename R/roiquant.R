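#' Quantification configuration
#'
#' Fixed-intensity thresholds and object rules for the HTT-aggregation ROI
#' analysis. Defaults are the published protocol: DAPI threshold 90, S830
#' threshold 50 ("pixels below these thresholds were excluded", i.e. a pixel
#' equal to the threshold is kept), DAPI objects under 25 pixels discarded as
#' debris. 8-neighbour connectivity is the default (the ImageJ particle
#' convention); no minimum S830 object size is imposed by default.
#'
#' @param dapi_threshold,s830_threshold integer intensities in [0, 255].
#' @param dapi_min_pixels,s830_min_pixels minimum object sizes (>= 1).
#' @param connectivity 4 or 8.
#' @param nuclear_object_rule how an S830 object straddling the nuclear
#'   boundary is assigned: `"pixel-partition"` (default) splits it by the
#'   nucleus mask into separate nuclear and extra-nuclear inclusions, which
#'   conserves the intra/extra pixel totals; `"majority"` assigns the whole
#'   object to the compartment holding >= 50% of its pixels (ties nuclear).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(dapi_threshold = 90L, s830_threshold = 50L,
                         dapi_min_pixels = 25L, s830_min_pixels = 1L,
                         connectivity = 8L,
                         nuclear_object_rule = c("pixel-partition",
                                                 "majority")) {
  stopifnot_scalar(dapi_threshold, "dapi_threshold", 0, 255, integer = TRUE)
  stopifnot_scalar(s830_threshold, "s830_threshold", 0, 255, integer = TRUE)
  stopifnot_scalar(dapi_min_pixels, "dapi_min_pixels", lo = 1, integer = TRUE)
  stopifnot_scalar(s830_min_pixels, "s830_min_pixels", lo = 1, integer = TRUE)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(list(dapi_threshold = as.integer(dapi_threshold),
                 s830_threshold = as.integer(s830_threshold),
                 dapi_min_pixels = as.integer(dapi_min_pixels),
                 s830_min_pixels = as.integer(s830_min_pixels),
                 connectivity = as.integer(connectivity),
                 nuclear_object_rule = match.arg(nuclear_object_rule)),
            class = "quant_config")
}

#' Threshold a channel image
#'
#' Keeps pixels with intensity >= `threshold` (pixels *below* the threshold
#' are excluded, so the boundary intensity is retained).
#'
#' @param image a [channel_image()] or integer matrix in [0, 255].
#' @param threshold integer intensity in [0, 255].
#' @return A logical matrix (the foreground mask).
#' @export
threshold_channel <- function(image, threshold) {
  stopifnot_scalar(threshold, "threshold", 0, 255)
  m <- if (inherits(image, "channel_image")) as_intensity_matrix(image)
       else image
  if (!is.matrix(m)) stop("`image` must be a matrix")
  m >= threshold
}

#' Label connected foreground objects
#'
#' Objects are maximal sets of adjacent foreground pixels under the chosen
#' connectivity. 4-connected components come from `EBImage::bwlabel`;
#' 8-connectivity additionally merges components that touch diagonally
#' (union-find on the label adjacency graph).
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `labeled_objects`: `labels` (integer matrix,
#'   0 = background, labels 1..n in raster order of first pixel), `objects`
#'   (data.frame: label, n_pixels, centroid_row, centroid_col; 0-based
#'   centroids) and `pixels` (list of linear pixel-index vectors).
#' @export
label_objects <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  m <- (mask > 0) * 1
  lab <- EBImage::bwlabel(m)          # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonally adjacent label pairs
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(edges)) {
      g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                       directed = FALSE)
      comp <- igraph::components(g)
      map <- seq_len(nlab)
      ids <- as.integer(igraph::V(g)$name)
      map[ids] <- nlab + comp$membership   # temporary merged ids
      fg <- lab > 0L
      lab[fg] <- map[lab[fg]]
    }
  }
  relabel_raster(lab)
}

# renumber labels 1..K in raster (column-major) order of first occurrence and
# build the object table + pixel lists
relabel_raster <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) {
    return(structure(list(labels = matrix(0L, nrow(lab), ncol(lab)),
                          objects = data.frame(label = integer(0),
                                               n_pixels = integer(0),
                                               centroid_row = numeric(0),
                                               centroid_col = numeric(0)),
                          pixels = list()),
                     class = "labeled_objects"))
  }
  vals <- lab[fg]
  first <- !duplicated(vals)
  new_id <- match(vals, vals[first])
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[fg] <- new_id
  pix <- split(fg, new_id)
  names(pix) <- NULL
  nr <- nrow(lab)
  rows <- (fg - 1L) %% nr
  cols <- (fg - 1L) %/% nr
  objects <- data.frame(
    label = seq_along(pix),
    n_pixels = vapply(pix, length, 1L),
    centroid_row = vapply(split(rows, new_id), mean, 1),
    centroid_col = vapply(split(cols, new_id), mean, 1),
    row.names = NULL)
  structure(list(labels = out, objects = objects, pixels = pix),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s), %d foreground pixel(s)\n",
              nrow(x$objects), sum(x$objects$n_pixels)))
  invisible(x)
}

#' Remove debris objects below a minimum pixel size
#'
#' Retains exactly the objects with `n_pixels >= min_pixels` ("less than 25
#' DAPI pixels" is debris, so a 25-pixel object is kept) and relabels the
#' raster consistently.
#'
#' @param objects a [label_objects()] result.
#' @param min_pixels minimum size (>= 1).
#' @return A `labeled_objects` with debris removed.
#' @export
filter_debris <- function(objects, min_pixels) {
  stopifnot(inherits(objects, "labeled_objects"))
  stopifnot_scalar(min_pixels, "min_pixels", lo = 1, integer = TRUE)
  keep <- objects$objects$n_pixels >= min_pixels
  lab <- objects$labels
  if (!all(keep)) {
    drop <- objects$objects$label[!keep]
    lab[lab %in% drop] <- 0L
  }
  relabel_raster(lab)
}

#' Partition S830 signal by the nuclear mask
#'
#' Counts above-threshold S830 pixels that co-localize with the
#' (debris-filtered) DAPI foreground as intra-nuclear and the rest as
#' extra-nuclear. Conservation holds on every input:
#' intra + extra = total S830 foreground.
#'
#' @param s830_mask,nucleus_mask logical matrices of the same shape.
#' @return A list with `n_pixels_intra` and `n_pixels_extra`.
#' @export
partition_signal <- function(s830_mask, nucleus_mask) {
  if (!is.matrix(s830_mask) || !is.matrix(nucleus_mask) ||
      !all(dim(s830_mask) == dim(nucleus_mask)))
    stop("masks must be matrices of the same shape")
  s <- s830_mask > 0; n <- nucleus_mask > 0
  list(n_pixels_intra = sum(s & n), n_pixels_extra = sum(s & !n))
}

#' Assign S830 objects to nuclear or cytoplasmic compartments
#'
#' Under `"pixel-partition"` each S830 object is split by the nucleus mask
#' and the connected components of the nuclear and extra-nuclear parts are
#' counted as separate inclusions (pixel totals per compartment are exactly
#' those of [partition_signal()]). Under `"majority"` the whole object goes
#' to the compartment holding at least half of its pixels (exact ties are
#' assigned nuclear and reported via the `ties` attribute).
#'
#' @param s830_objects a [label_objects()] result for the S830 mask.
#' @param nucleus_mask logical matrix (debris-filtered DAPI foreground).
#' @param rule "pixel-partition" or "majority".
#' @param connectivity 4 or 8, used to re-label split parts.
#' @return An object of class `classified_inclusions`: data.frame with
#'   columns `inclusion_id`, `compartment`, `size_px`; attributes `pixels`
#'   (per-inclusion pixel indices), `n_pixels_intra`/`n_pixels_extra` (the
#'   pixel-level partition, rule-independent) and `ties`.
#' @export
classify_inclusions <- function(s830_objects, nucleus_mask,
                                rule = c("pixel-partition", "majority"),
                                connectivity = 8L) {
  rule <- match.arg(rule)
  stopifnot(inherits(s830_objects, "labeled_objects"))
  lab <- s830_objects$labels
  if (!all(dim(lab) == dim(nucleus_mask)))
    stop("masks must be matrices of the same shape")
  nuc <- nucleus_mask > 0
  s830_fg <- lab > 0L
  intra_total <- sum(s830_fg & nuc)
  extra_total <- sum(s830_fg & !nuc)
  ties <- 0L
  if (rule == "pixel-partition") {
    intra <- label_objects(s830_fg & nuc, connectivity)
    extra <- label_objects(s830_fg & !nuc, connectivity)
    df <- data.frame(
      inclusion_id = seq_len(nrow(intra$objects) + nrow(extra$objects)),
      compartment = rep(c("nuclear", "cytoplasmic"),
                        c(nrow(intra$objects), nrow(extra$objects))),
      size_px = c(intra$objects$n_pixels, extra$objects$n_pixels),
      stringsAsFactors = FALSE)
    pixels <- c(intra$pixels, extra$pixels)
  } else {
    n_obj <- nrow(s830_objects$objects)
    compartment <- character(n_obj)
    for (i in seq_len(n_obj)) {
      frac_in <- mean(nuc[s830_objects$pixels[[i]]])
      if (frac_in == 0.5) ties <- ties + 1L
      compartment[i] <- if (frac_in >= 0.5) "nuclear" else "cytoplasmic"
    }
    df <- data.frame(inclusion_id = seq_len(n_obj),
                     compartment = compartment,
                     size_px = s830_objects$objects$n_pixels,
                     stringsAsFactors = FALSE)
    pixels <- s830_objects$pixels
  }
  structure(df, pixels = pixels, n_pixels_intra = intra_total,
            n_pixels_extra = extra_total, ties = ties,
            class = c("classified_inclusions", "data.frame"))
}

#' Per-ROI summary statistics
#'
#' The nine quantities reported per region of interest: nucleus count and
#' mean size, inclusion count and mean size, percentage of S830 signal
#' co-localized with DAPI, percentage of inclusions that are nuclear, number
#' of nuclear inclusions, percentage of nuclei containing an inclusion (a
#' nucleus contains an inclusion if at least one nuclear-inclusion pixel lies
#' in its pixel set), and mean nuclear-inclusion size. Ratios with a zero
#' denominator are reported as NA ("undefined"), never as 0, so that group
#' means are not biased by empty ROIs.
#'
#' @param nuclei a debris-filtered [label_objects()] result (DAPI).
#' @param inclusions a [classify_inclusions()] result.
#' @return A one-row data.frame of class `roi_stats` with columns `n_nuclei`,
#'   `mean_nucleus_px`, `n_inclusions`, `mean_inclusion_px`,
#'   `pct_signal_colocalized`, `pct_inclusions_nuclear`,
#'   `n_nuclear_inclusions`, `pct_nuclei_with_inclusions`,
#'   `mean_nuclear_inclusion_px`.
#' @export
summarize_roi <- function(nuclei, inclusions) {
  stopifnot(inherits(nuclei, "labeled_objects"),
            inherits(inclusions, "classified_inclusions"))
  n_nuclei <- nrow(nuclei$objects)
  mean_nucleus_px <- if (n_nuclei > 0) mean(nuclei$objects$n_pixels)
                     else NA_real_
  n_inc <- nrow(inclusions)
  nuclear <- inclusions$compartment == "nuclear"
  n_nuc_inc <- sum(nuclear)
  intra <- attr(inclusions, "n_pixels_intra")
  extra <- attr(inclusions, "n_pixels_extra")
  pct_sig <- if (intra + extra > 0) 100 * intra / (intra + extra) else NA_real_
  pct_inc_nuclear <- if (n_inc > 0) 100 * n_nuc_inc / n_inc else NA_real_
  mean_inc_px <- if (n_inc > 0) mean(inclusions$size_px) else NA_real_
  mean_nuc_inc_px <- if (n_nuc_inc > 0) mean(inclusions$size_px[nuclear])
                     else NA_real_
  pct_nuclei_with <- NA_real_
  if (n_nuclei > 0 && n_inc > 0) {
    pix <- attr(inclusions, "pixels")
    nuc_inc_px <- unlist(pix[nuclear], use.names = FALSE)
    if (length(nuc_inc_px)) {
      hit <- vapply(nuclei$pixels,
                    function(p) any(p %in% nuc_inc_px), logical(1))
      pct_nuclei_with <- 100 * sum(hit) / n_nuclei
    } else {
      pct_nuclei_with <- 0   # inclusions exist, none nuclear: a true zero
    }
  }
  structure(data.frame(
    n_nuclei = n_nuclei, mean_nucleus_px = mean_nucleus_px,
    n_inclusions = n_inc, mean_inclusion_px = mean_inc_px,
    pct_signal_colocalized = pct_sig,
    pct_inclusions_nuclear = pct_inc_nuclear,
    n_nuclear_inclusions = n_nuc_inc,
    pct_nuclei_with_inclusions = pct_nuclei_with,
    mean_nuclear_inclusion_px = mean_nuc_inc_px),
    class = c("roi_stats", "data.frame"))
}

#' Quantify one ROI image pair
#'
#' Convenience wrapper running the full per-ROI chain: threshold both
#' channels, label objects, remove DAPI debris, drop sub-minimum S830
#' objects, classify inclusions and summarize.
#'
#' @param dapi,s830 [channel_image()]s or integer matrices of equal shape.
#' @param config a [quant_config()].
#' @return A [summarize_roi()] result.
#' @export
quantify_roi <- function(dapi, s830, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  dapi_mask <- threshold_channel(dapi, config$dapi_threshold)
  s830_mask <- threshold_channel(s830, config$s830_threshold)
  nuclei <- filter_debris(label_objects(dapi_mask, config$connectivity),
                          config$dapi_min_pixels)
  s830_obj <- label_objects(s830_mask, config$connectivity)
  if (config$s830_min_pixels > 1L)
    s830_obj <- filter_debris(s830_obj, config$s830_min_pixels)
  incl <- classify_inclusions(s830_obj, nuclei$labels > 0L,
                              rule = config$nuclear_object_rule,
                              connectivity = config$connectivity)
  summarize_roi(nuclei, incl)
}

#' Grid a whole-section image into regions of interest
#'
#' Applies a deterministic k x k grid of equal, non-overlapping boxes centred
#' in the tissue bounding box (nine ROIs per section in the published
#' protocol, from an automated unbiased process).
#'
#' @param section_image a [channel_image()] or matrix.
#' @param n_rois number of ROIs; must be a perfect square (default 9).
#' @param tissue_threshold intensity defining the tissue bounding box.
#' @return A data.frame with one row per ROI: `roi`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive bounds, raster order).
#' @export
grid_rois <- function(section_image, n_rois = 9L, tissue_threshold = 1L) {
  k <- sqrt(n_rois)
  if (k != round(k)) stop("`n_rois` must be a perfect square")
  k <- as.integer(k)
  m <- if (inherits(section_image, "channel_image"))
         as_intensity_matrix(section_image) else section_image
  fg <- which(m >= tissue_threshold, arr.ind = TRUE)
  if (!nrow(fg)) stop("no tissue found at the given threshold")
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  h <- (r1 - r0 + 1L) %/% k
  w <- (c1 - c0 + 1L) %/% k
  if (h < 1L || w < 1L)
    stop("tissue bounding box smaller than the requested grid")
  # centre the k*h x k*w grid in the bounding box
  r_off <- r0 + ((r1 - r0 + 1L) - k * h) %/% 2L
  c_off <- c0 + ((c1 - c0 + 1L) - k * w) %/% 2L
  grid <- expand.grid(gr = seq_len(k), gc = seq_len(k))
  grid <- grid[order(grid$gr, grid$gc), ]
  data.frame(
    roi = seq_len(k * k),
    row0 = r_off + (grid$gr - 1L) * h,
    row1 = r_off + grid$gr * h - 1L,
    col0 = c_off + (grid$gc - 1L) * w,
    col1 = c_off + grid$gc * w - 1L,
    row.names = NULL)
}

#' Aggregate ROI statistics to per-mouse means
#'
#' Field-wise arithmetic mean over the ROIs of one mouse, skipping undefined
#' (NA) entries, with the number of contributing ROIs recorded per field.
#' The per-mouse mean is the unit of analysis for group comparisons.
#'
#' @param roi_stats a data.frame of stacked [summarize_roi()] rows.
#' @return A data.frame with columns `statistic`, `mean`, `n_rois`.
#' @export
aggregate_mouse <- function(roi_stats) {
  stat_cols <- c("n_nuclei", "mean_nucleus_px", "n_inclusions",
                 "mean_inclusion_px", "pct_signal_colocalized",
                 "pct_inclusions_nuclear", "n_nuclear_inclusions",
                 "pct_nuclei_with_inclusions", "mean_nuclear_inclusion_px")
  missing_cols <- setdiff(stat_cols, names(roi_stats))
  if (length(missing_cols))
    stop("missing statistic columns: ", paste(missing_cols, collapse = ", "))
  data.frame(
    statistic = stat_cols,
    mean = vapply(stat_cols,
                  function(s) mean(roi_stats[[s]], na.rm = TRUE), 1),
    n_rois = vapply(stat_cols,
                    function(s) sum(!is.na(roi_stats[[s]])), 1L),
    row.names = NULL)
}
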