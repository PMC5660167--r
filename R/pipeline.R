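#' Compact section configuration for demos and examples
#'
#' A reduced-field version of the default [section_sim_config()] (180 x 180
#' px at 1 um/px, ~25 fibres) that keeps all biological defaults - 55%
#' nuclear inclusions, nuclear/cytoplasmic size ratio giving a 70% nuclear
#' signal share, noise strictly below the thresholds - while simulating in
#' milliseconds. Used by [run_figure5_demo()] and the worked examples.
#'
#' @param seed integer seed or NULL.
#' @param ... overrides passed to [section_sim_config()].
#' @return A [section_sim_config()].
#' @export
demo_section_config <- function(seed = NULL, ...) {
  args <- list(
    image_size_px = c(180L, 180L),
    pixel_size_um = 1,
    fibre_mean_diameter_um = 36,
    fibre_diameter_cv = 0.25,
    nuclei_per_100fibres = 160,
    nucleus_radius_px = 6,
    inclusion_count_mean = 30,
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(section_sim_config, args)
}

roi_stat_names <- function() {
  c("n_nuclei", "mean_nucleus_px", "n_inclusions", "mean_inclusion_px",
    "pct_signal_colocalized", "pct_inclusions_nuclear",
    "n_nuclear_inclusions", "pct_nuclei_with_inclusions",
    "mean_nuclear_inclusion_px")
}

mouse_means_wide <- function(roi_stats) {
  agg <- aggregate_mouse(roi_stats)
  as.data.frame(as.list(stats::setNames(agg$mean, agg$statistic)))
}

#' Simulate and quantify a full group design
#'
#' End-to-end orchestration: for every mouse of every group, simulate
#' `n_rois_per_mouse` ROIs (18 in the published design: nine ROIs on each of
#' two sections) under the group's hypertrophy factor, quantify each ROI,
#' aggregate to per-mouse means, and run within-genotype treatment
#' comparisons (t-tests over per-mouse means - the mouse, not the ROI, is
#' the unit of analysis). Deterministic given `seed`.
#'
#' @param groups a data.frame with columns `group`, `genotype`, `treatment`,
#'   `n_mice`, `hypertrophy_factor`.
#' @param sim_config the baseline [section_sim_config()] (hypertrophy factors
#'   are applied per group via [apply_hypertrophy()]).
#' @param quant a [quant_config()].
#' @param n_rois_per_mouse ROIs simulated per mouse.
#' @param seed integer seed for the whole run.
#' @param out_dir optional output directory; when given, writes
#'   `roi_stats.csv`, `mouse_stats.csv`, `group_tests.csv` and
#'   `manifest.json` (config echo, package version, seed, file checksums).
#' @return A list with `roi_stats`, `mouse_stats`, `group_tests` and
#'   `manifest`.
#' @export
run_quantification <- function(groups, sim_config = demo_section_config(),
                               quant = quant_config(),
                               n_rois_per_mouse = 18L, seed = 1L,
                               out_dir = NULL) {
  need <- c("group", "genotype", "treatment", "n_mice", "hypertrophy_factor")
  if (!all(need %in% names(groups)))
    stop("`groups` needs columns: ", paste(need, collapse = ", "))
  stopifnot_scalar(n_rois_per_mouse, "n_rois_per_mouse", lo = 1,
                   integer = TRUE)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  base <- sim_config
  base$seed <- NULL  # one seed governs the whole run
  roi_rows <- list()
  with_seed(as.integer(seed), {
    for (gi in seq_len(nrow(groups))) {
      cfg <- apply_hypertrophy(base, groups$hypertrophy_factor[gi])
      for (mi in seq_len(groups$n_mice[gi])) {
        mouse_id <- sprintf("%s_m%02d", groups$group[gi], mi)
        for (ri in seq_len(n_rois_per_mouse)) {
          sim <- simulate_roi(cfg)
          st <- quantify_roi(sim$dapi, sim$s830, quant)
          roi_rows[[length(roi_rows) + 1L]] <- cbind(
            data.frame(group = groups$group[gi],
                       genotype = groups$genotype[gi],
                       treatment = groups$treatment[gi],
                       mouse = mouse_id, roi = ri,
                       stringsAsFactors = FALSE),
            as.data.frame(st))
        }
      }
    }
  })
  roi_stats <- do.call(rbind, roi_rows)
  mouse_stats <- do.call(rbind, lapply(
    split(roi_stats, roi_stats$mouse), function(d)
      cbind(d[1L, c("group", "genotype", "treatment", "mouse")],
            mouse_means_wide(d), row.names = NULL)))
  mouse_stats <- mouse_stats[order(mouse_stats$group, mouse_stats$mouse), ]
  rownames(mouse_stats) <- NULL

  group_tests <- group_treatment_tests(mouse_stats)

  manifest <- list(
    package = "myoquant",
    version = as.character(utils::packageVersion("myoquant")),
    seed = as.integer(seed),
    n_rois_per_mouse = as.integer(n_rois_per_mouse),
    groups = groups,
    sim_config = base[!vapply(base, is.null, TRUE)],
    quant_config = unclass(quant))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(roi_stats = "roi_stats.csv", mouse_stats = "mouse_stats.csv",
               group_tests = "group_tests.csv")
    utils::write.csv(roi_stats, file.path(out_dir, files["roi_stats"]),
                     row.names = FALSE)
    utils::write.csv(mouse_stats, file.path(out_dir, files["mouse_stats"]),
                     row.names = FALSE)
    utils::write.csv(group_tests, file.path(out_dir, files["group_tests"]),
                     row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$checksums) <- unname(files)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  list(roi_stats = roi_stats, mouse_stats = mouse_stats,
       group_tests = group_tests, manifest = manifest)
}

# within-genotype treatment t-tests over per-mouse means
group_treatment_tests <- function(mouse_stats) {
  rows <- list()
  for (g in unique(mouse_stats$genotype)) {
    d <- mouse_stats[mouse_stats$genotype == g, ]
    tr <- unique(d$treatment)
    if (length(tr) != 2L) next
    for (s in roi_stat_names()) {
      x <- d[[s]][d$treatment == tr[1L]]
      y <- d[[s]][d$treatment == tr[2L]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) next
      tt <- tryCatch(stats::t.test(x, y), error = function(e)
        list(statistic = c(t = NA_real_), p.value = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, statistic = s,
        mean_1 = mean(x), mean_2 = mean(y),
        treatment_1 = tr[1L], treatment_2 = tr[2L],
        t = unname(tt$statistic), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Quantify a directory of exported ROI TIFF pairs
#'
#' Reads ROI images following the naming convention
#' `<mouse>_<section>_<roi>_<channel>.tif` (channel `dapi` or `s830`) and
#' quantifies each pair. A DAPI file without its S830 counterpart (or vice
#' versa) is an error naming the missing file.
#'
#' @param images_dir directory of TIFF files.
#' @param quant a [quant_config()].
#' @param pixel_size_um pixel size of the exported images.
#' @return A data.frame: mouse, section, roi plus the nine ROI statistics.
#' @export
quantify_image_dir <- function(images_dir, quant = quant_config(),
                               pixel_size_um = 0.31) {
  files <- list.files(images_dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  parse <- regmatches(files,
                      regexec("^(.+)_([^_]+)_([^_]+)_(dapi|s830)\\.tiff?$",
                              files, ignore.case = TRUE))
  ok <- lengths(parse) == 5L
  if (!any(ok))
    stop("no files matching <mouse>_<section>_<roi>_<channel>.tif in ",
         images_dir)
  info <- do.call(rbind, lapply(parse[ok], function(p)
    data.frame(file = p[1L], mouse = p[2L], section = p[3L], roi = p[4L],
               channel = tolower(p[5L]), stringsAsFactors = FALSE)))
  key <- paste(info$mouse, info$section, info$roi, sep = "_")
  rows <- list()
  for (k in unique(key)) {
    sub <- info[key == k, ]
    for (ch in c("dapi", "s830"))
      if (!ch %in% sub$channel)
        stop("missing channel file: ", paste0(k, "_", ch, ".tif"))
    dapi <- read_channel_tiff(file.path(images_dir,
                                        sub$file[sub$channel == "dapi"]),
                              "DAPI", pixel_size_um)
    s830 <- read_channel_tiff(file.path(images_dir,
                                        sub$file[sub$channel == "s830"]),
                              "S830", pixel_size_um)
    st <- quantify_roi(dapi, s830, quant)
    rows[[length(rows) + 1L]] <- cbind(sub[1L, c("mouse", "section", "roi")],
                                       as.data.frame(st), row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Hypertrophy-dilution demonstration
#'
#' Reproduces, on synthetic data, the qualitative aggregation pattern seen
#' after myostatin-pathway inhibition: simulate a vehicle cohort (h = 1) and
#' a treated cohort (hypertrophy factor `h`, per-nucleus inclusion process
#' unchanged), quantify every ROI, and test three assertions over per-mouse
#' means: (1) the treated muscle has fewer nuclei per ROI (one-sided t-test);
#' (2) nuclear inclusions are unchanged or larger - a non-inferiority check:
#' a one-sided t-test for a treated *decrease* must not reject at
#' `alpha_decrease`; (3) feeding the measured nuclear density and per-nucleus
#' load through the per-mass model yields the verdict "dilution": the
#' modelled per-mass (ELISA-like) signal drops while the per-nucleus image
#' load does not.
#'
#' @param seed integer seed.
#' @param n_mice mice per group.
#' @param n_rois_per_mouse ROIs per mouse.
#' @param h hypertrophy factor of the treated group.
#' @param base_config baseline [section_sim_config()] for the vehicle group.
#' @param quant a [quant_config()].
#' @param tol tolerance passed to [reconcile()].
#' @param alpha_decrease significance level of the inclusion-size decrease
#'   test (a decrease is only declared when clearly supported).
#' @return A list of class `figure5_report`: per-group per-mouse means, the
#'   three assertion outcomes, the two ratios and the verdict.
#' @export
run_figure5_demo <- function(seed = 1L, n_mice = 8L, n_rois_per_mouse = 6L,
                             h = 1.3, base_config = demo_section_config(),
                             quant = quant_config(), tol = 0.1,
                             alpha_decrease = 0.01) {
  groups <- data.frame(
    group = c("R62_vehicle", "R62_treated"),
    genotype = "R6/2",
    treatment = c("vehicle", "ACVR2B/Fc"),
    n_mice = n_mice,
    hypertrophy_factor = c(1, h),
    stringsAsFactors = FALSE)
  run <- run_quantification(groups, base_config, quant,
                            n_rois_per_mouse = n_rois_per_mouse, seed = seed)
  ms <- run$mouse_stats
  veh <- ms[ms$treatment == "vehicle", ]
  trt <- ms[ms$treatment == "ACVR2B/Fc", ]

  t_nuc <- stats::t.test(trt$n_nuclei, veh$n_nuclei, alternative = "less")
  incl_t <- trt$mean_nuclear_inclusion_px
  incl_v <- veh$mean_nuclear_inclusion_px
  t_incl <- stats::t.test(incl_t[!is.na(incl_t)], incl_v[!is.na(incl_v)],
                          alternative = "less")

  load_of <- function(d) nuclear_load_from_stats(
    mean(d$mean_nuclear_inclusion_px, na.rm = TRUE),
    mean(d$pct_nuclei_with_inclusions, na.rm = TRUE))
  load_v <- load_of(veh); load_t <- load_of(trt)
  # measured nuclear areal density already contains the hypertrophy effect
  sig_v <- per_mass_signal(tissue_state(mean(veh$n_nuclei), load_v))
  sig_t <- per_mass_signal(tissue_state(mean(trt$n_nuclei), load_t))
  verdict <- reconcile(sig_t / sig_v, load_t / load_v, tol = tol)

  structure(list(
    seed = as.integer(seed), h = h, n_mice = n_mice,
    n_rois_per_mouse = n_rois_per_mouse,
    mouse_stats = ms,
    nuclei_vehicle = mean(veh$n_nuclei),
    nuclei_treated = mean(trt$n_nuclei),
    p_fewer_nuclei = t_nuc$p.value,
    fewer_nuclei = t_nuc$p.value < 0.05,
    incl_size_vehicle = mean(incl_v, na.rm = TRUE),
    incl_size_treated = mean(incl_t, na.rm = TRUE),
    p_inclusions_smaller = t_incl$p.value,
    inclusions_unchanged_or_larger = t_incl$p.value > alpha_decrease,
    elisa_ratio = verdict$elisa_ratio,
    image_ratio = verdict$image_ratio,
    verdict = verdict$verdict,
    pattern_reproduced = t_nuc$p.value < 0.05 &&
      t_incl$p.value > alpha_decrease &&
      verdict$verdict == "dilution"
  ), class = "figure5_report")
}

#' @export
print.figure5_report <- function(x, ...) {
  cat("Hypertrophy-dilution demonstration (synthetic cohorts)\n")
  cat(sprintf("  %d mice/group x %d ROIs, hypertrophy factor h = %.2f\n",
              x$n_mice, x$n_rois_per_mouse, x$h))
  cat(sprintf("  nuclei/ROI: vehicle %.1f vs treated %.1f (one-sided p = %.2g)\n",
              x$nuclei_vehicle, x$nuclei_treated, x$p_fewer_nuclei))
  cat(sprintf("  nuclear inclusion size (px): vehicle %.1f vs treated %.1f (p[decrease] = %.2g)\n",
              x$incl_size_vehicle, x$incl_size_treated,
              x$p_inclusions_smaller))
  cat(sprintf("  per-mass signal ratio %.2f, per-nucleus load ratio %.2f -> %s\n",
              x$elisa_ratio, x$image_ratio, x$verdict))
  cat(sprintf("  qualitative pattern reproduced: %s\n",
              if (x$pattern_reproduced) "yes" else "no"))
  invisible(x)
}
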