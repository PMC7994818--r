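# End-to-end runs: configuration, simulate -> quantify -> stats -> afm,
# with deterministic seeding, CSV interchange and a checksum manifest.

#' Run configuration
#'
#' Bundles every knob of an end-to-end synthetic run. A run is a pure
#' function of its configuration: identical configurations (including the
#' seed) produce byte-identical outputs.
#'
#' @param seed Master integer seed; all stage seeds are derived from it.
#' @param archetypes Named list of [tissue_archetype()] objects.
#' @param n_cells Named integer vector: cohort size per archetype (0 omits
#'   the archetype with a warning).
#' @param n_render Named integer vector: how many cells per archetype get a
#'   rendered image stack (capped at \code{n_cells}).
#' @param link A [lamin_link_params()].
#' @param imaging An [imaging_params()].
#' @param junction List: \code{n_cells}, \code{mean_area_um2} for the
#'   junction-network field rendered per archetype.
#' @param afm List: \code{moduli_Pa}, \code{grid} (rows, cols),
#'   \code{spring_constant}, \code{indenter_type} ("cone"/"pyramid"),
#'   \code{angle}, \code{noise_sd_N}, \code{max_force_N}.
#' @param stats List: \code{n_iterations}, \code{sided}, \code{loess_span},
#'   \code{bin_widths} (named: d_cell, d_nuc, strain).
#' @param reference Archetype whose mean Lamin defines the normalisation
#'   unit (the columnar archetype by default).
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L,
                       archetypes = archetype_presets(),
                       n_cells = c(squamous = 334L, cuboidal = 333L,
                                   columnar = 333L),
                       n_render = c(squamous = 12L, cuboidal = 12L,
                                    columnar = 12L),
                       link = lamin_link_params(),
                       imaging = imaging_params(),
                       junction = list(n_cells = 64L, mean_area_um2 = 50),
                       afm = list(moduli_Pa = c(1000, 5000, 10000, 20000),
                                  grid = c(4L, 4L), spring_constant = 0.1,
                                  indenter_type = "cone", angle = 25,
                                  noise_sd_N = 2e-11, max_force_N = 1e-9),
                       stats = list(n_iterations = 10000L, sided = "two",
                                    loess_span = 0.75,
                                    bin_widths = list(d_cell = 0.07,
                                                      d_nuc = 0.06,
                                                      strain = 0.01)),
                       reference = "columnar") {
  stopifnot(is.list(archetypes), length(archetypes) >= 1)
  for (a in archetypes) stopifnot(inherits(a, "tissue_archetype"))
  if (is.null(names(n_cells)) ||
      !all(names(n_cells) %in% names(archetypes)))
    stop("n_cells must be named by archetype", call. = FALSE)
  if (is.null(names(n_render)) ||
      !all(names(n_render) %in% names(archetypes)))
    stop("n_render must be named by archetype", call. = FALSE)
  stopifnot(inherits(link, "lamin_link_params"),
            inherits(imaging, "imaging_params"))
  if (!reference %in% names(archetypes))
    stop("reference must name one of the archetypes", call. = FALSE)
  if (!afm$indenter_type %in% c("cone", "pyramid"))
    stop("afm$indenter_type must be 'cone' or 'pyramid'", call. = FALSE)
  structure(list(seed = as.integer(seed), archetypes = archetypes,
                 n_cells = n_cells, n_render = n_render, link = link,
                 imaging = imaging, junction = junction, afm = afm,
                 stats = stats, reference = reference),
            class = "run_config")
}

#' Write / load a run configuration as YAML
#'
#' The resolved configuration (every default filled in) is serialised so a
#' run directory documents exactly what produced it.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return \code{write_run_config}: path, invisibly;
#'   \code{load_run_config}: a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  arch <- lapply(config$archetypes, function(a) unclass(a))
  yaml::write_yaml(list(seed = config$seed,
                        archetypes = arch,
                        n_cells = as.list(config$n_cells),
                        n_render = as.list(config$n_render),
                        link = unclass(config$link),
                        imaging = unclass(config$imaging),
                        junction = config$junction,
                        afm = config$afm,
                        stats = config$stats,
                        reference = config$reference),
                  path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("seed", "archetypes", "n_cells", "n_render", "link", "imaging",
            "junction", "afm", "stats", "reference")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("config is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  arch <- lapply(y$archetypes, function(a)
    do.call(tissue_archetype, a))
  names(arch) <- names(y$archetypes)
  run_config(seed = y$seed, archetypes = arch,
             n_cells = unlist(y$n_cells), n_render = unlist(y$n_render),
             link = do.call(lamin_link_params, y$link),
             imaging = do.call(imaging_params, y$imaging),
             junction = y$junction, afm = y$afm, stats = y$stats,
             reference = y$reference)
}

#' Simulate a full synthetic run
#'
#' Generates, under one seeded run directory: the ground-truth cohort CSV
#' (all archetypes), rendered nuclear stacks for a per-archetype subset,
#' one junction-network image per archetype with its ground-truth areas,
#' AFM force-curve grids for each configured modulus, the resolved
#' configuration, and a checksum manifest.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created; must not exist or be empty).
#' @return \code{outdir}, invisibly. Side effects: files under
#'   \code{outdir}.
#' @export
simulate_run <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(outdir) && length(dir(outdir)))
    stop("outdir exists and is not empty: ", outdir, call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "stacks"))
  dir.create(file.path(outdir, "junctions"))
  dir.create(file.path(outdir, "afm"), recursive = TRUE)

  # cohort ------------------------------------------------------------
  cohorts <- list()
  for (i in seq_along(config$archetypes)) {
    nm <- names(config$archetypes)[i]
    n <- if (nm %in% names(config$n_cells)) config$n_cells[[nm]] else 0L
    if (n < 1) {
      warning("archetype '", nm, "' has n_cells = 0 and is omitted",
              call. = FALSE)
      next
    }
    cohorts[[nm]] <- sample_cohort(config$archetypes[[i]], config$link,
                                   n, sub_seed(config$seed, i))
  }
  cohort <- do.call(rbind, cohorts)
  cohort$lamin_normalized <- normalize_to_reference(
    cohort$lamin, cohort$condition, config$reference)
  write_table_csv(cohort, file.path(outdir, "cohort.csv"))

  # rendered nuclei ----------------------------------------------------
  rendered <- character(0)
  for (nm in names(cohorts)) {
    nr <- if (nm %in% names(config$n_render)) config$n_render[[nm]] else 0L
    nr <- min(nr, nrow(cohorts[[nm]]))
    if (nr < 1) next
    rows <- cohorts[[nm]][seq_len(nr), ]
    for (j in seq_len(nr)) {
      st <- render_nucleus_stack(rows$true_a[j], rows$true_c[j],
                                 rows$lamin[j], config$imaging,
                                 seed = sub_seed(config$seed,
                                                 1000L + match(nm, names(cohorts)) * 100L + j))
      write_image_stack(st, file.path(outdir, "stacks", rows$cell_id[j]))
      rendered <- c(rendered, rows$cell_id[j])
    }
  }
  writeLines(rendered, file.path(outdir, "stacks", "rendered_ids.txt"))

  # junction fields ----------------------------------------------------
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    njc <- config$junction$n_cells
    side <- sqrt(njc * config$junction$mean_area_um2)
    centers <- with_rng(sub_seed(config$seed, 2000L + i),
                        matrix(stats::runif(2 * njc, 0, side), ncol = 2))
    jn <- render_junction_image(centers, seed = sub_seed(config$seed,
                                                         3000L + i))
    # 16-bit storage clips the (rare) negative noise excursions, exactly
    # as a camera would
    tiff::writeTIFF(pmax(jn$image, 0) / max(jn$image),
                    file.path(outdir, "junctions",
                              paste0(nm, ".tif")),
                    bits.per.sample = 16, compression = "none",
                    reduce = FALSE)
    jsonlite::write_json(list(pixel_size_um = jn$pixel_size,
                              intensity_scale = max(jn$image)),
                         file.path(outdir, "junctions",
                                   paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_table_csv(jn$truth, file.path(outdir, "junctions",
                                        paste0(nm, "_truth.csv")))
  }

  # AFM curve grids ----------------------------------------------------
  ind <- if (config$afm$indenter_type == "cone")
    indenter_cone(config$afm$angle) else indenter_pyramid(config$afm$angle)
  afm_truth <- list()
  for (i in seq_along(config$afm$moduli_Pa)) {
    E <- config$afm$moduli_Pa[i]
    ed <- file.path(outdir, "afm", sprintf("E%gPa", E))
    dir.create(ed)
    ncur <- prod(config$afm$grid)
    for (j in seq_len(ncur)) {
      cu <- generate_force_curve(E, config$afm$spring_constant, ind,
                                 max_force_N = config$afm$max_force_N,
                                 noise_sd_N = config$afm$noise_sd_N,
                                 seed = sub_seed(config$seed,
                                                 4000L + i * 100L + j))
      write_force_curve(cu, file.path(ed, sprintf("curve_%02d.csv", j)))
    }
    afm_truth[[i]] <- data.frame(region = sprintf("E%gPa", E),
                                 true_modulus_Pa = E,
                                 grid_rows = config$afm$grid[1],
                                 grid_cols = config$afm$grid[2])
  }
  write_table_csv(do.call(rbind, afm_truth),
                  file.path(outdir, "afm", "regions.csv"))

  write_run_config(config, file.path(outdir, "config.yaml"))
  write_manifest(outdir)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic CSV writer: fixed field order, no row names, full precision
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  sums <- as.character(tools::md5sum(file.path(outdir, files)))
  jsonlite::write_json(stats::setNames(as.list(sums), files),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}

#' Quantify the rendered outputs of a run
#'
#' Re-measures every rendered nucleus from its image stack (3D
#' segmentation, projection morphometry, in-mask Lamin intensity) and
#' every junction field (per-cell apical areas), recomputing all derived
#' indices from the measurements; ground truth is carried alongside under
#' \code{true_*} columns, never copied into measured columns. Nuclei whose
#' mask touches the stack boundary are flagged clipped and excluded, with
#' a reported count.
#'
#' @param rundir A directory produced by [simulate_run()].
#' @return Tibble of per-nucleus measurements (also written to
#'   \code{cohort_measured.csv} in \code{rundir}); junction areas go to
#'   \code{junctions/<archetype>_measured.csv}.
#' @export
quantify_run <- function(rundir) {
  ids <- readLines(file.path(rundir, "stacks", "rendered_ids.txt"))
  truth <- utils::read.csv(file.path(rundir, "cohort.csv"))
  rows <- list()
  n_clipped <- 0L
  for (id in ids) {
    st <- read_image_stack(file.path(rundir, "stacks", id))
    msk <- segment_nucleus_3d(st, "dapi")
    if (mask_clipped(msk)) {
      n_clipped <- n_clipped + 1L
      next
    }
    mor <- nucleus_morphometry(msk)
    shp <- spheroid_from_measurements(mor$cross_section_area, mor$height)
    lam <- lamin_in_nucleus_3d(st, msk, "lamin")
    rows[[id]] <- tibble::tibble(
      cell_id = id,
      cross_section_area = mor$cross_section_area,
      nuc_height = mor$height,
      d_nuc = mor$d_nuc,
      a = shp$a, c = shp$c,
      strain = surface_area_strain(shp)$strain,
      lamin_mean = lam$mean_intensity,
      lamin_total = lam$total_intensity)
  }
  if (n_clipped > 0)
    message(n_clipped, " nuclei excluded: mask clipped by the stack boundary")
  if (length(rows) == 0)
    stop("no usable nuclei in ", rundir, call. = FALSE)
  meas <- do.call(rbind, rows)
  meas <- merge(meas, truth, by = "cell_id", sort = TRUE)
  write_table_csv(meas, file.path(rundir, "cohort_measured.csv"))

  jdir <- file.path(rundir, "junctions")
  for (tf in list.files(jdir, pattern = "\\.tif$")) {
    nm <- sub("\\.tif$", "", tf)
    meta <- jsonlite::read_json(file.path(jdir, paste0(nm, ".json")),
                                simplifyVector = TRUE)
    img <- tiff::readTIFF(file.path(jdir, tf)) * meta$intensity_scale
    areas <- apical_areas_from_junctions(img, meta$pixel_size_um)
    write_table_csv(areas, file.path(jdir, paste0(nm, "_measured.csv")))
  }
  write_manifest(rundir)
  tibble::as_tibble(meas)
}

mask_clipped <- function(mask) {
  m <- mask$mask
  d <- dim(m)
  any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) || any(m[, d[2], ]) ||
    any(m[, , 1]) || any(m[, , d[3]])
}

#' Canonical correlation pairs
#'
#' The default pair list analysed by [stats_run()], with the conventional
#' bin width for each x variable: cell deformation index vs Lamin, cell vs
#' nuclear deformation index, nuclear deformation index vs Lamin, strain
#' vs Lamin, strain vs pSer22/Lamin fraction.
#'
#' @param bin_widths Named list with elements \code{d_cell}, \code{d_nuc},
#'   \code{strain}.
#' @return Data frame with columns \code{x}, \code{y}, \code{bin_width}.
#' @export
default_pairs <- function(bin_widths = list(d_cell = 0.07, d_nuc = 0.06,
                                            strain = 0.01)) {
  data.frame(
    x = c("true_d_cell", "true_d_cell", "true_d_nuc", "true_strain",
          "true_strain"),
    y = c("lamin_normalized", "true_d_nuc", "lamin_normalized", "lamin",
          "phospho_ratio"),
    bin_width = c(bin_widths$d_cell, bin_widths$d_cell, bin_widths$d_nuc,
                  bin_widths$strain, bin_widths$strain))
}

#' Correlation statistics over a cohort table
#'
#' For every requested (x, y) pair: Spearman coefficient with permutation
#' FDR, a binned scatter at the pair's bin width, and a LOESS trend.
#' Writes \code{correlations.csv}, \code{binned_<x>_<y>.csv} and
#' \code{loess_<x>_<y>.csv} under \code{outdir}.
#'
#' @param cohort Data frame (e.g. read from \code{cohort.csv}) or path to a
#'   CSV.
#' @param pairs Data frame with columns \code{x}, \code{y},
#'   \code{bin_width}; defaults to [default_pairs()].
#' @param outdir Output directory for the CSVs (created if needed);
#'   \code{NULL} skips writing.
#' @param n_iterations,seed,sided,loess_span Statistics parameters, see
#'   [permutation_fdr()] and [loess_trend()].
#' @param method Correlation method for the coefficient and the
#'   permutation test.
#' @return Tibble of per-pair results: \code{x}, \code{y}, \code{method},
#'   \code{coefficient}, \code{fdr}, \code{significant}, \code{n},
#'   \code{n_iterations}, \code{sided}, \code{seed}; the binned scatter
#'   and LOESS tables are attached as attributes \code{binned} and
#'   \code{loess} (named lists).
#' @export
stats_run <- function(cohort, pairs = default_pairs(), outdir = NULL,
                      n_iterations = 10000L, seed = 1L, sided = "two",
                      loess_span = 0.75, method = "spearman") {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  bad <- setdiff(unique(c(pairs$x, pairs$y)), names(cohort))
  if (length(bad))
    stop("unknown column(s) in pair spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  res <- list(); binned <- list(); loe <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- cohort[[pairs$x[i]]]
    y <- cohort[[pairs$y[i]]]
    key <- paste(pairs$x[i], pairs$y[i], sep = "_vs_")
    pf <- permutation_fdr(x, y, method = method,
                          n_iterations = n_iterations,
                          seed = sub_seed(seed, i), sided = sided)
    res[[i]] <- tibble::tibble(x = pairs$x[i], y = pairs$y[i],
                               method = pf$method,
                               coefficient = pf$coefficient,
                               fdr = pf$fdr, significant = pf$significant,
                               n = pf$n, n_iterations = pf$n_iterations,
                               sided = pf$sided, seed = pf$seed)
    binned[[key]] <- binned_scatter(x, y, pairs$bin_width[i])
    loe[[key]] <- loess_trend(x, y, span = loess_span)
    if (!is.null(outdir)) {
      write_table_csv(binned[[key]],
                      file.path(outdir, paste0("binned_", key, ".csv")))
      write_table_csv(loe[[key]],
                      file.path(outdir, paste0("loess_", key, ".csv")))
    }
  }
  out <- do.call(rbind, res)
  if (!is.null(outdir))
    write_table_csv(out, file.path(outdir, "correlations.csv"))
  attr(out, "binned") <- binned
  attr(out, "loess") <- loe
  out
}

#' Fit all AFM curves of a run
#'
#' Reads every per-region curve grid written by [simulate_run()], fits the
#' matching Sneddon-type law, and writes per-curve
#' (\code{afm/fits.csv}) and per-region (\code{afm/region_summary.csv})
#' tables. Regions where more than half the fits fail are flagged
#' unusable.
#'
#' @param rundir Run directory.
#' @return Tibble of per-region summaries.
#' @export
afm_run <- function(rundir) {
  adir <- file.path(rundir, "afm")
  regions <- utils::read.csv(file.path(adir, "regions.csv"))
  fit_rows <- list(); reg_rows <- list()
  for (i in seq_len(nrow(regions))) {
    rd <- file.path(adir, regions$region[i])
    files <- sort(list.files(rd, pattern = "\\.csv$", full.names = TRUE))
    curves <- lapply(files, read_force_curve)
    sm <- stiffness_map(curves,
                        c(regions$grid_rows[i], regions$grid_cols[i]))
    ft <- sm$fits
    ft$region <- regions$region[i]
    ft$file <- basename(files)
    fit_rows[[i]] <- ft
    reg_rows[[i]] <- tibble::tibble(region = regions$region[i],
                                    true_modulus_Pa = regions$true_modulus_Pa[i],
                                    median_modulus_Pa = sm$median,
                                    iqr_Pa = sm$iqr,
                                    n_ok = sum(sm$fits$ok),
                                    n_total = nrow(sm$fits),
                                    usable = sm$usable)
  }
  write_table_csv(do.call(rbind, fit_rows), file.path(adir, "fits.csv"))
  out <- do.call(rbind, reg_rows)
  write_table_csv(out, file.path(adir, "region_summary.csv"))
  write_manifest(rundir)
  out
}

#' Run the full pipeline
#'
#' simulate -> quantify -> stats -> afm under one run directory,
#' deterministic per configuration.
#'
#' @param config A [run_config()].
#' @param outdir Run directory.
#' @return List with the stats table (\code{correlations}), the measured
#'   cohort (\code{measured}), the AFM region summary (\code{afm}) and
#'   \code{outdir}.
#' @export
run_all <- function(config, outdir) {
  simulate_run(config, outdir)
  measured <- quantify_run(outdir)
  cohort <- utils::read.csv(file.path(outdir, "cohort.csv"))
  correlations <- stats_run(cohort,
                            pairs = default_pairs(config$stats$bin_widths),
                            outdir = file.path(outdir, "stats"),
                            n_iterations = config$stats$n_iterations,
                            seed = config$seed,
                            sided = config$stats$sided,
                            loess_span = config$stats$loess_span)
  afm <- afm_run(outdir)
  write_manifest(outdir)
  list(correlations = correlations, measured = measured, afm = afm,
       outdir = outdir)
}

#' Consistency audit of a cohort table
#'
#' Recomputes the derived indices of every row from its raw columns
#' through the geometry functions and checks agreement to a tolerance.
#' Guards against derived columns drifting from their definitions (or
#' being copied from ground truth).
#'
#' @param cohort Data frame with columns \code{true_apical_area},
#'   \code{true_height}, \code{true_d_cell}, \code{true_a}, \code{true_c},
#'   \code{true_d_nuc}, \code{true_strain}.
#' @param tol Absolute tolerance.
#' @return TRUE invisibly; error if any row is inconsistent.
#' @export
audit_cohort <- function(cohort, tol = 1e-9) {
  d_cell <- cell_deformation_index(cohort$true_apical_area,
                                   cohort$true_height)
  if (max(abs(d_cell - cohort$true_d_cell)) > tol)
    stop("d_cell column inconsistent with raw apical area / height",
         call. = FALSE)
  if (max(abs(2 * log(cohort$true_a / cohort$true_c) -
              cohort$true_d_nuc)) > tol)
    stop("d_nuc column inconsistent with semi-axes", call. = FALSE)
  strain <- surface_area_strain(spheroid_shape(cohort$true_a,
                                               cohort$true_c))$strain
  if (max(abs(strain - cohort$true_strain)) > tol)
    stop("strain column inconsistent with semi-axes", call. = FALSE)
  invisible(TRUE)
}
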