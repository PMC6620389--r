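# Batch processing: directories of SWC (and optional TIFF) inputs to
# per-neuron feature tables and cohort statistics.

#' Full pipeline configuration
#'
#' Bundles the classification, morphometry, segmentation and spatial
#' settings with the unit conversion and file-name parsing pattern. All
#' defaults are the standard thresholds of the method: 2 um angle windows,
#' 155 deg bend threshold, 4 um suppression, 8 um thickness windows, 2 SD
#' bead rule, 1 um interaction distance.
#'
#' @param classify A [classify_config()].
#' @param morph A [morph_config()].
#' @param segment A [segment_config()].
#' @param voxel_dims Voxel size (um) used both for SWC unit conversion of
#'   voxel-unit traces and for TIFF stacks.
#' @param swc_units `"um"` if traces are already in micrometres (the
#'   synthetic generator's convention), `"voxel"` to convert with
#'   `voxel_dims` at read time.
#' @param interaction_distance Interaction distance r (um) for the
#'   bend-outgrowth association test.
#' @param name_pattern Regex with named-by-position groups for
#'   STRAIN_SERIES_AGE_NEURON# file-name metadata.
#' @param n_boot Bootstrap resamples for group confidence intervals.
#' @param seed RNG seed for the stochastic steps (bootstrap).
#' @return A list of class `run_config`.
#' @export
run_config <- function(classify = classify_config(), morph = morph_config(),
                       segment = segment_config(),
                       voxel_dims = c(0.223, 0.223, 0.3),
                       swc_units = c("um", "voxel"),
                       interaction_distance = 1,
                       name_pattern = "^([^_]+)_([^_]+)_([^_]+)_([A-Za-z]+)([0-9]+)$",
                       n_boot = 2000, seed = 1) {
  structure(list(classify = classify, morph = morph, segment = segment,
                 voxel_dims = rep_len(voxel_dims, 3L),
                 swc_units = match.arg(swc_units),
                 interaction_distance = interaction_distance,
                 name_pattern = name_pattern, n_boot = n_boot, seed = seed),
            class = "run_config")
}

#' Parse STRAIN_SERIES_AGE_NEURON# metadata from a file name
#'
#' @param name File name (with or without extension/path).
#' @param pattern Regex with five groups: strain, series, age, neuron
#'   class, neuron number.
#' @return List with `strain`, `series`, `age`, `neuron_class`, `number`,
#'   `group` (strain_age), or `NULL` if the name does not match.
#' @export
parse_neuron_filename <- function(name,
                                  pattern = "^([^_]+)_([^_]+)_([^_]+)_([A-Za-z]+)([0-9]+)$") {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(name))
  m <- regmatches(base, regexec(pattern, base))[[1L]]
  if (length(m) != 6L) return(NULL)
  list(strain = m[2L], series = m[3L], age = m[4L],
       neuron_class = toupper(m[5L]), number = as.integer(m[6L]),
       group = paste(m[2L], m[4L], sep = "_"))
}

#' Quantify one neuron
#'
#' Runs read, classify (ALM or PLM), bend and bead detection, and - for
#' ALM neurons with an image stack - soma segmentation, and returns a
#' one-row feature summary.
#'
#' @param swc_path Path to the SWC trace.
#' @param tiff_path Optional path to the matching TIFF stack (ALM soma
#'   volume).
#' @param neuron_class `"ALM"` or `"PLM"`; if `NULL`, inferred from the
#'   file name.
#' @param cfg A [run_config()].
#' @param neuron_id Identifier; defaults to the file base name.
#' @return A one-row data frame (`neuron_summary`); on failure the row
#'   carries `ok = FALSE` and the error message, so batch runs continue.
#' @export
process_neuron <- function(swc_path, tiff_path = NULL, neuron_class = NULL,
                           cfg = run_config(), neuron_id = NULL) {
  neuron_id <- neuron_id %||% sub("\\.[A-Za-z0-9]+$", "",
                                  basename(swc_path))
  meta <- parse_neuron_filename(swc_path, cfg$name_pattern)
  neuron_class <- toupper(neuron_class %||% meta$neuron_class %||% "PLM")
  row <- data.frame(
    neuron_id = neuron_id, neuron_class = neuron_class,
    strain = meta$strain %||% NA_character_,
    age = meta$age %||% NA_character_,
    group = meta$group %||% NA_character_,
    main_length_um = NA_real_, soma_volume_um3 = NA_real_,
    soma_outgrowth_count = NA_integer_, soma_outgrowth_length_um = NA_real_,
    neurite_outgrowth_count = NA_integer_,
    neurite_outgrowth_length_um = NA_real_,
    bend_count = NA_integer_, bend_density = NA_real_,
    bead_count = NA_integer_, bead_density = NA_real_,
    ok = FALSE, error = NA_character_,
    config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("neuritemorph")),
    stringsAsFactors = FALSE)
  result <- tryCatch({
    scale <- if (cfg$swc_units == "voxel") cfg$voxel_dims else c(1, 1, 1)
    tree <- read_swc(swc_path, unit_scale = scale)
    ct <- if (neuron_class == "ALM") classify_alm(tree, cfg$classify)
          else classify_plm(tree, cfg$classify)
    inv <- branch_inventory(ct)
    geom <- main_branch_geometry(ct)
    bends <- detect_bends(geom, cfg$morph)
    beads <- detect_beads(geom, cfg$morph)
    so <- inv[inv$label == "somaoutgrowth", , drop = FALSE]
    no <- inv[inv$label == "neuriteoutgrowth", , drop = FALSE]
    row$main_length_um <- ct$main_length
    row$soma_outgrowth_count <- nrow(so)
    row$soma_outgrowth_length_um <- sum(so$length_um)
    row$neurite_outgrowth_count <- nrow(no)
    row$neurite_outgrowth_length_um <- sum(no$length_um)
    row$bend_count <- nrow(bends)
    row$bend_density <- nrow(bends) / ct$main_length
    row$bead_count <- nrow(beads)
    row$bead_density <- nrow(beads) / ct$main_length
    if (neuron_class == "ALM" && !is.null(tiff_path)) {
      stack <- read_stack(tiff_path, cfg$voxel_dims)
      seg <- segment_soma(stack, ct, cfg$segment)
      row$soma_volume_um3 <- seg$volume
    }
    row$ok <- TRUE
    attr(row, "events") <- list(ct = ct, bends = bends, beads = beads,
                                inventory = inv)
    row
  }, error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
  result
}

#' Quantify a directory of neurons and compute cohort statistics
#'
#' Processes every `*.swc` file (matching TIFF stacks are picked up by
#' base name), writes a per-neuron CSV and a cohort statistics JSON:
#' per-group means of the morphometric features with bootstrap confidence
#' intervals, the bend-outgrowth association test over neurons with both
#' event types, and pairwise two-sample KS comparisons of bend positions
#' between groups. Failures in single neurons are recorded in their row
#' and do not abort the batch. Deterministic under a fixed config seed.
#'
#' @param input_dir Directory of SWC (and optional TIFF) files.
#' @param cfg A [run_config()].
#' @param output_dir Where to write `neuron_summaries.csv` and
#'   `cohort_stats.json`; `NULL` skips writing.
#' @return List with `summaries` (data frame) and `stats` (list).
#' @export
process_cohort <- function(input_dir, cfg = run_config(),
                           output_dir = NULL) {
  swc_files <- sort(list.files(input_dir, pattern = "\\.swc$",
                               full.names = TRUE))
  if (!length(swc_files)) stop("no SWC files found in ", input_dir)
  rows <- list()
  positions <- list()
  for (f in swc_files) {
    tif <- sub("\\.swc$", ".tif", f)
    row <- process_neuron(f, tiff_path = if (file.exists(tif)) tif,
                          cfg = cfg)
    ev <- attr(row, "events")
    if (!is.null(ev) && row$neuron_class == "PLM") {
      positions[[row$neuron_id]] <- list(
        ep = positions_from_distal(ev$ct, ev$bends, ev$inventory,
                                   neuron_id = row$neuron_id),
        group = row$group)
    }
    attr(row, "events") <- NULL
    rows[[length(rows) + 1L]] <- row
  }
  summaries <- do.call(rbind, rows)
  stats_out <- list(config_hash = config_hash(cfg),
                    n_neurons = nrow(summaries),
                    n_failed = sum(!summaries$ok))
  ok <- summaries[summaries$ok, , drop = FALSE]
  groups <- unique(ok$group[!is.na(ok$group)])
  feature_cols <- c("bend_density", "bead_density",
                    "neurite_outgrowth_count", "soma_outgrowth_count",
                    "main_length_um", "soma_volume_um3")
  if (length(groups)) {
    gstats <- list()
    bi <- 0L
    for (g in groups) {
      sub <- ok[ok$group %in% g, , drop = FALSE]
      fs <- list(n = nrow(sub))
      for (fc in feature_cols) {
        vals <- sub[[fc]][!is.na(sub[[fc]])]
        if (length(vals) >= 2L) {
          bi <- bi + 1L
          ci <- bootstrap_ci_mean(vals, n_boot = cfg$n_boot,
                                  seed = cfg$seed + bi)
          fs[[fc]] <- list(mean = mean(vals), ci_low = ci[["low"]],
                           ci_high = ci[["high"]])
        } else if (length(vals) == 1L) {
          fs[[fc]] <- list(mean = vals, ci_low = NA, ci_high = NA)
        }
      }
      gstats[[g]] <- fs
    }
    stats_out$groups <- gstats
  }
  if (length(positions) >= 2L) {
    eps <- lapply(positions, `[[`, "ep")
    usable <- vapply(eps, function(ep)
      length(ep$bend_positions) > 0 && length(ep$outgrowth_positions) > 0,
      logical(1))
    if (sum(usable) >= 6L) {
      assoc <- suppressWarnings(
        association_test(eps, r = cfg$interaction_distance))
      stats_out$association <- list(
        n_neurons = assoc$n_neurons, statistic = assoc$statistic,
        p.value = assoc$p.value, r = assoc$r)
    } else {
      stats_out$association <- list(
        skipped = "fewer than 6 neurons with both bends and outgrowths")
    }
    pos_groups <- vapply(positions, `[[`, character(1), "group")
    gl <- unique(pos_groups[!is.na(pos_groups)])
    if (length(gl) >= 2L) {
      ks <- list()
      for (i in seq_along(gl)[-length(gl)]) for (j in (i + 1L):length(gl)) {
        a <- unlist(lapply(eps[pos_groups %in% gl[i]],
                           `[[`, "bend_positions"))
        b <- unlist(lapply(eps[pos_groups %in% gl[j]],
                           `[[`, "bend_positions"))
        if (length(a) && length(b)) {
          kt <- ks_two_sample(a, b)
          ks[[paste(gl[i], "vs", gl[j])]] <-
            list(D = kt$statistic, p.value = kt$p.value)
        }
      }
      if (length(ks)) stats_out$ks_bend_positions <- ks
    }
  } else if (nrow(summaries) < 2L) {
    warning("single-neuron cohort: cohort statistics skipped")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries,
                     file.path(output_dir, "neuron_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out,
                         file.path(output_dir, "cohort_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summaries = summaries, stats = stats_out)
}

#' Write a synthetic fixture set to disk
#'
#' Generates a cohort with [make_cohort()] and writes one SWC file per
#' neuron (named `STRAIN_SERIES_AGE_CLASS#.swc`) plus a JSON ground-truth
#' sidecar, ready for [process_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param output_dir Output directory.
#' @param strain,series,age,neuron_class Metadata baked into file names.
#' @return Character vector of SWC paths, invisibly.
#' @export
write_fixture_cohort <- function(spec, output_dir, strain = "WT",
                                 series = "A", age = "8",
                                 neuron_class = "PLM") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- make_cohort(spec)
  paths <- character(0)
  for (i in seq_along(cohort)) {
    base <- sprintf("%s_%s_%s_%s%d", strain, series, age, neuron_class, i)
    swc <- file.path(output_dir, paste0(base, ".swc"))
    write_swc(cohort[[i]]$tree, swc)
    jsonlite::write_json(cohort[[i]]$truth,
                         file.path(output_dir, paste0(base, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, swc)
  }
  invisible(paths)
}
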