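#' Read a schema-validated CSV table
#'
#' CSV dialect: UTF-8, comma-separated, header row, `.` decimal. Required
#' columns are checked by name and (optionally) type; extra metadata
#' columns pass through untouched. Errors name the offending column.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must be numeric.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character(0),
                               numeric_cols = character(0)) {
  .check(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  .check(length(miss) == 0,
         sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  for (cl in intersect(numeric_cols, names(df))) {
    .check(is.numeric(df[[cl]]),
           sprintf("column '%s' must be numeric", cl))
  }
  df
}

#' Write a table as CSV
#'
#' Counterpart of [read_table_checked()]; plain UTF-8 CSV with header, no
#' row names, full double precision.
#'
#' @param df data.frame.
#' @param path output path (parent directory is created).
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Bundles per-stage parameter objects with a master seed. Each stochastic
#' stage receives a seed derived deterministically from the master seed and
#' the stage name (see [derive_seed()]), so stages are independently
#' reproducible.
#'
#' @param master_seed integer master seed.
#' @param out_dir output directory for tables and the manifest.
#' @param synthetic a [synthetic_cohort_spec()].
#' @param assembly an [assembly_params()].
#' @param single_complex a [single_complex_params()].
#' @param scan_doses,scan_affs,scan_reps dose/affinity scan settings for the
#'   `dose_response` recipe.
#' @param spot_affinities affinities compared in the `single_complex`
#'   recipe.
#' @return an object of class `run_config`.
#' @export
run_config <- function(master_seed = 1L, out_dir = tempfile("quantalci_run_"),
                       synthetic = synthetic_cohort_spec(),
                       assembly = assembly_params(),
                       single_complex = single_complex_params(),
                       scan_doses = 10^seq(-3, 1, by = 1),
                       scan_affs = c(1, 0.01), scan_reps = 5L,
                       spot_affinities = c(1, 0.01)) {
  structure(list(master_seed = as.integer(master_seed), out_dir = out_dir,
                 synthetic = synthetic, assembly = assembly,
                 single_complex = single_complex, scan_doses = scan_doses,
                 scan_affs = scan_affs, scan_reps = scan_reps,
                 spot_affinities = spot_affinities),
            class = "run_config")
}

#' Run an end-to-end analysis recipe
#'
#' Chains the package's stages on synthetic inputs and writes every
#' intermediate table plus a JSON manifest (inputs, seeds, file checksums).
#' Rerunning with the same configuration reproduces the checksums exactly.
#'
#' Recipes:
#' * `dose_response`: synthetic spot-count cohort -> descriptor table ->
#'   per-dose means -> Hill fit and EC50 per affinity -> Fano table; plus a
#'   stochastic assembly scan -> logistic fit per affinity.
#' * `single_complex`: HyDeS tracks at the configured affinities (all three
#'   variants) -> per-spot descriptors -> left-tailed comparisons.
#' * `full`: both.
#'
#' @param config a [run_config()].
#' @param recipe one of `"dose_response"`, `"single_complex"`, `"full"`.
#' @return the manifest, invisibly: list with `recipe`, `master_seed`,
#'   `outputs` (named file list with md5 checksums), and per-stage seeds.
#' @export
run_pipeline <- function(config,
                         recipe = c("dose_response", "single_complex",
                                    "full")) {
  stopifnot(inherits(config, "run_config"))
  recipe <- match.arg(recipe)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  seeds <- list()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    write_table_checked(df, p)
    outputs[[name]] <<- p
    p
  }

  if (recipe %in% c("dose_response", "full")) {
    # synthetic cohorts per affinity -> descriptors -> Hill fits
    fits <- list()
    for (aff in config$scan_affs) {
      sp <- config$synthetic
      sp$relative_affinity <- aff
      sp$seed <- derive_seed(config$master_seed,
                             sprintf("synthetic_a%g", aff))
      seeds[[sprintf("synthetic_a%g", aff)]] <- sp$seed
      tc <- gen_spot_count_timecourses(sp)
      emit(tc, sprintf("spot_counts_aff%g", aff))
      desc <- descriptor_table(tc, id = "cell_id")
      emit(desc, sprintf("descriptors_aff%g", aff))
      means <- vapply(split(desc$max, desc$dose), mean, numeric(1))
      dd <- as.numeric(names(means))
      fit <- fit_hill(dd, unname(means))
      fits[[length(fits) + 1L]] <-
        data.frame(affinity = aff, y_max = fit$y_max, ka = fit$ka,
                   n = fit$n, r2 = fit$r2,
                   ec50 = if (fit$converged) ec50(fit) else NA_real_)
      fano <- group_fano(desc, c("species", "dose"), "auc")
      emit(fano, sprintf("fano_aff%g", aff))
    }
    emit(do.call(rbind, fits), "hill_fits")
    # stochastic assembly scan -> logistic fit per affinity
    ap <- config$assembly
    ap$seed <- derive_seed(config$master_seed, "assembly_scan")
    seeds$assembly_scan <- ap$seed
    scan <- scan_dose_affinity(ap, config$scan_doses, config$scan_affs,
                               n_reps = config$scan_reps)
    emit(scan, "assembly_scan")
    lfits <- lapply(config$scan_affs, function(aff) {
      sub <- scan[scan$aff == aff, ]
      means <- vapply(split(sub$auc, sub$dose), mean, numeric(1))
      fit <- fit_logistic(log10(as.numeric(names(means))), unname(means))
      data.frame(affinity = aff, y_max = fit$y_max, ka = fit$ka,
                 x0 = fit$x0, r2 = fit$r2,
                 ec50 = if (fit$converged) ec50(fit) else NA_real_)
    })
    emit(do.call(rbind, lfits), "logistic_fits")
  }

  if (recipe %in% c("single_complex", "full")) {
    desc_all <- list()
    for (variant in c("bound_toggle", "growth_scale", "dub_suppression")) {
      for (aff in config$spot_affinities) {
        p <- config$single_complex
        p$variant <- variant
        p$affinity <- aff
        p$seed <- derive_seed(config$master_seed,
                              sprintf("spots_%s_a%g", variant, aff))
        seeds[[sprintf("spots_%s_a%g", variant, aff)]] <- p$seed
        tracks <- simulate_single_complexes(p)
        desc <- spot_descriptors(tracks)
        desc$variant <- variant
        desc$affinity <- aff
        desc_all[[length(desc_all) + 1L]] <- desc
      }
    }
    desc_all <- do.call(rbind, desc_all)
    emit(desc_all, "spot_descriptors")
    comps <- lapply(split(desc_all, desc_all$variant), function(sub) {
      out <- compare_conditions(sub$auc, sub$affinity)
      out$variant <- sub$variant[1]
      out
    })
    emit(do.call(rbind, comps), "spot_comparisons")
  }

  manifest <- list(recipe = recipe, master_seed = config$master_seed,
                   seeds = seeds,
                   outputs = lapply(outputs, function(p)
                     list(path = p,
                          md5 = unname(tools::md5sum(p)))))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Per-spot descriptor table from simulated tracks
#'
#' Computes [compute_descriptors()] on each spot's intensity track (from
#' its formation onward).
#'
#' @param tracks a `spot_tracks` data.frame.
#' @return data.frame, one row per spot: `spot_id` plus descriptor columns.
#' @export
spot_descriptors <- function(tracks) {
  ids <- unique(tracks$spot_id)
  rows <- lapply(ids, function(g) {
    sub <- tracks[tracks$spot_id == g, , drop = FALSE]
    d <- as.data.frame(compute_descriptors(
      trajectory(sub$time, pmax(sub$intensity, 0))))
    cbind(data.frame(spot_id = g), d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
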