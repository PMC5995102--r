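#' Describe one specimen of a study
#'
#' @param specimen_id unique specimen identifier.
#' @param group_label treatment label (e.g. "defended"/"undefended").
#' @param stack_path path to a TIFF stack (mutually exclusive with
#'   `mesh_path`).
#' @param mesh_path path to an OBJ surface mesh.
#' @param landmarks_path optional landmark pair CSV for grid warping.
#' @param threshold iso-surface threshold (stack specimens only; the signal
#'   level is stack-specific and must be chosen per specimen).
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres (stack
#'   specimens).
#' @return A list of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, group_label, stack_path = NULL,
                            mesh_path = NULL, landmarks_path = NULL,
                            threshold = NULL, spacing = NULL) {
  if (is.null(stack_path) == is.null(mesh_path))
    abort("exactly one of stack_path/mesh_path must be given")
  if (!is.null(stack_path) && is.null(threshold))
    abort("stack specimens need an iso-surface threshold")
  structure(list(specimen_id = as.character(specimen_id),
                 group_label = as.character(group_label),
                 stack_path = stack_path, mesh_path = mesh_path,
                 landmarks_path = landmarks_path, threshold = threshold,
                 spacing = spacing),
            class = "specimen_record")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

#' Run a complete study from one configuration
#'
#' Orchestrates the full pipeline: obtain casts (either by simulating a
#' synthetic population or by extracting + wrapping the configured
#' specimens), star-align everything to a prototype, compute group mean
#' models, the displacement field, the dense Wilcoxon p/q fields, the
#' confidence-ellipsoid overlap map and the permutation validation, and
#' write `stats.tsv`, `overlap.tsv`, mean-model tables, coloured PLY
#' renders and a run manifest into `out_dir`. Stages whose inputs
#' (configuration hash) and recorded outputs are unchanged are not
#' recomputed on a re-run.
#'
#' @param config a [study_config()]. For a synthetic study include a
#'   `simulate` list (fields of [group_effect()] plus `n_control`,
#'   `n_treated`); for real specimens include `specimens`, a list of
#'   [specimen_record()]s (at least 2 per group for the statistical
#'   stages), and `grid_bbox`.
#' @param out_dir output directory.
#' @return A result bundle (list) with the casts, aligned groups, models,
#'   displacement field, test field, overlap map, permutation maps and
#'   file paths.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  stats_path <- file.path(out_dir, "stats.tsv")
  overlap_path <- file.path(out_dir, "overlap.tsv")
  cached <- FALSE
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    outs <- unlist(man$outputs)
    if (identical(man$config_hash[[1]], unname(hash)) &&
          length(outs) > 0 && all(file.exists(names(outs))) &&
          identical(unname(tools::md5sum(names(outs))), unname(outs)))
      cached <- TRUE
  }
  mw_log("run", sprintf("config hash %s%s", hash,
                        if (cached) " (outputs cached)" else ""), logfile)

  groups <- gather_casts(config, logfile)
  if (length(groups$casts) < 2 || length(unique(groups$labels)) < 2)
    abort("stage stats: need two groups with >= 2 specimens each")
  lab <- unique(groups$labels)
  ia <- which(groups$labels == lab[1])
  ib <- which(groups$labels == lab[2])
  if (length(ia) < 2 || length(ib) < 2)
    abort("stage stats: need >= 2 specimens per group")

  mw_log("align", sprintf("prototype: first %s cast", lab[1]), logfile)
  aligned <- align_group(groups$casts, prototype = ia[1],
                         allow_scaling = isTRUE(config$allow_scaling))
  ga <- aligned[ia]; gb <- aligned[ib]

  mw_log("stats", "mean models, displacement, rank-sum + q fields", logfile)
  model_a <- mean_model(ga)
  model_b <- mean_model(gb)
  disp <- displacement_field(model_a, model_b,
                             allow_scaling = isTRUE(config$allow_scaling))
  tests <- qvalue_map(wilcoxon_map(ga, gb))
  counts <- significance_counts(tests, config$p_threshold)

  mw_log("ellipsoids", "confidence ellipsoids + overlap map", logfile)
  ea <- confidence_ellipsoids(ga, config$ci_level)
  eb <- confidence_ellipsoids(gb, config$ci_level)
  overlap <- overlap_map(ea, eb)
  n_perm <- config$n_permutations %||% 3
  perms <- permute_and_test(aligned, groups$labels, fraction = 0.5,
                            n_permutations = n_perm,
                            seed = config$seed, ci_level = config$ci_level)

  mw_log("export", sprintf("writing results to %s", out_dir), logfile)
  stats_tbl <- tests |>
    dplyr::left_join(tibble(id = disp$id, dx = disp$dx, dy = disp$dy,
                            dz = disp$dz, magnitude = disp$magnitude),
                     by = "id")
  utils::write.table(stats_tbl, stats_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(overlap, overlap_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  model_a_path <- file.path(out_dir, sprintf("model_%s.csv", lab[1]))
  model_b_path <- file.path(out_dir, sprintf("model_%s.csv", lab[2]))
  export_point_table(model_a, model_a_path)
  export_point_table(model_b, model_b_path)
  ply_path <- file.path(out_dir, "displacement.ply")
  render_model(model_a[model_a$id %in% disp$id, ],
               tibble(id = disp$id, colour = colorize(disp$magnitude,
                                                      "magnitude")),
               ply_path)
  overlap_ply <- file.path(out_dir, "overlap.ply")
  render_model(model_a[model_a$id %in% overlap$id, ],
               tibble(id = overlap$id,
                      colour = colorize(overlap$overlap, "overlap")),
               overlap_ply)
  outputs <- c(stats_path, overlap_path, model_a_path, model_b_path,
               ply_path, overlap_ply)
  manifest <- list(tool = "morphowrap",
                   version = as.character(utils::packageVersion("morphowrap")),
                   config_hash = unname(hash), seed = config$seed,
                   groups = as.list(table(groups$labels)),
                   outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(casts = groups$casts, labels = groups$labels,
                 aligned = aligned, model_a = model_a, model_b = model_b,
                 displacement = disp, tests = tests, counts = counts,
                 fdr = fdr_summary(tests), ellipsoids_a = ea,
                 ellipsoids_b = eb, overlap = overlap,
                 permutations = perms, truth = groups$truth,
                 outputs = outputs, manifest = manifest_path,
                 cached = cached))
}

# obtain casts + labels, from the simulate block or from specimen records
gather_casts <- function(config, logfile) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    eff <- group_effect(
      global_scale = sim$global_scale %||% 1.1,
      spine_elongation = sim$spine_elongation %||% 1.3,
      head_bump_amplitude = sim$head_bump_amplitude %||% 40,
      individual_noise_sd = sim$individual_noise_sd %||% 5)
    base <- do.call(body_params,
                    sim$body %||% list())
    grid <- NULL
    if (!is.null(config$grid_rows) && !is.null(sim$grid_bbox))
      grid <- build_grid(config$grid_rows, config$grid_cols,
                         unlist(sim$grid_bbox))
    mw_log("simulate", sprintf("n = %d vs %d, seed %d",
                               sim$n_control %||% 10, sim$n_treated %||% 9,
                               config$seed), logfile)
    pop <- make_population(base, eff,
                           n_control = sim$n_control %||% 10,
                           n_treated = sim$n_treated %||% 9,
                           seed = config$seed, grid = grid)
    list(casts = c(pop$control, pop$treated),
         labels = rep(c("control", "treated"),
                      c(length(pop$control), length(pop$treated))),
         truth = pop$truth)
  } else if (!is.null(config$specimens)) {
    specs <- config$specimens
    if (is.null(config$grid_bbox))
      abort("specimen studies need a grid_bbox in the config")
    template <- build_grid(config$grid_rows, config$grid_cols,
                           unlist(config$grid_bbox))
    casts <- lapply(specs, function(sp) {
      if (!inherits(sp, "specimen_record")) sp <- do.call(specimen_record, sp)
      mesh <- if (!is.null(sp$mesh_path)) {
        read_mesh(sp$mesh_path)
      } else {
        mw_log("extract", sp$specimen_id, logfile)
        vol <- read_stack(sp$stack_path, spacing = sp$spacing)
        vol <- gaussian_blur(vol, config$blur_sigma_um)
        m <- extract_surface(vol, sp$threshold, config$cube_size_um)
        smooth_mesh(m, config$smoothing_passes)
      }
      mw_log("wrap", sp$specimen_id, logfile)
      lp <- if (!is.null(sp$landmarks_path))
        read_landmark_pairs(sp$landmarks_path)
      wrap_specimen(mesh, template, landmark_pairs = lp)
    })
    list(casts = casts,
         labels = vapply(specs, function(sp)
           if (inherits(sp, "specimen_record")) sp$group_label
           else sp$group_label, character(1)),
         truth = NULL)
  } else {
    abort("config needs either a simulate block or specimens")
  }
}
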