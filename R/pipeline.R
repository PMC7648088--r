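#' Hash a configuration list
#'
#' md5 of a canonical JSON rendering with recursively sorted keys, so the
#' hash is stable under key reordering.
#'
#' @param config a (nested) list.
#' @return hex string.
#' @export
config_hash <- function(config) canonical_hash(config)

provenance_record <- function(config, inputs = character(), seed = NA) {
  list(tool = "fibroswarm",
       version = as.character(utils::packageVersion("fibroswarm")),
       config_hash = config_hash(config),
       input_hashes = as.list(if (length(inputs) > 0)
         vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
         else stats::setNames(list(), character())),
       seed = seed,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

write_provenance <- function(prov, artefact_path) {
  jsonlite::write_json(prov, paste0(artefact_path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run a multi-stage analysis pipeline from a configuration
#'
#' Executes the selected stages in dependency order
#' (`simulate` -> `render` -> `piv`; `simulate`/`tracks` ->
#' `kinematics` / `similarity` / `landmarks`; `fractal` on an image input),
#' writing every artefact with a provenance sidecar (tool version, config
#' hash, input hashes, seed, timestamp).  Identical configuration and seed
#' produce byte-identical CSV artefacts.  Stage dependencies are checked
#' before any computation runs.
#'
#' @param config configuration list or path to a YAML file with one section
#'   per stage (`simulate`, `render`, `piv`, `kinematics`, `similarity`,
#'   `landmarks`, `fractal`) plus optional top-level `seed`, `tracks`
#'   (input CSV) and `movie` (input TIFF).
#' @param out_dir output directory (created if missing).
#' @param seed overrides the config seed.
#' @return named list of artefact paths and in-memory results, invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("fibroswarm_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  seed <- seed %||% config$seed %||% 1
  stages <- intersect(c("simulate", "render", "piv", "kinematics",
                        "similarity", "landmarks", "fractal"), names(config))
  if (length(stages) == 0) stop("plan error: no recognised stage in config")

  # ---- plan check before any computation ----
  have_tracks <- "simulate" %in% stages || !is.null(config$tracks)
  have_movie <- "render" %in% stages || !is.null(config$movie)
  for (st in intersect(c("kinematics", "similarity", "landmarks"), stages)) {
    if (!have_tracks) {
      stop("plan error: stage '", st, "' needs tracks (simulate stage or a ",
           "top-level 'tracks' input)")
    }
  }
  if ("render" %in% stages && !have_tracks) {
    stop("plan error: stage 'render' needs tracks")
  }
  if ("piv" %in% stages && !have_movie) {
    stop("plan error: stage 'piv' needs a movie (render stage or a ",
         "top-level 'movie' input)")
  }
  if ("fractal" %in% stages && is.null(config$fractal$input)) {
    stop("plan error: stage 'fractal' needs an input image path")
  }
  for (p in c(config$tracks, config$movie, config$fractal$input)) {
    if (!file.exists(p)) stop("plan error: input not found: ", p)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- unlist(c(config$tracks, config$movie, config$fractal$input))
  prov <- function() provenance_record(config, inputs %||% character(), seed)
  res <- list(out_dir = out_dir)

  tracks <- NULL
  if ("simulate" %in% stages) {
    sc <- do.call(swarm_config, c(config$simulate, list(seed = seed)))
    tracks <- simulate_tracks(sc)
    p <- file.path(out_dir, "tracks.csv")
    write_tracks(tracks, p)
    write_provenance(prov(), p)
    res$tracks <- p
  } else if (!is.null(config$tracks)) {
    tracks <- read_tracks(config$tracks)
  }

  movie <- NULL
  if ("render" %in% stages) {
    rc <- do.call(render_config, c(config$render, list(seed = seed)))
    movie <- render_movie(tracks, rc)
    p <- file.path(out_dir, "movie.tif")
    write_image_stack(movie, p)
    write_provenance(prov(), p)
    res$movie <- p
  } else if (!is.null(config$movie)) {
    movie <- read_image_stack(config$movie)
  }

  if ("piv" %in% stages) {
    pc <- do.call(piv_config, config$piv[setdiff(names(config$piv),
                                                 c("frame_pair", "channel"))])
    fp <- config$piv$frame_pair %||% c(1, 2)
    ch <- config$piv$channel %||% 1
    fld <- run_piv(stack_frame(movie, fp[1], ch), stack_frame(movie, fp[2], ch),
                   pc)
    g <- expand.grid(y = seq_along(fld$grid_y), x = seq_along(fld$grid_x))
    df <- data.frame(x = fld$grid_x[g$x], y = fld$grid_y[g$y],
                     u = fld$u[cbind(g$y, g$x)], v = fld$v[cbind(g$y, g$x)],
                     valid = as.integer(fld$valid[cbind(g$y, g$x)]))
    for (cn in c("u", "v")) df[[cn]] <- formatC(df[[cn]], format = "g", digits = 6)
    p <- file.path(out_dir, "piv.csv")
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    write_provenance(prov(), p)
    res$piv <- p
  }

  if ("kinematics" %in% stages) {
    kin <- do.call(step_kinematics, c(list(tracks), config$kinematics))
    p <- file.path(out_dir, "kinematics.csv")
    df <- as.data.frame(kin$steps)
    for (cn in c("t_min", "step_displacement", "velocity")) {
      df[[cn]] <- formatC(df[[cn]], format = "g", digits = 6)
    }
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    write_provenance(prov(), p)
    res$kinematics <- p
  }

  if ("similarity" %in% stages) {
    sim <- do.call(movement_similarity, c(list(tracks), config$similarity))
    p <- file.path(out_dir, "similarity.csv")
    df <- as.data.frame(sim$per_cell)
    df$score <- formatC(df$score, format = "g", digits = 6)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    write_provenance(prov(), p)
    jsonlite::write_json(list(global_score = sim$global_score),
                         file.path(out_dir, "similarity_global.json"),
                         auto_unbox = TRUE, digits = NA)
    res$similarity <- p
    res$global_score <- sim$global_score
  }

  if ("landmarks" %in% stages) {
    lmk <- do.call(landmark_displacement, c(list(tracks), config$landmarks))
    p <- file.path(out_dir, "landmarks.csv")
    df <- as.data.frame(lmk)
    for (cn in c("t_min", "mean_displacement", "cumulative")) {
      df[[cn]] <- formatC(df[[cn]], format = "g", digits = 6)
    }
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    write_provenance(prov(), p)
    res$landmarks <- p
  }

  if ("fractal" %in% stages) {
    st <- read_image_stack(config$fractal$input)
    img <- stack_frame(st, 1, 1)
    fm <- fractal_metrics(img,
                          pixel_threshold = config$fractal$pixel_threshold %||% 0.40)
    p <- file.path(out_dir, "fractal.json")
    jsonlite::write_json(list(fd = fm$fd, lacunarity = fm$lacunarity,
                              fit_r2 = fm$fit_r2),
                         p, auto_unbox = TRUE, digits = NA)
    write_provenance(prov(), p)
    res$fractal <- p
  }
  invisible(res)
}
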