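.PIPELINE_KEYS <- c("scenes", "field_deg_iprgc", "field_deg_periphery",
                    "field_deg_lum", "window", "illuminants", "transform",
                    "tiling", "output_dir", "seed")
.SCENE_KEYS <- c("path", "synthetic", "environment", "pixels_per_degree",
                 "quantity", "seed", "mean_reflectance", "height", "width")

# short stable identifier of the analysis configuration, embedded in every
# output file; the output location itself does not change the analysis
.config_hash <- function(config) {
  config$output_dir <- NULL
  s <- paste(deparse(config), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration of the end-to-end pipeline.  Recognized keys:
#' \code{scenes} (list; each entry either \code{path} to a cube container or
#' \code{synthetic: true} with \code{environment}, \code{seed} and optional
#' generator fields), \code{field_deg_iprgc} (default 1.37),
#' \code{field_deg_periphery} (2.4), \code{field_deg_lum} (0.36),
#' \code{window} (\code{raised_cosine}/\code{literal_cosine}),
#' \code{illuminants} (character vector of \code{EES}, \code{D:<cct>} or file
#' paths; applied to reflectance scenes), \code{transform}
#' (\code{log}/\code{none}), \code{tiling} (\code{grid} or
#' \code{jitter:<seed>}), \code{output_dir}, \code{seed}.  Unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config configuration list (as from \code{yaml::read_yaml}).
#' @export
validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown) > 0)
    stop("unknown_config_keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$scenes) || length(config$scenes) == 0)
    stop("no_scenes: configuration lists no scenes", call. = FALSE)
  for (i in seq_along(config$scenes)) {
    sc <- config$scenes[[i]]
    unknown <- setdiff(names(sc), .SCENE_KEYS)
    if (length(unknown) > 0)
      stop("unknown_config_keys: scene ", i, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (is.null(sc$path) && !isTRUE(sc$synthetic))
      stop("invalid_scene_entry: scene ", i,
           " needs either a path or synthetic: true", call. = FALSE)
  }
  defaults <- list(field_deg_iprgc = 1.37, field_deg_periphery = 2.4,
                   field_deg_lum = 0.36, window = "raised_cosine",
                   transform = "log", tiling = "grid",
                   output_dir = NULL, seed = 1L, illuminants = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!config$window %in% WINDOW_MODES)
    stop("invalid_window: ", config$window, call. = FALSE)
  if (!config$transform %in% c("none", "log"))
    stop("invalid_transform: ", config$transform, call. = FALSE)
  config
}

.resolve_illuminant <- function(label) {
  if (label == "EES") return(equalEnergySPD())
  if (startsWith(label, "D:"))
    return(cieDaylightSPD(as.numeric(sub("^D:", "", label))))
  readSpectrum(label, kind = "spd")
}

.load_scene <- function(entry, config) {
  if (isTRUE(entry$synthetic)) {
    spec <- sceneGeneratorSpec(
      environment = entry$environment,
      height = if (is.null(entry$height)) 180L else entry$height,
      width = if (is.null(entry$width)) 180L else entry$width,
      pixelsPerDegree = if (is.null(entry$pixels_per_degree)) 32
        else entry$pixels_per_degree,
      meanReflectance = entry$mean_reflectance,
      seed = if (is.null(entry$seed)) config$seed else entry$seed)
    generateScene(spec)
  } else {
    readScene(entry$path, environment = entry$environment,
              pixelsPerDegree = entry$pixels_per_degree)
  }
}

.jitter_seed <- function(tiling) {
  if (startsWith(tiling, "jitter:")) as.integer(sub("^jitter:", "", tiling))
  else NULL
}

.scene_records <- function(scene, config) {
  scene <- resampleScene(scene)
  maps <- computeAllChannels(scene)
  ppd <- pixelsPerDegree(scene)
  jseed <- .jitter_seed(config$tiling)
  shape <- dim(mapValues(maps$Mel))
  layouts <- list(
    parafovea = tilePatches(shape, receptiveFieldSpec(config$field_deg_iprgc,
                                                      config$window),
                            ppd, sceneId = sceneId(scene), jitterSeed = jseed),
    periphery = tilePatches(shape, receptiveFieldSpec(config$field_deg_periphery,
                                                      config$window),
                            ppd, sceneId = sceneId(scene), jitterSeed = jseed))
  lum_layout <- coCenteredLayout(layouts$parafovea,
                                 receptiveFieldSpec(config$field_deg_lum,
                                                    config$window), ppd)
  recs <- list()
  for (ch in c("Mel", "ipRGC1", "ipRGC2")) {
    for (ly in names(layouts))
      recs[[paste(ch, ly)]] <- contrastRecords(
        betweenPatchContrast(localExcitation(maps[[ch]], layouts[[ly]])))
  }
  recs[["Lum"]] <- contrastRecords(
    betweenPatchContrast(localExcitation(maps$Lum, lum_layout)))
  recs[["Rad"]] <- contrastRecords(
    betweenPatchContrast(localRadiance(scene, layouts$parafovea)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$environment <- environmentLabel(scene)
  out
}

.summaries <- function(records) {
  keys <- unique(records[, c("environment", "channel", "field_deg")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- records$environment == keys$environment[i] &
      records$channel == keys$channel[i] &
      records$field_deg == keys$field_deg[i]
    abs_s <- summarizeMedianIQR(records$local_value[sel])
    con_s <- summarizeMedianIQR(records$contrast[sel])
    data.frame(keys[i, ], n = sum(sel),
               absolute_median = abs_s[["median"]], absolute_iqr = abs_s[["iqr"]],
               contrast_median = con_s[["median"]], contrast_iqr = con_s[["iqr"]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.comparisons <- function(records, transform) {
  keys <- unique(records[, c("channel", "field_deg")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- records$channel == keys$channel[i] &
      records$field_deg == keys$field_deg[i]
    nat <- records[sel & records$environment == "natural", ]
    hm <- records[sel & records$environment == "human_made", ]
    if (nrow(nat) < 3 || nrow(hm) < 3) next
    for (metric in c("local_value", "contrast")) {
      tr <- if (metric == "local_value") transform else "none"
      cmp <- tryCatch(compareGroups(nat[[metric]], hm[[metric]], transform = tr),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      cmp$channel <- keys$channel[i]
      cmp$field_deg <- keys$field_deg[i]
      cmp$metric <- metric
      out[[length(out) + 1L]] <- cmp
    }
  }
  do.call(rbind, out)
}

.nrd_analysis <- function(scene_entries, config) {
  metrics <- c("Mel", "Lum", "Rad")
  means <- list()
  for (ill_label in config$illuminants) {
    ill <- .resolve_illuminant(ill_label)
    for (entry in scene_entries) {
      scene <- .load_scene(entry, config)
      if (quantity(scene) != "reflectance") next
      rad <- applyIlluminant(scene, ill)
      maps <- computeAllChannels(rad)
      layout <- tilePatches(dim(mapValues(maps$Mel)),
                            receptiveFieldSpec(config$field_deg_iprgc,
                                               config$window),
                            pixelsPerDegree(rad), sceneId = sceneId(rad))
      for (m in metrics) {
        vals <- if (m == "Rad") localRadiance(rad, layout)$local_value
        else localExcitation(maps[[m]], layout)$local_value
        means[[length(means) + 1L]] <- data.frame(
          illuminant = ill_label, metric = m,
          environment = environmentLabel(scene), mean_value = mean(vals))
      }
    }
  }
  means <- do.call(rbind, means)
  out <- list()
  for (m in metrics) {
    sub <- means[means$metric == m, ]
    agg <- stats::aggregate(mean_value ~ illuminant + environment, sub, mean)
    hm <- agg[agg$environment == "human_made", ]
    nat <- agg[agg$environment == "natural", ]
    if (nrow(hm) == 0 || nrow(nat) == 0) next
    ord <- match(hm$illuminant, nat$illuminant)
    tab <- nrdTable(stats::setNames(hm$mean_value, hm$illuminant),
                    nat$mean_value[ord])
    tab$metric <- m
    out[[m]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the full analysis: load or generate every scene, resample to the
#' 5-nm grid, compute all channel maps, tile parafoveal (1.37 deg) and
#' peripheral (2.4 deg) ipRGC fields plus co-centred luminance (0.36 deg)
#' fields, compute local values and between-patch contrasts, then
#' per-environment median/IQR summaries and natural vs human-made
#' comparisons; when illuminants are configured and scenes carry reflectance,
#' the per-illuminant normalized-relative-difference table is added.  With an
#' \code{output_dir} the records, summaries, comparisons and a parameter log
#' (all embedding the configuration hash) are written as CSV/text.
#' Deterministic given the configuration and seeds.
#'
#' @param config configuration list (see \code{\link{readPipelineConfig}}).
#' @return List: \code{records} (all patch records), \code{summary}
#'   (median/IQR table), \code{comparisons} (test table), \code{nrd}
#'   (NRD table or NULL), \code{config_hash}.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  hash <- .config_hash(config)
  records <- list()
  for (i in seq_along(config$scenes)) {
    entry <- config$scenes[[i]]
    scene <- tryCatch(.load_scene(entry, config), error = function(e)
      stop("stage_load[scene ", i, "]: ", conditionMessage(e), call. = FALSE))
    if (quantity(scene) == "reflectance") {
      ill <- .resolve_illuminant(
        if (is.null(config$illuminants)) "EES" else config$illuminants[[1]])
      scene <- applyIlluminant(scene, ill)
    }
    records[[i]] <- tryCatch(.scene_records(scene, config), error = function(e)
      stop("stage_records[", sceneId(scene), "]: ", conditionMessage(e),
           call. = FALSE))
  }
  records <- do.call(rbind, records)
  summary_tab <- .summaries(records)
  comparisons <- .comparisons(records, config$transform)
  nrd <- NULL
  if (!is.null(config$illuminants) && length(config$illuminants) > 1) {
    refl <- Filter(function(e) isTRUE(e$synthetic) ||
                     is.null(e$quantity) || e$quantity == "reflectance",
                   config$scenes)
    if (length(refl) > 0)
      nrd <- tryCatch(.nrd_analysis(refl, config), error = function(e) NULL)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    writeRecordsCSV(records, file.path(config$output_dir, "patch_records.csv"), hash)
    writeRecordsCSV(summary_tab, file.path(config$output_dir, "summary.csv"), hash)
    if (!is.null(comparisons))
      writeRecordsCSV(comparisons, file.path(config$output_dir, "comparisons.csv"), hash)
    if (!is.null(nrd))
      writeRecordsCSV(nrd, file.path(config$output_dir, "nrd.csv"), hash)
    log_lines <- c(paste("config", hash),
                   paste("window", config$window),
                   paste("transform", config$transform),
                   paste("tiling", config$tiling),
                   paste("seed", config$seed),
                   paste("fields_deg", config$field_deg_iprgc,
                         config$field_deg_periphery, config$field_deg_lum),
                   paste("illuminants",
                         paste(config$illuminants, collapse = ",")),
                   paste("n_scenes", length(config$scenes)))
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  }
  list(records = records, summary = summary_tab, comparisons = comparisons,
       nrd = nrd, config_hash = hash)
}
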