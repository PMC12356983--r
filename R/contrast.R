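#' Between-patch Michelson contrast within one scene
#'
#' For one scene, channel and field size, the contrast of each patch is the
#' absolute relative deviation of its local value from the scene mean of the
#' patches' local values: C_j = |(E_j - E_s) / E_s|, with E_s the unweighted
#' mean of the E_j.  Contrasts are never truncated at 1 (any truncation in
#' figures is plotting-only).
#'
#' @param records data.frame of patch records from
#'   \code{\link{localExcitation}} or \code{\link{localRadiance}} for a
#'   single scene/channel/field combination (>= 2 rows).
#' @return A \linkS4class{SceneContrastSet}.
#' @examples
#' rec <- data.frame(scene_id = "s", channel = "Mel", field_deg = 1.37,
#'                   patch_index = 1:3, x0 = 0, y0 = 0,
#'                   local_value = c(2, 2, 8), contrast = NA_real_)
#' contrastRecords(betweenPatchContrast(rec))$contrast  # 0.5 0.5 1.0
#' @export
betweenPatchContrast <- function(records) {
  if (nrow(records) < 2L)
    stop("single_patch: between-patch contrast needs >= 2 patches",
         call. = FALSE)
  if (length(unique(records$scene_id)) != 1L ||
      length(unique(records$channel)) != 1L ||
      length(unique(records$field_deg)) != 1L)
    stop("mixed_records: records must come from one scene, channel and field size",
         call. = FALSE)
  e_s <- mean(records$local_value)
  if (abs(e_s) < .Machine$double.eps * 100)
    stop("zero_scene_mean: scene mean excitation is zero; contrast undefined",
         call. = FALSE)
  records$contrast <- abs((records$local_value - e_s) / e_s)
  new("SceneContrastSet", sceneId = records$scene_id[1],
      channel = records$channel[1], fieldDeg = records$field_deg[1],
      sceneMean = e_s, records = records)
}

#' Paired melanopsin/luminance (or any two-channel) contrasts per field
#'
#' Compares the between-patch contrasts of two channels receptive field by
#' receptive field.  In \code{"physiological"} mode channel A (melanopsin by
#' default) is tiled at its own field size and channel B (luminance) is
#' windowed with its smaller field co-centred on the same patch centres --
#' the only pairing that yields exactly one B value per A field when the two
#' physiological sizes differ.  In \code{"matched"} mode both channels share
#' channel A's tiling and window, as in same-size replication analyses.
#'
#' @param maps named list of \linkS4class{ChannelMap}s containing the two
#'   requested channels (e.g. from \code{\link{computeAllChannels}}).
#' @param channelA,channelB channel names present in \code{maps}.
#' @param specA \linkS4class{ReceptiveFieldSpec} for channel A (default
#'   1.37 deg).
#' @param specB \linkS4class{ReceptiveFieldSpec} for channel B in
#'   physiological mode (default 0.36 deg).
#' @param mode \code{"physiological"} or \code{"matched"}.
#' @param layout optional pre-built \linkS4class{PatchLayout} for channel A.
#' @return data.frame with one row per patch: \code{scene_id},
#'   \code{patch_index}, \code{x0}, \code{y0}, \code{contrast_a},
#'   \code{contrast_b}, \code{local_a}, \code{local_b}, \code{mode}.
#' @export
pairChannelContrasts <- function(maps, channelA = "Mel", channelB = "Lum",
                                 specA = receptiveFieldSpec(1.37),
                                 specB = receptiveFieldSpec(0.36),
                                 mode = c("physiological", "matched"),
                                 layout = NULL) {
  mode <- match.arg(mode)
  a <- maps[[channelA]]; b <- maps[[channelB]]
  if (is.null(a) || is.null(b))
    stop("missing_channel: maps must contain ", channelA, " and ", channelB,
         call. = FALSE)
  ppd <- pixelsPerDegree(a)
  if (is.null(layout))
    layout <- tilePatches(dim(mapValues(a)), specA, ppd, sceneId = sceneId(a))
  layout_b <- if (mode == "physiological")
    coCenteredLayout(layout, specB, ppd) else layout
  rec_a <- betweenPatchContrast(localExcitation(a, layout))
  rec_b <- betweenPatchContrast(localExcitation(b, layout_b))
  ra <- contrastRecords(rec_a); rb <- contrastRecords(rec_b)
  data.frame(scene_id = ra$scene_id, patch_index = ra$patch_index,
             x0 = ra$x0, y0 = ra$y0,
             contrast_a = ra$contrast, contrast_b = rb$contrast,
             local_a = ra$local_value, local_b = rb$local_value,
             mode = mode, row.names = NULL)
}

#' Correlation between local excitation and contrast
#'
#' Pearson correlation (with two-sided p) between E_j and C_j pooled over the
#' scenes of one environment: the check that contrast carries information
#' independent of absolute excitation.
#'
#' @param sets list of \linkS4class{SceneContrastSet}s, or a data.frame with
#'   columns \code{local_value} and \code{contrast}.
#' @return List with \code{r}, \code{p_value}, \code{df}, \code{n}.
#' @export
contrastExcitationIndependence <- function(sets) {
  df <- if (is.data.frame(sets)) sets
  else do.call(rbind, lapply(sets, contrastRecords))
  e <- df$local_value; c_ <- df$contrast
  if (length(e) < 3L)
    stop("too_few_pairs: need >= 3 (E_j, C_j) pairs", call. = FALSE)
  if (stats::sd(e) == 0 || stats::sd(c_) == 0)
    stop("degenerate_variance: zero-variance input to the correlation",
         call. = FALSE)
  ct <- stats::cor.test(e, c_, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(e))
}

#' Median +/- IQR of channel-B contrast in bins of channel-A contrast
#'
#' Summary used for the "luminance exceeds melanopsin above ~0.25 contrast"
#' reading of the paired comparison: bins of the channel-A contrast (deciles
#' by default) with median and IQR of both channels per bin.
#'
#' @param pairs data.frame from \code{\link{pairChannelContrasts}} (may pool
#'   several scenes).
#' @param nBins number of quantile bins of \code{contrast_a} (default 10).
#' @return data.frame with one row per bin: bin midpoint, n, and median/IQR
#'   of both channels' contrasts.
#' @export
binContrastPairs <- function(pairs, nBins = 10) {
  br <- unique(stats::quantile(pairs$contrast_a, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 2L)
    stop("degenerate_variance: contrast_a has no spread to bin", call. = FALSE)
  bin <- cut(pairs$contrast_a, br, include.lowest = TRUE)
  agg <- lapply(split(pairs, bin), function(d) data.frame(
    n = nrow(d), mid_a = stats::median(d$contrast_a),
    median_a = stats::median(d$contrast_a), iqr_a = stats::IQR(d$contrast_a),
    median_b = stats::median(d$contrast_b), iqr_b = stats::IQR(d$contrast_b)))
  out <- do.call(rbind, agg)
  out$bin <- rownames(out)
  rownames(out) <- NULL
  out[out$n > 0, ]
}
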