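# Nominal spherical 10/20 electrode geometry.
#
# Electrode positions are constructed on a unit sphere from the standard
# 10/20 placement rules: sagittal-midline electrodes at multiples of 18
# degrees (10% of the 180-degree nasion-inion arc) from the vertex, the
# temporal/circumferential ring at 72 degrees with 18-degree azimuth steps,
# and intermediate electrodes placed by spherical linear interpolation
# between the midline and ring electrode of the same coronal row.  These
# are nominal positions for simulation, interpolation, and neighborhood
# definitions, not digitized coordinates.

# Spherical linear interpolation between two unit vectors.
slerp <- function(u, v, f) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  omega <- acos(max(-1, min(1, sum(u * v))))
  if (omega < 1e-12) return(u)
  (sin((1 - f) * omega) * u + sin(f * omega) * v) / sin(omega)
}

# Unit vector for polar angle from vertex (deg) and azimuth (deg,
# 0 = nasion/front, negative = left hemisphere seen from above).
# Coordinates: x = right, y = anterior, z = superior.
sph_unit <- function(polar, azimuth) {
  p <- polar * pi / 180; a <- azimuth * pi / 180
  c(sin(p) * sin(a), sin(p) * cos(a), cos(p))
}

#' Standard 40-channel 10/20 scalp montage with EOG channels
#'
#' Builds the nominal electrode geometry used throughout the package: 40
#' scalp electrodes of the extended 10/20 system on a unit sphere plus four
#' EOG channels (above/below the left eye and lateral to both eyes) that
#' carry no scalp position.
#'
#' @param channels optional character vector to subset (and order) the scalp
#'   channels; EOG channels are appended after subsetting.
#' @param eog logical; include the four EOG channels (default `TRUE`).
#' @return a data.frame with columns `label`, `type` (`"eeg"`/`"eog"`), and
#'   unit-sphere coordinates `x`, `y`, `z` (`NA` for EOG).
#' @examples
#' m <- montage_1020()
#' nrow(m[m$type == "eeg", ])  # 40
#' @export
montage_1020 <- function(channels = NULL, eog = TRUE) {
  # Each row: midline label (or NA), midline polar angle, front/back, and
  # lateral left-hemisphere electrodes with their slerp fraction toward the
  # row's electrode on the 72-degree ring.
  rows <- list(
    list(mid = "FPZ", polar = 72, front = TRUE,  left = "FP1", fr = 1),
    list(mid = NA,    polar = 54, front = TRUE,  left = "AF3", fr = 0.5),
    list(mid = "FZ",  polar = 36, front = TRUE,
         left = c("F3", "F5", "F7"), fr = c(0.5, 0.75, 1)),
    list(mid = "FCZ", polar = 18, front = TRUE,
         left = c("FC3", "FT7"), fr = c(0.5, 1)),
    list(mid = "CZ",  polar = 0,  front = TRUE,
         left = c("C3", "T7"), fr = c(0.5, 1)),
    list(mid = "CPZ", polar = 18, front = FALSE,
         left = c("CP3", "TP7"), fr = c(0.5, 1)),
    list(mid = "PZ",  polar = 36, front = FALSE,
         left = c("P3", "P5", "P7"), fr = c(0.5, 0.75, 1)),
    list(mid = "POZ", polar = 54, front = FALSE, left = "PO3", fr = 0.5),
    list(mid = "OZ",  polar = 72, front = FALSE, left = "O1", fr = 1)
  )
  pos <- list()
  for (r in rows) {
    az_mid <- if (r$front) 0 else 180
    mid_vec <- sph_unit(r$polar, az_mid)
    if (!is.na(r$mid)) pos[[r$mid]] <- mid_vec
    # ring electrode of this row: azimuth -(90 - polar) in front rows,
    # -(90 + polar) in back rows (T7 at -90, F7 at -54, P7 at -126, ...)
    anchor_az <- if (r$front) -(90 - r$polar) else -(90 + r$polar)
    anchor <- sph_unit(72, anchor_az)
    for (i in seq_along(r$left)) {
      v <- slerp(mid_vec, anchor, r$fr[i])
      pos[[r$left[i]]] <- v
      pos[[mirror_label(r$left[i])]] <- c(-v[1], v[2], v[3])
    }
  }
  xyz <- do.call(rbind, pos)
  df <- data.frame(label = names(pos), type = "eeg",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order_1020(df$label), ]
  if (!is.null(channels)) {
    missing <- setdiff(toupper(channels), df$label)
    if (length(missing))
      stop_param("unknown channel label(s): ", paste(missing, collapse = ", "))
    df <- df[match(toupper(channels), df$label), ]
  }
  if (eog) {
    df <- rbind(df, data.frame(
      label = c("VEOGU", "VEOGL", "HEOGL", "HEOGR"), type = "eog",
      x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  df
}

# FP1 -> FP2, F3 -> F4, FT7 -> FT8, ...
mirror_label <- function(lab) {
  n <- as.integer(regmatches(lab, regexpr("[0-9]+$", lab)))
  paste0(sub("[0-9]+$", "", lab), n + 1L)
}

order_1020 <- function(labels) {
  rows <- c("FP", "AF", "F", "FT", "FC", "T", "C", "TP", "CP", "P", "PO", "O")
  stem <- sub("([0-9]+|Z)$", "", labels)
  num <- rep(0L, length(labels))
  has <- grepl("[0-9]+$", labels)
  num[has] <- as.integer(regmatches(labels, regexpr("[0-9]+$", labels)))
  side <- ifelse(num == 0L, 0L, ifelse(num %% 2L == 1L, -num, num))
  order(match(stem, rows), side)
}

#' Channel adjacency from electrode geometry
#'
#' Two scalp channels are neighbors when their great-circle (angular)
#' distance is below `max_angle`.  By default the threshold adapts to the
#' montage density (1.6 times the median nearest-neighbor angle), so sparse
#' reduced montages remain connected.
#'
#' @param montage a montage data.frame from [montage_1020()].
#' @param max_angle neighbor threshold in degrees, or `NULL` for adaptive.
#' @return named list mapping each scalp channel to its neighbors' labels.
#' @export
channel_neighbors <- function(montage, max_angle = NULL) {
  sc <- montage[montage$type == "eeg", ]
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  n <- nrow(sc)
  ang <- acos(clamp_cos(tcrossprod(xyz))) * 180 / pi
  if (is.null(max_angle)) {
    nn <- apply(ang + diag(Inf, n), 1, min)
    max_angle <- 1.6 * median(nn)
  }
  out <- lapply(seq_len(n), function(i)
    sc$label[ang[i, ] <= max_angle & seq_len(n) != i])
  names(out) <- sc$label
  out
}

# Named spatial weight templates over a montage (unit max weight, Gaussian
# falloff with angular distance from a seed direction).  Used for effect
# topographies and the posterior weighting of the ongoing alpha rhythm.
#' Spatial weight template over the scalp
#'
#' @param montage montage data.frame.
#' @param preset one of `"frontocentral"`, `"left_parietal"`,
#'   `"right_parietal"`, `"left_frontal"`, `"right_frontal"`, `"posterior"`.
#' @param width Gaussian falloff width in degrees of angular distance.
#' @return named numeric weights (one per scalp channel, max 1).
#' @export
topography_weights <- function(montage, preset, width = 40) {
  seeds <- list(
    frontocentral = sph_unit(18, 0),
    left_parietal = sph_unit(50, -145),
    right_parietal = sph_unit(50, 145),
    left_frontal = sph_unit(50, -35),
    right_frontal = sph_unit(50, 35),
    posterior = sph_unit(60, 180)
  )
  if (!preset %in% names(seeds))
    stop_param("unknown topography preset: ", preset)
  sc <- montage[montage$type == "eeg", ]
  ang <- acos(clamp_cos(
    as.matrix(sc[, c("x", "y", "z")]) %*% seeds[[preset]]))
  w <- exp(-(ang[, 1] * 180 / pi)^2 / (2 * width^2))
  names(w) <- sc$label
  w
}
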