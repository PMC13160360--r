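## Plain-text (CSV) round-trip I/O for every container. Numeric columns
## are written with full precision so write -> read preserves values and
## masks exactly.

.fwrite <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

## exact writer: doubles serialized with 17 significant digits so that
## write -> read is bit-faithful (used by the grid/section round-trips)
.fwriteExact <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Write / read an echogram grid as long-format CSV
#'
#' One row per (ping, depth bin) with Sv, position, timing and one 0/1
#' column per mask layer; grid-level metadata (frequency, sound speed,
#' absorption, processing stage) travel as constant columns. The
#' round-trip is lossless, including mask layers and depth lines.
#'
#' @param grid an \linkS4class{EchogramGrid}.
#' @param path CSV path.
#' @return \code{writeEchogramCsv}: the path, invisibly;
#'   \code{readEchogramCsv}: the reconstructed grid.
#' @export
writeEchogramCsv <- function(grid, path) {
  np <- nrow(grid@Sv); nb <- ncol(grid@Sv)
  tops <- grid@depthEdges[-(nb + 1)]; bots <- grid@depthEdges[-1]
  df <- data.frame(
    ping = rep(seq_len(np), times = nb),
    time = rep(grid@pingTime, times = nb),
    latitude = rep(grid@latitude, times = nb),
    longitude = rep(grid@longitude, times = nb),
    distance_nmi = rep(grid@distance, times = nb),
    depth_top_m = rep(tops, each = np),
    depth_bottom_m = rep(bots, each = np),
    sv_db = as.vector(grid@Sv),
    frequency_khz = grid@frequency,
    sound_speed = grid@soundSpeed,
    absorption = grid@absorption,
    stage = grid@stage)
  for (nm in names(grid@masks))
    df[[paste0("mask_", nm)]] <- as.integer(as.vector(grid@masks[[nm]]))
  for (nm in names(grid@lines))
    df[[paste0("line_", nm)]] <- rep(grid@lines[[nm]], times = nb)
  .fwriteExact(df, path)
}

#' @rdname writeEchogramCsv
#' @export
readEchogramCsv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  np <- max(df$ping)
  nb <- nrow(df) / np
  first <- df[df$depth_top_m == df$depth_top_m[1], ]
  edges <- as.numeric(c(sort(unique(df$depth_top_m)),
                        max(df$depth_bottom_m)))
  g <- echogramGrid(df$frequency_khz[1],
                    matrix(as.numeric(df$sv_db), np, nb), edges,
                    pingTime = as.numeric(first$time),
                    latitude = as.numeric(first$latitude),
                    longitude = as.numeric(first$longitude),
                    distance = as.numeric(first$distance_nmi),
                    soundSpeed = as.numeric(df$sound_speed[1]),
                    absorption = as.numeric(df$absorption[1]),
                    stage = df$stage[1])
  for (nm in grep("^mask_", names(df), value = TRUE))
    g@masks[[sub("^mask_", "", nm)]] <- matrix(df[[nm]] == 1L, np, nb)
  for (nm in grep("^line_", names(df), value = TRUE))
    g@lines[[sub("^line_", "", nm)]] <- df[[nm]][seq_len(np)]
  validObject(g)
  g
}

#' Write / read a CTD section as long-format CSV
#'
#' Columns: lat, depth_m, temp_C, sal_gkg, sigma_theta, mask.
#'
#' @param section a \linkS4class{CtdSection}.
#' @param path CSV path.
#' @export
writeSectionCsv <- function(section, path) {
  nl <- length(section@latitude); nz <- length(section@depth)
  .fwriteExact(data.frame(
    lat = rep(section@latitude, times = nz),
    depth_m = rep(section@depth, each = nl),
    temp_C = as.vector(section@CT),
    sal_gkg = as.vector(section@SA),
    sigma_theta = as.vector(section@sigmaTheta),
    mask = as.integer(as.vector(section@mask))), path)
}

#' @rdname writeSectionCsv
#' @export
readSectionCsv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  lat <- as.numeric(sort(unique(df$lat)))
  z <- as.numeric(sort(unique(df$depth_m)))
  shape <- c(length(lat), length(z))
  new("CtdSection", latitude = lat, depth = z,
      CT = matrix(as.numeric(df$temp_C), shape[1], shape[2]),
      SA = matrix(as.numeric(df$sal_gkg), shape[1], shape[2]),
      sigmaTheta = matrix(as.numeric(df$sigma_theta), shape[1], shape[2]),
      mask = matrix(df$mask == 1L, shape[1], shape[2]))
}

#' Read CTD profiles from CSV
#'
#' Expects columns station, lat, lon, time, depth_m, temp_C, sal_gkg and
#' optionally sigma_theta (computed with \code{\link{linearSigmaTheta}}
#' when absent).
#'
#' @param path CSV path.
#' @return list of \linkS4class{CtdProfile}s (one per station).
#' @export
readCtdProfiles <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  lapply(split(df, df$station), function(d) {
    d <- d[order(d$depth_m), ]
    ctdProfile(d$station[1], d$depth_m, d$temp_C, d$sal_gkg,
               sigmaTheta = if ("sigma_theta" %in% names(d)) d$sigma_theta,
               latitude = d$lat[1], longitude = d$lon[1],
               time = as.character(d$time[1]))
  })
}
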