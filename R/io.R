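#' Write a ground-truth table to CSV
#'
#' One row per spheroid per timepoint. Numeric columns are written with 17
#' significant digits so that [read_truth()] round-trips the table without
#' loss; coordinates are in microns with the origin at the field's top-left
#' pixel corner.
#'
#' @param truth truth data.frame from [simulate_array()] or
#'   [simulate_invasion()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  out <- truth
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write truth table to '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a ground-truth table written by [write_truth()]
#'
#' @param path CSV file path.
#' @return data.frame with the original column types.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("id", "row", "col", "t_index"))
    if (nm %in% names(df)) df[[nm]] <- as.integer(df[[nm]])
  for (nm in setdiff(names(df), "clipped"))
    if (is.logical(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]]) # all-NA columns
  df
}

#' Write a simulated acquisition to a multi-page TIFF plus sidecar JSON
#'
#' Planes are written as 16-bit grayscale pages, one per (channel, timepoint)
#' in acquisition order; the sidecar JSON records the page order (channel
#' label and timepoint per page), `microns_per_pixel` and the microchamber
#' grid geometry, which is everything needed to re-interpret the stack.
#'
#' @param sim result of [simulate_array()] or [simulate_invasion()].
#' @param dir output directory (created if missing).
#' @param name base name for the `.tif` / `.json` pair.
#' @return list of the two file paths, invisibly.
#' @export
write_field_images <- function(sim, dir, name = "field") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  js <- file.path(dir, paste0(name, ".json"))
  planes <- lapply(sim$images, function(im) round(im$pixels) / 65535)
  tiff::writeTIFF(planes, tif, bits.per.sample = 16L)
  meta <- list(
    microns_per_pixel = sim$config$microns_per_pixel,
    grid = grid_geometry(sim$config),
    pages = lapply(sim$images, function(im)
      list(channel = im$channel, timepoint = im$timepoint,
           field_id = im$field_id)))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = tif, json = js))
}

#' Read an acquisition written by [write_field_images()]
#'
#' @param dir directory holding the pair.
#' @param name base name used when writing.
#' @return list with `images` (list of [field_image()], intensities restored
#'   to the 0--65535 scale) and `meta` (the sidecar metadata).
#' @export
read_field_images <- function(dir, name = "field") {
  tif <- file.path(dir, paste0(name, ".tif"))
  js <- file.path(dir, paste0(name, ".json"))
  planes <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  images <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    images[[k]] <- field_image(planes[[k]] * 65535,
                               meta$pages$channel[k],
                               meta$pages$timepoint[k],
                               meta$microns_per_pixel,
                               meta$pages$field_id[k])
  }
  list(images = images, meta = meta)
}
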