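# Artifact plumbing: the array-container bundle, plain-text image I/O
# (ASCII PGM/PPM), heatmap overlays, and run manifests.

#' Save / load an array bundle
#'
#' A single portable compressed container holding uniquely named numeric
#' arrays plus a structured manifest. Round-trips are lossless (bitwise for
#' the arrays).
#'
#' @param path Bundle file path.
#' @param arrays Named list of finite numeric arrays; names must be unique
#'   and non-empty. May be empty (manifest-only bundle).
#' @param manifest Arbitrary (JSON-representable) metadata list.
#' @return `load_bundle()` returns `list(arrays, manifest)`.
#' @export
save_bundle <- function(path, arrays = list(), manifest = list()) {
  nm <- names(arrays)
  if (length(arrays)) {
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
      stopf("array names must be unique and non-empty")
    }
    for (i in seq_along(arrays)) assert_finite(arrays[[i]], nm[i])
  }
  saveRDS(list(format = "spikesam-bundle", version = 1L,
               arrays = arrays, manifest = manifest),
          file = path, compress = "gzip")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stopf("bundle file '%s' does not exist", path)
  b <- tryCatch(readRDS(path),
                error = function(e) stopf("cannot read bundle '%s': %s",
                                          path, conditionMessage(e)))
  if (!is.list(b) || !identical(b$format, "spikesam-bundle")) {
    stopf("'%s' is not a spikesam bundle", path)
  }
  list(arrays = b$arrays, manifest = b$manifest)
}

#' Plain-text image I/O (ASCII PGM / PPM)
#'
#' `write_pgm()`/`read_pgm()` handle single-channel images as ASCII P2
#' portable graymaps; `write_ppm()` writes RGB arrays `(3, H, W)` as ASCII P3
#' pixmaps. Values are integers in `[0, 255]`.
#'
#' @param image Matrix `(H, W)` (PGM) or array `(3, H, W)` (PPM), values in
#'   `[0, 255]`.
#' @param path File path.
#' @return `read_pgm()` returns an `H x W` integer matrix.
#' @export
write_pgm <- function(image, path) {
  image <- round(as.matrix(image))
  if (any(image < 0) || any(image > 255)) stopf("PGM values must be in [0, 255]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "255"), con)
  write(t(image), file = con, ncolumns = ncol(image))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stopf("'%s' is not an ASCII PGM (P2) file", path)
  w <- as.integer(tok[2])
  h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stopf("PGM pixel count mismatch in '%s'", path)
  matrix(vals, h, w, byrow = TRUE)
}

#' @rdname write_pgm
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  if (length(d) != 3L || d[1] != 3L) stopf("PPM input must be (3, H, W)")
  image <- round(image)
  if (any(image < 0) || any(image > 255)) stopf("PPM values must be in [0, 255]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", d[3], d[2]), "255"), con)
  px <- matrix(0, d[2], 3 * d[3])
  for (c3 in 1:3) px[, seq(c3, 3 * d[3], by = 3)] <- image[c3, , ]
  write(t(px), file = con, ncolumns = min(3 * d[3], 30))
  invisible(path)
}

#' Blend a heatmap over an image
#'
#' Color-maps a normalized heatmap from blue (0) to red (1) and
#' alpha-blends it over the grayscale image; the heatmap is resized to the
#' image's resolution first. Deterministic: identical inputs give bitwise
#' identical output.
#'
#' @param image An [image_tensor()] (values in `[0, 255]`).
#' @param heatmap 2-D map with values in `[0, 1]`.
#' @param alpha Blend weight of the heatmap, in `[0, 1]`.
#' @return RGB array `(3, H, W)` with values in `[0, 255]`.
#' @export
render_overlay <- function(image, heatmap, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stopf("alpha must be a single value in [0, 1]")
  }
  image <- image_tensor(unclass(image))
  heatmap <- as.matrix(heatmap)
  if (any(heatmap < 0) || any(heatmap > 1)) stopf("heatmap must be in [0, 1]")
  d <- dim(image)
  gray <- matrix(colMeans(matrix(image, nrow = d[1])), d[2], d[3])
  v <- resize_heatmap(heatmap, d[2], d[3])
  out <- array(0, c(3L, d[2], d[3]))
  out[1, , ] <- (1 - alpha) * gray + alpha * 255 * v        # red ramps up
  out[2, , ] <- (1 - alpha) * gray
  out[3, , ] <- (1 - alpha) * gray + alpha * 255 * (1 - v)  # blue ramps down
  out
}

#' Write a run manifest
#'
#' Every artifact-producing command writes exactly one JSON manifest next to
#' its outputs recording the command, configuration snapshot, seeds, paths,
#' package version and timestamp, so the run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param config Configuration snapshot (list).
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of paths.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL,
                           inputs = character(), outputs = character()) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         inputs = inputs, outputs = outputs,
         package_version = as.character(utils::packageVersion("spikesam")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
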