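#' Write a heatmap as float TIFF with a JSON sidecar
#'
#' The activation grid is written as a single-channel 32-bit float TIFF and
#' the metadata (pixel size, inclusion class, box id) as `<path>.json`.
#'
#' @param heatmap A [heatmap_grid()].
#' @param path Output TIFF path.
#' @param box_id Optional box identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path, box_id = NULL) {
  stopifnot(inherits(heatmap, "heatmap_grid"))
  tiff::writeTIFF(heatmap$values, path, bits.per.sample = 32L)
  sidecar <- list(pixel_size_um = heatmap$pixel_size_um,
                  class = heatmap$inclusion_class,
                  box_id = box_id)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a heatmap written by [write_heatmap()]
#'
#' @param path TIFF path; the sidecar is expected at `<path>.json`.
#' @return A [heatmap_grid()] (with `box_id` attached as an attribute when
#'   present in the sidecar).
#' @export
read_heatmap <- function(path) {
  vals <- tiff::readTIFF(path)
  if (length(dim(vals)) == 3L) vals <- vals[, , 1L]
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("sidecar not found: ", sidecar_path)
  }
  meta <- jsonlite::fromJSON(sidecar_path)
  hm <- heatmap_grid(pmin(pmax(vals, 0), 1),
                     pixel_size_um = meta$pixel_size_um,
                     inclusion_class = meta$class)
  attr(hm, "box_id") <- meta$box_id
  hm
}

#' Read or write a pipeline configuration (YAML or JSON by extension)
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return For `read_config`, the configuration list (classed
#'   `pipeline_config`); for `write_config`, `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("unsupported config extension: ", ext))
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(config)
  switch(ext,
         yaml = , yml = yaml::write_yaml(cfg, path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported config extension: ", ext))
  invisible(path)
}

# Stable md5 hash of a configuration (hash of its canonical JSON form).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
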