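## The manifest container: a ZIP archive holding `manifest.json` (scene
## metadata: group filter, entity records, styles), one BinaryCIF sphere
## payload per entity, and one streamlined binary transform file per
## entity — 7 little-endian float32 per instance: unit quaternion
## (x, y, z, w) then translation (tx, ty, tz) in Angstrom. All output is
## canonical (sorted JSON keys, sorted archive entries, fixed
## timestamps), so write -> read -> write is byte-identical.

TRANSFORM_RECORD_BYTES <- 28L   # 7 x float32

## Build the manifest document with keys in sorted order at every level,
## so jsonlite serialization is canonical.
sorted_obj <- function(...) {
  x <- list(...)
  x[order(names(x))]
}

style_to_json <- function(s) sorted_obj(
  clip_enabled = s$clip_enabled, color = as.numeric(s$color),
  lod_bias = s$lod_bias, opacity = s$opacity, visible = s$visible)

json_to_style <- function(j) meso_style(
  color = as.numeric(j$color), visible = isTRUE(j$visible),
  opacity = as.numeric(j$opacity), clip_enabled = isTRUE(j$clip_enabled),
  lod_bias = as.integer(j$lod_bias))

#' Write a scene as a manifest container
#'
#' @param scene a [meso_scene()]
#' @param path output .zip path
#' @return `path`, invisibly
#' @export
write_manifest <- function(scene, path) {
  files <- list()
  ents <- scene$entities[order(names(scene$entities))]
  records <- lapply(ents, function(e) {
    payload <- sprintf("%s.bcif", e$id)
    transforms <- sprintf("%s.bin", e$id)
    rows <- scene$instances[scene$instances$entity_id == e$id, , drop = FALSE]
    ## sphere payload
    tmp <- tempfile(fileext = ".bcif")
    write_bcif(list(mesoscene_sphere = list(
      x = e$centers[, 1], y = e$centers[, 2], z = e$centers[, 3],
      radius = e$radii)), tmp, header = e$id)
    files[[payload]] <<- readBin(tmp, "raw", file.size(tmp))
    unlink(tmp)
    ## transforms: qx qy qz qw tx ty tz as float32 LE
    m <- t(as.matrix(rows[, c("qx", "qy", "qz", "qw", "tx", "ty", "tz")]))
    files[[transforms]] <<- writeBin(as.numeric(m), raw(), size = 4,
                                     endian = "little")
    sorted_obj(
      description = if (is.null(e$description)) NULL else e$description,
      group = as.list(e$group), id = e$id, instance_count = nrow(rows),
      label = e$label, payload = payload, transforms = transforms)
  })
  styles <- scene$styles[order(names(scene$styles))]
  doc <- sorted_obj(
    entities = unname(records),
    group_keys = as.list(scene$group_keys),
    name = scene$name,
    styles = lapply(styles, style_to_json),
    version = 1L)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  files[["manifest.json"]] <- c(charToRaw(as.character(js)), charToRaw("\n"))
  zip_write(files, path)
}

#' Read a manifest container into a scene
#'
#' @param path manifest .zip file
#' @return a [meso_scene()]
#' @export
read_manifest <- function(path) {
  files <- zip_read(path)
  if (is.null(files[["manifest.json"]]))
    stop("'", path, "' has no manifest.json: not a manifest container")
  doc <- jsonlite::fromJSON(rawToChar(files[["manifest.json"]]),
                            simplifyVector = FALSE)
  ents <- list(); inst <- list()
  for (rec in doc$entities) {
    for (f in c(rec$payload, rec$transforms))
      if (is.null(files[[f]]))
        stop("manifest references missing archive member '", f, "'")
    tmp <- tempfile(fileext = ".bcif")
    writeBin(files[[rec$payload]], tmp)
    sph <- read_bcif(tmp)[["mesoscene_sphere"]]
    unlink(tmp)
    ents[[rec$id]] <- meso_entity(
      id = rec$id, label = rec$label,
      centers = cbind(sph$x, sph$y, sph$z), radii = sph$radius,
      group = unlist(rec$group),
      description = rec$description)
    tf <- files[[rec$transforms]]
    if (length(tf) %% TRANSFORM_RECORD_BYTES != 0)
      stop("transform file '", rec$transforms, "' is truncated: ",
           length(tf), " bytes is not a multiple of ",
           TRANSFORM_RECORD_BYTES)
    n <- length(tf) / TRANSFORM_RECORD_BYTES
    if (n != rec$instance_count)
      stop("transform file '", rec$transforms, "' holds ", n,
           " records but manifest declares ", rec$instance_count)
    v <- readBin(tf, "double", n * 7, size = 4, endian = "little")
    m <- matrix(v, ncol = 7, byrow = TRUE)
    inst[[rec$id]] <- data.frame(
      entity_id = rec$id, qx = m[, 1], qy = m[, 2], qz = m[, 3],
      qw = m[, 4], tx = m[, 5], ty = m[, 6], tz = m[, 7],
      stringsAsFactors = FALSE)
  }
  styles <- lapply(doc$styles, json_to_style)
  meso_scene(ents, do.call(rbind, inst), name = doc$name,
             group_keys = unlist(doc$group_keys), styles = styles)
}
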