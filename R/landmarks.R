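#' Ground-truth landmark
#'
#' A named target point, stored both as a 0-based integer voxel index and as
#' a world coordinate in mm. When a [volume] is supplied the two
#' representations are checked for consistency and the voxel for being inside
#' the grid; when `world_mm` is omitted it is derived from the volume
#' geometry.
#'
#' @param name Label, e.g. `"LCA_ostium"`.
#' @param voxel Integer length-3, 0-based voxel index.
#' @param world_mm Numeric length-3 world coordinate (mm), or `NULL`.
#' @param volume Optional [volume] used for validation / derivation.
#' @return An object of class `"landmark"`.
#' @export
landmark <- function(name, voxel, world_mm = NULL, volume = NULL) {
  if (!is.character(name) || length(name) != 1)
    stop("'name' must be a single string", call. = FALSE)
  if (!is_int3(voxel))
    stop(sprintf("landmark '%s': 'voxel' must be three integer coordinates", name),
         call. = FALSE)
  voxel <- as.integer(voxel)
  if (!is.null(volume)) {
    if (!in_bounds(volume, voxel))
      stop(sprintf("landmark '%s': voxel (%s) is outside the volume bounds %s",
                   name, paste(voxel, collapse = ", "),
                   paste(dim(volume$data), collapse = " x ")), call. = FALSE)
    derived <- voxel_to_world(volume, voxel)
    if (is.null(world_mm)) world_mm <- derived
    else if (max(abs(as.numeric(world_mm) - derived)) > 1e-6)
      stop(sprintf("landmark '%s': world_mm is inconsistent with voxel, spacing and origin",
                   name), call. = FALSE)
  }
  if (is.null(world_mm)) world_mm <- as.numeric(voxel)
  if (length(world_mm) != 3 || any(!is.finite(world_mm)))
    stop(sprintf("landmark '%s': 'world_mm' must be three finite values", name),
         call. = FALSE)
  structure(list(name = name, voxel = voxel, world_mm = as.numeric(world_mm)),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark> %s: voxel (%s), world (%s) mm\n", x$name,
              paste(x$voxel, collapse = ", "),
              paste(format(x$world_mm, digits = 6), collapse = ", ")))
  invisible(x)
}

#' Read / write landmark files
#'
#' Landmarks round-trip through a JSON array of
#' `{"name": str, "voxel": [i,j,k], "world_mm": [x,y,z]}` records. An
#' optional `"volume"` field carrying a volume file name is preserved.
#'
#' @param path JSON file path.
#' @param volume Optional [volume]; when supplied, each landmark's voxel is
#'   validated against the volume bounds.
#' @return `read_landmarks`: a list of [landmark] objects (any `"volume"`
#'   fields attached as the `"volume_file"` attribute).
#' @export
read_landmarks <- function(path, volume = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e)
                     stop(sprintf("failed to parse landmark JSON '%s': %s",
                                  path, conditionMessage(e)), call. = FALSE))
  if (!is.list(recs))
    stop(sprintf("'%s': expected a JSON array of landmark records", path),
         call. = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    for (field in c("name", "voxel")) {
      if (is.null(r[[field]]))
        stop(sprintf("'%s': landmark record %d is missing the \"%s\" key",
                     path, i, field), call. = FALSE)
    }
    lm <- landmark(r$name, unlist(r$voxel),
                   world_mm = if (!is.null(r$world_mm)) unlist(r$world_mm),
                   volume = volume)
    if (!is.null(r$volume)) attr(lm, "volume_file") <- r$volume
    lm
  })
}

#' @rdname read_landmarks
#' @param landmarks A [landmark] or list of landmarks.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "landmark")) landmarks <- list(landmarks)
  recs <- lapply(landmarks, function(lm) {
    stopifnot(inherits(lm, "landmark"))
    r <- list(name = jsonlite::unbox(lm$name),
              voxel = as.integer(lm$voxel),
              world_mm = lm$world_mm)
    vf <- attr(lm, "volume_file")
    if (!is.null(vf)) r$volume <- jsonlite::unbox(vf)
    r
  })
  jsonlite::write_json(recs, path, digits = NA, pretty = TRUE)
  invisible(path)
}
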