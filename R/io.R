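#' Write and read image stacks as multi-page TIFF
#'
#' Stacks are written as 16-bit single-channel multi-page TIFF (one page
#' per depth plane) with voxel spacing and metadata in a JSON sidecar
#' (same path with extension `.json`). Intensities are scaled to the
#' 16-bit range on write and restored on read.
#'
#' @param stack an `image_stack`.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  rlang::check_installed(c("tiff", "jsonlite"))
  stopifnot(inherits(stack, "image_stack"))
  img <- stack$intensities
  top <- max(img, 1e-12)
  pages <- lapply(seq_len(dim(img)[stack$imaging_axis]), function(i) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[stack$imaging_axis]] <- i
    do.call(`[`, c(list(img), idx, list(drop = TRUE))) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(stack$meta,
            list(voxel_size_um = stack$voxel_size,
                 imaging_axis = stack$imaging_axis,
                 intensity_scale = top))
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param path path of a stack written by [write_stack_tiff()].
#' @export
read_stack_tiff <- function(path) {
  rlang::check_installed(c("tiff", "jsonlite"))
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  ax <- meta$imaging_axis
  d2 <- dim(pages[[1]])
  dims <- append(d2, length(pages), after = ax - 1)
  img <- array(0, dims)
  for (i in seq_along(pages)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- i
    img <- do.call(`[<-`, c(list(img), idx, list(pages[[i]])))
  }
  img <- img * meta$intensity_scale
  keep <- setdiff(names(meta),
                  c("voxel_size_um", "imaging_axis", "intensity_scale"))
  new_image_stack(img, meta$voxel_size_um, imaging_axis = ax,
                  meta = meta[keep])
}

#' Write a labeled microstructure to disk
#'
#' Labels go to a multi-page TIFF (one page per radial plane) with a JSON
#' descriptor holding the voxel size and achieved volume fractions.
#'
#' @param block a `voxel_microstructure`.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  rlang::check_installed(c("tiff", "jsonlite"))
  stopifnot(inherits(block, "voxel_microstructure"))
  dims <- dim(block$labels)
  pages <- lapply(seq_len(dims[1]), function(i) {
    matrix(as.double(block$labels[i, , ]), dims[2], dims[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_size_um = block$voxel_size, dims = dims,
         phi_smc = mean(block$labels == 1L)),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  rlang::check_installed(c("tiff", "jsonlite"))
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  dims <- meta$dims
  lab <- array(0L, dims)
  for (i in seq_along(pages)) lab[i, , ] <- as.integer(round(pages[[i]]))
  new_voxel_microstructure(lab, meta$voxel_size_um)
}
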