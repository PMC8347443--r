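# Stack containers and bit-exact I/O.  RI volumes are stored as physical
# values in 32-bit float multi-page TIFF (baseline, uncompressed, one strip
# per page) with a JSON sidecar carrying voxel size; no integer scaling.
# The codec is intentionally minimal: no R TIFF reader is available in the
# supported environment, so the package reads exactly the baseline dialect
# it writes (plus uncompressed grayscale variants) and errors loudly on
# anything else.

#' RI stack container
#'
#' @param voxels numeric 3-D array `(nz, ny, nx)` of refractive indices.
#' @param voxel_size_nm numeric `(dz, dy, dx)` in nm.
#' @param provenance free-text source description (path or phantom seed).
#' @return object of class `ri_stack`.
#' @export
ri_stack <- function(voxels, voxel_size_nm, provenance = "") {
  stopifnot(is.numeric(voxels), length(dim(voxels)) == 3,
            length(voxel_size_nm) == 3, all(voxel_size_nm > 0))
  rng <- range(voxels)  # one pass; NA/NaN propagate, Inf shows in range
  if (!all(is.finite(rng))) stop("RI stack contains non-finite values")
  structure(list(voxels = voxels, voxel_size_nm = as.numeric(voxel_size_nm),
                 provenance = provenance),
            class = "ri_stack")
}

#' Fluorescence stack container
#'
#' @param voxels numeric 3-D array of non-negative intensities (AU).
#' @inheritParams ri_stack
#' @return object of class `fluor_stack`.
#' @export
fluor_stack <- function(voxels, voxel_size_nm, provenance = "") {
  stopifnot(is.numeric(voxels), length(dim(voxels)) == 3)
  rng <- range(voxels)
  if (!all(is.finite(rng))) stop("fluorescence stack has non-finite values")
  if (rng[1] < 0) stop("fluorescence intensities must be >= 0")
  structure(list(voxels = voxels, voxel_size_nm = as.numeric(voxel_size_nm),
                 provenance = provenance),
            class = "fluor_stack")
}

#' @export
print.ri_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("RI stack %d x %d x %d (z,y,x), voxel %g x %g x %g nm, RI range [%.4f, %.4f]\n",
              d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
              x$voxel_size_nm[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.fluor_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Fluorescence stack %d x %d x %d (z,y,x), mean %.3g AU\n",
              d[1], d[2], d[3], mean(x$voxels)))
  invisible(x)
}

## ---- minimal baseline TIFF codec -------------------------------------

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

# Write a multi-page grayscale TIFF.  `voxels` is a (nz, ny, nx) array;
# page k holds slice z = k.  bits: 32 (IEEE float) or 8 (unsigned int).
write_tiff_gray <- function(path, voxels, bits = 32,
                            description = NULL) {
  stopifnot(length(dim(voxels)) == 3, bits %in% c(8L, 32L))
  nz <- dim(voxels)[1]; ny <- dim(voxels)[2]; nx <- dim(voxels)[3]
  bytes_px <- bits / 8L
  page_bytes <- nx * ny * bytes_px
  pad_data <- (nz * page_bytes) %% 2L
  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(description), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  }
  data_start <- 8L
  desc_off <- data_start + nz * page_bytes + pad_data
  ifd_start <- desc_off + length(desc)
  n_tags <- if (is.null(desc)) 10L else 11L
  ifd_size <- 2L + 12L * n_tags + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_start)
  # pixel data, page-major, rows of x within each row y
  perm <- aperm(voxels, c(3L, 2L, 1L))
  if (bits == 32L) {
    writeBin(as.numeric(perm), con, size = 4, endian = "little")
  } else {
    v <- as.integer(perm)
    if (any(v < 0 | v > 255)) stop("8-bit TIFF values must be in 0..255")
    writeBin(v, con, size = 1)
  }
  if (pad_data) writeBin(as.raw(0L), con)
  if (!is.null(desc)) writeBin(desc, con)

  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count); w4(value)
  }
  # SHORT values sit in the low bytes of the 4-byte value field (LE)
  for (k in seq_len(nz)) {
    w2(n_tags)
    tag(256L, 4L, 1L, nx)                        # ImageWidth
    tag(257L, 4L, 1L, ny)                        # ImageLength
    tag(258L, 3L, 1L, bits)                      # BitsPerSample
    tag(259L, 3L, 1L, 1L)                        # Compression: none
    tag(262L, 3L, 1L, 1L)                        # Photometric: BlackIsZero
    if (!is.null(desc)) tag(270L, 2L, length(desc), desc_off)
    tag(273L, 4L, 1L, data_start + (k - 1L) * page_bytes)  # StripOffsets
    tag(277L, 3L, 1L, 1L)                        # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                        # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)                # StripByteCounts
    tag(339L, 3L, 1L, if (bits == 32L) 3L else 1L)  # SampleFormat
    nxt <- if (k < nz) ifd_start + k * ifd_size else 0L
    w4(nxt)
  }
  invisible(path)
}

# Parse a baseline grayscale TIFF into a (nz, ny, nx) array.  Supports
# little- and big-endian, uncompressed, 8-bit unsigned or 32-bit float,
# single sample per pixel, arbitrary strips.
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop(sprintf("'%s' is not a TIFF file", path))
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop(sprintf("'%s' is not a TIFF file", path))
  ru <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = FALSE, endian = endian)
  }
  r4s <- function(off, n = 1L) {  # unsigned 32-bit via double to be safe
    lo <- ru(off, 2, n * 2L)
    if (endian == "little") lo[seq(1, 2 * n, 2)] + 65536 * lo[seq(2, 2 * n, 2)]
    else 65536 * lo[seq(1, 2 * n, 2)] + lo[seq(2, 2 * n, 2)]
  }
  if (ru(2, 2) != 42L) stop(sprintf("'%s' is not a TIFF file", path))

  pages <- list()
  meta <- list(description = NULL, xres = NULL, yres = NULL, resunit = 2L)
  ifd_off <- r4s(4)
  while (ifd_off != 0) {
    n_tags <- ru(ifd_off, 2)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd_off + 2 + (t - 1) * 12
      id <- ru(base, 2); type <- ru(base + 2, 2); count <- r4s(base + 4)
      tsz <- .tiff_type_size[[as.character(type)]]
      total <- tsz * count
      voff <- if (total <= 4) base + 8 else r4s(base + 8)
      val <- switch(as.character(type),
                    `3` = ru(voff, 2, count),
                    `4` = r4s(voff, count),
                    `1` = ru(voff, 1, count),
                    `2` = {
                      b <- raw[(voff + 1):(voff + count)]
                      z <- which(b == as.raw(0))
                      if (length(z)) b <- b[seq_len(z[1] - 1L)]
                      rawToChar(b)
                    },
                    `5` = {
                      q <- r4s(voff, 2L * count)
                      q[seq(1, 2 * count, 2)] / q[seq(2, 2 * count, 2)]
                    },
                    NULL)
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) {
      stop(sprintf("TIFF '%s': missing image dimensions", path))
    }
    bits <- g(258, 1L)[1]
    if (g(259, 1L) != 1L) {
      stop(sprintf("TIFF '%s': compressed TIFF is not supported", path))
    }
    if (g(277, 1L) != 1L) {
      stop(sprintf("TIFF '%s': only single-sample grayscale is supported",
                   path))
    }
    fmt <- g(339, 1L)[1]
    offs <- g(273); counts <- g(279)
    if (is.null(offs) || is.null(counts)) {
      stop(sprintf("TIFF '%s': missing strip layout", path))
    }
    buf <- raw(sum(counts))
    pos <- 0L
    for (s in seq_along(offs)) {
      buf[(pos + 1):(pos + counts[s])] <-
        raw[(offs[s] + 1):(offs[s] + counts[s])]
      pos <- pos + counts[s]
    }
    vals <- if (bits == 32L && fmt == 3L) {
      readBin(buf, "numeric", n = width * height, size = 4, endian = endian)
    } else if (bits == 8L && fmt %in% c(1L, 4L)) {
      as.numeric(readBin(buf, "integer", n = width * height, size = 1,
                         signed = FALSE))
    } else {
      stop(sprintf(
        "TIFF '%s': unsupported pixel format (%d-bit, sample format %d)",
        path, bits, fmt))
    }
    if (anyNA(vals)) stop(sprintf("TIFF '%s': non-numeric pixels", path))
    pages[[length(pages) + 1]] <- matrix(vals, nrow = width, ncol = height)
    if (!is.null(g(270))) meta$description <- g(270)
    if (!is.null(g(282))) meta$xres <- g(282)
    if (!is.null(g(283))) meta$yres <- g(283)
    if (!is.null(g(296))) meta$resunit <- g(296)
    ifd_off <- r4s(ifd_off + 2 + n_tags * 12)
  }
  if (length(pages) == 0) stop(sprintf("TIFF '%s': no pages", path))
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  arr <- array(NA_real_, dim = c(nx, ny, length(pages)))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), c(nx, ny))) {
      stop(sprintf("TIFF '%s': pages differ in size", path))
    }
    arr[, , k] <- pages[[k]]
  }
  list(voxels = aperm(arr, c(3L, 2L, 1L)), meta = meta)
}

## ---- sidecar metadata -------------------------------------------------

sidecar_candidates <- function(path) {
  stem <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  unique(c(paste0(stem, ".json"),
           paste0(sub("_(ri|fl|fluor)$", "", stem), "_meta.json")))
}

#' Write the JSON sidecar holding voxel geometry and provenance
#'
#' @param path sidecar path.
#' @param voxel_size_nm numeric `(dz, dy, dx)`.
#' @param extra named list of extra fields (dose, seed, ...).
#' @export
write_stack_meta <- function(path, voxel_size_nm, extra = list()) {
  obj <- c(list(voxel_size_nm = as.numeric(voxel_size_nm)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_voxel_size <- function(path, meta) {
  for (sc in sidecar_candidates(path)) {
    if (file.exists(sc)) {
      js <- jsonlite::read_json(sc, simplifyVector = TRUE)
      if (!is.null(js$voxel_size_nm) && length(js$voxel_size_nm) == 3) {
        return(list(vs = as.numeric(js$voxel_size_nm), extra = js))
      }
    }
  }
  if (!is.null(meta$description)) {
    js <- tryCatch(jsonlite::fromJSON(meta$description),
                   error = function(e) NULL)
    if (!is.null(js$voxel_size_nm) && length(js$voxel_size_nm) == 3) {
      return(list(vs = as.numeric(js$voxel_size_nm), extra = js))
    }
  }
  if (!is.null(meta$xres) && !is.null(meta$yres)) {
    # pixels per unit; unit 2 = inch, 3 = cm.  No z spacing in plain TIFF.
    unit_nm <- if (identical(meta$resunit, 3L)) 1e7 else 2.54e7
    stop(sprintf(paste0(
      "stack '%s': resolution tags give lateral size %.1f x %.1f nm but no ",
      "z spacing; provide a JSON sidecar with voxel_size_nm = [dz, dy, dx]"),
      path, unit_nm / meta$yres, unit_nm / meta$xres), call. = FALSE)
  }
  stop(sprintf(paste0(
    "stack '%s': no voxel-size metadata (no JSON sidecar, no embedded ",
    "description, no TIFF resolution tags); refusing to guess"),
    path), call. = FALSE)
}

## ---- public stack read/write -----------------------------------------

#' Write an RI stack as multi-page float32 TIFF plus JSON sidecar
#'
#' @param stack an [ri_stack].
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path, `NA` to skip; the voxel size is also
#'   embedded in the TIFF ImageDescription so the file is self-describing.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_ri_stack <- function(stack, path,
                           sidecar = paste0(sub("\\.tiff?$", "", path,
                                                ignore.case = TRUE), ".json"),
                           extra = list()) {
  stopifnot(inherits(stack, "ri_stack"))
  desc <- jsonlite::toJSON(list(voxel_size_nm = stack$voxel_size_nm),
                           auto_unbox = TRUE, digits = NA)
  write_tiff_gray(path, stack$voxels, bits = 32,
                  description = as.character(desc))
  if (!is.na(sidecar)) {
    write_stack_meta(sidecar, stack$voxel_size_nm,
                     c(list(provenance = stack$provenance), extra))
  }
  invisible(path)
}

#' @rdname write_ri_stack
#' @param stack a [fluor_stack] for `write_fluor_stack`.
#' @export
write_fluor_stack <- function(stack, path,
                              sidecar = paste0(sub("\\.tiff?$", "", path,
                                                   ignore.case = TRUE),
                                               ".json"),
                              extra = list()) {
  stopifnot(inherits(stack, "fluor_stack"))
  desc <- jsonlite::toJSON(list(voxel_size_nm = stack$voxel_size_nm),
                           auto_unbox = TRUE, digits = NA)
  write_tiff_gray(path, stack$voxels, bits = 32,
                  description = as.character(desc))
  if (!is.na(sidecar)) {
    write_stack_meta(sidecar, stack$voxel_size_nm,
                     c(list(provenance = stack$provenance), extra))
  }
  invisible(path)
}

#' Read a multi-page TIFF as an RI stack
#'
#' Page order is z order.  Voxel size is resolved from (in order) an
#' explicit argument, a JSON sidecar (`<stem>.json` or `<id>_meta.json`),
#' the embedded ImageDescription, or TIFF resolution tags; if none provides
#' a full `(dz, dy, dx)` the read fails rather than silently defaulting.
#'
#' @param path TIFF path.
#' @param voxel_size_nm optional explicit `(dz, dy, dx)` override.
#' @return an [ri_stack].
#' @export
read_ri_stack <- function(path, voxel_size_nm = NULL) {
  tf <- read_tiff_gray(path)
  vs <- if (!is.null(voxel_size_nm)) as.numeric(voxel_size_nm)
        else resolve_voxel_size(path, tf$meta)$vs
  ri_stack(tf$voxels, vs, provenance = path)
}

#' @rdname read_ri_stack
#' @export
read_fluor_stack <- function(path, voxel_size_nm = NULL) {
  tf <- read_tiff_gray(path)
  vs <- if (!is.null(voxel_size_nm)) as.numeric(voxel_size_nm)
        else resolve_voxel_size(path, tf$meta)$vs
  fluor_stack(pmax(tf$voxels, 0), vs, provenance = path)
}

#' Write a binary mask as 8-bit multi-page TIFF (0/255)
#'
#' @param mask logical 3-D array or a `cell_mask` object.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "cell_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  write_tiff_gray(path, array(as.integer(mask) * 255L, dim = dim(mask)),
                  bits = 8)
  invisible(path)
}

#' Read an 8-bit mask TIFF back as a logical array
#' @param path TIFF path.
#' @return logical 3-D array (nonzero = TRUE).
#' @export
read_mask <- function(path) {
  tf <- read_tiff_gray(path)
  tf$voxels > 0
}

#' Write a ground-truth label volume (0 medium, 1 cytoplasm, 2 nucleus, 3 NP)
#' @param scene a `phantom_scene`.
#' @param path output path.
#' @export
write_truth_labels <- function(scene, path) {
  lab <- array(0L, dim = dim(scene$cell_mask))
  lab[scene$cell_mask] <- 1L
  lab[scene$nucleus_mask] <- 2L
  lab[scene$np_mask] <- 3L
  write_tiff_gray(path, lab, bits = 8)
  invisible(path)
}

## ---- tabular outputs ---------------------------------------------------

#' Write the pipeline's tabular outputs
#'
#' Writes `fingerprints.csv` (cell_id, dose, bin_lo, percent),
#' `detections.csv` (cell_id, dose, band_voxels, band_percent,
#' n_components) and `coloc.csv` (cell_id, M1, dice, mean_fluor_au) into
#' `dir`.  Numbers keep full double precision (>= 6 significant digits).
#'
#' @param fingerprints,detections,coloc data frames with the columns above;
#'   empty frames yield headers-only files.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths.
#' @export
write_results <- function(fingerprints, detections, coloc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop(sprintf("%s must have columns: %s", what,
                   paste(cols, collapse = ", ")))
    }
    df[cols]
  }
  fp <- need(fingerprints, c("cell_id", "dose", "bin_lo", "percent"),
             "fingerprints")
  det <- need(detections, c("cell_id", "dose", "band_voxels", "band_percent",
                            "n_components"), "detections")
  cl <- need(coloc, c("cell_id", "M1", "dice", "mean_fluor_au"), "coloc")
  paths <- c(fingerprints = file.path(dir, "fingerprints.csv"),
             detections = file.path(dir, "detections.csv"),
             coloc = file.path(dir, "coloc.csv"))
  utils::write.csv(fp, paths["fingerprints"], row.names = FALSE)
  utils::write.csv(det, paths["detections"], row.names = FALSE)
  utils::write.csv(cl, paths["coloc"], row.names = FALSE)
  paths
}

#' Export one phantom cell to disk in the standard layout
#'
#' Writes `cell_<id>_ri.tif`, `cell_<id>_fl.tif`, `cell_<id>_truth.tif`
#' and `cell_<id>_meta.json` into `dir`.
#'
#' @param scene a `phantom_scene`.
#' @param stacks result of [render_stacks()] for that scene.
#' @param id cell identifier (string or integer).
#' @param dir output directory.
#' @return named vector of paths.
#' @export
write_cell <- function(scene, stacks, id, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- as.character(id)
  p <- c(ri = file.path(dir, sprintf("cell_%s_ri.tif", id)),
         fl = file.path(dir, sprintf("cell_%s_fl.tif", id)),
         truth = file.path(dir, sprintf("cell_%s_truth.tif", id)),
         meta = file.path(dir, sprintf("cell_%s_meta.json", id)))
  write_ri_stack(stacks$ri, p["ri"], sidecar = NA)
  write_fluor_stack(stacks$fluor, p["fl"], sidecar = NA)
  write_truth_labels(scene, p["truth"])
  write_stack_meta(p["meta"], stacks$ri$voxel_size_nm,
                   list(dose = scene$dose, seed = scene$seed))
  p
}
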