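# TIFF + OME companion-XML reading/writing. Channels are stored as 16-bit
# planes (camera counts 0..65535) in XYZCT order (z fastest, then channel);
# channel names and physical pixel/voxel sizes travel in an OME-XML
# companion file ("<path>.ome.xml") next to the TIFF — the OME companion
# layout for metadata-plus-binary pairs — so fields round-trip exactly.

ome_xml_for <- function(field) {
  d <- field_dim(field)
  nd <- length(d)
  px <- field$pixel_size
  sizez <- if (nd == 3L) d[3L] else 1L
  chans <- paste0(vapply(seq_along(field$channels), function(i) {
    sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            i - 1L, names(field$channels)[i])
  }, character(1)), collapse = "")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="%s">',
    '<Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="uint16" ',
    'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ',
    'PhysicalSizeX="%.17g" PhysicalSizeXUnit="µm" ',
    'PhysicalSizeY="%.17g" PhysicalSizeYUnit="µm" ',
    'PhysicalSizeZ="%.17g" PhysicalSizeZUnit="µm">',
    '%s<TiffData/></Pixels></Image></OME>'),
    field$field_id, d[2L], d[1L], sizez, length(field$channels),
    px[2L], px[1L], if (nd == 3L) px[3L] else 1, chans)
}

companion_path <- function(path) paste0(path, ".ome.xml")

#' Write a field as TIFF with an OME companion-XML file
#'
#' Planes are written z-fastest within each channel (dimension order
#' XYZCT) as uncompressed 16-bit data; intensities above 65535 are clipped
#' with a warning. Pixel sizes and channel names are written to an OME-XML
#' companion file `<path>.ome.xml` next to the TIFF.
#'
#' @param field an [image_field()].
#' @param path output file path (`.tiff`).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  d <- field_dim(field)
  nd <- length(d)
  planes <- list()
  for (ch in field$channels) {
    if (max(ch) > 65535) warn("intensities above 65535 clipped on write")
    ch <- pmin(pmax(round(ch), 0), 65535) / 65535
    if (nd == 2L) {
      planes <- c(planes, list(ch))
    } else {
      planes <- c(planes, lapply(seq_len(d[3L]), function(z) ch[, , z]))
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                  compression = "none")
  writeLines(ome_xml_for(field), companion_path(path), useBytes = TRUE)
  invisible(path)
}

parse_ome_companion <- function(path) {
  cp <- companion_path(path)
  if (!file.exists(cp)) return(NULL)
  doc <- tryCatch(xml2::read_xml(cp), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "ome")
  pix <- xml2::xml_find_first(doc, ".//ome:Pixels", ns)
  if (inherits(pix, "xml_missing")) return(NULL)
  att <- function(a) xml2::xml_attr(pix, a)
  chans <- xml2::xml_find_all(doc, ".//ome:Channel", ns)
  list(
    size = c(y = as.integer(att("SizeY")), x = as.integer(att("SizeX")),
             z = as.integer(att("SizeZ")), c = as.integer(att("SizeC"))),
    pixel_size = c(as.numeric(att("PhysicalSizeY")),
                   as.numeric(att("PhysicalSizeX")),
                   as.numeric(att("PhysicalSizeZ"))),
    channel_names = xml2::xml_attr(chans, "Name")
  )
}

#' Read a TIFF field (with or without OME companion metadata)
#'
#' Reads a field written by [write_field()] (bit-exact round trip, using
#' the `<path>.ome.xml` companion for sizes and channel names) or a plain
#' multi-plane TIFF, in which case the pixel size must be supplied and
#' planes are mapped to channels by `channel_names` (positionally, one
#' plane per channel, when no OME metadata is found).
#'
#' @param path TIFF file path.
#' @param pixel_size optional override / fallback µm-per-pixel (scalar or
#'   per-axis); required when the file has no physical metadata.
#' @param channel_names optional channel names used when the file carries
#'   none (defaults to `channel_1`, `channel_2`, ...).
#' @param field_id identifier (defaults to the file name).
#' @return An [image_field()].
#' @export
read_field <- function(path, pixel_size = NULL, channel_names = NULL,
                       field_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) == 0L) abort("no image planes in file")
  meta <- parse_ome_companion(path)
  n_planes <- length(planes)

  if (!is.null(meta)) {
    sz <- meta$size
    if (sz[["z"]] * sz[["c"]] != n_planes) {
      abort("plane count does not match OME metadata")
    }
    nz <- sz[["z"]]; nc <- sz[["c"]]
    nms <- meta$channel_names
    if (length(nms) != nc || any(is.na(nms))) {
      nms <- paste0("channel_", seq_len(nc))
    }
    if (!is.null(channel_names)) nms <- channel_names
    px <- if (nz > 1L) meta$pixel_size else meta$pixel_size[1:2]
    if (!is.null(pixel_size)) {
      px <- if (length(pixel_size) == 1L) {
        rep(pixel_size, if (nz > 1L) 3L else 2L)
      } else pixel_size
    }
  } else {
    nz <- 1L
    nc <- n_planes
    nms <- channel_names %||% paste0("channel_", seq_len(nc))
    if (is.null(pixel_size)) {
      abort("file carries no pixel-size metadata; supply `pixel_size`")
    }
    px <- if (length(pixel_size) == 1L) rep(pixel_size, 2L) else pixel_size
  }
  if (length(nms) != nc) abort("`channel_names` length must equal channel count")

  d2 <- dim(planes[[1L]])[1:2]
  to_counts <- function(m) round(m[, , drop = TRUE][seq_len(d2[1L]), , drop = FALSE] * 65535)
  channels <- lapply(seq_len(nc), function(ci) {
    if (nz == 1L) {
      to_counts(planes[[ci]])
    } else {
      arr <- array(0, c(d2, nz))
      for (z in seq_len(nz)) {
        arr[, , z] <- to_counts(planes[[(ci - 1L) * nz + z]])
      }
      arr
    }
  })
  names(channels) <- nms
  image_field(channels, px,
              field_id = field_id %||% sub("\\.(ome\\.)?tiff?$", "",
                                           basename(path)))
}

#' Write a cohort table as CSV
#'
#' @param cohort a tibble (e.g. from [run_cohort()] or
#'   [generate_cohort()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
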