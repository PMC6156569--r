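.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

#' Write a scattering volume as multi-component NIfTI plus JSON sidecar
#'
#' The coefficient volume is stored as a 4D NIfTI image (one component per
#' spherical-harmonics coefficient) with voxel spacing in mm. The sidecar
#' documents the basis convention (real, orthonormal, even degrees, no
#' Condon-Shortley phase, `(l, m)` lexicographic), the maximum degree, the
#' degree list, grid origin and the voxel-centered world convention
#' `world = origin + (index + 0.5) * spacing` (0-based indices).
#'
#' @param volume A [scattering_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param extra Named list merged into the sidecar (e.g. kernel,
#'   provenance).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, extra = list()) {
  stopifnot(inherits(volume, "scattering_volume"))
  img <- RNifti::asNifti(volume$coefficients)
  RNifti::pixdim(img) <- c(rep(volume$spacing, 3), 1)
  RNifti::writeNifti(img, path)
  sidecar <- c(list(
    format = "axdt-sh-volume",
    basis = list(convention = "real orthonormal, even degrees only, no Condon-Shortley phase, (l, m) lexicographic with m = -l..l",
                 max_degree = volume$basis$max_degree,
                 degrees = volume$basis$degrees$l,
                 orders = volume$basis$degrees$m,
                 n_components = volume$basis$size),
    grid = list(dims = volume$dims, spacing_mm = volume$spacing,
                origin_mm = volume$origin,
                indexing = "0-based; world = origin + (index + 0.5) * spacing")),
    extra)
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scattering volume written by [write_volume()]
#'
#' @param path Path to the NIfTI file; the JSON sidecar must sit next to it.
#' @return A [scattering_volume()].
#' @export
read_volume <- function(path) {
  side_path <- .sidecar_path(path)
  if (!file.exists(side_path)) {
    .axdt_stop("axdt_format_error", "missing sidecar %s", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(path))
  basis <- sh_basis(side$basis$max_degree)
  if (length(dim(arr)) != 4L || dim(arr)[4] != basis$size) {
    .axdt_stop("axdt_format_error",
               "volume has %d components but sidecar basis L=%d implies %d",
               if (length(dim(arr)) == 4L) dim(arr)[4] else 1L,
               basis$max_degree, basis$size)
  }
  scattering_volume(arr, basis, side$grid$spacing_mm, side$grid$origin_mm)
}

.protocol_to_list <- function(protocol) {
  list(
    frame = list(l = protocol$frame$l, t = protocol$frame$t),
    detector = list(nu = protocol$detector$nu, nv = protocol$detector$nv,
                    pitch_mm = protocol$detector$pitch),
    angle_unit = "degrees",
    poses = lapply(protocol$poses, function(p) {
      list(euler_deg = p$euler_angles * 180 / pi,
           tomo_deg = p$tomo_angle * 180 / pi)
    }))
}

.protocol_from_list <- function(x) {
  frame <- grating_frame(as.numeric(x$frame$l), as.numeric(x$frame$t))
  det <- detector_spec(x$detector$nu, x$detector$nv, x$detector$pitch_mm)
  poses <- lapply(x$poses, function(p) {
    pose(as.numeric(p$euler_deg) * pi / 180,
         as.numeric(p$tomo_deg) * pi / 180)
  })
  structure(list(poses = poses, frame = frame, detector = det),
            class = "acquisition_protocol")
}

#' Write an acquisition protocol as structured text (YAML)
#'
#' Angles are stored in degrees (radians internally), detector pitch in mm.
#'
#' @param protocol An [acquisition_protocol()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(.protocol_to_list(protocol), path, precision = 15)
  invisible(path)
}

#' Read an acquisition protocol written by [write_protocol()]
#' @param path Path to the YAML file.
#' @return An [acquisition_protocol()].
#' @export
read_protocol <- function(path) {
  .protocol_from_list(yaml::read_yaml(path))
}

#' Write a dark-field sinogram (NIfTI array + JSON sidecar)
#'
#' The per-pose detector frames are stored as a 3D array
#' `(nu, nv, n_pose)`; the sidecar carries the signal domain
#' (`"transmission"` for d in (0, 1], `"log"` for p = -log d), units and
#' the full acquisition protocol, so a sinogram file is self-describing.
#'
#' @param sinogram A [darkfield_sinogram()].
#' @param protocol The matching [acquisition_protocol()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sinogram, protocol, path) {
  stopifnot(inherits(sinogram, "darkfield_sinogram"),
            inherits(protocol, "acquisition_protocol"))
  if (sinogram$domain == "log" && any(sinogram$data < 0)) {
    .axdt_stop("axdt_invalid_data",
               "log-domain sinogram with negative values cannot be written")
  }
  RNifti::writeNifti(RNifti::asNifti(sinogram$data), path)
  sidecar <- list(format = "axdt-darkfield-sinogram",
                  domain = sinogram$domain,
                  units = "dimensionless (visibility reduction)",
                  protocol = .protocol_to_list(protocol))
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dark-field sinogram written by [write_sinogram()]
#'
#' Enforces the domain flag: a missing domain attribute is a format error,
#' and transmission-domain data must lie in (0, 1].
#'
#' @param path Path to the NIfTI file.
#' @return List with `sinogram` (a [darkfield_sinogram()]) and `protocol`.
#' @export
read_sinogram <- function(path) {
  side_path <- .sidecar_path(path)
  if (!file.exists(side_path)) {
    .axdt_stop("axdt_format_error", "missing sidecar %s", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
  if (is.null(side$domain)) {
    .axdt_stop("axdt_format_error", "sinogram sidecar lacks a domain flag")
  }
  arr <- as.array(RNifti::readNifti(path))
  sino <- darkfield_sinogram(arr, side$domain)
  list(sinogram = sino, protocol = .protocol_from_list(side$protocol))
}

#' Write streamlines in MRtrix TCK format
#'
#' Standard tractography container readable by MRtrix/mrview and most
#' neuroimaging viewers: a text header followed by little-endian float32
#' point triplets, streamlines separated by NaN triplets and the stream
#' terminated by an Inf triplet. Coordinates are world mm.
#'
#' @param streamlines List of streamlines from [track_streamlines()] (or
#'   any list of m x 3 matrices / lists with a `points` entry).
#' @param path Output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  pts <- lapply(streamlines, function(s) {
    if (is.list(s) && !is.null(s$points)) s$points else rbind(s)
  })
  header <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", length(pts), "\n")
  # fixed-width offset field keeps the header length self-consistent
  off <- nchar(header, type = "bytes") +
    nchar(sprintf("file: . %06d\nEND\n", 0), type = "bytes")
  hdr <- paste0(header, sprintf("file: . %06d\nEND\n", off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (p in pts) {
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK streamline file
#' @param path Path to the `.tck` file.
#' @return List of m x 3 point matrices.
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  end_pat <- as.raw(c(0x45, 0x4e, 0x44, 0x0a))  # "END\n"
  hdr_end <- NA
  for (i in seq_len(length(raw) - 3)) {
    if (all(raw[i:(i + 3)] == end_pat)) { hdr_end <- i + 3; break }
  }
  hdr <- rawToChar(raw[1:hdr_end])
  off <- as.integer(sub(".*file: \\. ([0-9]+).*", "\\1", hdr))
  vals <- readBin(raw[(off + 1):length(raw)], "numeric", size = 4,
                  n = (length(raw) - off) / 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_inf <- apply(m, 1, function(r) all(is.infinite(r)))
  m <- m[seq_len(which(is_inf)[1] - 1), , drop = FALSE]
  breaks <- which(apply(m, 1, function(r) all(is.nan(r))))
  starts <- c(1, head(breaks, -1) + 1)
  mapply(function(s, e) m[s:e, , drop = FALSE], starts, breaks - 1,
         SIMPLIFY = FALSE)
}

#' Export an orientation field as NIfTI maps (+ optional peak CSV)
#'
#' Writes `<prefix>_dir.nii.gz` (principal direction, 3 components),
#' `<prefix>_magnitude.nii.gz` (Funk-Radon magnitude) and
#' `<prefix>_anisotropy.nii.gz`, plus `<prefix>_peaks.csv` with one row per
#' peak (voxel indices, direction, magnitude) when `peaks_csv = TRUE`.
#'
#' @param field An [principal_orientation_field()] result.
#' @param prefix Output path prefix.
#' @param peaks_csv Also write the per-peak CSV?
#' @return Named character vector of the written paths, invisibly.
#' @export
write_orientation_field <- function(field, prefix, peaks_csv = FALSE) {
  dims <- field$dims
  dir_arr <- array(field$principal, c(dims, 3))
  mag_arr <- array(field$magnitude, dims)
  ani_arr <- array(field$anisotropy, dims)
  out <- c(dir = paste0(prefix, "_dir.nii.gz"),
           magnitude = paste0(prefix, "_magnitude.nii.gz"),
           anisotropy = paste0(prefix, "_anisotropy.nii.gz"))
  for (nm in names(out)) {
    arr <- switch(nm, dir = dir_arr, magnitude = mag_arr,
                  anisotropy = ani_arr)
    arr[is.na(arr)] <- 0
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(field$spacing, 3),
                             rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(img, out[[nm]])
  }
  if (peaks_csv) {
    rows <- list()
    for (v in seq_along(field$peaks)) {
      pk <- field$peaks[[v]]
      if (is.null(pk) || nrow(pk$directions) == 0) next
      ijk <- arrayInd(v, dims) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        i = ijk[1], j = ijk[2], k = ijk[3],
        x = pk$directions[, 1], y = pk$directions[, 2],
        z = pk$directions[, 3], magnitude = pk$magnitudes)
    }
    csv <- paste0(prefix, "_peaks.csv")
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(i = integer(), j = integer(), k = integer(),
                 x = numeric(), y = numeric(), z = numeric(),
                 magnitude = numeric())
    utils::write.csv(df, csv, row.names = FALSE)
    out <- c(out, peaks = csv)
  }
  invisible(out)
}
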