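#' Read and write MRC2014 density maps
#'
#' Minimal MRC2014 I/O for float maps.  Units follow the convention used
#' by deposited EM maps: the file header stores cell dimensions in
#' Angstroms, internal maps are in nm, so voxel sizes are divided by 10 on
#' read and multiplied by 10 on write.  The ORIGIN header record is
#' honoured (also in Angstroms); the older start-index records
#' (NXSTART/NYSTART/NZSTART) are ignored with a note, since MRC dialects
#' disagree about them.  Axis order must be the standard MAPC/MAPR/MAPS =
#' 1/2/3 (x fastest), which matches the internal array layout.
#'
#' @param path file path.
#' @return `read_mrc` returns a [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.size(path)
  if (sz < 1024) stop("corrupt MRC header: file shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) > 1e5))
    stop("corrupt MRC header: implausible dimensions")
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps_ <- hdr_int[19]
  if (!(mapc == 1 && mapr == 2 && maps_ == 3))
    stop("unsupported MRC axis order MAPC/MAPR/MAPS = ",
         mapc, "/", mapr, "/", maps_, " (only 1/2/3 is supported)")
  if (any(hdr_int[5:7] != 0))
    message("note: nonzero NXSTART/NYSTART/NZSTART ignored (ORIGIN is used)")
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  vox_nm <- cella[1] / max(mx, 1L) / 10
  vox_y <- cella[2] / max(my, 1L) / 10
  vox_z <- cella[3] / max(mz, 1L) / 10
  if (vox_nm <= 0) vox_nm <- 1
  if (abs(vox_y - vox_nm) > 1e-6 * vox_nm ||
      abs(vox_z - vox_nm) > 1e-6 * vox_nm)
    stop("anisotropic voxel sizes are not supported")
  origin_nm <- hdr_num[50:52] / 10
  nsymbt <- hdr_int[24]
  bytes_per <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, NA)
  if (is.na(bytes_per))
    stop("unsupported MRC mode ", mode, " (modes 0, 1, 2 are supported)")
  n_vox <- as.double(nx) * ny * nz
  if (sz < 1024 + nsymbt + n_vox * bytes_per)
    stop("corrupt/truncated MRC file: data block shorter than header promises")
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_vox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n_vox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"))
  density_map(array(vals, dim = c(nx, ny, nz)), vox_nm, origin_nm)
}

#' @rdname read_mrc
#' @param map a [density_map()]; written as mode 2 (float32).
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2L)                      # MODE 2: float32
  wi(c(0L, 0L, 0L))           # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * map$voxel_nm * 10)   # CELLA in Angstroms
  wf(c(90, 90, 90))           # CELLB
  wi(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1L)                      # ISPG
  wi(0L)                      # NSYMBT
  wi(rep(0L, 25))             # EXTRA
  wf(map$origin * 10)         # ORIGIN in Angstroms
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(map$values))   # RMS
  wi(0L)                      # NLABL
  writeBin(raw(800), con)     # labels
  wf(map$values)
  invisible(path)
}
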