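# Minimal single-frame DICOM series support (secondary input format).
# Scope: uncompressed little-endian transfer syntaxes (implicit and explicit
# VR), monochrome single-frame axial slices, 8/16-bit unsigned or signed
# integer pixels. Slices are ordered by world position along the slice
# normal; DICOM LPS patient axes are converted to the package's RAS
# convention on load.

.dcmTagKey <- function(group, element) sprintf("%04X,%04X", group, element)

.dcmParseFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  u16 <- function(at) as.integer(raw[at + 1]) + 256L * as.integer(raw[at + 2])
  u32 <- function(at) sum(as.numeric(raw[at + 1:4]) * c(1, 256, 65536, 16777216))
  pos <- 0L
  if (n > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 132L
  explicit <- TRUE  # meta group is always explicit VR
  syntax <- "1.2.840.10008.1.2.1"
  out <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= n) {
    group <- u16(pos); element <- u16(pos + 2)
    if (group > 2L) explicit <- (syntax != "1.2.840.10008.1.2")
    if (explicit) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% longVRs) { len <- u32(pos + 8); hdr <- 12L }
      else { len <- u16(pos + 6); hdr <- 8L }
    } else {
      vr <- ""; len <- u32(pos + 4); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    body <- pos + hdr
    if (body + len > n) stop("truncated DICOM element in ", path)
    key <- .dcmTagKey(group, element)
    keep <- key %in% c("0002,0010", "0020,0032", "0020,0037", "0028,0010",
                       "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                       "0028,1052", "0028,1053", "7FE0,0010")
    if (keep) {
      val <- raw[(body + 1):(body + len)]
      out[[key]] <- val
      if (key == "0002,0010")
        syntax <- trimws(rawToChar(val[val != as.raw(0)]))
    }
    pos <- body + len
    if (key == "7FE0,0010") break
  }
  str <- function(key) {
    v <- out[[key]]
    if (is.null(v)) return(NULL)
    trimws(rawToChar(v[v != as.raw(0)]))
  }
  nums <- function(key) as.numeric(strsplit(str(key), "\\\\")[[1]])
  us <- function(key) {
    v <- out[[key]]
    if (is.null(v)) return(NULL)
    as.integer(v[1]) + 256L * as.integer(v[2])
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- us("0028,0100"); pixrep <- us("0028,0103")
  if (is.null(rows) || is.null(cols) || is.null(bits))
    stop("missing image geometry tags in ", path)
  if (is.null(pixrep)) pixrep <- 0L
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit DICOM pixels are supported")
  px <- out[["7FE0,0010"]]
  if (is.null(px)) stop("missing pixel data in ", path)
  vals <- readBin(px, what = "integer", n = rows * cols, size = bits / 8,
                  signed = (pixrep == 1L && bits == 16L), endian = "little")
  if (bits == 8L && pixrep == 0L) vals <- as.integer(vals) %% 256L
  if (bits == 16L && pixrep == 0L) vals[vals < 0] <- vals[vals < 0] + 65536
  slope <- if (!is.null(str("0028,1053"))) nums("0028,1053") else 1
  inter <- if (!is.null(str("0028,1052"))) nums("0028,1052") else 0
  list(pixels = matrix(vals * slope + inter, nrow = cols, ncol = rows),
       ipp = nums("0020,0032"), iop = nums("0020,0037"),
       pixelSpacing = nums("0028,0030"), rows = rows, cols = cols)
}

readDicomSeries <- function(dir, sequence = "OTHER") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stop("DICOM series needs at least 2 slices in ", dir)
  slices <- lapply(files, .dcmParseFile)
  iop <- slices[[1]]$iop
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  steps <- diff(zpos)
  if (any(steps <= 0)) stop("duplicate DICOM slice positions in ", dir)
  if (max(abs(steps - median(steps))) > 0.01 * median(steps))
    stop("inconsistent DICOM slice spacing (> 1% deviation) in ", dir)
  ps <- slices[[1]]$pixelSpacing
  d <- c(slices[[1]]$cols, slices[[1]]$rows, length(slices))
  data <- array(0, d)
  for (k in seq_along(slices)) {
    if (!all(dim(slices[[k]]$pixels) == d[1:2]))
      stop("inconsistent DICOM slice dimensions in ", dir)
    data[, , k] <- slices[[k]]$pixels
  }
  # LPS affine: i along rows (row direction, column spacing), j across rows
  aff <- diag(4)
  aff[1:3, 1] <- rowdir * ps[2]
  aff[1:3, 2] <- coldir * ps[1]
  aff[1:3, 3] <- normal * median(steps)
  aff[1:3, 4] <- slices[[1]]$ipp
  # LPS -> RAS
  aff[1:2, ] <- -aff[1:2, ]
  spacing <- c(ps[2], ps[1], median(steps))
  ImageVolume(data, spacing = spacing, affine = aff, sequence = sequence)
}

# Internal writer used to build test fixtures at run time (explicit VR little
# endian, 16-bit unsigned). Intensities are rounded to integers.
writeDicomSeries <- function(vol, dir, shuffleNames = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol@data)
  affLps <- vol@affine
  affLps[1:2, ] <- -affLps[1:2, ]
  rowdir <- affLps[1:3, 1] / sqrt(sum(affLps[1:3, 1]^2))
  coldir <- affLps[1:3, 2] / sqrt(sum(affLps[1:3, 2]^2))
  colSp <- sqrt(sum(affLps[1:3, 1]^2))
  rowSp <- sqrt(sum(affLps[1:3, 2]^2))
  el <- function(group, element, vr, value) {
    hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little")
    if (vr %in% c("OB", "OW")) {
      c(hdr, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(as.integer(length(value)), raw(), size = 4, endian = "little"), value)
    } else {
      if (is.character(value)) {
        value <- charToRaw(value)
        if (length(value) %% 2 == 1)
          value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
      }
      c(hdr, charToRaw(vr),
        writeBin(as.integer(length(value)), raw(), size = 2, endian = "little"), value)
    }
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  ds <- function(x) paste(format(x, digits = 10, trim = TRUE), collapse = "\\")
  order <- if (shuffleNames) rev(seq_len(d[3])) else seq_len(d[3])
  for (pos in seq_len(d[3])) {
    k <- order[pos]
    ipp <- affLps[1:3, 4] + (k - 1) * affLps[1:3, 3]
    px <- as.integer(round(as.vector(vol@data[, , k])))
    if (any(px < 0 | px > 65535)) stop("DICOM writer supports uint16 intensities only")
    # pixel rows are written sequentially: row-major over (j rows, i cols)
    pxm <- matrix(px, nrow = d[1], ncol = d[2])
    pxraw <- writeBin(as.integer(pxm), raw(), size = 2, endian = "little")
    meta <- c(el(2L, 16L, "UI", "1.2.840.10008.1.2.1"))
    metaLen <- el(2L, 0L, "UL", writeBin(length(meta), raw(), size = 4, endian = "little"))
    body <- c(
      el(8L, 0x60L, "CS", "MR"),
      el(0x20L, 0x13L, "IS", as.character(k)),
      el(0x20L, 0x32L, "DS", ds(ipp)),
      el(0x20L, 0x37L, "DS", ds(c(rowdir, coldir))),
      el(0x28L, 2L, "US", us(1)),
      el(0x28L, 4L, "CS", "MONOCHROME2"),
      el(0x28L, 0x10L, "US", us(d[2])),
      el(0x28L, 0x11L, "US", us(d[1])),
      el(0x28L, 0x30L, "DS", ds(c(rowSp, colSp))),
      el(0x28L, 0x100L, "US", us(16)),
      el(0x28L, 0x101L, "US", us(16)),
      el(0x28L, 0x102L, "US", us(15)),
      el(0x28L, 0x103L, "US", us(0)),
      el(0x7FE0L, 0x10L, "OW", pxraw))
    out <- c(raw(128), charToRaw("DICM"), metaLen, meta, body)
    writeBin(out, file.path(dir, sprintf("slice_%03d.dcm", pos)))
  }
  invisible(dir)
}
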