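# Mask file I/O.
#
# No NIfTI/NRRD reader ships with the declared dependency set, so both
# formats are implemented here directly against their published layouts:
# NRRD with an attached header (raw / gzip / ascii encodings) and NIfTI-1
# single-file .nii / .nii.gz with an sform affine.  Only axis-aligned
# orientations are accepted: directional margins are defined on patient
# axes and oblique grids would require resampling, which is out of scope.

#' Read a binary structure mask
#'
#' Reads a NRRD (`.nrrd`) or NIfTI-1 (`.nii`, `.nii.gz`) volume and
#' returns a [voxel_mask] in the canonical LPS frame.  The orientation is
#' taken from the NRRD `space`/`space directions` fields or the NIfTI
#' sform and must be axis-aligned (permutations and flips of the patient
#' axes); oblique affines are rejected.
#'
#' Non-binary payloads are rejected unless `threshold` is given, in which
#' case voxels with `value > threshold` are occupied.
#'
#' @param path file path; format chosen by extension.
#' @param threshold optional numeric binarization threshold.
#' @return a [voxel_mask].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path, threshold = NULL) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    g <- read_nrrd_raw(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    g <- read_nifti_raw(path)
  } else {
    stop("unsupported mask format (expect .nrrd, .nii or .nii.gz): ", path,
         call. = FALSE)
  }
  vals <- g$values
  if (is.null(threshold)) {
    u <- unique(as.vector(vals))
    if (!all(u %in% c(0, 1)))
      stop("non-binary mask payload (values outside {0,1}); ",
           "pass threshold= to binarize", call. = FALSE)
    vox <- array(vals != 0, dim(vals))
  } else {
    vox <- array(vals > threshold, dim(vals))
  }
  voxel_mask(vox, spacing = g$spacing, origin = g$origin,
             axis_labels = g$axis_labels)
}

#' Write a binary structure mask
#'
#' Writes a [voxel_mask] as NRRD (attached header, LPS space) or NIfTI-1
#' (RAS sform).  Payload is uint8 0/1.  Round-tripping through either
#' format preserves dims, spacing (to float precision for NIfTI) and
#' every voxel.
#'
#' @param mask a [voxel_mask].
#' @param path output path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param encoding NRRD payload encoding: `"gzip"` (default), `"raw"` or
#'   `"ascii"` (plain-text, useful for small fixtures).  Ignored for
#'   NIfTI.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, encoding = c("gzip", "raw", "ascii")) {
  stopifnot(inherits(mask, "voxel_mask"))
  encoding <- match.arg(encoding)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_raw(mask, path, encoding)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_raw(mask, path)
  } else {
    stop("unsupported mask format (expect .nrrd, .nii or .nii.gz): ", path,
         call. = FALSE)
  }
  invisible(path)
}

## ---------------------------------------------------------------- NRRD

.NRRD_SPACES <- list(
  "left-posterior-superior"  = c(1, 1, 1),
  "right-anterior-superior"  = c(-1, -1, 1),
  "left-anterior-superior"   = c(1, -1, 1),
  "right-posterior-superior" = c(-1, 1, 1),
  "lps" = c(1, 1, 1), "ras" = c(-1, -1, 1)
)

write_nrrd_raw <- function(mask, path, encoding) {
  dm <- dim(mask$voxels)
  sp <- mask$spacing
  o <- mask$origin
  hdr <- c(
    "NRRD0004",
    "# ce4dct binary structure mask",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dm[1], dm[2], dm[3]),
    "space: left-posterior-superior",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)", o[1], o[2], o[3]),
    "endian: little",
    sprintf("encoding: %s", encoding)
  )
  payload <- as.raw(as.integer(mask$voxels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  if (encoding == "raw") {
    writeBin(payload, con)
  } else if (encoding == "gzip") {
    writeBin(memCompress(payload, type = "gzip"), con)
  } else {
    txt <- paste(as.integer(mask$voxels), collapse = " ")
    writeChar(paste0(txt, "\n"), con, eos = NULL)
  }
}

# parse "(a,b,c)" vector syntax
.parse_nrrd_vec <- function(tok) {
  tok <- gsub("[()]", "", tok)
  as.numeric(strsplit(tok, ",")[[1]])
}

read_nrrd_raw <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # attached header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line after header",
                           call. = FALSE)
  hdr_txt <- rawToChar(bytes[seq_len(hdr_end - 2L)])
  lines <- strsplit(hdr_txt, "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not a NRRD file: ", path, call. = FALSE)
  lines <- lines[-1]
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  if (is.null(kv$dimension) || as.integer(kv$dimension) != 3L)
    stop("only 3-dimensional NRRD supported", call. = FALSE)
  sizes <- as.integer(strsplit(kv$sizes, "[ \t]+")[[1]])
  type <- tolower(kv$type)
  enc <- tolower(kv$encoding)
  endian <- if (!is.null(kv$endian)) tolower(kv$endian) else "little"

  n <- prod(sizes)
  data_bytes <- bytes[hdr_end:length(bytes)][-1]
  rdr <- switch(type,
    "uint8" = , "uchar" = , "unsigned char" =
      function(b) as.numeric(readBin(b, "integer", n, size = 1,
                                     signed = FALSE)),
    "int16" = , "short" = , "signed short" =
      function(b) as.numeric(readBin(b, "integer", n, size = 2,
                                     signed = TRUE, endian = endian)),
    "int32" = , "int" =
      function(b) as.numeric(readBin(b, "integer", n, size = 4,
                                     endian = endian)),
    "float" =
      function(b) readBin(b, "double", n, size = 4, endian = endian),
    "double" =
      function(b) readBin(b, "double", n, size = 8, endian = endian),
    stop("unsupported NRRD type: ", type, call. = FALSE))
  vals <- switch(enc,
    "raw" = rdr(data_bytes),
    "gzip" = , "gz" = rdr(memDecompress(data_bytes, type = "gzip")),
    "ascii" = , "text" = , "txt" =
      as.numeric(strsplit(trimws(rawToChar(data_bytes)), "[ \t\n\r]+")[[1]]),
    stop("unsupported NRRD encoding: ", enc, call. = FALSE))
  if (length(vals) != n)
    stop("NRRD payload has ", length(vals), " values, expected ", n,
         call. = FALSE)
  vals <- array(vals, sizes)

  space <- tolower(if (!is.null(kv$space)) kv$space else
                     "left-posterior-superior")
  to_lps <- .NRRD_SPACES[[space]]
  if (is.null(to_lps)) stop("unsupported NRRD space: ", space, call. = FALSE)

  if (!is.null(kv[["space directions"]])) {
    toks <- regmatches(kv[["space directions"]],
                       gregexpr("\\([^)]*\\)", kv[["space directions"]]))[[1]]
    if (length(toks) != 3) stop("expected 3 space directions", call. = FALSE)
    D <- sapply(toks, .parse_nrrd_vec)  # columns = grid axes, in file space
  } else if (!is.null(kv$spacings)) {
    D <- diag(as.numeric(strsplit(kv$spacings, "[ \t]+")[[1]]))
  } else {
    D <- diag(3)
  }
  origin <- if (!is.null(kv[["space origin"]]))
    .parse_nrrd_vec(kv[["space origin"]]) else c(0, 0, 0)
  D <- D * to_lps          # row-wise sign flip into LPS
  origin <- origin * to_lps
  geom <- direction_matrix_to_labels(D)
  list(values = vals, spacing = geom$spacing, origin = origin,
       axis_labels = geom$labels)
}

# direction matrix (columns = grid axes, LPS components) -> labels+spacing;
# rejects oblique matrices
direction_matrix_to_labels <- function(D) {
  labels <- character(3)
  spacing <- numeric(3)
  for (g in 1:3) {
    col <- D[, g]
    nz <- which(abs(col) > 1e-6 * max(abs(col)))
    if (length(nz) != 1)
      stop("oblique orientation not supported (margins are defined on ",
           "patient axes)", call. = FALSE)
    spacing[g] <- abs(col[nz])
    labels[g] <- if (col[nz] > 0) .DIR_POS[nz] else .DIR_NEG[nz]
  }
  list(labels = labels, spacing = spacing)
}

## -------------------------------------------------------------- NIfTI-1

write_nifti_raw <- function(mask, path) {
  dm <- dim(mask$voxels)
  sp <- mask$spacing
  o <- mask$origin
  hdr <- raw(348)
  put <- function(h, off, val, what, size) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    h[(off + 1):(off + length(b))] <- b
    h
  }
  hdr <- put(hdr, 0L, 348L, "int", 4)                       # sizeof_hdr
  hdr <- put(hdr, 40L, as.integer(c(3L, dm, 1L, 1L, 1L, 1L)), "short", 2)
  hdr <- put(hdr, 70L, 2L, "short", 2)                      # datatype uint8
  hdr <- put(hdr, 72L, 8L, "short", 2)                      # bitpix
  hdr <- put(hdr, 76L, c(1, sp, 0, 0, 0, 0), "float", 4)    # pixdim
  hdr <- put(hdr, 108L, 352, "float", 4)                    # vox_offset
  hdr <- put(hdr, 112L, 1, "float", 4)                      # scl_slope
  hdr <- put(hdr, 116L, 0, "float", 4)                      # scl_inter
  hdr[124L] <- as.raw(2L)                                   # xyzt_units: mm
  hdr <- put(hdr, 252L, 0L, "short", 2)                     # qform_code
  hdr <- put(hdr, 254L, 1L, "short", 2)                     # sform_code
  # canonical LPS grid -> RAS affine: x_ras = -x_lps, y_ras = -y_lps
  hdr <- put(hdr, 280L, c(-sp[1], 0, 0, -o[1]), "float", 4) # srow_x
  hdr <- put(hdr, 296L, c(0, -sp[2], 0, -o[2]), "float", 4) # srow_y
  hdr <- put(hdr, 312L, c(0, 0, sp[3], o[3]), "float", 4)   # srow_z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))           # magic
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                                     # extension flag
  writeBin(as.raw(as.integer(mask$voxels)), con)
}

read_nifti_raw <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  get <- function(off, what, size, n = 1, signed = TRUE) {
    b <- hdr[(off + 1):(off + size * n)]
    if (what == "float") readBin(b, "double", n, size = size,
                                 endian = "little")
    else readBin(b, "integer", n, size = size, signed = signed,
                 endian = "little")
  }
  if (get(0, "int", 4) != 348L)
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("only single-file NIfTI (magic n+1) supported",
                           call. = FALSE)
  dims <- get(40, "short", 2, n = 8)
  extra <- if (dims[1] > 3) dims[5:(dims[1] + 1)] else integer(0)
  if (dims[1] < 3 || any(extra > 1))
    stop("only 3D NIfTI volumes supported", call. = FALSE)
  dm <- dims[2:4]
  datatype <- get(70, "short", 2)
  vox_offset <- get(108, "float", 4)
  scl_slope <- get(112, "float", 4)
  scl_inter <- get(116, "float", 4)
  sform_code <- get(254, "short", 2)
  if (sform_code <= 0)
    stop("NIfTI without sform (qform-only) not supported", call. = FALSE)
  srow <- rbind(get(280, "float", 4, n = 4),
                get(296, "float", 4, n = 4),
                get(312, "float", 4, n = 4))
  # skip to payload
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dm)
  vals <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                               endian = "little")),
    "8"   = as.numeric(readBin(con, "integer", n, size = 4,
                               endian = "little")),
    "16"  = readBin(con, "double", n, size = 4, endian = "little"),
    "64"  = readBin(con, "double", n, size = 8, endian = "little"),
    "256" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "512" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = "little")),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  if (length(vals) != n) stop("truncated NIfTI payload", call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vals <- array(vals, dm)
  # sform maps 0-based voxel indices to RAS; convert to LPS
  D_ras <- srow[, 1:3]
  o_ras <- srow[, 4]
  flip <- c(-1, -1, 1)
  D <- D_ras * flip
  origin <- o_ras * flip
  geom <- direction_matrix_to_labels(D)
  list(values = vals, spacing = geom$spacing, origin = origin,
       axis_labels = geom$labels)
}
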