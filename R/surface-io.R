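#' Per-vertex scalar field
#'
#' Wraps a length-V numeric vector together with the feature it measures
#' (cortical thickness, surface area, volume, a statistic, or a mask) and
#' its units.
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param feature one of `"CT"`, `"SA"`, `"CV"`, `"stat"`, `"mask"`.
#' @param units unit label (`"mm"`, `"mm2"`, `"mm3"`, `"unitless"`).
#' @return a `vertex_field` object.
#' @export
vertex_field <- function(values,
                         feature = c("stat", "CT", "SA", "CV", "mask"),
                         units = "unitless") {
  feature <- match.arg(feature)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("vertex field contains non-finite values")
  }
  structure(list(values = values, feature = feature, units = units),
            class = "vertex_field")
}

field_values <- function(x) if (inherits(x, "vertex_field")) x$values else x

TRIANGLE_MAGIC <- 16777214L # 0xFFFFFE, FreeSurfer binary triangle surface
CURV_MAGIC <- 16777215L     # 0xFFFFFF, FreeSurfer "new" curv (morph data)

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) stop("truncated file: could not read magic number")
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

write_int3 <- function(con, value) {
  b <- as.integer(c(value %/% 65536L, (value %/% 256L) %% 256L, value %% 256L))
  writeBin(b, con, size = 1L)
}

#' Read a FreeSurfer binary triangle surface
#'
#' Decodes the big-endian binary triangle-surface container used for
#' template meshes (e.g. `lh.white`). Face indices are converted to R's
#' 1-based convention.
#'
#' @param path file path.
#' @param hemisphere hemisphere label to attach; defaults from a leading
#'   `lh.`/`rh.` in the file name, else `"left"`.
#' @return a `surf_mesh`.
#' @export
read_surface <- function(path, hemisphere = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(hemisphere)) {
    hemisphere <- if (grepl("^rh\\.", basename(path))) "right" else "left"
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic == CURV_MAGIC) {
    stop("unsupported format: file is a curv (morph data) file, ",
         "not a triangle surface")
  }
  if (magic != TRIANGLE_MAGIC) {
    stop(sprintf("unsupported format: magic 0x%06X is not a triangle surface",
                 magic))
  }
  # comment line terminated by "\n\n"
  prev <- as.raw(0L)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L) stop("parse error at byte ", seek(con),
                               ": unterminated comment")
    if (ch == as.raw(10L) && prev == as.raw(10L)) break
    prev <- ch
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L) stop("parse error at byte ", seek(con),
                                ": missing vertex/face counts")
  V <- counts[1L]; F_ <- counts[2L]
  coords <- readBin(con, "double", n = 3L * V, size = 4L, endian = "big")
  if (length(coords) < 3L * V) stop("parse error at byte ", seek(con),
                                    ": truncated vertex coordinates")
  faces <- readBin(con, "integer", n = 3L * F_, size = 4L, endian = "big")
  if (length(faces) < 3L * F_) stop("parse error at byte ", seek(con),
                                    ": truncated face list")
  surf_mesh(matrix(coords, ncol = 3L, byrow = TRUE),
            matrix(faces, ncol = 3L, byrow = TRUE) + 1L,
            hemisphere)
}

#' Write a FreeSurfer binary triangle surface
#'
#' Writes big-endian per the public format: 3-byte magic, comment
#' terminated by two newlines, vertex/face counts, float32 coordinates,
#' int32 0-based faces. Output is deterministic, so two writes of the same
#' mesh are byte-identical.
#'
#' @param mesh a `surf_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surf_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, TRIANGLE_MAGIC)
  writeBin(charToRaw("created by surfmorph\n\n"), con)
  writeBin(as.integer(c(mesh$V, mesh$F)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$coords)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a per-vertex scalar field
#'
#' Accepts either the FreeSurfer "new" curv (morph data) binary format or a
#' plain-text file with one numeric value per line. The expected vertex
#' count is checked so silently mismatched templates are caught early.
#'
#' @param path file path.
#' @param expected_V required number of vertices.
#' @param feature,units passed to [vertex_field()].
#' @return a `vertex_field` of length `expected_V`.
#' @export
read_vertex_field <- function(path, expected_V, feature = "stat",
                              units = "unitless") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  magic <- try(read_int3(con), silent = TRUE)
  if (!inherits(magic, "try-error") && magic == CURV_MAGIC) {
    on.exit(close(con))
    hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    if (length(hdr) < 3L) stop("parse error: truncated curv header")
    vnum <- hdr[1L]
    if (hdr[3L] != 1L) stop("unsupported curv file: ", hdr[3L],
                            " values per vertex")
    vals <- readBin(con, "double", n = vnum, size = 4L, endian = "big")
    if (length(vals) < vnum) stop("parse error: truncated curv data")
  } else if (!inherits(magic, "try-error") && magic == TRIANGLE_MAGIC) {
    close(con)
    stop("unsupported format: file is a triangle surface, not a vertex field")
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      stop("parse error at line ", which(is.na(vals))[1L],
           ": non-numeric token '", lines[which(is.na(vals))[1L]], "'")
    }
  }
  if (length(vals) != expected_V) {
    stop("shape error: file has ", length(vals), " values, expected ",
         expected_V)
  }
  vertex_field(vals, feature, units)
}

#' Write a per-vertex scalar field
#'
#' @param field a `vertex_field` or numeric vector.
#' @param path output path.
#' @param format `"curv"` (FreeSurfer morph data, float32) or `"text"`
#'   (one value per line, full double precision).
#' @return `path`, invisibly.
#' @export
write_vertex_field <- function(field, path, format = c("curv", "text")) {
  format <- match.arg(format)
  vals <- field_values(field)
  if (format == "text") {
    writeLines(format(vals, digits = 17, trim = TRUE, scientific = FALSE),
               path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    write_int3(con, CURV_MAGIC)
    writeBin(as.integer(c(length(vals), 0L, 1L)), con, size = 4L,
             endian = "big")
    writeBin(as.numeric(vals), con, size = 4L, endian = "big")
  }
  invisible(path)
}
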