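# Image input/output: grayscale readers for PNG/TIFF/PGM and exporters
# for depth results (plain-text matrix, PNG, OBJ height-field mesh,
# profile CSV).

#' Read a grayscale image
#'
#' Reads PNG (via the png package), TIFF (via the tiff package, if
#' installed) or plain/raw PGM. Color inputs are converted to luminance
#' by channel averaging; values are returned in `[0, 1]`.
#'
#' @param path file path; format inferred from the extension.
#' @return numeric matrix.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the tiff package")
      }
      tiff::readTIFF(path)
    },
    pgm = read_pgm(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                           c(1, 2), mean)
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @keywords internal
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("truncated PGM")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (!length(c2) || c2 == "\n") break } }
      else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals / mx, h, w, byrow = TRUE)
}

#' Export a depth map
#'
#' Writes the finalized depth as a plain-text matrix and an 8-bit PNG
#' (NA pixels black), and optionally a Wavefront OBJ height-field mesh
#' for 3D viewing.
#'
#' @param dm a `depth_map` (or plain matrix).
#' @param stem output path stem; writes `<stem>.txt`, `<stem>.png` and
#'   (if `obj = TRUE`) `<stem>.obj`.
#' @param obj also write the OBJ mesh.
#' @param obj_scale height scale of the mesh in pixels.
#' @export
export_depth <- function(dm, stem, obj = FALSE, obj_scale = 60) {
  depth <- if (inherits(dm, "depth_map")) dm$depth else dm
  utils::write.table(depth, paste0(stem, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  z <- depth; z[is.na(z)] <- 0
  png::writePNG(pmin(pmax(z, 0), 1), paste0(stem, ".png"))
  if (obj) write_obj_heightfield(depth, paste0(stem, ".obj"), obj_scale)
  invisible(stem)
}

#' @keywords internal
write_obj_heightfield <- function(depth, path, scale = 60, step = 4L) {
  rows <- seq(1L, nrow(depth), by = step)
  cols <- seq(1L, ncol(depth), by = step)
  z <- depth[rows, cols]
  z[is.na(z)] <- 0
  nr <- length(rows); nc <- length(cols)
  vid <- matrix(seq_len(nr * nc), nr, nc)
  verts <- sprintf("v %d %d %.4f",
                   rep(cols, each = nr), rep(rows, nc), as.vector(z) * scale)
  faces <- character(0)
  if (nr > 1L && nc > 1L) {
    a <- vid[-nr, -nc]; b <- vid[-1, -nc]; cc <- vid[-1, -1]; d <- vid[-nr, -1]
    faces <- c(sprintf("f %d %d %d", a, b, cc),
               sprintf("f %d %d %d", a, cc, d))
  }
  writeLines(c("# height-field mesh", verts, faces), path)
  invisible(path)
}

#' Export a profile comparison as CSV
#'
#' @param model,truth numeric vectors (truth may be NULL).
#' @param path output CSV path.
#' @export
export_profile_csv <- function(model, path, truth = NULL) {
  df <- data.frame(index = seq_along(model), model = model)
  if (!is.null(truth)) df$truth <- truth
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
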