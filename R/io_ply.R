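# PLY point-cloud / mesh I/O.  Reads the ascii and binary_little_endian
# dialects; always writes binary_little_endian with double-precision
# coordinates so write -> read round trips are bitwise exact.

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(bytes, type, n) {
  switch(type,
    char = , int8 = readBin(bytes, "integer", n, 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(bytes, "integer", n, 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(bytes, "integer", n, 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n, 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", n, 4L, endian = "little"),
    float = , float32 = readBin(bytes, "double", n, 4L, endian = "little"),
    double = , float64 = readBin(bytes, "double", n, 8L, endian = "little"),
    stop("unsupported PLY property type: ", type, call. = FALSE)
  )
}

#' Read a PLY file
#'
#' Supports the ascii and binary_little_endian dialects, point clouds and
#' triangle meshes, with optional per-vertex normals and colors.
#'
#' @param path PLY file.
#' @return A list with `vertices` (N x 3), and `normals`, `colors`, `faces`
#'   when present (`faces` 1-based).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop("malformed PLY header: missing 'ply' magic", call. = FALSE)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(name,type,list_count_type))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed PLY header: no end_header", call. = FALSE)
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      k <- length(elements)
      if (k == 0) stop("malformed PLY header: property before element",
                       call. = FALSE)
      pr <- if (tok[2] == "list") {
        list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        list(name = tok[3], type = tok[2], list_count_type = NULL)
      }
      elements[[k]]$props <- c(elements[[k]]$props, list(pr))
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop("malformed PLY header: unexpected keyword '", tok[1], "'",
           call. = FALSE)
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  data <- list()
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    at <- 0L
    for (el in elements) {
      rows <- txt[at + seq_len(el$count)]
      at <- at + el$count
      has_list <- any(!vapply(el$props, function(p) is.null(p$list_count_type),
                              TRUE))
      if (!has_list) {
        vals <- matrix(as.numeric(unlist(strsplit(trimws(rows), "[ \t]+"))),
                       nrow = el$count, byrow = TRUE)
        cols <- lapply(seq_along(el$props), function(j) vals[, j])
        names(cols) <- vapply(el$props, `[[`, "", "name")
        data[[el$name]] <- cols
      } else {
        lst <- lapply(strsplit(trimws(rows), "[ \t]+"), function(tk) {
          cnt <- as.integer(tk[1])
          as.integer(tk[1 + seq_len(cnt)])
        })
        data[[el$name]] <- list(list_values = lst)
      }
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    pos <- 0L
    for (el in elements) {
      has_list <- any(!vapply(el$props, function(p) is.null(p$list_count_type),
                              TRUE))
      if (!has_list) {
        sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 0L)
        stride <- sum(sizes)
        offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
        base <- pos + (seq_len(el$count) - 1L) * stride
        cols <- lapply(seq_along(el$props), function(j) {
          sel <- as.vector(outer(seq_len(sizes[j]), base + offs[j], `+`))
          ply_read_bin(raw[sel], el$props[[j]]$type, el$count)
        })
        names(cols) <- vapply(el$props, `[[`, "", "name")
        data[[el$name]] <- cols
        pos <- pos + el$count * stride
      } else {
        if (length(el$props) != 1L)
          stop("unsupported PLY layout: list mixed with scalars",
               call. = FALSE)
        p <- el$props[[1]]
        csz <- ply_type_size[[p$list_count_type]]
        isz <- ply_type_size[[p$type]]
        stride <- csz + 3L * isz
        cnt_pos <- pos + (seq_len(el$count) - 1L) * stride + 1L
        uniform <- el$count > 0 && csz == 1L &&
          length(raw) >= pos + el$count * stride &&
          all(as.integer(raw[cnt_pos]) == 3L)
        if (uniform || el$count == 0L) {
          # fast path: pure triangle lists read in one vectorized pass
          sel <- as.vector(outer(seq_len(3L * isz),
                                 pos + (seq_len(el$count) - 1L) * stride + csz,
                                 `+`))
          idx <- ply_read_bin(raw[sel], p$type, 3L * el$count)
          lst <- if (el$count) asplit(matrix(as.integer(idx), ncol = 3L,
                                             byrow = TRUE), 1) else list()
          lst <- lapply(lst, as.integer)
          pos <- pos + el$count * stride
        } else {
          lst <- vector("list", el$count)
          i <- 1L
          while (i <= el$count) {
            cnt <- ply_read_bin(raw[pos + seq_len(csz)], p$list_count_type, 1L)
            idx <- ply_read_bin(raw[pos + csz + seq_len(cnt * isz)], p$type, cnt)
            lst[[i]] <- as.integer(idx)
            pos <- pos + csz + cnt * isz
            i <- i + 1L
          }
        }
        data[[el$name]] <- list(list_values = lst)
      }
    }
  }

  out <- list()
  v <- data[["vertex"]]
  if (!is.null(v)) {
    out$vertices <- cbind(v$x, v$y, v$z)
    if (all(c("nx", "ny", "nz") %in% names(v)))
      out$normals <- cbind(v$nx, v$ny, v$nz)
    if (all(c("red", "green", "blue") %in% names(v)))
      out$colors <- cbind(v$red, v$green, v$blue)
    if ("label" %in% names(v)) out$labels <- v$label
  }
  f <- data[["face"]]
  if (!is.null(f)) {
    lv <- f$list_values
    if (length(lv) && any(vapply(lv, length, 0L) != 3L))
      stop("only triangle meshes are supported", call. = FALSE)
    out$faces <- if (length(lv)) do.call(rbind, lv) + 1L
                 else matrix(integer(), 0, 3)
  }
  out
}

#' Write a PLY file
#'
#' Writes a point cloud or triangle mesh.  The binary dialect (default)
#' stores coordinates and normals as doubles, making write/read round trips
#' bitwise exact; colors are stored as uchar, labels as int.
#'
#' @param path output file.
#' @param vertices N x 3 matrix.
#' @param faces optional F x 3 matrix of 1-based indices.
#' @param normals optional N x 3 matrix.
#' @param colors optional N x 3 integer matrix (0-255).
#' @param labels optional integer vector (written as a `label` property).
#' @param format `"binary"` (binary_little_endian) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(path, vertices, faces = NULL, normals = NULL,
                      colors = NULL, labels = NULL,
                      format = c("binary", "ascii")) {
  format <- match.arg(format)
  vertices <- as_points3(vertices, "vertices")
  n <- nrow(vertices)
  props <- c("property double x", "property double y", "property double z")
  if (!is.null(normals))
    props <- c(props, "property double nx", "property double ny",
               "property double nz")
  if (!is.null(colors))
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
  if (!is.null(labels)) props <- c(props, "property int label")
  header <- c(
    "ply",
    paste("format", if (format == "binary") "binary_little_endian" else "ascii",
          "1.0"),
    paste("element vertex", n), props,
    if (!is.null(faces)) c(paste("element face", nrow(faces)),
                           "property list uchar int vertex_indices"),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "binary") {
    blocks <- list(matrix(writeBin(as.vector(t(vertices)), raw(), size = 8,
                                   endian = "little"), nrow = 24L))
    if (!is.null(normals))
      blocks <- c(blocks, list(matrix(writeBin(as.vector(t(normals)), raw(),
                                               size = 8, endian = "little"),
                                      nrow = 24L)))
    if (!is.null(colors))
      blocks <- c(blocks, list(matrix(as.raw(t(colors)), nrow = 3L)))
    if (!is.null(labels))
      blocks <- c(blocks, list(matrix(writeBin(as.integer(labels), raw(),
                                               size = 4, endian = "little"),
                                      nrow = 4L)))
    if (n > 0) writeBin(as.vector(do.call(rbind, blocks)), con)
    if (!is.null(faces) && nrow(faces) > 0) {
      im <- matrix(writeBin(as.integer(t(faces) - 1L), raw(), size = 4,
                            endian = "little"), nrow = 12L)
      writeBin(as.vector(rbind(matrix(as.raw(3L), 1L, ncol(im)), im)), con)
    }
  } else {
    rows <- fmt_num(vertices[, 1])
    rows <- paste(fmt_num(vertices[, 1]), fmt_num(vertices[, 2]),
                  fmt_num(vertices[, 3]))
    if (!is.null(normals))
      rows <- paste(rows, fmt_num(normals[, 1]), fmt_num(normals[, 2]),
                    fmt_num(normals[, 3]))
    if (!is.null(colors))
      rows <- paste(rows, colors[, 1], colors[, 2], colors[, 3])
    if (!is.null(labels)) rows <- paste(rows, as.integer(labels))
    writeLines(rows, con)
    if (!is.null(faces))
      writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
                 con)
  }
  invisible(path)
}

#' @rdname read_ply
#' @return `read_ply_mesh`: a [triangle_mesh()].
#' @export
read_ply_mesh <- function(path) {
  d <- read_ply(path)
  if (is.null(d$faces)) stop("PLY file has no faces: ", path, call. = FALSE)
  triangle_mesh(d$vertices, d$faces, normals = d$normals, colors = d$colors)
}

#' @rdname write_ply
#' @param mesh a [triangle_mesh()].
#' @export
write_ply_mesh <- function(path, mesh, format = c("binary", "ascii")) {
  write_ply(path, mesh$vertices, faces = mesh$faces, normals = mesh$normals,
            colors = mesh$colors, format = match.arg(format))
}
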