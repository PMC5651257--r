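#' @include AllClasses.R accessors.R
NULL

## Mesh I/O for the two lossless triangle-mesh formats the package uses on
## disk: OFF (ASCII) and PLY (ASCII or binary little-endian). Vertex order
## is preserved exactly: momentum fields are vertex-indexed, so order is
## semantic. Face indices are 0-based both on disk (native to OFF/PLY) and
## in memory.

.detectFormat <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("off", "ply")) return(toupper(ext))
    stop(sprintf("cannot infer mesh format from extension of '%s'", path))
}

.tokensNoComments <- function(lines) {
    lines <- sub("#.*$", "", lines)
    toks <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
    toks[nzchar(toks)]
}

.readOFF <- function(path) {
    lines <- readLines(path, warn = FALSE)
    toks <- .tokensNoComments(lines)
    if (length(toks) == 0L || toupper(toks[1L]) != "OFF")
        stop(sprintf("'%s': not an OFF file (missing OFF keyword)", path))
    toks <- toks[-1L]
    if (length(toks) < 3L)
        stop(sprintf("'%s': truncated OFF header", path))
    nv <- as.integer(toks[1L]); nf <- as.integer(toks[2L])
    toks <- toks[-(1:3)]
    if (is.na(nv) || is.na(nf) || nv < 1L)
        stop(sprintf("'%s': empty or malformed OFF mesh (counts '%s %s')",
                     path, nv, nf))
    if (length(toks) < 3L * nv)
        stop(sprintf("'%s': expected %d vertex coordinates, found %d",
                     path, 3L * nv, length(toks)))
    V <- matrix(as.numeric(toks[seq_len(3L * nv)]), nv, 3L, byrow = TRUE)
    if (any(!is.finite(V)))
        stop(sprintf("'%s': non-numeric vertex coordinate near record %d",
                     path, which(!is.finite(rowSums(V)))[1L]))
    toks <- toks[-seq_len(3L * nv)]
    F <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
        if (length(toks) < 1L)
            stop(sprintf("'%s': truncated at face record %d", path, i))
        cnt <- as.integer(toks[1L])
        if (is.na(cnt) || cnt != 3L)
            stop(sprintf("'%s': face record %d is not a triangle (count %s)",
                         path, i, toks[1L]))
        idx <- as.integer(toks[2:4])
        if (any(is.na(idx)) || any(idx < 0L) || any(idx >= nv))
            stop(sprintf("'%s': face index out of range at face record %d",
                         path, i))
        F[i, ] <- idx
        toks <- toks[-(1:4)]
    }
    triSurface(V, F)
}

.writeOFF <- function(surface, path) {
    V <- surface@vertices; F <- surface@faces
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(V), nrow(F)), con)
    writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
    if (nrow(F) > 0L)
        writeLines(sprintf("3 %d %d %d", F[, 1], F[, 2], F[, 3]), con)
    invisible(NULL)
}

.parsePLYHeader <- function(con) {
    hdr <- character(0)
    repeat {
        ln <- readLines(con, n = 1L)
        if (length(ln) == 0L) stop("PLY: end of file inside header")
        hdr <- c(hdr, ln)
        if (trimws(ln) == "end_header") break
    }
    if (trimws(hdr[1L]) != "ply") stop("not a PLY file (missing 'ply' magic)")
    fmt <- grep("^format ", trimws(hdr), value = TRUE)
    if (length(fmt) != 1L) stop("PLY: missing format line")
    fmt <- strsplit(trimws(fmt), "[[:space:]]+")[[1L]][2L]
    if (!fmt %in% c("ascii", "binary_little_endian"))
        stop(sprintf("PLY: unsupported format '%s'", fmt))
    elements <- list(); cur <- NULL
    for (ln in trimws(hdr)) {
        t <- strsplit(ln, "[[:space:]]+")[[1L]]
        if (t[1L] == "element") {
            cur <- t[2L]
            elements[[cur]] <- list(count = as.integer(t[3L]),
                                    props = list())
        } else if (t[1L] == "property" && !is.null(cur)) {
            p <- if (t[2L] == "list")
                list(kind = "list", countType = t[3L], itemType = t[4L],
                     name = t[5L])
            else list(kind = "scalar", type = t[2L], name = t[3L])
            elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
        }
    }
    list(format = fmt, elements = elements)
}

.plyTypeInfo <- function(type) {
    switch(type,
        char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
        uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
        short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
        ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
        int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
        uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
        float = , float32 = list(what = "double", size = 4L, signed = TRUE),
        double = , float64 = list(what = "double", size = 8L, signed = TRUE),
        stop(sprintf("PLY: unsupported property type '%s'", type)))
}

.readPLY <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- .parsePLYHeader(con)
    ve <- hdr$elements[["vertex"]]
    fe <- hdr$elements[["face"]]
    if (is.null(ve) || ve$count < 1L)
        stop(sprintf("'%s': PLY file has no vertices", path))
    vnames <- vapply(ve$props, `[[`, "", "name")
    if (!all(c("x", "y", "z") %in% vnames))
        stop(sprintf("'%s': PLY vertex element lacks x/y/z", path))
    nf <- if (is.null(fe)) 0L else fe$count

    if (hdr$format == "ascii") {
        toks <- .tokensNoComments(readLines(con, warn = FALSE))
        npv <- length(ve$props)
        need <- ve$count * npv
        if (length(toks) < need)
            stop(sprintf("'%s': truncated PLY vertex data", path))
        vm <- matrix(as.numeric(toks[seq_len(need)]), ve$count, npv,
                     byrow = TRUE)
        toks <- toks[-seq_len(need)]
        V <- vm[, match(c("x", "y", "z"), vnames), drop = FALSE]
        F <- matrix(0L, nf, 3L)
        for (i in seq_len(nf)) {
            cnt <- as.integer(toks[1L])
            if (is.na(cnt) || cnt != 3L)
                stop(sprintf("'%s': PLY face %d is not a triangle", path, i))
            F[i, ] <- as.integer(toks[2:4])
            toks <- toks[-(1:4)]
        }
    } else {
        V <- matrix(0, ve$count, 3L)
        types <- lapply(ve$props, function(p) {
            if (p$kind != "scalar")
                stop("PLY: list property on vertex element is unsupported")
            .plyTypeInfo(p$type)
        })
        buf <- matrix(0, ve$count, length(ve$props))
        for (i in seq_len(ve$count)) {
            for (j in seq_along(types)) {
                ti <- types[[j]]
                buf[i, j] <- readBin(con, ti$what, n = 1L, size = ti$size,
                                     signed = ti$signed, endian = "little")
            }
        }
        V <- buf[, match(c("x", "y", "z"), vnames), drop = FALSE]
        F <- matrix(0L, nf, 3L)
        if (nf > 0L) {
            lp <- fe$props[[1L]]
            if (lp$kind != "list")
                stop("PLY: face element must start with a list property")
            ct <- .plyTypeInfo(lp$countType); it <- .plyTypeInfo(lp$itemType)
            for (i in seq_len(nf)) {
                cnt <- readBin(con, ct$what, n = 1L, size = ct$size,
                               signed = ct$signed, endian = "little")
                if (cnt != 3L)
                    stop(sprintf("'%s': PLY face %d is not a triangle",
                                 path, i))
                F[i, ] <- readBin(con, it$what, n = 3L, size = it$size,
                                  signed = it$signed, endian = "little")
            }
        }
    }
    if (nf > 0L && (min(F) < 0L || max(F) >= nrow(V)))
        stop(sprintf("'%s': face index out of range", path))
    triSurface(V, F)
}

.writePLY <- function(surface, path, binary = TRUE) {
    V <- surface@vertices; F <- surface@faces
    fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
    hdr <- c("ply", paste("format", fmt),
             sprintf("element vertex %d", nrow(V)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(F)),
             "property list uchar int vertex_indices",
             "end_header")
    if (binary) {
        con <- file(path, "wb")
        on.exit(close(con))
        writeLines(hdr, con, sep = "\n")
        writeBin(as.vector(t(V)), con, size = 8L, endian = "little")
        for (i in seq_len(nrow(F))) {
            writeBin(as.raw(3L), con)
            writeBin(as.integer(F[i, ]), con, size = 4L, endian = "little")
        }
    } else {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(hdr, con)
        writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
        if (nrow(F) > 0L)
            writeLines(sprintf("3 %d %d %d", F[, 1], F[, 2], F[, 3]), con)
    }
    invisible(NULL)
}

#' Read a triangulated surface from OFF or PLY
#'
#' Supports ASCII OFF and ASCII / binary little-endian PLY. The vertex
#' order of the file is preserved exactly and face indices are kept
#' 0-based, matching the on-disk convention of both formats.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"OFF"` or `"PLY"`.
#' @return a [TriSurface-class].
#' @seealso [writeSurface()]
#' @export
readSurface <- function(path, format = c("auto", "OFF", "PLY")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    if (format == "auto") format <- .detectFormat(path)
    surf <- switch(format, OFF = .readOFF(path), PLY = .readPLY(path))
    if (nrow(surf@vertices) < 3L || nrow(surf@faces) < 1L)
        stop(sprintf("'%s': empty mesh (%d vertices, %d faces)", path,
                     nrow(surf@vertices), nrow(surf@faces)))
    surf
}

#' Write a triangulated surface to OFF or PLY
#'
#' Binary PLY stores coordinates as IEEE doubles (bit-exact roundtrip);
#' ASCII formats print 17 significant digits, which also roundtrips
#' doubles exactly.
#'
#' @param surface a [TriSurface-class].
#' @param path output file path.
#' @param format `"auto"` (from extension), `"OFF"`, `"PLY"` (binary
#'   little-endian) or `"PLY_ASCII"`.
#' @return invisibly, NULL.
#' @seealso [readSurface()]
#' @export
writeSurface <- function(surface, path,
                         format = c("auto", "OFF", "PLY", "PLY_ASCII")) {
    format <- match.arg(format)
    stopifnot(is(surface, "TriSurface"))
    validObject(surface)
    if (nrow(surface@vertices) < 3L || nrow(surface@faces) < 1L)
        stop("refusing to write an empty mesh")
    if (format == "auto") format <- .detectFormat(path)
    switch(format,
        OFF = .writeOFF(surface, path),
        PLY = .writePLY(surface, path, binary = TRUE),
        PLY_ASCII = .writePLY(surface, path, binary = FALSE))
    invisible(NULL)
}

#' Read a momentum field from CSV or flat binary
#'
#' CSV files carry columns `vertex_index, px, py, pz` (0-based indices,
#' rows in vertex order). Flat binary files (`.bin`) are float64
#' little-endian triples with a JSON sidecar `<path>.json` recording
#' `vertex_count` and `dtype`; the binary roundtrip is bit-exact.
#'
#' @param path file path (`.csv` or `.bin`).
#' @param vertexCount optional expected vertex count; a mismatch with the
#'   file contents (or the sidecar's declared count) is an error, since
#'   momenta are only meaningful relative to a specific template.
#' @return a [MomentumField-class].
#' @seealso [writeMomenta()]
#' @export
readMomenta <- function(path, vertexCount = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") {
        df <- utils::read.csv(path)
        need <- c("vertex_index", "px", "py", "pz")
        if (!all(need %in% names(df)))
            stop(sprintf("'%s': momentum CSV must have columns %s", path,
                         paste(need, collapse = ", ")))
        df <- df[order(df$vertex_index), , drop = FALSE]
        vals <- as.matrix(df[, c("px", "py", "pz")])
        dimnames(vals) <- NULL
    } else if (ext == "bin") {
        sidecar <- paste0(path, ".json")
        if (!file.exists(sidecar))
            stop(sprintf("missing JSON sidecar '%s'", sidecar))
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        n <- as.integer(meta$vertex_count)
        if (!identical(meta$dtype, "float64"))
            stop(sprintf("'%s': unsupported dtype '%s'", path, meta$dtype))
        raw <- readBin(path, "double", n = 3L * n + 1L, size = 8L,
                       endian = "little")
        if (length(raw) != 3L * n)
            stop(sprintf("'%s': %d values on disk but sidecar declares vertex_count = %d",
                         path, length(raw), n))
        vals <- matrix(raw, n, 3L, byrow = TRUE)
    } else {
        stop(sprintf("unsupported momentum format '.%s'", ext))
    }
    if (!is.null(vertexCount) && nrow(vals) != vertexCount)
        stop(sprintf("'%s' has %d rows but vertex_count = %d was declared",
                     path, nrow(vals), vertexCount))
    momentumField(vals)
}

#' Write a momentum field to CSV or flat binary
#'
#' @param field a [MomentumField-class].
#' @param path output path; `.csv` selects CSV, `.bin` selects float64
#'   little-endian binary with a `<path>.json` sidecar.
#' @return invisibly, NULL.
#' @seealso [readMomenta()]
#' @export
writeMomenta <- function(field, path) {
    stopifnot(is(field, "MomentumField"))
    validObject(field)
    vals <- field@values
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") {
        df <- data.frame(vertex_index = seq_len(nrow(vals)) - 1L,
                         px = vals[, 1], py = vals[, 2], pz = vals[, 3])
        utils::write.csv(df, path, row.names = FALSE)
    } else if (ext == "bin") {
        con <- file(path, "wb")
        writeBin(as.vector(t(vals)), con, size = 8L, endian = "little")
        close(con)
        jsonlite::write_json(list(vertex_count = nrow(vals),
                                  dtype = "float64"),
                             paste0(path, ".json"), auto_unbox = TRUE)
    } else {
        stop(sprintf("unsupported momentum format '.%s'", ext))
    }
    invisible(NULL)
}
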