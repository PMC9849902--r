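#' Construct a ShapeSet
#'
#' @param coords numeric array n x p x 2, or a list of p x 2 matrices.
#' @param info data.frame of per-sample metadata; missing columns among
#'   `individual_id`, `sex`, `age`, `origin`, `observer_id`, `beard`,
#'   `head_deviation` are filled with defaults (ids `s1..sn`, NA sex/age,
#'   origin "unknown", observer "obs1", flags FALSE).
#' @param scheme a [LandmarkScheme-class]; defaults to a scheme with no
#'   semi-landmark curves matching the point count.
#' @return a [ShapeSet-class].
#' @examples
#' tri <- list(rbind(c(0, 0), c(1, 0), c(0, 2)))
#' ShapeSet(tri)
#' @export
ShapeSet <- function(coords, info = NULL, scheme = NULL) {
  if (is.list(coords)) {
    p <- nrow(coords[[1]])
    arr <- array(NA_real_, c(length(coords), p, 2))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  n <- dim(coords)[1]
  if (is.null(scheme))
    scheme <- LandmarkScheme(dim(coords)[2], seq_len(dim(coords)[2]))
  if (is.null(info)) info <- data.frame(row.names = seq_len(max(n, 0)))
  defaults <- list(individual_id = paste0("s", seq_len(n)),
                   sex = NA_character_, age = NA_real_,
                   origin = "unknown", observer_id = "obs1",
                   beard = FALSE, head_deviation = FALSE)
  for (col in names(defaults))
    if (is.null(info[[col]])) info[[col]] <- rep_len(defaults[[col]], n)
  rownames(info) <- NULL
  new("ShapeSet", coords = coords, info = info, scheme = scheme)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by common digitizing tools: records of
#' `LM=<k>` followed by k whitespace-separated coordinate pairs, with
#' optional `IMAGE=`, `ID=` and `SCALE=` lines per record. Coordinates are
#' multiplied by `SCALE` when present. TPS digitizers store image
#' coordinates with a down-positive y-axis; on read the y-axis is flipped
#' to the mathematical up-positive convention (recorded in the returned
#' object's metadata as attribute `yFlipped`) so that downstream grids and
#' morphs render faces upright. Record order is preserved.
#'
#' @param path TPS file path.
#' @param scheme optional [LandmarkScheme-class]; when given, a record
#'   whose point count differs from `scheme@nTotal` is an error.
#' @param flipY flip the y-axis to up-positive (default TRUE).
#' @return a [ShapeSet-class]; `info$individual_id` from `ID=` lines.
#' @export
readTPS <- function(path, scheme = NULL, flipY = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0 && length(lines) > 0)
    stop("not a TPS file: no LM= records in ", path)
  shapes <- list(); ids <- character(0); scales <- numeric(0)
  images <- character(0)
  ends <- c(starts[-1] - 1, length(lines))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1],
                                         ignore.case = TRUE)))
    if (is.na(k)) stop("malformed LM= count in record ", r)
    iscoord <- grepl("^[-+0-9.eE]+\\s+[-+0-9.eE]+\\s*$", block)
    iscoord[1] <- FALSE
    coordlines <- block[iscoord]
    if (length(coordlines) != k)
      stop("record ", r, ": LM=", k, " but ", length(coordlines),
           " coordinate lines found")
    xy <- do.call(rbind, lapply(strsplit(coordlines, "\\s+"), function(v)
      as.numeric(v[1:2])))
    if (any(!is.finite(xy))) stop("record ", r, ": non-finite coordinates")
    if (!is.null(scheme) && k != scheme@nTotal)
      stop("record ", r, ": ", k, " points do not match scheme nTotal = ",
           scheme@nTotal)
    keyval <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), block, ignore.case = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", block[hit[1]],
                           ignore.case = TRUE) else NA_character_
    }
    sc <- suppressWarnings(as.numeric(keyval("SCALE")))
    if (!is.na(sc)) xy <- xy * sc
    if (flipY) xy[, 2] <- -xy[, 2]
    shapes[[r]] <- xy
    id <- keyval("ID")
    ids[r] <- if (is.na(id)) paste0("s", r) else id
    images[r] <- keyval("IMAGE")
    scales[r] <- if (is.na(sc)) NA_real_ else sc
  }
  ss <- ShapeSet(shapes,
                 info = data.frame(individual_id = ids, stringsAsFactors = FALSE),
                 scheme = scheme)
  ss@info$image <- images
  ss@info$scale <- scales
  attr(ss@info, "yFlipped") <- flipY
  ss
}

#' Write a ShapeSet to a TPS file
#'
#' Emits the dialect parsed by [readTPS()]; the y-axis flip applied on read
#' is inverted on write so that read-write round trips are lossless. No
#' `SCALE=` line is written (coordinates are already in common units).
#'
#' @param shapes a [ShapeSet-class].
#' @param path output file path.
#' @param flipY undo the up-positive y convention on write (default TRUE).
#' @param digits coordinate precision (default 12 significant digits).
#' @return `path`, invisibly.
#' @export
writeTPS <- function(shapes, path, flipY = TRUE, digits = 12) {
  stopifnot(is(shapes, "ShapeSet"))
  co <- shapeCoords(shapes)
  n <- dim(co)[1]
  out <- character(0)
  for (i in seq_len(n)) {
    xy <- co[i, , , drop = TRUE]
    if (dim(co)[2] == 1) xy <- matrix(xy, 1, 2)
    if (flipY) xy[, 2] <- -xy[, 2]
    out <- c(out, paste0("LM=", nrow(xy)),
             paste(formatC(xy[, 1], format = "g", digits = digits),
                   formatC(xy[, 2], format = "g", digits = digits)),
             paste0("ID=", shapes@info$individual_id[i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write landmark tables (CSV alternative to TPS)
#'
#' Long-format tables with columns `individual_id`, `point_index`, `x`,
#' `y`; coordinates are stored in the package's up-positive convention.
#'
#' @param path CSV path.
#' @param scheme optional [LandmarkScheme-class].
#' @return a [ShapeSet-class] (reader); the writer returns `path`.
#' @export
readLandmarkTable <- function(path, scheme = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(tab$individual_id)
  shapes <- lapply(ids, function(id) {
    sub <- tab[tab$individual_id == id, ]
    as.matrix(sub[order(sub$point_index), c("x", "y")])
  })
  ShapeSet(shapes, info = data.frame(individual_id = as.character(ids)),
           scheme = scheme)
}

#' @rdname readLandmarkTable
#' @param shapes a [ShapeSet-class].
#' @export
writeLandmarkTable <- function(shapes, path) {
  co <- shapeCoords(shapes)
  n <- dim(co)[1]; p <- dim(co)[2]
  tab <- data.frame(
    individual_id = rep(shapes@info$individual_id, each = p),
    point_index = rep(seq_len(p), n),
    x = as.vector(t(co[, , 1])), y = as.vector(t(co[, , 2])))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Apply the morphometric sample-exclusion rules
#'
#' Retains samples without a beard, without considerable head-position
#' deviation, and whose origin belongs to the allowed set, reporting how
#' many samples each rule removed. Rules are applied in the order beard,
#' head deviation, origin; a sample failing several rules is counted under
#' the first. Idempotent and order-preserving.
#'
#' @param shapes a [ShapeSet-class] with populated flags and origin.
#' @param allowedOrigins character vector of admissible origins; `NULL`
#'   disables the origin rule.
#' @return list with elements `shapes` (the retained [ShapeSet-class]) and
#'   `removed` (named integer vector: beard, head_deviation, origin).
#' @examples
#' ss <- ShapeSet(replicate(5, matrix(rnorm(6), 3, 2), simplify = FALSE))
#' ss@info$beard[2] <- TRUE
#' applyMorphometricExclusions(ss)$removed
#' @export
applyMorphometricExclusions <- function(shapes, allowedOrigins = NULL) {
  info <- sampleInfo(shapes)
  beard <- isTRUE_v(info$beard)
  headdev <- !beard & isTRUE_v(info$head_deviation)
  origin <- if (is.null(allowedOrigins)) rep(FALSE, nrow(info))
            else !beard & !headdev & !(info$origin %in% allowedOrigins)
  keep <- !(beard | headdev | origin)
  list(shapes = shapes[which(keep)],
       removed = c(beard = sum(beard), head_deviation = sum(headdev),
                   origin = sum(origin)))
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)
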