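## Frames: one time point of a trajectory. Coordinates are always stored in
## nm (the GRO/Martini convention); boxes are orthorhombic.

#' Construct a trajectory frame
#'
#' @param coordinates N x 3 numeric matrix of bead positions in nm.
#' @param box Length-3 positive box vector (nm), orthorhombic.
#' @param time Time stamp in ps.
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(coordinates, box, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L || !is.numeric(coordinates))
    stop_validation("coordinates must be an N x 3 numeric matrix")
  if (!all(is.finite(coordinates)))
    stop_validation("coordinates must all be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop_validation("box must be 3 strictly positive lengths (nm)")
  structure(list(coordinates = unname(coordinates), box = box,
                 time = as.numeric(time)),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("cg_frame: %d beads, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$coordinates), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Minimum-image displacement under periodic boundaries
#'
#' Returns the displacement `a - b` wrapped into the primary image of an
#' orthorhombic box, so each component lies in `[-box/2, box/2]` and its
#' norm is the minimum distance over all periodic images.
#'
#' @param a,b Points (length-3 vectors) or N x 3 matrices, in nm.
#' @param box Length-3 positive box vector (nm).
#' @return Displacement vector(s), same shape as the broadcast of `a - b`.
#' @export
minimum_image_displacement <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_validation("box must be 3 strictly positive lengths")
  d <- if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, nrow = max(1, NROW(b)), ncol = 3,
                                         byrow = TRUE)
    b <- if (is.matrix(b)) b else matrix(b, nrow = nrow(a), ncol = 3,
                                         byrow = TRUE)
    a - b
  } else {
    a - b
  }
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
    d - sweep_box * round(d / sweep_box)
  } else {
    d - box * round(d / box)
  }
}

## squared minimum-image distances from one point to rows of a matrix
min_image_dist2 <- function(point, coords, box) {
  d <- minimum_image_displacement(coords,
                                  matrix(point, nrow(coords), 3, byrow = TRUE),
                                  box)
  rowSums(d * d)
}

#' Read a multi-frame coordinate file
#'
#' @param path File path.
#' @param dialect `"gro_multiframe"` (concatenated GRO frames, native nm) or
#'   `"xyz_multiframe"` (XYZ with coordinates taken as nm; a `time=` token
#'   in the comment line is honoured).
#' @return List of [cg_frame()] objects in time order. Non-monotone time
#'   stamps raise a warning but frames are kept in file order.
#' @export
read_frames <- function(path, dialect = c("gro_multiframe", "xyz_multiframe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop_parse("empty trajectory file: ", path)
  frames <- if (dialect == "gro_multiframe") parse_gro_frames(lines, path)
            else parse_xyz_frames(lines, path)
  n <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(n)) != 1L)
    stop_parse("inconsistent bead count across frames in ", path)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times, strictly = FALSE))
    warning("non-monotone time stamps in ", path, "; frames kept in file order")
  frames
}

parse_gro_frames <- function(lines, path) {
  frames <- list()
  i <- 1L
  nlines <- length(lines)
  while (i <= nlines) {
    if (i + 1L > nlines) stop_parse("truncated GRO frame header at line ", i,
                                    " of ", path)
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L)
      stop_parse("bad atom count at line ", i + 1L, " of ", path)
    if (i + 1L + natoms + 1L > nlines)
      stop_parse("truncated GRO frame starting at line ", i, " of ", path)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    x <- suppressWarnings(as.numeric(substr(at, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(at, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(at, 37L, 44L)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
      stop_parse("malformed GRO atom line ", i + 1L + bad, " of ", path)
    }
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1L]]
    box <- suppressWarnings(as.numeric(boxline))
    if (anyNA(box) || length(box) < 3L)
      stop_parse("malformed box line ", i + 2L + natoms, " of ", path)
    if (length(box) > 3L && any(abs(box[4:length(box)]) > 1e-9))
      stop_validation("triclinic boxes are not supported (line ",
                      i + 2L + natoms, " of ", path, ")")
    time <- 0
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
    frames[[length(frames) + 1L]] <-
      cg_frame(cbind(x, y, z), box[1:3], time)
    i <- i + natoms + 3L
  }
  frames
}

parse_xyz_frames <- function(lines, path) {
  frames <- list()
  i <- 1L
  nlines <- length(lines)
  while (i <= nlines) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || natoms < 1L)
      stop_parse("bad atom count at line ", i, " of ", path)
    if (i + 1L + natoms > nlines)
      stop_parse("truncated XYZ frame starting at line ", i, " of ", path)
    comment <- lines[i + 1L]
    at <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    bad <- which(vapply(at, length, integer(1)) < 4L)
    if (length(bad))
      stop_parse("malformed XYZ atom line ", i + 1L + bad[1L], " of ", path)
    coords <- t(vapply(at, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(coords))
      stop_parse("non-numeric coordinate in XYZ frame starting at line ", i,
                 " of ", path)
    time <- 0
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    if (length(tm)) time <- as.numeric(sub("time=\\s*", "", tm))
    box <- c(0, 0, 0)
    bm <- regmatches(comment,
                     regexpr("box=\\s*[-0-9.eE+]+,[-0-9.eE+]+,[-0-9.eE+]+",
                             comment))
    if (length(bm))
      box <- as.numeric(strsplit(sub("box=\\s*", "", bm), ",")[[1L]])
    if (all(box == 0))
      stop_parse("XYZ frame starting at line ", i, " of ", path,
                 " lacks a box= token in its comment line")
    frames[[length(frames) + 1L]] <- cg_frame(coords, box, time)
    i <- i + natoms + 2L
  }
  frames
}

#' Write frames to a multi-frame coordinate file
#'
#' @param frames List of `cg_frame` objects.
#' @param topology A `cg_topology` supplying residue/bead names (GRO only;
#'   may be `NULL` for the XYZ dialect).
#' @param path Output path.
#' @param dialect Output format, as in [read_frames()].
#' @return `path`, invisibly. GRO coordinates are written at the format's
#'   native 3-decimal (0.001 nm) precision.
#' @export
write_frames <- function(frames, topology = NULL, path,
                         dialect = c("gro_multiframe", "xyz_multiframe")) {
  dialect <- match.arg(dialect)
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gro_multiframe") {
    if (is.null(topology))
      stop_validation("GRO output requires a topology for atom names")
    n <- n_beads(topology)
    resid <- topology$residue_index %% 100000L
    atid <- (topology$bead_id + 1L) %% 100000L
    prefix <- sprintf("%5d%-5s%5s%5d", resid,
                      substr(topology$residue_name, 1L, 5L),
                      substr(topology$bead_name, 1L, 5L), atid)
    for (f in frames) {
      if (nrow(f$coordinates) != n)
        stop_validation("frame bead count does not match topology")
      writeLines(sprintf("synthetic CG frame t= %.3f", f$time), con)
      writeLines(sprintf("%5d", n), con)
      writeLines(paste0(prefix,
                        sprintf("%8.3f%8.3f%8.3f", f$coordinates[, 1],
                                f$coordinates[, 2], f$coordinates[, 3])), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]),
                 con)
    }
  } else {
    names_v <- if (!is.null(topology)) substr(topology$bead_name, 1L, 4L)
    for (f in frames) {
      n <- nrow(f$coordinates)
      nm <- if (is.null(names_v)) rep("X", n) else names_v
      writeLines(sprintf("%d", n), con)
      writeLines(sprintf("time= %.3f box= %.5f,%.5f,%.5f", f$time,
                         f$box[1], f$box[2], f$box[3]), con)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", nm, f$coordinates[, 1],
                         f$coordinates[, 2], f$coordinates[, 3]), con)
    }
  }
  invisible(path)
}
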