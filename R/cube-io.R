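#' @include AllGenerics.R
NULL

#' Construct a ScalarField
#'
#' @param values Numeric 3-d array of voxel values (first axis slowest in
#'   cube-file order), or a vector together with \code{counts}, given in
#'   cube-file order (last axis fastest-varying).
#' @param origin Grid origin, length-3, bohr.
#' @param axes 3 x 3 matrix of voxel step vectors (rows), bohr; defaults to a
#'   unit cubic grid.
#' @param atoms \code{data.frame(number, charge, x, y, z)}; defaults to one
#'   dummy atom at the origin so emitted cube files stay standard.
#' @param counts Integer length-3 grid extents, required when \code{values}
#'   is a plain vector.
#' @return A validated [ScalarField-class].
#' @export
scalarField <- function(values, origin = c(0, 0, 0), axes = diag(3),
                        atoms = NULL, counts = NULL) {
  if (is.null(dim(values))) {
    if (is.null(counts))
      stop("counts are required when values is not an array")
    counts <- as.integer(counts)
    if (length(values) != prod(counts))
      stop("length(values) must equal prod(counts)")
    # file order is last-axis-fastest; R arrays are first-index-fastest
    values <- aperm(array(values, dim = rev(counts)), c(3L, 2L, 1L))
  }
  if (is.null(atoms))
    atoms <- data.frame(number = 1L, charge = 1, x = 0, y = 0, z = 0)
  new("ScalarField", origin = as.numeric(origin),
      axes = matrix(as.numeric(axes), 3, 3), atoms = atoms,
      values = values)
}

#' @describeIn scalarField Grid extents along the three axes.
#' @param x A \code{ScalarField}.
#' @export
setMethod("gridCounts", "ScalarField", function(x) dim(x@values))
#' @describeIn scalarField Grid origin (bohr).
#' @export
setMethod("gridOrigin", "ScalarField", function(x) x@origin)
#' @describeIn scalarField 3 x 3 matrix of voxel step vectors (bohr).
#' @export
setMethod("gridAxes", "ScalarField", function(x) x@axes)
#' @describeIn scalarField Atom table.
#' @export
setMethod("gridAtoms", "ScalarField", function(x) x@atoms)
#' @describeIn scalarField 3-d array of voxel values.
#' @export
setMethod("fieldValues", "ScalarField", function(x) x@values)
#' @describeIn scalarField Voxel volume, the determinant of the axes matrix
#'   (bohr^3).
#' @export
setMethod("voxelVolume", "ScalarField", function(x) det(x@axes))

#' @export
setMethod("show", "ScalarField", function(object) {
  d <- dim(object@values)
  cat("ScalarField ", d[1], " x ", d[2], " x ", d[3],
      " (", prod(d), " voxels, ", nrow(object@atoms), " atom(s))\n", sep = "")
  cat("  origin (bohr):", format(object@origin, digits = 6), "\n")
  cat("  voxel volume (bohr^3):", format(det(object@axes), digits = 6), "\n")
  cat("  value range:", format(range(object@values), digits = 6), "\n")
  invisible(NULL)
})

## Element-wise arithmetic between geometry-identical fields, and between a
## field and a plain number; the header is preserved bit-for-bit.
#' @export
setMethod("Arith", signature("ScalarField", "ScalarField"), function(e1, e2) {
  bad <- .geometryMismatch(e1, e2)
  if (length(bad))
    stop("geometry mismatch between fields: ", paste(bad, collapse = ", "))
  out <- e1
  out@values <- callGeneric(e1@values, e2@values)
  out
})

#' @export
setMethod("Arith", signature("ScalarField", "numeric"), function(e1, e2) {
  out <- e1
  out@values <- callGeneric(e1@values, e2)
  out
})

#' @export
setMethod("Arith", signature("numeric", "ScalarField"), function(e1, e2) {
  out <- e2
  out@values <- callGeneric(e1, e2@values)
  out
})

## ---------------------------------------------------------------------------
## Gaussian cube format
## ---------------------------------------------------------------------------

.cubeTokens <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop("parse error at line ", lineno, ": non-numeric token '",
         toks[which(is.na(vals))[1]], "'")
  vals
}

#' Read a Gaussian cube file
#'
#' Parses the standard cube layout: two comment lines; an atom-count/origin
#' line; three axis lines (point count + step vector); one line per atom;
#' then voxel values, up to six per line, with the last grid axis varying
#' fastest. A negative atom count (the convention signalling that an
#' orbital-index line follows the atoms) is accepted and the extra line is
#' skipped. All positions are interpreted as bohr.
#'
#' @param source Path to a cube file, or a character vector of its lines.
#' @return A [ScalarField-class].
#' @seealso [writeCube()]
#' @export
readCube <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  if (length(lines) < 7L) stop("parse error: cube file too short")
  head3 <- .cubeTokens(lines[3], 3)
  natoms <- as.integer(head3[1])
  origin <- head3[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    ax <- .cubeTokens(lines[3 + i], 3 + i)
    counts[i] <- as.integer(ax[1])
    axes[i, ] <- ax[2:4]
  }
  if (any(counts < 1L)) stop("parse error: non-positive grid extent")
  na <- abs(natoms)
  if (na < 1L) stop("parse error: cube file declares no atoms")
  atom_rows <- lapply(seq_len(na), function(i) .cubeTokens(lines[6 + i], 6 + i))
  atoms <- data.frame(
    number = vapply(atom_rows, function(r) as.integer(r[1]), integer(1)),
    charge = vapply(atom_rows, function(r) r[2], numeric(1)),
    x = vapply(atom_rows, function(r) r[3], numeric(1)),
    y = vapply(atom_rows, function(r) r[4], numeric(1)),
    z = vapply(atom_rows, function(r) r[5], numeric(1))
  )
  first_value_line <- 7L + na
  if (natoms < 0L) first_value_line <- first_value_line + 1L  # orbital indices
  nval <- prod(counts)
  vals <- numeric(nval)
  filled <- 0L
  for (i in seq(first_value_line, length.out = max(0L, length(lines) - first_value_line + 1L))) {
    if (!nzchar(trimws(lines[i]))) next
    v <- .cubeTokens(lines[i], i)
    if (filled + length(v) > nval)
      stop("truncation error: more values than the declared grid (",
           nval, ") at line ", i)
    vals[filled + seq_along(v)] <- v
    filled <- filled + length(v)
  }
  if (filled != nval)
    stop("truncation error: expected ", nval, " values, found ", filled)
  scalarField(values = vals, origin = origin, axes = axes, atoms = atoms,
              counts = counts)
}

#' Write a Gaussian cube file
#'
#' Emits the field in the conventional layout (first axis slowest, last axis
#' fastest, six values per line, fixed scientific notation with seven
#' significant digits so that a read/write round trip agrees to better than
#' 1e-6 relative). Output is byte-deterministic for identical inputs.
#'
#' @param field A [ScalarField-class].
#' @param path Output path; \code{NULL} returns the lines without writing.
#' @param comments Character vector of up to two header comment lines.
#' @return Invisibly (or visibly when \code{path} is \code{NULL}), the
#'   character vector of emitted lines.
#' @export
writeCube <- function(field, path = NULL,
                      comments = c("cdftools scalar field",
                                   "OUTER LOOP: AXIS 1, INNER LOOP: AXIS 3")) {
  stopifnot(is(field, "ScalarField"))
  validObject(field)
  comments <- rep_len(as.character(comments), 2L)
  counts <- dim(field@values)
  fmt_head <- function(n, v) sprintf("%5d%13.6f%13.6f%13.6f", n, v[1], v[2], v[3])
  out <- c(comments,
           fmt_head(nrow(field@atoms), field@origin),
           vapply(1:3, function(i) fmt_head(counts[i], field@axes[i, ]),
                  character(1)),
           vapply(seq_len(nrow(field@atoms)), function(i) {
             a <- field@atoms[i, ]
             sprintf("%5d%13.6f%13.6f%13.6f%13.6f",
                     as.integer(a$number), a$charge, a$x, a$y, a$z)
           }, character(1)))
  flat <- as.vector(aperm(field@values, c(3L, 2L, 1L)))  # file order
  token <- sprintf("%14.6E", flat)
  groups <- ceiling(seq_along(token) / 6)
  value_lines <- vapply(split(token, groups), paste0, character(1),
                        collapse = "")
  out <- c(out, unname(value_lines))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
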