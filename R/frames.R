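#' Construct a trajectory frame
#'
#' A frame holds the geometric substrate every CEC operation works on:
#' chemical element symbols, Cartesian coordinates in Angstrom, an optional
#' orthorhombic box, and a timestamp in femtoseconds.
#'
#' @param elements Character vector of element symbols (e.g. `"O"`, `"H"`).
#'   Symbols are case-normalized (`"HO"` -> `"Ho"`, `"o"` -> `"O"`).
#' @param positions Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param box Optional numeric vector of three orthorhombic box lengths
#'   (Angstrom), or `NULL` for a non-periodic system.
#' @param time Timestamp in fs (`NA` if unknown).
#' @param index Frame ordinal within its trajectory (`NA` if free-standing).
#' @return An object of class `cec_frame` with fields `elements`,
#'   `positions`, `box`, `time`, `index` and `natoms`.
#' @export
cec_frame <- function(elements, positions, box = NULL, time = NA_real_,
                      index = NA_integer_) {
  positions <- as.matrix(positions)
  if (is.vector(positions)) positions <- matrix(positions, ncol = 3L)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("positions must have 3 columns (x, y, z in Angstrom)")
  if (length(elements) != nrow(positions))
    stop("length(elements) (", length(elements),
         ") must equal nrow(positions) (", nrow(positions), ")")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
      stop("box must be three positive orthorhombic lengths (Angstrom)")
  }
  elements <- normalize_element(elements)
  structure(
    list(elements = elements, positions = unname(positions), box = box,
         time = as.numeric(time), index = index,
         natoms = nrow(positions)),
    class = "cec_frame")
}

normalize_element <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[A-Za-z][A-Za-z]?$", x)
  if (any(bad))
    stop("invalid element symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 2)))
}

#' @export
print.cec_frame <- function(x, ...) {
  cat("CEC frame:", x$natoms, "atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)),
            sort(table(x$elements), decreasing = TRUE),
            sep = ":", collapse = " "), ")\n")
  if (!is.null(x$box))
    cat("  box:", paste(format(x$box), collapse = " x "), "Angstrom\n")
  if (!is.na(x$time)) cat("  time:", x$time, "fs\n")
  invisible(x)
}

#' Construct an ordered series of frames
#'
#' All frames must share the same atom count and element ordering; `dt` is
#' the constant spacing between consecutive frames in fs.
#'
#' @param frames List of [cec_frame()] objects.
#' @param dt Inter-frame spacing (fs), > 0.
#' @return Object of class `cec_frames` with fields `frames`, `dt`.
#' @export
cec_frames <- function(frames, dt = 0.5) {
  if (!length(frames)) stop("frames must be a non-empty list")
  if (!all(vapply(frames, inherits, logical(1), "cec_frame")))
    stop("all entries must be cec_frame objects")
  dt <- as.numeric(dt)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0 (fs)")
  ref <- frames[[1L]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (f$natoms != ref$natoms)
      stop("frame ", i, " has ", f$natoms, " atoms; frame 1 has ", ref$natoms)
    if (!identical(f$elements, ref$elements))
      stop("frame ", i, " element ordering differs from frame 1")
    frames[[i]]$index <- i
  }
  structure(list(frames = frames, dt = dt), class = "cec_frames")
}

#' @export
print.cec_frames <- function(x, ...) {
  cat("CEC frame series:", length(x$frames), "frames of",
      x$frames[[1L]]$natoms, "atoms, dt =", x$dt, "fs\n")
  invisible(x)
}

#' @export
length.cec_frames <- function(x) length(x$frames)

## ---- minimum-image geometry -------------------------------------------------

#' Minimum-image displacement vector(s)
#'
#' Applies the minimum-image convention for an orthorhombic box; with
#' `box = NULL` the plain displacement is returned.
#'
#' @param dr Numeric 3-vector or n x 3 matrix of displacements (Angstrom).
#' @param box Orthorhombic box lengths or `NULL`.
#' @return Displacement(s) folded into `[-L/2, L/2)` per component.
#' @export
mic_vec <- function(dr, box = NULL) {
  if (is.null(box)) return(dr)
  if (is.matrix(dr)) {
    sweep(dr, 2L, box, function(d, L) d - L * round(d / L))
  } else {
    dr - box * round(dr / box)
  }
}

## distance between two atoms of a frame under minimum image
frame_dist <- function(frame, i, j) {
  sqrt(sum(mic_vec(frame$positions[j, ] - frame$positions[i, ], frame$box)^2))
}

## displacement r_j - r_i under minimum image
frame_disp <- function(frame, i, j) {
  mic_vec(frame$positions[j, ] - frame$positions[i, ], frame$box)
}

## unwrap the coordinates of a set of atoms about the first one, so a
## molecule straddling the box boundary becomes contiguous
unwrap_about_first <- function(frame, atoms) {
  unwrap_about_ref(frame, atoms, frame$positions[atoms[1L], ])
}

## unwrap atom coordinates to the minimum image about an arbitrary
## reference point; with a common reference across species the CEC is
## invariant (up to that lattice vector) under lattice translations of any
## molecule
unwrap_about_ref <- function(frame, atoms, ref) {
  pos <- frame$positions[atoms, , drop = FALSE]
  if (is.null(frame$box)) return(pos)
  shifted <- mic_vec(sweep(pos, 2L, ref), frame$box)
  sweep(shifted, 2L, ref, `+`)
}
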