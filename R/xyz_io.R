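#' Read an (extended) XYZ trajectory
#'
#' Parses a concatenated-frame XYZ file. Comment lines are scanned for the
#' extended-XYZ `Lattice="ax ay az bx by bz cx cy cz"` convention (only
#' diagonal, i.e. orthorhombic, lattices are accepted) and for a `Time=<fs>`
#' tag; both are optional.
#'
#' @param path Path to the XYZ file.
#' @param dt Inter-frame spacing (fs) used when comment lines carry no
#'   `Time=` metadata. When at least two frames carry timestamps, `dt` is
#'   inferred from them instead.
#' @return A [cec_frames()] series.
#' @export
read_xyz_trajectory <- function(path, dt = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ## drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  pos <- 1L
  fidx <- 0L
  natoms_ref <- NA_integer_
  while (pos <= length(lines)) {
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0L)
      stop("XYZ parse error in frame ", fidx, ", line ", pos,
           ": malformed atom-count line '", lines[pos], "'")
    if (is.na(natoms_ref)) natoms_ref <- n
    if (n != natoms_ref)
      stop("XYZ parse error in frame ", fidx, ", line ", pos,
           ": atom count ", n, " differs from frame 1 (", natoms_ref, ")")
    if (pos + 1L + n > length(lines))
      stop("XYZ parse error in frame ", fidx, ": truncated frame")
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    elements <- character(n)
    xyz <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      tok <- strsplit(trimws(atom_lines[k]), "[[:space:]]+")[[1L]]
      if (length(tok) < 4L)
        stop("XYZ parse error in frame ", fidx, ", line ", pos + 1L + k,
             ": expected 'element x y z'")
      co <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(co)))
        stop("XYZ parse error in frame ", fidx, ", line ", pos + 1L + k,
             ": non-numeric coordinate")
      elements[k] <- tok[1L]
      xyz[k, ] <- co
    }
    frames[[fidx]] <- cec_frame(elements, xyz,
                                box = parse_xyz_lattice(comment, fidx),
                                time = parse_xyz_time(comment),
                                index = fidx)
    pos <- pos + 2L + n
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (sum(!is.na(times)) >= 2L) {
    dts <- diff(times[!is.na(times)])
    if (length(unique(round(dts, 9))) == 1L && dts[1L] > 0) dt <- dts[1L]
  }
  cec_frames(frames, dt = dt)
}

parse_xyz_lattice <- function(comment, fidx) {
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1L]]
  if (length(m) < 2L) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(trimws(m[2L]), "[[:space:]]+")[[1L]]))
  if (length(v) != 9L || any(is.na(v)))
    stop("XYZ parse error in frame ", fidx, ": malformed Lattice entry")
  L <- matrix(v, 3L, 3L, byrow = TRUE)
  off <- L; diag(off) <- 0
  if (any(abs(off) > 1e-8))
    stop("unsupported box in frame ", fidx,
         ": only orthorhombic (diagonal) lattices are supported")
  diag(L)
}

parse_xyz_time <- function(comment) {
  m <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1L]]
  if (length(m) < 2L) return(NA_real_)
  suppressWarnings(as.numeric(m[2L]))
}

#' Write a frame series as extended XYZ
#'
#' @param series A [cec_frames()] series (or a single [cec_frame()]).
#' @param path Output path.
#' @param digits Coordinate decimals (default 8, ample for 1e-6 roundtrips).
#' @export
write_xyz_trajectory <- function(series, path, digits = 8L) {
  if (inherits(series, "cec_frame")) series <- cec_frames(list(series), dt = 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in series$frames) {
    comment <- character(0)
    if (!is.null(f$box))
      comment <- c(comment, sprintf(
        'Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f"',
        f$box[1L], f$box[2L], f$box[3L]))
    if (!is.na(f$time)) comment <- c(comment, sprintf("Time=%.6f", f$time))
    comment <- c(comment, 'Properties=species:S:1:pos:R:3')
    writeLines(as.character(f$natoms), con)
    writeLines(paste(comment, collapse = " "), con)
    fmt <- paste0("%-2s %.", digits, "f %.", digits, "f %.", digits, "f")
    writeLines(sprintf(fmt, f$elements, f$positions[, 1L],
                       f$positions[, 2L], f$positions[, 3L]), con)
  }
  invisible(path)
}

#' Read a single-frame PDB file
#'
#' Atom records are parsed with \pkg{bio3d}; the element is taken from the
#' element column when present, otherwise inferred from the atom name. A
#' `CRYST1` record with 90/90/90 angles populates the box; any other angles
#' raise an error (only orthorhombic cells are supported).
#'
#' @param path Path to a PDB file with a single model.
#' @return A [cec_frame()].
#' @export
read_pdb_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!nrow(at)) stop("PDB parse error: no ATOM/HETATM records in ", path)
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z)))
    stop("PDB parse error: missing coordinates in ", path)
  elesy <- trimws(as.character(at$elesy))
  need <- is.na(elesy) | !nzchar(elesy)
  if (any(need))   # atom2ele warns while guessing non-standard names
    elesy[need] <- suppressWarnings(
      bio3d::atom2ele(trimws(as.character(at$elety[need]))))
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    cr <- cr[1L]
    vals <- suppressWarnings(as.numeric(c(
      substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
      substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54))))
    if (any(is.na(vals))) stop("PDB parse error: malformed CRYST1 record")
    if (any(abs(vals[4:6] - 90) > 1e-6))
      stop("unsupported box: CRYST1 angles ",
           paste(vals[4:6], collapse = "/"),
           " (only orthorhombic 90/90/90 cells are supported)")
    if (all(vals[1:3] > 0)) box <- vals[1:3]
  }
  cec_frame(elesy, cbind(at$x, at$y, at$z), box = box)
}

#' Write CEC tracking outputs
#'
#' Writes three files: `<prefix>.xyz`, the input trajectory with a
#' pseudo-atom `X` appended at the CEC position of each frame;
#' `<prefix>_track.csv`, one row per frame (frame, time_fs, cec x/y/z,
#' n_states, c1_sq, and xi when supplied); and `<prefix>_manifest.json`
#' recording parameters so runs are auditable.
#'
#' @param series The analysed [cec_frames()] series.
#' @param results List of `cec_result` objects, one per frame.
#' @param prefix Output path prefix.
#' @param xi Optional numeric vector of the proton-dissociation CV per frame.
#' @param manifest Optional named list merged into the JSON manifest.
#' @return Invisibly, the vector of written paths.
#' @export
write_cec_outputs <- function(series, results, prefix, xi = NULL,
                              manifest = list()) {
  if (!length(results))
    stop("results is empty: one cec_result per frame is required")
  if (length(results) != length(series$frames))
    stop("length mismatch: ", length(results), " results for ",
         length(series$frames), " frames")
  if (!is.null(xi) && length(xi) != length(results))
    stop("length mismatch: xi must have one value per frame")
  aug <- lapply(seq_along(series$frames), function(i) {
    f <- series$frames[[i]]
    cec_frame(c(f$elements, "X"), rbind(f$positions, results[[i]]$cec),
              box = f$box, time = f$time, index = f$index)
  })
  xyz_path <- paste0(prefix, ".xyz")
  write_xyz_trajectory(cec_frames(aug, dt = series$dt), xyz_path)

  track <- data.frame(
    frame = seq_along(results),
    time_fs = vapply(seq_along(results), function(i) {
      t <- series$frames[[i]]$time
      if (is.na(t)) (i - 1L) * series$dt else t
    }, numeric(1)),
    cec_x = vapply(results, function(r) r$cec[1L], numeric(1)),
    cec_y = vapply(results, function(r) r$cec[2L], numeric(1)),
    cec_z = vapply(results, function(r) r$cec[3L], numeric(1)),
    n_states = vapply(results, function(r) r$n_states, numeric(1)),
    c1_sq = vapply(results, function(r) r$weights[1L], numeric(1)))
  if (!is.null(xi)) track$xi <- xi
  csv_path <- paste0(prefix, "_track.csv")
  utils::write.csv(track, csv_path, row.names = FALSE)

  man <- utils::modifyList(list(
    package = "cectrack",
    version = as.character(utils::packageVersion("cectrack")),
    n_frames = length(results),
    n_atoms = series$frames[[1L]]$natoms,
    dt_fs = series$dt), manifest)
  man_path <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(xyz = xyz_path, track = csv_path, manifest = man_path))
}
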