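#' Gas-phase hydronium-water training grid
#'
#' Collinear O-H-O geometries for calibrating the exponential
#' charge-transfer model: for each oxygen-oxygen distance the shared proton
#' is placed at evenly spaced O-H distances from 0.9 Angstrom to the O-O
#' midpoint (where the transfer coordinate is zero). Spectator hydrogens
#' are idealized — only the transfer coordinate matters for the fit, but
#' the geometries are emitted as valid XYZ so an external
#' electronic-structure code can evaluate the charge-transfer factors on
#' them. The defaults give the standard 6 x 6 = 36-point grid
#' (r_OO in {2.2, 2.4, 2.6, 2.8, 3.0, 3.2} Angstrom).
#'
#' @param roo_values Oxygen-oxygen distances (Angstrom), all > 1.8.
#' @param n_h_positions Shared-proton positions per r_OO.
#' @return Object of class `training_grid`: `frames` (list of
#'   [cec_frame()]) and `labels` (data.frame `r_oo`, `r_oh`, `delta`).
#' @export
generate_h3o_water_grid <- function(roo_values = c(2.2, 2.4, 2.6, 2.8, 3.0, 3.2),
                                    n_h_positions = 6L) {
  if (any(roo_values <= 1.8)) stop("all r_OO must exceed 1.8 Angstrom")
  if (any(roo_values / 2 <= 0.9))
    stop("infeasible grid: r_OO/2 must exceed the 0.9 Angstrom start")
  rows <- do.call(rbind, lapply(roo_values, function(roo)
    data.frame(r_oo = roo,
               r_oh = seq(0.9, roo / 2, length.out = n_h_positions))))
  rows$delta <- 2 * rows$r_oh - rows$r_oo
  frames <- lapply(seq_len(nrow(rows)), function(i)
    zundel_frame(rows$r_oo[i], rows$r_oh[i]))
  structure(list(frames = frames, labels = rows, pair = "h3o-water"),
            class = "training_grid")
}

#' Gas-phase acid-water training grid
#'
#' Carboxyl-O...H...water-O geometries: 7 oxygen-oxygen distances evenly
#' spaced over [2.2, 2.8] Angstrom and 9 shared-proton O-H distances evenly
#' spaced over [1.0, r_OO - 1.0] Angstrom, giving the standard
#' 7 x 9 = 63-point grid. Carboxyl placement is idealized and planar.
#'
#' @param roo_values Oxygen-oxygen distances (Angstrom), all > 2.0.
#' @param n_h_positions Shared-proton positions per r_OO.
#' @return A `training_grid` (see [generate_h3o_water_grid()]); each frame
#'   is accompanied by the [acid_spec()] in field `acid`.
#' @export
generate_glu_water_grid <- function(roo_values = seq(2.2, 2.8, length.out = 7L),
                                    n_h_positions = 9L) {
  if (any(roo_values <= 2.0)) stop("all r_OO must exceed 2.0 Angstrom")
  if (any(roo_values - 1.0 < 1.0))
    stop("infeasible grid: r_OO - 1.0 must be at least 1.0 Angstrom")
  rows <- do.call(rbind, lapply(roo_values, function(roo)
    data.frame(r_oo = roo,
               r_oh = seq(1.0, roo - 1.0, length.out = n_h_positions))))
  rows$delta <- 2 * rows$r_oh - rows$r_oo
  frames <- lapply(seq_len(nrow(rows)), function(i)
    glu_water_frame(rows$r_oo[i], rows$r_oh[i]))
  structure(list(frames = frames, labels = rows, pair = "glu-water",
                 acid = acid_spec(o_atoms = c(1L, 4L),
                                  group_atoms = c(1L, 3L, 4L))),
            class = "training_grid")
}

## planar carboxyl with the donating O at the origin, shared H on +x,
## water acceptor at (r_oo, 0, 0)
glu_water_frame <- function(r_oo, r_oh, oh_len = 0.97) {
  cpos <- 1.25 * c(cos(110 * pi / 180), sin(110 * pi / 180), 0)
  u1 <- -cpos / sqrt(sum(cpos^2))                 # C -> O1 direction
  th <- 124 * pi / 180                            # O-C-O angle
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
  u2 <- c(rot %*% u1[1:2], 0)
  o2 <- cpos + 1.25 * u2
  b <- 127.75 * pi / 180
  acc_h <- sweep(rbind(c(cos(b), sin(b), 0), c(cos(b), -sin(b), 0)) * -oh_len,
                 2L, c(r_oo, 0, 0), `+`)
  cec_frame(c("O", "H", "C", "O", "O", "H", "H"),
            rbind(c(0, 0, 0), c(r_oh, 0, 0), cpos, o2,
                  c(r_oo, 0, 0), acc_h))
}

#' @export
print.training_grid <- function(x, ...) {
  cat("Training grid (", x$pair, "): ", nrow(x$labels), " geometries, r_OO ",
      format(min(x$labels$r_oo)), "-", format(max(x$labels$r_oo)),
      " Angstrom\n", sep = "")
  invisible(x)
}

#' Write / read a training grid as extended XYZ
#'
#' The (r_OO, r_OH, delta) labels are recorded in each frame's comment
#' line, so the grid roundtrips through the file.
#'
#' @param grid A `training_grid`.
#' @param path Output path.
#' @export
write_training_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(grid$frames)) {
    f <- grid$frames[[i]]
    writeLines(as.character(f$natoms), con)
    writeLines(sprintf("pair=%s r_oo=%.6f r_oh=%.6f delta=%.6f", grid$pair,
                       grid$labels$r_oo[i], grid$labels$r_oh[i],
                       grid$labels$delta[i]), con)
    writeLines(sprintf("%-2s %.8f %.8f %.8f", f$elements,
                       f$positions[, 1L], f$positions[, 2L],
                       f$positions[, 3L]), con)
  }
  invisible(path)
}

#' @rdname write_training_grid
#' @export
read_training_grid <- function(path) {
  series <- read_xyz_trajectory(path, dt = 1)
  lines <- readLines(path, warn = FALSE)
  comments <- grep("r_oo=", lines, value = TRUE)
  getnum <- function(tag) as.numeric(sub(paste0(".*", tag, "=([-0-9.eE+]+).*"),
                                         "\\1", comments))
  pair <- sub(".*pair=([^ ]+).*", "\\1", comments[1L])
  labels <- data.frame(r_oo = getnum("r_oo"), r_oh = getnum("r_oh"),
                       delta = getnum("delta"))
  structure(list(frames = series$frames, labels = labels, pair = pair),
            class = "training_grid")
}

#' Fit the exponential charge-transfer model
#'
#' Nonlinear least squares of `f_CT = exp(k (delta - delta0))` on the
#' charge-transfer factors, initialized from the exact log-linear
#' regression `ln f = k delta - k delta0` (which is itself the solution of
#' the log-space least-squares problem, available via `log_space = TRUE`).
#' For symmetric pairs such as hydronium-water, where the state weights are
#' equal when the proton is equally shared, `delta0` can be constrained to
#' zero with `fix_delta0 = TRUE`.
#'
#' @param deltas Transfer coordinates (Angstrom), not all equal.
#' @param fct Charge-transfer factors, all > 0.
#' @param weights Optional least-squares weights.
#' @param fix_delta0 Constrain `delta0 = 0`.
#' @param log_space Minimize residuals of `ln f` instead of `f`.
#' @return Object of class `ct_fit`: `k` (1/Angstrom), `delta0` (Angstrom),
#'   `residual_rms` (on `f_CT`), `n_points`, and `covariance` (2 x 2; the
#'   `delta0` row/column is zero when fixed).
#' @export
fit_ct_parameters <- function(deltas, fct, weights = NULL,
                              fix_delta0 = FALSE, log_space = FALSE) {
  deltas <- as.numeric(deltas)
  fct <- as.numeric(fct)
  if (length(deltas) != length(fct)) stop("deltas and fct lengths differ")
  if (length(deltas) < 3L) stop("need at least 3 points to fit")
  if (any(!is.finite(fct)) || any(fct <= 0))
    stop("domain error: all charge-transfer factors must be positive")
  if (stats::sd(deltas) < 1e-12)
    stop("unidentifiable fit: all transfer coordinates are equal")
  w <- if (is.null(weights)) rep(1, length(deltas)) else as.numeric(weights)

  ## exact log-linear initialization
  lf <- log(fct)
  if (fix_delta0) {
    k0 <- sum(w * deltas * lf) / sum(w * deltas^2)
    d0 <- 0
  } else {
    co <- stats::coef(stats::lm(lf ~ deltas, weights = w))
    k0 <- unname(co[2L])
    d0 <- unname(-co[1L] / co[2L])
  }
  if (!is.finite(k0) || k0 <= 0)
    stop("fit failed: charge-transfer factors do not increase with delta ",
         "(fitted k = ", format(k0), " must be > 0)")

  dat <- data.frame(deltas = deltas, fct = fct, lf = lf)
  form <- if (log_space) {
    if (fix_delta0) lf ~ k * deltas else lf ~ k * (deltas - delta0)
  } else {
    if (fix_delta0) fct ~ exp(k * deltas) else fct ~ exp(k * (deltas - delta0))
  }
  start <- if (fix_delta0) list(k = k0) else list(k = k0, delta0 = d0)
  fit <- minpack.lm::nlsLM(form, data = dat, start = start, weights = w,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  est <- stats::coef(fit)
  k <- unname(est["k"])
  delta0 <- if (fix_delta0) 0 else unname(est["delta0"])
  vc <- matrix(0, 2L, 2L, dimnames = list(c("k", "delta0"),
                                          c("k", "delta0")))
  vcf <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(vcf)) {
    nm <- rownames(vcf)
    vc[nm, nm] <- vcf
  }
  resid <- fct - exp(pmin(pmax(k * (deltas - delta0), -50), 50))
  structure(list(k = k, delta0 = delta0,
                 residual_rms = sqrt(mean(resid^2)),
                 n_points = length(deltas), covariance = vc,
                 log_space = log_space, fix_delta0 = fix_delta0),
            class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat(sprintf(
    "Charge-transfer fit: k = %.4f 1/A (se %.2g), delta0 = %.4f A%s, rms %.3g on %d points\n",
    x$k, sqrt(x$covariance["k", "k"]), x$delta0,
    if (x$fix_delta0) " (fixed)" else "", x$residual_rms, x$n_points))
  invisible(x)
}

#' Simulate a charge-transfer table from the exponential model
#'
#' Evaluates `f_CT = exp(k (delta - delta0))` on a training grid's transfer
#' coordinates, optionally with multiplicative lognormal noise — the shape
#' of table an electronic-structure scan of the grid would produce.
#'
#' @param grid A `training_grid` (or a numeric vector of deltas).
#' @param k,delta0 Model parameters.
#' @param noise_sd Lognormal sigma of the multiplicative noise (0 = exact).
#' @param seed Integer seed for the noise.
#' @return Data frame `r_oo`, `r_oh`, `delta`, `fct` (columns `r_oo`,
#'   `r_oh` only when a grid is supplied).
#' @export
simulate_ct_table <- function(grid, k, delta0 = 0, noise_sd = 0,
                              seed = NULL) {
  if (inherits(grid, "training_grid")) {
    out <- grid$labels
  } else {
    out <- data.frame(delta = as.numeric(grid))
  }
  fct <- exp(k * (out$delta - delta0))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    fct <- fct * exp(stats::rnorm(length(fct), sd = noise_sd))
  }
  out$fct <- fct
  out
}
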