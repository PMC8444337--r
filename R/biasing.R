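## Boltzmann constant in kcal/(mol K)
KB_KCALMOL <- 0.0019872041

#' Smooth minimum of two distances
#'
#' `softmin(d1, d2) = -(1/kappa) ln(exp(-kappa d1) + exp(-kappa d2))`,
#' evaluated via a shift-by-minimum (log-sum-exp) scheme so no finite input
#' can overflow or underflow. The value never exceeds `min(d1, d2)` and
#' falls short of it by at most `ln(2)/kappa`, attained exactly on the
#' diagonal `d1 = d2`.
#'
#' @param d1,d2 Distances (Angstrom); vectorized.
#' @param kappa Sharpness (1/Angstrom), > 0; default 40.
#' @return Smoothed minimum (Angstrom).
#' @export
softmin <- function(d1, d2, kappa = 40) {
  if (kappa <= 0) stop("kappa must be > 0")
  pmin(d1, d2) - log1p(exp(-kappa * abs(d1 - d2))) / kappa
}

#' Proton-dissociation collective variable
#'
#' The smooth minimum of the distances between the CEC and the two acid
#' carboxyl oxygens, with its analytic gradient. The gradient components
#' over `{cec, o1, o2}` sum to zero (translational invariance).
#'
#' @param cec CEC position (3-vector, Angstrom).
#' @param o1,o2 Carboxyl oxygen positions (3-vectors, Angstrom).
#' @param kappa Softmin sharpness (1/Angstrom), default 40.
#' @return List with `value` (Angstrom) and gradients `d_cec`, `d_o1`,
#'   `d_o2` (3-vectors).
#' @export
xi_cv <- function(cec, o1, o2, kappa = 40) {
  v1 <- cec - o1
  v2 <- cec - o2
  d1 <- sqrt(sum(v1^2))
  d2 <- sqrt(sum(v2^2))
  if (d1 < 1e-9 || d2 < 1e-9)
    stop("geometry error: CEC coincides with a carboxyl oxygen")
  value <- softmin(d1, d2, kappa)
  ## softmin weights via the stable difference form
  w1 <- 1 / (1 + exp(-kappa * (d2 - d1)))
  w2 <- 1 - w1
  g1 <- w1 * v1 / d1
  g2 <- w2 * v2 / d2
  list(value = value, d_cec = g1 + g2, d_o1 = -g1, d_o2 = -g2)
}

#' Atomic-position gradient of the dissociation CV
#'
#' Chains the CV gradient through the CEC Jacobian so the bias force on
#' every atom of the hop network is available for analysis:
#' `d xi / d r_I = (d xi / d cec) J_I`, plus the direct carboxyl-oxygen
#' terms.
#'
#' @param frame A [cec_frame()].
#' @param stateset A [enumerate_states()] result.
#' @param o1,o2 Atom indices of the two carboxyl oxygens.
#' @param params,charges See [compute_cec()].
#' @param kappa Softmin sharpness (1/Angstrom).
#' @return List with `value` and `gradient` (natoms x 3 matrix).
#' @export
xi_atomic_gradient <- function(frame, stateset, o1, o2,
                               params = default_ct_params(),
                               charges = default_charge_table(),
                               kappa = 40) {
  cec <- cec_value(frame, stateset, params, charges)
  xi <- xi_cv(cec, frame$positions[o1, ], frame$positions[o2, ], kappa)
  J <- cec_gradient(frame, stateset, params, charges)
  grad <- t(vapply(seq_len(frame$natoms), function(I)
    as.numeric(xi$d_cec %*% J[, , I]), numeric(3L)))
  grad[o1, ] <- grad[o1, ] + xi$d_o1
  grad[o2, ] <- grad[o2, ] + xi$d_o2
  list(value = xi$value, gradient = grad)
}

#' Well-tempered metadynamics bias state
#'
#' Holds the deposited hills and the deposition rule parameters. Defaults
#' follow the published proton-dissociation protocol: 0.2 kcal/mol initial
#' height, 0.1 Angstrom width, 50 fs stride, bias factor 12 (suited to a
#' barrier of roughly 9 kcal/mol), softmin sharpness 40 1/Angstrom, 300 K.
#'
#' @param height0 Initial hill height (kcal/mol), > 0.
#' @param width Gaussian sigma (Angstrom), > 0.
#' @param gamma Bias factor, > 1.
#' @param stride_fs Deposition interval (fs).
#' @param temperature Temperature (K).
#' @param kappa Softmin sharpness carried for bookkeeping (1/Angstrom).
#' @return Object of class `bias_state` with empty hill registers
#'   (`centers`, `heights`, `times`).
#' @export
bias_state <- function(height0 = 0.2, width = 0.1, gamma = 12,
                       stride_fs = 50, temperature = 300, kappa = 40) {
  if (height0 <= 0) stop("height0 must be > 0")
  if (width <= 0) stop("width must be > 0")
  if (gamma <= 1) stop("gamma must be > 1 (well-tempered bias factor)")
  structure(list(centers = numeric(0), heights = numeric(0),
                 times = numeric(0), height0 = height0, width = width,
                 gamma = gamma, stride_fs = stride_fs,
                 temperature = temperature, kappa = kappa),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf(
    "Well-tempered bias: %d hills (h0 = %g kcal/mol, sigma = %g A, gamma = %g, stride = %g fs, T = %g K)\n",
    length(x$centers), x$height0, x$width, x$gamma, x$stride_fs,
    x$temperature))
  invisible(x)
}

#' Evaluate the metadynamics bias
#'
#' Exact sum over the deposited (unmerged) Gaussian hills, with the
#' analytic derivative; vectorized over `cv_value`.
#'
#' @param bias A [bias_state()].
#' @param cv_value CV value(s) (Angstrom).
#' @return List with `energy` (kcal/mol) and `derivative` (kcal/mol/A).
#' @export
evaluate_bias <- function(bias, cv_value) {
  if (!length(bias$centers))
    return(list(energy = numeric(length(cv_value)) * 0,
                derivative = numeric(length(cv_value)) * 0))
  s2 <- bias$width^2
  out <- vapply(cv_value, function(s) {
    dx <- s - bias$centers
    g <- bias$heights * exp(-dx^2 / (2 * s2))
    c(sum(g), -sum(g * dx) / s2)
  }, numeric(2L))
  list(energy = out[1L, ], derivative = out[2L, ])
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian at `cv_value` with height
#' `h0 exp(-V_bias(cv_value) / (kB (gamma - 1) T))`, the bias evaluated
#' before deposition — so repeated deposits at a fixed point have strictly
#' decreasing heights and the accumulated bias stays bounded.
#'
#' @param bias A [bias_state()].
#' @param cv_value Deposition center (Angstrom).
#' @param time_fs Optional timestamp for the hill record.
#' @return The updated `bias_state`.
#' @export
deposit_hill <- function(bias, cv_value, time_fs = NA_real_) {
  v <- evaluate_bias(bias, cv_value)$energy
  dT <- (bias$gamma - 1) * bias$temperature
  h <- bias$height0 * exp(-v / (KB_KCALMOL * dT))
  bias$centers <- c(bias$centers, cv_value)
  bias$heights <- c(bias$heights, h)
  bias$times <- c(bias$times, time_fs)
  bias
}

#' Polynomial coefficients of the symmetric double well
#'
#' `V(x) = barrier ((x/a)^2 - 1)^2`: minima of zero at `x = -a, +a` and a
#' barrier of `barrier` kcal/mol at `x = 0`.
#'
#' @param barrier Barrier height (kcal/mol).
#' @param half_width Half-separation `a` of the minima (Angstrom).
#' @return Coefficient vector `c0..c4` for `V(x) = sum c_j x^j`.
#' @export
double_well_coefs <- function(barrier = 3, half_width = 1) {
  a <- half_width
  c(barrier, 0, -2 * barrier / a^2, 0, barrier / a^4)
}

#' Evaluate a polynomial potential
#'
#' @param coefs Coefficients `c0..cN` of `V(x) = sum c_j x^j`.
#' @param x Position(s).
#' @return `V(x)`.
#' @export
poly_potential <- function(coefs, x) {
  vapply(x, function(s) sum(coefs * s^(seq_along(coefs) - 1L)), numeric(1))
}

#' Toy overdamped-Langevin metadynamics run
#'
#' Demonstrates enhanced sampling on a 1-D model potential: overdamped
#' Langevin dynamics on the CV with a well-tempered bias accumulating under
#' the standard deposition rule. The integrator (compiled) evaluates the
#' bias on a fine interpolation grid (`grid_dx`); the hills themselves are
#' returned unmerged in the `bias_state`. The free-energy estimate is
#' `F(s) = -(gamma/(gamma-1)) V_bias(s)`, shifted to a zero minimum.
#'
#' @param coefs Polynomial potential coefficients (see
#'   [double_well_coefs()]); the potential must be bounded below on the
#'   domain.
#' @param bias A [bias_state()] supplying the hill settings.
#' @param n_steps Number of integration steps.
#' @param dt_fs Timestep (fs).
#' @param diffusion CV diffusion constant (Angstrom^2/fs).
#' @param x0 Initial CV value (Angstrom).
#' @param domain Allowed CV interval; leaving it aborts with an error
#'   naming the step.
#' @param biased Deposit hills (`TRUE`) or run plain Langevin (`FALSE`).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param record_stride Store the CV every this many steps.
#' @param grid_dx Bias interpolation grid spacing (Angstrom).
#' @return List with `cv` (recorded trajectory), `times` (fs), `bias`
#'   (updated [bias_state()]), and `fes` (data.frame `cv`, `F` in
#'   kcal/mol; zero rows for unbiased runs).
#' @export
run_toy_metad <- function(coefs = double_well_coefs(3), bias = bias_state(),
                          n_steps = 4e6, dt_fs = 1, diffusion = 2e-5,
                          x0 = -1, domain = c(-2.5, 2.5), biased = TRUE,
                          seed = 1L, record_stride = 10L, grid_dx = 0.001) {
  if (poly_potential(coefs, domain[1L]) < -1e6 ||
      poly_potential(coefs, domain[2L]) < -1e6)
    stop("potential must be bounded below on the domain")
  stride_steps <- max(1L, as.integer(round(bias$stride_fs / dt_fs)))
  set.seed(seed)
  res <- metad_langevin_cpp(
    coefs, as.double(n_steps), dt_fs, diffusion,
    KB_KCALMOL * bias$temperature, x0, domain[1L], domain[2L], grid_dx,
    biased, bias$height0, bias$width,
    KB_KCALMOL * (bias$gamma - 1) * bias$temperature,
    stride_steps, as.integer(record_stride))
  if (res$error_step >= 0)
    stop("trajectory left the domain [", domain[1L], ", ", domain[2L],
         "] at step ", res$error_step)
  bias$centers <- res$hill_centers
  bias$heights <- res$hill_heights
  bias$times <- res$hill_times
  grid <- seq(domain[1L], domain[2L], by = grid_dx)
  fes <- if (biased) {
    Fgrid <- -(bias$gamma / (bias$gamma - 1)) * res$bias_grid
    data.frame(cv = grid, F = Fgrid - min(Fgrid))
  } else {
    data.frame(cv = numeric(0), F = numeric(0))
  }
  list(cv = res$cv, times = res$cv_times, bias = bias, fes = fes)
}

#' Barrier estimate from a reconstructed free-energy profile
#'
#' Locates the free-energy minimum on each side of zero and the maximum
#' between them, then reads each stationary value as a local average over
#' `+/- halfwidth` (which suppresses hill-placement wiggles without biasing
#' the estimate the way a global max-minus-min would). The barrier is the
#' top value minus the mean of the two well values.
#'
#' @param fes Data frame with columns `cv`, `F` (from [run_toy_metad()]).
#' @param halfwidth Averaging half-width about each stationary point
#'   (Angstrom).
#' @return Barrier estimate (kcal/mol).
#' @export
fes_barrier <- function(fes, halfwidth = 0.05) {
  if (!nrow(fes)) stop("empty free-energy profile")
  local_avg <- function(x0) mean(fes$F[abs(fes$cv - x0) <= halfwidth])
  left <- fes[fes$cv < 0, ]
  right <- fes[fes$cv > 0, ]
  if (!nrow(left) || !nrow(right)) stop("fes grid does not straddle zero")
  xl <- left$cv[which.min(left$F)]
  xr <- right$cv[which.min(right$F)]
  mid <- fes[fes$cv >= xl & fes$cv <= xr, ]
  xt <- mid$cv[which.max(mid$F)]
  local_avg(xt) - (local_avg(xl) + local_avg(xr)) / 2
}
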