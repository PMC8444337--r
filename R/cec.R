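#' Proton-transfer coordinate of a hop
#'
#' `delta = |r_H - r_donorO| - |r_H - r_acceptorO|` with minimum-image
#' distances: negative while the shared proton sits on the donor, zero at
#' the midpoint of a symmetric pair, and increasing as the proton moves
#' toward the acceptor. Swapping donor and acceptor flips the sign.
#'
#' @param frame A [cec_frame()].
#' @param hop A hop (from [find_acceptor_hops()] or an enumeration path).
#' @return The transfer coordinate in Angstrom.
#' @export
hop_delta <- function(frame, hop) {
  d1 <- frame_dist(frame, hop$shared_h, hop$donor_o)
  d2 <- frame_dist(frame, hop$shared_h, hop$acceptor_o)
  if (d1 < 1e-9 || d2 < 1e-9)
    stop("geometry error: shared H coincides with an oxygen")
  d1 - d2
}

#' Exponential charge-transfer factor
#'
#' `f_CT = exp(k * (delta - delta0))`: the ratio by which excess-charge
#' weight is passed from a donor state to its acceptor state across one
#' proton hop. `f_CT = 1` at `delta = delta0` (equal sharing) and grows
#' monotonically as the proton moves toward the acceptor; the exponent is
#' clipped to +/-50 before exponentiation so no physically unreachable
#' geometry can overflow.
#'
#' @param delta Transfer coordinate(s), Angstrom.
#' @param params Either a list with `k` and `delta0` (see
#'   [lookup_ct_params()]) or a single-row [ct_params()] table.
#' @return Dimensionless factor(s), > 0.
#' @export
charge_transfer_factor <- function(delta, params) {
  if (inherits(params, "ct_params")) {
    if (nrow(params) != 1L)
      stop("pass a single-row ct_params table or a list(k=, delta0=)")
    params <- list(k = params$k, delta0 = params$delta0)
  }
  expo <- params$k * (delta - params$delta0)
  exp(pmin(pmax(expo, -50), 50))
}

## unnormalized state weights: per state, sum over its paths of the product
## of charge-transfer factors along the path (root: empty product = 1)
path_products <- function(stateset, frame, params) {
  vapply(stateset$states, function(s) {
    sum(vapply(s$paths, function(path) {
      if (!length(path)) return(1)
      prod(vapply(path, function(hop) {
        p <- lookup_ct_params(params, hop$pair_kind)
        charge_transfer_factor(hop_delta(frame, hop), p)
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

#' Diabatic state weights
#'
#' The unnormalized weight of each state is the product of charge-transfer
#' factors along its hop path from the root (the root carries the empty
#' product, 1); normalization then enforces `sum(c_i^2) = 1`, so
#' `c_1^2 = 1 / (1 + sum over paths of prod f_CT)`.
#'
#' @param stateset A [enumerate_states()] result.
#' @param frame The frame the states were enumerated on.
#' @param params A [ct_params()] table covering every hop pair kind.
#' @return Numeric vector of `c_i^2` values summing to 1.
#' @export
state_weights <- function(stateset, frame, params) {
  u <- path_products(stateset, frame, params)
  u / sum(u)
}

#' Center of charge of one diabatic state
#'
#' The excess-charge-weighted mean position of the protonated species'
#' atoms, `sum_I q_I r_I / sum_I q_I`, with the species' coordinates
#' unwrapped to the minimum image about its first atom so box-straddling
#' molecules do not produce artificial centers. Excess charges (net +1 e)
#' are used, never raw force-field charges of a neutral species, whose net
#' charge of zero would make the denominator singular.
#'
#' @param frame A [cec_frame()].
#' @param state One state of a `cec_states` set.
#' @param charges A [charge_table()].
#' @return 3-vector (Angstrom).
#' @export
center_of_charge <- function(frame, state, charges) {
  q <- species_excess_charges(frame, state$atoms, state$kind, charges)
  pos <- unwrap_about_first(frame, state$atoms)
  colSums(pos * q) / sum(q)
}

#' Compute the center of excess charge of a frame
#'
#' The adiabatic CEC is the state-weighted average of the diabatic centers
#' of charge, `sum_i c_i^2 COC_i`. Alongside the position, the per-atom
#' excess charges `sum_i c_i^2 q_I^i` (which sum to +1 e) and the
#' excess-charge dipole `sum_I q_I^excess r_I` (equal to +1 e times the CEC
#' position) are returned.
#'
#' @param frame A [cec_frame()].
#' @param stateset A [enumerate_states()] result.
#' @param weights Optional precomputed [state_weights()]; computed from
#'   `params` when `NULL`.
#' @param params A [ct_params()] table (required when `weights` is `NULL`).
#' @param charges A [charge_table()].
#' @return Object of class `cec_result` with fields `cec`, `weights`,
#'   `per_atom_excess`, `dipole`, `n_states`.
#' @export
compute_cec <- function(frame, stateset, weights = NULL,
                        params = default_ct_params(),
                        charges = default_charge_table()) {
  if (is.null(weights)) weights <- state_weights(stateset, frame, params)
  if (length(weights) != length(stateset$states))
    stop("need one weight per state")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must be normalized to 1")
  cec <- c(0, 0, 0)
  per_atom <- numeric(frame$natoms)
  dipole <- c(0, 0, 0)
  ## all species unwrap about one anchor (the root species' first atom) so
  ## the CEC is covariant under lattice translations of any molecule
  anchor <- frame$positions[stateset$states[[1L]]$atoms[1L], ]
  for (i in seq_along(stateset$states)) {
    s <- stateset$states[[i]]
    q <- species_excess_charges(frame, s$atoms, s$kind, charges)
    pos <- unwrap_about_ref(frame, s$atoms, anchor)
    coc <- colSums(pos * q) / sum(q)
    cec <- cec + weights[i] * coc
    per_atom[s$atoms] <- per_atom[s$atoms] + weights[i] * q
    dipole <- dipole + colSums(pos * (weights[i] * q))
  }
  structure(list(cec = cec, weights = weights, per_atom_excess = per_atom,
                 dipole = dipole, n_states = length(stateset$states)),
            class = "cec_result")
}

#' @export
print.cec_result <- function(x, ...) {
  cat(sprintf("CEC at (%.4f, %.4f, %.4f) Angstrom from %d states (c1^2 = %.3f)\n",
              x$cec[1L], x$cec[2L], x$cec[3L], x$n_states, x$weights[1L]))
  invisible(x)
}

#' Per-atom excess charges and the excess-charge dipole
#'
#' Convenience accessor for the dipole view of the CEC: the per-atom excess
#' charge is the state-population-weighted average of the diabatic charges,
#' and its dipole (about the coordinate origin) equals the total excess
#' charge (+1 e) times the CEC position.
#'
#' @inheritParams compute_cec
#' @return List with `per_atom_excess` (e) and `dipole` (e Angstrom).
#' @export
excess_charge_dipole <- function(frame, stateset, weights = NULL,
                                 params = default_ct_params(),
                                 charges = default_charge_table()) {
  r <- compute_cec(frame, stateset, weights, params, charges)
  list(per_atom_excess = r$per_atom_excess, dipole = r$dipole)
}

#' Analytic gradient of the CEC with respect to atomic positions
#'
#' Chain rule through the state weights: the Jacobian block of atom `I`
#' combines the center-of-charge term (`c_i^2 q_I^i` times the identity for
#' atoms in state i's species) with the weight term through every hop's
#' transfer coordinate, `d c_i^2 / d delta_h = k_h c_i^2 ([h in path_i] -
#' sum_{j: h in path_j} c_j^2)`. Atoms in no state's species and in no hop
#' have exactly zero blocks, so the CEC is strictly local to the enumerated
#' shells. The blocks of all atoms sum to the identity (translational
#' covariance).
#'
#' @param frame A [cec_frame()].
#' @param stateset A [enumerate_states()] result.
#' @param params A [ct_params()] table.
#' @param charges A [charge_table()].
#' @return A `3 x 3 x natoms` array; `[, , I]` is `d cec / d r_I` (rows:
#'   CEC components, columns: coordinates of atom I).
#' @export
cec_gradient <- function(frame, stateset, params = default_ct_params(),
                         charges = default_charge_table()) {
  ns <- length(stateset$states)
  ## per-path products and per-state sums
  upaths <- lapply(stateset$states, function(s)
    vapply(s$paths, function(path) {
      if (!length(path)) return(1)
      prod(vapply(path, function(hop) {
        p <- lookup_ct_params(params, hop$pair_kind)
        charge_transfer_factor(hop_delta(frame, hop), p)
      }, numeric(1)))
    }, numeric(1)))
  u <- vapply(upaths, sum, numeric(1))
  S <- sum(u)
  w <- u / S

  ## COCs and the COC part of the Jacobian
  J <- array(0, dim = c(3L, 3L, frame$natoms))
  cocs <- matrix(0, ns, 3L)
  anchor <- frame$positions[stateset$states[[1L]]$atoms[1L], ]
  for (i in seq_len(ns)) {
    s <- stateset$states[[i]]
    q <- species_excess_charges(frame, s$atoms, s$kind, charges)
    pos <- unwrap_about_ref(frame, s$atoms, anchor)
    cocs[i, ] <- colSums(pos * q)
    for (a in seq_along(s$atoms)) {
      I <- s$atoms[a]
      J[, , I] <- J[, , I] + diag(3L) * (w[i] * q[a])
    }
  }

  ## unique hops and du_i/ddelta_h accumulation
  hop_key <- function(h) paste(h$donor_o, h$shared_h, h$acceptor_o)
  hops <- list()           # key -> hop
  du <- list()             # key -> numeric(ns), du_i/ddelta_h
  for (i in seq_len(ns)) {
    s <- stateset$states[[i]]
    for (p in seq_along(s$paths)) {
      for (hop in s$paths[[p]]) {
        key <- hop_key(hop)
        if (is.null(hops[[key]])) {
          hops[[key]] <- hop
          du[[key]] <- numeric(ns)
        }
        kh <- lookup_ct_params(params, hop$pair_kind)$k
        du[[key]][i] <- du[[key]][i] + upaths[[i]][p] * kh
      }
    }
  }

  for (key in names(hops)) {
    hop <- hops[[key]]
    dwd <- (du[[key]] - w * sum(du[[key]])) / S    # dw_i/ddelta_h
    Tvec <- colSums(cocs * dwd)                     # sum_i COC_i dw_i/ddelta
    vHD <- frame_disp(frame, hop$donor_o, hop$shared_h)
    vHA <- frame_disp(frame, hop$acceptor_o, hop$shared_h)
    uHD <- vHD / sqrt(sum(vHD^2))
    uHA <- vHA / sqrt(sum(vHA^2))
    J[, , hop$shared_h] <- J[, , hop$shared_h] + Tvec %o% (uHD - uHA)
    J[, , hop$donor_o] <- J[, , hop$donor_o] + Tvec %o% (-uHD)
    J[, , hop$acceptor_o] <- J[, , hop$acceptor_o] + Tvec %o% uHA
  }
  J
}

#' Evaluate the CEC position for a fixed state set
#'
#' Recomputes transfer coordinates, weights and centers of charge on the
#' supplied frame while keeping the state topology fixed — the smooth map
#' whose derivative [cec_gradient()] returns. Useful for finite-difference
#' checks and for evaluating the CEC along short geometry perturbations
#' without re-enumeration.
#'
#' @inheritParams cec_gradient
#' @return The CEC position (3-vector, Angstrom).
#' @export
cec_value <- function(frame, stateset, params = default_ct_params(),
                      charges = default_charge_table()) {
  compute_cec(frame, stateset, weights = NULL, params = params,
              charges = charges)$cec
}

#' Track the CEC along a trajectory
#'
#' Runs topology assignment, state enumeration and the CEC evaluation on
#' every frame of a series.
#'
#' @param series A [cec_frames()] series.
#' @param params A [ct_params()] table.
#' @param charges A [charge_table()].
#' @param acid Optional [acid_spec()].
#' @param max_shell,cutoff Enumeration controls, see [enumerate_states()].
#' @return List of `cec_result` objects, one per frame.
#' @export
track_cec <- function(series, params = default_ct_params(),
                      charges = default_charge_table(), acid = NULL,
                      max_shell = 3L, cutoff = 2.5) {
  lapply(series$frames, function(f) {
    topo <- assign_topology(f, acid = acid)
    states <- enumerate_states(f, topo, max_shell = max_shell,
                               cutoff = cutoff)
    compute_cec(f, states, params = params, charges = charges)
  })
}
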