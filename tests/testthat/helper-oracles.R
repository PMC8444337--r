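## Shared oracles and builders for the suite. Everything here is written
## independently of the package internals it checks.

## Finite-difference Jacobian of the CEC (central differences), the oracle
## for the analytic gradient.
fd_cec_jacobian <- function(frame, stateset, params = default_ct_params(),
                            charges = default_charge_table(), h = 1e-5) {
  J <- array(0, dim = c(3L, 3L, frame$natoms))
  for (I in seq_len(frame$natoms)) {
    for (cc in 1:3) {
      fp <- frame
      fp$positions[I, cc] <- fp$positions[I, cc] + h
      fm <- frame
      fm$positions[I, cc] <- fm$positions[I, cc] - h
      J[, cc, I] <- (cec_value(fp, stateset, params, charges) -
                       cec_value(fm, stateset, params, charges)) / (2 * h)
    }
  }
  J
}

## Relative Jacobian mismatch, scaled by the larger of 1 and the FD norm.
jacobian_rel_err <- function(frame, stateset, ...) {
  Ja <- cec_gradient(frame, stateset, ...)
  Jn <- fd_cec_jacobian(frame, stateset, ...)
  max(abs(Ja - Jn)) / max(1, max(abs(Jn)))
}

## Hand-coded weight oracle: walks every state's hop paths with plain
## loops, recomputing delta and the exponential factor directly from the
## coordinates (no calls into the weight machinery under test).
brute_force_weights <- function(stateset, frame, params) {
  dist3 <- function(i, j) {
    dr <- frame$positions[j, ] - frame$positions[i, ]
    if (!is.null(frame$box)) dr <- dr - frame$box * round(dr / frame$box)
    sqrt(sum(dr^2))
  }
  u <- numeric(length(stateset$states))
  for (i in seq_along(stateset$states)) {
    tot <- 0
    for (path in stateset$states[[i]]$paths) {
      prodf <- 1
      for (hop in path) {
        row <- params[params$pair_kind == hop$pair_kind, ]
        if (nrow(row) == 0) {  # mirrored pair
          parts <- rev(strsplit(hop$pair_kind, "-")[[1]])
          row <- params[params$pair_kind == paste(parts, collapse = "-"), ]
          row$delta0 <- -row$delta0
        }
        delta <- dist3(hop$shared_h, hop$donor_o) -
          dist3(hop$shared_h, hop$acceptor_o)
        prodf <- prodf * exp(row$k * (delta - row$delta0))
      }
      tot <- tot + prodf
    }
    u[i] <- tot
  }
  u / sum(u)
}

## Collinear O-H-O...(H-O)* wire with the bridging protons at prescribed
## O-H distances; used to build states with exact charge-transfer factors.
make_wire_frame <- function(r_oo, r_oh_bridge, oh_len = 0.97) {
  n <- length(r_oh_bridge) + 1L
  elements <- character(0)
  pos <- NULL
  add <- function(el, p) {
    elements <<- c(elements, el)
    pos <<- rbind(pos, p)
  }
  for (i in seq_len(n)) {
    ox <- (i - 1L) * r_oo
    add("O", c(ox, 0, 0))
    if (i < n) add("H", c(ox + r_oh_bridge[i], 0, 0))
    add("H", c(ox, oh_len * cos(i), oh_len * sin(i)))
    if (i %in% c(1L, n)) add("H", c(ox, -oh_len * cos(i), -oh_len * sin(i)))
  }
  cec_frame(elements, pos)
}

## a rigid rotation matrix from an axis/angle
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle)
  sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
}

## minimal single-model PDB text for a water molecule
water_pdb_lines <- function(cryst_angles = c(90, 90, 90)) {
  c(sprintf("CRYST1   15.640   15.640   15.640 %6.2f %6.2f %6.2f P 1           1",
            cryst_angles[1], cryst_angles[2], cryst_angles[3]),
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.970   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.243   0.939   0.000  1.00  0.00           H",
    "END")
}
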