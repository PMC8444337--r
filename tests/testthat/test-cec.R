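test_that("the transfer coordinate is the signed O-H distance difference", {
  f <- cec_frame(c("O", "H", "O"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(2.5, 0, 0)))
  hop <- list(donor_o = 1L, shared_h = 2L, acceptor_o = 3L)
  expect_equal(hop_delta(f, hop), 1.0 - 1.5)
  expect_equal(hop_delta(f, list(donor_o = 3L, shared_h = 2L,
                                 acceptor_o = 1L)), 0.5)
  ## midpoint of a symmetric pair
  fm <- cec_frame(c("O", "H", "O"),
                  rbind(c(0, 0, 0), c(1.25, 0, 0), c(2.5, 0, 0)))
  expect_equal(hop_delta(fm, hop), 0)
  ## coincident atoms are a geometry error
  fc <- cec_frame(c("O", "H", "O"),
                  rbind(c(0, 0, 0), c(0, 0, 0), c(2.5, 0, 0)))
  expect_error(hop_delta(fc, hop), "geometry")
})

test_that("the charge-transfer factor is exponential, unit at delta0, clipped", {
  expect_equal(charge_transfer_factor(0, list(k = 4.234, delta0 = 0)), 1.0)
  expect_equal(charge_transfer_factor(0.5361, list(k = 2.946,
                                                   delta0 = 0.5361)), 1.0)
  expect_equal(charge_transfer_factor(-0.3, list(k = 4.234, delta0 = 0)),
               exp(-1.2702), tolerance = 1e-12)
  d <- seq(-1, 1, by = 0.05)
  fct <- charge_transfer_factor(d, list(k = 2.946, delta0 = 0.5361))
  expect_true(all(diff(fct) > 0))
  ## clipping keeps absurd geometries finite
  expect_equal(charge_transfer_factor(1e6, list(k = 4.234, delta0 = 0)),
               exp(50))
  expect_equal(charge_transfer_factor(-1e6, list(k = 4.234, delta0 = 0)),
               exp(-50))
})

test_that("state weights are normalized path products", {
  params <- default_ct_params()
  ## equal sharing: f = 1 -> (1/2, 1/2)
  f_eq <- make_wire_frame(2.6, 1.3)
  st_eq <- enumerate_states(f_eq, assign_topology(f_eq))
  expect_equal(state_weights(st_eq, f_eq, params), c(0.5, 0.5),
               tolerance = 1e-12)

  ## f = 0.25 -> (0.8, 0.2): place the proton so k*delta = ln(1/4)
  delta <- log(0.25) / 4.234
  f_q <- make_wire_frame(2.6, (2.6 + delta) / 2)
  st_q <- enumerate_states(f_q, assign_topology(f_q))
  expect_equal(state_weights(st_q, f_q, params), c(0.8, 0.2),
               tolerance = 1e-9)

  ## linear three-state chain with both factors 1 -> thirds
  f_3 <- make_wire_frame(2.6, c(1.3, 1.3))
  st_3 <- enumerate_states(f_3, assign_topology(f_3))
  expect_length(st_3, 3L)
  expect_equal(state_weights(st_3, f_3, params), rep(1 / 3, 3L),
               tolerance = 1e-12)

  ## unknown pair kinds are a configuration error naming the kind
  st_bad <- st_eq
  st_bad$states[[2L]]$paths[[1L]][[1L]]$pair_kind <- "h3o-methanol"
  expect_error(state_weights(st_bad, f_eq, params), "h3o-methanol")
})

test_that("weights agree with the hand-coded path-product oracle", {
  params <- default_ct_params()
  cases <- list(
    make_wire_frame(2.6, 1.15),
    make_wire_frame(2.55, c(1.2, 1.05)),
    make_wire_frame(2.6, c(1.28, 1.22, 1.1)),
    perturb_frame(make_wire_frame(2.6, c(1.3, 1.3)), sd = 0.03, seed = 5L))
  for (f in cases) {
    st <- enumerate_states(f, assign_topology(f))
    expect_lte(length(st), 4L)
    expect_equal(state_weights(st, f, params),
                 brute_force_weights(st, f, params), tolerance = 1e-12)
  }
})

test_that("the center of charge follows the excess-charge distribution", {
  z <- make_zundel_scan(n_frames = 3L)$frames[[1L]]
  st <- enumerate_states(z, assign_topology(z))
  root <- st$states[[1L]]
  hpos <- z$positions[setdiff(root$atoms, 1L), ]

  ## all excess charge on the hydrogens -> centroid of the 3 H
  ct_h <- charge_table(list(hydronium = c(O = 0, H = 1 / 3)))
  expect_equal(center_of_charge(z, root, ct_h), colMeans(hpos),
               tolerance = 1e-12)

  ## all excess charge on one atom -> that atom's position
  ct_o <- charge_table(list(hydronium = c(O = 1, H = 0)))
  expect_equal(center_of_charge(z, root, ct_o), z$positions[1L, ],
               tolerance = 1e-12)

  ## planar symmetric hydronium with equal charges sits on the oxygen
  ang <- 2 * pi * (0:2) / 3
  sym <- cec_frame(c("O", "H", "H", "H"),
                   rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0) * 0.97))
  st_s <- enumerate_states(sym, assign_topology(sym))
  expect_equal(center_of_charge(sym, st_s$states[[1L]],
                                default_charge_table()),
               c(0, 0, 0), tolerance = 1e-12)

  ## role missing from the table is a configuration error
  expect_error(center_of_charge(z, root,
                                charge_table(list(hydronium = c(O = 1)))),
               "lacks role")
  ## charges not summing to +1 e are rejected
  expect_error(center_of_charge(z, root,
                                charge_table(list(hydronium = c(O = 0.5,
                                                                H = 0.5)))),
               "sum")
})

test_that("the CEC is the weighted average of diabatic centers", {
  params <- default_ct_params()
  charges <- default_charge_table()

  ## single state: CEC = COC
  iso <- make_ideal_network(branching = c(0, 0, 0))
  st1 <- enumerate_states(iso, assign_topology(iso))
  r1 <- compute_cec(iso, st1, params = params, charges = charges)
  expect_equal(r1$cec, center_of_charge(iso, st1$states[[1L]], charges))
  expect_equal(r1$n_states, 1L)

  ## symmetric Zundel: CEC on the O-O bisecting plane
  zs <- make_zundel_scan(r_oo = 2.6, n_frames = 3L)$frames[[3L]]
  sts <- enumerate_states(zs, assign_topology(zs))
  rs <- compute_cec(zs, sts, params = params, charges = charges)
  expect_equal(rs$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(rs$cec[1L], 1.3, tolerance = 1e-9)

  ## explicit (0.8, 0.2) mixture reproduces the weighted average
  delta <- log(0.25) / 4.234
  fq <- make_wire_frame(2.6, (2.6 + delta) / 2)
  stq <- enumerate_states(fq, assign_topology(fq))
  w <- state_weights(stq, fq, params)
  cocs <- t(vapply(stq$states, function(s)
    center_of_charge(fq, s, charges), numeric(3L)))
  rq <- compute_cec(fq, stq, params = params, charges = charges)
  expect_equal(rq$cec, colSums(w * cocs), tolerance = 1e-12)
  expect_equal(rq$cec, 0.8 * cocs[1L, ] + 0.2 * cocs[2L, ],
               tolerance = 1e-9)
})

test_that("per-atom excess charges conserve +1 e and give the dipole identity", {
  params <- default_ct_params()
  base <- make_ideal_network()
  for (seed in 1:25) {
    f <- perturb_frame(base, sd = 0.04, seed = seed)
    st <- enumerate_states(f, assign_topology(f))
    r <- compute_cec(f, st, params = params)
    expect_lt(abs(sum(r$weights) - 1), 1e-12)
    expect_lt(abs(sum(r$per_atom_excess) - 1), 1e-9)
    expect_lt(max(abs(r$dipole - r$cec)), 1e-9)
  }
  ## single-state species reproduces the charge table exactly
  iso <- make_ideal_network(branching = c(0, 0, 0))
  st1 <- enumerate_states(iso, assign_topology(iso))
  ed <- excess_charge_dipole(iso, st1, params = params)
  expect_equal(unname(ed$per_atom_excess[iso$elements == "O"]), 0.25)
  expect_equal(unname(ed$per_atom_excess[iso$elements == "H"]), rep(0.25, 3))
})

test_that("atoms outside the three shells cannot move the CEC", {
  net <- make_ideal_network()
  far_water <- rbind(c(14, 0, 0), c(14.97, 0, 0), c(13.76, 0.9, 0))
  f <- cec_frame(c(net$elements, "O", "H", "H"),
                 rbind(net$positions, far_water))
  topo <- assign_topology(f)
  st <- enumerate_states(f, topo)
  expect_length(st, 22L)
  r0 <- compute_cec(f, st)
  f2 <- f
  f2$positions[f$natoms - 2L, ] <- f2$positions[f$natoms - 2L, ] + c(0, 5, 1)
  f2$positions[f$natoms, ] <- f2$positions[f$natoms, ] + c(1, 1, 1)
  st2 <- enumerate_states(f2, assign_topology(f2))
  r2 <- compute_cec(f2, st2)
  expect_identical(r2$cec, r0$cec)
  expect_equal(r0$per_atom_excess[(f$natoms - 2L):f$natoms], rep(0, 3L))
})

test_that("the CEC moves continuously through the equal-sharing point", {
  ## shared proton stepped 0.01 Angstrom per frame across delta = 0
  scan <- make_zundel_scan(r_oo = 2.6, n_frames = 41L)
  results <- track_cec(scan)
  cecs <- t(vapply(results, `[[`, numeric(3L), "cec"))
  for (i in 2:nrow(cecs)) {
    datom <- max(sqrt(rowSums((scan$frames[[i]]$positions -
                                 scan$frames[[i - 1L]]$positions)^2)))
    dcec <- sqrt(sum((cecs[i, ] - cecs[i - 1L, ])^2))
    expect_lte(dcec, 10 * datom)
  }
  ## and along a full Grotthuss hand-off
  sh <- make_shuttle_trajectory(4L, 2L, 40L)
  rs <- track_cec(sh)
  cs <- t(vapply(rs, `[[`, numeric(3L), "cec"))
  for (i in 2:nrow(cs)) {
    datom <- max(sqrt(rowSums((sh$frames[[i]]$positions -
                                 sh$frames[[i - 1L]]$positions)^2)))
    expect_lte(sqrt(sum((cs[i, ] - cs[i - 1L, ])^2)), 10 * datom)
  }
})

test_that("periodic boxes are honoured: wrapped species give the same CEC", {
  z <- make_zundel_scan(n_frames = 5L)$frames[[2L]]
  zb <- cec_frame(z$elements, z$positions, box = c(10, 10, 10))
  r0 <- compute_cec(zb, enumerate_states(zb, assign_topology(zb)))
  zw <- zb
  zw$positions[1L, ] <- zw$positions[1L, ] + c(10, -10, 10)  # wrap the donor O
  rw <- compute_cec(zw, enumerate_states(zw, assign_topology(zw)))
  expect_equal(rw$weights, r0$weights, tolerance = 1e-12)
  ## the CEC agrees up to a lattice translation
  expect_equal((rw$cec - r0$cec) %% 10, c(0, 0, 0), tolerance = 1e-9)
})
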