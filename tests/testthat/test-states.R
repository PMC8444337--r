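test_that("state counts match the hop-tree combinatorics", {
  iso <- make_ideal_network(branching = c(0, 0, 0))
  expect_length(enumerate_states(iso, assign_topology(iso)), 1L)

  z <- make_zundel_scan(n_frames = 3L)$frames[[1L]]
  expect_length(enumerate_states(z, assign_topology(z)), 2L)

  net1 <- make_ideal_network(branching = c(3, 0, 0))
  expect_length(enumerate_states(net1, assign_topology(net1)), 4L)

  net <- make_ideal_network()     # 1 + 3 + 6 + 12
  st <- enumerate_states(net, assign_topology(net))
  expect_length(st, 22L)
  expect_equal(as.integer(table(vapply(st$states, `[[`, integer(1), "shell"))),
               c(1L, 3L, 6L, 12L))
})

test_that("state count is monotone in cutoff and shell depth", {
  net <- make_ideal_network()
  topo <- assign_topology(net)
  counts_shell <- vapply(0:3, function(ms)
    length(enumerate_states(net, topo, max_shell = ms)), integer(1))
  expect_equal(counts_shell[1L], 1L)   # shell 0 is always just the root
  expect_true(all(diff(counts_shell) >= 0))

  counts_cut <- vapply(c(1.0, 1.7, 2.5, 3.0), function(cf)
    length(enumerate_states(net, topo, cutoff = cf)), integer(1))
  expect_true(all(diff(counts_cut) >= 0))
  expect_equal(counts_cut[1L], 1L)     # below the H-bond length: root only
})

test_that("paths are chained simple hop sequences with shell = length", {
  net <- perturb_frame(make_ideal_network(), sd = 0.02, seed = 11L)
  topo <- assign_topology(net)
  st <- enumerate_states(net, topo)
  for (s in st$states) {
    for (path in s$paths) {
      expect_length(path, s$shell)
      if (length(path) > 1L) {
        ## the next hop's donor O belongs to this hop's acceptor molecule
        for (i in seq_len(length(path) - 1L))
          expect_identical(path[[i]]$acceptor_mol,
                           topo$mol_of_o[path[[i + 1L]]$donor_o])
      }
      ## simple path: no molecule revisited
      mols <- vapply(path, `[[`, integer(1), "acceptor_mol")
      expect_false(anyDuplicated(mols) > 0)
    }
  }
})

test_that("enumeration is invariant under rigid motions and lattice shifts", {
  net <- make_ideal_network()
  topo <- assign_topology(net)
  n0 <- length(enumerate_states(net, topo))

  shifted <- net
  shifted$positions <- sweep(net$positions, 2L, c(3.2, -1.1, 0.7), `+`)
  expect_equal(length(enumerate_states(shifted, assign_topology(shifted))), n0)

  R <- rotation_matrix(c(1, 2, 3), 1.1)
  rotated <- net
  rotated$positions <- net$positions %*% t(R)
  expect_equal(length(enumerate_states(rotated, assign_topology(rotated))), n0)

  ## periodic frame: translating one molecule by a lattice vector changes
  ## nothing, and the weights agree too
  z <- make_zundel_scan(n_frames = 5L)$frames[[2L]]
  zb <- cec_frame(z$elements, z$positions, box = c(12, 12, 12))
  st0 <- enumerate_states(zb, assign_topology(zb))
  w0 <- state_weights(st0, zb, default_ct_params())
  zshift <- zb
  zshift$positions[5:7, 1L] <- zshift$positions[5:7, 1L] + 12
  st1 <- enumerate_states(zshift, assign_topology(zshift))
  expect_equal(length(st1), length(st0))
  expect_equal(state_weights(st1, zshift, default_ct_params()), w0,
               tolerance = 1e-12)
})

test_that("ring-closure duplicates can be merged without changing the CEC", {
  ## a 4-molecule diamond: the root donates to two waters that both donate
  ## to the same far acceptor -> two simple paths reach one molecule
  oh <- 0.97
  y <- 1.4
  x2 <- 2.2
  elements <- c("O", "H", "H", "H",
                "O", "H", "H",
                "O", "H", "H",
                "O", "H", "H")
  pos <- rbind(
    c(0, 0, 0), c(oh * 0.83, y * 0.6, 0), c(oh * 0.83, -y * 0.6, 0),
    c(-oh, 0, 0),
    c(x2, y, 0), c(x2 + 0.8, y * 0.55, 0), c(x2, y + oh, 0),
    c(x2, -y, 0), c(x2 + 0.8, -y * 0.55, 0), c(x2, -y - oh, 0),
    c(x2 + 2.2, 0, 0), c(x2 + 2.2 + oh, 0.4, 0), c(x2 + 2.2 + oh, -0.4, 0))
  f <- cec_frame(elements, pos)
  topo <- assign_topology(f)
  st <- enumerate_states(f, topo)
  mols <- vapply(st$states, `[[`, integer(1), "mol")
  expect_gt(sum(duplicated(mols)), 0L)

  merged <- enumerate_states(f, topo, merge_ring_paths = TRUE)
  expect_lt(length(merged), length(st))
  expect_equal(sum(vapply(merged$states, function(s) length(s$paths),
                          integer(1))),
               length(st$states))
  r1 <- compute_cec(f, st)
  r2 <- compute_cec(f, merged)
  expect_equal(r1$cec, r2$cec, tolerance = 1e-12)
})
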