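## Synthetic-geometry generators. These define the study conditions every
## stage is exercised under: idealized internal geometries (0.97 Angstrom
## O-H bonds, tetrahedral angles) are used throughout because the CEC math
## depends only on the distances entering the transfer coordinate and on the
## species atom positions.

## orthonormal frame perpendicular to a unit vector
perp_frame <- function(u) {
  ref <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

#' Idealized fully hydrogen-bonded network around a hydronium
#'
#' Builds a ring-free tree: a central hydronium donates `branching[1]`
#' hydrogen bonds, each first-shell water donates `branching[2]` onward,
#' and so on; all donated H...O acceptor distances equal `hbond_len`.
#' Waters branch along tetrahedral directions in a fixed orientation about
#' each incoming bond, which keeps branches from colliding (the defaults
#' give a minimum nonbonded distance of about 1.6 Angstrom and no stray
#' H...O contact within the 2.5 Angstrom hydrogen-bond criterion). With the
#' default branching `(3, 2, 2)` the three-shell state enumeration resolves
#' 1 + 3 + 6 + 12 = 22 states, in the middle of the 20-30 states typical of
#' a condensed-phase excess proton.
#'
#' @param branching Integer vector: hydrogen bonds donated by the root and
#'   by each subsequent shell's waters (root at most 3, waters at most 2).
#' @param hbond_len Donated H...O distance (Angstrom), default 1.6.
#' @param oh_len Covalent O-H length (Angstrom), default 0.97.
#' @return A [cec_frame()] (no box).
#' @export
make_ideal_network <- function(branching = c(3L, 2L, 2L), hbond_len = 1.6,
                               oh_len = 0.97) {
  branching <- as.integer(branching)
  if (any(branching < 0)) stop("branching must be non-negative")
  if (branching[1L] > 3L) stop("the hydronium donates at most 3 hydrogen bonds")
  if (length(branching) > 1L && any(branching[-1L] > 2L))
    stop("waters donate at most 2 hydrogen bonds")
  step <- oh_len + hbond_len
  ct <- -1 / 3                       # cos of the tetrahedral angle
  st <- sqrt(1 - ct^2)
  elements <- "O"
  pos <- matrix(0, 1L, 3L)
  add_atom <- function(el, p) {
    elements <<- c(elements, el)
    pos <<- rbind(pos, p)
    nrow(pos)
  }
  ## hydronium: three O-H bonds in a trigonal pyramid about +z
  zax <- c(0, 0, 1)
  fr <- perp_frame(zax)
  queue <- list()
  for (j in 0:2) {
    ph <- 2 * pi * j / 3
    d <- ct * zax + st * (cos(ph) * fr$e1 + sin(ph) * fr$e2)
    add_atom("H", d * oh_len)
    if (j < branching[1L]) {
      oI <- add_atom("O", d * step)
      queue[[length(queue) + 1L]] <- list(o = oI, u = d, shell = 1L)
    }
  }
  while (length(queue)) {
    nd <- queue[[1L]]
    queue <- queue[-1L]
    b <- if (nd$shell < length(branching)) branching[nd$shell + 1L] else 0L
    fr <- perp_frame(nd$u)
    phi0 <- 0
    for (j in 0:1) {                 # each water carries two hydrogens
      ph <- phi0 + 2 * pi * j / 3
      d <- ct * (-nd$u) + st * (cos(ph) * fr$e1 + sin(ph) * fr$e2)
      add_atom("H", pos[nd$o, ] + d * oh_len)
      if (j < b) {
        oI <- add_atom("O", pos[nd$o, ] + d * step)
        queue[[length(queue) + 1L]] <- list(o = oI, u = d,
                                            shell = nd$shell + 1L)
      }
    }
  }
  frame <- cec_frame(elements, pos)
  check_no_clash(frame)
  frame
}

check_no_clash <- function(frame, min_dist = 0.8, bonded_tol = 1.05) {
  D <- as.matrix(stats::dist(frame$positions))
  diag(D) <- Inf
  ## covalent O-H pairs are allowed below min_dist
  oh <- outer(frame$elements == "O", frame$elements == "H", `&`)
  bonded <- (oh | t(oh)) & D < bonded_tol * 1.05
  if (min(D[!bonded]) < min_dist)
    stop("geometry error: nonbonded atoms closer than ", min_dist,
         " Angstrom (", format(min(D[!bonded]), digits = 4), ")")
  invisible(TRUE)
}

#' Zundel-like proton scan between two waters
#'
#' Frames in which the shared proton of an O...H...O pair moves linearly
#' from a donor-bound position (O-H = 0.9 Angstrom) to the O-O midpoint,
#' where the transfer coordinate is zero and the CEC lies on the bisecting
#' plane by symmetry. Spectator hydrogens are idealized and static.
#'
#' @param r_oo O-O separation (Angstrom, >= 2.2).
#' @param n_frames Number of frames in the scan.
#' @param dt Frame spacing (fs).
#' @return A [cec_frames()] series.
#' @export
make_zundel_scan <- function(r_oo = 2.6, n_frames = 21L, dt = 0.5) {
  if (r_oo < 2.2) stop("r_oo must be >= 2.2 Angstrom")
  r_oh <- seq(0.9, r_oo / 2, length.out = n_frames)
  frames <- lapply(seq_len(n_frames), function(i) {
    zundel_frame(r_oo, r_oh[i], time = (i - 1L) * dt)
  })
  cec_frames(frames, dt = dt)
}

## one O...H...O geometry: donor at origin with two spectator H (xz plane),
## shared H on the +x axis, acceptor water at (r_oo, 0, 0) with two
## spectator H (xy plane)
zundel_frame <- function(r_oo, r_oh, time = NA_real_, oh_len = 0.97) {
  a <- 115 * pi / 180
  donor_h <- rbind(c(cos(a), 0, sin(a)), c(cos(a), 0, -sin(a))) * oh_len
  ## acceptor spectators mirror the donor ones in x (and lie in the xy
  ## plane), so the symmetric geometry is an exact mirror pair
  acc_h <- sweep(rbind(c(-cos(a), sin(a), 0), c(-cos(a), -sin(a), 0)) * oh_len,
                 2L, c(r_oo, 0, 0), `+`)
  cec_frame(c("O", "H", "H", "H", "O", "H", "H"),
            rbind(c(0, 0, 0), c(r_oh, 0, 0), donor_h,
                  c(r_oo, 0, 0), acc_h),
            time = time)
}

#' Sinusoidal 1-D test track for spectrum checks
#'
#' A position track oscillating at a known wavenumber along x, with
#' optional seeded Gaussian noise; the spectrum of such a track must peak
#' within one grid step of `freq_cm`.
#'
#' @param freq_cm Oscillation wavenumber (cm^-1); must be below the Nyquist
#'   limit `1/(2 dt)` expressed in cm^-1.
#' @param dt_fs Sampling interval (fs).
#' @param n Number of samples.
#' @param amplitude Oscillation amplitude (Angstrom).
#' @param noise Gaussian noise s.d. added to every coordinate (Angstrom).
#' @param seed Integer seed fixing the noise.
#' @return An `n x 3` matrix of positions (Angstrom).
#' @export
make_oscillating_track <- function(freq_cm, dt_fs = 0.5, n = 4096L,
                                   amplitude = 0.05, noise = 0, seed = 1L) {
  nyquist_cm <- CM1_PER_INV_FS / (2 * dt_fs)
  if (any(freq_cm >= nyquist_cm))
    stop("freq_cm (", max(freq_cm), ") violates the Nyquist limit (",
         format(nyquist_cm, digits = 6), " cm^-1 at dt = ", dt_fs, " fs)")
  t <- (seq_len(n) - 1L) * dt_fs
  x <- rowSums(vapply(freq_cm, function(f)
    amplitude * sin(2 * pi * (f / CM1_PER_INV_FS) * t), numeric(n)))
  track <- cbind(x, 0, 0)
  if (noise > 0) {
    set.seed(seed)
    track <- track + matrix(stats::rnorm(3L * n, sd = noise), n, 3L)
  }
  track
}

#' Grotthuss shuttle trajectory along a water wire
#'
#' A linear wire of waters along x; the excess proton starts on the first
#' molecule and is handed off molecule-to-molecule: in each hop the
#' bridging hydrogen moves from 1.0 Angstrom off its donor oxygen to
#' 1.0 Angstrom off the acceptor, following a smooth minimum-jerk profile
#' so continuity checks are meaningful at every frame. All O-H distances
#' stay within [0.9, 1.8] Angstrom and the identity of the protonated
#' species changes exactly `hops` times.
#'
#' @param n_waters Number of waters in the wire (>= hops + 1).
#' @param hops Number of proton hand-offs.
#' @param frames_per_hop Frames spent on each hand-off.
#' @param r_oo O-O spacing along the wire (Angstrom).
#' @param dt Frame spacing (fs).
#' @return A [cec_frames()] series.
#' @export
make_shuttle_trajectory <- function(n_waters = 4L, hops = 2L,
                                    frames_per_hop = 40L, r_oo = 2.55,
                                    dt = 0.5) {
  n_waters <- as.integer(n_waters)
  hops <- as.integer(hops)
  if (n_waters < hops + 1L) stop("wire needs at least hops + 1 molecules")
  ox <- (seq_len(n_waters) - 1L) * r_oo
  oh <- 0.97
  ## static atoms per molecule: O, a bridging H toward the next molecule
  ## (for all but the last), and perpendicular H(s) completing the water
  elements <- character(0)
  base_pos <- NULL
  bridge_h <- integer(n_waters)      # bridging H index per molecule
  perp <- function(i, sgn, tilt = 90) {
    a <- tilt * pi / 180
    c(ox[i] + oh * cos(a), sgn * oh * sin(a) * cos(i), oh * sin(a) * sin(i))
  }
  add <- function(el, p) {
    elements <<- c(elements, el)
    base_pos <<- rbind(base_pos, p)
    nrow(base_pos)
  }
  for (i in seq_len(n_waters)) {
    add("O", c(ox[i], 0, 0))
    if (i < n_waters)
      bridge_h[i] <- add("H", c(ox[i] + 1.0, 0, 0))
    add("H", perp(i, +1))
    if (i == n_waters) add("H", perp(i, -1))
  }
  ## the extra proton starts on molecule 1, opposite the bridge
  extra <- add("H", perp(1L, -1))

  minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
  n_frames <- hops * frames_per_hop + 1L
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pos <- base_pos
    k <- f - 1L
    hop_i <- min(hops, k %/% frames_per_hop + 1L)
    done <- if (k >= hops * frames_per_hop) hops else hop_i - 1L
    ## completed hops: bridging H rests 1.0 Angstrom before its acceptor
    if (done >= 1L) for (m in seq_len(done))
      pos[bridge_h[m], 1L] <- ox[m + 1L] - 1.0
    if (done < hops) {
      s <- minjerk((k - (hop_i - 1L) * frames_per_hop) / frames_per_hop)
      pos[bridge_h[hop_i], 1L] <- ox[hop_i] + 1.0 +
        s * (r_oo - 2.0)
    }
    frames[[f]] <- cec_frame(elements, pos, time = (f - 1L) * dt)
  }
  cec_frames(frames, dt = dt)
}

#' Toy neutral-acid cluster
#'
#' A carboxyl group (C, two oxygens, the acid proton on the first oxygen)
#' hydrogen-bonded to a short chain of waters: the protonated acid is the
#' root state and each water extends the hop network by one shell.
#'
#' @param n_waters Number of waters chained off the acid proton.
#' @param r_oo O...O spacing (Angstrom).
#' @param r_oh Acid O-H distance (Angstrom).
#' @return List with `frame` ([cec_frame()]) and `acid` ([acid_spec()]).
#' @export
make_acid_water_cluster <- function(n_waters = 2L, r_oo = 2.6, r_oh = 1.0) {
  oh <- 0.97
  elements <- c("O", "H", "C", "O")
  cdir <- c(cos(110 * pi / 180), sin(110 * pi / 180), 0)
  cpos <- 1.25 * cdir
  ## carbonyl O roughly anti to the C-O1 bond, in plane
  o2 <- cpos + 1.25 * c(cos(155 * pi / 180), sin(155 * pi / 180), 0)
  pos <- rbind(c(0, 0, 0), c(r_oh, 0, 0), cpos, o2)
  for (i in seq_len(n_waters)) {
    ox <- i * r_oo
    pos <- rbind(pos, c(ox, 0, 0))
    elements <- c(elements, "O")
    if (i < n_waters) {
      pos <- rbind(pos, c(ox + 1.0, 0, 0))
      elements <- c(elements, "H")
    }
    a <- 115 * pi / 180
    pos <- rbind(pos, c(ox + oh * cos(a), oh * sin(a) * cos(i),
                        oh * sin(a) * sin(i)))
    elements <- c(elements, "H")
    if (i == n_waters) {
      pos <- rbind(pos, c(ox + oh * cos(a), -oh * sin(a) * cos(i),
                          -oh * sin(a) * sin(i)))
      elements <- c(elements, "H")
    }
  }
  list(frame = cec_frame(elements, pos),
       acid = acid_spec(o_atoms = c(1L, 4L), group_atoms = c(1L, 3L, 4L)))
}

#' Randomly perturbed copy of a frame
#'
#' Adds seeded isotropic Gaussian jitter to every coordinate — the standard
#' way the test-suite turns one idealized fixture into an ensemble of
#' "random fixture frames".
#'
#' @param frame A [cec_frame()].
#' @param sd Jitter standard deviation (Angstrom).
#' @param seed Integer seed.
#' @return A perturbed [cec_frame()].
#' @export
perturb_frame <- function(frame, sd = 0.04, seed = 1L) {
  set.seed(seed)
  frame$positions <- frame$positions +
    matrix(stats::rnorm(3L * frame$natoms, sd = sd), frame$natoms, 3L)
  frame
}
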