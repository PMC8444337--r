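#' Enumerate diabatic proton-hop states
#'
#' Breadth-first expansion of the bonding topologies reachable from the
#' protonated root species by Grotthuss hops through up to `max_shell`
#' solvation shells of hydrogen-bond acceptors (H...O distance within
#' `cutoff`). The root topology is state 1; every hop transfers the shared
#' hydrogen to the acceptor molecule and produces a child state one shell
#' further out. A path never revisits a molecule it has already passed
#' through (which also forbids the transferred proton from hopping straight
#' back to its donor); two branches may still reach the same molecule along
#' distinct simple paths, in which case both states are kept and their
#' weights add under normalization — set `merge_ring_paths = TRUE` to
#' collapse such duplicates into a single state carrying several paths.
#'
#' Three shells are the default because state populations already die off in
#' the fourth shell; in liquid-water networks this typically resolves
#' 20-30 states around a hydrated excess proton.
#'
#' @param frame A [cec_frame()].
#' @param topology The [assign_topology()] result.
#' @param max_shell Maximum number of hops from the root (default 3).
#' @param cutoff Hydrogen-bond H...O criterion (Angstrom, default 2.5).
#' @param merge_ring_paths Collapse states sharing the same protonated
#'   species into one multi-path state (default `FALSE`).
#' @return Object of class `cec_states`: a list of states, each with
#'   `id`, `mol`, `kind`, `atoms` (the protonated species), `shell`,
#'   `paths` (list of hop chains from the root) and `h_assign`.
#' @export
enumerate_states <- function(frame, topology, max_shell = 3L, cutoff = 2.5,
                             merge_ring_paths = FALSE) {
  max_shell <- as.integer(max_shell)
  if (max_shell < 0L) stop("max_shell must be >= 0")
  root_mol <- topology$root_mol
  h_assign0 <- base_h_assign(topology)
  root <- list(id = 1L, mol = root_mol,
               kind = topology$molecules[[root_mol]]$kind,
               atoms = topology$molecules[[root_mol]]$atoms,
               shell = 0L, paths = list(list()),
               h_assign = h_assign0, visited = root_mol)
  states <- list(root)
  queue <- list(root)
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    if (s$shell >= max_shell) next
    hops <- state_hops(frame, topology, s$mol, s$kind, s$h_assign,
                       cutoff = cutoff, forbidden_mols = s$visited)
    for (hop in hops) {
      amol <- hop$acceptor_mol
      h_assign <- s$h_assign
      h_assign[hop$shared_h] <- amol
      child <- list(
        id = length(states) + 1L,
        mol = amol,
        kind = protonated_kind(topology$molecules[[amol]]$kind),
        atoms = sort(c(topology$molecules[[amol]]$heavy_atoms,
                       which(h_assign == amol))),
        shell = s$shell + 1L,
        paths = list(c(s$paths[[1L]], list(hop))),
        h_assign = h_assign,
        visited = c(s$visited, amol))
      states[[child$id]] <- child
      queue[[length(queue) + 1L]] <- child
    }
  }
  if (merge_ring_paths) states <- merge_duplicate_species(states)
  structure(list(states = states, root_id = 1L, max_shell = max_shell,
                 cutoff = cutoff, natoms = frame$natoms),
            class = "cec_states")
}

merge_duplicate_species <- function(states) {
  keys <- vapply(states, function(s) paste(s$atoms, collapse = ","),
                 character(1))
  out <- list()
  for (i in seq_along(states)) {
    j <- match(keys[i], vapply(out, function(s)
      paste(s$atoms, collapse = ","), character(1)))
    if (is.na(j)) {
      s <- states[[i]]
      s$id <- length(out) + 1L
      out[[s$id]] <- s
    } else {
      out[[j]]$paths <- c(out[[j]]$paths, states[[i]]$paths)
    }
  }
  out
}

#' @export
print.cec_states <- function(x, ...) {
  shells <- vapply(x$states, `[[`, integer(1), "shell")
  cat("CEC state set: ", length(x$states), " diabatic states (root + shells ",
      paste(table(shells[shells > 0]), collapse = "/"),
      "), cutoff ", x$cutoff, " Angstrom\n", sep = "")
  invisible(x)
}

#' @export
length.cec_states <- function(x) length(x$states)

#' Serialize a state set to a JSON-ready list
#'
#' @param stateset A `cec_states` object.
#' @return A list (one entry per state) of id, shell, protonated atoms and
#'   hop paths, suitable for `jsonlite::write_json()`.
#' @export
states_as_list <- function(stateset) {
  lapply(stateset$states, function(s) list(
    id = s$id, shell = s$shell, kind = s$kind, atoms = s$atoms,
    paths = lapply(s$paths, function(p) lapply(p, function(h)
      list(donor_o = h$donor_o, shared_h = h$shared_h,
           acceptor_o = h$acceptor_o, pair_kind = h$pair_kind)))))
}
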