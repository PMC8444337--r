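#' Declare an acid group
#'
#' Weak-acid (e.g. glutamate carboxyl) groups are declared explicitly by
#' listing their heavy atoms and, among those, the oxygens that can carry or
#' accept the acid proton. Both carboxyl oxygens are potential proton
#' carriers.
#'
#' @param o_atoms Atom indices of the acid oxygens.
#' @param group_atoms Atom indices of all heavy atoms of the group
#'   (defaults to `o_atoms`; include the carboxyl carbon so the species'
#'   charge table can place excess charge on it).
#' @param kind Base label used to build pair kinds (default `"glu"`, giving
#'   hop pair kinds `"glu-water"` and `"water-glu"`) and, with
#'   `-neutral`/`-anion` suffixes, the species kind.
#' @return Object of class `acid_spec`.
#' @export
acid_spec <- function(o_atoms, group_atoms = o_atoms, kind = "glu") {
  o_atoms <- as.integer(o_atoms)
  group_atoms <- as.integer(union(group_atoms, o_atoms))
  if (!length(o_atoms)) stop("acid_spec needs at least one oxygen atom")
  structure(list(o_atoms = o_atoms, group_atoms = group_atoms, kind = kind),
            class = "acid_spec")
}

#' Assign a covalent bonding topology to a frame
#'
#' Every hydrogen is assigned to its nearest oxygen under the minimum-image
#' convention (ties within 1e-9 Angstrom broken by lower atom index).
#' Molecules are then labelled by hydrogen count per oxygen (water = 2,
#' hydronium = 3) and, for a declared acid group, by the protonation of the
#' acid oxygens. Exactly one species must carry the excess proton: a
#' hydronium or a neutral (protonated) acid. That species becomes the root
#' state of the diabatic-state enumeration.
#'
#' @param frame A [cec_frame()] containing O and H atoms.
#' @param acid Optional [acid_spec()] declaring an acid group.
#' @return Object of class `cec_topology` with fields `molecules`,
#'   `h_to_heavy`, `mol_of_o`, `root_mol`, `acid`.
#' @export
assign_topology <- function(frame, acid = NULL) {
  o_idx <- which(frame$elements == "O")
  h_idx <- which(frame$elements == "H")
  if (!length(o_idx) || !length(h_idx))
    stop("frame must contain O and H atoms")
  if (!is.null(acid) && !inherits(acid, "acid_spec"))
    stop("acid must be an acid_spec object")

  ## nearest-O assignment for every H (minimum image), ties -> lower index
  h_to_heavy <- rep(NA_integer_, frame$natoms)
  for (h in h_idx) {
    d <- vapply(o_idx, function(o) frame_dist(frame, h, o), numeric(1))
    best <- min(d)
    h_to_heavy[h] <- o_idx[which(d <= best + 1e-9)[1L]]
  }

  acid_heavy <- if (is.null(acid)) integer(0) else acid$group_atoms
  acid_o <- if (is.null(acid)) integer(0) else acid$o_atoms
  water_o <- setdiff(o_idx, acid_heavy)

  molecules <- list()
  mol_of_o <- rep(NA_integer_, frame$natoms)
  mid <- 0L
  for (o in water_o) {
    mid <- mid + 1L
    hs <- h_idx[h_to_heavy[h_idx] == o]
    kind <- switch(as.character(length(hs)),
                   "2" = "water", "3" = "hydronium", NA_character_)
    if (is.na(kind))
      stop("unsupported input: oxygen atom ", o, " carries ", length(hs),
           " hydrogens (only water and hydronium species are supported)")
    molecules[[mid]] <- list(id = mid, kind = kind, heavy_atoms = o,
                             o_atoms = o, h_atoms = hs,
                             atoms = sort(c(o, hs)))
    mol_of_o[o] <- mid
  }
  if (!is.null(acid)) {
    mid <- mid + 1L
    hs <- h_idx[h_to_heavy[h_idx] %in% acid_o]
    if (length(hs) > 1L)
      stop("unsupported input: acid group carries ", length(hs),
           " protons (at most one is supported)")
    kind <- if (length(hs)) paste0("acid-neutral") else "acid-anion"
    molecules[[mid]] <- list(id = mid, kind = kind,
                             heavy_atoms = acid$group_atoms,
                             o_atoms = acid_o, h_atoms = hs,
                             atoms = sort(c(acid$group_atoms, hs)))
    mol_of_o[acid_o] <- mid
  }

  prot <- which(vapply(molecules, function(m)
    m$kind %in% c("hydronium", "acid-neutral"), logical(1)))
  if (!length(prot))
    stop("no excess proton: no hydronium and no protonated acid found")
  if (length(prot) > 1L)
    stop("unsupported input: more than one protonated species (molecules ",
         paste(prot, collapse = ", "), ")")

  structure(list(molecules = molecules, h_to_heavy = h_to_heavy,
                 mol_of_o = mol_of_o, root_mol = prot, acid = acid,
                 natoms = frame$natoms),
            class = "cec_topology")
}

#' @export
print.cec_topology <- function(x, ...) {
  kinds <- vapply(x$molecules, `[[`, character(1), "kind")
  cat("CEC topology:", length(x$molecules), "molecules (",
      paste(names(table(kinds)), table(kinds), sep = ":", collapse = " "),
      "), root =", x$root_mol, "(", kinds[x$root_mol], ")\n")
  invisible(x)
}

## species kind of a molecule once it holds an extra proton
protonated_kind <- function(base_kind) {
  switch(base_kind,
         water = "hydronium",
         `acid-anion` = "acid-neutral",
         stop("molecule of kind '", base_kind, "' cannot accept a proton"))
}

## pair kind of a hop, by donor species kind and acceptor base kind
hop_pair_kind <- function(donor_kind, acceptor_base_kind, acid_kind = "glu") {
  if (donor_kind == "hydronium" && acceptor_base_kind == "water")
    return("h3o-water")
  if (donor_kind == "acid-neutral" && acceptor_base_kind == "water")
    return(paste0(acid_kind, "-water"))
  if (donor_kind == "hydronium" && acceptor_base_kind == "acid-anion")
    return(paste0("water-", acid_kind))
  stop("unsupported donor/acceptor combination: ", donor_kind, " -> ",
       acceptor_base_kind)
}

## hops available from a (possibly hypothetical) protonated species.
## h_assign maps every H atom to the molecule currently holding it;
## forbidden_mols are molecules this path has already visited.
state_hops <- function(frame, topology, prot_mol, donor_kind, h_assign,
                       cutoff = 2.5, forbidden_mols = integer(0)) {
  mol <- topology$molecules[[prot_mol]]
  h_atoms <- which(h_assign == prot_mol)
  species_heavy <- mol$heavy_atoms
  acid_kind <- if (is.null(topology$acid)) "glu" else topology$acid$kind
  o_all <- which(!is.na(topology$mol_of_o))
  hops <- list()
  for (h in h_atoms) {
    ## the O this H sits on within the donor species
    d_own <- vapply(mol$o_atoms, function(o) frame_dist(frame, h, o),
                    numeric(1))
    donor_o <- mol$o_atoms[which.min(d_own)]
    for (o in o_all) {
      amol <- topology$mol_of_o[o]
      if (amol == prot_mol || amol %in% forbidden_mols) next
      if (frame_dist(frame, h, o) > cutoff) next
      akind <- topology$molecules[[amol]]$kind
      if (!akind %in% c("water", "acid-anion")) next
      hops[[length(hops) + 1L]] <- list(
        donor_o = donor_o, shared_h = h, acceptor_o = o,
        acceptor_mol = amol,
        pair_kind = hop_pair_kind(donor_kind, akind, acid_kind))
    }
  }
  hops
}

#' Find hydrogen-bond acceptor hops from a protonated species
#'
#' One hop is returned for every (hydrogen of the donor species, acceptor
#' oxygen) pair whose minimum-image H-to-acceptor-O distance is within
#' `cutoff` (default 2.5 Angstrom, the standard hydrogen-bond H...O
#' criterion). Acceptor oxygens belonging to the donor species itself are
#' excluded. An empty list is a valid result.
#'
#' @param frame A [cec_frame()].
#' @param topology The [assign_topology()] result.
#' @param donor_species Atom indices of the donating protonated species;
#'   defaults to the root species.
#' @param cutoff Shared-H to acceptor-O distance cutoff (Angstrom).
#' @return List of hops, each with `donor_o`, `shared_h`, `acceptor_o`,
#'   `acceptor_mol` and `pair_kind`.
#' @export
find_acceptor_hops <- function(frame, topology, donor_species = NULL,
                               cutoff = 2.5) {
  mol_ids <- vapply(topology$molecules, `[[`, integer(1), "id")
  if (is.null(donor_species)) {
    prot_mol <- topology$root_mol
  } else {
    hit <- which(vapply(topology$molecules, function(m)
      all(donor_species %in% m$atoms), logical(1)))
    if (!length(hit))
      stop("donor_species does not match a molecule of the topology")
    prot_mol <- mol_ids[hit[1L]]
  }
  donor_kind <- topology$molecules[[prot_mol]]$kind
  if (!donor_kind %in% c("hydronium", "acid-neutral"))
    stop("donor species (molecule ", prot_mol, ", ", donor_kind,
         ") is not protonated")
  h_assign <- base_h_assign(topology)
  state_hops(frame, topology, prot_mol, donor_kind, h_assign, cutoff)
}

base_h_assign <- function(topology) {
  h_assign <- rep(NA_integer_, topology$natoms)
  for (m in topology$molecules) h_assign[m$h_atoms] <- m$id
  h_assign
}
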