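#' Charge-transfer parameter table
#'
#' Holds the exponential charge-transfer model parameters per donor-acceptor
#' pair kind: `f_CT = exp(k * (delta - delta0))`, with `k` in 1/Angstrom and
#' `delta0` in Angstrom.
#'
#' @param pair_kind Character vector of pair-kind labels, named
#'   `"<donor>-<acceptor>"` (e.g. `"h3o-water"`, `"glu-water"`).
#' @param k Inverse lengths (1/Angstrom), all > 0.
#' @param delta0 Lengths (Angstrom), finite.
#' @param functional Optional label of the electronic-structure functional
#'   the parameters were fitted against.
#' @return A `data.frame` of class `ct_params`.
#' @export
ct_params <- function(pair_kind, k, delta0, functional = NA_character_) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be finite and > 0")
  if (any(!is.finite(delta0))) stop("delta0 must be finite")
  out <- data.frame(pair_kind = as.character(pair_kind), k = as.numeric(k),
                    delta0 = as.numeric(delta0),
                    functional = as.character(functional),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_params", "data.frame")
  out
}

#' Reference charge-transfer parameters
#'
#' The shipped values are the published least-squares fits of the
#' exponential charge-transfer model to constrained-DFT charge-transfer
#' factors for hydronium-water and glutamic-acid-water pairs in the gas
#' phase. BLYP is the default because it matches the functional typically
#' used to propagate the ab initio MD the CEC is analysed on; the
#' hydronium-water fit is also available for the range-separated hybrid
#' wB97X (the two give very similar CEC spectra).
#'
#' @param functional `"BLYP"` (default) or `"wB97X"` for the
#'   hydronium-water pair; the acid-water pair is BLYP-fitted in either case.
#' @return A [ct_params()] table with rows `h3o-water` and `glu-water`.
#' @export
default_ct_params <- function(functional = c("BLYP", "wB97X")) {
  functional <- match.arg(functional)
  k_h3o <- if (functional == "BLYP") 4.234 else 4.898
  ct_params(pair_kind = c("h3o-water", "glu-water"),
            k = c(k_h3o, 2.946),
            delta0 = c(0, 0.5361),
            functional = c(functional, "BLYP"))
}

#' Look up charge-transfer parameters for a pair kind
#'
#' If `pair_kind` is absent but its mirror (`"b-a"` for `"a-b"`) is present,
#' the mirrored parameters are returned with `delta0` negated: reversing the
#' roles of donor and acceptor flips the sign of the transfer coordinate, so
#' the reverse charge-transfer factor is `1 / f_forward(-delta)`, i.e. the
#' same `k` with `-delta0`.
#'
#' @param params A [ct_params()] table.
#' @param pair_kind A single pair-kind label.
#' @return A list with `k` and `delta0`.
#' @export
lookup_ct_params <- function(params, pair_kind) {
  i <- match(pair_kind, params$pair_kind)
  if (!is.na(i)) return(list(k = params$k[i], delta0 = params$delta0[i]))
  parts <- strsplit(pair_kind, "-", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) {
    j <- match(paste(rev(parts), collapse = "-"), params$pair_kind)
    if (!is.na(j)) return(list(k = params$k[j], delta0 = -params$delta0[j]))
  }
  stop("no charge-transfer parameters for pair kind '", pair_kind,
       "' (available: ", paste(params$pair_kind, collapse = ", "), ")")
}

#' Read / write charge-transfer parameter files (JSON)
#'
#' The file is a JSON array of objects with fields `pair_kind`, `k`,
#' `delta0` and optionally `functional`.
#'
#' @param path File path.
#' @return `read_ct_params` returns a [ct_params()] table.
#' @export
read_ct_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  d <- jsonlite::fromJSON(path)
  if (!all(c("pair_kind", "k", "delta0") %in% names(d)))
    stop("parameter file must provide pair_kind, k and delta0: ", path)
  ct_params(d$pair_kind, d$k, d$delta0,
            if ("functional" %in% names(d)) d$functional else NA_character_)
}

#' @rdname read_ct_params
#' @param params A [ct_params()] table to write.
#' @export
write_ct_params <- function(params, path) {
  jsonlite::write_json(as.data.frame(unclass(params)), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Excess-charge table
#'
#' Per protonated-species kind, the excess charge carried by each atom role
#' (element symbol), in units of e. The excess charge of an atom is defined
#' as its charge in the protonated species minus its charge in the
#' deprotonated parent, so the roles of a protonated species must sum to
#' +1 e. The shipped defaults are documented symmetric stand-ins (they place
#' the excess charge evenly over the species) and are fully overridable via
#' [read_charge_table()].
#'
#' @param tables Named list: species kind -> named numeric vector of
#'   per-atom excess charges by element role.
#' @return Object of class `charge_table`.
#' @export
charge_table <- function(tables) {
  if (!is.list(tables) || is.null(names(tables)))
    stop("tables must be a named list of role->charge vectors")
  for (nm in names(tables)) {
    q <- tables[[nm]]
    if (is.null(names(q)) || !is.numeric(q) || any(!is.finite(q)))
      stop("charge table for species '", nm,
           "' must be a named finite numeric vector")
  }
  structure(tables, class = "charge_table")
}

#' @rdname charge_table
#' @export
default_charge_table <- function() {
  charge_table(list(
    hydronium = c(O = 0.25, H = 0.25),        # O + 3 H -> sums to +1 e
    `acid-neutral` = c(C = 0.10, O = 0.20, H = 0.50)  # C + 2 O + 1 H -> +1 e
  ))
}

#' Read / write excess-charge tables (JSON)
#'
#' Schema: `{ "<species>": [ {"role": "O", "q": 0.25}, ... ], ... }`.
#'
#' @param path File path.
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path)) stop("charge-table file not found: ", path)
  d <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  charge_table(lapply(d, function(tab) {
    if (!all(c("role", "q") %in% names(tab)))
      stop("each species entry needs 'role' and 'q' fields: ", path)
    stats::setNames(as.numeric(tab$q), as.character(tab$role))
  }))
}

#' @rdname read_charge_table
#' @param charges A [charge_table()] to write.
#' @export
write_charge_table <- function(charges, path) {
  out <- lapply(unclass(charges), function(q)
    data.frame(role = names(q), q = as.numeric(q)))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## per-atom excess charges for one species, validated to sum to +1 e
species_excess_charges <- function(frame, atoms, kind, charges) {
  tab <- charges[[kind]]
  if (is.null(tab))
    stop("no charge-table entry for species kind '", kind, "'")
  roles <- frame$elements[atoms]
  miss <- setdiff(unique(roles), names(tab))
  if (length(miss))
    stop("charge table for '", kind, "' lacks role(s): ",
         paste(miss, collapse = ", "))
  q <- unname(tab[roles])
  if (abs(sum(q) - 1) > 1e-9)
    stop("excess charges of species '", kind, "' sum to ", sum(q),
         " (must be +1 e within 1e-9); adjust the charge table")
  q
}
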