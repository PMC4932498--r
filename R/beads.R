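# MARTINI-style constants used throughout. One CG bead maps ~4 heavy atoms;
# the standard bead mass is 72 amu and the Lennard-Jones sigma 0.47 nm, so a
# bead radius of 0.26 nm (~sigma/2, rounded up) is used for surface-area work.
.martini <- list(
  bead_mass     = 72,      # amu, standard 4:1 bead
  bead_radius   = 0.26,    # nm, SASA radius for a regular bead
  probe_radius  = 0.26,    # nm, half a water-bead diameter
  bond_r0       = 0.47,    # nm, alkyl-chain bond equilibrium
  bond_k        = 1250,    # kJ mol-1 nm-2, standard bond constant
  branch_r0     = 0.35,    # nm, dendron node-node / node-amine bonds
  water_per_bead = 4,
  water_number_density = 8.34  # beads nm-3 (33.37 waters nm-3 / 4)
)

#' Recognised bead roles
#'
#' Roles drive every downstream selection: `tail` and `ring` beads are the
#' hydrophobic set used for aggregate detection and core geometry,
#' `terminal-amine` beads are the charged groups counted against siRNA
#' phosphates, and the nucleic-acid roles carry the duplex metadata.
#'
#' @return Character vector of valid `role` values.
#' @export
bead_roles <- function() {
  c("head-node", "terminal-amine", "ring", "tail",
    "phosphate", "sugar", "base", "water", "ion-Na", "ion-Cl")
}

.hydrophobic_roles <- c("ring", "tail")

#' Construct a bead table
#'
#' A bead table is the per-bead metadata of a molecule or frame: one row per
#' bead with its MARTINI type, integer charge (in e), mass (amu) and role.
#' Indices are 0-based internally, matching the convention of the exported
#' bonded-term tables; file writers convert to 1-based serial numbers.
#'
#' @param name short bead labels
#' @param martini_type MARTINI type tokens (Qd, Qa, C1, P1, P4, Na, Nd, Nda, ...)
#' @param charge integer charges in elementary units, each in -1/0/+1
#' @param role one of [bead_roles()]
#' @param mass bead masses in amu (default: standard 72)
#' @return data.frame with columns `index`, `name`, `martini_type`, `charge`,
#'   `mass`, `role`, `hydrophobic`
#' @export
bead_table <- function(name, martini_type, charge, role,
                       mass = rep(.martini$bead_mass, length(name))) {
  n <- length(name)
  stopifnot(length(martini_type) == n, length(charge) == n,
            length(role) == n, length(mass) == n)
  if (!all(charge %in% c(-1L, 0L, 1L)))
    stop("bead charges must be -1, 0 or +1 elementary charges")
  bad <- setdiff(unique(role), bead_roles())
  if (length(bad))
    stop("unknown bead role(s): ", paste(bad, collapse = ", "))
  # role-type contracts: protonated amines are Qd(+1), phosphates Qa(-1)
  if (any(role == "terminal-amine" & (charge != 1L | martini_type != "Qd")))
    stop("terminal-amine beads must be Qd with charge +1")
  if (any(role == "phosphate" & (charge != -1L | martini_type != "Qa")))
    stop("phosphate beads must be Qa with charge -1")
  if (any(role %in% .hydrophobic_roles & charge != 0L))
    stop("tail and ring beads must be uncharged")
  data.frame(
    index = seq_len(n) - 1L,
    name = as.character(name),
    martini_type = as.character(martini_type),
    charge = as.integer(charge),
    mass = as.numeric(mass),
    role = as.character(role),
    hydrophobic = role %in% .hydrophobic_roles,
    stringsAsFactors = FALSE
  )
}

#' Construct a bonded-term table
#'
#' @param kind one of `bond`, `angle`, `elastic` per term
#' @param i,j 0-based bead indices of the term (first two sites)
#' @param k optional third site for angles (NA for 2-body terms)
#' @param equilibrium nm for bonds/elastic terms, degrees for angles
#' @param force_constant kJ mol-1 nm-2 (bonds/elastic) or kJ mol-1 rad-2
#' @return data.frame of bonded terms
#' @export
bonded_table <- function(kind = character(), i = integer(), j = integer(),
                         k = NA_integer_, equilibrium = numeric(),
                         force_constant = numeric()) {
  n <- length(kind)
  d <- data.frame(
    kind = as.character(kind),
    i = as.integer(i), j = as.integer(j),
    k = rep_len(as.integer(k), n),
    equilibrium = as.numeric(equilibrium),
    force_constant = as.numeric(force_constant),
    stringsAsFactors = FALSE
  )
  if (n && any(d$equilibrium <= 0))
    stop("bonded equilibrium values must be positive")
  if (n && any(!d$kind %in% c("bond", "angle", "elastic")))
    stop("bonded term kind must be bond, angle or elastic")
  d
}

# duplicate (kind, sorted 2-body indices) detection used by topology checks
.bonded_duplicated <- function(bonded) {
  two <- bonded$kind != "angle"
  key <- ifelse(two,
                paste(bonded$kind, pmin(bonded$i, bonded$j),
                      pmax(bonded$i, bonded$j)),
                paste(bonded$kind, bonded$i, bonded$j, bonded$k))
  duplicated(key)
}

#' Assemble a molecule topology
#'
#' @param name molecule name
#' @param beads a [bead_table()]
#' @param bonded a [bonded_table()]
#' @return object of class `cg_topology` with fields `name`, `beads`,
#'   `bonded`, `net_charge`
#' @export
cg_topology <- function(name, beads, bonded = bonded_table()) {
  if (any(.bonded_duplicated(bonded)))
    stop("duplicate bonded terms in topology '", name, "'")
  nb <- nrow(beads)
  idx <- c(bonded$i, bonded$j, bonded$k[!is.na(bonded$k)])
  if (length(idx) && (min(idx) < 0 || max(idx) >= nb))
    stop("bonded term references a bead outside the topology")
  structure(
    list(name = name, beads = beads, bonded = bonded,
         net_charge = as.integer(sum(beads$charge))),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology '%s': %d beads, net charge %+d e\n",
              x$name, nrow(x$beads), x$net_charge))
  cat("  roles: ",
      paste(sprintf("%s=%d", names(table(x$beads$role)),
                    as.integer(table(x$beads$role))), collapse = ", "), "\n")
  tb <- table(x$bonded$kind)
  if (length(tb))
    cat("  bonded:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  invisible(x)
}
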