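# Resname codes used in coordinate files, one per molecule kind.
.kind_resname <- c(AD = "AD", siRNA = "RNA", water = "W",
                   Na = "ION", Cl = "ION")
.resname_kind <- function(resname, atomname) {
  kind <- c(AD = "AD", RNA = "siRNA", W = "water")[resname]
  ion <- resname == "ION"
  kind[ion & atomname == "NA+"] <- "Na"
  kind[ion & atomname == "CL-"] <- "Cl"
  unname(kind)
}

#' Write a frame in GRO format
#'
#' Standard fixed-width GRO: nm coordinates at three decimals, 1-based atom
#' numbering, free-format box line. Residue number and name encode the
#' molecule id and kind; the atom name is the bead name.
#'
#' @param frame a [cg_frame()]
#' @param path output file
#' @param title first-line comment
#' @return `path`, invisibly
#' @export
write_gro <- function(frame, path, title = "dendrimicelle CG frame") {
  b <- frame$beads
  n <- nrow(frame$positions)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  resno <- b$molecule_id %% 100000L
  atomno <- seq_len(n) %% 100000L
  lines[3:(n + 2)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              resno,
                              .kind_resname[b$molecule_kind],
                              substr(b$name, 1, 5),
                              atomno,
                              frame$positions[, 1],
                              frame$positions[, 2],
                              frame$positions[, 3])
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f",
                          frame$box[1], frame$box[2], frame$box[3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GRO file
#'
#' Recovers positions, box and the molecule id / kind / bead-name metadata
#' written by [write_gro()]. Charges, masses and roles are format-lossy in
#' GRO; beads are returned with zero charge, standard mass and a role
#' inferred from the molecule kind (solvent/ion roles are exact, solute
#' beads are tagged by name).
#'
#' @param path GRO file
#' @return a [cg_frame()]
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(n + 2)]
  resno <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atomname <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  kind <- .resname_kind(resname, atomname)
  role <- .infer_role(kind, atomname)
  charge <- integer(n)
  charge[role == "terminal-amine"] <- 1L
  charge[role == "phosphate"] <- -1L
  charge[role == "ion-Na"] <- 1L
  charge[role == "ion-Cl"] <- -1L
  # types recoverable from the role; others default to the generic polar bead
  type <- rep("P4", n)
  type[role %in% c("terminal-amine", "ion-Na")] <- "Qd"
  type[role %in% c("phosphate", "ion-Cl")] <- "Qa"
  type[role %in% c("tail", "ring")] <- "C1"
  type[role == "sugar"] <- "P1"
  beads <- bead_table(atomname, type, charge, role)
  beads$molecule_id <- resno
  beads$molecule_kind <- kind
  cg_frame(unname(cbind(x, y, z)), box, beads)
}

.infer_role <- function(kind, atomname) {
  role <- rep("head-node", length(kind))
  role[kind == "water"] <- "water"
  role[kind == "Na"] <- "ion-Na"
  role[kind == "Cl"] <- "ion-Cl"
  role[kind == "AD" & grepl("^C\\d", atomname)] <- "tail"
  role[kind == "AD" & atomname == "RNG"] <- "ring"
  role[kind == "AD" & grepl("^NH", atomname)] <- "terminal-amine"
  role[kind == "siRNA" & atomname == "PO4"] <- "phosphate"
  role[kind == "siRNA" & atomname == "RIB"] <- "sugar"
  role[kind == "siRNA" & grepl("^B\\d", atomname)] <- "base"
  role
}

#' Write a frame in PDB format
#'
#' Uses bio3d when available (coordinates are converted nm -> Angstrom);
#' falls back to a minimal fixed-width writer otherwise.
#'
#' @param frame a [cg_frame()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cg_pdb <- function(frame, path) {
  b <- frame$beads
  xyz <- frame$positions * 10
  if (requireNamespace("bio3d", quietly = TRUE)) {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     resno = b$molecule_id,
                     resid = .kind_resname[b$molecule_kind],
                     eleno = seq_len(nrow(b)),
                     elety = substr(b$name, 1, 4),
                     chain = rep("A", nrow(b)))
  } else {
    lines <- sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f",
                     seq_len(nrow(b)) %% 100000L, substr(b$name, 1, 4),
                     .kind_resname[b$molecule_kind], "A",
                     b$molecule_id %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ITP-style topology text

#' Write an ITP-style topology file
#'
#' Sections: `[ moleculetype ]`, `[ atoms ]` (1-based numbering, charges,
#' masses), `[ bonds ]`, `[ angles ]`, and -- when the topology carries an
#' elastic network -- a dedicated second `[ bonds ] ; elastic network`
#' section holding the harmonic restraints with their force constant.
#'
#' @param topology a [cg_topology()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_itp <- function(topology, path) {
  b <- topology$beads
  out <- c(
    sprintf("; CG topology for %s (net charge %+d e)",
            topology$name, topology$net_charge),
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  1", gsub("\\s", "_", topology$name)),
    "",
    "[ atoms ]",
    ";  nr  type  resnr  resid  atom  cgnr  charge  mass",
    sprintf("%5d %5s %6d %6s %5s %5d %7.1f %7.1f",
            b$index + 1L, b$martini_type, 1L,
            gsub("\\s", "_", topology$name),
            b$name, b$index + 1L, as.numeric(b$charge), b$mass)
  )
  bd <- topology$bonded
  bonds <- bd[bd$kind == "bond", , drop = FALSE]
  if (nrow(bonds)) {
    out <- c(out, "", "[ bonds ]", ";  i  j  funct  r0(nm)  k",
             sprintf("%5d %5d  1 %8.4f %10.1f",
                     bonds$i + 1L, bonds$j + 1L,
                     bonds$equilibrium, bonds$force_constant))
  }
  ang <- bd[bd$kind == "angle", , drop = FALSE]
  if (nrow(ang)) {
    out <- c(out, "", "[ angles ]", ";  i  j  k  funct  theta0(deg)  ktheta",
             sprintf("%5d %5d %5d  2 %8.2f %10.1f",
                     ang$i + 1L, ang$j + 1L, ang$k + 1L,
                     ang$equilibrium, ang$force_constant))
  }
  el <- bd[bd$kind == "elastic", , drop = FALSE]
  if (nrow(el)) {
    out <- c(out, "", "[ bonds ] ; elastic network",
             ";  i  j  funct  r0(nm)  k",
             sprintf("%5d %5d  1 %8.4f %10.1f",
                     el$i + 1L, el$j + 1L,
                     el$equilibrium, el$force_constant))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read an ITP-style topology file written by [write_itp()]
#'
#' @param path ITP file
#' @return a [cg_topology()]; terms from the elastic-network bonds section
#'   come back with kind `elastic`
#' @export
read_itp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  sec <- NULL; elastic <- FALSE
  name <- "molecule"
  atoms <- list(); bonds <- list(); angles <- list(); el <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- trimws(sub("\\].*$", "", sub("^\\[", "", ln)))
      elastic <- sec == "bonds" && grepl("elastic", ln)
      next
    }
    if (grepl("^;", trimws(ln))) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (is.null(sec)) next
    if (sec == "moleculetype") {
      name <- tok[1]
    } else if (sec == "atoms") {
      atoms[[length(atoms) + 1L]] <-
        data.frame(type = tok[2], atom = tok[5],
                   charge = as.numeric(tok[7]), mass = as.numeric(tok[8]))
    } else if (sec == "bonds" && !elastic) {
      bonds[[length(bonds) + 1L]] <-
        data.frame(i = as.integer(tok[1]) - 1L, j = as.integer(tok[2]) - 1L,
                   r0 = as.numeric(tok[4]), k = as.numeric(tok[5]))
    } else if (sec == "bonds" && elastic) {
      el[[length(el) + 1L]] <-
        data.frame(i = as.integer(tok[1]) - 1L, j = as.integer(tok[2]) - 1L,
                   r0 = as.numeric(tok[4]), k = as.numeric(tok[5]))
    } else if (sec == "angles") {
      angles[[length(angles) + 1L]] <-
        data.frame(i = as.integer(tok[1]) - 1L, j = as.integer(tok[2]) - 1L,
                   k3 = as.integer(tok[3]) - 1L,
                   th0 = as.numeric(tok[5]), kth = as.numeric(tok[6]))
    }
  }
  at <- do.call(rbind, atoms)
  role <- .infer_role(rep(if (grepl("RNA|siRNA", name)) "siRNA" else "AD",
                          nrow(at)), at$atom)
  beads <- bead_table(at$atom, at$type, as.integer(round(at$charge)), role,
                      at$mass)
  bonded <- bonded_table()
  if (length(bonds)) {
    bb <- do.call(rbind, bonds)
    bonded <- rbind(bonded, bonded_table("bond", bb$i, bb$j, NA_integer_,
                                         bb$r0, bb$k))
  }
  if (length(angles)) {
    aa <- do.call(rbind, angles)
    bonded <- rbind(bonded, bonded_table("angle", aa$i, aa$j, aa$k3,
                                         aa$th0, aa$kth))
  }
  if (length(el)) {
    ee <- do.call(rbind, el)
    bonded <- rbind(bonded, bonded_table("elastic", ee$i, ee$j, NA_integer_,
                                         ee$r0, ee$k))
  }
  cg_topology(name, beads, bonded)
}

#' Export a system (topologies + coordinates) to disk
#'
#' @param topologies named list of [cg_topology()] objects
#' @param frame a [cg_frame()]
#' @param dir output directory (created if absent)
#' @param basename file stem; writes `<stem>.gro` plus one
#'   `<stem>_<molecule>.itp` per topology, and `<stem>.pdb` when
#'   `pdb = TRUE`
#' @param pdb also write a PDB copy of the coordinates
#' @return named character vector of written paths
#' @export
export_system <- function(topologies, frame, dir, basename = "system",
                          pdb = FALSE) {
  if (inherits(topologies, "cg_topology")) topologies <- list(topologies)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  gro <- file.path(dir, paste0(basename, ".gro"))
  tryCatch(write_gro(frame, gro),
           error = function(e) stop("writing ", gro, ": ", conditionMessage(e)))
  paths["gro"] <- gro
  for (tp in topologies) {
    f <- file.path(dir, sprintf("%s_%s.itp", basename,
                                gsub("\\W", "_", tp$name)))
    tryCatch(write_itp(tp, f),
             error = function(e) stop("writing ", f, ": ", conditionMessage(e)))
    paths[tp$name] <- f
  }
  if (pdb) {
    f <- file.path(dir, paste0(basename, ".pdb"))
    write_cg_pdb(frame, f)
    paths["pdb"] <- f
  }
  paths
}

#' Write a trajectory as a series of GRO frames
#'
#' @param trajectory a [cg_trajectory()]
#' @param path output file; frames are concatenated with the time in each
#'   frame title (`t=<ns>`)
#' @return `path`, invisibly
#' @export
write_trajectory_gro <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    tmp <- tempfile(fileext = ".gro")
    write_gro(f, tmp, title = sprintf("frame %d t=%.3f ns", i,
                                      trajectory$times[i]))
    writeLines(readLines(tmp), con)
    unlink(tmp)
  }
  invisible(path)
}
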