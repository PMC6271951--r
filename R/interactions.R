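# Distance-based classification of protein-ligand contacts and aggregation
# into per-residue interaction profiles.

.CONTACT_CLASSES <- c("hbond", "halogen_bond", "aromatic", "hydrophobic",
                      "destabilizing")

#' Default distance cutoffs per contact class
#'
#' Heavy-atom distance criteria (Angstrom): hydrogen bond donor-acceptor
#' <= 3.5 (no angle term, since hydrogens are frequently absent from PDB
#' inputs); ligand halogen to protein N/O/S <= 3.6; aromatic atom pairs
#' <= 5.0; apolar-apolar <= 4.5; hydrophilic-hydrophobic (destabilizing)
#' <= 4.0. Overlaps are resolved by the fixed precedence
#' hbond > halogen_bond > aromatic > hydrophobic > destabilizing.
#'
#' @return Named numeric vector of cutoffs.
#' @export
contact_cutoffs <- function() {
  c(hbond = 3.5, halogen_bond = 3.6, aromatic = 5.0, hydrophobic = 4.5,
    destabilizing = 4.0)
}

#' Chemical roles of a single atom
#'
#' Documented role rules: `donor` = N/O bearing at least one hydrogen;
#' `acceptor` = N/O not positively charged; `aromatic` = member of an
#' aromatic ring; `hydrophobic` = C or S bonded only to C, S or H;
#' `hydrophilic` = N or O; `halogen` = F/Cl/Br/I (its own role, excluded
#' from hydrophobic). Roles may overlap except hydrophobic/hydrophilic.
#'
#' @param element Element symbol.
#' @param n_h Number of attached hydrogens.
#' @param neighbor_elements Element symbols of bonded heavy atoms.
#' @param aromatic Is the atom part of an aromatic ring?
#' @param charge Formal charge.
#' @return Character vector of roles (possibly empty).
#' @export
atom_roles <- function(element, n_h = 0L, neighbor_elements = character(),
                       aromatic = FALSE, charge = 0L) {
  if (!(element %in% .ORGANIC_ELEMENTS)) {
    stop(sprintf("unknown element: %s", element))
  }
  roles <- character()
  if (element %in% c("F", "Cl", "Br", "I")) return("halogen")
  if (element %in% c("N", "O")) {
    roles <- c(roles, "hydrophilic")
    if (n_h >= 1L) roles <- c(roles, "donor")
    if (charge <= 0L) roles <- c(roles, "acceptor")
  }
  if (element %in% c("C", "S") &&
      all(neighbor_elements %in% c("C", "S", "H"))) {
    roles <- c(roles, "hydrophobic")
  }
  if (aromatic) roles <- c(roles, "aromatic")
  roles
}

# ---- protein-side role dictionary ------------------------------------------

.SC_DONOR <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH")
.SC_ACCEPTOR <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))
.SC_AROMATIC <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
# carbons adjacent to N/O (not hydrophobic by the bonded-only-to-C/S/H rule)
.SC_POLAR_C <- list(
  SER = "CB", THR = "CB", ASP = "CG", ASN = "CG", GLU = "CD", GLN = "CD",
  ARG = c("CD", "CZ"), LYS = "CE", TYR = "CZ", PRO = "CD", MET = character())

# Role flags for protein atoms identified by residue and atom name.
.protein_roles <- function(residue_name, atom_name, element) {
  n <- length(atom_name)
  get <- function(tab) {
    vapply(seq_len(n), function(i) {
      atom_name[i] %in% tab[[residue_name[i]]]
    }, TRUE)
  }
  donor <- (atom_name == "N") | get(.SC_DONOR)
  acceptor <- (atom_name %in% c("O", "OXT")) | get(.SC_ACCEPTOR)
  aromatic <- get(.SC_AROMATIC)
  hydrophilic <- element %in% c("N", "O")
  polar_c <- (atom_name == "C") | get(.SC_POLAR_C)
  hydrophobic <- element %in% c("C", "S") & !polar_c & !hydrophilic
  data.frame(donor = donor, acceptor = acceptor, aromatic = aromatic,
             hydrophobic = hydrophobic, hydrophilic = hydrophilic,
             halogen = rep(FALSE, n))
}

# Role flags for ligand atoms from elements and 3D connectivity. Bonds are
# guessed from heavy-atom distances (<= 1.8 A); aromatic membership is
# approximated as membership in a 5- or 6-ring of the bonded graph.
.ligand_roles <- function(element, xyz, h_xyz = NULL) {
  n <- length(element)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= 1.8 & upper.tri(d)
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  in_ring <- rep(FALSE, n)
  if (igraph::gsize(g) > 0) {
    for (v in seq_len(n)) {
      nbrs <- as.integer(igraph::neighbors(g, v))
      for (w in nbrs) {
        g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(v, w)))
        sp <- suppressWarnings(igraph::distances(g2, v, w))
        if (is.finite(sp) && sp >= 2 && sp <= 5) {
          in_ring[v] <- TRUE
          break
        }
      }
    }
  }
  n_h <- rep(0L, n)
  if (!is.null(h_xyz) && nrow(h_xyz)) {
    for (v in seq_len(n)) {
      dh <- sqrt(colSums((t(h_xyz) - xyz[v, ])^2))
      n_h[v] <- sum(dh <= 1.3)
    }
  }
  out <- lapply(seq_len(n), function(v) {
    nbrs <- which((adj | t(adj))[v, ])
    atom_roles(element[v], n_h = n_h[v],
               neighbor_elements = element[nbrs], aromatic = in_ring[v])
  })
  data.frame(
    donor = vapply(out, function(r) "donor" %in% r, TRUE),
    acceptor = vapply(out, function(r) "acceptor" %in% r, TRUE),
    aromatic = vapply(out, function(r) "aromatic" %in% r, TRUE),
    hydrophobic = vapply(out, function(r) "hydrophobic" %in% r, TRUE),
    hydrophilic = vapply(out, function(r) "hydrophilic" %in% r, TRUE),
    halogen = vapply(out, function(r) "halogen" %in% r, TRUE))
}

#' Read a protein-ligand complex from a PDB file
#'
#' ATOM records form the protein; HETATM records with the given residue name
#' form the ligand. Protein atom roles come from a residue/atom-name
#' dictionary of the standard amino acids; ligand roles are derived from
#' elements and distance-guessed connectivity ([atom_roles()] rules).
#'
#' @param path PDB file path.
#' @param ligand_resname Ligand residue name (default `"LIG"`).
#' @return An `oxa_complex`: list with `protein` and `ligand` site tables
#'   (columns `element`, `x`, `y`, `z`, `residue_number`, `residue_name`,
#'   `atom_name`, plus role flags).
#' @export
read_complex_pdb <- function(path, ligand_resname = "LIG") {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  is_lig <- a$resid == ligand_resname
  prot <- a[a$type == "ATOM" & !is_lig, , drop = FALSE]
  lig <- a[is_lig, , drop = FALSE]
  if (!nrow(prot)) stop("complex has no protein atoms")
  if (!nrow(lig)) stop(sprintf("complex has no ligand atoms (resname %s)",
                               ligand_resname))
  elem_of <- function(d) {
    e <- trimws(d$elesy)
    bad <- is.na(e) | !nzchar(e)
    e[bad] <- substr(trimws(d$elety[bad]), 1, 1)
    paste0(toupper(substr(e, 1, 1)), tolower(substring(e, 2)))
  }
  pe <- elem_of(prot)
  keep_h <- pe != "H"
  psites <- data.frame(element = pe[keep_h], x = prot$x[keep_h],
                       y = prot$y[keep_h], z = prot$z[keep_h],
                       residue_number = prot$resno[keep_h],
                       residue_name = prot$resid[keep_h],
                       atom_name = trimws(prot$elety[keep_h]))
  psites <- cbind(psites, .protein_roles(psites$residue_name,
                                         psites$atom_name, psites$element))
  le <- elem_of(lig)
  lh <- le == "H"
  lsites <- data.frame(element = le[!lh], x = lig$x[!lh], y = lig$y[!lh],
                       z = lig$z[!lh], residue_number = lig$resno[!lh],
                       residue_name = lig$resid[!lh],
                       atom_name = trimws(lig$elety[!lh]))
  lxyz <- as.matrix(lsites[, c("x", "y", "z")])
  hxyz <- cbind(lig$x[lh], lig$y[lh], lig$z[lh])
  lsites <- cbind(lsites, .ligand_roles(lsites$element, lxyz, hxyz))
  structure(list(protein = psites, ligand = lsites), class = "oxa_complex")
}

#' @export
print.oxa_complex <- function(x, ...) {
  cat(sprintf("<oxa_complex> %d protein atoms, %d ligand atoms\n",
              nrow(x$protein), nrow(x$ligand)))
  invisible(x)
}

#' Write a complex to a PDB file
#'
#' @param complex An `oxa_complex`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_complex_pdb <- function(complex, path) {
  p <- complex$protein; l <- complex$ligand
  xyz <- c(t(as.matrix(rbind(p, l)[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
    resno = c(p$residue_number, l$residue_number),
    resid = c(p$residue_name, l$residue_name),
    elety = c(p$atom_name, l$atom_name),
    elesy = c(p$element, l$element),
    chain = c(rep("A", nrow(p)), rep("L", nrow(l))))
  invisible(path)
}

#' Detect and classify protein-ligand contacts
#'
#' Every protein-ligand atom pair within the largest class cutoff is tested
#' against the class rules in fixed precedence
#' (hbond > halogen_bond > aromatic > hydrophobic > destabilizing) and
#' yields at most one contact. Halogens form a first-class contact category
#' (ligand halogen toward protein N/O/S) rather than being folded into
#' hydrophilic-hydrophobic contacts.
#'
#' @param complex An `oxa_complex`.
#' @param cutoffs Named cutoffs (default [contact_cutoffs()]).
#' @return Data frame of contacts: `residue_number`, `residue_name`,
#'   `protein_atom`, `ligand_atom`, `ligand_element`, `distance`,
#'   `contact_class`.
#' @export
detect_contacts <- function(complex, cutoffs = contact_cutoffs()) {
  p <- complex$protein; l <- complex$ligand
  if (!nrow(p)) stop("complex has no protein atoms")
  if (!nrow(l)) stop("complex has no ligand atoms")
  pm <- as.matrix(p[, c("x", "y", "z")])
  lm <- as.matrix(l[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
  d <- sqrt(pmax(d2, 0))
  maxcut <- max(cutoffs)
  idx <- which(d <= maxcut, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(residue_number = integer(), residue_name = character(),
                      protein_atom = character(), ligand_atom = character(),
                      ligand_element = character(), distance = numeric(),
                      contact_class = character()))
  }
  pi <- idx[, 1]; li <- idx[, 2]
  dd <- d[idx]
  cls <- rep(NA_character_, nrow(idx))
  hb <- dd <= cutoffs[["hbond"]] &
    ((p$donor[pi] & l$acceptor[li]) | (p$acceptor[pi] & l$donor[li]))
  xb <- dd <= cutoffs[["halogen_bond"]] & l$halogen[li] &
    p$element[pi] %in% c("N", "O", "S")
  ar <- dd <= cutoffs[["aromatic"]] & p$aromatic[pi] & l$aromatic[li]
  hh <- dd <= cutoffs[["hydrophobic"]] & p$hydrophobic[pi] & l$hydrophobic[li]
  ds <- dd <= cutoffs[["destabilizing"]] &
    ((p$hydrophilic[pi] & l$hydrophobic[li]) |
       (p$hydrophobic[pi] & l$hydrophilic[li]))
  cls[ds] <- "destabilizing"
  cls[hh] <- "hydrophobic"
  cls[ar] <- "aromatic"
  cls[xb] <- "halogen_bond"
  cls[hb] <- "hbond"
  keep <- !is.na(cls)
  out <- data.frame(residue_number = p$residue_number[pi][keep],
                    residue_name = p$residue_name[pi][keep],
                    protein_atom = p$atom_name[pi][keep],
                    ligand_atom = l$atom_name[li][keep],
                    ligand_element = l$element[li][keep],
                    distance = dd[keep],
                    contact_class = cls[keep])
  out[order(out$residue_number, out$protein_atom, out$ligand_atom), ,
      drop = FALSE]
}

#' Per-residue interaction profiles over a compound set
#'
#' For each binding-site residue: the fraction of compounds forming at least
#' one contact with it, and the class composition of all its contacts
#' (fractions over the residue's observed contacts, summing to 1 where any
#' exist).
#'
#' @param contact_sets List of contact tables (one per docked compound, from
#'   [detect_contacts()]).
#' @param residues Integer vector of residue numbers to profile (default:
#'   residues observed in any contact set).
#' @return Data frame: `residue_number`, `fraction_of_compounds`, and one
#'   composition column per contact class.
#' @export
residue_profiles <- function(contact_sets, residues = NULL) {
  if (is.null(residues)) {
    residues <- sort(unique(unlist(lapply(contact_sets,
                                          function(cs) cs$residue_number))))
  }
  n_cmp <- length(contact_sets)
  out <- lapply(residues, function(rn) {
    touched <- vapply(contact_sets, function(cs) {
      any(cs$residue_number == rn)
    }, TRUE)
    classes <- unlist(lapply(contact_sets, function(cs) {
      cs$contact_class[cs$residue_number == rn]
    }))
    comp <- as.numeric(table(factor(classes, levels = .CONTACT_CLASSES)))
    if (length(classes)) comp <- comp / length(classes)
    row <- data.frame(residue_number = rn,
                      fraction_of_compounds = if (n_cmp) mean(touched) else 0)
    row[.CONTACT_CLASSES] <- as.list(comp)
    row
  })
  do.call(rbind, out)
}

#' Per-residue share of halogen bonds
#'
#' @param contact_sets List of contact tables (one per compound).
#' @return Data frame `residue_number`, `n_halogen_bonds`, `share` (shares
#'   sum to 1 when any halogen bonds exist; zero rows otherwise).
#' @export
halogen_contributions <- function(contact_sets) {
  res <- unlist(lapply(contact_sets, function(cs) {
    cs$residue_number[cs$contact_class == "halogen_bond"]
  }))
  if (!length(res)) {
    return(data.frame(residue_number = integer(), n_halogen_bonds = integer(),
                      share = numeric()))
  }
  tab <- table(res)
  data.frame(residue_number = as.integer(names(tab)),
             n_halogen_bonds = as.integer(tab),
             share = as.numeric(tab) / sum(tab))
}
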