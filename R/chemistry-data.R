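# Base chemistry tables: ring membership, intra-base bonds, hydrogen
# attachment and H-bonding roles. Roles are a pure function of
# (base, atom name) and identical across structures.

.base_ring <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# all base heavy atoms (ring + exocyclic)
.base_heavy <- list(
  A = c(.base_ring$A, "N6"),
  G = c(.base_ring$G, "O6", "N2"),
  C = c(.base_ring$C, "O2", "N4"),
  U = c(.base_ring$U, "O2", "O4")
)

# intra-base bonds, used for ring-neighbour geometry
.base_bonds <- local({
  pur <- rbind(c("N9", "C8"), c("C8", "N7"), c("N7", "C5"), c("C5", "C4"),
               c("C4", "N9"), c("C4", "N3"), c("N3", "C2"), c("C2", "N1"),
               c("N1", "C6"), c("C6", "C5"))
  pyr <- rbind(c("N1", "C2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
               c("C5", "C6"), c("C6", "N1"))
  list(A = rbind(pur, c("C6", "N6")),
       G = rbind(pur, c("C6", "O6"), c("C2", "N2")),
       C = rbind(pyr, c("C2", "O2"), c("C4", "N4")),
       U = rbind(pyr, c("C2", "O2"), c("C4", "O4")))
})

.base_neighbors <- lapply(.base_bonds, function(b) {
  atoms <- unique(c(b[, 1], b[, 2]))
  nb <- lapply(atoms, function(a) sort(unique(c(b[b[, 1] == a, 2], b[b[, 2] == a, 1]))))
  names(nb) <- atoms
  nb
})

# Base hydrogens: name, parent heavy atom, placement rule and bond length (A).
# Rules: "ring" = in-plane external bisector of the two ring neighbours;
# "amino" = two sp2 amino hydrogens in the base plane, at 120 degrees from the
# attached carbon. N-H 1.01 A, C-H 1.08 A. O2'-H (0.96 A) is placed along the
# C2'->O2' bond extension: only its contribution to solvent occlusion/area
# matters, not its precise torsion.
.base_hydrogens <- list(
  A = data.frame(h = c("H2", "H8", "H61", "H62"),
                 parent = c("C2", "C8", "N6", "N6"),
                 rule = c("ring", "ring", "amino", "amino"),
                 len = c(1.08, 1.08, 1.01, 1.01), stringsAsFactors = FALSE),
  G = data.frame(h = c("H1", "H8", "H21", "H22"),
                 parent = c("N1", "C8", "N2", "N2"),
                 rule = c("ring", "ring", "amino", "amino"),
                 len = c(1.01, 1.08, 1.01, 1.01), stringsAsFactors = FALSE),
  C = data.frame(h = c("H5", "H6", "H41", "H42"),
                 parent = c("C5", "C6", "N4", "N4"),
                 rule = c("ring", "ring", "amino", "amino"),
                 len = c(1.08, 1.08, 1.01, 1.01), stringsAsFactors = FALSE),
  U = data.frame(h = c("H3", "H5", "H6"),
                 parent = c("N3", "C5", "C6"),
                 rule = c("ring", "ring", "ring"),
                 len = c(1.01, 1.08, 1.08), stringsAsFactors = FALSE)
)

# amino nitrogens and the ring carbon they hang from
.amino_carbon <- list(A = c(N6 = "C6"), G = c(N2 = "C2"),
                      C = c(N4 = "C4"), U = character(0))

# H-bonding role table and direction-vector geometry per (base, atom).
# geometry: "bisector"  one in-plane vector along the external bisector of the
#                       two ring-bond neighbours (ring N-H donors, ring-N
#                       acceptors, ring C-H neutrals share this direction);
#           "amino"     two N->H vectors of the sp2 amino group;
#           "carbonyl"  two in-plane lone-pair vectors at +/-60 degrees from
#                       the extension of the C->O bond;
#           "centroid"  one in-plane vector from the base-ring centroid
#                       through the atom (neutral carbons without hydrogens:
#                       guanine C2).
# Glycosidic nitrogens (N9 purine / N1 pyrimidine) and pure ring-junction
# carbons carry no role and are never determinants.
.role_table_data <- local({
  rt <- rbind(
    data.frame(base = "A",
               atom = c("N1", "C2", "N3", "N6", "N7", "C8"),
               role = c("acceptor", "neutral", "acceptor", "donor", "acceptor", "neutral"),
               geometry = c("bisector", "bisector", "bisector", "amino", "bisector", "bisector"),
               stringsAsFactors = FALSE),
    data.frame(base = "G",
               atom = c("N1", "N2", "C2", "N3", "O6", "N7", "C8"),
               role = c("donor", "donor", "neutral", "acceptor", "acceptor", "acceptor", "neutral"),
               geometry = c("bisector", "amino", "centroid", "bisector", "carbonyl", "bisector", "bisector"),
               stringsAsFactors = FALSE),
    data.frame(base = "C",
               atom = c("O2", "N3", "N4", "C5", "C6"),
               role = c("acceptor", "acceptor", "donor", "neutral", "neutral"),
               geometry = c("carbonyl", "bisector", "amino", "bisector", "bisector"),
               stringsAsFactors = FALSE),
    data.frame(base = "U",
               atom = c("O2", "N3", "O4", "C5", "C6"),
               role = c("acceptor", "donor", "acceptor", "neutral", "neutral"),
               geometry = c("carbonyl", "bisector", "carbonyl", "bisector", "bisector"),
               stringsAsFactors = FALSE))
  rt
})

# carbonyl oxygens and their attached carbon
.carbonyl_carbon <- list(G = c(O6 = "C6"), C = c(O2 = "C2"),
                         U = c(O2 = "C2", O4 = "C4"), A = character(0))

#' Hydrogen-bonding role table for a base
#'
#' The fixed assignment of donor / acceptor / neutral roles to the base heavy
#' atoms of A, C, G and U. Glycosidic nitrogens and pure ring-junction carbons
#' carry no role.
#'
#' @param base_type One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return Named character vector mapping base heavy-atom name to role.
#' @export
role_table <- function(base_type) {
  if (!base_type %in% c("A", "C", "G", "U"))
    stop("unknown base letter: ", base_type)
  rt <- .role_table_data[.role_table_data$base == base_type, ]
  stats::setNames(rt$role, rt$atom)
}
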