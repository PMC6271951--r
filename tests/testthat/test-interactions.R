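# Contact classification and residue interaction profiles.

# minimal hand-built complex: site tables with explicit roles
site_row <- function(element, x, y, z, rn = 1L, rname = "LIG", aname = element,
                     donor = FALSE, acceptor = FALSE, aromatic = FALSE,
                     hydrophobic = FALSE, hydrophilic = FALSE, halogen = FALSE) {
  data.frame(element = element, x = x, y = y, z = z, residue_number = rn,
             residue_name = rname, atom_name = aname, donor = donor,
             acceptor = acceptor, aromatic = aromatic,
             hydrophobic = hydrophobic, hydrophilic = hydrophilic,
             halogen = halogen)
}

toy_complex <- function(protein, ligand) {
  structure(list(protein = protein, ligand = ligand), class = "oxa_complex")
}

test_that("atom role rules follow the documented conventions", {
  expect_setequal(atom_roles("N", n_h = 1, neighbor_elements = c("C", "C")),
                  c("donor", "acceptor", "hydrophilic"))
  expect_setequal(atom_roles("C", neighbor_elements = c("C", "C"),
                             aromatic = TRUE),
                  c("aromatic", "hydrophobic"))
  expect_identical(atom_roles("Br", neighbor_elements = "C"), "halogen")
  expect_setequal(atom_roles("O", n_h = 0), c("acceptor", "hydrophilic"))
  expect_identical(atom_roles("N", n_h = 0, charge = 1L), "hydrophilic")
  expect_identical(atom_roles("C", neighbor_elements = c("C", "O")), character())
  expect_error(atom_roles("Xe"), "unknown element")
})

test_that("contacts classify by distance rules with fixed precedence", {
  pN <- site_row("N", 0, 0, 0, rn = 202, rname = "LYS", aname = "NZ",
                 donor = TRUE, acceptor = TRUE, hydrophilic = TRUE)
  pC <- site_row("C", 40, 0, 0, rn = 278, rname = "LEU", aname = "CD1",
                 hydrophobic = TRUE)
  pS <- site_row("S", 20, 0, 0, rn = 287, rname = "MET", aname = "SD",
                 hydrophobic = TRUE)
  lO <- site_row("O", 0, 2.9, 0, rn = 900, acceptor = TRUE, hydrophilic = TRUE)
  lCl <- site_row("Cl", 20, 3.2, 0, rn = 900, halogen = TRUE)
  lfar <- site_row("C", 40, 6.0, 0, rn = 900, aromatic = TRUE,
                   hydrophobic = TRUE)
  ct <- detect_contacts(toy_complex(rbind(pN, pC, pS), rbind(lO, lCl, lfar)))
  expect_identical(nrow(ct), 2L)
  expect_identical(ct$contact_class[ct$residue_number == 202], "hbond")
  # ligand halogen toward a protein S heavy atom within 3.6 A
  expect_identical(ct$contact_class[ct$residue_number == 287], "halogen_bond")
  # halogen beats hydrophilic-hydrophobic against a protein N as well
  ct2 <- detect_contacts(toy_complex(pN, lCl[, ] |> transform(x = 0)))
  expect_identical(ct2$contact_class, "halogen_bond")
  # a hydrophilic-hydrophobic pair inside 4 A is destabilizing
  ct3 <- detect_contacts(toy_complex(pC, lO |> transform(x = 40, y = 3.5)))
  expect_identical(ct3$contact_class, "destabilizing")
  # beyond every cutoff: nothing
  expect_identical(nrow(detect_contacts(toy_complex(pC, lfar))), 0L)
  expect_error(detect_contacts(toy_complex(pN[0, ], lO)), "no protein")
})

test_that("classification is invariant under rigid rotation and translation", {
  pres <- data.frame(residue_number = c(201, 233, 157, 278),
                     contact_class = c("hbond", "halogen_bond", "aromatic",
                                       "hydrophobic"))
  cx <- generate_complex(pres)
  base <- detect_contacts(cx)
  set.seed(77)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]),
                   cos(th[1])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    rot <- Rx %*% Rz
    shift <- runif(3, -20, 20)
    cx2 <- cx
    for (part in c("protein", "ligand")) {
      xyz <- as.matrix(cx2[[part]][, c("x", "y", "z")]) %*% t(rot)
      cx2[[part]][, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
    }
    moved <- detect_contacts(cx2)
    expect_identical(sort(paste(moved$residue_number, moved$contact_class)),
                     sort(paste(base$residue_number, base$contact_class)))
  }
})

test_that("generated complexes realize exactly the prescribed contacts", {
  pres <- data.frame(residue_number = c(233, 278),
                     contact_class = c("halogen_bond", "hydrophobic"))
  ct <- detect_contacts(generate_complex(pres))
  expect_identical(nrow(ct), 2L)  # exactly those two contacts
  expect_identical(ct$contact_class[order(ct$residue_number)],
                   c("halogen_bond", "hydrophobic"))
  one <- detect_contacts(generate_complex(
    data.frame(residue_number = 201, contact_class = "hbond")))
  expect_identical(nrow(one), 1L)
  expect_identical(one$contact_class, "hbond")
  expect_identical(one$residue_number, 201L)
  # empty prescription yields no contacts
  expect_identical(nrow(detect_contacts(generate_complex(NULL))), 0L)
  # all five classes round-trip, with every distance within its class cutoff
  all5 <- data.frame(residue_number = c(201, 233, 157, 278, 236),
                     contact_class = c("hbond", "halogen_bond", "aromatic",
                                       "hydrophobic", "destabilizing"))
  ct5 <- detect_contacts(generate_complex(all5))
  got <- unique(ct5[, c("residue_number", "contact_class")])
  expect_identical(got[order(got$residue_number), ]$contact_class,
                   all5[order(all5$residue_number), ]$contact_class)
  cuts <- contact_cutoffs()
  expect_true(all(ct5$distance <= cuts[ct5$contact_class] + 1e-9))
  expect_error(generate_complex(data.frame(residue_number = 1,
                                           contact_class = "vanderwaals")),
               "unsupported")
  expect_error(generate_complex(data.frame(residue_number = c(1, 1),
                                           contact_class = c("hbond", "aromatic"))),
               "unsatisfiable")
})

test_that("complexes survive a PDB round trip with identical contact classes", {
  pres <- data.frame(residue_number = c(201, 233, 278, 236, 157),
                     contact_class = c("hbond", "halogen_bond", "hydrophobic",
                                       "destabilizing", "aromatic"))
  cx <- generate_complex(pres)
  tmp <- tempfile(fileext = ".pdb")
  write_complex_pdb(cx, tmp)
  back <- read_complex_pdb(tmp)
  a <- detect_contacts(cx); b <- detect_contacts(back)
  expect_identical(sort(paste(a$residue_number, a$contact_class)),
                   sort(paste(b$residue_number, b$contact_class)))
})

test_that("residue profiles aggregate contact fractions and compositions", {
  ct_of <- function(rns, classes) {
    data.frame(residue_number = rns, residue_name = "GLY", protein_atom = "N",
               ligand_atom = "X1", ligand_element = "C", distance = 3.0,
               contact_class = classes)
  }
  sets <- list(
    ct_of(c(201, 201, 233), c("hbond", "hydrophobic", "hbond")),
    ct_of(201, "hbond"),
    ct_of(c(233, 276), c("halogen_bond", "halogen_bond")))
  prof <- residue_profiles(sets, residues = c(201, 233, 276, 999))
  p201 <- prof[prof$residue_number == 201, ]
  expect_equal(p201$fraction_of_compounds, 2 / 3)
  expect_equal(p201$hbond, 2 / 3)        # 2 of 3 contacts at 201
  expect_equal(p201$hydrophobic, 1 / 3)
  p233 <- prof[prof$residue_number == 233, ]
  expect_equal(p233$fraction_of_compounds, 2 / 3)
  expect_equal(p233$hbond + p233$halogen_bond, 1)
  p999 <- prof[prof$residue_number == 999, ]
  expect_equal(p999$fraction_of_compounds, 0)
  expect_equal(sum(p999[, c("hbond", "halogen_bond", "aromatic",
                            "hydrophobic", "destabilizing")]), 0)
  # composition rows sum to one wherever contacts exist
  comp <- prof[prof$residue_number != 999,
               c("hbond", "halogen_bond", "aromatic", "hydrophobic",
                 "destabilizing")]
  expect_equal(unname(rowSums(comp)), rep(1, 3))
})

test_that("halogen-bond shares split per residue and sum to one", {
  hb <- function(rn) data.frame(residue_number = rn, residue_name = "GLN",
                                protein_atom = "NE2", ligand_atom = "Cl1",
                                ligand_element = "Cl", distance = 3.2,
                                contact_class = "halogen_bond")
  sets <- list(rbind(hb(233), hb(233)), rbind(hb(233), hb(276)))
  sh <- halogen_contributions(sets)
  expect_equal(sh$share[sh$residue_number == 233], 0.75)
  expect_equal(sh$share[sh$residue_number == 276], 0.25)
  expect_equal(sum(sh$share), 1)
  none <- halogen_contributions(list(hb(233)[0, ]))
  expect_identical(nrow(none), 0L)
})
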