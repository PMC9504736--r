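test_that("planted hydrophobic contacts are counted exactly", {
  tc <- toy_complex(10,
    ligand = list(elements = rep("C", 5),
                  near = list(list(residue = 1, distance = 4),
                              list(residue = 2, distance = 7),
                              list(residue = 3, distance = 9),
                              list(residue = 4, distance = 9.9))),
    seed = 21)
  m <- as_structure(tc$atoms)
  lig <- extract_ligand(m, "LIG")
  p <- select_pocket(m, "A", 1, 10)
  hc <- hydrophobic_contacts(p, lig, cutoff = 10)
  expect_equal(nrow(hc), 4L)
  expect_equal(sort(hc$resnum), 1:4)
  expect_equal(sort(hc$distance), c(4, 7, 9, 9.9), tolerance = 0.05)
  ## vanishing cutoff removes everything on a non-clashing complex
  expect_equal(nrow(hydrophobic_contacts(p, lig, cutoff = 0.1)), 0L)
  ## count is monotone in the cutoff
  n_at <- vapply(c(5, 8, 10, 12),
                 function(ct) nrow(hydrophobic_contacts(p, lig, ct)),
                 integer(1))
  expect_true(all(diff(n_at) >= 0))
})

test_that("only nonpolar residues enter the hydrophobic count", {
  tc <- toy_complex(4, resnames = c("LEU", "SER", "ARG", "GLY"),
    ligand = list(elements = rep("C", 4),
                  near = list(list(residue = 1, distance = 5),
                              list(residue = 2, distance = 5),
                              list(residue = 3, distance = 5),
                              list(residue = 4, distance = 5))),
    seed = 22)
  m <- as_structure(tc$atoms)
  p <- select_pocket(m, "A", 1, 4)
  lig <- extract_ligand(m, "LIG")
  hc <- hydrophobic_contacts(p, lig)
  expect_equal(sort(hc$resname), c("GLY", "LEU"))
  ## but every residue competes for the binding locus
  prof <- ligand_profile(p, lig)
  expect_setequal(prof$locus$resnum, 1:4)
})

test_that("a planted protein-ligand hydrogen bond is found in both directions", {
  ## protein donor (backbone N) to ligand carbonyl O at 2.9 A / 170 deg
  prot <- rbind(mk_atom(1, "N", "GLY", 1, 0, 0, 0, "N"),
                mk_atom(2, "CA", "GLY", 1, 1.45, 0, 0, "C"))
  ang <- 170 * pi / 180
  o <- c(cos(ang), sin(ang), 0) * 2.9
  lig_at <- rbind(
    mk_atom(10, "O1", "LIG", 900, o[1], o[2], o[3], "O",
            record = "HETATM", chain = "X"),
    mk_atom(11, "C1", "LIG", 900, o[1], o[2] - 1.23, o[3], "C",
            record = "HETATM", chain = "X")
  )
  m <- as_structure(rbind(prot, lig_at))
  p <- select_pocket(m, "A", 1, 1)
  lig <- extract_ligand(m, "LIG")
  hb <- ligand_hbonds(p, lig)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$direction, "protein_donor")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)

  ## ligand amine N donating to a protein backbone O
  prot2 <- rbind(mk_atom(1, "O", "GLY", 1, 0, 0, 0, "O"),
                 mk_atom(2, "C", "GLY", 1, 0, -1.23, 0, "C"),
                 mk_atom(3, "CA", "GLY", 1, 1.3, -2, 0, "C"))
  lig2 <- rbind(
    mk_atom(10, "N1", "LIG", 900, 0, 3.0, 0, "N", record = "HETATM",
            chain = "X"),
    mk_atom(11, "C1", "LIG", 900, 0, 4.45, 0, "C", record = "HETATM",
            chain = "X")
  )
  m2 <- as_structure(rbind(prot2, lig2))
  hb2 <- ligand_hbonds(select_pocket(m2, "A", 1, 1),
                       extract_ligand(m2, "LIG"))
  expect_equal(nrow(hb2), 1L)
  expect_equal(hb2$direction, "ligand_donor")

  ## a nitrile nitrogen (triple-bond neighbor) cannot donate
  lig3 <- rbind(
    mk_atom(10, "N1", "LIG", 900, 0, 3.0, 0, "N", record = "HETATM",
            chain = "X"),
    mk_atom(11, "C1", "LIG", 900, 0, 4.16, 0, "C", record = "HETATM",
            chain = "X")
  )
  m3 <- as_structure(rbind(prot2, lig3))
  expect_equal(nrow(ligand_hbonds(select_pocket(m3, "A", 1, 1),
                                  extract_ligand(m3, "LIG"))), 0L)

  ## moving the ligand far away empties the result
  lig_far <- lig_at
  lig_far$x <- lig_far$x + 50
  mf <- as_structure(rbind(prot, lig_far))
  expect_equal(nrow(ligand_hbonds(select_pocket(mf, "A", 1, 1),
                                  extract_ligand(mf, "LIG"))), 0L)
})

test_that("the binding locus ranks nearest residues with deterministic ties", {
  tc <- toy_complex(8,
    ligand = list(elements = rep("C", 3),
                  near = list(list(residue = 5, distance = 3),
                              list(residue = 2, distance = 6),
                              list(residue = 7, distance = 8))),
    seed = 30)
  m <- as_structure(tc$atoms)
  p <- select_pocket(m, "A", 1, 8)
  prof <- ligand_profile(p, extract_ligand(m, "LIG"))
  expect_equal(prof$locus$resnum[1:3], c(5L, 2L, 7L))
  expect_warning(all_res <- binding_locus(prof, k = 99), "exceeds")
  expect_equal(nrow(all_res), 8L)
})

test_that("interaction sweeps always hold one row per interaction", {
  set.seed(100)
  for (k in 1:100) {
    n_near <- sample(0:4, 1)
    dists <- runif(n_near, 3, 9.5)
    near <- lapply(seq_len(n_near), function(i)
      list(residue = i, distance = dists[i]))
    tc <- toy_complex(8, ligand = list(elements = rep("C", 4), near = near),
                      seed = 1000 + k)
    m <- as_structure(tc$atoms)
    prof <- ligand_profile(select_pocket(m, "A", 1, 8),
                           extract_ligand(m, "LIG"))
    expect_equal(prof$n_hydrophobic, n_near)
    expect_equal(prof$n_hb, 0L)
    sw <- interaction_sweep(prof)
    expect_equal(nrow(sw), prof$n_hb + prof$n_hydrophobic)
    ## every locus residue is accounted for by a contact or bond when close
    expect_true(all(diff(sw$distance[sw$type == "hydrophobic"]) >= 0))
  }
})

test_that("ligand interaction counts survive rigid-body motion", {
  tc <- toy_complex(8,
    ligand = list(elements = rep("C", 4),
                  near = list(list(residue = 1, distance = 5),
                              list(residue = 3, distance = 8))),
    seed = 55)
  m <- as_structure(tc$atoms)
  base <- ligand_profile(select_pocket(m, "A", 1, 8),
                         extract_ligand(m, "LIG"))
  for (s in 1:3) {
    mt <- transform_structure(m, s)
    prof <- ligand_profile(select_pocket(mt, "A", 1, 8),
                           extract_ligand(mt, "LIG"))
    expect_equal(prof$n_hydrophobic, base$n_hydrophobic)
    expect_equal(sort(prof$hydrophobic$distance),
                 sort(base$hydrophobic$distance), tolerance = 1e-6)
  }
})
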