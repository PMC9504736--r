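## random dense pocket: CA + CB residues scattered in a box, mixed classes
random_pocket <- function(n = 25, box = 18, seed = 1) {
  set.seed(seed)
  names20 <- c(polarity_classes()$nonpolar, polarity_classes()$polar,
               polarity_classes()$charged)
  rows <- lapply(seq_len(n), function(i) {
    pos <- runif(3, 0, box)
    rn <- sample(names20, 1)
    at <- rbind(
      mk_atom(2 * i - 1, "CA", rn, i, pos[1], pos[2], pos[3], "C"),
      if (rn != "GLY")
        mk_atom(2 * i, "CB", rn, i, pos[1] + 0.9, pos[2] + 0.9,
                pos[3] + 0.6, "C")
    )
    at
  })
  select_pocket(as_structure(do.call(rbind, rows)), "A", 1, n)
}

test_that("residues classify into the standard polarity classes", {
  expect_equal(as.character(classify_residue(c("LEU", "GLY", "TRP"))),
               rep("nonpolar", 3))
  expect_equal(as.character(classify_residue("ASP")), "charged")
  expect_equal(as.character(classify_residue("SER")), "polar")
  expect_error(classify_residue("MSE"), "unclassified")
  expect_equal(as.character(classify_residue("MSE",
                                             extra = c(MSE = "nonpolar"))),
               "nonpolar")
})

test_that("composition percentages follow the counts and sum to ~100", {
  atoms <- do.call(rbind, list(
    mk_atom(1, "CA", "LEU", 1, 0, 0, 0, "C"),
    mk_atom(2, "CA", "LEU", 2, 30, 0, 0, "C"),
    mk_atom(3, "CA", "SER", 3, 60, 0, 0, "C"),
    mk_atom(4, "CA", "ASP", 4, 90, 0, 0, "C")
  ))
  cs <- composition(select_pocket(as_structure(atoms), "A", 1, 4))
  expect_equal(unname(cs$percent), c(50, 25, 25))
  for (seed in 1:5) {
    p <- random_pocket(seed = seed)
    cs <- composition(p)
    rounded <- round(cs$percent, 1)
    expect_lte(abs(sum(rounded) - 100), 0.8)
  }
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  donor <- rbind(mk_atom(1, "N", "GLY", 1, 0, 0, 0, "N"),
                 mk_atom(2, "CA", "GLY", 1, 1.45, 0, 0, "C"))
  mk_acc <- function(d) {
    ## acceptor O at distance d from N, antecedent angle ~160 degrees
    ang <- 160 * pi / 180
    o <- c(cos(ang), sin(ang), 0) * d
    rbind(mk_atom(3, "O", "GLY", 3, o[1], o[2], o[3], "O"),
          mk_atom(4, "C", "GLY", 3, o[1], o[2] + 1.23, o[3], "C"),
          mk_atom(5, "CA", "GLY", 3, o[1] + 1.4, o[2] + 2, o[3], "C"))
  }
  near <- select_pocket(as_structure(rbind(donor, mk_acc(2.9))), "A", 1, 3)
  hb <- detect_hbonds(near)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$angle, 160, tolerance = 0.5)
  far <- select_pocket(as_structure(rbind(donor, mk_acc(5.0))), "A", 1, 3)
  expect_equal(nrow(detect_hbonds(far)), 0L)
  ## tightening the angle cutoff removes the bond
  expect_equal(nrow(detect_hbonds(near, angle_min = 170)), 0L)
})

test_that("the contact network equals brute-force enumeration on random pockets", {
  nonpolar <- polarity_classes()$nonpolar
  for (seed in 1:30) {
    p <- random_pocket(n = 20, seed = seed)
    got <- nonpolar_contact_network(p, cutoff = 10)
    want <- oracle_contacts(p, 10, nonpolar)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      g <- got[order(got$resnum_a, got$resnum_b), ]
      expect_equal(g$resnum_a, want$resnum_a)
      expect_equal(g$resnum_b, want$resnum_b)
      expect_equal(g$distance, want$distance, tolerance = 1e-9)
    }
    ## cross + inside partitions the set
    expect_equal(sum(got$kind == "cross") + sum(got$kind == "inside"),
                 nrow(got))
  }
})

test_that("contacts beyond the cutoff are excluded and shrinking the cutoff nests", {
  tc <- toy_complex(8, contacts = list(list(a = 1, b = 3, distance = 12)),
                    seed = 4)
  p <- select_pocket(tc, "A", 1, 8)
  expect_equal(nrow(nonpolar_contact_network(p, cutoff = 10)), 0L)
  p2 <- random_pocket(n = 25, seed = 99)
  full <- nonpolar_contact_network(p2, cutoff = 10)
  for (cut in c(8, 6, 4)) {
    sub <- nonpolar_contact_network(p2, cutoff = cut)
    expect_true(all(paste(sub$resnum_a, sub$resnum_b) %in%
                      paste(full$resnum_a, full$resnum_b)))
    expect_true(all(sub$distance < cut))
  }
})

test_that("contacts split by secondary-structure element membership", {
  ## helix residues renamed to LEU so they count as nonpolar
  h <- ideal_helix(14)
  h$atoms$resname <- "LEU"
  p <- select_pocket(h, "A", 1, 14)
  ann <- assign_sse(p)
  el <- group_elements(ann)
  cc <- nonpolar_contact_network(p, el, cutoff = 10)
  expect_gt(nrow(cc), 0)
  in_el <- !is.na(el$residue_element)
  for (k in seq_len(nrow(cc))) {
    ia <- match(cc$resnum_a[k], ann$resnum)
    ib <- match(cc$resnum_b[k], ann$resnum)
    same <- in_el[ia] && in_el[ib] &&
      el$residue_element[ia] == el$residue_element[ib]
    expect_equal(cc$kind[k], if (same) "inside" else "cross")
  }
})

test_that("hydrogen bonds and contacts are invariant under rigid motion", {
  tc <- toy_complex(10,
    contacts = list(list(a = 1, b = 4, distance = 8)),
    hbonds = list(list(donor = 2, acceptor = 6, distance = 3.0,
                       angle = 150)),
    seed = 12)
  p <- select_pocket(tc, "A", 1, 10)
  hb0 <- detect_hbonds(p)
  cc0 <- nonpolar_contact_network(p, cutoff = 10)
  for (s in 1:3) {
    pt <- select_pocket(transform_structure(tc, s), "A", 1, 10)
    hb <- detect_hbonds(pt)
    cc <- nonpolar_contact_network(pt, cutoff = 10)
    expect_equal(nrow(hb), nrow(hb0))
    expect_equal(hb$distance, hb0$distance, tolerance = 1e-6)
    expect_equal(cc$distance, cc0$distance, tolerance = 1e-6)
  }
})

test_that("distance statistics use the population SD and handle edge cases", {
  one <- contact_statistics(7.0)
  expect_equal(one$n, 1L)
  expect_equal(one$mean, 7.0)
  expect_equal(one$sd, 0)
  d <- c(6, 7, 8, 9)
  st <- contact_statistics(d)
  expect_equal(st$mean, mean(d))
  expect_equal(st$sd, sqrt(mean((d - mean(d))^2)))   # population, not sample
  empty <- contact_statistics(data.frame(distance = numeric(0),
                                         kind = character(0)), "cross")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("the mode detector recovers a planted two-component mixture", {
  x <- simulate_contact_distances(1000, means = c(7.7, 8.3), sd = 0.2,
                                  seed = 1)
  modes <- distance_modes(x, bin_width = 0.25, smooth = 3)
  expect_equal(length(modes), 2L)
  expect_lte(abs(modes[1] - 7.7), 0.25)
  expect_lte(abs(modes[2] - 8.3), 0.25)
  ## a unimodal control stays unimodal
  set.seed(2)
  expect_equal(length(distance_modes(rnorm(1000, 8, 0.2))), 1L)
})
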