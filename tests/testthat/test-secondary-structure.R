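test_that("ideal helices are assigned H over their interior", {
  for (n in c(10, 15, 20)) {
    p <- select_pocket(ideal_helix(n), "A", 1, n)
    ann <- assign_sse(p)
    expect_gte(sum(ann$state == "H"), n - 4)
    expect_equal(ann$state[3:(n - 3)], rep("H", n - 5))
  }
})

test_that("a lone extended chain gets no helix states", {
  bb <- pocketprofiler:::build_backbone(12, phi = -139, psi = 135)
  s <- pocketprofiler:::backbone_structure(bb, rep("ALA", 12))
  ann <- assign_sse(select_pocket(s, "A", 1, 12))
  expect_false(any(ann$state == "H"))
})

test_that("the antiparallel strand pair is recognized as strands", {
  sp <- ideal_strand_pair(8)
  expect_equal(nrow(sp$atoms) / 4, 16)   # backbone-only residues
  ann <- assign_sse(select_pocket(sp, "A", 1, 100))
  ## both strands carry E states
  expect_gt(sum(ann$state[1:8] == "E"), 0)
  expect_gt(sum(ann$state[9:16] == "E"), 0)
  expect_false(any(ann$state == "H"))
  ## far-separated strands cannot hydrogen-bond
  far <- assign_sse(select_pocket(ideal_strand_pair(6, separation = 20),
                                  "A", 1, 100))
  expect_true(all(far$state == "C"))
})

test_that("tiny pockets are all-coil without error", {
  p <- select_pocket(ideal_helix(4), "A", 1, 4)
  expect_true(all(assign_sse(p)$state == "C"))
})

test_that("group_elements matches direct run scanning", {
  mk_ann <- function(states) {
    ann <- data.frame(chain = "A", resnum = seq_along(states), icode = "",
                      resname = "ALA", state = states,
                      stringsAsFactors = FALSE)
    class(ann) <- c("sse_annotation", "data.frame")
    ann
  }
  el <- group_elements(mk_ann(strsplit("CCHHHHHCCEEECC", "")[[1]]))
  expect_equal(nrow(el$elements), 2L)
  expect_equal(el$elements$state, c("H", "E"))
  expect_equal(el$elements$length, c(5L, 3L))
  expect_equal(nrow(group_elements(mk_ann(rep("C", 9)))$elements), 0L)

  ## randomized annotations against the exhaustive run scanner
  set.seed(42)
  for (k in 1:20) {
    states <- sample(c("H", "E", "C"), 50, replace = TRUE)
    got <- group_elements(mk_ann(states))
    want <- oracle_elements(states, 4L, 2L)
    expect_equal(nrow(got$elements), length(want))
    if (length(want)) {
      expect_equal(got$elements$state,
                   vapply(want, `[[`, "", "state"))
      expect_equal(got$elements$length,
                   vapply(want, function(w) as.integer(w$length), integer(1)))
    }
    ## partition: no residue in two elements, lengths bounded by pocket size
    re <- got$residue_element
    expect_true(all(table(re[!is.na(re)]) ==
                      got$elements$length[sort(unique(re[!is.na(re)]))]))
    expect_lte(sum(got$elements$length), 50L)
  }
})

test_that("assignment is invariant under rigid-body motion", {
  h <- ideal_helix(15)
  ann1 <- assign_sse(select_pocket(h, "A", 1, 15))
  for (s in 1:3) {
    ann2 <- assign_sse(select_pocket(transform_structure(h, s), "A", 1, 15))
    expect_identical(ann1$state, ann2$state)
  }
})

test_that("external STRIDE and DSSP assignments load and map to three states", {
  stride <- c(
    "REM  -------------------- Secondary structure summary ---------------",
    "ASG  ALA A    1    1    C          Coil    360.00    126.00     120.1",
    "ASG  LEU A    2    2    H    AlphaHelix    -57.00    -47.00      20.0",
    "ASG  GLY A    3    3    G      310Helix    -60.00    -30.00      10.0",
    "ASG  VAL A    4    4    E        Strand   -139.00    135.00       5.0",
    "ASG  SER A    5    5    B        Bridge   -100.00    120.00       5.0"
  )
  f <- tempfile(); writeLines(stride, f)
  ann <- load_external_sse(f)
  expect_equal(ann$state, c("C", "H", "H", "E", "E"))
  expect_equal(ann$resnum, 1:5)

  dssp <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >",
    "    2    2 A L  E   ",
    "    3    3 A G  T   "
  )
  f2 <- tempfile(); writeLines(dssp, f2)
  ann2 <- load_external_sse(f2, format = "dssp")
  expect_equal(ann2$state, c("H", "E", "C"))

  one <- tempfile()
  writeLines(c("ASG  VAL A    9    1    E        Strand   -139.0 135.0 5.0"),
             one)
  expect_equal(load_external_sse(one)$state, "E")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(load_external_sse(empty), "empty")
})

test_that("an external file written from internal ground truth matches it", {
  n <- 16
  p <- select_pocket(ideal_helix(n), "A", 1, n)
  internal <- assign_sse(p)
  stride <- sprintf("ASG  %s %s %4d %4d    %s    xxx    0.0 0.0 0.0",
                    internal$resname, internal$chain, internal$resnum,
                    seq_len(n), internal$state)
  f <- tempfile(); writeLines(stride, f)
  external <- match_annotation(p, load_external_sse(f))
  expect_identical(external$state, internal$state)
  ## unmatched residues produce a warning and fall back to coil
  expect_warning(m <- match_annotation(
    select_pocket(ideal_helix(n + 2), "A", 1, n + 2),
    load_external_sse(f)), "no external state")
  expect_equal(m$state[n + 1], "C")
})
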