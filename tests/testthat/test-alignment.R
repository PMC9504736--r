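test_that("self-alignment gives 100% identity and an all-star line", {
  al <- align_sequences("MILVAYQK", "MILVAYQK")
  expect_equal(al$identity, 100)
  expect_equal(al$conservation, strrep("*", 8))
  expect_equal(al$aligned_a, al$aligned_b)
})

test_that("optimal scores match exhaustive alignment enumeration", {
  open <- 10; ext <- 0.5
  score_of <- function(a, b) {
    align_sequences(a, b, matrix = "BLOSUM62", gap_open = open,
                    gap_extend = ext)$score
  }
  ## the worked micro-example
  expect_equal(score_of("ACDE", "ACE"),
               oracle_align_score("ACDE", "ACE", blosum62, open, ext))
  ## exhaustive over every pair of length <= 3 on a 2-letter alphabet
  pool <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
  }))
  for (a in pool) {
    for (b in pool) {
      expect_equal(score_of(a, b),
                   oracle_align_score(a, b, blosum62, open, ext),
                   info = paste(a, b))
    }
  }
  ## random longer pairs over a 4-letter alphabet
  set.seed(3)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "D", "E"), sample(1:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E"), sample(1:6, 1), TRUE),
               collapse = "")
    expect_equal(score_of(a, b),
                 oracle_align_score(a, b, blosum62, open, ext),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric", {
  set.seed(4)
  for (k in 1:10) {
    a <- paste(sample(c("A", "C", "D", "E", "K", "L"), 8, TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "K", "L"), 6, TRUE),
               collapse = "")
    expect_equal(align_sequences(a, b)$score, align_sequences(b, a)$score)
  }
})

test_that("identity percentage honors both denominator modes", {
  al <- align_sequences("AAAA", "AATT")
  expect_equal(identity_percent(al, "shorter_sequence_length"), 50)
  expect_equal(identity_percent(al, "alignment_length"), 50)
  expect_equal(align_sequences("QWERTYKLMN", "QWERTYKLMN")$identity, 100)
})

test_that("conservation symbols follow the Clustal group tables", {
  expect_equal(conservation_line("L", "L"), "*")
  expect_equal(conservation_line("V", "I"), ":")   # strong group MILV
  expect_equal(conservation_line("S", "A"), ":")   # strong group STA
  expect_equal(conservation_line("A", "V"), ".")   # weak group ATV only
  expect_equal(conservation_line("A", "-"), " ")
  expect_equal(conservation_line("W", "D"), " ")
  ## line length always equals alignment length
  set.seed(5)
  for (k in 1:10) {
    a <- paste(sample(c("A", "C", "D", "E", "K", "L", "V"),
                      sample(2:9, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "K", "L", "V"),
                      sample(2:9, 1), TRUE), collapse = "")
    al <- align_sequences(a, b)
    expect_equal(nchar(al$conservation), nchar(al$aligned_a))
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    ## no column with two gaps
    ga <- strsplit(al$aligned_a, "")[[1]]
    gb <- strsplit(al$aligned_b, "")[[1]]
    expect_false(any(ga == "-" & gb == "-"))
  }
})

test_that("pocket sequences map residues and keep the numbering", {
  g <- as_structure(mk_atom(1, "CA", "GLY", 5, 0, 0, 0, "C"))
  ps <- pocket_sequence(select_pocket(g, "A", 5, 5))
  expect_equal(ps$seq, "G")
  h <- select_pocket(ideal_helix(12), "A", 1, 12)
  expect_equal(pocket_sequence(h)$seq, strrep("A", 12))
  ## a missing residue is omitted with a warning
  hm <- ideal_helix(12)
  hm$atoms <- hm$atoms[hm$atoms$resnum != 6, ]
  expect_warning(ps2 <- pocket_sequence(select_pocket(hm, "A", 1, 12)),
                 "missing")
  expect_equal(nchar(ps2$seq), 11)
})

test_that("Clustal ALN output and FASTA round-trips are well formed", {
  a <- paste(rep("ACDEFGHIKL", 8), collapse = "")
  b <- paste(rep("ACDEFGHIKM", 8), collapse = "")
  al <- align_sequences(a, b)
  f <- tempfile(fileext = ".aln")
  write_clustal(al, f, names = c("jak_a", "jak_b"))
  lines <- readLines(f)
  expect_match(lines[1], "CLUSTAL")
  body <- lines[grepl("^jak_a", lines)]
  expect_true(all(nchar(gsub("^jak_a\\s+", "", body)) <= 60))
  ff <- tempfile(fileext = ".fasta")
  write_fasta(c(sa = a, sb = b), ff)
  back <- read_fasta(ff)
  expect_equal(unname(back["sa"]), a)
  expect_equal(unname(back["sb"]), b)
})
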