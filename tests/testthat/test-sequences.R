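test_that("FASTA round trip, case normalization and degenerate input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acdg", ">y", "MKV", "LLT"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2)
  expect_equal(seqs[[1]]$id, "x")
  expect_equal(seqs[[1]]$residues, "ACDG")
  expect_equal(length(seqs[[1]]), 4)
  expect_equal(seqs[[2]]$residues, "MKVLLT")
  expect_equal(seqs[[1]]$first_residue_number, 1L)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "no records")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  expect_equal(read_fasta(out)[[2]]$residues, "MKVLLT")

  expect_error(protein_sequence("ABZ"), "non-canonical")
})

test_that("region extraction respects residue numbering", {
  full <- gen_idr_sequence(631, composition_preset("tad_like"), seed = 11)
  tad <- extract_region(full, 280, 631)
  expect_equal(length(tad), 352)
  expect_equal(tad$first_residue_number, 280L)
  dbdtad <- extract_region(full, 83, 631)
  expect_equal(length(dbdtad), 549)
  expect_error(extract_region(full, 632, 640), "outside")
  expect_error(extract_region(full, 100, 90))
  # a region of a region keeps absolute numbering
  sub <- extract_region(tad, 300, 310)
  expect_equal(length(sub), 11)
  expect_equal(substr(sub$residues, 1, 11),
               substr(full$residues, 300, 310))
})

test_that("five-category scheme partitions the alphabet and categorizes", {
  sch <- category_scheme()
  expect_setequal(names(sch), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_equal(unname(categorize(protein_sequence("RKDE"), sch)),
               c("cation", "cation", "anion", "anion"))
  expect_equal(unname(categorize(protein_sequence("FYW"), sch)),
               rep("aromatic", 3))
  expect_equal(unname(sch["H"]), "hydrophilic")  # His uncharged here
  expect_error(protein_sequence("B"), "non-canonical")
  expect_error(category_scheme(cation = c("R", "K", "H")), "partition")
})

test_that("composition fractions sum to one and combine charged+polar", {
  fr <- composition_fractions(poly_seq("A", 37))
  expect_equal(unname(fr["aliphatic"]), 1.0)
  expect_equal(unname(fr["charged_polar"]), 0.0)
  fr2 <- composition_fractions(protein_sequence("RKDEGNSHQT"))
  expect_equal(unname(fr2["charged_polar"]), 1.0)
  set.seed(42)
  for (i in 1:20) {
    s <- gen_idr_sequence(sample(5:200, 1), composition_preset("tad_like"),
                          seed = i)
    fr <- composition_fractions(s)
    expect_equal(sum(fr[1:5]), 1, tolerance = 1e-12)
    expect_equal(unname(fr["charged_polar"]),
                 unname(fr["cation"] + fr["anion"] + fr["hydrophilic"]))
  }
})

test_that("categorize commutes with extract_region", {
  s <- gen_idr_sequence(120, composition_preset("tad_like"), seed = 5)
  cats_then_cut <- categorize(s)[21:80]
  cut_then_cats <- categorize(extract_region(s, 21, 80))
  expect_equal(unname(cats_then_cut), unname(cut_then_cats))
})

test_that("composition of a concatenation is the length-weighted mean", {
  a <- gen_idr_sequence(60, composition_preset("tad_like"), seed = 1)
  b <- gen_idr_sequence(140, composition_preset("aliphatic_rich"), seed = 2)
  ab <- protein_sequence(paste0(a$residues, b$residues))
  fa <- composition_fractions(a)
  fb <- composition_fractions(b)
  fab <- composition_fractions(ab)
  expect_equal(fab, (60 * fa + 140 * fb) / 200, tolerance = 1e-14)
})

test_that("sliding profiles: degenerate windows and limits", {
  s <- poly_seq("S", 30)
  p <- sliding_profiles(s, window = 9)
  expect_true(all(p$bias == 1.0))
  expect_error(sliding_profiles(s, window = 4), "odd")
  expect_error(sliding_profiles(s, window = 31), "larger")

  # alternating charge cancels to within 1/window away from the termini
  # (truncated edge windows can only reach 1/4 for window 7)
  ke <- protein_sequence(paste(rep(c("K", "E"), 25), collapse = ""))
  p2 <- sliding_profiles(ke, window = 7)
  expect_true(all(abs(p2$charge[4:47]) <= 1 / 7 + 1e-12))
  expect_true(all(abs(p2$charge) <= 1 / 4 + 1e-12))

  # constant hydropathy input
  p3 <- sliding_profiles(poly_seq("I", 15), window = 5)
  expect_true(all(p3$hydropathy == kyte_doolittle()["I"]))

  # window 1 reproduces raw values
  r <- gen_idr_sequence(40, composition_preset("tad_like"), seed = 9)
  p4 <- sliding_profiles(r, window = 1)
  expect_equal(p4$hydropathy, unname(kyte_doolittle()[seq_chars(r)]))
  expect_equal(p4$charge, unname(residue_charges()[seq_chars(r)]))
})

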