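acyclic <- fragmentation_policy(bond_rule = "all_acyclic")

test_that("canonicalization aromatizes, strips stereo, and is idempotent", {
  expect_equal(canonicalize_smiles("C1=CC=CC=C1"), "c1ccccc1")
  expect_equal(canonicalize_smiles("N[C@@H](C)C(=O)O"),
               canonicalize_smiles("NC(C)C(=O)O"))
  expect_error(canonicalize_smiles("C1CC"), "unparsable")
  probes <- c("Cc1ccccc1", "OC(=O)/C=C/C(=O)O", "C[C@H](N)C(=O)O",
              "*c1ccc(cc1)C(F)(F)F", "c1ccc2[nH]ccc2c1", "CC(=O)N1CCCCC1")
  canon <- canonicalize_smiles(probes)
  expect_identical(canonicalize_smiles(canon), canon)
})

test_that("single cuts of small molecules match hand enumeration", {
  tol <- enumerate_cuts("Cc1ccccc1", acyclic, cid = "tol")
  expect_equal(nrow(tol), 1L)
  expect_equal(tol$core_smiles, canonicalize_smiles("[*]c1ccccc1"))
  expect_equal(tol$substituent_smiles, canonicalize_smiles("[*]C"))
  expect_equal(tol$substituent_heavy_atoms, 1L)

  eb <- enumerate_cuts("CCc1ccccc1", acyclic, cid = "eb")
  expect_equal(nrow(eb), 2L)
  expect_setequal(
    paste(eb$core_smiles, eb$substituent_smiles),
    paste(canonicalize_smiles(c("[*]c1ccccc1", "[*]Cc1ccccc1")),
          canonicalize_smiles(c("[*]CC", "[*]C"))))

  expect_equal(nrow(enumerate_cuts("C", acyclic)), 0L)      # no bond
  expect_equal(nrow(enumerate_cuts("c1ccccc1", acyclic)), 0L) # ring only
})

test_that("size restrictions control core/substituent assignment", {
  # bibenzyl's central bond splits into equal halves: no strict core
  bb <- enumerate_cuts("c1ccccc1CCc1ccccc1", acyclic)
  expect_false(canonicalize_smiles("[*]Cc1ccccc1") %in% bb$substituent_smiles)
  # without the smaller-than-core rule both assignments appear
  loose <- fragmentation_policy(bond_rule = "all_acyclic",
                                require_substituent_smaller_than_core = FALSE)
  bb2 <- enumerate_cuts("c1ccccc1CCc1ccccc1", loose)
  benzyl <- canonicalize_smiles("[*]Cc1ccccc1")
  expect_equal(sum(bb2$substituent_smiles == benzyl & bb2$core_smiles == benzyl), 2L)
  # substituent size cap discards large substituents
  tight <- fragmentation_policy(bond_rule = "all_acyclic",
                                max_substituent_heavy_atoms = 1L)
  eb <- enumerate_cuts("CCc1ccccc1", tight)
  expect_equal(nrow(eb), 1L)
  expect_equal(eb$substituent_heavy_atoms, 1L)
})

test_that("retrosynthetic rules restrict cuts to labile bonds", {
  # acetanilide: only the amide C-N bond is retrosynthetically cleavable
  ret <- enumerate_cuts("CC(=O)Nc1ccccc1", fragmentation_policy())
  expect_equal(nrow(ret), 1L)
  expect_equal(ret$substituent_smiles, canonicalize_smiles("[*]C(=O)C"))
  # the same molecule has three acyclic heavy-atom cuts in exhaustive mode
  expect_equal(nrow(enumerate_cuts("CC(=O)Nc1ccccc1", acyclic)), 3L)
  # ethyl benzoate: the acyl C-O bond cleaves; the alkyl C-O bond is not an
  # ether (its oxygen sits on a carbonyl) so it stays intact
  eb <- enumerate_cuts("CCOC(=O)c1ccccc1", fragmentation_policy())
  expect_equal(nrow(eb), 1L)
  expect_equal(eb$substituent_smiles, canonicalize_smiles("[*]OCC"))
  # retro cuts are a subset of acyclic cuts for assorted molecules
  for (s in c("CCNC(=O)c1ccccc1", "COc1ccc(CC(=O)NC)cc1",
              "CS(=O)(=O)Nc1ccc(OCC)cc1")) {
    r <- enumerate_cuts(s, fragmentation_policy())
    a <- enumerate_cuts(s, acyclic)
    expect_true(all(paste(r$core_smiles, r$substituent_smiles) %in%
                      paste(a$core_smiles, a$substituent_smiles)))
  }
})

test_that("retro pattern files are validated", {
  p <- write_tsv_lines(c("# comment", "[CX3;$([CX3]=[OX1])]!@[NX3] amide"))
  pats <- read_retro_patterns(p)
  expect_equal(pats$pattern_id, "amide")
  bad <- write_tsv_lines("[CX3](=[OX1])[NX3] threeatoms")
  expect_error(read_retro_patterns(bad), "exactly 2 atoms")
  invalid <- write_tsv_lines("[QQ] nonsense")
  expect_error(read_retro_patterns(invalid), "invalid SMARTS")
})

test_that("series assembly groups compounds by shared core", {
  cmp <- data.frame(cid = c("T1", "E1", "P1"),
                    smiles = c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1"))
  bs <- build_series(cmp, acyclic)
  phenyl <- canonicalize_smiles("[*]c1ccccc1")
  m <- series_map(bs)
  expect_equal(m[[phenyl]], c("E1", "P1", "T1"))
  # no shared core, no series
  bs2 <- build_series(data.frame(cid = c("A", "B"),
                                 smiles = c("Cc1ccccc1", "c1ccncc1")), acyclic)
  expect_equal(nrow(bs2$series), 0L)
  expect_error(build_series(data.frame(cid = c("A", "A"),
                                       smiles = c("CCO", "CCN")), acyclic),
               "duplicate")
})

test_that("the hydrogen analog joins its series only when admitted", {
  cmp <- data.frame(cid = c("B", "T", "E"),
                    smiles = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1"))
  with_h <- series_map(build_series(cmp, acyclic))
  phenyl <- canonicalize_smiles("[*]c1ccccc1")
  expect_true("B" %in% with_h[[phenyl]])
  no_h <- fragmentation_policy(bond_rule = "all_acyclic",
                               allow_hydrogen_substituent = FALSE)
  without <- series_map(build_series(cmp, no_h))
  expect_false("B" %in% without[[phenyl]])
  # the H membership reconstructs to the parent compound
  bs <- build_series(cmp, acyclic)
  h_row <- bs$members[bs$members$cid == "B", ]
  expect_equal(h_row$substituent_smiles, "[*][H]")
  expect_equal(reattach_fragments(phenyl, h_row$substituent_smiles),
               canonicalize_smiles("c1ccccc1"))
})

test_that("every extracted membership reconstructs its parent compound", {
  s <- small_synthetic(77, n_series = 4L, decoys = 4L)
  bs <- build_series(s$lib$compounds, acyclic)
  expect_gt(nrow(bs$members), 0L)
  core_of <- bs$series$core_smiles[match(bs$members$as_id, bs$series$as_id)]
  for (i in seq_len(nrow(bs$members))) {
    rebuilt <- reattach_fragments(core_of[i], bs$members$substituent_smiles[i])
    original <- s$lib$compounds$smiles[
      s$lib$compounds$cid == bs$members$cid[i]]
    expect_identical(rebuilt, original)
  }
})

test_that("series extraction is invariant to input order and policy tightening", {
  s <- small_synthetic(88, n_series = 3L, decoys = 4L)
  cmp <- s$lib$compounds
  m1 <- series_map(build_series(cmp, acyclic))
  set.seed(1)
  m2 <- series_map(build_series(cmp[sample(nrow(cmp)), ], acyclic))
  expect_identical(m1[order(names(m1))], m2[order(names(m2))])
  # a tighter size cap never creates a new series, and never adds members
  tight <- fragmentation_policy(bond_rule = "all_acyclic",
                                max_substituent_heavy_atoms = 3L)
  mt <- series_map(build_series(cmp, tight))
  expect_true(all(names(mt) %in% names(m1)))
  for (k in names(mt)) expect_true(all(mt[[k]] %in% m1[[k]]))
  # retro mode is a restriction of all-acyclic
  mr <- series_map(build_series(cmp, fragmentation_policy()))
  expect_true(all(names(mr) %in% names(m1)))
  for (k in names(mr)) expect_true(all(mr[[k]] %in% m1[[k]]))
})

test_that("series tables round-trip through the TSV format", {
  s <- small_synthetic(99, n_series = 3L, decoys = 2L)
  bs <- build_series(s$lib$compounds, acyclic)
  p <- tempfile(fileext = ".tsv")
  write_series_table(bs, p)
  bs2 <- read_series_table(p)
  expect_equal(bs2$series, bs$series, ignore_attr = TRUE)
  expect_equal(bs2$members, bs$members, ignore_attr = TRUE)
})

test_that("attachment-point bookkeeping: cores and substituents carry one token", {
  s <- small_synthetic(66, n_series = 2L, decoys = 2L)
  bs <- build_series(s$lib$compounds, acyclic)
  expect_true(all(n_attachment_points(bs$series$core_smiles) == 1L))
  subs <- setdiff(unique(bs$members$substituent_smiles), "[*][H]")
  expect_true(all(n_attachment_points(subs) == 1L))
})
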