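test_that("templates cover every edge exactly once", {
  t1 <- build_smiles_template(simple_graph(1))
  expect_equal(sum(vapply(t1$tokens, function(tk) tk$t == "atom", logical(1))), 1L)
  expect_equal(t1$n_closures, 0L)

  t5 <- build_smiles_template(cycle_graph(5))
  expect_equal(t5$n_closures, 1L)                 # one ring closure pair
  atom_slots <- sum(vapply(t5$tokens, function(tk) tk$t == "atom", logical(1)))
  expect_equal(atom_slots, 5L)

  tp <- build_smiles_template(path_graph(3))
  expect_equal(tp$n_closures, 0L)

  # every edge appears exactly once as a tree bond or a closure pair
  set.seed(5)
  for (i in 1:6) {
    g <- random_connected_graph(sample(4:8, 1), extra = sample(0:3, 1))
    t <- build_smiles_template(g)
    tree_e <- unlist(lapply(t$tokens, function(tk) if (tk$t == "bond") tk$e))
    ring_e <- unlist(lapply(t$tokens, function(tk) if (tk$t == "ring") tk$e))
    expect_setequal(c(tree_e, unique(ring_e)), seq_len(nrow(g$edges)))
    expect_equal(length(tree_e) + length(unique(ring_e)), nrow(g$edges))
    expect_equal(t$n_closures, nrow(g$edges) - (g$n - 1L))
  }
})

test_that("reference SMILES strings", {
  expect_equal(generate_isomers("CH4", output = "smiles")$smiles, "C")
  expect_equal(generate_isomers("C2H6", output = "smiles")$smiles, "CC")
  expect_setequal(obabel_canonical(generate_isomers("C2H6O", output = "smiles")$smiles),
                  obabel_canonical(c("CCO", "COC")))
})

test_that("bracket atoms appear exactly when implied hydrogens are non-standard", {
  # with the fixed valence table N=3, ammonia-like N never needs brackets,
  # but an override S=6 forces explicit H counts
  s <- generate_isomers("SH6", valence_overrides = c(S = 6))$molecules[[1]]
  expect_equal(write_smiles(s, valences = c(S = 6L)), "[SH6]")
  expect_equal(generate_isomers("H3N", output = "smiles")$smiles, "N")
})

test_that("SMILES round-trip: parse back, isomorphic, pairwise distinct", {
  for (fm in c("C2H4O", "C3H6", "C4H4O")) {
    smis <- generate_isomers(fm, output = "smiles")$smiles
    can <- obabel_canonical(smis)
    expect_length(can, length(smis))          # every line parses
    expect_equal(anyDuplicated(can), 0L)      # outputs pairwise non-isomorphic
    # heavy-atom composition survives the round trip
    f <- parse_formula(fm)
    for (cs in can) {
      # canonical SMILES may use lowercase aromatic atoms
      atoms <- toupper(regmatches(cs, gregexpr("Cl|Br|[BCNOSPFIbcnops]", cs))[[1]])
      expect_equal(sort(atoms), sort(rep(names(f$counts), f$counts)))
    }
  }
})

test_that("furan Kekule SMILES re-parses with the right features", {
  mols <- generate_isomers("C4H4O")$molecules
  # the alternating arrangement: two doubles, no atom carrying both
  kek <- Filter(function(m) {
    if (sum(m$bonds == 2L) != 2L || nrow(m$graph$edges) != 5L ||
        !all(m$graph$degree == 2L)) return(FALSE)
    dbl <- m$graph$edges[m$bonds == 2L, , drop = FALSE]
    length(unique(as.vector(dbl))) == 4L
  }, mols)
  expect_length(kek, 1L)
  smi <- write_smiles(kek[[1]])
  can <- obabel_canonical(smi)
  expect_equal(can, obabel_canonical("o1cccc1")) # aromatic furan canonicalises alike
})

test_that("SDfile blocks are valid V2000 and agree with the SMILES output", {
  sdf <- generate_isomers("C2H4O", output = "sdf")$sdf
  expect_length(sdf, 3L)
  for (blk in sdf) {
    lines <- strsplit(blk, "\n")[[1]]
    expect_match(lines[4], "V2000")
    expect_true("M  END" %in% lines)
    expect_equal(lines[length(lines)], "$$$$")
    na <- as.integer(substr(lines[4], 1, 3))
    nb <- as.integer(substr(lines[4], 4, 6))
    expect_equal(length(lines), 4L + na + nb + 2L)
  }
  # ethene: 2 atoms, 1 bond of order 2
  eth <- generate_isomers("C2H4", output = "sdf")$sdf
  lines <- strsplit(eth[[1]], "\n")[[1]]
  expect_equal(as.integer(substr(lines[4], 1, 3)), 2L)
  expect_equal(as.integer(substr(lines[4], 4, 6)), 1L)
  bond <- lines[4L + 2L + 1L]
  expect_equal(as.integer(substr(bond, 7, 9)), 2L)

  # SDF and SMILES describe identical molecule multisets
  expect_setequal(obabel_canonical_sdf(paste(sdf, collapse = "\n")),
                  obabel_canonical(generate_isomers("C2H4O", output = "smiles")$smiles))
})

test_that("CH4 and furan molfiles have the stated shapes", {
  ch4 <- generate_isomers("CH4", output = "sdf")$sdf[[1]]
  lines <- strsplit(ch4, "\n")[[1]]
  expect_equal(as.integer(substr(lines[4], 1, 3)), 1L)
  expect_equal(as.integer(substr(lines[4], 4, 6)), 0L)
  mols <- generate_isomers("C4H4O")$molecules
  kek <- Filter(function(m) sum(m$bonds == 2L) == 2L &&
                  nrow(m$graph$edges) == 5L && all(m$graph$degree == 2L), mols)
  lines <- strsplit(write_sdf(kek[[1]], 1), "\n")[[1]]
  expect_equal(as.integer(substr(lines[4], 1, 3)), 5L)
  expect_equal(as.integer(substr(lines[4], 4, 6)), 5L)
  bond_orders <- as.integer(substr(lines[4 + 5 + seq_len(5)], 7, 9))
  expect_equal(sum(bond_orders == 2L), 2L)
})
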