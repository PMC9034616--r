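# element-preserving subgroup, edge flowers and multiplicity assignment

furan_setup <- function() {
  g <- cycle_graph(5)
  f <- parse_formula("C4H4O")
  fp <- find_flowers(g)
  N <- compute_N(g, fp)
  L <- assign_elements(g, f, N = N, fp = fp)[[1]]
  list(g = g, f = f, fp = fp, N = N, L = L)
}

test_that("element-preserving subgroup filters N and acts on edges", {
  s <- furan_setup()
  eN <- edge_preserving_subgroup(s$N, s$L, s$g)
  expect_equal(eN$order, 2)                       # id + reflection through O
  for (p in eN$members) expect_equal(sort(p), seq_len(nrow(s$g$edges)))

  # an element list breaking the path's reflection leaves a trivial edge group
  p5 <- path_graph(5)
  N5 <- compute_N(p5)          # reflection survives the singleton-flower colours
  expect_equal(edge_preserving_subgroup(N5, c("O", "C", "C", "C", "C"), p5)$order, 1)
  expect_equal(edge_preserving_subgroup(N5, c("C", "C", "O", "C", "C"), p5)$order,
               N5$order)

  # a member swapping differently-labelled vertices is rejected
  cyc4 <- cycle_graph(4)
  N4 <- automorphism_group(cyc4)                  # full dihedral group, order 8
  eN4 <- edge_preserving_subgroup(N4, c("O", "C", "C", "C"), cyc4)
  expect_equal(eN4$order, 2)                      # only id + reflection fixing O
})

test_that("filtered subgroup equals a fresh colour-constrained computation", {
  set.seed(31)
  for (i in 1:6) {
    g <- random_connected_graph(sample(4:7, 1), extra = sample(0:2, 1))
    f_syms <- c("C", "N", "O")
    fp <- find_flowers(g)
    N <- compute_N(g, fp)
    L <- sample(f_syms, g$n, replace = TRUE)
    eN <- edge_preserving_subgroup(N, L, g)
    # fresh: automorphisms preserving flower colours AND elements jointly
    joint <- as.integer(interaction(flower_coloring(g, fp), factor(L, f_syms)))
    fresh <- automorphism_group(g, joint)
    idx <- isogen:::edge_index_map(g)
    fresh_edges <- lapply(fresh$members, function(p) {
      as.integer(idx[as.character(isogen:::edge_key(p[g$edges[, 1]],
                                                    p[g$edges[, 2]], g$n))])
    })
    expect_setequal(vapply(eN$members, perm_key, character(1)),
                    vapply(fresh_edges, perm_key, character(1)))
  }
})

test_that("edge flowers split vertex flowers by element", {
  st <- star_graph(3)                              # leaves 1..3 at centre 4
  fp <- find_flowers(st)
  ef1 <- edge_flowers(st, c("C", "C", "C", "C"), fp)
  expect_equal(ef1, list(1:3))                     # all leaves alike: one flower
  ef2 <- edge_flowers(st, c("O", "C", "C", "C"), fp)
  expect_equal(sort(lengths(ef2)), c(1L, 2L))      # O leaf splits off
  expect_equal(edge_flowers(cycle_graph(5), rep("C", 5), find_flowers(cycle_graph(5))),
               list())
})

test_that("furan bond assignments: the computed orbit classes", {
  # brute force over all 3^5 multiplicity vectors for the O-placed 5-ring:
  # the two O edges are forced single, leaving a triple on one of 3 C-C edges
  # (2 orbits) or two doubles (2 orbits) -- 4 classes in total
  s <- furan_setup()
  eN <- edge_preserving_subgroup(s$N, s$L, s$g)
  efp <- edge_flowers(s$g, s$L, s$fp)
  mols <- assign_multiplicities(s$g, s$L, s$f, eN, efp)

  target <- edge_budget(s$f)$bond_total
  valv <- unname(s$f$valences[s$L])
  all_vecs <- isogen:::multiplicity_vectors(nrow(s$g$edges), target)
  ok <- Filter(function(mv) {
    inc <- integer(5)
    for (i in seq_len(5)) {
      inc[s$g$edges[i, 1]] <- inc[s$g$edges[i, 1]] + mv[i]
      inc[s$g$edges[i, 2]] <- inc[s$g$edges[i, 2]] + mv[i]
    }
    all(inc <= valv)
  }, all_vecs)
  classes <- unique(vapply(ok, function(mv) {
    imgs <- vapply(eN$members, function(p) paste(mv[order(p)], collapse = ""),
                   character(1))
    max(imgs)
  }, character(1)))
  expect_equal(length(mols), length(classes))
  expect_equal(length(mols), 4L)
  # the emitted representatives are exactly the class maxima
  expect_setequal(vapply(mols, function(m) paste(m$bonds, collapse = ""),
                         character(1)), classes)
})

test_that("single-atom molecules and hydrogen bookkeeping", {
  g1 <- simple_graph(1)
  f <- parse_formula("CH4")
  mols <- assign_multiplicities(g1, "C", f,
                                structure(list(order = 1, members = list(integer(0))),
                                          class = "perm_group"), list())
  expect_length(mols, 1L)
  expect_equal(mols[[1]]$implicit_h, 4L)
  # wrong hydrogen count: empty stream
  f2 <- parse_formula("CH2")
  expect_length(assign_multiplicities(g1, "C", f2,
                                      structure(list(order = 1, members = list(integer(0))),
                                                class = "perm_group"), list()), 0L)
})

test_that("conservation laws hold for every generated molecule", {
  for (fm in c("C3H4O", "C2H3N", "C4H6")) {
    f <- parse_formula(fm)
    b <- edge_budget(f)
    r <- generate_isomers(f)
    expect_gt(r$count, 0)
    for (mol in r$molecules) {
      expect_equal(sum(mol$bonds), b$bond_total)
      expect_equal(sum(mol$implicit_h), f$hydrogens)
      expect_true(all(mol$implicit_h >= 0L))
      # per-vertex: incident multiplicity sum + implicit H = valence
      inc <- integer(mol$graph$n)
      for (i in seq_len(nrow(mol$graph$edges))) {
        inc[mol$graph$edges[i, 1]] <- inc[mol$graph$edges[i, 1]] + mol$bonds[i]
        inc[mol$graph$edges[i, 2]] <- inc[mol$graph$edges[i, 2]] + mol$bonds[i]
      }
      expect_equal(inc + mol$implicit_h, unname(f$valences[mol$elements]))
    }
  }
})

test_that("bond orbits match brute force under the full element-preserving group", {
  # independent of the flower machinery: orbit-reduce with the complete
  # automorphism group of the labelled skeleton
  for (fm in c("C3H4O", "C3H2")) {
    f <- parse_formula(fm)
    for (g in generate_simple_graphs(f)) {
      fp <- find_flowers(g)
      N <- compute_N(g, fp)
      for (L in assign_elements(g, f, N = N, fp = fp)) {
        mine <- assign_multiplicities(g, L, f,
                                      edge_preserving_subgroup(N, L, g),
                                      edge_flowers(g, L, fp))
        # full labelled-graph automorphisms on edges
        Afull <- Filter(function(p) all(act_on_list(p, L) == L),
                        automorphism_group(g)$members)
        idx <- isogen:::edge_index_map(g)
        Ae <- lapply(Afull, function(p) {
          as.integer(idx[as.character(isogen:::edge_key(p[g$edges[, 1]],
                                                        p[g$edges[, 2]], g$n))])
        })
        target <- edge_budget(f)$bond_total
        valv <- unname(f$valences[L])
        vecs <- Filter(function(mv) {
          inc <- integer(g$n)
          for (i in seq_along(mv)) {
            inc[g$edges[i, 1]] <- inc[g$edges[i, 1]] + mv[i]
            inc[g$edges[i, 2]] <- inc[g$edges[i, 2]] + mv[i]
          }
          all(inc <= valv)
        }, isogen:::multiplicity_vectors(nrow(g$edges), target))
        classes <- unique(vapply(vecs, function(mv) {
          max(vapply(Ae, function(p) paste(mv[order(p)], collapse = ","),
                     character(1)))
        }, character(1)))
        expect_setequal(vapply(mine, function(m) paste(m$bonds, collapse = ","),
                               character(1)), classes)
      }
    }
  }
})
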