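test_that("automorphism groups of reference graphs have the known orders", {
  cyc5 <- cycle_graph(5)
  expect_equal(automorphism_group(cyc5)$order, 10)        # dihedral: 5 rotations x 2
  expect_equal(automorphism_group(simple_graph(1))$order, 1)
  # furan colouring: one ring vertex distinguished leaves id + one reflection
  expect_equal(automorphism_group(cyc5, c(2, 1, 1, 1, 1))$order, 2)
  expect_equal(automorphism_group(complete_graph(4))$order, 24)
})

test_that("group members are closed, contain the identity and match BLISS", {
  set.seed(11)
  for (i in 1:8) {
    g <- random_connected_graph(sample(4:7, 1), extra = sample(0:2, 1))
    A <- automorphism_group(g)
    expect_equal(A$order, length(A$members))
    keys <- vapply(A$members, perm_key, character(1))
    expect_true(perm_key(seq_len(g$n)) %in% keys)
    for (p in A$members[seq_len(min(5, length(A$members)))]) {
      q <- A$members[[sample(length(A$members), 1)]]
      expect_true(perm_key(q[p]) %in% keys)               # closure
      # each member maps edges onto edges
      relab <- cbind(p[g$edges[, 1]], p[g$edges[, 2]])
      expect_equal(simple_graph(g$n, relab)$edges, g$edges)
    }
    expect_equal(A$order, igraph_aut_order(g))            # independent oracle
  }
})

test_that("flowers are found with the right members and minor orders", {
  st <- star_graph(3)                          # leaves 1,2,3 at centre 4
  fp <- find_flowers(st)
  expect_equal(fp$flowers, list(1:3))
  expect_equal(fp$minor_order, 6)

  expect_equal(find_flowers(cycle_graph(5))$flowers, list())
  expect_equal(find_flowers(cycle_graph(5))$minor_order, 1)

  # flowers of sizes 3, 2, 2 give |M| = 3! * 2! * 2! = 24
  # centre 4 holds {1,2,3}; centre 6 holds {7,8}; centre 9 holds {10,11}
  g <- simple_graph(11, rbind(c(1, 4), c(2, 4), c(3, 4), c(4, 5), c(5, 6),
                              c(6, 7), c(6, 8), c(5, 9), c(9, 10), c(9, 11)))
  fp <- find_flowers(g)
  expect_equal(sort(lengths(fp$flowers)), c(2L, 2L, 3L))
  expect_equal(fp$minor_order, 24)

  # two mutually adjacent leaves: two singleton flowers, no minor automorphism
  k2 <- simple_graph(2, rbind(c(1, 2)))
  fp2 <- find_flowers(k2)
  expect_equal(lengths(fp2$flowers), c(1L, 1L))
  expect_equal(fp2$minor_order, 1)
})

test_that("flower colouring is positional within flowers, reserved elsewhere", {
  st <- star_graph(3)
  expect_equal(flower_coloring(st), c(1L, 2L, 3L, 0L))
  expect_equal(flower_coloring(cycle_graph(5)), rep(0L, 5))
  # two flowers: same position in different flowers shares a colour
  g <- simple_graph(6, rbind(c(1, 3), c(2, 3), c(3, 4), c(4, 5), c(4, 6)))
  fp <- find_flowers(g)
  col <- flower_coloring(g, fp)
  expect_equal(col[c(1, 2)], c(1L, 2L))
  expect_equal(col[c(5, 6)], c(1L, 2L))
  expect_equal(col[c(3, 4)], c(0L, 0L))
})

test_that("Aut(G) = NM: order factorises and decomposition is unique", {
  p3 <- path_graph(3)                          # flower {1,3} at centre 2
  expect_equal(compute_N(p3)$order, 1)
  expect_equal(automorphism_group(p3)$order, 2)

  st <- star_graph(3)
  expect_equal(compute_N(st)$order, 1)
  expect_equal(automorphism_group(st)$order, 6)

  set.seed(23)
  for (i in 1:12) {
    g <- random_connected_graph(sample(4:8, 1), extra = sample(0:2, 1))
    fp <- find_flowers(g)
    N <- compute_N(g, fp)
    A <- automorphism_group(g)
    expect_equal(A$order, N$order * fp$minor_order)
    # unique factorisation gamma = nu . mu over explicit N and M
    M <- minor_subgroup_members(g, fp)
    expect_equal(length(M), fp$minor_order)
    prods <- character()
    for (nu in N$members) for (mu in M) prods <- c(prods, perm_key(nu[mu]))
    expect_equal(anyDuplicated(prods), 0L)
    expect_setequal(prods, vapply(A$members, perm_key, character(1)))
  }
})

test_that("list action follows the defining identity and group laws", {
  p <- c(2, 3, 1, 4, 6, 5, 7, 8, 9, 10)                   # (1 2 3)(5 6)
  L <- c("C", "C", "O", "S", "O", "C", "C", "C", "C", "C")
  expect_equal(act_on_list(p, L),
               c("O", "C", "C", "S", "C", "O", "C", "C", "C", "C"))
  expect_equal(act_on_list(p, L)[p], L)                   # defining property
  expect_equal(act_on_list(seq_along(L), L), L)           # identity
  pinv <- order(p)
  expect_equal(act_on_list(pinv, act_on_list(p, L)), L)   # inverse law
  expect_error(act_on_list(p, L[-1]), "lengths differ")
})

test_that("class-maximum test agrees with exhaustive canon(L) = L", {
  label_cmp_oracle <- function(L, A, ord) {
    rk <- match(L, ord)
    all(vapply(A, function(p) isogen:::lex_cmp(rk[order(p)], rk) <= 0,
               logical(1)))
  }
  graphs <- c(generate_simple_graphs(edge_budget(parse_formula("C5H12")),
                                     n = 5, max_degree = 4),
              list(cycle_graph(5), star_graph(4), path_graph(6),
                   complete_graph(4)))
  ord <- c("C", "N", "O")
  counted_one_per_class <- 0L
  for (g in graphs) {
    fp <- find_flowers(g)
    N <- compute_N(g, fp)
    A <- automorphism_group(g)$members
    combos <- expand.grid(rep(list(ord), g$n), stringsAsFactors = FALSE)
    n_max <- 0L
    n_classes <- length(unique(apply(combos, 1, function(L) {
      # class id: the maximal image under the full group
      rk <- match(unname(unlist(L)), ord)
      imgs <- vapply(A, function(p) paste(rk[order(p)], collapse = ""),
                     character(1))
      max(imgs)
    })))
    for (r in seq_len(nrow(combos))) {
      L <- unname(unlist(combos[r, ]))
      mine <- is_class_maximum(L, N, fp, label_order = ord)
      expect_identical(mine, label_cmp_oracle(L, A, ord))
      if (mine) n_max <- n_max + 1L
    }
    expect_equal(n_max, n_classes)     # exactly one representative per class
    counted_one_per_class <- counted_one_per_class + 1L
  }
  expect_gte(counted_one_per_class, 5L)
})

test_that("trivial N and no flowers accept every list", {
  # path of 3: the flower {1,3} absorbs the whole symmetry, so N is trivial
  g <- path_graph(3)
  fp <- find_flowers(g)
  N <- compute_N(g, fp)
  expect_equal(N$order, 1)
  no_flowers <- structure(list(flowers = list(), centers = integer(),
                               minor_order = 1), class = "flower_partition")
  for (L in list(c("O", "C", "C"), c("C", "O", "C"), c("C", "C", "O")))
    expect_true(is_class_maximum(L, N, no_flowers))
  # singleton flowers at both ends of a path of 4 leave the reflection in N
  expect_equal(compute_N(path_graph(4))$order, 2)
})
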