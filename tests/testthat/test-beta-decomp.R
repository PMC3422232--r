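# The six index decompositions and the pairwise drivers.

test_that("compositional decompositions reproduce the printed examples", {
  d <- sorensen_decomposition(5, 1, 1)
  expect_equal(d$beta.sor, 1 / 6, tolerance = 1e-12)
  expect_equal(d$beta.sim, 1 / 6, tolerance = 1e-12)
  expect_equal(d$beta.sne, 0)

  j <- jaccard_decomposition(5, 1, 1)
  expect_equal(j$beta.jac, 2 / 7, tolerance = 1e-12)
  expect_equal(j$beta.jtu, 2 / 7, tolerance = 1e-12)

  j2 <- jaccard_decomposition(5, 1, 4)
  expect_equal(j2$beta.jac, 0.5, tolerance = 1e-12)
  expect_equal(j2$beta.jtu, 2 / 7, tolerance = 1e-12)
  expect_equal(j2$beta.jne, 0.5 - 2 / 7, tolerance = 1e-12)

  # disjoint communities: total = turnover = 1
  d0 <- sorensen_decomposition(0, 3, 5)
  expect_equal(d0$beta.sor, 1)
  expect_equal(d0$beta.sim, 1)
  # nested pair: turnover 0
  expect_equal(sorensen_decomposition(4, 0, 3)$beta.sim, 0)
  # identical communities: all zeros
  expect_equal(unlist(jaccard_decomposition(7, 0, 0)),
               c(beta.jac = 0, beta.jtu = 0, beta.jne = 0))
})

test_that("phylogenetic decompositions accept branch partitions directly", {
  p <- phylosor_decomposition(c(a = 5, b = 1, c = 8))
  expect_equal(p$phylosor, 9 / 19, tolerance = 1e-12)
  expect_equal(p$phylosor.turn, 1 / 6, tolerance = 1e-12)
  u <- unifrac_decomposition(c(a = 5, b = 1, c = 5))
  expect_equal(u$unifrac, 6 / 11, tolerance = 1e-12)
  expect_equal(u$unifrac.turn, 2 / 7, tolerance = 1e-12)
  # equal unique branch lengths force the PD component to exactly 0
  expect_identical(phylosor_decomposition(2.5, 1.3, 1.3)$phylosor.pd, 0)
  # no shared branches: total 1
  expect_equal(unifrac_decomposition(0, 2, 5)$unifrac, 1)
})

test_that("an all-zero partition is an undefined-index error", {
  expect_error(sorensen_decomposition(0, 0, 0), "undefined")
  expect_error(phylosor_decomposition(c(a = 0, b = 0, c = 0)), "undefined")
  expect_error(sorensen_decomposition(-1, 1, 1), "non-negative")
})

test_that("subtraction components match the closed forms", {
  set.seed(303)
  a <- sample(0:20, 500, replace = TRUE)
  b <- sample(0:20, 500, replace = TRUE)
  c_ <- sample(0:20, 500, replace = TRUE)
  keep <- (a + b > 0) & (a + c_ > 0)  # both communities non-empty
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]
  expect_equal(sorensen_decomposition(a, b, c_)$beta.sne,
               closed_beta_sne(a, b, c_), tolerance = 1e-12)
  expect_equal(jaccard_decomposition(a, b, c_)$beta.jne,
               closed_beta_jne(a, b, c_), tolerance = 1e-12)
})

test_that("turnover depends only on (a, min(b, c)) and the PD component grows with max(b, c)", {
  base <- phylosor_decomposition(5, 1, 4)
  for (cc in 5:9) {
    d <- phylosor_decomposition(5, 1, cc)
    expect_equal(d$phylosor.turn, base$phylosor.turn, tolerance = 1e-12)
    expect_gt(d$phylosor.pd, base$phylosor.pd)
    base <- d
  }
  u1 <- unifrac_decomposition(3, 2, 7)
  u2 <- unifrac_decomposition(3, 7, 2)  # swap is symmetric
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("additivity, bounds and the Sorensen <= Jaccard ordering hold on random partitions", {
  set.seed(404)
  n <- 2000
  a <- runif(n, 0, 50); b <- runif(n, 0, 50); c_ <- runif(n, 0, 50)
  s <- decompose_partition(a, b, c_, "sorensen")
  j <- decompose_partition(a, b, c_, "jaccard")
  for (d in list(s, j)) {
    expect_true(all(abs(d$total - (d$turnover + d$diff)) <= 1e-12))
    expect_true(all(d$total >= 0 & d$total <= 1))
    expect_true(all(d$turnover >= 0 & d$turnover <= d$total + 1e-12))
    expect_true(all(d$diff >= -1e-12))
  }
  expect_true(all(s$total <= j$total + 1e-12))
})

test_that("pairwise_cbd matches a direct set-arithmetic oracle", {
  set.seed(505)
  species <- paste0("sp", 1:20)
  comm <- random_comm(5, species)
  tab <- pairwise_cbd(comm, family = "both")
  for (r in seq_len(nrow(tab))) {
    si <- species[comm[tab$site_i[r], ] > 0]
    sj <- species[comm[tab$site_j[r], ] > 0]
    expect_equal(tab$a[r], length(intersect(si, sj)))
    expect_equal(tab$b[r], length(setdiff(si, sj)))
    expect_equal(tab$c[r], length(setdiff(sj, si)))
  }
  so <- tab[tab$family == "sorensen", ]
  expect_equal(so$total, sorensen_decomposition(so$a, so$b, so$c)$beta.sor)
})

test_that("pairwise_pbd equals the single-pair operations on random trees", {
  set.seed(606)
  for (rep in 1:5) {
    tr <- random_tree(10)
    comm <- random_comm(3, tr$tip.label)
    tab <- pairwise_pbd(tr, comm, family = "both")
    for (r in seq_len(nrow(tab))) {
      tj <- colnames(comm)[comm[tab$site_i[r], ] > 0]
      tk <- colnames(comm)[comm[tab$site_j[r], ] > 0]
      bp <- branch_partition(tr, tj, tk)
      expect_equal(unname(c(tab$a[r], tab$b[r], tab$c[r])), unname(bp),
                   tolerance = 1e-12)
      ref <- if (tab$family[r] == "sorensen") {
        unlist(phylosor_decomposition(bp))
      } else {
        unlist(unifrac_decomposition(bp))
      }
      expect_equal(unname(c(tab$total[r], tab$turnover[r], tab$pd_component[r])),
                   unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("pairwise_pbd totals agree with an independent PhyloSor implementation", {
  set.seed(707)
  tr <- ape::rtree(15)
  comm <- random_comm(4, tr$tip.label)
  tab <- pairwise_pbd(tr, comm, family = "sorensen")
  ref <- 1 - as.matrix(picante::phylosor(comm, tr))
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$total[r], ref[tab$site_i[r], tab$site_j[r]],
                 tolerance = 1e-10)
})

test_that("identical sites give zero dissimilarity in the pairwise driver", {
  ex <- pbd_example("pd_gradient")
  comm <- ex$comm[c("A", "A", "B"), ]
  rownames(comm) <- c("A1", "A2", "B")
  tab <- pairwise_pbd(ex$tree, comm, family = "sorensen")
  r <- tab[tab$site_i == "A1" & tab$site_j == "A2", ]
  expect_equal(r$total, 0)
  expect_equal(r$turnover, 0)
  expect_equal(r$pd_component, 0)
})

test_that("empty sites yield flagged NA rows instead of failing the matrix", {
  ex <- pbd_example("pd_gradient")
  comm <- rbind(ex$comm, Z = 0L)
  expect_warning(tab <- pairwise_pbd(ex$tree, comm), "empty site")
  expect_true(all(is.na(tab$total[tab$site_j == "Z"])))
  expect_true(all(!is.na(tab$total[tab$site_j != "Z"])))
  expect_warning(ctab <- pairwise_cbd(comm), "empty site")
  expect_true(all(is.na(ctab$total[ctab$site_j == "Z"])))
})

test_that("species/tree mismatches error unless pruning is enabled, and abundances collapse", {
  ex <- pbd_example("pd_gradient")
  comm <- cbind(ex$comm, ghost = 1L)
  expect_error(pairwise_pbd(ex$tree, comm), "not tips of the tree")
  expect_message(tab <- pairwise_pbd(ex$tree, comm, prune_missing = TRUE),
                 "pruning")
  ref <- pairwise_pbd(ex$tree, ex$comm)
  expect_equal(tab[, -(1:2)], ref[, -(1:2)], tolerance = 1e-12)

  ab <- ex$comm * 3L
  expect_message(tab2 <- pairwise_pbd(ex$tree, ab), "collapsing")
  expect_equal(tab2, ref)
})
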