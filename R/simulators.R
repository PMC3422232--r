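# Random tree generators (Yule, PDA), random community pairs with
# prescribed (a, b, c) overlap structure, the full simulation study, and
# the small worked examples used in the documentation and tests.

#' Simulate a Yule (pure-birth) tree
#'
#' Constant-rate pure-birth process: at each event a uniformly random
#' extant lineage splits, with exponential inter-event waiting times whose
#' total rate is proportional to the number of lineages. The process tends
#' to produce relatively balanced trees. Backed by [ape::rphylo()] with
#' zero extinction.
#'
#' @param n_tips Number of tips (at least 2).
#' @param branch_lengths `"exponential"` (default) keeps the ultrametric
#'   waiting-time branch lengths of the process; `"unit"` sets every branch
#'   length to 1, retaining only the Yule topology.
#' @param seed Optional integer seed.
#' @return A rooted binary `"phylo"` object with tips `t1..tn`.
#' @seealso [pda_tree()]
#' @export
yule_tree <- function(n_tips, branch_lengths = c("exponential", "unit"),
                      seed = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2)
    stop("'n_tips' must be an integer >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
  if (branch_lengths == "unit") tree$edge.length <- rep(1, nrow(tree$edge))
  validate_phylogeny(tree)
}

#' Simulate a PDA (uniform-topology) tree
#'
#' Draws uniformly from the labeled rooted binary topologies
#' ("proportional to distinguishable arrangements"): each new tip is
#' attached to a uniformly random branch of the growing tree. Because most
#' arrangements are uneven, PDA trees are on average markedly less balanced
#' than Yule trees. Backed by [ape::rtopology()] with `rooted = TRUE`.
#'
#' @inheritParams yule_tree
#' @param branch_lengths `"unit"` (default) sets every branch length to 1;
#'   `"exponential"` draws i.i.d. exponential(1) lengths.
#' @return A rooted binary `"phylo"` object with tips `t1..tn`.
#' @export
pda_tree <- function(n_tips, branch_lengths = c("unit", "exponential"),
                     seed = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2)
    stop("'n_tips' must be an integer >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  if (n_tips == 2L) {
    tree <- ape::read.tree(text = "(t1:1,t2:1);")
  } else {
    tree <- ape::rtopology(n_tips, rooted = TRUE)
  }
  tree$edge.length <- switch(branch_lengths,
                             unit = rep(1, nrow(tree$edge)),
                             exponential = stats::rexp(nrow(tree$edge)))
  validate_phylogeny(tree)
}

# Colless imbalance: sum over internal nodes of |tips(left) - tips(right)|.
# Binary trees only; used to contrast Yule and PDA tree shapes.
colless_imbalance <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  cnt <- numeric(max(tr$edge))
  cnt[seq_len(n)] <- 1
  for (i in seq_len(nrow(tr$edge)))
    cnt[tr$edge[i, 1L]] <- cnt[tr$edge[i, 1L]] + cnt[tr$edge[i, 2L]]
  internal <- unique(tr$edge[, 1L])
  sum(vapply(internal, function(v) {
    ch <- cnt[tr$edge[tr$edge[, 1L] == v, 2L]]
    if (length(ch) != 2L)
      stop("Colless imbalance requires a binary tree", call. = FALSE)
    abs(ch[1L] - ch[2L])
  }, numeric(1)))
}

# Draw n raw (a, b, c) triples, each coordinate uniform on
# [abc_min, abc_max]; no feasibility constraint applied here.
draw_abc <- function(n, abc_min, abc_max) {
  span <- abc_max - abc_min + 1L
  matrix(abc_min - 1L + sample.int(span, 3L * n, replace = TRUE), ncol = 3L,
         dimnames = list(NULL, c("a", "b", "c")))
}

#' Sample a community pair with uniform overlap structure
#'
#' Draws integers `a`, `b`, `c` independently uniform on
#' `[abc_min, abc_max]`, redrawing the whole triple until
#' `a + b + c <= length(pool)` (rejection keeps the marginals uniform
#' conditional on feasibility), then samples `a + b + c` distinct species
#' from the pool: `a` shared, `b` unique to the first community, `c`
#' unique to the second.
#'
#' @param pool Character vector of species labels (the regional pool).
#' @param abc_min,abc_max Bounds of the uniform distribution for each of
#'   `a`, `b`, `c` (defaults 1 and 100).
#' @param seed Optional integer seed.
#' @return List with `first` and `second` (character vectors of species)
#'   and `counts` (named `c(a, b, c)`).
#' @export
sample_community_pair <- function(pool, abc_min = 1L, abc_max = 100L,
                                  seed = NULL) {
  pool <- unique(as.character(pool))
  if (abc_min < 1L || abc_max < abc_min)
    stop("need 1 <= abc_min <= abc_max", call. = FALSE)
  if (3L * abc_min > length(pool))
    stop("infeasible configuration: 3 * abc_min exceeds the pool size",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  repeat {
    abc <- draw_abc(1L, abc_min, abc_max)
    if (sum(abc) <= length(pool)) break
  }
  a <- unname(abc[1L, "a"]); b <- unname(abc[1L, "b"]); c_ <- unname(abc[1L, "c"])
  sp <- sample(pool, a + b + c_)
  list(first = sp[seq_len(a + b)],
       second = c(sp[seq_len(a)], sp[a + b + seq_len(c_)]),
       counts = c(a = a, b = b, c = c_))
}

#' Simulation study: compositional vs phylogenetic beta diversity
#'
#' Reproduces the theoretical study design: random community pairs with
#' `a`, `b`, `c` uniform on `[abc_min, abc_max]` (rejection to a common
#' species pool of `pool_size`), placed on one regional tree per requested
#' tree model, with all six compositional and six phylogenetic index
#' components computed per pair. A single branch-length mode is applied to
#' both trees so that the cross-model comparison isolates tree shape.
#'
#' @param pool_size Regional pool size (default 100).
#' @param n_pairs Number of community pairs (default 10000).
#' @param abc_min,abc_max Uniform bounds for `a`, `b`, `c` (defaults 1,
#'   100).
#' @param tree_models Character vector among `"pda"`, `"yule"`; one
#'   regional tree is generated per model.
#' @param branch_length_mode `"unit"` (default) or `"exponential"`,
#'   applied to every generated tree.
#' @param seed Optional integer seed.
#' @return An object of class `"pbd_simulation"`: list with `pairs` (one
#'   row per pair: counts, the six compositional values, and per tree
#'   model the six phylogenetic values), `correlations` (Pearson
#'   correlations of matched compositional/phylogenetic components per
#'   model, plus cross-model correlations of the phylogenetic components
#'   when both models are run), `trees` and `config`.
#' @examples
#' \donttest{
#' study <- run_simulation_study(pool_size = 50, n_pairs = 500,
#'                               abc_max = 50, seed = 1)
#' study$correlations
#' }
#' @export
run_simulation_study <- function(pool_size = 100L, n_pairs = 10000L,
                                 abc_min = 1L, abc_max = 100L,
                                 tree_models = c("pda", "yule"),
                                 branch_length_mode = c("unit", "exponential"),
                                 seed = NULL) {
  branch_length_mode <- match.arg(branch_length_mode)
  tree_models <- match.arg(tree_models, c("pda", "yule"), several.ok = TRUE)
  if (pool_size < 3L) stop("'pool_size' must be at least 3", call. = FALSE)
  if (n_pairs < 2L) stop("'n_pairs' must be at least 2", call. = FALSE)
  if (3L * abc_min > pool_size)
    stop("infeasible configuration: 3 * abc_min exceeds 'pool_size'",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pool <- paste0("s", seq_len(pool_size))

  # one regional tree per model, tips relabeled to the pool
  trees <- lapply(tree_models, function(mod) {
    tr <- switch(mod,
                 pda = pda_tree(pool_size, branch_lengths = branch_length_mode),
                 yule = yule_tree(pool_size, branch_lengths = branch_length_mode))
    tr$tip.label <- pool
    tr
  })
  names(trees) <- tree_models

  # feasible (a, b, c) triples by rejection
  abc <- matrix(0L, n_pairs, 3L, dimnames = list(NULL, c("a", "b", "c")))
  filled <- 0L
  while (filled < n_pairs) {
    cand <- draw_abc(n_pairs, abc_min, abc_max)
    ok <- rowSums(cand) <= pool_size
    take <- min(sum(ok), n_pairs - filled)
    if (take > 0L)
      abc[filled + seq_len(take), ] <- cand[which(ok)[seq_len(take)], ]
    filled <- filled + take
  }
  a <- abc[, "a"]; b <- abc[, "b"]; c_ <- abc[, "c"]

  # community membership matrices (pairs x pool)
  J <- matrix(FALSE, n_pairs, pool_size)
  K <- matrix(FALSE, n_pairs, pool_size)
  for (i in seq_len(n_pairs)) {
    sp <- sample.int(pool_size, a[i] + b[i] + c_[i])
    J[i, sp[seq_len(a[i] + b[i])]] <- TRUE
    K[i, sp[c(seq_len(a[i]), a[i] + b[i] + seq_len(c_[i]))]] <- TRUE
  }

  cbd <- cbind(sorensen_decomposition(a, b, c_), jaccard_decomposition(a, b, c_))

  pbd_for_tree <- function(tree) {
    et <- edge_tip_incidence(tree)
    inc <- et$inc[, match(pool, et$tips), drop = FALSE]
    w <- et$w
    ej <- (J %*% t(inc)) > 0
    ek <- (K %*% t(inc)) > 0
    storage.mode(ej) <- "double"; storage.mode(ek) <- "double"
    pd_j <- drop(ej %*% w)
    pd_k <- drop(ek %*% w)
    pd_u <- drop(((ej + ek) > 0) %*% w)
    pa <- pd_j + pd_k - pd_u
    pb <- pd_u - pd_k
    pc <- pd_u - pd_j
    cbind(phylosor_decomposition(pa, pb, pc),
          unifrac_decomposition(pa, pb, pc))
  }
  pbd <- lapply(trees, pbd_for_tree)

  pairs <- cbind(data.frame(a = a, b = b, c = c_), cbd)
  for (mod in tree_models) {
    pm <- pbd[[mod]]
    names(pm) <- paste(mod, names(pm), sep = ".")
    pairs <- cbind(pairs, pm)
  }

  matched <- data.frame(
    pbd_index = c("phylosor", "phylosor.turn", "phylosor.pd",
                  "unifrac", "unifrac.turn", "unifrac.pd"),
    cbd_index = c("beta.sor", "beta.sim", "beta.sne",
                  "beta.jac", "beta.jtu", "beta.jne"))
  cors <- do.call(rbind, lapply(tree_models, function(mod) {
    data.frame(comparison = paste0(mod, "_vs_cbd"),
               x = paste(mod, matched$pbd_index, sep = "."),
               y = matched$cbd_index,
               pearson_r = vapply(seq_len(nrow(matched)), function(i)
                 stats::cor(pbd[[mod]][[matched$pbd_index[i]]],
                            cbd[[matched$cbd_index[i]]]),
                 numeric(1)))
  }))
  if (length(tree_models) == 2L) {
    cross <- data.frame(
      comparison = "yule_vs_pda",
      x = paste(tree_models[1L], matched$pbd_index, sep = "."),
      y = paste(tree_models[2L], matched$pbd_index, sep = "."),
      pearson_r = vapply(matched$pbd_index, function(ix)
        stats::cor(pbd[[tree_models[1L]]][[ix]],
                   pbd[[tree_models[2L]]][[ix]]),
        numeric(1)))
    cors <- rbind(cors, cross)
  }
  rownames(cors) <- NULL

  structure(list(pairs = pairs, correlations = cors, trees = trees,
                 config = list(pool_size = pool_size, n_pairs = n_pairs,
                               abc_min = abc_min, abc_max = abc_max,
                               tree_models = tree_models,
                               branch_length_mode = branch_length_mode,
                               seed = seed)),
            class = "pbd_simulation")
}

#' @export
print.pbd_simulation <- function(x, ...) {
  cfg <- x$config
  cat("Beta-diversity simulation study:", cfg$n_pairs, "community pairs,",
      "pool of", cfg$pool_size, "species\n")
  cat("  tree model(s):", paste(cfg$tree_models, collapse = ", "),
      " branch lengths:", cfg$branch_length_mode,
      " seed:", if (is.null(cfg$seed)) "<none>" else cfg$seed, "\n")
  cat("  correlations:\n")
  print(x$correlations, digits = 3)
  invisible(x)
}

#' Worked example trees and communities
#'
#' Small synthetic datasets used throughout the documentation and tests.
#'
#' * `"clustered_pair"`: fully balanced 8-tip tree, all branch lengths 1,
#'   with two communities occupying the two opposite basal clades. The
#'   communities share no species and no branches: compositional and
#'   phylogenetic dissimilarity are both maximal (PhyloSor = 1), each
#'   community has Faith's PD 7.
#' * `"interleaved_pair"`: the same tree with one community holding one
#'   tip of each cherry and the other the complementary tips. Again no
#'   shared species, but most branches are shared: PhyloSor = 0.4, each
#'   community has PD 10.
#' * `"pd_gradient"`: a 10-species unit-branch-length tree with six
#'   communities A-F. A and B have equal PD; B's branches are nested
#'   within those of C-F, whose unique branch length grows steadily. Along
#'   A-B..A-F total phylogenetic dissimilarity rises while the turnover
#'   component stays constant; along B-C..B-F turnover is exactly 0 and
#'   the whole signal is the PD-difference component.
#'
#' @param name One of `"clustered_pair"`, `"interleaved_pair"`,
#'   `"pd_gradient"`.
#' @return List with `tree` (a `"phylo"`) and `comm` (binary
#'   sites-by-species matrix).
#' @examples
#' ex <- pbd_example("clustered_pair")
#' pairwise_pbd(ex$tree, ex$comm, family = "sorensen")
#' @export
pbd_example <- function(name = c("clustered_pair", "interleaved_pair",
                                 "pd_gradient")) {
  name <- match.arg(name)
  balanced8 <- paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
                      "((t5:1,t6:1):1,(t7:1,t8:1):1):1);")
  if (name == "clustered_pair") {
    tree <- parse_newick(balanced8)
    comm <- rbind(A = c(1, 1, 1, 1, 0, 0, 0, 0),
                  B = c(0, 0, 0, 0, 1, 1, 1, 1))
    colnames(comm) <- paste0("t", 1:8)
  } else if (name == "interleaved_pair") {
    tree <- parse_newick(balanced8)
    comm <- rbind(A = c(1, 0, 1, 0, 1, 0, 1, 0),
                  B = c(0, 1, 0, 1, 0, 1, 0, 1))
    colnames(comm) <- paste0("t", 1:8)
  } else {
    tree <- parse_newick(paste0(
      "((s1:1,((s2:1,s3:1):1,s4:1):1):1,",
      "(s5:1,(s6:1,(s7:1,(s8:1,(s9:1,s10:1):1):1):1):1):1);"))
    species <- paste0("s", 1:10)
    comm <- matrix(0L, 6L, 10L,
                   dimnames = list(LETTERS[1:6], species))
    present <- list(A = c("s1", "s2", "s3"),
                    B = c("s2", "s3", "s4"),
                    C = c("s2", "s3", "s4", "s6"),
                    D = c("s2", "s3", "s4", "s7"),
                    E = c("s2", "s3", "s4", "s9"),
                    F = c("s2", "s3", "s4", "s9", "s10"))
    for (s in names(present)) comm[s, present[[s]]] <- 1L
  }
  list(tree = tree, comm = comm)
}
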