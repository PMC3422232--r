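# Tip-shuffling null model and standardized effect sizes.
#
# The null model permutes species labels across the tips of the regional
# phylogeny while leaving the community table untouched. Topology and
# branch lengths are preserved, so per-site species richness and every
# compositional (Sorensen/Jaccard family) index are held exactly constant;
# only the mapping of species identities onto the tree -- and hence the
# phylogenetic indices -- varies. A standardized effect size (SES)
# contrasts the observed phylogenetic beta diversity with this null:
#
#   SES = (X_obs - mean(X_null)) / sd(X_null)
#
# |SES| > 1.96 flags phylogenetic structure beyond what species
# composition alone predicts.

#' Permute species labels across the tips of a tree
#'
#' Returns a tree with identical topology and branch lengths and a
#' uniformly random permutation of its tip labels. Uses R's global random
#' number generator; call `set.seed()` (or pass `seed` to the drivers) for
#' reproducibility.
#'
#' @inheritParams write_newick
#' @return A `"phylo"` object.
#' @export
shuffle_tip_labels <- function(tree) {
  tree <- validate_phylogeny(tree)
  tree$tip.label <- sample(tree$tip.label)
  tree
}

#' Null distributions of phylogenetic beta diversity under tip shuffling
#'
#' Generates `n_rand` independent tip-label permutations of `tree` and
#' recomputes all pairwise phylogenetic beta diversity components for each,
#' holding the community table (and therefore richness and compositional
#' beta diversity) exactly constant. Deterministic given `seed` and
#' `n_rand`.
#'
#' @inheritParams pairwise_pbd
#' @param n_rand Number of randomizations (9999 by default, the
#'   conventional choice; use fewer for exploratory runs).
#' @param seed Optional integer seed applied before the first shuffle.
#' @return An object of class `"pbd_null"`: a list with `observed` (the
#'   [pairwise_pbd()] table), `null` (array `n_rand` x pair/family rows x
#'   3 components), `n_rand`, `seed` and `family`.
#' @seealso [standardized_effect_size()], [ses_pbd()]
#' @export
null_pbd_distribution <- function(tree, comm,
                                  n_rand = 9999, seed = NULL,
                                  family = c("both", "sorensen", "jaccard"),
                                  prune_missing = FALSE) {
  family <- match.arg(family)
  fam <- resolve_family(family)
  if (!is.numeric(n_rand) || length(n_rand) != 1L || n_rand < 1)
    stop("'n_rand' must be a positive integer", call. = FALSE)
  n_rand <- as.integer(n_rand)
  if (!is.null(seed)) set.seed(seed)
  # validate inputs (and fail loudly) once, before the loop
  observed <- pairwise_pbd(tree, comm, family = family,
                           prune_missing = prune_missing)
  tree <- validate_phylogeny(tree)
  comm <- suppressMessages(as_incidence_matrix(comm))
  keep <- intersect(colnames(comm), tree$tip.label)
  comm <- comm[, keep, drop = FALSE]
  et <- edge_tip_incidence(tree)
  comp <- c("total", "turnover", "pd_component")
  null <- array(NA_real_, dim = c(n_rand, nrow(observed), length(comp)),
                dimnames = list(NULL, NULL, comp))
  for (r in seq_len(n_rand)) {
    labels <- sample(et$tips)
    tab <- suppressWarnings(
      pbd_pairs_core(comm, et$inc, et$w, match(colnames(comm), labels),
                     fam))
    null[r, , ] <- as.matrix(tab[, comp])
  }
  structure(list(observed = observed, null = null,
                 n_rand = n_rand, seed = seed, family = fam),
            class = "pbd_null")
}

#' @export
print.pbd_null <- function(x, ...) {
  cat("Tip-shuffling null distributions of phylogenetic beta diversity\n")
  cat("  pairs x families:", nrow(x$observed),
      " randomizations:", x$n_rand,
      " seed:", if (is.null(x$seed)) "<none>" else x$seed, "\n")
  invisible(x)
}

#' Standardized effect sizes from a null distribution
#'
#' For every site pair, index family and component, computes
#' `ses = (observed - null_mean) / null_sd`, with `null_sd` the sample
#' standard deviation (`n - 1` denominator) of the null values. When the
#' null distribution is degenerate (`null_sd = 0`, e.g. on a star tree
#' where tip shuffling is a symmetry) the SES is reported as `NA` and both
#' significance flags are `FALSE`. Significance is flagged at the
#' two-sided +/-1.96 convention; `ses > 1.96` indicates higher phylogenetic
#' beta diversity than expected given compositional beta diversity,
#' `ses < -1.96` lower.
#'
#' @param dist A `"pbd_null"` object from [null_pbd_distribution()].
#' @return Long-format data.frame with one row per pair, family and
#'   component: `site_i`, `site_j`, `family`, `component`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `significant_high`, `significant_low`,
#'   `n_rand`, `seed`, `sd_type`.
#' @export
standardized_effect_size <- function(dist) {
  if (!inherits(dist, "pbd_null"))
    stop("'dist' must be a \"pbd_null\" object", call. = FALSE)
  obs <- dist$observed
  comp <- dimnames(dist$null)[[3L]]
  rows <- lapply(seq_along(comp), function(k) {
    nm <- dist$null[, , k, drop = FALSE]
    dim(nm) <- dim(dist$null)[1:2]
    mu <- colMeans(nm)
    sd_ <- apply(nm, 2L, stats::sd)
    o <- obs[[comp[k]]]
    ses <- ifelse(is.na(sd_) | sd_ == 0, NA_real_, (o - mu) / sd_)
    data.frame(site_i = obs$site_i, site_j = obs$site_j, family = obs$family,
               component = comp[k], observed = o,
               null_mean = mu, null_sd = sd_, ses = ses,
               significant_high = !is.na(ses) & ses > 1.96,
               significant_low = !is.na(ses) & ses < -1.96,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$site_i, obs$site_i), match(out$site_j, obs$site_j),
               out$family, match(out$component, comp))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$n_rand <- dist$n_rand
  out$seed <- if (is.null(dist$seed)) NA_integer_ else dist$seed
  out$sd_type <- "sample"
  out
}

#' Observed phylogenetic beta diversity with standardized effect sizes
#'
#' Convenience driver: runs [null_pbd_distribution()] followed by
#' [standardized_effect_size()].
#'
#' @inheritParams null_pbd_distribution
#' @return The long-format SES table of [standardized_effect_size()].
#' @examples
#' ex <- pbd_example("pd_gradient")
#' ses <- ses_pbd(ex$tree, ex$comm, n_rand = 99, seed = 1, family = "sorensen")
#' head(ses)
#' @export
ses_pbd <- function(tree, comm, n_rand = 9999, seed = NULL,
                    family = c("both", "sorensen", "jaccard"),
                    prune_missing = FALSE) {
  standardized_effect_size(
    null_pbd_distribution(tree, comm, n_rand = n_rand, seed = seed,
                          family = family, prune_missing = prune_missing))
}
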