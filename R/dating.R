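# Dating the recombination arrest of an XY pair from synonymous divergence:
# codon-bootstrap the concatenated gametologue alignment, fit dS branch
# lengths on the fixed species topology, make the tree ultrametric with a
# mean-path-length clock, and calibrate node ages against a known species
# split.

.ds_core <- function(ca, cb) {
  tb <- codon_tables()
  usable <- !is.na(ca) & !is.na(cb) & !tb$is_stop[ca] & !tb$is_stop[cb]
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) xy_error("no usable codons in alignment", "xy_length_error")
  pt <- ng86_pair_tables()
  S <- (sum(tb$S_sites[ca]) + sum(tb$S_sites[cb])) / 2
  Sd <- sum(pt$Sd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  if (pS >= 0.75) {
    xy_error(sprintf("synonymous sites saturated (pS = %.3f)", pS),
             "xy_saturation_error")
  }
  -0.75 * log(1 - 4 * pS / 3)
}

# dS distance matrix from a taxa x codons integer matrix
ds_matrix_codons <- function(mat) {
  taxa <- rownames(mat)
  n <- nrow(mat)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- tryCatch(.ds_core(mat[i, ], mat[j, ]),
        xy_saturation_error = function(e) {
          xy_error(sprintf("saturated pair: %s / %s", taxa[i], taxa[j]),
                   "xy_saturation_error")
        })
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

# stack per-gene alignments (named character vectors sharing a taxon set)
# into one taxa x codons integer matrix
concat_codon_matrix <- function(alignments) {
  if (is.character(alignments)) alignments <- list(alignments)
  if (!length(alignments) || !length(alignments[[1L]])) {
    xy_error("empty concatenation", "xy_config_error")
  }
  taxa <- names(alignments[[1L]])
  mats <- lapply(alignments, function(a) {
    if (!setequal(names(a), taxa)) {
      xy_error("alignments do not share a taxon set", "xy_config_error")
    }
    do.call(rbind, lapply(a[taxa], seq_to_codons))
  })
  out <- do.call(cbind, mats)
  rownames(out) <- taxa
  out
}

codon_matrix_to_alignment <- function(mat) {
  setNames(vapply(seq_len(nrow(mat)), function(i) codons_to_seq(mat[i, ]),
                  character(1)), rownames(mat))
}

#' Codon bootstrap of a concatenated alignment
#'
#' Resamples codon columns with replacement up to the original concatenated
#' length, preserving the reading frame needed for dS estimation.
#'
#' @param alignments a named character vector (one alignment) or a list of
#'   per-gene alignments sharing a taxon set; genes are concatenated first.
#' @param n_rounds number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return list of `n_rounds` replicate alignments (named character vectors),
#'   each of the original concatenated length.
#' @export
bootstrap_concatenation <- function(alignments, n_rounds = 100, seed = NULL) {
  mat <- concat_codon_matrix(alignments)
  if (ncol(mat) == 0L) xy_error("empty concatenation", "xy_config_error")
  with_seed(seed, {
    lapply(seq_len(n_rounds), function(r) {
      codon_matrix_to_alignment(mat[, sample.int(ncol(mat), replace = TRUE),
                                    drop = FALSE])
    })
  })
}

#' Fit dS branch lengths on a fixed topology
#'
#' Computes the pairwise dS matrix of the alignment and fits non-negative
#' branch lengths on the given topology by (non-negative) least squares.
#'
#' @param topology an `ape::phylo` covering all alignment taxa.
#' @param alignment named character vector of aligned coding sequences, or a
#'   taxa x codons integer codon matrix.
#' @return the topology with dS branch lengths.
#' @export
fit_branch_lengths <- function(topology, alignment) {
  dm <- if (is.matrix(alignment) && is.numeric(alignment)) {
    ds_matrix_codons(alignment)
  } else {
    ds_matrix(alignment)
  }
  fit_branch_lengths_dm(topology, dm)
}

# least-squares branch lengths from a precomputed distance matrix
fit_branch_lengths_dm <- function(topology, dm) {
  taxa <- rownames(dm)
  if (!all(topology$tip.label %in% taxa) || !all(taxa %in% topology$tip.label)) {
    xy_error("topology tips do not match alignment taxa", "xy_config_error")
  }
  if (length(taxa) == 2L) {
    tr <- topology
    tr$edge.length <- rep(dm[1, 2] / 2, nrow(tr$edge))
    return(tr)
  }
  unrooted <- ape::unroot(topology)
  fit <- phangorn::nnls.tree(as.dist(dm), unrooted, method = "unrooted")
  fit$edge.length[fit$edge.length < 0] <- 0
  fit
}

# Mean-path-length node ages of a rooted tree with branch lengths: the age of
# an internal node is the mean path length to its descendant tips, clamped so
# a parent is never younger than its children (strict-clock smoothing).
node_ages_mpl <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  dn <- ape::dist.nodes(tree)
  desc <- phangorn::Descendants(tree, type = "tips")
  ages <- numeric(ntip + nnode)
  for (node in (ntip + 1L):(ntip + nnode)) {
    ages[node] <- mean(dn[node, desc[[node]]])
  }
  # enforce age monotonicity bottom-up
  for (e in rev(ape::postorder(tree))) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    ages[par] <- max(ages[par], ages[chi])
  }
  ages
}

# rooted ultrametric tree from a rooted topology and node ages
ultrametric_from_ages <- function(tree, ages) {
  out <- tree
  out$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  out
}

root_at <- function(tree, outgroup) {
  if (ape::is.rooted(tree)) return(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# scaled age of the MRCA of a tip pair under a calibration
calibrated_age <- function(tree, node_tips, calibration_tips, calibration_age_ma) {
  ages <- node_ages_mpl(tree)
  cal <- ape::getMRCA(tree, calibration_tips)
  node <- ape::getMRCA(tree, node_tips)
  desc <- phangorn::Descendants(tree, cal, type = "tips")[[1L]]
  node_desc <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  if (!all(node_desc %in% desc)) {
    xy_error("focal split is not nested within the calibration node",
             "xy_calibration_error")
  }
  if (ages[cal] <= 0) xy_error("calibration node has zero depth", "xy_calibration_error")
  list(age = ages[node] * calibration_age_ma / ages[cal],
       ages = ages * calibration_age_ma / ages[cal], node = node, cal = cal)
}

#' Calibrate dS trees and date the X/Y split
#'
#' Implements the dating step: average the branch lengths of the bootstrap
#' replicate trees (shared fixed topology), make the averaged tree
#' ultrametric with a mean-path-length clock, anchor the calibration node at
#' a known age, and read off the age of the X/Y split.  The 95% confidence
#' interval is the 2.5th/97.5th percentile of the split age over the
#' individual bootstrap replicates.
#'
#' @param ds_tree point-estimate tree with dS branch lengths, or `NULL` to
#'   use the bootstrap average alone.
#' @param calibration_tips two or more tip labels whose MRCA is the
#'   calibration node.
#' @param calibration_age_ma age assigned to the calibration node (Ma).
#' @param bootstrap_trees list of replicate trees with dS branch lengths
#'   (same topology); may be empty, in which case no CI is computed.
#' @param xy_tips the two tip labels whose MRCA is the X/Y split (default
#'   `c("X", "Y")`).
#' @param outgroup tip used to root unrooted input trees (default: first
#'   calibration tip absent from `xy_tips`).
#' @return an object of class `dated_tree`: list with `xy_age_ma`, `ci95`,
#'   `calibration_age_ma`, `boot_ages_ma`, and `tree` (ultrametric, branch
#'   lengths in Ma).
#' @export
calibrate_and_date <- function(ds_tree, calibration_tips, calibration_age_ma,
                               bootstrap_trees = list(),
                               xy_tips = c("X", "Y"), outgroup = NULL) {
  trees <- bootstrap_trees
  if (is.null(ds_tree)) {
    if (!length(trees)) xy_error("no trees to calibrate", "xy_config_error")
    ds_tree <- trees[[1L]]
    ds_tree$edge.length <- rowMeans(
      vapply(trees, function(t) t$edge.length, numeric(nrow(ds_tree$edge))))
  }
  if (is.null(outgroup)) {
    og <- setdiff(ds_tree$tip.label, c(xy_tips, calibration_tips))
    outgroup <- if (length(og)) og[length(og)] else calibration_tips[1L]
  }
  point <- root_at(ds_tree, outgroup)
  res <- calibrated_age(point, xy_tips, calibration_tips, calibration_age_ma)
  if (res$age > calibration_age_ma + 1e-9) {
    xy_error("X/Y split dated older than the calibration node",
             "xy_calibration_error")
  }
  boot_ages <- vapply(trees, function(t) {
    calibrated_age(root_at(t, outgroup), xy_tips, calibration_tips,
                   calibration_age_ma)$age
  }, numeric(1))
  ci <- if (length(boot_ages)) {
    unname(quantile(boot_ages, c(0.025, 0.975), type = 7))
  } else c(NA_real_, NA_real_)
  structure(list(
    xy_age_ma = res$age,
    ci95 = ci,
    calibration_age_ma = calibration_age_ma,
    calibration_tips = calibration_tips,
    boot_ages_ma = boot_ages,
    tree = ultrametric_from_ages(point, res$ages)
  ), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("X/Y split: %.2f Ma (95%% CI %.2f-%.2f), calibration %s = %.1f Ma\n",
              x$xy_age_ma, x$ci95[1], x$ci95[2],
              paste(x$calibration_tips, collapse = "/"), x$calibration_age_ma))
  invisible(x)
}

#' Rescale a calibrated age to a different calibration
#'
#' Node ages of an ultrametric tree scale linearly with the calibration age,
#' so re-dating under an alternative species-split estimate is a
#' proportional rescaling.
#'
#' @param age_ma age estimated under the original calibration.
#' @param from_calibration_ma original calibration age (Ma).
#' @param to_calibration_ma alternative calibration age (Ma).
#' @return rescaled age (Ma).
#' @examples
#' rescale_age(61.05, 85.7, 88)  # ~62.69
#' @export
rescale_age <- function(age_ma, from_calibration_ma, to_calibration_ma) {
  if (from_calibration_ma <= 0) xy_error("invalid 'from_calibration_ma'", "xy_config_error")
  age_ma * to_calibration_ma / from_calibration_ma
}

#' Date an X/Y split from gametologue alignments
#'
#' One-stop wrapper: concatenate the per-gene alignments, run the codon
#' bootstrap, fit dS branch lengths on the fixed topology for every
#' replicate, and calibrate.
#'
#' @param alignments list of per-gene named alignments (taxa must include
#'   `xy_tips`).
#' @param topology fixed species topology (`ape::phylo`) containing all taxa.
#' @param calibration_tips,calibration_age_ma calibration node (MRCA of the
#'   tips) and its age in Ma.
#' @param xy_tips tip labels of the X and Y copies.
#' @param n_boot bootstrap rounds (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return a `dated_tree` (see [calibrate_and_date()]).
#' @export
date_xy_from_alignments <- function(alignments, topology,
                                    calibration_tips, calibration_age_ma,
                                    xy_tips = c("X", "Y"),
                                    n_boot = 100, seed = NULL) {
  mat <- concat_codon_matrix(alignments)
  if (ncol(mat) == 0L) xy_error("empty concatenation", "xy_config_error")
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(r) {
      mat[, sample.int(ncol(mat), replace = TRUE), drop = FALSE]
    })
  })
  boot_trees <- lapply(boots, function(m) {
    fit_branch_lengths_dm(topology, ds_matrix_codons(m))
  })
  calibrate_and_date(NULL, calibration_tips, calibration_age_ma,
                     bootstrap_trees = boot_trees, xy_tips = xy_tips)
}

#' Fixed species topology with published node ages
#'
#' Time-calibrated eight-taxon amniote/outgroup topology used by the
#' gametologue simulator and the dating examples: squamates (the focal
#' basilisk lineage and the green anole, split 85.7 Ma), archosaur/turtle,
#' three mammals, and *Xenopus* as the root outgroup.  Branch lengths are in
#' Myr.
#'
#' @return an `ape::phylo` ultrametric tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((((Basiliscus:85.7,Anolis:85.7):194.3,(Gallus:255,Trionyx:255):25):32,",
    "((Human:90,Mouse:90):70,Monodelphis:160):152):40,Xenopus:352);"))
}
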