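# Codon bootstrap, least-squares branch lengths, clock calibration.

test_that("bootstrap replicates keep the original length and respect the seed", {
  aln <- list(c(X = "ATGGGTAAA", Y = "ATGGGCAAA", O = "ATGGGTAAG"),
              c(X = "TTACCC", Y = "TTACCA", O = "TTGCCC"))
  reps <- bootstrap_concatenation(aln, n_rounds = 20, seed = 5)
  expect_length(reps, 20)
  expect_true(all(vapply(reps, function(r) all(nchar(r) == 15), logical(1))))
  expect_true(all(vapply(reps, function(r) identical(names(r), c("X", "Y", "O")),
                         logical(1))))
  # default round count is 100
  expect_length(bootstrap_concatenation(aln[[1]], seed = 1), 100)
  # seed determinism
  expect_identical(bootstrap_concatenation(aln, n_rounds = 5, seed = 9),
                   bootstrap_concatenation(aln, n_rounds = 5, seed = 9))
  expect_error(bootstrap_concatenation(list(), seed = 1),
               class = "xy_config_error")
})

test_that("two-taxon branch lengths sum to the pairwise dS", {
  topo <- ape::read.tree(text = "(A:1,B:1);")
  aln <- c(A = strrep("GGT", 10), B = paste0(strrep("GGT", 9), "GGC"))
  fit <- fit_branch_lengths(topo, aln)
  expect_equal(sum(fit$edge.length), pairwise_ds(aln[[1]], aln[[2]])$ds,
               tolerance = 1e-9)
})

test_that("additive distances on a fixed topology are recovered exactly", {
  topo <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # construct an additive matrix from known branch lengths
  bl <- c(A = 0.10, B = 0.05, C = 0.08, D = 0.12, AB = 0.03, CD = 0.04)
  dm <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  path <- function(i, j) {
    inner <- if (i %in% c("A","B") && j %in% c("A","B")) 0
             else if (i %in% c("C","D") && j %in% c("C","D")) 0
             else bl[["AB"]] + bl[["CD"]]
    bl[[i]] + bl[[j]] + inner
  }
  for (i in rownames(dm)) for (j in colnames(dm)) {
    if (i != j) dm[i, j] <- path(i, j)
  }
  fit <- xyturnover:::fit_branch_lengths_dm(topo, dm)
  fitted <- ape::cophenetic.phylo(fit)[rownames(dm), colnames(dm)]
  expect_equal(fitted, dm, tolerance = 1e-8)
})

test_that("clock-like distances recover the generating node ages", {
  # generating tree (((A,B):.,C):.,D) with node ages AB 0.1, ABC 0.25,
  # root 0.4; pairwise clock distances are twice the MRCA age
  topo <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  age_of <- function(i, j) {
    if (all(c(i, j) %in% c("A", "B"))) 0.1
    else if (all(c(i, j) %in% c("A", "B", "C"))) 0.25
    else 0.4
  }
  taxa <- c("A", "B", "C", "D")
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  for (i in taxa) for (j in taxa) if (i != j) dm[i, j] <- 2 * age_of(i, j)
  fit <- xyturnover:::fit_branch_lengths_dm(topo, dm)
  expect_equal(ape::cophenetic.phylo(fit)[taxa, taxa], dm, tolerance = 1e-8)
  dated <- calibrate_and_date(fit, calibration_tips = c("A", "C"),
                              calibration_age_ma = 0.25,
                              xy_tips = c("A", "B"), outgroup = "D")
  expect_equal(dated$xy_age_ma, 0.1, tolerance = 1e-8)
  depths <- ape::node.depth.edgelength(dated$tree)
  expect_lt(diff(range(depths[1:4])), 1e-9)
})

test_that("calibration is proportional and rescaling matches the closed form", {
  # X/Y split depth exactly half the calibration depth -> half the age
  tr <- ape::read.tree(text = "((X:0.5,Y:0.5):0.5,Out:1);")
  dated <- calibrate_and_date(tr, calibration_tips = c("X", "Out"),
                              calibration_age_ma = 88,
                              xy_tips = c("X", "Y"), outgroup = "Out")
  expect_equal(dated$xy_age_ma, 44, tolerance = 1e-9)
  # linearity in the calibration age
  dated2 <- calibrate_and_date(tr, calibration_tips = c("X", "Out"),
                               calibration_age_ma = 176,
                               xy_tips = c("X", "Y"), outgroup = "Out")
  expect_equal(dated2$xy_age_ma, 88, tolerance = 1e-9)
  expect_equal(rescale_age(61.05, 85.7, 88), 61.05 * 88 / 85.7)
})

test_that("the calibrated tree is ultrametric within tolerance", {
  cfg <- gametologue_cfg(40)
  gams <- simulate_gametologues(cfg, default_species_tree(),
                                n_per_stratum = 2, seed = 11)
  dated <- date_xy_from_alignments(lapply(gams, `[[`, "alignment"),
                                   attr(gams, "topology"),
                                   calibration_tips = c("X", "Anolis"),
                                   calibration_age_ma = 85.7,
                                   n_boot = 20, seed = 2)
  depths <- ape::node.depth.edgelength(dated$tree)
  tip_depths <- depths[seq_along(dated$tree$tip.label)]
  expect_lt(diff(range(tip_depths)), 1e-9)
  expect_lte(dated$xy_age_ma, 85.7)
  expect_length(dated$boot_ages_ma, 20)
})

test_that("bootstrap CI widens as the alignment shrinks", {
  shallow <- ape::read.tree(
    text = "((Basiliscus:85.7,Anolis:85.7):100,Gallus:185.7);")
  widths <- vapply(c(3000L, 600L, 120L), function(nc) {
    cfg <- gametologue_cfg(50, n_codons = nc)
    gams <- simulate_gametologues(cfg, shallow,
                                  n_per_stratum = 1, seed = 21)
    d <- date_xy_from_alignments(list(gams[[1]]$alignment),
                                 attr(gams, "topology"),
                                 calibration_tips = c("X", "Anolis"),
                                 calibration_age_ma = 85.7,
                                 n_boot = 60, seed = 3)
    diff(d$ci95)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("a split not nested in the calibration node is rejected", {
  tr <- ape::read.tree(text = "((X:0.5,Y:0.5):0.5,Out:1);")
  expect_error(
    calibrate_and_date(tr, calibration_tips = c("X", "Y"),
                       calibration_age_ma = 10, xy_tips = c("X", "Out"),
                       outgroup = "Out"),
    class = "xy_calibration_error")
})
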