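# k-mer subtraction pipeline: genome filter, k-mer index, read screening,
# greedy assembly, male-specificity validation.

test_that("reads with ambiguous bases are removed up front", {
  reads <- c(a = "ACGTACGT", b = "ACGNACGT")
  expect_equal(names(remove_ambiguous_reads(reads)), "a")
})

test_that("genome filter removes exactly the mappable reads", {
  genome <- c(chr = random_dna(5000))
  inside <- substr(genome[[1]], 101, 200)
  rc_inside <- revcomp(substr(genome[[1]], 301, 400))
  foreign <- random_dna(100)
  reads <- c(r1 = inside, r2 = rc_inside, r3 = foreign)
  kept <- filter_genome_mapped(reads, genome)
  expect_equal(names(kept), "r3")
  expect_length(filter_genome_mapped(character(0), genome), 0)
})

test_that("k-mer index applies the frequency cutoff", {
  # one k-mer occurring 12 times, another 9 times
  r12 <- rep(strrep("ACGT", 10)[1], 12)
  k <- 35L
  km_a <- substr(paste0(strrep("A", 20), strrep("C", 20)), 1, k)
  km_b <- substr(paste0(strrep("G", 20), strrep("T", 20)), 1, k)
  reads <- c(rep(km_a, 12), rep(km_b, 9))
  idx <- build_kmer_index(reads, k = k, min_count = 10)
  expect_true(km_a %in% idx$kmers)
  expect_false(km_b %in% idx$kmers)
  expect_equal(idx$counts[idx$kmers == km_a], 12L)
  # defaults follow the published procedure
  expect_equal(formals(build_kmer_index)$k, 35L)
  expect_equal(formals(build_kmer_index)$min_count, 10L)
  # k-mers containing N never enter the index
  idxN <- build_kmer_index(rep(paste0("N", substr(km_a, 2, k)), 15), k = k,
                           min_count = 10)
  expect_length(idxN$kmers, 0)
  expect_error(build_kmer_index(c("ACGT"), k = 35), class = "xy_config_error")
})

test_that("a single shared k-mer removes a read", {
  k <- 10L
  idx_reads <- rep("ACGTACGTAC", 12)
  idx <- build_kmer_index(idx_reads, k = k, min_count = 10)
  fully_indexed <- "ACGTACGTAC"
  one_kmer <- paste0(random_dna(20), "ACGTACGTAC", random_dna(20))
  clean <- strrep("A", 40)
  set.seed(77)
  out <- subtract_by_kmers(c(a = fully_indexed, b = one_kmer, c = clean), idx)
  expect_equal(names(out), "c")
  # reverse-complement sharing is also screened
  rc_read <- paste0(strrep("T", 15), revcomp("ACGTACGTAC"), strrep("T", 15))
  out2 <- subtract_by_kmers(c(r = rc_read), idx)
  expect_length(out2, 0)
  # too-short reads are dropped with a warning and counted
  expect_warning(out3 <- subtract_by_kmers(c(s = "ACGT", c = clean), idx),
                 "shorter than k")
  expect_equal(attr(out3, "n_dropped_short"), 1L)
})

test_that("raising min_count or k only grows the surviving read set", {
  set.seed(88)
  signature <- vapply(1:40, function(i) random_dna(60), character(1))
  signature <- rep(signature, times = sample(5:15, 40, replace = TRUE))
  reads <- setNames(
    vapply(1:60, function(i) {
      if (i <= 30) paste0(random_dna(10), sample(signature, 1), random_dna(10))
      else random_dna(80)
    }, character(1)), paste0("r", 1:60))
  survivors <- function(k, mc) {
    idx <- build_kmer_index(signature, k = k, min_count = mc)
    names(subtract_by_kmers(reads, idx))
  }
  s_base <- survivors(25, 3)
  expect_true(all(s_base %in% survivors(25, 6)))   # higher cutoff
  expect_true(all(s_base %in% survivors(35, 3)))   # longer k-mers
})

test_that("greedy assembly merges hand-checkable overlaps deterministically", {
  out <- assemble_contigs(c(a = "ACGTACGT", b = "TACGTTTT"), min_overlap = 5)
  expect_equal(unname(out), "ACGTACGTTTT")
  # duplicates collapse to a single contig
  out2 <- assemble_contigs(c(x = "ACGTACGT", y = "ACGTACGT"), min_overlap = 5)
  expect_equal(unname(out2), "ACGTACGT")
  # result independent of read input order
  set.seed(12)
  tx <- random_dna(400)
  starts <- sort(sample(1:300, 40, replace = TRUE))
  reads <- setNames(substring(tx, starts, starts + 99), paste0("r", 1:40))
  a1 <- assemble_contigs(reads, 30)
  a2 <- assemble_contigs(rev(reads), 30)
  expect_identical(sort(unname(a1)), sort(unname(a2)))
})

test_that("shredded transcripts reassemble to near-full length", {
  set.seed(13)
  tx <- random_dna(600)
  reads <- simulate_reads(c(t1 = tx), depth = 10, read_length = 100,
                          seed = 14, stranded = TRUE)
  contigs <- assemble_contigs(setNames(reads$seq, reads$id), 30)
  expect_gte(max(nchar(contigs)), 0.9 * nchar(tx))
  expect_true(all(vapply(contigs, grepl, logical(1), x = tx, fixed = TRUE)))
})

test_that("validation separates male-specific from shared contigs", {
  set.seed(15)
  shared <- random_dna(3000)
  male_only <- random_dna(800)
  male_genome <- c(chrA = shared, chrY = male_only)
  female_genome <- c(chrA = shared)
  contigs <- c(y_ctg = substr(male_only, 101, 500),
               shared_ctg = substr(shared, 501, 900),
               junk = random_dna(300))
  v <- validate_male_specific(contigs, male_genome, female_genome)
  expect_equal(v$status[v$id == "y_ctg"], "ACCEPTED")
  expect_equal(v$status[v$id == "shared_ctg"], "REJECTED_FEMALE_PRESENT")
  expect_equal(v$status[v$id == "junk"], "REJECTED_LOW_MALE_IDENTITY")
  expect_equal(v$male_identity[v$id == "y_ctg"], 1.0)
})

test_that("end-to-end subtraction recovers the planted Y transcripts", {
  fx <- subtract_fixture()
  expect_equal(fx$scores$precision, 1.0)
  expect_equal(fx$scores$recall, 1.0)
  expect_gt(length(fx$res$accepted), 0)
  # every accepted contig sits inside a truth Y transcript
  expect_false(any(is.na(fx$scores$contig_map)))
})

test_that("the sex-swapped mirror run accepts nothing", {
  fx <- subtract_fixture()
  expect_equal(unname(fx$mirror$stats["n_accepted"]), 0L)
})
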