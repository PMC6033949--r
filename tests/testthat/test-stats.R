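test_that("GII follows the insertion-count scaling with the TA denominator", {
  fx <- gii_fixture()
  st <- compute_gene_stats(fx$lib, fx$genes, fx$ta_index, constant_k = 72)
  st <- st[match(c("gA", "gB", "gC"), st$gene_id), ]
  # 72 TA, 10 insertions: the constant cancels
  expect_equal(st$gii[1], 10)
  # 36 TA, 9 insertions: 9 * 72 / 36
  expect_equal(st$gii[2], 18)
  # insertions at 50/500/950 in a 1..1000 gene: 950 sits in the excluded
  # 3' tenth, so 2 * 72 / 36
  expect_equal(st$insertions_effective[3], 2L)
  expect_equal(st$gii[3], 4)
  expect_equal(st$ta_full, c(72L, 36L, 36L))
})

test_that("GII ignores read counts and collapses orientations", {
  fx <- gii_fixture()
  boosted <- fx$lib
  boosted$sites$read_count <- boosted$sites$read_count * 50L
  s1 <- compute_gene_stats(fx$lib, fx$genes, fx$ta_index)
  s2 <- compute_gene_stats(boosted, fx$genes, fx$ta_index)
  expect_equal(s1$gii, s2$gii)
  expect_equal(s2$reads_effective, 50 * s1$reads_effective)

  # the same position hit in both orientations is one disrupted site
  dup <- fx$lib$sites[fx$lib$sites$chromosome == "cA", ]
  dup$orientation <- "reverse"
  both <- merge_libraries(fx$lib, insertion_library(dup))
  s3 <- compute_gene_stats(both, fx$genes, fx$ta_index)
  expect_equal(s3$insertions_effective, s1$insertions_effective)
  s4 <- compute_gene_stats(both, fx$genes, fx$ta_index,
                           collapse_orientation = FALSE)
  expect_equal(s4$insertions_effective[s4$gene_id == "gA"], 20L)
})

test_that("genes without TA sites are flagged undefined", {
  g <- toy_genome(c1 = paste0(strrep("GC", 50), "TA", strrep("GC", 50)))
  genes <- toy_annotation(c("no_ta", "with_ta"), "c1", c(1L, 81L),
                          c(80L, 202L), c("+", "+"))
  lib <- toy_library("c1", 101L)
  st <- compute_gene_stats(lib, genes, index_ta_sites(g))
  expect_false(st$defined[st$gene_id == "no_ta"])
  expect_true(is.na(st$gii[st$gene_id == "no_ta"]))
  expect_true(st$defined[st$gene_id == "with_ta"])
})

test_that("region fractions partition sites into exon/intron/IGR", {
  g <- toy_genome(c1 = plant_ta(100L, c(5L, 50L)))
  genes <- toy_annotation("g1", "c1", 11L, 90L, "+")
  lib <- toy_library("c1", c(5L, 50L))
  rf <- region_fractions(lib, genes)
  expect_equal(unname(rf), c(0.5, 0, 0.5), ignore_attr = TRUE)
  expect_equal(sum(rf), 1)

  # a site in the gap between two exons is intronic
  genes2 <- toy_annotation("g1", "c1", 11L, 90L, "+",
                           exons = list(cbind(start = c(11L, 61L),
                                              end = c(40L, 90L))))
  rf2 <- region_fractions(toy_library("c1", 50L), genes2)
  expect_equal(unname(rf2["intron"]), 1)

  # all sites intergenic
  rf3 <- region_fractions(toy_library("c1", 5L), genes)
  expect_equal(unname(rf3["igr"]), 1)
})

test_that("ORF segment bins follow the ceiling rule in gene orientation", {
  genes <- toy_annotation("g1", "c1", 1L, 250L, "+")
  lib <- toy_library("c1", c(1L, 125L, 250L))
  sp <- segment_profile(lib, genes)
  expect_equal(sum(sp$orf_bins), 3L)
  expect_equal(which(sp$orf_bins > 0), c(1L, 13L, 25L))

  # minus strand: offsets measured from the 3' (right) end
  genes_m <- toy_annotation("g1", "c1", 1L, 250L, "-")
  sp_m <- segment_profile(toy_library("c1", 1L), genes_m)
  expect_equal(which(sp_m$orf_bins > 0), 25L)
})

test_that("intergenic sites bin to the nearer gene end, ties 5'-ward", {
  genes <- toy_annotation(c("g1", "g2"), "c1", c(1L, 300L), c(100L, 400L),
                          c("+", "+"))
  # site at 200 is 100 bp from both g1's end and g2's start: tie -> g1,
  # which is on '+', so the site is downstream of g1
  sp <- segment_profile(toy_library("c1", 200L), genes,
                        flank_bp = 500L, flank_bin_bp = 100L)
  expect_equal(sum(sp$downstream_bins), 1L)
  expect_equal(sum(sp$upstream_bins), 0L)
  expect_equal(which(sp$downstream_bins > 0), 1L)

  # site at 210 is nearer g2 ('+'), hence upstream of it
  sp2 <- segment_profile(toy_library("c1", 210L), genes,
                         flank_bp = 500L, flank_bin_bp = 100L)
  expect_equal(sum(sp2$upstream_bins), 1L)

  # beyond the flank window
  sp3 <- segment_profile(toy_library("c1", 200L), genes,
                         flank_bp = 50L, flank_bin_bp = 10L)
  expect_equal(sp3$n_beyond_flank, 1L)
})

test_that("logo matrix reflects flank composition in insertion orientation", {
  # context ATG CGA [TA] TAC GCA around a TA at position 101
  left <- "ATGCGA"; right <- "TACGCA"
  pad <- strrep("G", 95)
  g <- toy_genome(c1 = paste0(pad, left, "TA", right, pad))
  idx <- index_ta_sites(g)
  p <- 102L
  expect_true(p %in% idx$c1)

  lm_f <- logo_matrix(toy_library("c1", p), g, flank_k = 6)
  expect_equal(dim(lm_f), c(4L, 14L))
  expect_true(all(abs(colSums(lm_f) - 1) < 1e-9))
  expect_equal(unname(lm_f["T", "T"]), 1)   # central dinucleotide fixed
  expect_equal(unname(lm_f["A", "A"]), 1)
  expect_equal(unname(lm_f["A", "-6"]), 1)  # 'A' of ATGCGA
  expect_equal(unname(lm_f["A", "-1"]), 1)  # ...A right before the T
  expect_equal(unname(lm_f["T", "+1"]), 1)  # T of TACGCA

  # a reverse-orientation site contributes the reverse complement context
  lm_r <- logo_matrix(toy_library("c1", p, orientation = "reverse"), g,
                      flank_k = 6)
  # position -1 of a reverse site is the complement of the forward +1 base
  expect_equal(unname(lm_r[, "-1"]), unname(lm_f[c("T", "G", "C", "A"), "+1"]))
  expect_equal(unname(lm_r["T", "T"]), 1)

  empty <- insertion_library(
    data.frame(chromosome = character(0), position = integer(0),
               orientation = character(0), read_count = integer(0)))
  expect_error(logo_matrix(empty, g), "no insertion")
})

test_that("single-site logos are one-hot", {
  set.seed(71)
  g <- toy_genome(c1 = random_dna(200))
  idx <- index_ta_sites(g)
  p <- idx$c1[idx$c1 > 10 & idx$c1 < 190][1]
  lm <- logo_matrix(toy_library("c1", p), g, flank_k = 3)
  expect_true(all(colSums(lm == 1) == 1))
})

test_that("saturation curve accumulates unique sites monotonically", {
  l1 <- toy_library("c1", c(1L, 2L))
  l2 <- toy_library("c1", c(2L, 3L))
  l3 <- toy_library("c1", 3L)
  sc <- saturation_curve(list(l1, l2, l3))
  expect_equal(sc$cumulative, c(2L, 3L, 3L))

  # identical libraries: flat after the first
  sc2 <- saturation_curve(list(l1, l1, l1))
  expect_equal(sc2$cumulative, c(2L, 2L, 2L))

  # disjoint equal-size libraries: linear growth
  l4 <- toy_library("c1", c(10L, 11L))
  l5 <- toy_library("c1", c(20L, 21L))
  sc3 <- saturation_curve(list(l1, l4, l5))
  expect_equal(sc3$cumulative, c(2L, 4L, 6L))

  # monotone for any ordering; final value equals the full merge
  set.seed(83)
  libs <- lapply(1:5, function(i) toy_library("c1", sample(1:40, 10) * 3L))
  sc4 <- saturation_curve(libs, n_orderings = 10)
  expect_true(all(diff(sc4$cumulative) >= 0))
  expect_true(all(diff(sc4$mean) >= 0))
  expect_equal(sc4$cumulative[5],
               n_sites(merge_libraries(libs)))
})

test_that("venn overlap partitions the union", {
  a <- toy_library("c1", c(1L, 2L, 3L))
  b <- toy_library("c1", c(2L, 3L, 4L))
  expect_equal(unname(venn_overlap(a, b)), c(1L, 2L, 1L))
  expect_equal(unname(venn_overlap(a, a)), c(0L, 3L, 0L))
  d <- toy_library("c2", c(1L, 2L))
  expect_equal(unname(venn_overlap(a, d)), c(3L, 0L, 2L))
  # orientation distinguishes sites only in stranded mode
  a_rev <- toy_library("c1", c(1L, 2L, 3L), orientation = "reverse")
  expect_equal(unname(venn_overlap(a, a_rev)["shared"]), 0L)
  expect_equal(unname(venn_overlap(a, a_rev, stranded = FALSE)["shared"]), 3L)
})

test_that("normalization R2 distinguishes proportional from shuffled counts", {
  set.seed(97)
  n <- 200
  ta <- sample(20:150, n, replace = TRUE)
  st <- data.frame(gene_id = paste0("g", 1:n),
                   gene_length = ta * 10L,
                   ta_full = ta,
                   insertions_full = ta * 3L)
  r2 <- normalization_r2(st)
  expect_equal(unname(r2["r2_ta_vs_insertions"]), 1.0)

  # permuted insertion counts: no relation to TA count
  st$insertions_full <- sample(st$insertions_full)
  r2p <- normalization_r2(st)
  expect_lt(unname(r2p["r2_ta_vs_insertions"]), 0.05)

  st$insertions_full <- 7L
  expect_warning(r2c <- normalization_r2(st), "zero variance")
  expect_true(all(is.na(r2c)))
})

test_that("density per kb scales with genome size and site count", {
  g1 <- toy_genome(c1 = strrep("G", 1000))
  lib <- toy_library("c1", seq(1L, 500L, length.out = 10))
  expect_equal(density_per_kb(lib, g1), 10)
  g2 <- toy_genome(c1 = strrep("G", 1000), c2 = strrep("G", 1000))
  expect_equal(density_per_kb(lib, g2), 5)
  empty <- insertion_library(
    data.frame(chromosome = character(0), position = integer(0),
               orientation = character(0), read_count = integer(0)))
  expect_equal(density_per_kb(empty, g1), 0)
})

test_that("gene stats TSV export is readable", {
  fx <- gii_fixture()
  st <- compute_gene_stats(fx$lib, fx$genes, fx$ta_index)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_stats(st, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$gii, st$gii)
})
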