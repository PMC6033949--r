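write_fastq <- function(seqs, path) {
  ids <- sprintf("r%03d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  path
}

test_that("junction spec validates its fields", {
  expect_error(junction_read_spec(transposon_terminus = ""), "non-empty")
  expect_error(junction_read_spec(mismatch_rate = 0.6), "mismatch_rate")
  expect_error(junction_read_spec(min_fragment_len = 60,
                                  max_fragment_len = 50), "fragment_len")
})

test_that("trimming recovers the genomic fragment between terminus and adapter", {
  spec <- junction_read_spec()
  frag <- "ACGTACGTACGTACGTAA"
  reads <- c(
    paste0(spec$transposon_terminus, frag, spec$adapter_tail),  # full layout
    paste0("GGGGGGGGGGGGGGGG", frag, spec$adapter_tail),        # no terminus
    paste0(spec$transposon_terminus, "ACGTACGTAC",
           spec$adapter_tail))                                  # too short
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  out <- trim_junction_reads(fq, spec)
  expect_equal(out$sequence, frag)
  s <- attr(out, "summary")
  expect_equal(unname(s["no_terminus"]), 1L)
  expect_equal(unname(s["too_short"]), 1L)
  expect_equal(unname(s["retained"]), 1L)
})

test_that("tandem terminus copies are stripped and fragments never retain one", {
  spec <- junction_read_spec()
  frag <- "CCGTACGTACGTACGTCCAA"
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(paste0(spec$transposon_terminus, spec$transposon_terminus,
                     frag, spec$adapter_tail), fq)
  out <- trim_junction_reads(fq, spec)
  expect_equal(out$sequence, frag)
  expect_false(any(grepl(spec$transposon_terminus, out$sequence, fixed = TRUE)))
})

test_that("trimming tolerates mismatches within the allowance", {
  spec <- junction_read_spec()  # 16 bp terminus, 5% -> 1 mismatch allowed
  term1 <- spec$transposon_terminus
  substr(term1, 5, 5) <- if (substr(term1, 5, 5) == "A") "C" else "A"
  frag <- "TTGCATTGCATTGCATTGCA"
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(paste0(term1, frag, spec$adapter_tail), fq)
  out <- trim_junction_reads(fq, spec)
  expect_equal(out$sequence, frag)
})

test_that("truncation caps fragments at max_fragment_len", {
  spec <- junction_read_spec()
  long_frag <- strrep("ACGTG", 20)  # 100 bp
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(paste0(spec$transposon_terminus, long_frag), fq)
  out <- trim_junction_reads(fq, spec)
  expect_equal(nchar(out$sequence), spec$max_fragment_len)
  expect_equal(out$sequence, substr(long_frag, 1, spec$max_fragment_len))
})

test_that("fragments sampled verbatim from unique loci map back exactly", {
  set.seed(23)
  g <- toy_genome(c1 = random_dna(3000), c2 = random_dna(2000))
  frags <- character(0)
  truth <- list()
  for (i in 1:20) {
    chr <- sample(names(g), 1)
    L <- Biostrings::width(g)[names(g) == chr]
    fl <- sample(20:40, 1)
    s <- sample(L - fl, 1)
    f <- substr(as.character(g[[chr]]), s, s + fl - 1)
    strand <- sample(c("+", "-"), 1)
    frags[i] <- if (strand == "+") f else rc(f)
    truth[[i]] <- list(chr = chr, start = s, strand = strand)
  }
  for (method in c("exhaustive", "seed")) {
    aln <- map_fragments(stats::setNames(frags, paste0("f", 1:20)), g,
                         method = method)
    expect_equal(nrow(aln), 20)
    for (i in 1:20) {
      row <- aln[aln$fragment_id == paste0("f", i), ]
      expect_equal(row$chromosome, truth[[i]]$chr)
      expect_equal(row$start, truth[[i]]$start)
      expect_equal(row$strand, truth[[i]]$strand)
      expect_equal(row$mismatches, 0L)
    }
  }
})

test_that("repeated loci are dropped as multi-mapped, with reason codes", {
  unit <- random_dna(30)
  g <- toy_genome(c1 = paste0(random_dna(200), unit, random_dna(200), unit,
                              random_dna(100)))
  aln <- map_fragments(c(dup = unit, none = strrep("A", 25)), g)
  expect_equal(nrow(aln), 0)
  dropped <- attr(aln, "dropped")
  expect_equal(dropped$reason[dropped$fragment_id == "dup"], "multi_mapped")
  expect_equal(dropped$reason[dropped$fragment_id == "none"], "unmapped")
})

test_that("a palindromic-context fragment maps uniquely despite strands", {
  # a fragment equal to its own reverse complement has the same best locus
  # on both strands only if the locus is counted twice; the mapper must
  # treat the two strand alignments at one locus as distinct candidates
  set.seed(31)
  half <- random_dna(15)
  pal <- paste0(half, rc(half))  # 30 bp palindrome
  g <- toy_genome(c1 = paste0(random_dna(100), pal, random_dna(100)))
  aln <- map_fragments(c(p = pal), g)
  # both strands tie at 0 mismatches at the same locus -> multi-mapped
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "dropped")$reason, "multi_mapped")
})

test_that("seeded and exhaustive mapping agree on random fragment sets", {
  set.seed(41)
  g <- toy_genome(c1 = random_dna(4000))
  seqchr <- as.character(g[[1]])
  frags <- vapply(1:30, function(i) {
    # inject up to 2 mismatches; mismatched fragments are kept >= 40 bp so
    # every candidate locus retains a 12 bp exact stretch (the regime where
    # the two methods are guaranteed identical)
    nmm <- sample(0:2, 1)
    fl <- if (nmm == 0) sample(16:50, 1) else sample(40:50, 1)
    s <- sample(4000 - fl, 1)
    f <- substr(seqchr, s, s + fl - 1)
    if (nmm > 0) {
      at <- sample(fl, nmm)
      for (a in at) {
        old <- substr(f, a, a)
        substr(f, a, a) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    if (runif(1) < 0.5) f else rc(f)
  }, character(1))
  a1 <- map_fragments(stats::setNames(frags, 1:30), g, method = "exhaustive")
  a2 <- map_fragments(stats::setNames(frags, 1:30), g, method = "seed")
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("insertion sites snap to the abutting TA in both orientations", {
  # genome with one TA at 101; fragments start at the T (forward) or end
  # one base past it (reverse)
  set.seed(53)
  left <- random_dna(100, letters = c("C", "G"))
  right <- random_dna(100, letters = c("C", "G"))
  core <- random_dna(60)
  g <- toy_genome(c1 = paste0(left, "TA", core, right))
  idx <- index_ta_sites(g)
  expect_true(101L %in% idx$c1)

  fwd_frag <- substr(as.character(g[[1]]), 101, 130)   # starts at the T
  rev_frag <- rc(substr(as.character(g[[1]]), 73, 102)) # 5' end at the A
  aln <- map_fragments(c(f = fwd_frag, r = rev_frag, f2 = fwd_frag,
                         f3 = fwd_frag), g)
  lib <- call_insertion_sites(aln, idx)
  s <- lib$sites
  expect_equal(nrow(s), 2)
  expect_equal(s$position, c(101L, 101L))
  expect_equal(sort(s$orientation), c("forward", "reverse"))
  # triple-submitted forward fragment collapses to read_count 3
  expect_equal(s$read_count[s$orientation == "forward"], 3L)
  expect_equal(s$read_count[s$orientation == "reverse"], 1L)
})

test_that("junctions beyond the snap window are dropped", {
  set.seed(59)
  pad <- random_dna(80, letters = c("C", "G"))
  core <- random_dna(60, letters = c("C", "G"))  # keep 81 the only TA
  pad2 <- random_dna(80, letters = c("C", "G"))
  g <- toy_genome(c1 = paste0(pad, "TA", core, pad2))
  idx <- index_ta_sites(g)
  seqchr <- as.character(g[[1]])
  aln <- map_fragments(c(near = substr(seqchr, 83, 112),   # 2 bp from the TA
                         far = substr(seqchr, 95, 124)), g) # 14 bp away
  lib <- call_insertion_sites(aln, idx, snap_window = 2L)
  expect_equal(lib$sites$position, 81L)
  expect_equal(attr(lib$sites, "n_no_ta"), 1L)
})

test_that("library merges union sites and sum read counts", {
  a <- toy_library("c1", c(10L, 20L), read_count = c(1L, 2L), label = "A")
  b <- toy_library("c1", c(20L, 30L), orientation = c("forward", "reverse"),
                   read_count = c(3L, 1L), label = "B")
  m <- merge_libraries(a, b)
  expect_equal(nrow(m$sites), 3)
  expect_equal(m$sites$read_count[m$sites$position == 20L], 5L)

  # self-merge: identical keys, doubled counts
  self <- merge_libraries(a, a)
  expect_equal(self$sites[, 1:3], a$sites[, 1:3])
  expect_equal(self$sites$read_count, 2L * a$sites$read_count)

  # associativity / commutativity on keys
  c3 <- toy_library("c2", 5L, label = "C")
  key <- function(l) paste(l$sites$chromosome, l$sites$position,
                           l$sites$orientation)
  expect_setequal(key(merge_libraries(merge_libraries(a, b), c3)),
                  key(merge_libraries(a, merge_libraries(b, c3))))
  expect_setequal(key(merge_libraries(b, a)), key(merge_libraries(a, b)))
})

test_that("site TSV round trips and validates against the TA index", {
  g <- toy_genome(c1 = "GGTAGGGGTAGG")
  idx <- index_ta_sites(g)
  lib <- toy_library("c1", c(3L, 9L), orientation = c("forward", "reverse"),
                     read_count = c(4L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(lib, path)
  back <- read_sites_tsv(path, ta_index = idx, label = lib$label)
  expect_equal(back$sites, lib$sites)

  bad <- lib
  bad$sites$position[1] <- 5L
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(bad, path2)
  expect_error(read_sites_tsv(path2, ta_index = idx), "not in TA index")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chromosome\tposition\torientation\tread_count", empty)
  e <- read_sites_tsv(empty, ta_index = idx)
  expect_equal(nrow(e$sites), 0)
})

test_that("SAM alignments are accepted in place of the native mapper", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:c1\tLN:1000",
    paste("f1", 0, "c1", 101, 42, "30M", "*", 0, 0,
          strrep("A", 30), strrep("I", 30), "NM:i:1", sep = "\t"),
    paste("f2", 16, "c1", 201, 42, "30M", "*", 0, 0,
          strrep("A", 30), strrep("I", 30), "NM:i:0", sep = "\t"),
    paste("f3", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 30), strrep("I", 30), sep = "\t")), sam)
  aln <- read_alignments_sam(sam)
  expect_equal(nrow(aln), 2)
  expect_equal(aln$start, c(101L, 201L))
  expect_equal(aln$end, c(130L, 230L))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$mismatches, c(1L, 0L))
})
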