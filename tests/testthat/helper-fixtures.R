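# shared fixture builders and independent oracles (kept deliberately naive;
# they must not share code paths with the package internals they check)

toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

toy_annotation <- function(gene_id, chromosome, start, end, strand,
                           exons = NULL) {
  df <- data.frame(gene_id = gene_id, chromosome = chromosome,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  if (is.null(exons)) {
    exons <- lapply(seq_len(nrow(df)), function(i) {
      cbind(start = df$start[i], end = df$end[i])
    })
  }
  df$exons <- exons
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

toy_library <- function(chromosome, position, orientation = "forward",
                        read_count = 1L, label = "toy") {
  n <- max(length(chromosome), length(position))
  insertion_library(
    data.frame(chromosome = rep_len(chromosome, n),
               position = rep_len(as.integer(position), n),
               orientation = rep_len(orientation, n),
               read_count = rep_len(as.integer(read_count), n),
               stringsAsFactors = FALSE),
    label = label)
}

# sequence of `len` background G's with "TA" planted at each position
# (positions must be >= 1, <= len - 1, and pairwise >= 2 apart)
plant_ta <- function(len, positions) {
  s <- rep("G", len)
  for (p in positions) {
    s[p] <- "T"
    s[p + 1] <- "A"
  }
  paste(s, collapse = "")
}

# naive TA scan: the O(n) reference for index_ta_sites
naive_ta_scan <- function(seq) {
  which(vapply(seq_len(max(nchar(seq) - 1L, 0L)),
               function(i) substr(seq, i, i + 1L) == "TA", logical(1)))
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

mm_vec <- function(strings, ref) {
  refc <- strsplit(ref, "")[[1]]
  vapply(strsplit(strings, ""), function(ch) sum(ch != refc), integer(1))
}

# brute-force unique-best ungapped mapping oracle: every offset, both
# strands, min-mismatch locus must be unique and <= max_mm
oracle_map <- function(frag, genome, max_mm = 3L) {
  hits <- data.frame(chrom = character(0), start = integer(0),
                     strand = character(0), mm = integer(0),
                     stringsAsFactors = FALSE)
  fl <- nchar(frag)
  for (chr in names(genome)) {
    seqchr <- as.character(genome[[chr]])
    L <- nchar(seqchr)
    if (L < fl) next
    starts <- seq_len(L - fl + 1L)
    wins <- substring(seqchr, starts, starts + fl - 1L)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") frag else rc(frag)
      mm <- mm_vec(wins, q)
      keep <- which(mm <= max_mm)
      if (length(keep)) {
        hits <- rbind(hits, data.frame(chrom = chr, start = starts[keep],
                                       strand = strand, mm = mm[keep],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(hits) == 0L) return(list(status = "unmapped"))
  best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  if (nrow(best) > 1L) return(list(status = "multi_mapped"))
  list(status = "unique", chrom = best$chrom, start = best$start,
       strand = best$strand, mm = best$mm)
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# fixture for the GII arithmetic examples: three genes with exactly
# controlled TA counts and insertion positions
gii_fixture <- function() {
  pos_a <- seq(10L, 720L, by = 10L)                       # 72 TA in gene A
  pos_b <- seq(10L, 360L, by = 10L)                       # 36 TA in gene B
  pos_c <- c(50L, 500L, 950L, seq(100L, 420L, by = 10L))  # 36 TA in gene C
  genome <- toy_genome(cA = plant_ta(1000L, pos_a),
                       cB = plant_ta(600L, pos_b),
                       cC = plant_ta(1100L, pos_c))
  genes <- toy_annotation(
    gene_id = c("gA", "gB", "gC"),
    chromosome = c("cA", "cB", "cC"),
    start = c(1L, 1L, 1L), end = c(800L, 500L, 1000L),
    strand = c("+", "+", "+"))
  lib <- toy_library(
    chromosome = c(rep("cA", 10), rep("cB", 9), rep("cC", 3)),
    position = c(pos_a[1:10], pos_b[1:9], c(50L, 500L, 950L)))
  list(genome = genome, genes = genes, lib = lib,
       ta_index = index_ta_sites(genome))
}
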