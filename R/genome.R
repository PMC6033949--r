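#' Load a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a `DNAStringSet`, uppercasing
#' sequences and validating that only the alphabet `A,C,G,T,N` is used.
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one entry per record.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) stop("FASTA file contains no records: ", fasta_path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(raw) <- ids
  raw <- Biostrings::BStringSet(toupper(raw))
  if (any(Biostrings::width(raw) == 0L)) {
    stop("empty sequence record(s): ",
         paste(ids[Biostrings::width(raw) == 0L], collapse = ", "))
  }
  bad <- vapply(seq_along(raw), function(i) {
    letters <- Biostrings::uniqueLetters(raw[[i]])
    any(!letters %in% c("A", "C", "G", "T", "N"))
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) contain letters outside A,C,G,T,N (RNA 'U' is rejected): ",
         paste(ids[bad], collapse = ", "))
  }
  Biostrings::DNAStringSet(raw)
}

#' Load gene annotation from a GFF3 file
#'
#' Parses `gene` features (with optional `exon` children attached through
#' their `Parent` attribute) into a gene table. Genes without explicit
#' exons are treated as single-exon genes spanning the full gene interval;
#' introns are the gaps between consecutive exons.
#'
#' @param gff_path Path to a GFF3 file with `gene` (and optionally `exon`)
#'   features.
#' @param genome A genome from [load_genome()]; used to validate seqids and
#'   coordinate bounds.
#' @return A `data.frame` of class `gene_annotation`, sorted by
#'   (chromosome, start), with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` and a list column `exons` (two-column matrices of
#'   1-based inclusive exon intervals).
#' @export
load_annotation <- function(gff_path, genome) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  if (length(g) == 0L) stop("no 'gene' features in ", gff_path)
  gene_id <- as.character(g$ID)
  if (any(is.na(gene_id) | gene_id == "")) {
    stop("gene feature(s) without an ID attribute in ", gff_path)
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  chrom <- as.character(GenomicRanges::seqnames(g))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown) > 0L) {
    stop("annotation seqid(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  }
  start <- GenomicRanges::start(g)
  end <- GenomicRanges::end(g)
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start < 1L | end > lens)) {
    stop("gene interval(s) outside chromosome bounds: ",
         paste(gene_id[start < 1L | end > lens], collapse = ", "))
  }
  strand <- as.character(GenomicRanges::strand(g))
  strand[!strand %in% c("+", "-")] <- "+"

  ex <- gr[type == "exon"]
  parents <- if (length(ex)) {
    vapply(as.list(ex$Parent), function(z) {
      if (length(z)) sub("^gene:", "", z[1]) else NA_character_
    }, character(1))
  } else {
    character(0)
  }
  exons <- vector("list", length(g))
  for (i in seq_along(g)) {
    hit <- which(parents == gene_id[i])
    if (length(hit) == 0L) {
      exons[[i]] <- cbind(start = start[i], end = end[i])
    } else {
      es <- GenomicRanges::start(ex)[hit]
      ee <- GenomicRanges::end(ex)[hit]
      o <- order(es)
      es <- es[o]; ee <- ee[o]
      if (any(es < start[i]) || any(ee > end[i])) {
        stop("exon outside parent gene span for gene ", gene_id[i])
      }
      if (length(es) > 1L && any(es[-1L] <= ee[-length(ee)])) {
        stop("overlapping exons for gene ", gene_id[i])
      }
      exons[[i]] <- cbind(start = es, end = ee)
    }
  }

  out <- data.frame(gene_id = gene_id, chromosome = chrom, start = start,
                    end = end, strand = strand, stringsAsFactors = FALSE)
  out$exons <- exons
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Index all TA dinucleotide target sites in a genome
#'
#' A TA site is identified by the 1-based coordinate of its `T` on the
#' forward strand; since `TA` is its own reverse complement the site is a
#' single shared target for both insertion orientations. Overlapping
#' occurrences (e.g. `TATA` giving positions 1 and 3) are all indexed.
#' Positions involving `N` are never sites.
#'
#' @param genome A genome from [load_genome()].
#' @return A `ta_index`: a named list of strictly increasing integer
#'   vectors (one per chromosome) with attribute `total` (total site count)
#'   and `chrom_lengths`.
#' @export
index_ta_sites <- function(genome) {
  mi <- Biostrings::vmatchPattern("TA", genome)
  idx <- lapply(seq_along(genome), function(i) IRanges::start(mi[[i]]))
  names(idx) <- names(genome)
  structure(idx,
            total = sum(lengths(idx)),
            chrom_lengths = stats::setNames(Biostrings::width(genome),
                                            names(genome)),
            class = "ta_index")
}

#' @export
print.ta_index <- function(x, ...) {
  cat("TA site index:", attr(x, "total"), "sites on", length(x),
      "chromosome(s)\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", length(x[[nm]]), " sites\n", sep = "")
  }
  invisible(x)
}

#' Effective (insertion-scoring) region of each gene
#'
#' Insertions landing in the 3'-terminal fraction of a gene often leave a
#' functional truncated product, so that portion of the gene is excluded
#' when counting disruptive insertions. The effective region is the
#' 5'-most `floor((1 - excluded_fraction) * L)` bases of the genomic span,
#' measured in gene orientation.
#'
#' @param genes A `gene_annotation` table from [load_annotation()].
#' @param excluded_fraction Fraction of gene length excluded at the 3' end
#'   (default 0.10).
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`. Genes whose effective length rounds to zero get `NA`
#'   bounds.
#' @export
effective_region <- function(genes, excluded_fraction = 0.10) {
  if (!is.numeric(excluded_fraction) || length(excluded_fraction) != 1L ||
      excluded_fraction < 0 || excluded_fraction >= 1) {
    stop("excluded_fraction must be a single value in [0, 1)")
  }
  L <- genes$end - genes$start + 1L
  keep <- as.integer(floor((1 - excluded_fraction) * L))
  s <- ifelse(genes$strand == "+", genes$start, genes$end - keep + 1L)
  e <- ifelse(genes$strand == "+", genes$start + keep - 1L, genes$end)
  s[keep == 0L] <- NA_integer_
  e[keep == 0L] <- NA_integer_
  data.frame(gene_id = genes$gene_id, chromosome = genes$chromosome,
             start = as.integer(s), end = as.integer(e),
             strand = genes$strand, stringsAsFactors = FALSE)
}

# count of sorted positions in [s, e] via binary search
.count_in_interval <- function(pos, s, e) {
  if (is.na(s) || is.na(e) || length(pos) == 0L) return(0L)
  findInterval(e, pos) - findInterval(s - 1L, pos)
}

#' TA site counts per gene
#'
#' Counts TA sites (by the position of the T) inside either the full gene
#' span or the 3'-truncated effective region.
#'
#' @param ta_index A `ta_index` from [index_ta_sites()].
#' @param genes A `gene_annotation` table.
#' @param region `"full"` (whole gene span) or `"effective"` (the region
#'   from [effective_region()]).
#' @param excluded_fraction Passed to [effective_region()] when
#'   `region = "effective"`.
#' @return Named integer vector of TA counts, one per gene.
#' @export
ta_counts_per_gene <- function(ta_index, genes, region = c("full", "effective"),
                               excluded_fraction = 0.10) {
  region <- match.arg(region)
  if (region == "effective") {
    iv <- effective_region(genes, excluded_fraction)
  } else {
    iv <- genes
  }
  n <- vapply(seq_len(nrow(iv)), function(i) {
    .count_in_interval(ta_index[[iv$chromosome[i]]], iv$start[i], iv$end[i])
  }, integer(1))
  stats::setNames(n, genes$gene_id)
}

#' Write a TA site index to disk
#'
#' @param ta_index A `ta_index`.
#' @param path Output file.
#' @param format `"tsv"` (chromosome, 1-based position) or `"bed"`
#'   (0-based half-open intervals covering the TA dinucleotide).
#' @return `path`, invisibly.
#' @export
write_ta_index <- function(ta_index, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  chrom <- rep(names(ta_index), lengths(ta_index))
  pos <- unlist(ta_index, use.names = FALSE)
  if (format == "tsv") {
    df <- data.frame(chromosome = chrom, position = pos)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(chrom = chrom, start = pos - 1L, end = pos + 1L)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
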