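#' Per-gene insertion statistics and the Gene Insertion Index
#'
#' For every annotated gene, counts TA sites and insertions and computes
#' the Gene Insertion Index
#' \deqn{GII = \frac{\mathrm{insertions} \times K}{\mathrm{TA\ sites}}}
#' where insertions are unique disrupted TA positions within the gene's
#' effective region (the 3'-terminal `excluded_fraction` of the gene is
#' ignored, insertions there being tolerated even in essential genes), the
#' TA denominator is the full-gene TA count, and `K` is the genome-average
#' TA count per gene (72 for the compact yeast genome this analysis was
#' designed around). Read density is the summed read count over the same
#' effective region divided by the full-gene TA count; it serves as the
#' secondary classifier feature.
#'
#' @param library An `insertion_library`.
#' @param genes A `gene_annotation` table.
#' @param ta_index A `ta_index`.
#' @param constant_k Genome-average TA sites per gene (default 72). Set
#'   `constant_k = NULL` to recompute it as `mean(ta_full)` over the
#'   supplied annotation (useful for synthetic genomes).
#' @param excluded_fraction 3'-end fraction excluded (default 0.10).
#' @param collapse_orientation If `TRUE` (default) a TA position hit in
#'   both orientations counts as one disrupted position.
#' @param reads_in_effective_region If `TRUE` (default) read counts are
#'   summed over the effective region only, mirroring the insertion
#'   numerator; if `FALSE`, over the full gene span.
#' @return A `data.frame` with one row per gene: `gene_id`, `gene_length`,
#'   `ta_full`, `ta_effective`, `insertions_full`, `insertions_effective`,
#'   `reads_effective`, `gii`, `read_density`, `defined` (FALSE when
#'   `ta_full == 0`, in which case `gii`/`read_density` are `NA`). The
#'   `constant_k` actually used is attached as an attribute.
#' @export
compute_gene_stats <- function(library, genes, ta_index, constant_k = 72,
                               excluded_fraction = 0.10,
                               collapse_orientation = TRUE,
                               reads_in_effective_region = TRUE) {
  ta_full <- ta_counts_per_gene(ta_index, genes, "full")
  ta_eff <- ta_counts_per_gene(ta_index, genes, "effective", excluded_fraction)
  eff <- effective_region(genes, excluded_fraction)

  s <- library$sites
  # per chromosome: sorted positions with (collapsed) counts
  by_chr <- split(s[, c("position", "read_count")], s$chromosome)
  by_chr <- lapply(by_chr, function(d) {
    if (collapse_orientation) {
      d <- stats::aggregate(list(read_count = d$read_count),
                            by = list(position = d$position), FUN = sum)
    }
    d[order(d$position), , drop = FALSE]
  })

  count_range <- function(chr, s1, e1) {
    d <- by_chr[[chr]]
    if (is.null(d) || is.na(s1) || is.na(e1)) return(c(0L, 0L))
    i1 <- findInterval(s1 - 1L, d$position) + 1L
    i2 <- findInterval(e1, d$position)
    if (i2 < i1) return(c(0L, 0L))
    c(i2 - i1 + 1L, sum(d$read_count[i1:i2]))
  }

  n <- nrow(genes)
  ins_full <- integer(n); ins_eff <- integer(n); reads_eff <- numeric(n)
  for (i in seq_len(n)) {
    cf <- count_range(genes$chromosome[i], genes$start[i], genes$end[i])
    ce <- count_range(eff$chromosome[i], eff$start[i], eff$end[i])
    ins_full[i] <- cf[1]
    ins_eff[i] <- ce[1]
    reads_eff[i] <- if (reads_in_effective_region) ce[2] else cf[2]
  }

  if (is.null(constant_k)) constant_k <- mean(ta_full)
  defined <- ta_full > 0L
  gii <- ifelse(defined, ins_eff * constant_k / ta_full, NA_real_)
  read_density <- ifelse(defined, reads_eff / ta_full, NA_real_)

  out <- data.frame(gene_id = genes$gene_id,
                    gene_length = genes$end - genes$start + 1L,
                    ta_full = as.integer(ta_full),
                    ta_effective = as.integer(ta_eff),
                    insertions_full = ins_full,
                    insertions_effective = ins_eff,
                    reads_effective = reads_eff,
                    gii = gii,
                    read_density = read_density,
                    defined = defined,
                    stringsAsFactors = FALSE)
  attr(out, "constant_k") <- constant_k
  out
}

#' Write per-gene insertion statistics as TSV
#'
#' @param stats Table from [compute_gene_stats()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# locate containing gene index for each (chromosome, position); NA if IGR.
# genes must be sorted by (chromosome, start) and non-overlapping.
.containing_gene <- function(chrom, pos, genes) {
  out <- rep(NA_integer_, length(pos))
  for (chr in unique(chrom)) {
    gsel <- which(genes$chromosome == chr)
    psel <- which(chrom == chr)
    if (length(gsel) == 0L) next
    k <- findInterval(pos[psel], genes$start[gsel])
    inside <- k >= 1L & pos[psel] <= genes$end[gsel][pmax(k, 1L)]
    out[psel[inside]] <- gsel[k[inside]]
  }
  out
}

#' Fractions of insertions in exons, introns and intergenic regions
#'
#' Every insertion site is assigned to exactly one region class: inside a
#' gene's exon, inside a gene but in an intron gap, or intergenic (IGR).
#'
#' @param library An `insertion_library`.
#' @param genes A `gene_annotation` table (non-overlapping genes).
#' @return Named numeric vector `c(exon =, intron =, igr =)` summing to 1,
#'   with attribute `counts`.
#' @export
region_fractions <- function(library, genes) {
  s <- library$sites
  if (nrow(s) == 0L) stop("empty insertion library")
  gi <- .containing_gene(s$chromosome, s$position, genes)
  in_exon <- rep(FALSE, nrow(s))
  hit <- which(!is.na(gi))
  for (i in hit) {
    ex <- genes$exons[[gi[i]]]
    in_exon[i] <- any(s$position[i] >= ex[, 1] & s$position[i] <= ex[, 2])
  }
  counts <- c(exon = sum(in_exon),
              intron = sum(!is.na(gi)) - sum(in_exon),
              igr = sum(is.na(gi)))
  structure(counts / nrow(s), counts = counts)
}

#' Positional insertion profile along ORFs and their flanks
#'
#' Each gene is divided into `n_bins` equal segments (5' to 3' in gene
#' orientation); an insertion at gene-relative offset `d` (1-based) in a
#' gene of length `L` falls in bin `ceiling(d * n_bins / L)`. Intergenic
#' insertions are assigned to the nearer end of the nearest gene (exact
#' ties going to the gene 5'-ward in genome coordinates) and binned
#' upstream or downstream by distance in `flank_bin_bp` steps out to
#' `flank_bp`.
#'
#' @param library An `insertion_library`.
#' @param genes A `gene_annotation` table.
#' @param n_bins Number of ORF segments (default 25).
#' @param flank_bp Flank extent covered (default 1000 bp).
#' @param flank_bin_bp Flank bin width (default 100 bp).
#' @return A `segment_profile` object: list with `orf_bins` (length
#'   `n_bins`), `upstream_bins`, `downstream_bins`, and
#'   `n_beyond_flank`.
#' @export
segment_profile <- function(library, genes, n_bins = 25L,
                            flank_bp = 1000L, flank_bin_bp = 100L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  s <- library$sites
  gi <- .containing_gene(s$chromosome, s$position, genes)
  n_flank_bins <- as.integer(ceiling(flank_bp / flank_bin_bp))

  orf_bins <- integer(n_bins)
  up <- integer(n_flank_bins)
  down <- integer(n_flank_bins)
  beyond <- 0L

  inside <- which(!is.na(gi))
  if (length(inside)) {
    g <- gi[inside]
    L <- genes$end[g] - genes$start[g] + 1L
    d <- ifelse(genes$strand[g] == "+",
                s$position[inside] - genes$start[g] + 1L,
                genes$end[g] - s$position[inside] + 1L)
    b <- pmin(pmax(ceiling(d * n_bins / L), 1L), n_bins)
    tb <- tabulate(b, nbins = n_bins)
    orf_bins <- orf_bins + tb
  }

  igr <- which(is.na(gi))
  for (i in igr) {
    chr <- s$chromosome[i]; p <- s$position[i]
    gsel <- which(genes$chromosome == chr)
    if (length(gsel) == 0L) { beyond <- beyond + 1L; next }
    k <- findInterval(p, genes$start[gsel])
    prev <- if (k >= 1L) gsel[k] else NA_integer_
    nxt <- if (k < length(gsel)) gsel[k + 1L] else NA_integer_
    dprev <- if (is.na(prev)) Inf else p - genes$end[prev]
    dnxt <- if (is.na(nxt)) Inf else genes$start[nxt] - p
    if (is.infinite(dprev) && is.infinite(dnxt)) { beyond <- beyond + 1L; next }
    # nearer gene wins; tie -> 5'-ward gene in coordinates (prev)
    if (dprev <= dnxt) { gene <- prev; dist <- dprev; side <- "right" }
    else { gene <- nxt; dist <- dnxt; side <- "left" }
    if (dist > flank_bp) { beyond <- beyond + 1L; next }
    # left of a '+' gene or right of a '-' gene is upstream of that gene
    upstream <- (side == "left") == (genes$strand[gene] == "+")
    b <- min(max(ceiling(dist / flank_bin_bp), 1L), n_flank_bins)
    if (upstream) up[b] <- up[b] + 1L else down[b] <- down[b] + 1L
  }

  structure(list(orf_bins = orf_bins, upstream_bins = up,
                 downstream_bins = down, n_beyond_flank = beyond,
                 n_bins = n_bins, flank_bp = flank_bp,
                 flank_bin_bp = flank_bin_bp),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("Segment profile: ", sum(x$orf_bins), " ORF insertions in ",
      x$n_bins, " bins; ", sum(x$upstream_bins), " upstream / ",
      sum(x$downstream_bins), " downstream flank insertions (",
      x$n_beyond_flank, " beyond ", x$flank_bp, " bp)\n", sep = "")
  invisible(x)
}

#' Plot an ORF/flank insertion profile
#'
#' @param x A `segment_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.segment_profile <- function(x, ...) {
  vals <- c(rev(x$upstream_bins), x$orf_bins, x$downstream_bins)
  cols <- c(rep("grey60", length(x$upstream_bins)),
            rep("steelblue", x$n_bins),
            rep("grey60", length(x$downstream_bins)))
  graphics::barplot(vals, col = cols, border = NA,
                    xlab = "upstream | ORF segments | downstream",
                    ylab = "insertions", ...)
  invisible(x)
}

#' Nucleotide composition around insertion sites
#'
#' Builds a position frequency matrix of the `flank_k` bases on either
#' side of the target TA dinucleotide across unique insertion sites, in
#' insertion orientation: reverse-orientation sites contribute the
#' reverse complement of their genomic context, so transposon-specific
#' sequence preference is visible regardless of strand. Sites whose flank
#' would run off the chromosome (or covers an `N`) are skipped and
#' counted.
#'
#' @param library An `insertion_library`.
#' @param genome A genome from [load_genome()].
#' @param flank_k Number of flanking positions on each side (default 6).
#' @return A 4 x (2 `flank_k` + 2) matrix of class `logo_matrix`: rows
#'   `A,C,G,T`, columns `-k..-1, T, A, +1..+k` (the central two columns
#'   are the TA itself, frequency 1 by construction). Attributes
#'   `n_sites` (used) and `n_skipped`.
#' @export
logo_matrix <- function(library, genome, flank_k = 6L) {
  s <- library$sites
  if (nrow(s) == 0L) stop("no insertion sites to build a logo from")
  k <- as.integer(flank_k)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- s$position - k >= 1L & s$position + 1L + k <= lens[s$chromosome]
  ctx <- character(sum(ok))
  j <- 0L
  for (chr in unique(s$chromosome[ok])) {
    sel <- which(ok & s$chromosome == chr)
    seqchr <- as.character(genome[[chr]])
    cc <- substring(seqchr, s$position[sel] - k, s$position[sel] + 1L + k)
    rev_sel <- s$orientation[sel] == "reverse"
    if (any(rev_sel)) {
      cc[rev_sel] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(cc[rev_sel])))
    }
    ctx[j + seq_along(sel)] <- cc
    j <- j + length(sel)
  }
  has_n <- grepl("N", ctx, fixed = TRUE)
  ctx <- ctx[!has_n]
  n_skipped <- sum(!ok) + sum(has_n)
  if (length(ctx) == 0L) stop("no usable insertion sites (all near edges or N)")

  w <- 2L * k + 2L
  mat <- matrix(unlist(strsplit(ctx, "", fixed = TRUE), use.names = FALSE),
                ncol = w, byrow = TRUE)
  freq <- vapply(seq_len(w), function(col) {
    tab <- table(factor(mat[, col], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(ctx)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  colnames(freq) <- c(as.character(-k:-1), "T", "A", as.character(1:k))
  colnames(freq)[(k + 3L):w] <- paste0("+", 1:k)
  structure(freq, n_sites = length(ctx), n_skipped = n_skipped,
            class = c("logo_matrix", class(freq)))
}

#' Write a logo matrix as TSV
#'
#' @param logo A `logo_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(logo, path) {
  df <- data.frame(base = rownames(logo), unclass(logo), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative unique-site saturation curve
#'
#' Pools libraries one at a time (in the given order) and reports the
#' cumulative count of unique insertion sites; a plateau indicates the
#' combined library is approaching saturation. Optionally repeats over
#' random orderings to report a mean and standard deviation per step.
#'
#' @param libraries List of `insertion_library` objects, in pooling order.
#' @param n_orderings If > 0, also evaluate this many random orderings.
#' @param seed RNG seed for the random orderings.
#' @param stranded Count forward/reverse at the same TA separately
#'   (default `TRUE`).
#' @return List with `cumulative` (counts for the given order), and when
#'   requested `mean` and `sd` across random orderings.
#' @export
saturation_curve <- function(libraries, n_orderings = 0L, seed = 1L,
                             stranded = TRUE) {
  stopifnot(length(libraries) >= 1L)
  keys <- lapply(libraries, function(l) {
    s <- l$sites
    if (stranded) paste(s$chromosome, s$position, s$orientation)
    else unique(paste(s$chromosome, s$position))
  })
  cum_for <- function(ord) {
    seen <- character(0)
    out <- integer(length(ord))
    for (i in seq_along(ord)) {
      seen <- unique(c(seen, keys[[ord[i]]]))
      out[i] <- length(seen)
    }
    out
  }
  res <- list(cumulative = cum_for(seq_along(keys)))
  if (n_orderings > 0L) {
    set.seed(seed)
    curves <- vapply(seq_len(n_orderings),
                     function(i) cum_for(sample(seq_along(keys))),
                     integer(length(keys)))
    res$mean <- rowMeans(curves)
    res$sd <- apply(curves, 1L, stats::sd)
  }
  res
}

#' Pairwise overlap of two insertion libraries
#'
#' @param lib_a,lib_b `insertion_library` objects over the same genome.
#' @param stranded Count forward/reverse at the same TA separately.
#' @return Named integer vector `c(only_a =, shared =, only_b =)`
#'   partitioning the union of the two site sets.
#' @export
venn_overlap <- function(lib_a, lib_b, stranded = TRUE) {
  key <- function(l) {
    s <- l$sites
    if (stranded) paste(s$chromosome, s$position, s$orientation)
    else unique(paste(s$chromosome, s$position))
  }
  a <- key(lib_a); b <- key(lib_b)
  shared <- length(intersect(a, b))
  c(only_a = length(a) - shared, shared = shared, only_b = length(b) - shared)
}

#' Squared correlations supporting the TA-count normalization choice
#'
#' Computes the squared Pearson correlation, across genes, between
#' full-gene insertion count and (a) the gene's TA-site count and (b) the
#' gene's length. A higher TA correlation supports normalizing insertion
#' counts by TA sites rather than by length.
#'
#' @param stats Table from [compute_gene_stats()].
#' @return Named numeric vector
#'   `c(r2_ta_vs_insertions =, r2_length_vs_insertions =)`; `NA` with a
#'   warning if a variable has zero variance.
#' @export
normalization_r2 <- function(stats) {
  if (nrow(stats) < 3L) stop("need at least 3 genes")
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  out <- c(r2_ta_vs_insertions = r2(stats$ta_full, stats$insertions_full),
           r2_length_vs_insertions = r2(stats$gene_length,
                                        stats$insertions_full))
  if (anyNA(out)) {
    warning("zero variance; correlation undefined for: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Insertion density per kilobase of genome
#'
#' @param library An `insertion_library`.
#' @param genome A genome from [load_genome()].
#' @param stranded Count forward/reverse at the same TA separately.
#' @return Unique insertions per kb (numeric scalar).
#' @export
density_per_kb <- function(library, genome, stranded = TRUE) {
  n_sites(library, stranded) / (sum(Biostrings::width(genome)) / 1000)
}

#' Density plot of GII by gene label
#'
#' Overlays kernel density estimates of the Gene Insertion Index for
#' essential (red) and non-essential (blue) genes, the visual check that
#' the two classes separate.
#'
#' @param stats Table from [compute_gene_stats()].
#' @param labels `data.frame` with columns `gene_id`,
#'   `label` (`"essential"`/`"non_essential"`).
#' @param ... Passed to [plot()].
#' @export
plot_gii_density <- function(stats, labels, ...) {
  m <- merge(stats[stats$defined, c("gene_id", "gii")], labels, by = "gene_id")
  de <- stats::density(m$gii[m$label == "essential"])
  dn <- stats::density(m$gii[m$label == "non_essential"])
  plot(dn, col = "blue", main = "GII by essentiality label",
       xlab = "Gene Insertion Index", ylim = range(0, de$y, dn$y), ...)
  graphics::lines(de, col = "red")
  graphics::legend("topright", legend = c("essential", "non-essential"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(list(essential = de, non_essential = dn))
}
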