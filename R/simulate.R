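#' Configuration for synthetic Tn-seq data
#'
#' Collects every knob of the simulator. The defaults describe a
#' desk-scale surrogate of a compact yeast Tn-seq experiment: a 2 Mb
#' genome in two chromosomes at 41% GC, 2,000 non-overlapping genes
#' occupying ~80% of the genome (~20% intergenic), 20% of genes
#' essential, 40,000 unique insertions drawn with intergenic enrichment
#' and strong suppression inside the 5'-most 90% of essential genes
#' (insertions remain tolerated in the 3'-terminal
#' `edge_tolerance_fraction`), and log-normal per-site read counts.
#'
#' @param seed Base RNG seed; stage `k` of the simulator uses
#'   `seed + k` so stages are individually reproducible.
#' @param chromosome_lengths Integer vector of chromosome lengths (bp).
#' @param gc_content Genome GC fraction.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Min/max gene length (uniform; bp).
#' @param intron_fraction Fraction of genes given a single intron.
#' @param fraction_essential Fraction of genes labelled essential.
#' @param n_insertions Unique (site, orientation) insertions to draw.
#' @param igr_enrichment Multiplicative weight on intergenic TA sites.
#' @param essential_body_suppression Multiplicative weight (in `[0,1]`) on
#'   TA sites inside the effective region of essential genes; 0 forbids
#'   such insertions entirely.
#' @param edge_tolerance_fraction 3'-end fraction of essential genes where
#'   insertions stay unpenalized (default 0.10, matching the analysis-side
#'   exclusion).
#' @param sequence_bias Named list mapping flank position (e.g. `"-3"`,
#'   `"+5"`) to a named numeric vector of per-base weight multipliers,
#'   applied in insertion orientation.
#' @param read_count Per-site read-count law: `list(distribution =
#'   "lognormal", meanlog =, sdlog =)` or `list(distribution =
#'   "geometric", prob =)`; counts are rounded up to at least 1. Use
#'   `list(distribution = "constant", value = 1)` for unit counts.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosome_lengths = c(1000000L, 1000000L),
                              gc_content = 0.41,
                              n_genes = 2000L,
                              gene_length_range = c(300L, 1300L),
                              intron_fraction = 0.02,
                              fraction_essential = 0.20,
                              n_insertions = 40000L,
                              igr_enrichment = 3.5,
                              essential_body_suppression = 0.05,
                              edge_tolerance_fraction = 0.10,
                              sequence_bias = list(),
                              read_count = list(distribution = "lognormal",
                                                meanlog = 0, sdlog = 1.2)) {
  stopifnot(all(chromosome_lengths > 0),
            gc_content >= 0, gc_content <= 1,
            n_genes >= 0,
            length(gene_length_range) == 2L,
            gene_length_range[1] >= 2L,
            gene_length_range[1] <= gene_length_range[2],
            intron_fraction >= 0, intron_fraction <= 1,
            fraction_essential >= 0, fraction_essential <= 1,
            n_insertions >= 0,
            igr_enrichment > 0,
            essential_body_suppression >= 0,
            essential_body_suppression <= 1,
            edge_tolerance_fraction >= 0, edge_tolerance_fraction < 1)
  if (length(sequence_bias) > 0) {
    offs <- suppressWarnings(as.integer(names(sequence_bias)))
    if (any(is.na(offs)) || any(offs == 0L)) {
      stop("sequence_bias names must be nonzero flank offsets like '-3', '5'")
    }
    if (any(unlist(sequence_bias) <= 0)) stop("bias weights must be positive")
  }
  structure(list(seed = as.integer(seed),
                 chromosome_lengths = as.integer(chromosome_lengths),
                 gc_content = gc_content,
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 intron_fraction = intron_fraction,
                 fraction_essential = fraction_essential,
                 n_insertions = as.integer(n_insertions),
                 igr_enrichment = igr_enrichment,
                 essential_body_suppression = essential_body_suppression,
                 edge_tolerance_fraction = edge_tolerance_fraction,
                 sequence_bias = sequence_bias,
                 read_count = read_count),
            class = "simulation_config")
}

# largest-remainder allocation of n items proportional to w
.allocate <- function(n, w) {
  ideal <- n * w / sum(w)
  base <- floor(ideal)
  extra <- n - sum(base)
  if (extra > 0) {
    give <- order(ideal - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Simulate a genome with non-overlapping annotated genes
#'
#' Draws i.i.d. nucleotides at the configured GC content and places
#' `n_genes` non-overlapping genes (uniform lengths, random strands,
#' occasional single-intron structure) with randomly sized intergenic
#' gaps, allocating genes to chromosomes proportional to length.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (a `DNAStringSet`) and `genes` (a
#'   `gene_annotation` table).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  lens <- config$chromosome_lengths
  chrom_names <- paste0("chr", seq_along(lens))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chrom_names))

  if (config$n_genes == 0L) {
    genes <- data.frame(gene_id = character(0), chromosome = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    genes$exons <- list()
    class(genes) <- c("gene_annotation", "data.frame")
    return(list(genome = genome, genes = genes))
  }

  glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 config$n_genes, replace = TRUE)
  n_per_chrom <- .allocate(config$n_genes, lens)
  gi <- 0L
  rows <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ng <- n_per_chrom[ci]
    if (ng == 0L) next
    gl <- glen[gi + seq_len(ng)]
    total_gap <- lens[ci] - sum(gl)
    if (total_gap < 0L) {
      stop("infeasible packing: genes exceed chromosome ", chrom_names[ci])
    }
    # random gap sizes (ng + 1 slots) via normalized exponentials
    gprop <- stats::rexp(ng + 1L)
    gaps <- .allocate(total_gap, gprop)
    starts <- cumsum(gaps[seq_len(ng)] + c(0L, gl[-ng])) + 1L
    rows[[ci]] <- data.frame(
      gene_id = sprintf("gene_%04d", gi + seq_len(ng)),
      chromosome = chrom_names[ci],
      start = as.integer(starts),
      end = as.integer(starts + gl - 1L),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
    gi <- gi + ng
  }
  genes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  exons <- vector("list", nrow(genes))
  has_intron <- stats::runif(nrow(genes)) < config$intron_fraction &
    (genes$end - genes$start + 1L) >= 300L
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    if (has_intron[i]) {
      L <- e - s + 1L
      il <- max(20L, as.integer(round(0.1 * L)))
      i1 <- s + as.integer(floor((L - il) / 2))
      exons[[i]] <- cbind(start = c(s, i1 + il),
                          end = c(i1 - 1L, e))
    } else {
      exons[[i]] <- cbind(start = s, end = e)
    }
  }
  genes$exons <- exons
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_annotation", "data.frame")
  list(genome = genome, genes = genes)
}

#' Assign essential / non-essential ground-truth labels
#'
#' @param genes A `gene_annotation` table.
#' @param fraction_essential Fraction labelled essential (rounded).
#' @param seed RNG seed.
#' @return `data.frame` with `gene_id`, `label`.
#' @export
simulate_gene_labels <- function(genes, fraction_essential = 0.20, seed = 2L) {
  set.seed(seed)
  n_ess <- round(nrow(genes) * fraction_essential)
  ess <- sample(genes$gene_id, n_ess)
  data.frame(gene_id = genes$gene_id,
             label = ifelse(genes$gene_id %in% ess,
                            "essential", "non_essential"),
             stringsAsFactors = FALSE)
}

# per-candidate sequence-context bias multiplier, in insertion orientation
.context_bias <- function(genome, chrom, pos, orientation, bias) {
  w <- rep(1, length(pos))
  if (length(bias) == 0L) return(w)
  offs <- as.integer(names(bias))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    seqchr <- as.character(genome[[chr]])
    L <- lens[[chr]]
    for (k in seq_along(offs)) {
      off <- offs[k]
      wt <- bias[[k]]
      # forward orientation: offset -j is j bases 5' of the T (pos - j),
      # offset +j is j bases 3' of the A (pos + 1 + j); reverse orientation
      # mirrors through the TA and complements.
      fw <- orientation[sel] == "forward"
      coord <- integer(length(sel))
      coord[fw] <- if (off < 0L) pos[sel][fw] + off else pos[sel][fw] + 1L + off
      coord[!fw] <- if (off < 0L) pos[sel][!fw] + 1L - off else
        pos[sel][!fw] - off
      valid <- coord >= 1L & coord <= L
      base <- rep(NA_character_, length(sel))
      base[valid] <- substring(seqchr, coord[valid], coord[valid])
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      base[!fw & valid] <- comp[base[!fw & valid]]
      mult <- wt[base]
      mult[is.na(mult)] <- 1
      w[sel] <- w[sel] * mult
    }
  }
  w
}

#' Simulate an insertion library with configurable bias
#'
#' Every (TA site, orientation) pair is a candidate insertion with weight
#' `1 x igr_enrichment (if intergenic) x essential_body_suppression (if in
#' an essential gene's effective region) x sequence-context multipliers`;
#' `n_insertions` candidates are drawn without replacement proportional to
#' weight (so a site is hit at most once per orientation), and read counts
#' are drawn from the configured distribution.
#'
#' @param genome A `DNAStringSet` from [simulate_genome()].
#' @param genes The matching `gene_annotation`.
#' @param labels Ground-truth labels from [simulate_gene_labels()].
#' @param config A [simulation_config()].
#' @param label Library label.
#' @return List with `library` (an `insertion_library`) and `truth`
#'   (per-candidate weights, labels, and the realized draw).
#' @export
simulate_insertions <- function(genome, genes, labels, config,
                                label = "simulated") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  ta <- index_ta_sites(genome)
  chrom <- rep(names(ta), lengths(ta))
  pos <- unlist(ta, use.names = FALSE)
  if (length(pos) == 0L) stop("genome has no TA sites")

  gi <- .containing_gene(chrom, pos, genes)
  w_site <- rep(1, length(pos))
  w_site[is.na(gi)] <- config$igr_enrichment
  if (nrow(genes) > 0L) {
    eff <- effective_region(genes, config$edge_tolerance_fraction)
    essential <- genes$gene_id %in% labels$gene_id[labels$label == "essential"]
    ing <- which(!is.na(gi))
    cond <- essential[gi[ing]] & !is.na(eff$start[gi[ing]]) &
      pos[ing] >= eff$start[gi[ing]] & pos[ing] <= eff$end[gi[ing]]
    in_eff <- ing[which(cond)]
    w_site[in_eff] <- w_site[in_eff] * config$essential_body_suppression
  }

  # candidate universe: both orientations of every TA site
  cand <- data.frame(chromosome = rep(chrom, 2L), position = rep(pos, 2L),
                     orientation = rep(c("forward", "reverse"),
                                       each = length(pos)),
                     stringsAsFactors = FALSE)
  w <- rep(w_site, 2L) * .context_bias(genome, cand$chromosome, cand$position,
                                       cand$orientation, config$sequence_bias)
  available <- sum(w > 0)
  if (config$n_insertions > available) {
    stop("n_insertions (", config$n_insertions,
         ") exceeds available weighted candidates (", available, ")")
  }

  # weighted sampling without replacement via exponential race:
  # drawing the n smallest rexp(1)/w_i is equivalent to sequential
  # draws proportional to w
  key <- stats::rexp(length(w)) / w
  take <- order(key)[seq_len(config$n_insertions)]
  sites <- cand[take, , drop = FALSE]

  rc <- config$read_count
  n <- nrow(sites)
  sites$read_count <- switch(
    rc$distribution,
    lognormal = pmax(1L, as.integer(ceiling(stats::rlnorm(n, rc$meanlog,
                                                          rc$sdlog)))),
    geometric = stats::rgeom(n, rc$prob) + 1L,
    constant = rep(as.integer(rc$value), n),
    stop("unknown read_count distribution: ", rc$distribution))

  lib <- insertion_library(sites, label = label, ta_index = ta)
  truth <- list(labels = labels,
                candidates = cbind(cand, weight = w),
                realized = lib$sites,
                config = config)
  class(truth) <- "synthetic_truth"
  list(library = lib, truth = truth)
}

#' Simulate transposon-genome junction reads
#'
#' Emits, for every insertion site and every one of its reads, a read of
#' the form `transposon_terminus + genomic fragment + adapter` truncated
#' to `read_length`, where the genomic fragment starts at the TA's T in
#' insertion orientation and has uniform random length within the spec's
#' fragment window. This is the inverse of [trim_junction_reads()] /
#' [call_insertion_sites()]: at zero error rate the pipeline recovers
#' every uniquely mappable site.
#'
#' @param library An `insertion_library`.
#' @param genome The matching genome.
#' @param spec A [junction_read_spec()].
#' @param read_length Total read length (must exceed the terminus).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed RNG seed.
#' @param fastq_path If non-`NULL`, write the reads as FASTQ (Phred+33,
#'   constant quality) to this path.
#' @return Invisibly, a `data.frame` with `id`, `sequence` of all reads.
#' @export
simulate_junction_reads <- function(library, genome, spec,
                                    read_length = 100L, error_rate = 0,
                                    seed = 3L, fastq_path = NULL) {
  stopifnot(inherits(spec, "junction_read_spec"))
  if (read_length <= nchar(spec$transposon_terminus)) {
    stop("read_length must exceed the transposon terminus length")
  }
  set.seed(seed)
  s <- library$sites
  idx <- rep(seq_len(nrow(s)), s$read_count)
  n <- length(idx)
  flen <- sample(seq(spec$min_fragment_len, spec$max_fragment_len),
                 n, replace = TRUE)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))

  frags <- character(n)
  for (chr in unique(s$chromosome)) {
    sel <- which(s$chromosome[idx] == chr)
    seqchr <- as.character(genome[[chr]])
    p <- s$position[idx[sel]]
    fw <- s$orientation[idx[sel]] == "forward"
    fl <- flen[sel]
    # clamp fragments at chromosome ends
    fl[fw] <- pmin(fl[fw], lens[[chr]] - p[fw] + 1L)
    fl[!fw] <- pmin(fl[!fw], p[!fw] + 1L)
    f <- character(length(sel))
    f[fw] <- substring(seqchr, p[fw], p[fw] + fl[fw] - 1L)
    if (any(!fw)) {
      raw <- substring(seqchr, p[!fw] + 2L - fl[!fw], p[!fw] + 1L)
      f[!fw] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(raw)))
    }
    frags[sel] <- f
  }

  reads <- substr(paste0(spec$transposon_terminus, frags, spec$adapter_tail),
                  1L, read_length)
  if (error_rate > 0) {
    rl <- nchar(reads)
    n_err <- stats::rbinom(n, rl, error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample(rl[i], n_err[i])
      for (a in at) {
        old <- substr(reads[i], a, a)
        substr(reads[i], a, a) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
  }
  ids <- sprintf("read_%07d", seq_len(n))
  out <- data.frame(id = ids, sequence = reads, stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) {
    x <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, fastq_path, format = "fastq", qualities = q)
  }
  invisible(out)
}

#' Simulate labelled (GII, read density) training features
#'
#' Draws per-gene features from a two-component mixture mimicking the
#' observed separation in real labelled sets: essential genes' GII
#' concentrates near 0 (exponential), non-essential genes' GII around a
#' mode near 3.5 (truncated normal); read density tracks GII with
#' multiplicative noise. Component overlap is tuned so a held-out
#' classifier accuracy in the mid-90% range is expected.
#'
#' @param n_essential,n_nonessential Class sizes (defaults 161 / 171,
#'   a typical labelled-set size for a compact yeast genome).
#' @param essential_gii_mean Mean of the essential (exponential) GII
#'   component (default 0.45).
#' @param nonessential_gii_mode,nonessential_gii_sd Mode and sd of the
#'   non-essential (truncated-normal) component (defaults 3.5, 1.1).
#' @param density_scale Mean reads per TA site for a fully non-essential
#'   gene (default 5).
#' @param seed RNG seed.
#' @return `data.frame` with `gene_id`, `label`, `gii`, `read_density` --
#'   directly usable as both the stats and labels arguments of
#'   [fit_nep_model()].
#' @export
simulate_training_features <- function(n_essential = 161L,
                                       n_nonessential = 171L,
                                       essential_gii_mean = 0.45,
                                       nonessential_gii_mode = 3.5,
                                       nonessential_gii_sd = 1.1,
                                       density_scale = 5,
                                       seed = 4L) {
  set.seed(seed)
  g_ess <- stats::rexp(n_essential, rate = 1 / essential_gii_mean)
  g_non <- stats::rnorm(n_nonessential, nonessential_gii_mode,
                        nonessential_gii_sd)
  while (any(g_non < 0)) {
    g_non[g_non < 0] <- stats::rnorm(sum(g_non < 0), nonessential_gii_mode,
                                     nonessential_gii_sd)
  }
  gii <- c(g_ess, g_non)
  n <- length(gii)
  read_density <- gii * density_scale *
    exp(stats::rnorm(n, 0, 0.5)) / nonessential_gii_mode
  data.frame(gene_id = sprintf("sim_%04d", seq_len(n)),
             label = rep(c("essential", "non_essential"),
                         c(n_essential, n_nonessential)),
             gii = gii, read_density = read_density,
             stringsAsFactors = FALSE)
}

#' Write simulated genome / annotation / truth / config to disk
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @param genes A `gene_annotation` table.
#' @rdname write_genome_fasta
#' @export
write_annotation_gff3 <- function(genes, path) {
  n_ex <- vapply(genes$exons, nrow, integer(1))
  ex_all <- do.call(rbind, genes$exons)
  gidx <- rep(seq_len(nrow(genes)), n_ex)
  feat <- data.frame(
    chromosome = c(genes$chromosome, genes$chromosome[gidx]),
    start = c(genes$start, ex_all[, 1]),
    end = c(genes$end, ex_all[, 2]),
    strand = c(genes$strand, genes$strand[gidx]),
    type = c(rep("gene", nrow(genes)), rep("exon", length(gidx))),
    ID = c(genes$gene_id,
           paste0(genes$gene_id[gidx], ".exon",
                  unlist(lapply(n_ex, seq_len)))),
    stringsAsFactors = FALSE)
  parent <- c(rep(list(character(0)), nrow(genes)),
              as.list(genes$gene_id[gidx]))
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chromosome,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand,
    type = feat$type, ID = feat$ID,
    Parent = methods::as(parent, "CharacterList"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @param truth A `synthetic_truth` (realized sites and labels are
#'   written; candidate weights omitted for size).
#' @rdname write_genome_fasta
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$realized, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param config A `simulation_config`.
#' @rdname write_genome_fasta
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
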