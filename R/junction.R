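#' Junction-read trimming specification
#'
#' Describes how transposon-genome junction reads are structured: the
#' transposon terminus expected at the 5' end of every informative read,
#' the sequencing adapter expected at the 3' end, the per-match mismatch
#' tolerance, and the fragment length window retained for mapping.
#' Defaults correspond to a TcBuster-style library (16 bp terminus,
#' 10 bp adapter, 5% mismatch rate, fragments of 16-50 bp).
#'
#' @param transposon_terminus Nucleotide string expected as read prefix.
#' @param adapter_tail Nucleotide string expected as read suffix.
#' @param mismatch_rate Fraction of mismatches tolerated per match
#'   (allowance is `ceiling(mismatch_rate * matched_length)`).
#' @param min_fragment_len Fragments shorter than this after trimming are
#'   discarded.
#' @param max_fragment_len Fragments are truncated to this length.
#' @return A `junction_read_spec` object.
#' @export
junction_read_spec <- function(transposon_terminus = "AATATCTCGACAAAGG",
                               adapter_tail = "ATACCACGAC",
                               mismatch_rate = 0.05,
                               min_fragment_len = 16L,
                               max_fragment_len = 50L) {
  transposon_terminus <- toupper(transposon_terminus)
  adapter_tail <- toupper(adapter_tail)
  if (nchar(transposon_terminus) == 0L) stop("transposon_terminus must be non-empty")
  if (!grepl("^[ACGTN]*$", transposon_terminus) || !grepl("^[ACGTN]*$", adapter_tail)) {
    stop("terminus/adapter must be nucleotide strings (A,C,G,T,N)")
  }
  if (!is.numeric(mismatch_rate) || mismatch_rate < 0 || mismatch_rate >= 0.5) {
    stop("mismatch_rate must be in [0, 0.5)")
  }
  min_fragment_len <- as.integer(min_fragment_len)
  max_fragment_len <- as.integer(max_fragment_len)
  if (min_fragment_len < 1L || min_fragment_len > max_fragment_len) {
    stop("need 1 <= min_fragment_len <= max_fragment_len")
  }
  structure(list(transposon_terminus = transposon_terminus,
                 adapter_tail = adapter_tail,
                 mismatch_rate = mismatch_rate,
                 min_fragment_len = min_fragment_len,
                 max_fragment_len = max_fragment_len),
            class = "junction_read_spec")
}

#' @export
print.junction_read_spec <- function(x, ...) {
  cat("Junction read spec:\n",
      "  terminus: ", x$transposon_terminus, "\n",
      "  adapter:  ", x$adapter_tail, "\n",
      "  mismatch rate: ", x$mismatch_rate,
      ", fragment length: ", x$min_fragment_len, "-", x$max_fragment_len,
      "\n", sep = "")
  invisible(x)
}

# mismatch counts between equal-width strings and a reference string
.string_mm <- function(strings, ref) {
  n <- length(strings)
  if (n == 0L) return(integer(0))
  w <- nchar(ref)
  mat <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
                ncol = w, byrow = TRUE)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  as.integer(rowSums(mat != matrix(refc, n, w, byrow = TRUE)))
}

#' Trim transposon-genome junction reads to genomic fragments
#'
#' Three passes, mirroring the usual junction-library trimming recipe:
#' (1) reads whose 5' end matches the transposon terminus (within the
#' mismatch allowance) have the terminus removed; reads without it are
#' discarded entirely; (2) any further terminus copy at the new 5' end
#' (nonspecific tandem amplification) is removed the same way; (3) the
#' 3' adapter -- possibly truncated by the read end -- is located as the
#' longest read suffix matching an adapter prefix (minimum 3 bp overlap)
#' and removed. Fragments shorter than `min_fragment_len` are then
#' discarded and the rest truncated to `max_fragment_len`.
#'
#' @param fastq Path to a FASTQ file (4-line records, Phred+33; qualities
#'   are ignored).
#' @param spec A [junction_read_spec()].
#' @return A `data.frame` with columns `id`, `sequence` (one row per
#'   retained read), with a `summary` attribute counting reads discarded
#'   at each step.
#' @export
trim_junction_reads <- function(fastq, spec) {
  stopifnot(inherits(spec, "junction_read_spec"))
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", fastq, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(reads))
  seqs <- toupper(as.character(reads))
  n_input <- length(seqs)

  term <- spec$transposon_terminus
  tl <- nchar(term)
  allow_term <- ceiling(spec$mismatch_rate * tl)

  # pass 1: require and strip the terminus prefix
  long_enough <- nchar(seqs) >= tl
  has_term <- rep(FALSE, length(seqs))
  if (any(long_enough)) {
    mm <- .string_mm(substr(seqs[long_enough], 1L, tl), term)
    has_term[long_enough] <- mm <= allow_term
  }
  n_no_terminus <- sum(!has_term)
  seqs <- substring(seqs[has_term], tl + 1L)
  ids <- ids[has_term]

  # pass 2: strip further terminus copies at the 5' end (tandem artifacts)
  n_second_terminus <- 0L
  repeat {
    long_enough <- nchar(seqs) >= tl
    again <- rep(FALSE, length(seqs))
    if (any(long_enough)) {
      mm <- .string_mm(substr(seqs[long_enough], 1L, tl), term)
      again[long_enough] <- mm <= allow_term
    }
    if (!any(again)) break
    n_second_terminus <- n_second_terminus + sum(again)
    seqs[again] <- substring(seqs[again], tl + 1L)
  }

  # pass 3: remove the 3' adapter (longest suffix matching an adapter
  # prefix wins; minimum overlap 3 bp; allowance capped below the overlap)
  ad <- spec$adapter_tail
  alen <- nchar(ad)
  if (alen > 0L && length(seqs) > 0L) {
    L <- nchar(seqs)
    cut_at <- rep(NA_integer_, length(seqs))  # first base of removed suffix
    o_hi <- min(alen, max(L))
    o_lo <- min(3L, alen)
    for (o in if (o_hi >= o_lo) seq(o_hi, o_lo, by = -1L) else integer(0)) {
      idxs <- which(is.na(cut_at) & L >= o)
      if (length(idxs) == 0L) next
      adp <- substr(ad, 1L, o)
      allow <- min(ceiling(spec$mismatch_rate * o), o - 1L)
      mm <- .string_mm(substring(seqs[idxs], L[idxs] - o + 1L, L[idxs]), adp)
      hit <- idxs[mm <= allow]
      cut_at[hit] <- L[hit] - o + 1L
    }
    trim <- !is.na(cut_at)
    seqs[trim] <- substr(seqs[trim], 1L, cut_at[trim] - 1L)
  }

  # length filter and truncation
  keep <- nchar(seqs) >= spec$min_fragment_len
  n_too_short <- sum(!keep)
  seqs <- seqs[keep]
  ids <- ids[keep]
  seqs <- substr(seqs, 1L, spec$max_fragment_len)

  out <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(input = n_input,
                            no_terminus = n_no_terminus,
                            extra_terminus_stripped = n_second_terminus,
                            too_short = n_too_short,
                            retained = nrow(out))
  out
}

#' Uniquely map genomic fragments by ungapped alignment
#'
#' Each fragment is aligned without gaps against both strands of every
#' chromosome. A fragment is retained only if exactly one location attains
#' the minimum mismatch count and that count is at most `max_mismatches`;
#' fragments tied at the best mismatch count are dropped as multi-mapped.
#'
#' @param fragments A `data.frame` with columns `id`, `sequence` (as from
#'   [trim_junction_reads()]) or a named character vector.
#' @param genome A genome from [load_genome()].
#' @param max_mismatches Maximum mismatches allowed (default 3).
#' @param method `"exhaustive"` scans every offset; `"seed"` uses an exact
#'   12-mer seed index (identical results whenever the best alignment
#'   contains a 12 bp exact stretch -- always true for 0-mismatch hits of
#'   fragments of at least 12 bp); `"auto"` picks `"seed"` for genomes
#'   over 200 kb.
#' @return A `data.frame` of alignments with columns `fragment_id`,
#'   `chromosome`, `start`, `end`, `strand`, `mismatches` (coordinates
#'   1-based inclusive on the forward strand), plus a `dropped` attribute:
#'   a `data.frame` of `fragment_id`, `reason` (`"unmapped"` or
#'   `"multi_mapped"`).
#' @export
map_fragments <- function(fragments, genome, max_mismatches = 3L,
                          method = c("auto", "exhaustive", "seed")) {
  method <- match.arg(method)
  if (is.character(fragments)) {
    fragments <- data.frame(
      id = if (is.null(names(fragments))) as.character(seq_along(fragments))
           else names(fragments),
      sequence = unname(fragments), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(fragments)))
  if (method == "auto") {
    method <- if (sum(Biostrings::width(genome)) > 200000L) "seed" else "exhaustive"
  }
  seqs <- toupper(fragments$sequence)
  uniq <- unique(seqs)
  chrom_seqs <- as.character(genome)
  res <- if (method == "seed") {
    .cpp_map_seeded(uniq, chrom_seqs, as.integer(max_mismatches))
  } else {
    .cpp_map_exhaustive(uniq, chrom_seqs, as.integer(max_mismatches))
  }
  j <- match(seqs, uniq)
  status <- res$status[j]
  ok <- status == 1L
  aln <- data.frame(
    fragment_id = fragments$id[ok],
    chromosome = names(genome)[res$chrom[j][ok]],
    start = res$start[j][ok],
    end = res$start[j][ok] + nchar(seqs[ok]) - 1L,
    strand = c("+", "-")[res$strand[j][ok] + 1L],
    mismatches = res$mismatches[j][ok],
    stringsAsFactors = FALSE)
  dropped <- data.frame(
    fragment_id = fragments$id[!ok],
    reason = c("unmapped", "", "multi_mapped")[status[!ok] + 1L],
    stringsAsFactors = FALSE)
  attr(aln, "dropped") <- dropped
  aln
}

#' Read alignments from a SAM file
#'
#' Accepts alignments produced by any external aligner in place of
#' [map_fragments()]. Only mapped records are returned; the `NM` tag is
#' used for the mismatch count when present (0 otherwise). Multi-mapper
#' filtering is assumed to have been done by the aligner.
#'
#' @param sam_path Path to a SAM file (with `@SQ` header lines).
#' @return An alignment `data.frame` as from [map_fragments()].
#' @export
read_alignments_sam <- function(sam_path) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(x$pos) & bitwAnd(x$flag, 4L) == 0L
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(x$pos))
  nm[is.na(nm)] <- 0L
  data.frame(fragment_id = x$qname[mapped],
             chromosome = as.character(x$rname)[mapped],
             start = x$pos[mapped],
             end = x$pos[mapped] + x$qwidth[mapped] - 1L,
             strand = as.character(x$strand)[mapped],
             mismatches = nm[mapped],
             stringsAsFactors = FALSE)
}

#' Construct an insertion library
#'
#' @param sites A `data.frame` with columns `chromosome`, `position`,
#'   `orientation` (`"forward"`/`"reverse"`), `read_count`.
#' @param label Library name.
#' @param ta_index Optional `ta_index`; when given, every position must be
#'   a TA site.
#' @return An `insertion_library` object.
#' @export
insertion_library <- function(sites, label = "library", ta_index = NULL) {
  req <- c("chromosome", "position", "orientation", "read_count")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  sites <- sites[, req, drop = FALSE]
  sites$position <- as.integer(sites$position)
  sites$read_count <- as.integer(sites$read_count)
  if (nrow(sites) > 0L) {
    if (!all(sites$orientation %in% c("forward", "reverse"))) {
      stop("orientation must be 'forward' or 'reverse'")
    }
    if (any(sites$read_count < 1L)) stop("read_count must be >= 1")
    key <- paste(sites$chromosome, sites$position, sites$orientation)
    if (anyDuplicated(key)) {
      stop("duplicate (chromosome, position, orientation) keys in sites")
    }
    if (!is.null(ta_index)) .validate_ta_positions(sites, ta_index)
    o <- order(sites$chromosome, sites$position, sites$orientation)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(list(label = label, sites = sites), class = "insertion_library")
}

.validate_ta_positions <- function(sites, ta_index) {
  bad <- vapply(seq_len(nrow(sites)), function(i) {
    pos <- ta_index[[sites$chromosome[i]]]
    is.null(pos) || !(sites$position[i] %in% pos)
  }, logical(1))
  if (any(bad)) {
    off <- utils::head(sites[bad, c("chromosome", "position")], 10L)
    stop("position(s) not in TA index: ",
         paste(off$chromosome, off$position, sep = ":", collapse = ", "),
         if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L) else "")
  }
  invisible(TRUE)
}

#' @export
print.insertion_library <- function(x, ...) {
  cat("Insertion library '", x$label, "': ", nrow(x$sites),
      " unique sites, ", sum(x$sites$read_count), " reads\n", sep = "")
  invisible(x)
}

#' Number of unique insertion sites in a library
#'
#' @param library An `insertion_library`.
#' @param stranded If `FALSE`, forward/reverse insertions at the same TA
#'   site count once.
#' @return Integer site count.
#' @export
n_sites <- function(library, stranded = TRUE) {
  s <- library$sites
  if (stranded) nrow(s)
  else length(unique(paste(s$chromosome, s$position)))
}

#' Call insertion sites from fragment alignments
#'
#' The junction-proximal end of each alignment (the 5' end of the fragment
#' in read orientation) must abut a TA dinucleotide: for a `+`-strand
#' alignment the fragment is expected to begin at the T of the TA; for a
#' `-`-strand alignment the fragment's 5' end sits at the alignment end,
#' on the reverse strand, so the TA's T is expected one base inside the
#' alignment end. A snap window tolerates small end-repair offsets: the
#' nearest TA within `snap_window` bp wins, ties going to the 5'-most
#' (smaller-coordinate) TA. Alignments with no TA in the window are
#' dropped; duplicates of (chromosome, position, orientation) collapse
#' with `read_count` equal to their multiplicity.
#'
#' @param alignments Alignment `data.frame` from [map_fragments()] or
#'   [read_alignments_sam()].
#' @param ta_index A `ta_index` from [index_ta_sites()].
#' @param label Library label.
#' @param snap_window Maximum distance (bp, default 2) between the
#'   junction-implied T position and an indexed TA.
#' @return An `insertion_library`, with attribute `n_no_ta` on its `sites`
#'   slot reporting how many alignments had no TA within the window.
#' @export
call_insertion_sites <- function(alignments, ta_index, label = "library",
                                 snap_window = 2L) {
  if (nrow(alignments) == 0L) {
    return(insertion_library(
      data.frame(chromosome = character(0), position = integer(0),
                 orientation = character(0), read_count = integer(0)),
      label = label))
  }
  t0 <- ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
  snapped <- rep(NA_integer_, nrow(alignments))
  for (chr in unique(alignments$chromosome)) {
    pos <- ta_index[[chr]]
    sel <- which(alignments$chromosome == chr)
    if (is.null(pos) || length(pos) == 0L) next
    ti <- t0[sel]
    k <- findInterval(ti, pos)
    lo <- ifelse(k >= 1L, pos[pmax(k, 1L)], NA_integer_)        # TA at or left of ti
    hi <- ifelse(k < length(pos), pos[pmin(k + 1L, length(pos))], NA_integer_)
    dlo <- abs(ti - lo)
    dhi <- abs(hi - ti)
    dlo[is.na(dlo)] <- .Machine$integer.max
    dhi[is.na(dhi)] <- .Machine$integer.max
    best <- ifelse(dlo <= dhi, lo, hi)   # tie -> smaller coordinate (5'-ward)
    bestd <- pmin(dlo, dhi)
    best[bestd > snap_window] <- NA_integer_
    snapped[sel] <- best
  }
  ok <- !is.na(snapped)
  n_no_ta <- sum(!ok)
  df <- data.frame(
    chromosome = alignments$chromosome[ok],
    position = snapped[ok],
    orientation = ifelse(alignments$strand[ok] == "+", "forward", "reverse"),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    lib <- insertion_library(cbind(df, read_count = integer(0)), label = label)
    attr(lib$sites, "n_no_ta") <- n_no_ta
    return(lib)
  }
  agg <- stats::aggregate(list(read_count = rep(1L, nrow(df))),
                          by = df[c("chromosome", "position", "orientation")],
                          FUN = sum)
  lib <- insertion_library(agg, label = label, ta_index = ta_index)
  attr(lib$sites, "n_no_ta") <- n_no_ta
  lib
}

#' Merge insertion libraries
#'
#' Union of sites keyed by (chromosome, position, orientation); read
#' counts at shared keys are summed.
#'
#' @param ... `insertion_library` objects (or a single list of them).
#' @param label Label for the merged library.
#' @param ta_index Optional `ta_index` used to validate merged positions.
#' @return An `insertion_library`.
#' @export
merge_libraries <- function(..., label = "merged", ta_index = NULL) {
  libs <- list(...)
  if (length(libs) == 1L && !inherits(libs[[1]], "insertion_library")) {
    libs <- libs[[1]]
  }
  if (length(libs) == 0L) stop("need at least one library")
  stopifnot(all(vapply(libs, inherits, logical(1), "insertion_library")))
  all_sites <- do.call(rbind, lapply(libs, function(l) l$sites))
  if (nrow(all_sites) == 0L) {
    return(insertion_library(all_sites, label = label))
  }
  agg <- stats::aggregate(
    list(read_count = all_sites$read_count),
    by = all_sites[c("chromosome", "position", "orientation")],
    FUN = sum)
  insertion_library(agg, label = label, ta_index = ta_index)
}

#' Read / write insertion-site tables
#'
#' Tab-separated files with columns `chromosome`, `position` (1-based T
#' coordinate), `orientation`, `read_count`. `read_sites_tsv()` validates
#' positions against a TA index when one is supplied; the write/read
#' round trip preserves the library exactly.
#'
#' @param path File path.
#' @param ta_index Optional `ta_index` for validation.
#' @param label Library label for the returned object.
#' @return `read_sites_tsv()`: an `insertion_library`.
#' @export
read_sites_tsv <- function(path, ta_index = NULL, label = "library") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer",
                                         "character", "integer"))
  insertion_library(df, label = label, ta_index = ta_index)
}

#' @param library An `insertion_library`.
#' @rdname read_sites_tsv
#' @return `write_sites_tsv()`: `path`, invisibly.
#' @export
write_sites_tsv <- function(library, path) {
  utils::write.table(library$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an insertion library as BED (0-based half-open)
#'
#' @param library An `insertion_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(library, path) {
  s <- library$sites
  df <- data.frame(chrom = s$chromosome,
                   start = s$position - 1L,
                   end = s$position + 1L,
                   name = paste0("ins_", seq_len(nrow(s))),
                   score = s$read_count,
                   strand = ifelse(s$orientation == "forward", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
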