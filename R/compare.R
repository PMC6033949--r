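#' Screen for condition-specific essential genes
#'
#' The two-condition screen: a gene dispensable under condition A (NEP
#' above `nonessential_cutoff_a`, e.g. glucose) but apparently required
#' under condition B (NEP below `essential_cutoff_b`, e.g. methanol) is a
#' candidate condition-specific gene. Genes excluded in either condition
#' (low TA count, marker, undefined features) are dropped from the screen
#' and listed separately.
#'
#' @param records_a,records_b `essentiality_records` from
#'   [classify_essentiality()] for the two conditions, over the same gene
#'   universe.
#' @param nonessential_cutoff_a Condition-A NEP must exceed this
#'   (default 0.9).
#' @param essential_cutoff_b Condition-B NEP must fall below this
#'   (default 0.5).
#' @param condition_a,condition_b Condition names used in the output.
#' @return `data.frame` of candidates sorted by condition-B NEP ascending:
#'   `gene_id`, `nep_a`, `nep_b`; excluded gene ids in attribute
#'   `excluded_genes`.
#' @export
condition_specific_candidates <- function(records_a, records_b,
                                          nonessential_cutoff_a = 0.9,
                                          essential_cutoff_b = 0.5,
                                          condition_a = "A",
                                          condition_b = "B") {
  .check_same_universe(records_a, records_b)
  m <- merge(records_a[, c("gene_id", "nep", "exclusion_reason")],
             records_b[, c("gene_id", "nep", "exclusion_reason")],
             by = "gene_id", suffixes = c("_a", "_b"))
  excluded <- m$exclusion_reason_a != "none" | m$exclusion_reason_b != "none"
  u <- m[!excluded, , drop = FALSE]
  sel <- u$nep_a > nonessential_cutoff_a & u$nep_b < essential_cutoff_b
  out <- u[sel, c("gene_id", "nep_a", "nep_b"), drop = FALSE]
  out <- out[order(out$nep_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- m$gene_id[excluded]
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  out
}

.check_same_universe <- function(records_a, records_b) {
  only_a <- setdiff(records_a$gene_id, records_b$gene_id)
  only_b <- setdiff(records_b$gene_id, records_a$gene_id)
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop("gene universes differ; only in A: ",
         paste(utils::head(only_a, 5L), collapse = ", "),
         if (length(only_a) > 5L) "..." else "",
         "; only in B: ",
         paste(utils::head(only_b, 5L), collapse = ", "),
         if (length(only_b) > 5L) "..." else "")
  }
  invisible(TRUE)
}

#' Full per-gene comparison of two conditions
#'
#' @param records_a,records_b `essentiality_records` over the same gene
#'   universe.
#' @return List with `genes` (per-gene `nep_a`, `nep_b`, `category_a`,
#'   `category_b`, `delta = nep_b - nep_a`) and `crosstab` (category_a x
#'   category_b counts).
#' @export
compare_report <- function(records_a, records_b) {
  .check_same_universe(records_a, records_b)
  m <- merge(records_a[, c("gene_id", "nep", "category")],
             records_b[, c("gene_id", "nep", "category")],
             by = "gene_id", suffixes = c("_a", "_b"))
  names(m) <- c("gene_id", "nep_a", "category_a", "nep_b", "category_b")
  m$delta <- m$nep_b - m$nep_a
  list(genes = m,
       crosstab = table(category_a = m$category_a,
                        category_b = m$category_b))
}
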