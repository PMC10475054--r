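#' Filter protein identifications by the acceptance criteria
#'
#' A record is accepted iff it satisfies all of: a minimum number of
#' identified peptides (default 2, inclusive), a local false discovery rate
#' strictly below `max_fdr` (default 1%), a peptide identification
#' probability of at least `peptide_prob_min` (default 95%), and a protein
#' probability clearing `protein_threshold`.  The published protein threshold
#' ("5.0%") is ambiguous next to a 95% peptide threshold, so its semantics
#' are selectable: `"as_printed"` requires `protein_prob >= protein_threshold`
#' (the literal reading) while `"complement"` requires
#' `protein_prob >= 1 - protein_threshold`.  The filter is a pure,
#' order-independent predicate.
#'
#' @param records Data frame with columns `n_peptides`, `peptide_prob`,
#'   `protein_prob`, `local_fdr` (probabilities in `[0, 1]`).
#' @param min_peptides Minimum peptide count (inclusive).
#' @param max_fdr FDR bound (exclusive).
#' @param peptide_prob_min Peptide probability bound (inclusive).
#' @param protein_threshold Protein probability threshold.
#' @param protein_rule `"as_printed"` or `"complement"`.
#' @return The accepted subset of `records`.
#' @export
#' @examples
#' tbl <- simulate_id_table(id_table_spec(5, 3, seed = 1))
#' nrow(filter_identifications(tbl))  # 5
filter_identifications <- function(records, min_peptides = 2,
                                   max_fdr = 0.01, peptide_prob_min = 0.95,
                                   protein_threshold = 0.05,
                                   protein_rule = c("as_printed",
                                                    "complement")) {
  protein_rule <- match.arg(protein_rule)
  needed <- c("n_peptides", "peptide_prob", "protein_prob", "local_fdr")
  if (!is.data.frame(records) || !all(needed %in% names(records)))
    stop("`records` needs columns ", paste(needed, collapse = ", "))
  if (nrow(records) == 0) return(records)
  for (p in c("peptide_prob", "protein_prob", "local_fdr")) {
    bad <- which(records[[p]] < 0 | records[[p]] > 1 | !is.finite(records[[p]]))
    if (length(bad))
      stop("malformed ", p, " in record(s): ",
           paste(if ("protein_id" %in% names(records))
             records$protein_id[bad] else bad, collapse = ", "))
  }
  prot_min <- if (protein_rule == "as_printed") protein_threshold
  else 1 - protein_threshold
  keep <- records$n_peptides >= min_peptides &
    records$local_fdr < max_fdr &
    records$peptide_prob >= peptide_prob_min &
    records$protein_prob >= prot_min
  records[keep, , drop = FALSE]
}

#' Filter glycopeptide identifications
#'
#' Conjunctive, inclusive thresholds on the absolute log-probability and the
#' Delta Mod localization score ("equal to or greater than"), applied as a
#' pure predicate.
#'
#' @param records Data frame with columns `log_prob_abs` and
#'   `delta_mod_score` (both `>= 0`).
#' @param min_log_prob Minimum |log prob| (inclusive, default 3).
#' @param min_delta_mod Minimum Delta Mod Score (inclusive, default 50).
#' @return The accepted subset of `records`.
#' @export
filter_glycopeptides <- function(records, min_log_prob = 3,
                                 min_delta_mod = 50) {
  needed <- c("log_prob_abs", "delta_mod_score")
  if (!is.data.frame(records) || !all(needed %in% names(records)))
    stop("`records` needs columns ", paste(needed, collapse = ", "))
  if (nrow(records) == 0) return(records)
  if (any(records$log_prob_abs < 0) || any(records$delta_mod_score < 0))
    stop("scores must be >= 0")
  records[records$log_prob_abs >= min_log_prob &
            records$delta_mod_score >= min_delta_mod, , drop = FALSE]
}

#' Per-category spectral-count composition profile
#'
#' Aggregates MS/MS spectral counts of (already filtered) identification
#' records into per-sample percent composition by functional category, and
#' per-protein percentages for top-k queries.
#'
#' @param records Filtered identification table with a `category` column and
#'   one `msms_<sample>` count column per sample (any columns matching
#'   `msms_prefix`).
#' @param msms_prefix Prefix identifying spectral-count columns.
#' @return Object of class `category_profile`: list with `percent` (matrix,
#'   samples x categories, rows summing to 100), `protein_percent` (matrix,
#'   samples x proteins) and `totals` (spectral counts per sample).
#' @export
category_profile <- function(records, msms_prefix = "msms_") {
  if (!is.data.frame(records) || !"category" %in% names(records))
    stop("`records` needs a `category` column")
  cols <- grep(paste0("^", msms_prefix), names(records), value = TRUE)
  if (!length(cols)) stop("no spectral-count columns matching prefix `",
                          msms_prefix, "`")
  if (nrow(records) == 0) stop("no records to profile")
  samples <- sub(paste0("^", msms_prefix), "", cols)
  cats <- sort(unique(records$category))
  percent <- matrix(0, length(samples), length(cats),
                    dimnames = list(samples, cats))
  prot_ids <- if ("protein_id" %in% names(records)) records$protein_id
  else as.character(seq_len(nrow(records)))
  protein_percent <- matrix(0, length(samples), nrow(records),
                            dimnames = list(samples, prot_ids))
  totals <- stats::setNames(numeric(length(samples)), samples)
  for (i in seq_along(samples)) {
    counts <- records[[cols[i]]]
    total <- sum(counts)
    if (total <= 0)
      stop("zero total spectral counts for sample `", samples[i], "`")
    totals[i] <- total
    percent[i, ] <- 100 * vapply(cats, function(cc)
      sum(counts[records$category == cc]), numeric(1)) / total
    protein_percent[i, ] <- 100 * counts / total
  }
  structure(list(percent = percent, protein_percent = protein_percent,
                 totals = totals),
            class = "category_profile")
}

#' @export
print.category_profile <- function(x, digits = 1, ...) {
  cat("Functional-category composition (% of MS/MS counts)\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Decoy-fraction FDR estimate for synthetic tables
#'
#' The simple target-decoy ratio `n_decoy / n_target`, intended only for
#' synthetic identification tables carrying planted decoys; real searches
#' come with their own local-FDR values, consumed as-is by
#' [filter_identifications()].
#'
#' @param n_decoy,n_target Decoy and target match counts.
#' @return Estimated FDR fraction.
#' @export
estimate_fdr_decoy <- function(n_decoy, n_target) {
  if (n_target <= 0) stop("n_target must be positive")
  if (n_decoy < 0) stop("n_decoy must be >= 0")
  n_decoy / n_target
}
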