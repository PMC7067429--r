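# Published recovery-bucket arithmetic. The shipped fixture
# (extdata/table3_recovery.tsv) carries the published per-isoform
# recovery buckets over six anemonefish transcriptome assemblies; these
# helpers recompute the headline counts from it, and work identically on
# bucket tables produced by tabulate_recovery() on synthetic data.

#' Read a recovery-bucket table
#'
#' @param path TSV with columns `complete`, `partial`, `missing_0`,
#'   `missing_1_2`, `missing_3p`, `total` (default: the shipped published
#'   fixture).
#' @return A data.frame; stops if any row total does not equal the sum of
#'   its missing columns.
#' @export
read_recovery_buckets <- function(path = system.file(
  "extdata", "table3_recovery.tsv", package = "prohoscan")) {
  tab <- read_report(path)
  stopifnot(all(c("complete", "partial", "missing_0", "missing_1_2",
                  "missing_3p", "total") %in% names(tab)))
  rowsum <- tab$missing_0 + tab$missing_1_2 + tab$missing_3p
  if (!all(rowsum == tab$total))
    stop("inconsistent bucket table: row totals do not match")
  tab
}

# bucket label ("0", "1", "2", "3+") -> lower bound
.bucket_floor <- function(x) as.integer(sub("\\+$", "", x))

#' Isoforms completely recovered in at least k species
#'
#' Sums the `total` column over bucket rows whose complete-recovery count
#' is at least `k`.
#'
#' @param buckets A recovery-bucket table (see [read_recovery_buckets()]).
#' @param k Minimum number of species with complete recovery.
#' @return Integer count of isoforms.
#' @export
isoforms_complete_in_at_least <- function(buckets, k = 2) {
  sum(buckets$total[.bucket_floor(buckets$complete) >= k])
}
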