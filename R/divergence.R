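# Pairwise substitution counting between aligned coding sequences and
# molecular-clock dating of gene splits against teosinte calibration points.

.UNAMBIGUOUS_BASES <- c("A", "C", "G", "T")

#' Count nucleotide differences between two aligned sequences
#'
#' Exact mismatch count over comparable positions of a given alignment
#' (no aligner is run). Comparison is case-insensitive; any position with a
#' gap or an ambiguity code (anything outside A/C/G/T) in either sequence is
#' excluded from the comparable sites.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (or `Biostrings`
#'   objects coercible with `as.character`).
#' @return A list of class `aligned_pair`: `length` (alignment columns),
#'   `n_sites` (comparable positions), `n_diff` (mismatches), `divergence`
#'   (`n_diff / n_sites`).
#' @examples
#' count_differences("ACGTA", "ACGTT")  # 1 difference over 5 sites
#' count_differences("AC-TA", "ACGTA")  # gap column excluded: 4 sites
#' @export
count_differences <- function(seq_a, seq_b) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (nchar(a) != nchar(b)) {
    stop("sequences must be aligned to equal length (", nchar(a), " vs ",
         nchar(b), ")")
  }
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  comparable <- av %in% .UNAMBIGUOUS_BASES & bv %in% .UNAMBIGUOUS_BASES
  n_sites <- sum(comparable)
  if (n_sites == 0L) stop("no comparable (unambiguous, ungapped) sites")
  n_diff <- sum(comparable & av != bv)
  structure(
    list(length = nchar(a), n_sites = n_sites, n_diff = n_diff,
         divergence = n_diff / n_sites),
    class = "aligned_pair"
  )
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("aligned pair: %d columns, %d comparable sites, %d differences (d = %.5g)\n",
              x$length, x$n_sites, x$n_diff, x$divergence))
  invisible(x)
}

#' Read a pre-aligned sequence pair from FASTA
#'
#' Reads exactly two aligned records and returns their difference summary.
#'
#' @param path Path to a FASTA file containing two equal-length records.
#' @return An `aligned_pair` (see [count_differences()]) with a `names`
#'   element giving the two record names.
#' @export
read_aligned_pair <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2L) {
    stop("expected exactly 2 FASTA records, found ", length(seqs))
  }
  out <- count_differences(as.character(seqs[[1L]]), as.character(seqs[[2L]]))
  out$names <- names(seqs)
  out
}

#' Molecular-clock divergence time of a gene pair
#'
#' Under a strict clock with per-lineage substitution rate `mu`, two
#' sequences separated for `T` years accumulate `2 mu T` substitutions per
#' site, so `T = (n_diff/n_sites) / (2 mu)`. No multiple-hit correction is
#' applied: at the divergences this package targets (around 1%) the
#' correction is below 1%.
#'
#' @param n_diff,n_sites Mismatch and comparable-site counts (e.g. from
#'   [count_differences()]).
#' @param mu Substitution rate per site per year; default `3.3e-8`,
#'   consistent with rates calculated for maize.
#' @return Divergence time in years.
#' @examples
#' divergence_time(15, 1296)  # ~175,000 years
#' @export
divergence_time <- function(n_diff, n_sites, mu = 3.3e-8) {
  stopifnot(is.numeric(n_diff), is.numeric(n_sites), is.numeric(mu))
  if (any(n_sites <= 0)) stop("n_sites must be positive")
  if (any(mu <= 0)) stop("substitution rate mu must be positive")
  if (any(n_diff < 0) || any(n_diff > n_sites)) {
    stop("n_diff must lie in [0, n_sites]")
  }
  (n_diff / n_sites) / (2 * mu)
}

#' Place a divergence time against calibration splits
#'
#' Orders an estimated divergence time relative to named calibration points
#' (by default the *mexicana*/*parviglumis* split at ~60,000 years and the
#' *parviglumis*/*luxurians* split at ~140,000 years). A divergence older
#' than a split predates it.
#'
#' @param T_years Estimated divergence time in years.
#' @param splits Named positive numeric vector of calibration split times in
#'   years.
#' @return A data.frame ordered by split age with columns `split`,
#'   `split_years`, `relation` (`"predates"`, `"postdates"` or
#'   `"coincident"`).
#' @examples
#' place_against_splits(divergence_time(15, 1296))
#' @export
place_against_splits <- function(T_years,
                                 splits = c("mexicana-parviglumis" = 60000,
                                            "parviglumis-luxurians" = 140000)) {
  stopifnot(is.numeric(T_years), length(T_years) == 1L, T_years >= 0,
            is.numeric(splits), length(splits) >= 1L, all(splits > 0),
            !is.null(names(splits)))
  splits <- sort(splits)
  relation <- ifelse(T_years > splits, "predates",
                     ifelse(T_years < splits, "postdates", "coincident"))
  data.frame(split = names(splits), split_years = unname(splits),
             relation = unname(relation), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Date the divergence of an aligned gene pair
#'
#' Convenience wrapper: counts differences (from a FASTA path, an
#' `aligned_pair`, or two raw sequences), converts to a divergence time, and
#' places it against the calibration splits.
#'
#' @param pair A FASTA path, an `aligned_pair`, or a character vector of two
#'   aligned sequences.
#' @param mu Substitution rate per site per year. Default `3.3e-8`.
#' @param splits Calibration splits, see [place_against_splits()].
#' @return A list of class `dating_result`: `n_diff`, `n_sites`,
#'   `divergence`, `mu`, `years`, `splits` (placement data.frame).
#' @export
date_divergence <- function(pair, mu = 3.3e-8,
                            splits = c("mexicana-parviglumis" = 60000,
                                       "parviglumis-luxurians" = 140000)) {
  ap <- if (inherits(pair, "aligned_pair")) {
    pair
  } else if (is.character(pair) && length(pair) == 1L) {
    read_aligned_pair(pair)
  } else if (is.character(pair) && length(pair) == 2L) {
    count_differences(pair[1L], pair[2L])
  } else {
    stop("pair must be a FASTA path, an aligned_pair, or two sequences")
  }
  years <- divergence_time(ap$n_diff, ap$n_sites, mu)
  structure(
    list(n_diff = ap$n_diff, n_sites = ap$n_sites,
         divergence = ap$divergence, mu = mu, years = years,
         splits = place_against_splits(years, splits)),
    class = "dating_result"
  )
}

#' @export
print.dating_result <- function(x, ...) {
  cat(sprintf("divergence: %d of %d sites (d = %.5g), mu = %g /site/yr\n",
              x$n_diff, x$n_sites, x$divergence, x$mu))
  cat(sprintf("estimated split: %.0f years ago\n", x$years))
  for (i in seq_len(nrow(x$splits))) {
    cat(sprintf("  %s %s (%.0f years)\n", x$splits$relation[i],
                x$splits$split[i], x$splits$split_years[i]))
  }
  invisible(x)
}
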