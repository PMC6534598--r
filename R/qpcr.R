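# Relative expression from qRT-PCR Ct tables (target vs. a tubulin
# reference) and the expression/barrier-strength association analysis.

#' Relative expression from a pair of Ct values
#'
#' Standard delta-Ct quantification assuming amplification efficiency
#' exactly 2: `2^(ct_reference - ct_target)`. Additive shifts common to both
#' genes (loading, cDNA amount) cancel exactly.
#'
#' @param ct_target,ct_reference Finite Ct values (cycles); vectorised.
#' @return Relative expression of the target vs. the reference gene.
#' @examples
#' relative_expression(20, 20)  # 1
#' relative_expression(19, 20)  # 2: one cycle earlier = twice the template
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!is.numeric(ct_target) || !is.numeric(ct_reference) ||
      !all(is.finite(ct_target)) || !all(is.finite(ct_reference))) {
    stop("Ct values must be finite numbers (undetermined Ct is missing data, ",
         "drop it before calling)")
  }
  2^(ct_reference - ct_target)
}

# Validate the long-format Ct table used throughout.
.check_ct_table <- function(ct) {
  need <- c("line_name", "gene", "biological_rep", "technical_rep", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("Ct table must contain columns: ", paste(need, collapse = ", "))
  }
  if (!all(ct$gene %in% c("target", "reference"))) {
    stop("gene column must be 'target' or 'reference'")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  ct
}

#' Summarise relative expression per line from a Ct table
#'
#' Technical replicates are averaged on the Ct scale within each biological
#' replicate first; each biological replicate then yields one relative
#' expression value (`2^(mean Ct reference - mean Ct target)`), and the line
#' summary is the mean and standard error of the mean (SEM) over biological
#' replicates.
#'
#' @param ct Long-format Ct data.frame with columns `line_name`, `gene`
#'   (`"target"`/`"reference"`), `biological_rep`, `technical_rep`, `ct`.
#' @return A data.frame with one row per line: `line_name`,
#'   `relative_expression`, `sem`, `n_biological`.
#' @export
summarize_expression <- function(ct) {
  ct <- .check_ct_table(ct)
  out <- lapply(split(ct, ct$line_name), function(d) {
    per_bio <- vapply(split(d, d$biological_rep), function(b) {
      tgt <- b$ct[b$gene == "target"]
      ref <- b$ct[b$gene == "reference"]
      if (length(ref) == 0L) {
        stop("line '", d$line_name[1L], "' biological replicate ",
             b$biological_rep[1L], " has no reference-gene measurements")
      }
      if (length(tgt) == 0L) {
        stop("line '", d$line_name[1L], "' biological replicate ",
             b$biological_rep[1L], " has no target-gene measurements")
      }
      relative_expression(mean(tgt), mean(ref))
    }, numeric(1))
    if (length(per_bio) < 2L) {
      stop("line '", d$line_name[1L],
           "' needs at least 2 biological replicates for a SEM")
    }
    data.frame(
      line_name = d$line_name[1L],
      relative_expression = mean(per_bio),
      sem = stats::sd(per_bio) / sqrt(length(per_bio)),
      n_biological = length(per_bio),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Association between female-gene expression and barrier strength
#'
#' Joins per-line expression summaries with measured barrier strengths by
#' line name, computes the Spearman rank correlation, and reports whether
#' lines expressing below the barrier threshold behave as barrier-less
#' (barrier strength near 1), the signature of a threshold response.
#'
#' @param summaries Data.frame from [summarize_expression()] (`line_name`,
#'   `relative_expression`).
#' @param strengths Data.frame with columns `line_name` and
#'   `barrier_strength`, one row per line.
#' @param threshold Expression threshold below which no barrier is expected.
#'   Default 0.1.
#' @param bs_tolerance Half-width of the "no barrier" band around a
#'   barrier strength of 1. Default 0.5.
#' @return A list: `rho` (Spearman), `n`, a per-line `table` with
#'   `below_threshold` flags, and `threshold_consistent` (TRUE when every
#'   below-threshold line has barrier strength within `bs_tolerance` of 1).
#' @export
expression_barrier_association <- function(summaries, strengths,
                                           threshold = 0.1,
                                           bs_tolerance = 0.5) {
  stopifnot(is.data.frame(summaries), is.data.frame(strengths),
            all(c("line_name", "relative_expression") %in% names(summaries)),
            all(c("line_name", "barrier_strength") %in% names(strengths)))
  merged <- merge(summaries[c("line_name", "relative_expression")],
                  strengths[c("line_name", "barrier_strength")],
                  by = "line_name")
  unpaired <- union(setdiff(summaries$line_name, strengths$line_name),
                    setdiff(strengths$line_name, summaries$line_name))
  if (length(unpaired) > 0L) {
    stop("unpaired lines (present in only one input): ",
         paste(unpaired, collapse = ", "))
  }
  if (nrow(merged) < 3L) stop("need at least 3 paired lines")
  rho <- stats::cor(merged$relative_expression, merged$barrier_strength,
                    method = "spearman")
  merged$below_threshold <- merged$relative_expression < threshold
  below <- merged[merged$below_threshold, , drop = FALSE]
  consistent <- nrow(below) == 0L ||
    all(abs(below$barrier_strength - 1) <= bs_tolerance)
  list(rho = rho, n = nrow(merged), table = merged,
       threshold_consistent = consistent)
}
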