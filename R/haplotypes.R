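# Deterministic genetic model of the Tcb1 locus: haplotype semantics,
# two-locus gamete frequencies, pollen acceptance rules and the analytic
# linked-marker segregation expectations used to score ears.

# The four haplotype configurations of the tightly linked Tcb1-male /
# Tcb1-female gene pair. Functionality flags are fixed vocabulary, not data.
.TCB1_HAPLOTYPES <- data.frame(
  name              = c("Tcb1-s", "Tcb1-m", "Tcb1-f", "tcb1"),
  male_functional   = c(TRUE,     TRUE,     FALSE,    FALSE),
  female_functional = c(TRUE,     FALSE,    TRUE,     FALSE),
  stringsAsFactors  = FALSE
)

.SU1_ALLELES <- c("Su1", "su1")
.R1_ALLELES <- c("R1-sc", "r1-r")

#' Tcb1 haplotype vocabulary
#'
#' Returns the table of the four recognised haplotypes at the Tcb1 locus with
#' their male/female gene functionality flags: `Tcb1-s` carries functional
#' male and female genes, `Tcb1-m` male only, `Tcb1-f` female only, and
#' `tcb1` (standard maize) neither.
#'
#' @param name Optional character vector of haplotype names; if given, the
#'   table is subset (and validated) to those rows, in order.
#' @return A data.frame with columns `name`, `male_functional`,
#'   `female_functional`.
#' @examples
#' haplotype_info()
#' haplotype_info("Tcb1-m")$male_functional
#' @export
haplotype_info <- function(name = NULL) {
  if (is.null(name)) {
    return(.TCB1_HAPLOTYPES)
  }
  idx <- match(name, .TCB1_HAPLOTYPES$name)
  if (anyNA(idx)) {
    stop("unknown Tcb1 haplotype name(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "),
         " (must be one of ", paste(.TCB1_HAPLOTYPES$name, collapse = ", "), ")")
  }
  .TCB1_HAPLOTYPES[idx, , drop = FALSE]
}

# A gamete's haplotype field is stored as a single string; heterodiploid
# pollen (a duplication carrying a second haplotype) joins two names with "+".
.split_gamete_haps <- function(x) strsplit(x, "+", fixed = TRUE)[[1L]]

.is_male_functional <- function(haps) haplotype_info(haps)$male_functional
.is_female_functional <- function(haps) haplotype_info(haps)$female_functional

# Default relative expression (vs. the tubulin reference) attached to a
# female-functional allele; full-strength Tcb1-s lines sit at 1 on this scale.
.default_expression <- function(haps) ifelse(.is_female_functional(haps), 1, 0)

#' Construct a diploid plant genotype at the Tcb1 locus
#'
#' A plant is described by its two chromosome-4 phases (Tcb1 haplotype plus
#' the linked `su1` endosperm marker allele, in cis), the recombination
#' fraction between them, the unlinked `r1` kernel-colour marker genotype,
#' `mop1` status, and a per-allele expression level of the female barrier
#' gene (relative to the tubulin reference). Expression is attached to
#' alleles, not plants, so epigenetically silenced lineages and their `mop1`
#' revertants are represented as expression changes on an otherwise
#' female-functional haplotype.
#'
#' @param hap1,hap2 Haplotype names (see [haplotype_info()]).
#' @param su1 Length-2 character, the `su1` marker alleles in cis with
#'   `hap1` and `hap2` (`"Su1"` or `"su1"`).
#' @param r Recombination fraction between the Tcb1 locus and `su1`, in
#'   `[0, 0.5]`. Default 0.06 (~6 cM).
#' @param r1 Length-2 character, `r1` genotype (`"R1-sc"` sires purple
#'   kernels, `"r1-r"` yellow/white). Unlinked to Tcb1: independent
#'   assortment.
#' @param mop1 `"wildtype"` or `"mutant"`.
#' @param expression Length-2 numeric, relative expression of the female
#'   gene on each allele; defaults to 1 for female-functional haplotypes and
#'   0 otherwise.
#' @param duplication_hap Optional haplotype name carried on a chromosome-4
#'   duplication (trisomic carrier); pollen then receives the extra
#'   haplotype with probability `dup_transmission`, producing heterodiploid
#'   gametes.
#' @param dup_transmission Transmission rate of the duplication through
#'   pollen, in `[0, 1]`; default 0.5.
#' @return An object of class `plant_genotype`.
#' @examples
#' # The mutant-screen material: Tcb1-s with Su1 in cis, over maize tcb1 su1
#' repulsion_het <- plant_genotype("Tcb1-s", "tcb1", su1 = c("Su1", "su1"))
#' gamete_frequencies(repulsion_het)
#' @export
plant_genotype <- function(hap1, hap2, su1 = c("Su1", "Su1"), r = 0.06,
                           r1 = c("r1-r", "r1-r"), mop1 = "wildtype",
                           expression = NULL,
                           duplication_hap = NULL, dup_transmission = 0.5) {
  haps <- c(hap1, hap2)
  haplotype_info(haps)  # validates names
  stopifnot(length(su1) == 2L, length(r1) == 2L)
  if (!all(su1 %in% .SU1_ALLELES)) {
    stop("su1 alleles must be in {", paste(.SU1_ALLELES, collapse = ", "), "}")
  }
  if (!all(r1 %in% .R1_ALLELES)) {
    stop("r1 alleles must be in {", paste(.R1_ALLELES, collapse = ", "), "}")
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("recombination fraction r must be a single value in [0, 0.5]")
  }
  mop1 <- match.arg(mop1, c("wildtype", "mutant"))
  if (is.null(expression)) {
    expression <- .default_expression(haps)
  }
  stopifnot(length(expression) == 2L, all(is.finite(expression)))
  if (any(expression < 0)) stop("expression levels must be nonnegative")
  if (!is.null(duplication_hap)) {
    haplotype_info(duplication_hap)
    stopifnot(length(duplication_hap) == 1L,
              is.numeric(dup_transmission), dup_transmission >= 0,
              dup_transmission <= 1)
  }
  # Phase bookkeeping: repulsion = the functional barrier haplotype is in cis
  # with the dominant Su1 allele, so only recombinant pollen carries Tcb1+su1.
  fem <- .is_female_functional(haps)
  phase <- NA_character_
  if (sum(fem) == 1L) {
    phase <- if (su1[fem] == "Su1") "repulsion" else "coupling"
  }
  structure(
    list(haplotypes = haps, su1 = su1, r = r, r1 = r1, mop1 = mop1,
         expression = expression, phase = phase,
         duplication_hap = duplication_hap,
         dup_transmission = if (is.null(duplication_hap)) 0 else dup_transmission),
    class = "plant_genotype"
  )
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat(sprintf("Tcb1 genotype: %s %s / %s %s  (r = %g, phase = %s)\n",
              x$haplotypes[1L], x$su1[1L], x$haplotypes[2L], x$su1[2L],
              x$r, x$phase))
  cat(sprintf("  r1: %s/%s  mop1: %s  expression: %g / %g\n",
              x$r1[1L], x$r1[2L], x$mop1,
              x$expression[1L], x$expression[2L]))
  if (!is.null(x$duplication_hap)) {
    cat(sprintf("  duplication: +%s (pollen transmission %g)\n",
                x$duplication_hap, x$dup_transmission))
  }
  invisible(x)
}

#' Gamete frequencies for a diploid parent
#'
#' Two-locus gamete distribution between the Tcb1 haplotype and the linked
#' `su1` marker: the two parental classes each occur at `(1 - r)/2`, the two
#' recombinant classes at `r/2`. Duplicate classes (e.g. from homozygotes)
#' are pooled. If the parent carries a chromosome-4 duplication, each pollen
#' class is split into a haploid and a heterodiploid (`"hapA+hapB"`) class
#' according to the duplication transmission rate.
#'
#' @param parent A [plant_genotype()].
#' @return A data.frame with columns `haplotype`, `su1`, `prob`; probabilities
#'   sum to 1.
#' @examples
#' het <- plant_genotype("Tcb1-s", "tcb1", su1 = c("Su1", "su1"), r = 0.06)
#' gamete_frequencies(het)  # parental classes 0.47, recombinant 0.03
#' @export
gamete_frequencies <- function(parent) {
  stopifnot(inherits(parent, "plant_genotype"))
  r <- parent$r
  h <- parent$haplotypes
  s <- parent$su1
  out <- data.frame(
    haplotype = c(h, h),
    su1       = c(s, rev(s)),
    prob      = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2),
    stringsAsFactors = FALSE
  )
  if (!is.null(parent$duplication_hap)) {
    t <- parent$dup_transmission
    dup <- out
    dup$haplotype <- paste(dup$haplotype, parent$duplication_hap, sep = "+")
    dup$prob <- dup$prob * t
    out$prob <- out$prob * (1 - t)
    out <- rbind(out, dup)
  }
  out <- stats::aggregate(prob ~ haplotype + su1, data = out, FUN = sum)
  out <- out[out$prob > 0, , drop = FALSE]
  out <- out[order(-out$prob, out$haplotype, out$su1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is the female crossing barrier active in a pistil?
#'
#' The barrier is active when at least one allele is female-functional
#' (carries an intact Tcb1-female gene) *and* its expression level is at or
#' above the threshold required to produce a detectable barrier. Silenced
#' epialleles with sub-threshold expression produce no barrier even though
#' the coding sequence is intact.
#'
#' @param female A [plant_genotype()].
#' @param threshold Positive expression threshold (relative to the tubulin
#'   reference) below which no detectable barrier forms. Default 0.1.
#' @return Logical scalar.
#' @export
barrier_active <- function(female, threshold = 0.1) {
  stopifnot(inherits(female, "plant_genotype"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  any(.is_female_functional(female$haplotypes) &
        female$expression >= threshold)
}

#' Probability that a pistil accepts a pollen grain
#'
#' Gametophytic acceptance rule: a pistil without an active barrier accepts
#' all pollen. An active barrier accepts pollen whose own (haploid or
#' heterodiploid) genotype includes a male-functional haplotype; any other
#' pollen sires a kernel only through residual leak. Heterodiploid pollen is
#' accepted if *any* of its haplotypes is male-functional (the functional
#' male gene is dominant over the null).
#'
#' @param female A [plant_genotype()] describing the pollen receiver.
#' @param pollen Character vector of 1 or 2 haplotype names carried by the
#'   pollen grain, or a single `"hapA+hapB"` string for heterodiploid pollen.
#' @param leak Residual siring probability of incompatible pollen on a
#'   barrier-active ear, in `[0, 1]`. Default 0.03, within the observed
#'   0-7% band.
#' @param threshold Expression threshold passed to [barrier_active()].
#' @return Acceptance probability in `[0, 1]`.
#' @examples
#' tester <- plant_genotype("Tcb1-s", "Tcb1-s")
#' pollen_acceptance(tester, "tcb1", leak = 0)             # 0: rejected
#' pollen_acceptance(tester, c("Tcb1-s", "tcb1"))          # 1: heterodiploid
#' pollen_acceptance(plant_genotype("tcb1", "tcb1"), "tcb1")  # 1: no barrier
#' @export
pollen_acceptance <- function(female, pollen, leak = 0.03, threshold = 0.1) {
  stopifnot(inherits(female, "plant_genotype"))
  if (!is.numeric(leak) || length(leak) != 1L || is.na(leak) ||
      leak < 0 || leak > 1) {
    stop("leak must be a single probability in [0, 1]")
  }
  if (length(pollen) == 1L && grepl("+", pollen, fixed = TRUE)) {
    pollen <- .split_gamete_haps(pollen)
  }
  if (length(pollen) < 1L || length(pollen) > 2L) {
    stop("a pollen gamete carries 1 or 2 haplotypes")
  }
  haplotype_info(pollen)
  if (!barrier_active(female, threshold)) {
    return(1)
  }
  if (any(.is_male_functional(pollen))) 1 else leak
}

#' Expected su1-homozygous kernel fraction in the open-pollinated screen
#'
#' In an open-pollinated block of `Tcb1-s Su1 / tcb1 su1` repulsion
#' heterozygotes, pollen on a barrier-carrying ear is restricted to the
#' male-functional (Tcb1-s) classes, of which a fraction `r` carries `su1`
#' by recombination; ovules are unselected and transmit `su1` with
#' probability 1/2. Hence sugary kernels appear at `r/2` (about 3% at
#' r = 0.06) on barrier ears and at 1/4 on ears with no barrier, where the
#' predominantly `su1` maize pollen is freely accepted.
#'
#' @param barrier Logical (vectorised): is the female barrier functional?
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return Expected fraction of su1/su1 kernels.
#' @examples
#' expected_marker_segregation(TRUE, 0.06)   # 0.03
#' expected_marker_segregation(FALSE, 0.06)  # 0.25
#' @export
expected_marker_segregation <- function(barrier, r) {
  stopifnot(is.logical(barrier), !anyNA(barrier))
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fraction r must be in [0, 0.5]")
  }
  ifelse(barrier, r / 2, 0.25)
}

#' Map female-gene expression to barrier leak through a monotone step
#'
#' Partial epigenetic reversion raises expression to an
#' elevated-but-sub-maximal level; observed barrier strength rises with
#' expression but the functional form is unknown, so the mapping is a
#' monotone decreasing step function: below `threshold` there is no barrier
#' (leak 1), between `threshold` and `full_level` an intermediate barrier
#' (`partial_leak`), and at or above `full_level` the full-strength barrier
#' (`full_leak`).
#'
#' @param expression Nonnegative numeric vector of relative expression.
#' @param threshold Expression below which no barrier forms. Default 0.1.
#' @param full_level Expression at which the barrier is full strength.
#'   Default 1.
#' @param partial_leak Leak of a partial barrier. Default 0.2.
#' @param full_leak Leak of a full-strength barrier. Default 0.03.
#' @return Numeric vector of leak probabilities.
#' @export
leak_from_expression <- function(expression, threshold = 0.1, full_level = 1,
                                 partial_leak = 0.2, full_leak = 0.03) {
  stopifnot(is.numeric(expression), all(expression >= 0),
            threshold > 0, full_level >= threshold,
            partial_leak >= full_leak)
  ifelse(expression < threshold, 1,
         ifelse(expression < full_level, partial_leak, full_leak))
}
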