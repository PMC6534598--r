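# Stochastic simulators of the three experimental designs used to probe the
# female crossing barrier: mixed pollination onto three receiver ears, the
# open-pollinated knockout screen, and the mop1 reversion test. Kernel sires
# are independent multinomial draws; there is no silk-position or
# pollen-depletion structure.

# Default calibrated per-kernel siring bias on a neutral ear: with an equal
# mix, 60% of kernels are sired by tcb1 pollen and 40% by Tcb1-s-class
# (male-functional) pollen.
.DEFAULT_BIAS <- c("tcb1" = 0.6, "Tcb1-s" = 0.4)

# Competition class of a pollen gamete for the acceptance bias: any gamete
# carrying a male-functional haplotype competes as Tcb1-s-class pollen.
.gamete_class <- function(hap_string) {
  haps <- .split_gamete_haps(hap_string)
  if (any(.is_male_functional(haps))) "Tcb1-s" else "tcb1"
}

.check_bias <- function(bias) {
  if (!is.numeric(bias) || is.null(names(bias)) ||
      !setequal(names(bias), c("tcb1", "Tcb1-s")) || any(bias <= 0)) {
    stop("acceptance_bias must be a positive numeric vector with names ",
         "'tcb1' and 'Tcb1-s'")
  }
  bias
}

# Expand a donor's gametes over the unlinked r1 colour marker (independent
# assortment) and tag each class with its mixing weight and competition bias.
.donor_pollen <- function(donor, donor_id, mix_weight, bias) {
  g <- gamete_frequencies(donor)
  r1 <- unique(donor$r1)
  out <- do.call(rbind, lapply(r1, function(a) {
    d <- g
    d$r1 <- a
    d$prob <- d$prob * mean(donor$r1 == a)
    d
  }))
  out$donor <- donor_id
  out$class <- vapply(out$haplotype, .gamete_class, character(1))
  out$weight <- mix_weight * out$prob * unname(bias[out$class])
  out
}

# Draw one ear: kernel sires are multinomial over the pooled pollen classes
# weighted by mix x bias x acceptance; ovules are unselected and drawn from
# the receiver's own gamete distribution (su1 marginal only).
.sire_ear <- function(female, pool, leak, threshold, n_kernels,
                      ear_id, receiver_class) {
  acc <- vapply(pool$haplotype, function(h) {
    pollen_acceptance(female, h, leak = leak, threshold = threshold)
  }, numeric(1))
  w <- pool$weight * acc
  if (sum(w) <= 0) {
    stop("no pollen class is accepted on ear '", ear_id,
         "': cannot sire any kernels")
  }
  counts <- as.vector(stats::rmultinom(1L, n_kernels, w))
  fg <- gamete_frequencies(female)
  p_ovule_su1 <- sum(fg$prob[fg$su1 == "su1"])
  sugary <- sum(vapply(seq_along(counts), function(i) {
    if (pool$su1[i] == "su1" && counts[i] > 0) {
      stats::rbinom(1L, counts[i], p_ovule_su1)
    } else 0L
  }, numeric(1)))
  n_purple <- sum(counts[pool$r1 == "R1-sc"])
  data.frame(
    ear_id = ear_id,
    receiver_class = receiver_class,
    n_purple = n_purple,
    n_yellow = n_kernels - n_purple,
    n_sugary = as.integer(sugary),
    n_total = n_kernels,
    n_sired_donorA = sum(counts[pool$donor == "A"]),
    n_sired_donorB = sum(counts[pool$donor == "B"]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a mixed-pollination test on three receiver ears
#'
#' Pollen from two donors is mixed and applied to three ears: a
#' `Tcb1-s/Tcb1-s` tester (verifies the male function of the test donor), the
#' test female itself (probes its female barrier), and a neutral `tcb1` maize
#' ear (calibrates the ratio of functional pollen in the mix). Each kernel's
#' sire is an independent draw with weight proportional to mixing weight
#' times the per-kernel acceptance bias times the receiver's acceptance
#' probability. Donors must differ in their `r1` colour marker so progeny can
#' be assigned: `R1-sc` pollen sires purple kernels, `r1-r` yellow/white.
#'
#' @param test_female A [plant_genotype()], the pollen receiver under test.
#' @param donorA,donorB [plant_genotype()]s of the two pollen donors; their
#'   `r1` allele sets must be disjoint.
#' @param mix_weight Mixing weight of donor A's pollen, in `(0, 1)`;
#'   donor B gets `1 - mix_weight`. Default 0.5.
#' @param n_kernels Kernels scored per ear. Default 300.
#' @param leak Residual acceptance of incompatible pollen on barrier-active
#'   ears. Default 0.03.
#' @param acceptance_bias Named relative siring weights for the `"tcb1"` and
#'   `"Tcb1-s"` pollen competition classes on any ear; default `60:40`.
#' @param threshold Expression threshold for [barrier_active()].
#' @param seed Integer seed; the draw is reproducible bit-for-bit.
#' @return A data.frame of three ear-count rows (`receiver_class` =
#'   `"tester"`, `"test"`, `"neutral"`) with kernel-colour, sugary and
#'   ground-truth donor-sired counts; the seed is stored as an attribute.
#' @examples
#' tcb1_R <- plant_genotype("tcb1", "tcb1", r1 = c("R1-sc", "R1-sc"))
#' ko     <- plant_genotype("Tcb1-m", "tcb1")
#' simulate_mixed_pollination(ko, tcb1_R, ko, n_kernels = 200, seed = 7)
#' @export
simulate_mixed_pollination <- function(test_female, donorA, donorB,
                                       mix_weight = 0.5, n_kernels = 300L,
                                       leak = 0.03,
                                       acceptance_bias = c("tcb1" = 0.6, "Tcb1-s" = 0.4),
                                       threshold = 0.1, seed = 1L) {
  stopifnot(inherits(test_female, "plant_genotype"),
            inherits(donorA, "plant_genotype"),
            inherits(donorB, "plant_genotype"),
            n_kernels > 0, mix_weight > 0, mix_weight < 1)
  .check_bias(acceptance_bias)
  if (length(intersect(unique(donorA$r1), unique(donorB$r1))) > 0L) {
    stop("donors share r1 kernel-colour marker alleles: progeny could not ",
         "be assigned to a donor (unscoreable design)")
  }
  set.seed(seed)
  pool <- rbind(
    .donor_pollen(donorA, "A", mix_weight, acceptance_bias),
    .donor_pollen(donorB, "B", 1 - mix_weight, acceptance_bias)
  )
  tester  <- plant_genotype("Tcb1-s", "Tcb1-s")
  neutral <- plant_genotype("tcb1", "tcb1")
  out <- rbind(
    .sire_ear(tester, pool, leak, threshold, n_kernels, "ear_tester", "tester"),
    .sire_ear(test_female, pool, leak, threshold, n_kernels, "ear_test", "test"),
    .sire_ear(neutral, pool, leak, threshold, n_kernels, "ear_neutral", "neutral")
  )
  attr(out, "seed") <- seed
  out
}

#' Simulate the open-pollinated knockout screen
#'
#' A block of `Tcb1-s Su1 / tcb1 su1` repulsion heterozygotes is
#' open-pollinated from its own pooled pollen cloud. A configurable fraction
#' of plants carry a knocked-out female gene (male function retained). On
#' barrier ears the cloud is filtered to male-functional pollen (plus leak),
#' giving an expected sugary-kernel fraction of `r/2`; knockout ears accept
#' all pollen and segregate sugary at 1/4. Ground truth is returned for
#' scoring.
#'
#' @param n_plants Number of ears in the block. Default 6000.
#' @param kernels_per_ear Kernels scored per ear. Default 300.
#' @param r Recombination fraction between Tcb1 and `su1`. Default 0.06.
#' @param leak Residual acceptance of incompatible pollen on barrier ears.
#'   Default 0.03.
#' @param knockout_fraction Fraction of plants whose female gene is knocked
#'   out. Default 0.
#' @param seed Integer seed.
#' @return A data.frame with one row per ear: `ear_id`, `n_sugary`,
#'   `n_total`, `sugary_fraction` and the hidden truth column `barrier`.
#' @examples
#' scr <- simulate_open_pollinated_screen(n_plants = 100, seed = 3)
#' mean(scr$sugary_fraction)  # ~ 0.03 + leak effect
#' @export
simulate_open_pollinated_screen <- function(n_plants = 6000L,
                                            kernels_per_ear = 300L,
                                            r = 0.06, leak = 0.03,
                                            knockout_fraction = 0,
                                            seed = 1L) {
  stopifnot(n_plants > 0, kernels_per_ear > 0,
            knockout_fraction >= 0, knockout_fraction <= 1,
            leak >= 0, leak <= 1)
  if (r < 0 || r > 0.5) stop("recombination fraction r must be in [0, 0.5]")
  set.seed(seed)
  barrier <- stats::runif(n_plants) >= knockout_fraction
  # Common pollen cloud pooled over all plants. Barrier plants are
  # Tcb1-s Su1/tcb1 su1; knockout plants Tcb1-m Su1/tcb1 su1 -- the male
  # side, and hence the cloud's class structure, is identical.
  het <- plant_genotype("Tcb1-s", "tcb1", su1 = c("Su1", "su1"), r = r)
  cloud <- gamete_frequencies(het)
  male <- vapply(cloud$haplotype,
                 function(h) any(.is_male_functional(.split_gamete_haps(h))),
                 logical(1))
  # Acceptance-weighted su1 fraction of the pollen reaching ovules.
  w_barrier <- cloud$prob * ifelse(male, 1, leak)
  p_su1_barrier <- sum(w_barrier[cloud$su1 == "su1"]) / sum(w_barrier)
  p_su1_open <- sum(cloud$prob[cloud$su1 == "su1"])
  # Ears are su1 heterozygotes: ovule transmits su1 with probability 1/2.
  p_sugary <- ifelse(barrier, p_su1_barrier, p_su1_open) / 2
  n_sugary <- stats::rbinom(n_plants, kernels_per_ear, p_sugary)
  data.frame(
    ear_id = sprintf("ear_%05d", seq_len(n_plants)),
    n_sugary = n_sugary,
    n_total = as.integer(kernels_per_ear),
    sugary_fraction = n_sugary / kernels_per_ear,
    barrier = barrier,
    stringsAsFactors = FALSE
  )
}

#' Simulate the mop1 reversion experiment
#'
#' Each female carries an epigenetically silenced female-functional allele
#' (`Tcb1-f` at sub-threshold expression) over `tcb1`. With probability
#' `reversion_prob` the allele reverts: expression rises to
#' `expression_reverted` (at or above `threshold`) and the ear forms a
#' partial barrier whose leak is drawn uniformly from `partial_leak_band`.
#' Non-reverted females behave as barrier-less `tcb1` ears. Every female is
#' scored by mixed pollination (a `tcb1; R1-sc` donor vs. a `Tcb1-s; r1`
#' tester donor) against a neutral `tcb1` control ear, and classified with
#' [classify_ear()].
#'
#' @param n_females Number of females tested. Default 36.
#' @param reversion_prob Per-female reversion probability. Default 0.18
#'   (middle of the observed ~14-22% range).
#' @param expression_base Expression of the silenced allele. Default 0.03.
#' @param expression_reverted Expression after reversion. Default 0.3.
#' @param threshold Barrier expression threshold. Default 0.1.
#' @param partial_leak_band Length-2 numeric, uniform band from which a
#'   reverted female's leak is drawn. Default `c(0.05, 0.35)`.
#' @param n_kernels Kernels scored per ear. Default 300.
#' @param mix_weight Mixing weight of the `tcb1` donor. Default 0.5.
#' @param acceptance_bias Per-kernel siring bias, as in
#'   [simulate_mixed_pollination()].
#' @param seed Integer seed.
#' @return A data.frame with one row per female: ground truth (`reverted`,
#'   `expression`, `leak`), test- and control-ear kernel counts, the exact
#'   test p-value, tier and barrier strength.
#' @export
simulate_reversion_experiment <- function(n_females = 36L,
                                          reversion_prob = 0.18,
                                          expression_base = 0.03,
                                          expression_reverted = 0.3,
                                          threshold = 0.1,
                                          partial_leak_band = c(0.05, 0.35),
                                          n_kernels = 300L,
                                          mix_weight = 0.5,
                                          acceptance_bias = c("tcb1" = 0.6, "Tcb1-s" = 0.4),
                                          seed = 1L) {
  stopifnot(n_females > 0, reversion_prob >= 0, reversion_prob <= 1,
            length(partial_leak_band) == 2L,
            all(partial_leak_band >= 0), all(partial_leak_band <= 1),
            partial_leak_band[1] <= partial_leak_band[2])
  .check_bias(acceptance_bias)
  set.seed(seed)
  donor_tcb1 <- plant_genotype("tcb1", "tcb1", r1 = c("R1-sc", "R1-sc"))
  donor_tester <- plant_genotype("Tcb1-s", "Tcb1-s", r1 = c("r1-r", "r1-r"))
  pool <- rbind(
    .donor_pollen(donor_tcb1, "A", mix_weight, acceptance_bias),
    .donor_pollen(donor_tester, "B", 1 - mix_weight, acceptance_bias)
  )
  neutral <- plant_genotype("tcb1", "tcb1")
  reverted <- stats::runif(n_females) < reversion_prob
  expr <- ifelse(reverted, expression_reverted, expression_base)
  leak <- ifelse(reverted,
                 stats::runif(n_females, partial_leak_band[1], partial_leak_band[2]),
                 1)
  rows <- lapply(seq_len(n_females), function(i) {
    fem <- plant_genotype("Tcb1-f", "tcb1", expression = c(expr[i], 0))
    test <- .sire_ear(fem, pool, leak[i], threshold, n_kernels,
                      sprintf("female_%02d_test", i), "test")
    ctrl <- .sire_ear(neutral, pool, leak[i], threshold, n_kernels,
                      sprintf("female_%02d_control", i), "control")
    cls <- classify_ear(test, ctrl)
    data.frame(
      female_id = sprintf("female_%02d", i),
      reverted = reverted[i],
      expression = expr[i],
      leak = leak[i],
      test_n_purple = test$n_purple, test_n_yellow = test$n_yellow,
      control_n_purple = ctrl$n_purple, control_n_yellow = ctrl$n_yellow,
      p_value = cls$p_value,
      tier = cls$tier,
      barrier_strength = cls$barrier_strength,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Estimate the pollen acceptance bias from a neutral ear
#'
#' Method-of-moments estimate of the per-kernel siring bias between the
#' `tcb1` and `Tcb1-s` pollen classes from the kernel counts of a neutral
#' (barrier-less) ear, correcting for an unequal mixing weight.
#'
#' @param n_tcb1_sired,n_compat_sired Kernel counts sired by the `tcb1`-class
#'   and the male-functional (`Tcb1-s`-class) donor on the neutral ear.
#' @param mix_weight Mixing weight of the `tcb1`-class donor. Default 0.5.
#' @return Named numeric `c(tcb1 = ..., "Tcb1-s" = ...)` summing to 1.
#' @export
estimate_acceptance_bias <- function(n_tcb1_sired, n_compat_sired,
                                     mix_weight = 0.5) {
  stopifnot(n_tcb1_sired >= 0, n_compat_sired >= 0,
            n_tcb1_sired + n_compat_sired > 0,
            mix_weight > 0, mix_weight < 1)
  odds <- (n_tcb1_sired / n_compat_sired) * (1 - mix_weight) / mix_weight
  c("tcb1" = odds / (1 + odds), "Tcb1-s" = 1 / (1 + odds))
}

#' Estimate barrier leak from a test/control ear pair
#'
#' On a barrier-active ear the odds of a `tcb1`-sired kernel are the neutral
#' odds multiplied by the leak, so the leak is estimated as the inverse of
#' the barrier-strength odds ratio (with the same zero-cell correction).
#'
#' @param test,control Ear counts as in [barrier_strength()].
#' @param correction Zero-cell correction, see [barrier_strength()].
#' @return Estimated leak probability.
#' @export
estimate_leak <- function(test, control, correction = 0.5) {
  1 / barrier_strength(test, control, correction = correction)
}
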