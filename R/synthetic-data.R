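# Seeded fixture generators: every analysis stage can be fed synthetic
# inputs with known ground truth, written as plain-text TSV/FASTA plus a
# truth JSON. Each design draws from its own stream derived from
# (seed, design), so adding designs never perturbs existing fixtures.

.FIXTURE_DESIGNS <- c("mixed_pollination", "screen", "reversion", "qpcr",
                      "seqpair")

.fixture_seed <- function(seed, design) {
  idx <- match(design, .FIXTURE_DESIGNS)
  if (is.na(idx)) {
    stop("unknown fixture design '", design, "'; must be one of: ",
         paste(.FIXTURE_DESIGNS, collapse = ", "))
  }
  as.integer((as.numeric(seed) + 7919 * idx) %% .Machine$integer.max)
}

.write_truth <- function(truth, out_dir, stem) {
  path <- file.path(out_dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Generate a mixed-pollination fixture
#'
#' Simulates the three-receiver mixed pollination (a `tcb1; R1-sc` donor vs.
#' a `Tcb1-s; r1` donor onto tester, test and neutral ears) with known leak,
#' bias and mixing weight, and writes the ear counts plus a truth JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Fixture seed; the per-design stream is derived from it.
#' @param mix_weight Mixing weight of the `tcb1` donor. Default 0.5.
#' @param leak True barrier leak. Default 0.03.
#' @param acceptance_bias Per-kernel siring bias. Default 60:40.
#' @param n_kernels Kernels per ear. Default 300.
#' @return Invisibly, a list with `paths` (ears TSV, truth JSON), the ear
#'   `data`, and the `truth` list.
#' @export
make_mix_fixture <- function(out_dir, seed = 1L, mix_weight = 0.5,
                             leak = 0.03,
                             acceptance_bias = c("tcb1" = 0.6, "Tcb1-s" = 0.4),
                             n_kernels = 300L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- .fixture_seed(seed, "mixed_pollination")
  donor_tcb1 <- plant_genotype("tcb1", "tcb1", r1 = c("R1-sc", "R1-sc"))
  donor_tester <- plant_genotype("Tcb1-s", "Tcb1-s", r1 = c("r1-r", "r1-r"))
  test_female <- plant_genotype("Tcb1-s", "Tcb1-s")
  ears <- simulate_mixed_pollination(
    test_female, donor_tcb1, donor_tester,
    mix_weight = mix_weight, n_kernels = n_kernels, leak = leak,
    acceptance_bias = acceptance_bias, seed = s
  )
  spec <- sprintf(
    "design=mixed_pollination seed=%d mix_weight=%g leak=%g bias_tcb1=%g n_kernels=%d",
    seed, mix_weight, leak, acceptance_bias[["tcb1"]], n_kernels)
  ears_path <- file.path(out_dir, "mix_ears.tsv")
  write_ear_counts(ears, ears_path, header_lines = spec)
  truth <- list(design = "mixed_pollination", seed = seed,
                mix_weight = mix_weight, leak = leak,
                acceptance_bias = as.list(acceptance_bias),
                n_kernels = n_kernels)
  truth_path <- .write_truth(truth, out_dir, "mix")
  invisible(list(paths = c(ears = ears_path, truth = truth_path),
                 data = ears, truth = truth))
}

#' Generate an open-pollinated screen fixture
#'
#' @inheritParams make_mix_fixture
#' @param n_plants,kernels_per_ear,r,leak,knockout_fraction Passed to
#'   [simulate_open_pollinated_screen()].
#' @return Invisibly, `paths`, `data`, `truth` as in [make_mix_fixture()].
#' @export
make_screen_fixture <- function(out_dir, seed = 1L, n_plants = 6000L,
                                kernels_per_ear = 300L, r = 0.06,
                                leak = 0.03, knockout_fraction = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- .fixture_seed(seed, "screen")
  ears <- simulate_open_pollinated_screen(
    n_plants = n_plants, kernels_per_ear = kernels_per_ear, r = r,
    leak = leak, knockout_fraction = knockout_fraction, seed = s
  )
  spec <- sprintf(
    "design=screen seed=%d n_plants=%d kernels_per_ear=%d r=%g leak=%g knockout_fraction=%g",
    seed, n_plants, kernels_per_ear, r, leak, knockout_fraction)
  ears_path <- file.path(out_dir, "screen_ears.tsv")
  write_ear_counts(ears, ears_path, header_lines = spec)
  truth <- list(design = "screen", seed = seed, n_plants = n_plants,
                kernels_per_ear = kernels_per_ear, r = r, leak = leak,
                knockout_fraction = knockout_fraction)
  truth_path <- .write_truth(truth, out_dir, "screen")
  invisible(list(paths = c(ears = ears_path, truth = truth_path),
                 data = ears, truth = truth))
}

#' Generate a mop1 reversion-experiment fixture
#'
#' @inheritParams make_mix_fixture
#' @param n_females,reversion_prob,n_kernels Passed to
#'   [simulate_reversion_experiment()].
#' @return Invisibly, `paths`, `data`, `truth` as in [make_mix_fixture()].
#' @export
make_reversion_fixture <- function(out_dir, seed = 1L, n_females = 36L,
                                   reversion_prob = 0.18, n_kernels = 300L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- .fixture_seed(seed, "reversion")
  res <- simulate_reversion_experiment(
    n_females = n_females, reversion_prob = reversion_prob,
    n_kernels = n_kernels, seed = s
  )
  spec <- sprintf("design=reversion seed=%d n_females=%d reversion_prob=%g n_kernels=%d",
                  seed, n_females, reversion_prob, n_kernels)
  path <- file.path(out_dir, "reversion_females.tsv")
  write_ear_counts(res, path, header_lines = spec)
  truth <- list(design = "reversion", seed = seed, n_females = n_females,
                reversion_prob = reversion_prob, n_kernels = n_kernels,
                n_reverted = sum(res$reverted))
  truth_path <- .write_truth(truth, out_dir, "reversion")
  invisible(list(paths = c(females = path, truth = truth_path),
                 data = res, truth = truth))
}

#' Generate a qRT-PCR Ct-table fixture
#'
#' For each line with true relative expression `e`, technical-replicate Ct
#' values are drawn as `baseline_ct + N(0, sigma)` for the reference gene
#' and `baseline_ct - log2(e) + N(0, sigma)` for the target, in the standard
#' 3 biological x 3 technical layout. With `sigma = 0` the planted fold
#' changes are recovered exactly.
#'
#' @inheritParams make_mix_fixture
#' @param expression Named numeric vector of true relative expression per
#'   line. The default emulates a standard maize line, a full-strength
#'   barrier line, a silenced lineage, and a partial mop1 revertant at
#'   400-fold the standard line / 8-fold the silenced lineage.
#' @param sigma Technical-replicate Ct noise SD (cycles). Default 0.2.
#' @param baseline_ct Reference-gene Ct. Default 20.
#' @return Invisibly, `paths`, `data` (the Ct table), `truth`.
#' @export
make_qpcr_fixture <- function(out_dir, seed = 1L,
                              expression = c("W22" = 0.001, "Tcb1-s" = 1,
                                             "tcb1-f_sl2" = 0.05,
                                             "mop1_revertant" = 0.4),
                              sigma = 0.2, baseline_ct = 20) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (any(expression <= 0) || is.null(names(expression))) {
    stop("expression must be a named vector of positive fold changes")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.fixture_seed(seed, "qpcr"))
  grid <- expand.grid(technical_rep = 1:3, biological_rep = 1:3,
                      gene = c("target", "reference"),
                      line_name = names(expression),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mean_ct <- ifelse(grid$gene == "reference", baseline_ct,
                    baseline_ct - log2(expression[grid$line_name]))
  grid$ct <- mean_ct + stats::rnorm(nrow(grid), 0, sigma)
  grid$sample_id <- sprintf("%s_b%d_t%d_%s", grid$line_name,
                            grid$biological_rep, grid$technical_rep,
                            substr(grid$gene, 1, 3))
  ct <- grid[, c("sample_id", "line_name", "gene", "biological_rep",
                 "technical_rep", "ct")]
  spec <- sprintf("design=qpcr seed=%d sigma=%g baseline_ct=%g lines=%s",
                  seed, sigma, baseline_ct,
                  paste(sprintf("%s:%g", names(expression), expression),
                        collapse = ","))
  path <- file.path(out_dir, "qpcr_ct.tsv")
  write_ct_table(ct, path, header_lines = spec)
  truth <- list(design = "qpcr", seed = seed, sigma = sigma,
                baseline_ct = baseline_ct, expression = as.list(expression))
  truth_path <- .write_truth(truth, out_dir, "qpcr")
  invisible(list(paths = c(ct = path, truth = truth_path),
                 data = ct, truth = truth))
}

#' Generate an aligned sequence-pair fixture with planted substitutions
#'
#' Draws a random coding-length nucleotide sequence and plants exactly
#' `n_sub` substitutions (and optionally `n_gaps` gap columns) to produce an
#' aligned pair, written as a two-record FASTA whose headers embed the
#' generating parameters.
#'
#' @inheritParams make_mix_fixture
#' @param length Alignment length in nucleotides. Default 1296.
#' @param n_sub Number of substituted positions. Default 15.
#' @param n_gaps Number of gap columns introduced into the second sequence.
#'   Default 0.
#' @return Invisibly, `paths`, `data` (named character vector of the two
#'   sequences), `truth`.
#' @export
make_seqpair_fixture <- function(out_dir, seed = 1L, length = 1296L,
                                 n_sub = 15L, n_gaps = 0L) {
  if (n_sub + n_gaps > length) {
    stop("n_sub + n_gaps exceeds the alignment length: impossible spec")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.fixture_seed(seed, "seqpair"))
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, length, replace = TRUE)
  b <- a
  touched <- sample.int(length, n_sub + n_gaps)
  sub_pos <- sort(touched[seq_len(n_sub)])
  gap_pos <- sort(touched[seq_len(n_gaps) + n_sub])
  for (i in sub_pos) b[i] <- sample(setdiff(bases, a[i]), 1L)
  b[gap_pos] <- "-"
  seqs <- Biostrings::BStringSet(c(paste(a, collapse = ""),
                                   paste(b, collapse = "")))
  names(seqs) <- c(
    sprintf("synthetic_target design=seqpair seed=%d length=%d", seed, length),
    sprintf("synthetic_homolog n_sub=%d n_gaps=%d", n_sub, n_gaps)
  )
  path <- file.path(out_dir, "seqpair_synthetic.fa")
  Biostrings::writeXStringSet(seqs, path)
  truth <- list(design = "seqpair", seed = seed, length = length,
                n_sub = n_sub, n_gaps = n_gaps,
                substituted_positions = sub_pos, gap_positions = gap_pos)
  truth_path <- .write_truth(truth, out_dir, "seqpair")
  invisible(list(paths = c(fasta = path, truth = truth_path),
                 data = stats::setNames(as.character(seqs),
                                        c("synthetic_target",
                                          "synthetic_homolog")),
                 truth = truth))
}

#' Generate a fixture by design name
#'
#' Dispatcher over the five fixture designs:
#' `"mixed_pollination"`, `"screen"`, `"reversion"`, `"qpcr"`, `"seqpair"`.
#'
#' @param design Design name.
#' @param out_dir Output directory.
#' @param seed Fixture seed.
#' @param ... Design-specific parameters, forwarded to the `make_*_fixture`
#'   function.
#' @return The invisible result of the dispatched generator.
#' @export
make_fixture <- function(design, out_dir, seed = 1L, ...) {
  .fixture_seed(seed, design)  # validates the design name
  switch(design,
    mixed_pollination = make_mix_fixture(out_dir, seed = seed, ...),
    screen            = make_screen_fixture(out_dir, seed = seed, ...),
    reversion         = make_reversion_fixture(out_dir, seed = seed, ...),
    qpcr              = make_qpcr_fixture(out_dir, seed = seed, ...),
    seqpair           = make_seqpair_fixture(out_dir, seed = seed, ...)
  )
}
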