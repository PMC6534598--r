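# Plain-text interchange: TSV tables for ear counts, plant genotypes and Ct
# measurements. Files may begin with "#" comment lines recording how they
# were generated; readers skip them.

.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0L) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read ear-count tables
#'
#' Ear counts are exchanged as TSV with one row per ear; any columns beyond
#' the counts (ground truth, classifications) round-trip unchanged. Comment
#' lines starting with `#` may record provenance and are skipped on read.
#'
#' @param ears Data.frame of ear counts.
#' @param path File path.
#' @param header_lines Optional character vector written as `#` comments.
#' @return `write_ear_counts` returns `path` invisibly; `read_ear_counts`
#'   the data.frame.
#' @export
write_ear_counts <- function(ears, path, header_lines = character()) {
  stopifnot(is.data.frame(ears))
  .write_tsv(ears, path, header_lines)
}

#' @rdname write_ear_counts
#' @export
read_ear_counts <- function(path) {
  ears <- .read_tsv(path)
  counts <- intersect(c("n_purple", "n_yellow", "n_sugary", "n_total"),
                      names(ears))
  if (length(counts) == 0L) {
    stop("no kernel-count columns found in ", path)
  }
  for (col in counts) {
    if (any(ears[[col]] < 0)) stop("negative counts in column ", col)
  }
  if (all(c("n_total", "n_sugary") %in% names(ears)) &&
      any(ears$n_sugary > ears$n_total)) {
    stop("n_sugary exceeds n_total")
  }
  ears
}

#' Read a plant genotype table
#'
#' One row per plant with columns `plant_id`, `hap1`, `hap2`, `su1_1`,
#' `su1_2`, `r`, `mop1`, `expr1`, `expr2`. Haplotype names are validated
#' bit-exactly against the four-name vocabulary (see [haplotype_info()]).
#'
#' @param path TSV file path.
#' @return A named list of [plant_genotype()] objects keyed by `plant_id`.
#' @export
read_genotype_table <- function(path) {
  tab <- .read_tsv(path)
  need <- c("plant_id", "hap1", "hap2", "su1_1", "su1_2", "r", "mop1",
            "expr1", "expr2")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("genotype table is missing columns: ", paste(missing, collapse = ", "))
  }
  plants <- lapply(seq_len(nrow(tab)), function(i) {
    plant_genotype(tab$hap1[i], tab$hap2[i],
                   su1 = c(tab$su1_1[i], tab$su1_2[i]),
                   r = tab$r[i], mop1 = tab$mop1[i],
                   expression = c(tab$expr1[i], tab$expr2[i]))
  })
  names(plants) <- tab$plant_id
  plants
}

#' Write / read qRT-PCR Ct tables
#'
#' Long-format Ct measurements: `sample_id`, `line_name`, `gene`
#' (`"target"`/`"reference"`), `biological_rep`, `technical_rep`, `ct`.
#'
#' @param ct Data.frame of Ct measurements.
#' @param path File path.
#' @param header_lines Optional `#` comment lines.
#' @return `write_ct_table` returns `path` invisibly; `read_ct_table` the
#'   validated data.frame.
#' @export
write_ct_table <- function(ct, path, header_lines = character()) {
  .check_ct_table(ct)
  .write_tsv(ct, path, header_lines)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  .check_ct_table(.read_tsv(path))
}
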