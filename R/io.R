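# Plain TSV input/output for the pipeline's tables.

#' Read a count matrix and sample sheet from TSV
#'
#' The counts file has a header `feature_id  length_bp  <sample columns>`;
#' the sample sheet maps `sample_id` to `condition` and `replicate`.
#'
#' @param counts_path,samples_path input paths.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, setdiff(names(tab), c("feature_id", "length_bp")),
                          drop = FALSE])
  rownames(counts) <- tab$feature_id
  count_matrix(counts, tab$length_bp, samples)
}

#' Write a count matrix and sample sheet to TSV
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output paths.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  tab <- data.frame(feature_id = rownames(cm$counts),
                    length_bp = cm$length_bp, cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a PSM table (and optional channel map) from TSV
#'
#' Expects columns `protein_id  peptide_seq  spectrum_id  rank  q_value
#' interference_pct  ch1..chN`.
#'
#' @param path PSM TSV path.
#' @param channel_map_path optional TSV with `channel`, `condition`,
#'   `replicate`; attached as the `channel_map` attribute.
#' @return PSM data frame.
#' @export
read_psm_table <- function(path, channel_map_path = NULL) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(channel_map_path))
    attr(psms, "channel_map") <-
      utils::read.delim(channel_map_path, stringsAsFactors = FALSE)
  psms
}

#' Write a PSM table (and its channel map) to TSV
#'
#' @param psms PSM data frame.
#' @param path output path.
#' @param channel_map_path optional output path for the channel map.
#' @export
write_psm_table <- function(psms, path, channel_map_path = NULL) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cm <- attr(psms, "channel_map")
  if (!is.null(channel_map_path) && !is.null(cm))
    utils::write.table(cm, channel_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a raw sequencing-QC table from TSV
#'
#' Columns `sample_id`, `total_reads`, `mapped_reads`, `mapped_wo_dup`,
#' `properly_paired` (all in units of 10^6 reads) and optionally `lane`
#' and `group`; the package ships the read accounting of the motivating
#' 24-library HiSeq run as
#' `system.file("extdata", "rnaseq_qc_readcounts.tsv", package =
#' "crossomics")`.
#'
#' @param path input path.
#' @return data frame suitable for [qc_summary()].
#' @export
read_qc_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
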