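#' Read annotated protein records from FASTA + segment table
#'
#' Sequences come from a FASTA file; transmembrane annotation from a TSV with
#' columns `id`, `start`, `end` (1-based inclusive, one row per segment).
#' Sequences without a row in the table are returned unannotated.
#'
#' @param fasta Path to a protein FASTA file.
#' @param segments Path to the segment TSV, or `NULL` for no annotation.
#' @return Named list of [protein_record()] objects.
#' @export
read_protein_records <- function(fasta, segments = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seg_tab <- if (is.null(segments)) NULL else read_segment_table(segments)
  recs <- lapply(seq_along(seqs), function(i) {
    seg <- if (!is.null(seg_tab)) {
      s <- seg_tab[seg_tab$id == ids[i], c("start", "end"), drop = FALSE]
      if (nrow(s)) s else NULL
    } else NULL
    desc <- sub("^\\S+\\s*", "", names(seqs)[i])
    protein_record(ids[i], as.character(seqs[[i]]), seg, desc)
  })
  setNames(recs, ids)
}

#' Read a TM segment table
#'
#' Plain TSV `id<TAB>start<TAB>end`, 1-based inclusive, with or without a
#' header line.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `id`, `start`, `end`.
#' @export
read_segment_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\\b", first)
  tab <- read.delim(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:3] <- c("id", "start", "end")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab[, c("id", "start", "end")]
}

#' Write QTY analog sequences as FASTA
#'
#' Analog IDs get the suffix `_QTY`.
#'
#' @param results List of `qty_result` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_analog_fasta <- function(results, path) {
  seqs <- Biostrings::AAStringSet(
    vapply(results, function(r) r$analog_sequence, character(1)))
  names(seqs) <- vapply(results, function(r) paste0(r$native$id, "_QTY"),
                        character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tabulate QTY sequence characteristics
#'
#' One row per subunit with the columns of a native-vs-analog characteristics
#' table: isoelectric point and molecular weight for both sequences, and the
#' overall and TM variation percentages.
#'
#' @param results List of `qty_result` objects.
#' @return data.frame with columns `id`, `pI`, `pI_QTY`, `MW`, `MW_QTY`,
#'   `total_variation_pct`, `tm_variation_pct`.
#' @export
characteristics_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(id = r$native$id,
               pI = round(r$native_pi, 2),
               pI_QTY = round(r$analog_pi, 2),
               MW = round(r$native_mw, 2),
               MW_QTY = round(r$analog_mw, 2),
               total_variation_pct = r$overall_variation_pct,
               tm_variation_pct = r$tm_variation_pct,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
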