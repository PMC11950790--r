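# The QTY substitution map: hydrophobic -> structurally analogous hydrophilic.
QTY_MAP <- c(L = "Q", I = "T", V = "T", F = "Y")

#' Apply the QTY code to an annotated sequence
#'
#' Replaces hydrophobic residues with their hydrophilic structural analogs
#' (L with Q, I and V with T, F with Y). By default substitutions are
#' confined to the annotated transmembrane segments, where the hydrophobic
#' residues face the lipid bilayer; `scope = "whole_sequence"` converts every
#' position.
#'
#' @param record A [protein_record()].
#' @param scope `"tm_only"` (default) or `"whole_sequence"`.
#' @return An object of class `qty_result`: the native record, the analog
#'   sequence, a data.frame of substitutions (`position`, `from`, `to`),
#'   variation percentages (overall and within-TM, both rounded to 2
#'   decimals), and molecular weight / isoelectric point of native and
#'   analog.
#' @examples
#' rec <- protein_record("toy", "LIVF", tm_segments = cbind(1, 4))
#' res <- apply_qty_code(rec)
#' res$analog_sequence       # "QTTY"
#' res$substitutions
#' @seealso [variation_percentages()], [render_alignment()]
#' @export
apply_qty_code <- function(record, scope = c("tm_only", "whole_sequence")) {
  stopifnot(inherits(record, "protein_record"))
  scope <- match.arg(scope)
  aa <- strsplit(record$sequence, "")[[1]]
  if (scope == "tm_only") {
    if (nrow(record$tm_segments) == 0L)
      stop(sprintf(
        "record '%s' has no TM annotation; apply_qty_code(scope = \"tm_only\") requires at least one segment",
        record$id), call. = FALSE)
    in_scope <- tm_mask(record)
  } else {
    in_scope <- rep(TRUE, length(aa))
  }
  sub_idx <- which(in_scope & aa %in% names(QTY_MAP))
  analog <- aa
  analog[sub_idx] <- QTY_MAP[aa[sub_idx]]
  analog_seq <- paste(analog, collapse = "")
  subs <- data.frame(position = sub_idx,
                     from = aa[sub_idx],
                     to = unname(QTY_MAP[aa[sub_idx]]),
                     stringsAsFactors = FALSE)
  res <- structure(list(
    native = record,
    analog_sequence = analog_seq,
    substitutions = subs,
    scope = scope,
    native_mw = molecular_weight(record$sequence),
    analog_mw = molecular_weight(analog_seq),
    native_pi = isoelectric_point(record$sequence),
    analog_pi = isoelectric_point(analog_seq)
  ), class = "qty_result")
  vp <- variation_percentages(res)
  res$overall_variation_pct <- vp$overall_pct
  res$tm_variation_pct <- vp$tm_pct
  res
}

#' Overall and transmembrane variation percentages
#'
#' Overall variation is the number of substitutions over the full sequence
#' length; TM variation is the number of substitutions inside TM segments
#' over the total number of TM residues. Both are percentages rounded to two
#' decimals (round-half-even).
#'
#' @param result A `qty_result` from [apply_qty_code()].
#' @return List with `overall_pct` and `tm_pct`. If the record carries no TM
#'   annotation, `tm_pct` is `NA` with a warning rather than a silent 0.
#' @export
variation_percentages <- function(result) {
  stopifnot(inherits(result, "qty_result"))
  n <- nchar(result$native$sequence)
  overall <- round(100 * nrow(result$substitutions) / n, 2)
  mask <- tm_mask(result$native)
  n_tm <- sum(mask)
  if (n_tm == 0L) {
    warning("no TM residues: tm_pct is undefined (NA)")
    tm <- NA_real_
  } else {
    tm <- round(100 * sum(mask[result$substitutions$position]) / n_tm, 2)
  }
  list(overall_pct = overall, tm_pct = tm)
}

#' Invert a QTY result back to the native sequence
#'
#' Reconstructs the native sequence from the analog sequence and the recorded
#' substitution list; used to verify that the substitution record is a
#' complete, lossless account of the conversion.
#'
#' @param result A `qty_result`.
#' @return The native sequence (character scalar).
#' @export
reverse_qty <- function(result) {
  stopifnot(inherits(result, "qty_result"))
  aa <- strsplit(result$analog_sequence, "")[[1]]
  aa[result$substitutions$position] <- result$substitutions$from
  paste(aa, collapse = "")
}

#' @export
print.qty_result <- function(x, ...) {
  cat(sprintf("<qty_result> %s: %d substitution(s), overall %.2f%%, TM %s%%\n",
              x$native$id, nrow(x$substitutions), x$overall_variation_pct,
              ifelse(is.na(x$tm_variation_pct), "NA",
                     sprintf("%.2f", x$tm_variation_pct))))
  cat(sprintf("  MW %.2f -> %.2f Da; pI %.2f -> %.2f\n",
              x$native_mw, x$analog_mw, x$native_pi, x$analog_pi))
  invisible(x)
}

#' Render a native-vs-analog sequence alignment
#'
#' Text alignment in three-line blocks: native sequence, marker line, analog
#' sequence. `|` marks identical positions and `*` substituted ones. With
#' `annotate_tm = TRUE` a fourth line above each block marks TM positions
#' with `H` (helix).
#'
#' @param native A [protein_record()].
#' @param analog_sequence Analog sequence of equal length.
#' @param width Block width in columns (default 60).
#' @param annotate_tm Mark TM segments above each block.
#' @return A character scalar (lines joined by newline), invisibly printable
#'   with `cat()`.
#' @export
render_alignment <- function(native, analog_sequence, width = 60,
                             annotate_tm = FALSE) {
  stopifnot(inherits(native, "protein_record"))
  n <- nchar(native$sequence)
  if (nchar(analog_sequence) != n)
    stop(sprintf("length mismatch: native %d vs analog %d",
                 n, nchar(analog_sequence)))
  a <- strsplit(native$sequence, "")[[1]]
  b <- strsplit(analog_sequence, "")[[1]]
  marker <- ifelse(a == b, "|", "*")
  tm <- if (annotate_tm) ifelse(tm_mask(native), "H", " ") else NULL
  starts <- seq(1L, n, by = width)
  blocks <- vapply(starts, function(s) {
    e <- min(s + width - 1L, n)
    lines <- c(
      if (annotate_tm) paste(tm[s:e], collapse = ""),
      paste(a[s:e], collapse = ""),
      paste(marker[s:e], collapse = ""),
      paste(b[s:e], collapse = "")
    )
    paste(lines, collapse = "\n")
  }, character(1))
  paste(blocks, collapse = "\n\n")
}
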