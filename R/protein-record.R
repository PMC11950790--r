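#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table head tail
NULL

AA1 <- c("A","R","N","D","C","E","Q","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Construct an annotated protein record
#'
#' Bundles a one-letter amino-acid sequence with its transmembrane (TM)
#' segment annotation. Segment coordinates are 1-based inclusive residue
#' indices, the convention used throughout the package (and by UniProt
#' `TRANSMEM` features, the expected source of the annotation).
#'
#' @param id Accession or subunit name (e.g. `"NDUA1"`).
#' @param sequence Character scalar over the 20 canonical one-letter codes.
#' @param tm_segments Two-column matrix/data.frame of `(start, end)` residue
#'   intervals, 1-based inclusive, or `NULL` for an unannotated sequence.
#' @param description Optional free-text description.
#'
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `tm_segments` (a data.frame with columns `start`, `end`, sorted,
#'   non-overlapping) and `description`.
#' @examples
#' rec <- protein_record("toy", "MLLIVFAGKR", tm_segments = cbind(2, 7))
#' rec
#' @export
protein_record <- function(id, sequence, tm_segments = NULL, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  bad <- which(!strsplit(sequence, "")[[1]] %in% AA1)
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 substr(sequence, bad[1], bad[1]), bad[1], id))
  }
  n <- nchar(sequence)
  if (is.null(tm_segments) || NROW(tm_segments) == 0L) {
    seg <- data.frame(start = integer(0), end = integer(0))
  } else {
    seg <- as.data.frame(tm_segments)[, 1:2]
    names(seg) <- c("start", "end")
    seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
    if (any(is.na(seg$start)) || any(is.na(seg$end)))
      stop("TM segment bounds must be integers")
    if (any(seg$start < 1L) || any(seg$end > n) || any(seg$end < seg$start))
      stop(sprintf("TM segments must satisfy 1 <= start <= end <= %d", n))
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      stop("TM segments must be non-overlapping")
    rownames(seg) <- NULL
  }
  structure(list(id = id, sequence = sequence, tm_segments = seg,
                 description = description),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, %d TM segment(s)\n",
              x$id, nchar(x$sequence), nrow(x$tm_segments)))
  if (nrow(x$tm_segments))
    cat("  TM:", paste(sprintf("%d-%d", x$tm_segments$start, x$tm_segments$end),
                       collapse = ", "), "\n")
  invisible(x)
}

# logical mask over residue positions covered by TM segments
tm_mask <- function(record) {
  m <- rep(FALSE, nchar(record$sequence))
  for (i in seq_len(nrow(record$tm_segments)))
    m[record$tm_segments$start[i]:record$tm_segments$end[i]] <- TRUE
  m
}
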