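# alphabets used by the generator: TM cores are enriched in the four
# QTY-substitutable hydrophobics; everything else is drawn from a polar set
# that deliberately excludes L/I/V/F so the hydrophobic bias is exact
SYNTH_HYDROPHOBIC <- c("L", "I", "V", "F")
SYNTH_POLAR <- c("S", "T", "N", "Q", "G", "A", "D", "E", "K", "R", "H", "P")

#' Generate an annotated TM-like sequence
#'
#' Random sequence whose TM segments are enriched in the QTY-substitutable
#' hydrophobics (L, I, V, F) at probability `hydrophobic_bias`, with loops
#' drawn from a polar alphabet. Deterministic for a fixed seed.
#'
#' @param id Record identifier.
#' @param length Total sequence length.
#' @param tm_fraction Fraction of residues inside TM segments (default 0.4).
#' @param n_segments Number of TM segments (default 2).
#' @param hydrophobic_bias Probability that a TM position is L/I/V/F
#'   (default 0.7, a typical TM hydrophobic density).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A [protein_record()].
#' @export
make_tm_sequence <- function(id = "synthetic", length = 120L,
                             tm_fraction = 0.4, n_segments = 2L,
                             hydrophobic_bias = 0.7, seed = NULL) {
  stopifnot(length >= 10L, tm_fraction > 0, tm_fraction <= 1,
            hydrophobic_bias >= 0, hydrophobic_bias <= 1, n_segments >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tm_total <- max(n_segments, round(length * tm_fraction))
  seg_len <- rep(tm_total %/% n_segments, n_segments)
  seg_len[seq_len(tm_total %% n_segments)] <-
    seg_len[seq_len(tm_total %% n_segments)] + 1L
  gap <- (length - tm_total) %/% (n_segments + 1L)
  starts <- integer(n_segments); pos <- gap + 1L
  for (i in seq_len(n_segments)) {
    starts[i] <- pos
    pos <- pos + seg_len[i] + gap
  }
  seg <- data.frame(start = starts, end = starts + seg_len - 1L)
  aa <- sample(SYNTH_POLAR, length, replace = TRUE)
  for (i in seq_len(n_segments)) {
    idx <- seg$start[i]:seg$end[i]
    hydro <- stats::runif(length(idx)) < hydrophobic_bias
    aa[idx][hydro] <- sample(SYNTH_HYDROPHOBIC, sum(hydro), replace = TRUE)
    aa[idx][!hydro] <- sample(SYNTH_POLAR, sum(!hydro), replace = TRUE)
  }
  protein_record(id, paste(aa, collapse = ""), seg,
                 description = sprintf("synthetic TM sequence (bias %.2f)",
                                       hydrophobic_bias))
}

#' Ideal alpha-helix coordinates
#'
#' Schematic helix along +z: backbone (N, CA, C, O) and a CB pseudo-atom on
#' an ideal helical wheel with the canonical 1.5 A rise and 100 degree twist
#' per residue (consecutive CA-CA distance about 3.8 A). Geometry is
#' deterministic and regular; it is a fixture for superposition and scoring
#' tests, not a physical model.
#'
#' @param n_residues Number of residues (>= 4).
#' @param rise Rise per residue, angstroms.
#' @param twist Twist per residue, degrees.
#' @param sequence Optional one-letter sequence of length `n_residues` for
#'   residue names (default poly-alanine).
#' @param chain Chain ID.
#' @param start_resno First author residue number.
#' @return A `structure_model` with `source = "synthetic"`.
#' @export
make_helix <- function(n_residues, rise = 1.5, twist = 100,
                       sequence = NULL, chain = "A", start_resno = 1L) {
  stopifnot(n_residues >= 4L)
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  stopifnot(nchar(sequence) == n_residues)
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  name3 <- setNames(names(AA3), AA3)
  if (anyNA(name3[aa1])) stop("non-canonical residue in helix sequence")
  # cylindrical placement per atom: radius, phase offset (deg), z offset
  geom <- rbind(N  = c(1.56, -27, -0.90),
                CA = c(2.30,   0,  0.00),
                C  = c(1.64,  27,  0.90),
                O  = c(2.80,  27,  1.10),
                CB = c(3.30, -10, -0.25))
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    phi0 <- (i - 1L) * twist * pi / 180
    z0 <- (i - 1L) * rise
    atoms <- if (aa1[i] == "G") c("N", "CA", "C", "O") else rownames(geom)
    g <- geom[atoms, , drop = FALSE]
    phi <- phi0 + g[, 2] * pi / 180
    rows[[i]] <- data.frame(
      chain = chain, resno = start_resno + i - 1L, insert = "",
      resid = unname(name3[aa1[i]]), elety = atoms,
      element = unname(elem[atoms]),
      x = g[, 1] * cos(phi), y = g[, 1] * sin(phi), z = z0 + g[, 3],
      o = 1, stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), model_id = "helix",
                  source = "synthetic")
}

rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a toy multi-chain complex with ground truth
#'
#' The native complex packs parallel ideal helices on a line with 10 A axis
#' spacing, so adjacent chains are in heavy-atom contact. The model is the
#' native under a named perturbation, and the returned truth record carries
#' the exact transform / noise / deletions so downstream expectations (RMSD,
#' LRMS, correspondence trimming) are computable without re-generation.
#'
#' Perturbation types:
#' * `rigid`: whole-model rotation about z (`angle_deg`) plus `shift`.
#' * `gaussian`: iid normal noise, `sigma` angstroms per coordinate.
#' * `ligand_shift`: rigid translation of the last chain only, by `shift`.
#' * `loop_deletion`: deletes `fraction` of residues from the *native*
#'   (emulating unmodelled CryoEM loops); the model keeps all residues.
#'
#' @param n_chains Number of chains (default 3).
#' @param n_residues Residues per chain (default 30).
#' @param perturbation List with a `type` field and type-specific fields,
#'   e.g. `list(type = "gaussian", sigma = 0.5)`.
#' @param hydrophobic_bias TM hydrophobic enrichment of the chain sequences.
#' @param seed Integer seed.
#' @return List: `native`, `model` (both `structure_model`), `truth` (the
#'   perturbation parameters, per-chain sequences and any deleted residues).
#' @export
make_toy_complex <- function(n_chains = 3L, n_residues = 30L,
                             perturbation = list(type = "rigid",
                                                 angle_deg = 30,
                                                 shift = c(5, 0, 0)),
                             hydrophobic_bias = 0.7, seed = 1L) {
  stopifnot(n_chains >= 2L, n_residues >= 4L)
  if (!is.null(seed)) set.seed(seed)
  chains <- LETTERS[seq_len(n_chains)]
  parts <- vector("list", n_chains)
  seqs <- character(n_chains)
  for (i in seq_len(n_chains)) {
    hydro <- stats::runif(n_residues) < hydrophobic_bias
    aa <- character(n_residues)
    aa[hydro] <- sample(SYNTH_HYDROPHOBIC, sum(hydro), replace = TRUE)
    aa[!hydro] <- sample(SYNTH_POLAR, sum(!hydro), replace = TRUE)
    seqs[i] <- paste(aa, collapse = "")
    h <- make_helix(n_residues, sequence = seqs[i], chain = chains[i])
    h <- transform_model(h, diag(3), c(10 * (i - 1L), 0, 0))
    parts[[i]] <- h$atoms
  }
  native <- structure_model(do.call(rbind, parts), model_id = "toy_native",
                            source = "synthetic")
  truth <- list(perturbation = perturbation, sequences = setNames(seqs, chains))
  model <- native
  model$model_id <- "toy_model"
  if (perturbation$type == "rigid") {
    R <- rotation_z(perturbation$angle_deg)
    model <- transform_model(model, R, perturbation$shift)
    truth$rotation <- R; truth$translation <- perturbation$shift
  } else if (perturbation$type == "gaussian") {
    sigma <- perturbation$sigma
    xyz <- as_xyz(model$atoms) +
      matrix(stats::rnorm(3L * nrow(model$atoms), sd = sigma), ncol = 3L)
    model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
    truth$sigma <- sigma
    n <- nrow(model$atoms)
    truth$expected_rmsd <- sigma * sqrt((3 * n - 6) / n)
  } else if (perturbation$type == "ligand_shift") {
    lig <- chains[n_chains]
    sel <- model$atoms$chain == lig
    model$atoms$x[sel] <- model$atoms$x[sel] + perturbation$shift[1]
    model$atoms$y[sel] <- model$atoms$y[sel] + perturbation$shift[2]
    model$atoms$z[sel] <- model$atoms$z[sel] + perturbation$shift[3]
    truth$ligand_chain <- lig
    truth$expected_lrms <- sqrt(sum(perturbation$shift^2))
  } else if (perturbation$type == "loop_deletion") {
    res <- unique(native$atoms[, c("chain", "resno")])
    n_del <- floor(nrow(res) * perturbation$fraction)
    del <- res[sample(nrow(res), n_del), , drop = FALSE]
    keep <- !paste(native$atoms$chain, native$atoms$resno) %in%
      paste(del$chain, del$resno)
    native$atoms <- native$atoms[keep, , drop = FALSE]
    truth$deleted_residues <- del[order(del$chain, del$resno), ]
    rownames(truth$deleted_residues) <- NULL
  } else {
    stop(sprintf("unknown perturbation type '%s'", perturbation$type))
  }
  list(native = native, model = model, truth = truth)
}
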