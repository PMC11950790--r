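# Bondi-style van der Waals radii (angstroms) for elements seen in protein
# heavy atoms; configurable through the `vdw` argument.
VDW_DEFAULT <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
                 SE = 1.90)

# residues whose side chains face the lipid in TM helices
HYDROPHOBIC_SET_DEFAULT <- c("L", "I", "V", "F", "M", "W", "A")

# deterministic near-uniform points on the unit sphere (golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere-point sampling: each atom's sphere
#' (vdW radius plus probe) carries a golden-spiral point set, and the
#' accessible fraction is the share of points outside every neighbouring
#' expanded sphere. Atom areas are summed per residue.
#'
#' @param model A `structure_model` (heavy atoms; hydrogens, if present, are
#'   ignored).
#' @param probe_radius Probe (water) radius, angstroms (default 1.4).
#' @param n_sphere_points Quadrature points per atom (default 960; >= 100).
#' @param vdw Named element -> radius vector (angstroms).
#' @return A `surface_report`: `per_residue` data.frame (`chain`, `resno`,
#'   `insert`, `resid`, `sasa`), `per_atom` vector, `total_sasa` (A^2), and
#'   the parameters used.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4,
                               n_sphere_points = 960, vdw = VDW_DEFAULT) {
  stopifnot(inherits(model, "structure_model"), n_sphere_points >= 100)
  a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  unknown <- setdiff(unique(a$element), names(vdw))
  if (length(unknown))
    stop(sprintf("no vdW radius for element(s): %s",
                 paste(unknown, collapse = ", ")))
  n <- nrow(a)
  xyz <- as_xyz(a)
  rad <- unname(vdw[a$element]) + probe_radius
  pts <- golden_spiral_points(n_sphere_points)
  sasa <- numeric(n)
  max_rad <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + max_rad)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    if (!length(nb)) {
      sasa[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(sp[free, , drop = FALSE], 2L, xyz[j, ])^2)
      free[free] <- dj >= rad[j]^2
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(free) / n_sphere_points
  }
  res_key <- paste(a$chain, a$resno, a$insert)
  per_res <- unique(a[, c("chain", "resno", "insert", "resid")])
  per_res$sasa <- as.numeric(
    tapply(sasa, factor(res_key, levels = unique(res_key)), sum))
  rownames(per_res) <- NULL
  structure(list(per_residue = per_res, per_atom = sasa,
                 total_sasa = sum(sasa), probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "surface_report")
}

#' Hydrophobic fraction of the solvent-accessible surface
#'
#' SASA of hydrophobic residues over total SASA, optionally restricted to
#' annotated TM residues (the membrane-facing region of interest; the
#' extramembrane surface is then disregarded).
#'
#' @param report A `surface_report` from [shrake_rupley_sasa()].
#' @param hydrophobic_set One-letter codes counted as hydrophobic (default
#'   L, I, V, F, M, W, A; add `"P"` to reproduce a broader Type-II helix
#'   definition).
#' @param tm_residues Optional data.frame (`chain`, `resno`) of TM residues;
#'   when given, both numerator and denominator are restricted to it.
#' @return List: `fraction`, `hydrophobic_sasa`, `total_sasa` (over the
#'   selected residues). An empty selection is an error, not a silent 0.
#' @export
hydrophobic_fraction <- function(report,
                                 hydrophobic_set = HYDROPHOBIC_SET_DEFAULT,
                                 tm_residues = NULL) {
  stopifnot(inherits(report, "surface_report"))
  pr <- report$per_residue
  if (!is.null(tm_residues)) {
    keep <- paste(pr$chain, pr$resno) %in%
      paste(tm_residues$chain, tm_residues$resno)
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr) == 0L)
      stop("TM mask selects no residues: hydrophobic fraction undefined")
  }
  aa1 <- unname(AA3[pr$resid])
  if (anyNA(aa1))
    stop(sprintf("non-standard residue name(s): %s",
                 paste(unique(pr$resid[is.na(aa1)]), collapse = ", ")))
  total <- sum(pr$sasa)
  hydro <- sum(pr$sasa[aa1 %in% hydrophobic_set])
  list(fraction = if (total > 0) hydro / total else NA_real_,
       hydrophobic_sasa = hydro, total_sasa = total)
}

#' Relabel residues of a structure according to a QTY conversion
#'
#' Renames substituted residues (keeping coordinates fixed) so that
#' surface-composition changes attributable purely to the substitution can
#' be isolated from conformational change.
#'
#' @param model A `structure_model` with a single relevant chain numbering.
#' @param qty A `qty_result`; substitution positions are matched to residue
#'   numbers via `resno_offset` (author number = position + offset).
#' @param chain Chain to relabel (default: all chains).
#' @param resno_offset Offset from sequence position to author residue
#'   number (default 0).
#' @return The relabelled `structure_model`.
#' @export
relabel_qty <- function(model, qty, chain = NULL, resno_offset = 0L) {
  stopifnot(inherits(model, "structure_model"), inherits(qty, "qty_result"))
  name3 <- setNames(names(AA3), AA3)
  sel <- if (is.null(chain)) rep(TRUE, nrow(model$atoms)) else
    model$atoms$chain %in% chain
  for (k in seq_len(nrow(qty$substitutions))) {
    pos <- qty$substitutions$position[k] + resno_offset
    hit <- sel & model$atoms$resno == pos
    model$atoms$resid[hit] <- name3[[qty$substitutions$to[k]]]
  }
  model
}
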