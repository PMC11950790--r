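BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# all heavy-atom distances between two atom tables below a cutoff, returned
# as residue-number pairs; cross distance matrix is computed in blocks to
# bound memory on large chains
residue_contact_pairs <- function(atoms_a, atoms_b, cutoff) {
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L || cutoff <= 0)
    return(data.frame(resno_a = integer(0), resno_b = integer(0)))
  xa <- as_xyz(atoms_a); xb <- as_xyz(atoms_b)
  hits_a <- integer(0); hits_b <- integer(0)
  block <- 2000L
  for (s in seq(1L, nrow(xa), by = block)) {
    e <- min(s + block - 1L, nrow(xa))
    d2 <- outer(rowSums(xa[s:e, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * tcrossprod(xa[s:e, , drop = FALSE], xb)
    idx <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(idx)) {
      hits_a <- c(hits_a, atoms_a$resno[s:e][idx[, 1]])
      hits_b <- c(hits_b, atoms_b$resno[idx[, 2]])
    }
  }
  unique(data.frame(resno_a = hits_a, resno_b = hits_b))
}

#' Inter-chain residue contacts
#'
#' Residue pairs across two chains with any heavy-atom distance below the
#' cutoff — the native-contact definition underlying Fnat.
#'
#' @param model A `structure_model`.
#' @param chain_a,chain_b Chain IDs.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 5.0).
#' @return A `contact_set`: data.frame `pairs` (`resno_a`, `resno_b`) plus
#'   the cutoff and chain IDs as attributes. An empty set is allowed.
#' @export
native_contacts <- function(model, chain_a, chain_b, cutoff = 5.0) {
  stopifnot(inherits(model, "structure_model"))
  aa <- get_atoms(model, chain = chain_a, heavy_only = TRUE)
  ab <- get_atoms(model, chain = chain_b, heavy_only = TRUE)
  if (nrow(aa) == 0L) stop(sprintf("chain '%s' missing from model", chain_a))
  if (nrow(ab) == 0L) stop(sprintf("chain '%s' missing from model", chain_b))
  pairs <- residue_contact_pairs(aa, ab, cutoff)
  pairs <- pairs[order(pairs$resno_a, pairs$resno_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, cutoff = cutoff,
                 chain_a = chain_a, chain_b = chain_b),
            class = "contact_set")
}

#' Fraction of native contacts preserved in a model
#'
#' @param native,model `contact_set` objects for the same chain pair.
#' @return `|native intersect model| / |native|`. An empty native set is an
#'   error: the interface is not scoreable, not a 0.
#' @export
fnat <- function(native, model) {
  stopifnot(inherits(native, "contact_set"), inherits(model, "contact_set"))
  if (nrow(native$pairs) == 0L)
    stop("empty native contact set: Fnat undefined; exclude this interface")
  kn <- paste(native$pairs$resno_a, native$pairs$resno_b)
  km <- paste(model$pairs$resno_a, model$pairs$resno_b)
  sum(kn %in% km) / length(kn)
}

# paired backbone coordinate matrices for a residue subset of the
# correspondence (NULL subset = all pairs of the given chains)
paired_backbone <- function(native, model, corr, chains_a, resno_keep = NULL) {
  p <- corr$pairs[corr$pairs$chain_a %in% chains_a, , drop = FALSE]
  if (!is.null(resno_keep)) {
    key <- paste(p$chain_a, p$resno_a)
    p <- p[key %in% resno_keep, , drop = FALSE]
  }
  X <- list(); Y <- list()
  for (nm in BACKBONE_ATOMS) {
    aa <- get_atoms(native, elety = nm)
    ab <- get_atoms(model, elety = nm)
    ia <- match(paste(p$chain_a, p$resno_a, p$insert_a),
                paste(aa$chain, aa$resno, aa$insert))
    ib <- match(paste(p$chain_b, p$resno_b, p$insert_b),
                paste(ab$chain, ab$resno, ab$insert))
    ok <- !is.na(ia) & !is.na(ib)
    X[[nm]] <- as_xyz(aa[ia[ok], ]); Y[[nm]] <- as_xyz(ab[ib[ok], ])
  }
  list(native = do.call(rbind, X), model = do.call(rbind, Y))
}

#' Ligand and interface RMSDs for one chain pair
#'
#' DockQ geometry terms. LRMS: the model is fitted on the receptor (larger
#' chain) backbone, and the backbone RMSD of the ligand (smaller chain) is
#' reported. iRMS: native interface residues are those with any inter-chain
#' heavy-atom distance below `interface_cutoff`; the fit and the RMSD are
#' both over the backbone atoms of these residues. Backbone is N, CA, C, O.
#'
#' @param native,model `structure_model` objects.
#' @param chain_a,chain_b Chain IDs in the native structure.
#' @param correspondence A `correspondence_map` covering both chains.
#' @param interface_cutoff Native interface definition, angstroms (default 10).
#' @return List: `lrms`, `irms` (angstroms), `receptor`, `ligand`,
#'   `n_interface_residues`. With fewer than 3 interface residues `irms` is
#'   `NA` with a warning.
#' @export
interface_rmsds <- function(native, model, chain_a, chain_b, correspondence,
                            interface_cutoff = 10.0) {
  sizes <- c(nrow(chain_residues(native, chain_a)),
             nrow(chain_residues(native, chain_b)))
  # receptor = larger chain; tie broken lexicographically
  if (sizes[1] > sizes[2] || (sizes[1] == sizes[2] && chain_a < chain_b)) {
    receptor <- chain_a; ligand <- chain_b
  } else {
    receptor <- chain_b; ligand <- chain_a
  }
  rec <- paired_backbone(native, model, correspondence, receptor)
  lig <- paired_backbone(native, model, correspondence, ligand)
  fit <- kabsch_fit(rec$native, rec$model)
  lig_fit <- sweep(lig$model %*% fit$rotation, 2L, fit$translation, "+")
  lrms <- sqrt(mean(rowSums((lig_fit - lig$native)^2)))

  aa <- get_atoms(native, chain = chain_a, heavy_only = TRUE)
  ab <- get_atoms(native, chain = chain_b, heavy_only = TRUE)
  cp <- residue_contact_pairs(aa, ab, interface_cutoff)
  iface <- unique(c(paste(chain_a, cp$resno_a), paste(chain_b, cp$resno_b)))
  n_iface <- length(iface)
  if (n_iface < 3L) {
    warning("fewer than 3 native interface residues: iRMS undefined")
    irms <- NA_real_
  } else {
    ib <- paired_backbone(native, model, correspondence, c(chain_a, chain_b),
                          resno_keep = iface)
    ifit <- kabsch_fit(ib$native, ib$model)
    irms <- ifit$rmsd
  }
  list(lrms = lrms, irms = irms, receptor = receptor, ligand = ligand,
       n_interface_residues = n_iface)
}

#' DockQ composite interface score
#'
#' `DockQ = (Fnat + 1/(1+(LRMS/8.5)^2) + 1/(1+(iRMS/1.5)^2)) / 3`, the
#' standard combination of contact recovery and the two RMSD terms scaled to
#' \[0, 1\].
#'
#' @param fnat Fraction of native contacts in \[0, 1\].
#' @param lrms,irms Ligand and interface RMSD, angstroms (>= 0).
#' @param d_lrms,d_irms Scaling constants (defaults 8.5 and 1.5).
#' @return Score in \[0, 1\].
#' @export
dockq_score <- function(fnat, lrms, irms, d_lrms = 8.5, d_irms = 1.5) {
  stopifnot(fnat >= 0, fnat <= 1, lrms >= 0, irms >= 0)
  (fnat + 1 / (1 + (lrms / d_lrms)^2) + 1 / (1 + (irms / d_irms)^2)) / 3
}

#' CAPRI quality class of a DockQ score
#'
#' Bins: `>= 0.80` High; `[0.49, 0.80)` Medium; `[0.23, 0.49)` Acceptable;
#' `< 0.23` Incorrect. Boundaries belong to the better class.
#'
#' @param dockq Score(s) in \[0, 1\].
#' @return Character vector of classes.
#' @export
capri_class <- function(dockq) {
  stopifnot(all(dockq >= 0 & dockq <= 1))
  ifelse(dockq >= 0.80, "High",
         ifelse(dockq >= 0.49, "Medium",
                ifelse(dockq >= 0.23, "Acceptable", "Incorrect")))
}

#' Score every contacting chain pair of a complex
#'
#' Enumerates chain pairs of the mapped chains, scores each pair that has at
#' least one native contact (interfaces without native contacts are not
#' scoreable and are excluded, not scored 0), and aggregates: medians of
#' DockQ/Fnat/LRMS/iRMS over scored interfaces and an overall DockQ
#' (unweighted mean by default, native-contact-weighted on request).
#'
#' @param native,model `structure_model` objects.
#' @param chain_map Named vector `c(native_chain = model_chain)`, or `NULL`
#'   for identical chain IDs.
#' @param contact_cutoff Native contact cutoff, angstroms (default 5).
#' @param interface_cutoff iRMS interface definition, angstroms (default 10).
#' @param weighted Use native-contact-weighted overall mean.
#' @return A `complex_score_report`: `per_interface` data.frame (`chain_pair`,
#'   `fnat`, `lrms`, `irms`, `dockq`, `capri_class`, `n_native_contacts`),
#'   `overall_dockq`, `medians`, `n_interfaces`.
#' @export
score_complex <- function(native, model, chain_map = NULL,
                          contact_cutoff = 5.0, interface_cutoff = 10.0,
                          weighted = FALSE) {
  if (is.null(chain_map)) {
    common <- intersect(chain_ids(native), chain_ids(model))
    chain_map <- setNames(common, common)
  }
  if (length(chain_map) < 2L) stop("need at least 2 mapped chains")
  corr <- build_correspondence(native, model, chain_map)
  chains <- names(chain_map)
  rows <- list()
  for (i in seq_len(length(chains) - 1L)) {
    for (j in seq((i + 1L), length(chains))) {
      ca <- chains[i]; cb <- chains[j]
      nat_c <- native_contacts(native, ca, cb, contact_cutoff)
      if (nrow(nat_c$pairs) == 0L) next
      mod_c <- native_contacts(model, chain_map[[ca]], chain_map[[cb]],
                               contact_cutoff)
      fn <- fnat(nat_c, mod_c)
      rr <- interface_rmsds(native, model, ca, cb, corr, interface_cutoff)
      dq <- dockq_score(fn, rr$lrms, ifelse(is.na(rr$irms), 0, rr$irms))
      rows[[paste0(ca, "-", cb)]] <- data.frame(
        chain_pair = paste0(ca, "-", cb), fnat = fn, lrms = rr$lrms,
        irms = rr$irms, dockq = dq, capri_class = capri_class(dq),
        n_native_contacts = nrow(nat_c$pairs), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no contacting chain pairs: empty report")
    return(structure(list(per_interface = NULL, overall_dockq = NA_real_,
                          medians = NULL, n_interfaces = 0L),
                     class = "complex_score_report"))
  }
  per <- do.call(rbind, rows); rownames(per) <- NULL
  w <- if (weighted) per$n_native_contacts else rep(1, nrow(per))
  structure(list(
    per_interface = per,
    overall_dockq = sum(per$dockq * w) / sum(w),
    medians = c(dockq = median(per$dockq), fnat = median(per$fnat),
                lrms = median(per$lrms), irms = median(per$irms, na.rm = TRUE)),
    n_interfaces = nrow(per)), class = "complex_score_report")
}

#' @export
print.complex_score_report <- function(x, ...) {
  cat(sprintf("<complex_score_report> %d interface(s), overall DockQ %.3f\n",
              x$n_interfaces, x$overall_dockq))
  if (!is.null(x$medians))
    cat(sprintf("  medians: DockQ %.3f, Fnat %.3f, LRMS %.3f A, iRMS %.3f A\n",
                x$medians["dockq"], x$medians["fnat"], x$medians["lrms"],
                x$medians["irms"]))
  invisible(x)
}
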