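# residue-identity compatibility under the QTY code (3-letter names):
# equal names always pair; a native hydrophobic residue pairs with its
# hydrophilic analog (L~Q, I~T, V~T, F~Y) in either direction.
qty_compatible <- function(resid_a, resid_b) {
  a1 <- unname(AA3[resid_a]); b1 <- unname(AA3[resid_b])
  same <- !is.na(a1) & !is.na(b1) & a1 == b1
  fwd <- !is.na(a1) & a1 %in% names(QTY_MAP) & QTY_MAP[a1] == b1
  rev <- !is.na(b1) & b1 %in% names(QTY_MAP) & QTY_MAP[b1] == a1
  same | (!is.na(fwd) & fwd) | (!is.na(rev) & rev)
}

#' Build a residue correspondence between two models
#'
#' Pairs residues of mapped chains by author residue number (plus insertion
#' code). Residues present in only one structure — typically unstructured
#' loops missing from a CryoEM reference — are trimmed and listed, so the
#' downstream superposition compares only commonly resolved residues. QTY
#' substitutions (L~Q, I/V~T, F~Y) do not break pairing; any other residue
#' identity clash is dropped with a warning.
#'
#' @param reference,model `structure_model` objects.
#' @param chain_map Named character vector `c(ref_chain = model_chain)`, or
#'   `NULL` to pair identically named chains.
#' @return A `correspondence_map`: `pairs` (data.frame `chain_a`, `resno_a`,
#'   `insert_a`, `resid_a`, `chain_b`, `resno_b`, `insert_b`, `resid_b`),
#'   `dropped_a` (reference residues absent from the model), `dropped_b`
#'   (model residues absent from the reference), `mismatched` (number-paired
#'   residues with incompatible identity, excluded).
#' @export
build_correspondence <- function(reference, model, chain_map = NULL) {
  stopifnot(inherits(reference, "structure_model"),
            inherits(model, "structure_model"))
  if (is.null(chain_map)) {
    common <- intersect(chain_ids(reference), chain_ids(model))
    if (!length(common)) stop("no common chain IDs; supply chain_map")
    chain_map <- setNames(common, common)
  }
  stopifnot(!is.null(names(chain_map)))
  pairs <- list(); da <- list(); db <- list(); mm <- list()
  for (ca in names(chain_map)) {
    cb <- chain_map[[ca]]
    ra <- chain_residues(reference, ca)
    rb <- chain_residues(model, cb)
    if (nrow(ra) == 0L) stop(sprintf("chain '%s' absent from reference", ca))
    if (nrow(rb) == 0L) stop(sprintf("chain '%s' absent from model", cb))
    if (anyDuplicated(paste(ra$resno, ra$insert)) ||
        anyDuplicated(paste(rb$resno, rb$insert)))
      stop("duplicate residue numbers within a chain")
    ka <- paste(ra$resno, ra$insert); kb <- paste(rb$resno, rb$insert)
    ia <- match(kb, ka)
    hit <- !is.na(ia)
    p <- data.frame(chain_a = rep(ca, sum(hit)), resno_a = ra$resno[ia[hit]],
                    insert_a = ra$insert[ia[hit]], resid_a = ra$resid[ia[hit]],
                    chain_b = rep(cb, sum(hit)), resno_b = rb$resno[hit],
                    insert_b = rb$insert[hit], resid_b = rb$resid[hit],
                    stringsAsFactors = FALSE)
    ok <- qty_compatible(p$resid_a, p$resid_b)
    mm[[ca]] <- p[!ok, , drop = FALSE]
    pairs[[ca]] <- p[ok, , drop = FALSE]
    da[[ca]] <- ra[!ka %in% kb, , drop = FALSE]
    db[[ca]] <- rb[hit == FALSE, , drop = FALSE]
  }
  pairs <- do.call(rbind, pairs); rownames(pairs) <- NULL
  mism <- do.call(rbind, mm); rownames(mism) <- NULL
  if (nrow(pairs) == 0L) stop("no common residues between reference and model")
  if (nrow(mism))
    warning(sprintf("%d residue pair(s) with QTY-incompatible identity dropped",
                    nrow(mism)))
  structure(list(pairs = pairs,
                 dropped_a = do.call(rbind, da),
                 dropped_b = do.call(rbind, db),
                 mismatched = mism,
                 chain_map = chain_map),
            class = "correspondence_map")
}

#' Optimal least-squares rigid fit (Kabsch)
#'
#' Closed-form optimal rotation and translation mapping `mobile` onto `ref`,
#' via SVD of the covariance with determinant correction so the result is a
#' proper rotation (no reflection).
#'
#' @param ref,mobile n x 3 coordinate matrices, row i of each paired.
#' @return List: `rotation` (3x3, det +1), `translation` (length 3), `rmsd`.
#'   The fitted coordinates are `mobile %*% rotation + translation` (row
#'   vectors).
#' @export
kabsch_fit <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  stopifnot(ncol(ref) == 3L, ncol(mobile) == 3L, nrow(ref) == nrow(mobile))
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 paired points for a rigid fit")
  cx <- colMeans(ref); cy <- colMeans(mobile)
  A <- sweep(mobile, 2L, cy); B <- sweep(ref, 2L, cx)
  sv <- svd(A)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate geometry: points are collinear or coincident")
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  list(rotation = R, translation = as.numeric(cx - cy %*% R), rmsd = rmsd)
}

#' Superpose a model onto a reference over corresponded C-alpha atoms
#'
#' Least-squares rigid superposition (Kabsch) over the CA atoms of the
#' paired residues, with optional iterative outlier rejection: after each
#' fit, pairs deviating more than `cutoff` angstroms are removed and the fit
#' repeated, emulating refinement-style superposition commands.
#'
#' @param correspondence A `correspondence_map` from [build_correspondence()].
#' @param reference,model The two `structure_model` objects.
#' @param atom_set Atom names used for the fit (default `"CA"`).
#' @param outlier_rejection `NULL` (off, the default) or
#'   `list(cutoff = 2.0, max_cycles = 5)`.
#' @return A `superposition_result`: `rotation`, `translation`, `n_pairs`
#'   (pairs retained in the final fit), `rmsd` (angstroms, over retained
#'   pairs), `rejected` (data.frame of rejected pairs with deviations),
#'   `deviations` (per retained pair, after fit).
#' @export
kabsch_superpose <- function(correspondence, reference, model,
                             atom_set = "CA", outlier_rejection = NULL) {
  stopifnot(inherits(correspondence, "correspondence_map"))
  p <- correspondence$pairs
  X <- list(); Y <- list(); keep_lab <- list()
  for (nm in atom_set) {
    aa <- get_atoms(reference, elety = nm)
    ab <- get_atoms(model, elety = nm)
    ia <- match(paste(p$chain_a, p$resno_a, p$insert_a),
                paste(aa$chain, aa$resno, aa$insert))
    ib <- match(paste(p$chain_b, p$resno_b, p$insert_b),
                paste(ab$chain, ab$resno, ab$insert))
    ok <- !is.na(ia) & !is.na(ib)
    X[[nm]] <- as_xyz(aa[ia[ok], ]); Y[[nm]] <- as_xyz(ab[ib[ok], ])
    keep_lab[[nm]] <- paste0(p$chain_a[ok], ":", p$resno_a[ok], p$insert_a[ok],
                             ":", nm)
  }
  X <- do.call(rbind, X); Y <- do.call(rbind, Y)
  lab <- unlist(keep_lab, use.names = FALSE)
  if (is.null(X) || nrow(X) < 3L)
    stop("fewer than 3 corresponded atoms available for superposition")
  rejected <- data.frame(atom = character(0), deviation = numeric(0))
  keep <- rep(TRUE, nrow(X))
  cycles <- if (is.null(outlier_rejection)) 0L else
    as.integer(outlier_rejection$max_cycles)
  fit <- kabsch_fit(X, Y)
  if (cycles > 0L) {
    cutoff <- outlier_rejection$cutoff
    for (i in seq_len(cycles)) {
      dev <- sqrt(rowSums((sweep(Y[keep, , drop = FALSE] %*% fit$rotation,
                                 2L, fit$translation, "+") -
                             X[keep, , drop = FALSE])^2))
      out <- dev > cutoff
      if (!any(out) || sum(keep) - sum(out) < 3L) break
      idx <- which(keep)[out]
      rejected <- rbind(rejected,
                        data.frame(atom = lab[idx], deviation = dev[out]))
      keep[idx] <- FALSE
      fit <- kabsch_fit(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    }
  }
  dev <- sqrt(rowSums((sweep(Y[keep, , drop = FALSE] %*% fit$rotation, 2L,
                             fit$translation, "+") -
                         X[keep, , drop = FALSE])^2))
  structure(list(rotation = fit$rotation,
                 translation = fit$translation,
                 n_pairs = sum(keep), rmsd = fit$rmsd,
                 rejected = rejected,
                 deviations = setNames(dev, lab[keep])),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD %.3f A (%d rejected)\n",
              x$n_pairs, x$rmsd, nrow(x$rejected)))
  invisible(x)
}

#' Summarize per-subunit superposition results
#'
#' @param results Named list of `superposition_result` objects (names are
#'   subunit labels).
#' @return List with `table` (subunit, n_pairs, rmsd, n_rejected) and
#'   `summary` (min/max/median RMSD).
#' @export
rmsd_report <- function(results) {
  stopifnot(length(results) >= 1L)
  tab <- data.frame(
    subunit = names(results),
    n_pairs = vapply(results, function(r) r$n_pairs, integer(1)),
    rmsd = round(vapply(results, function(r) r$rmsd, numeric(1)), 3),
    n_rejected = vapply(results, function(r) nrow(r$rejected), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       summary = c(min = min(tab$rmsd), max = max(tab$rmsd),
                   median = median(tab$rmsd)))
}
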