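# Independent oracles, deliberately coded apart from the package internals:
# a quaternion (Horn) rigid superposition, a pH grid search for the
# isoelectric point, an O(n^2) contact scan, and a from-scratch DockQ for
# two-chain fixtures. Package functions are only used here to *extract*
# coordinates, never to compute the quantity being checked.

# Horn's closed-form quaternion superposition: returns the optimal RMSD and
# the fitted mobile coordinates (rows), mapping `mobile` onto `ref`.
quat_superpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  cx <- colMeans(ref); cy <- colMeans(mobile)
  B <- sweep(ref, 2, cx); A <- sweep(mobile, 2, cy)
  S <- crossprod(A, B)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],       S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],       S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],       S[3,1]+S[1,3],        S[2,3]+S[3,2],      -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values[1]
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- A %*% t(R)
  msd <- (sum(B^2) + sum(A^2) - 2 * lambda) / nrow(ref)
  list(rmsd = sqrt(max(0, msd)),
       fitted = sweep(fitted, 2, cx, "+"),
       rotation = R)
}

# brute-force pI: densest |net charge| grid point on [0, 14]
grid_pi <- function(sequence, step = 1e-4) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  pka_pos <- c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98)
  pka_neg <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  ph <- seq(0, 14, by = step)
  charge <- 1 / (1 + 10^(ph - pka_pos["Nterm"])) -
    1 / (1 + 10^(pka_neg["Cterm"] - ph))
  for (r in c("K", "R", "H")) {
    k <- sum(aa == r)
    if (k) charge <- charge + k / (1 + 10^(ph - pka_pos[r]))
  }
  for (r in c("D", "E", "C", "Y")) {
    k <- sum(aa == r)
    if (k) charge <- charge - k / (1 + 10^(pka_neg[r] - ph))
  }
  ph[which.min(abs(charge))]
}

# O(n^2) residue contact scan over two atom tables (heavy atoms assumed)
brute_contacts <- function(atoms_a, atoms_b, cutoff) {
  out <- list()
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                  (atoms_a$y[i] - atoms_b$y[j])^2 +
                  (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d < cutoff)
        out[[length(out) + 1L]] <- c(atoms_a$resno[i], atoms_b$resno[j])
    }
  }
  if (!length(out))
    return(data.frame(resno_a = integer(0), resno_b = integer(0)))
  m <- unique(do.call(rbind, out))
  data.frame(resno_a = m[, 1], resno_b = m[, 2])
}

# from-scratch DockQ for a two-chain fixture sharing residue numbering.
# Uses only raw atom tables plus the helpers above.
oracle_dockq <- function(native, model, chain_a, chain_b,
                         contact_cutoff = 5, interface_cutoff = 10) {
  heavy <- function(m, ch) {
    a <- m$atoms
    a[a$chain == ch & a$element != "H", , drop = FALSE]
  }
  na <- heavy(native, chain_a); nb <- heavy(native, chain_b)
  ma <- heavy(model, chain_a); mb <- heavy(model, chain_b)
  nat <- brute_contacts(na, nb, contact_cutoff)
  mod <- brute_contacts(ma, mb, contact_cutoff)
  kn <- paste(nat$resno_a, nat$resno_b)
  km <- paste(mod$resno_a, mod$resno_b)
  fn <- sum(kn %in% km) / length(kn)

  bb <- function(a) a[a$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  paired_bb <- function(an, am) {
    an <- bb(an); am <- bb(am)
    key_n <- paste(an$resno, an$elety); key_m <- paste(am$resno, am$elety)
    common <- intersect(key_n, key_m)
    list(nat = as.matrix(an[match(common, key_n), c("x", "y", "z")]),
         mod = as.matrix(am[match(common, key_m), c("x", "y", "z")]))
  }
  # receptor = larger chain (residue count), tie -> lexicographic
  n_ra <- length(unique(na$resno)); n_rb <- length(unique(nb$resno))
  if (n_ra > n_rb || (n_ra == n_rb && chain_a < chain_b)) {
    rec_n <- na; rec_m <- ma; lig_n <- nb; lig_m <- mb
  } else {
    rec_n <- nb; rec_m <- mb; lig_n <- na; lig_m <- ma
  }
  rec <- paired_bb(rec_n, rec_m); lig <- paired_bb(lig_n, lig_m)
  fit <- quat_superpose(rec$nat, rec$mod)
  cy <- colMeans(as.matrix(rec$mod)); cx <- colMeans(as.matrix(rec$nat))
  lig_fit <- sweep(sweep(lig$mod, 2, cy) %*% t(fit$rotation), 2, cx, "+")
  lrms <- sqrt(mean(rowSums((lig_fit - lig$nat)^2)))

  icont <- brute_contacts(na, nb, interface_cutoff)
  ires_a <- unique(icont$resno_a); ires_b <- unique(icont$resno_b)
  ia <- paired_bb(na[na$resno %in% ires_a, ], ma[ma$resno %in% ires_a, ])
  ib <- paired_bb(nb[nb$resno %in% ires_b, ], mb[mb$resno %in% ires_b, ])
  irms <- quat_superpose(rbind(ia$nat, ib$nat), rbind(ia$mod, ib$mod))$rmsd

  dq <- (fn + 1 / (1 + (lrms / 8.5)^2) + 1 / (1 + (irms / 1.5)^2)) / 3
  list(fnat = fn, lrms = lrms, irms = irms, dockq = dq,
       n_native = length(kn))
}

# random rotation matrix (uniform via QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
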