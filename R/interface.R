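# Interface quantification: Shrake-Rupley solvent-accessible surface area,
# buried (contact) area by the difference formula, contact residue pairs, and
# groove-lining helix identification.

#' SASA parameters
#'
#' @param probe_radius solvent probe radius, A (water: 1.4).
#' @param n_sphere_points quadrature points per atom (>= 64); points are a
#'   deterministic golden-section spiral, so no seed is involved.
#' @param radii_table named vector of van der Waals radii by element, A.
#' @param ca_only_radius radius used for CA atoms in C-alpha-only structures
#'   (inflated to mimic residue bulk).
#' @return object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii_table = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                                        H = 1.2),
                        ca_only_radius = 2.4) {
  if (probe_radius < 0 || n_sphere_points < 64)
    stop_gd("need probe_radius >= 0 and n_sphere_points >= 64",
            class = "groovedock_value_error")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_table = radii_table, ca_only_radius = ca_only_radius),
            class = "sasa_params")
}

# deterministic golden-section spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(s, p) {
  a <- s$atoms[s$atoms$is_heavy, , drop = FALSE]
  ca_only <- !any(a$name %in% c("N", "C", "O"))
  r <- unname(p$radii_table[toupper(a$element)])
  if (ca_only) r[a$name == "CA"] <- p$ca_only_radius
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1]
    stop_gd("no radius for atom %s %s/%d %s (element '%s')", a$name[bad],
            a$chain[bad], a$resno[bad], a$resid[bad], a$element[bad],
            class = "groovedock_lookup_error")
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each heavy atom, the accessible area is the fraction of quadrature
#' points on its probe-expanded sphere not buried inside any other atom's
#' expanded sphere, times the expanded-sphere area. Hydrogens are ignored.
#'
#' @param s a [structure3d()].
#' @param p a [sasa_params()].
#' @return numeric vector of per-atom areas (A^2) over the heavy atoms, in
#'   atom order, with attribute `total`.
#' @export
sasa <- function(s, p = sasa_params()) {
  a <- s$atoms[s$atoms$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop_gd("empty structure", class = "groovedock_empty_error")
  X <- as.matrix(a[, c("x", "y", "z")])
  R <- .atom_radii(s, p) + p$probe_radius
  pts <- .sphere_points(p$n_sphere_points)
  n <- nrow(X)
  d2 <- .pairwise_dist2(X, X)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    P <- sweep(pts * R[i], 2, X[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, nrow(P))
      for (j in nb) {
        if (!any(acc)) break
        dj <- (P[acc, 1] - X[j, 1])^2 + (P[acc, 2] - X[j, 2])^2 +
          (P[acc, 3] - X[j, 3])^2
        acc[acc] <- dj >= R[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    areas[i] <- frac * 4 * pi * R[i]^2
  }
  attr(areas, "total") <- sum(areas)
  areas
}

# merge two structures for complex SASA; identities must not collide
.combine_structures <- function(a, b) {
  key_a <- paste(a$atoms$chain, a$atoms$resno, a$atoms$name)
  key_b <- paste(b$atoms$chain, b$atoms$resno, b$atoms$name)
  if (any(key_a %in% key_b))
    stop_gd("structures share atom identities; relabel chains before combining",
            class = "groovedock_value_error")
  structure3d(rbind(a$atoms, b$atoms), id = paste(a$id, b$id, sep = "+"))
}

#' Buried (contact) interface area between two structures
#'
#' The buried area is the difference between the accessible surface area of
#' the two isolated partners and that of the complex:
#' `[sasa(a) + sasa(b)] - sasa(a+b)`, summed over both partners, with the
#' per-partner split from per-atom differences. Small negative quadrature
#' noise is clamped to zero with a warning.
#'
#' @param a,b [structure3d()] partners with disjoint atom identities.
#' @param p a [sasa_params()].
#' @return object of class `interface_result` with `buried_area`,
#'   `per_partner_buried`, and the isolated/complex totals.
#' @export
buried_area <- function(a, b, p = sasa_params()) {
  sa <- sasa(a, p); sb <- sasa(b, p)
  sab <- sasa(.combine_structures(a, b), p)
  na <- sum(a$atoms$is_heavy)
  da <- sum(sa) - sum(sab[seq_len(na)])
  db <- sum(sb) - sum(sab[-seq_len(na)])
  clamp <- function(x) {
    if (x < 0) {
      warning(sprintf("negative buried area (%.3f A^2) clamped to 0 (quadrature noise)", x))
      0
    } else x
  }
  da <- clamp(da); db <- clamp(db)
  structure(list(buried_area = da + db, per_partner_buried = c(da, db),
                 sasa_isolated = c(attr(sa, "total"), attr(sb, "total")),
                 sasa_complex = attr(sab, "total"),
                 contacts = NULL, groove_lining = NULL),
            class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("<interface_result> buried area %.1f A^2 (partners: %.1f + %.1f)\n",
              x$buried_area, x$per_partner_buried[1], x$per_partner_buried[2]))
  if (!is.null(x$contacts))
    cat(sprintf("  %d contact residue pairs\n", nrow(x$contacts)))
  if (!is.null(x$groove_lining))
    cat("  groove-lining helices:", paste(x$groove_lining, collapse = " "), "\n")
  invisible(x)
}

#' Contact residue pairs between two structures
#'
#' Unique residue pairs with any inter-body heavy-atom distance strictly below
#' the cutoff, sorted lexicographically.
#'
#' @param a,b [structure3d()] objects.
#' @param cutoff contact distance, A.
#' @return data.frame with columns chain_a, resno_a, chain_b, resno_b.
#' @export
contact_pairs <- function(a, b, cutoff = 4.5) {
  A <- a$atoms[a$atoms$is_heavy, , drop = FALSE]
  B <- b$atoms[b$atoms$is_heavy, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer()))
  d2 <- .pairwise_dist2(as.matrix(A[, c("x", "y", "z")]),
                        as.matrix(B[, c("x", "y", "z")]))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer()))
  pr <- unique(data.frame(chain_a = A$chain[hit[, 1]], resno_a = A$resno[hit[, 1]],
                          chain_b = B$chain[hit[, 2]], resno_b = B$resno[hit[, 2]],
                          stringsAsFactors = FALSE))
  pr <- pr[order(pr$chain_a, pr$resno_a, pr$chain_b, pr$resno_b), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' Identify the groove-lining helices of a bundle
#'
#' Labels of the bundle helices having at least one contact residue pair with
#' the probe structure (e.g. a docked M4 helix), sorted. The bundle must carry
#' the `helices` label table produced by the bundle builders (or supply one).
#'
#' @param bundle labelled bundle [structure3d()].
#' @param docked_probe probe [structure3d()].
#' @param cutoff contact distance, A.
#' @param helices optional label table (label, chain, start, end).
#' @return character vector of helix labels.
#' @export
groove_lining <- function(bundle, docked_probe, cutoff = 4.5, helices = NULL) {
  tab <- helices %||% attr(bundle, "helices")
  if (is.null(tab))
    stop_gd("bundle has no helix label table", class = "groovedock_value_error")
  cp <- contact_pairs(bundle, docked_probe, cutoff)
  if (nrow(cp) == 0) return(character())
  hit <- vapply(seq_len(nrow(tab)), function(k) {
    any(cp$chain_a == tab$chain[k] & cp$resno_a >= tab$start[k] &
          cp$resno_a <= tab$end[k])
  }, TRUE)
  sort(tab$label[hit])
}
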