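# Template-guided rigid docking: superpose the template's groove-filling helix
# onto the receptor's target M4, rotate about the M4 axis to minimize steric
# clashes, then transfer the query bundle onto the oriented template.

#' Clash-counting parameters
#'
#' A clash is an inter-body heavy-atom pair with centre distance strictly
#' below `cutoff`. 2.5 A flags severe overlap on stripped (side-chain-free)
#' structures without penalizing packing contacts.
#'
#' @param cutoff distance cutoff, A.
#' @param exclude_intra only count pairs between the two bodies (kept for the
#'   result metadata; the pair counters are inter-body by construction).
#' @return object of class `clash_params`.
#' @export
clash_params <- function(cutoff = 2.5, exclude_intra = TRUE) {
  if (cutoff <= 0) stop_gd("cutoff must be > 0", class = "groovedock_value_error")
  structure(list(cutoff = cutoff, exclude_intra = exclude_intra),
            class = "clash_params")
}

#' Count steric clashes between two structures
#'
#' Number of inter-structure heavy-atom pairs with centre distance strictly
#' less than the cutoff; symmetric in its two arguments and independent of
#' atom storage order.
#'
#' @param a,b [structure3d()] objects (non-empty).
#' @param p a [clash_params()].
#' @return integer clash count.
#' @export
count_clashes <- function(a, b, p = clash_params()) {
  A <- coords(a, heavy_only = TRUE); B <- coords(b, heavy_only = TRUE)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop_gd("empty structure in clash count", class = "groovedock_empty_error")
  .count_clashes_xyz(A, B, p$cutoff)
}

.count_clashes_xyz <- function(A, B, cutoff) {
  sum(.pairwise_dist2(A, B) < cutoff^2)
}

#' Scan rotations about an axis for the minimum-clash orientation
#'
#' Evaluates the clash count of `mobile` against `receptor` at rotations
#' 0, step, ..., 360 - step degrees about the given axis, and returns the
#' angle of minimum clash count (ties broken towards the smallest angle, for
#' determinism).
#'
#' @param mobile [structure3d()] to rotate.
#' @param axis list with `point` and `direction` (e.g. [fit_helix_axis()]).
#' @param receptor fixed [structure3d()].
#' @param step scan step, degrees; must divide 360 evenly.
#' @param p a [clash_params()].
#' @return list with `best_angle`, `clash_count` (at the best angle), and
#'   `scan` (data.frame angle, clashes).
#' @export
rotation_scan <- function(mobile, axis, receptor, step = 1, p = clash_params()) {
  if (abs(360 / step - round(360 / step)) > 1e-9)
    stop_gd("step must divide 360 evenly", class = "groovedock_value_error")
  M <- coords(mobile, heavy_only = TRUE)
  Rc <- coords(receptor, heavy_only = TRUE)
  if (nrow(Rc) == 0) stop_gd("empty receptor", class = "groovedock_empty_error")
  angles <- seq(0, 360 - step, by = step)
  n_ang <- length(angles)
  # Exact interval accumulation in cylindrical coordinates about the scan
  # axis: a mobile atom stays on a circle (radius r_m, height z_m), so the
  # pair (i, j) clashes exactly for scan angles with
  # cos(phi_m + theta - phi_r) > (r_m^2 + r_r^2 + dz^2 - cutoff^2) / (2 r_m r_r),
  # an angular interval. Pairs outside cutoff in radius or height never clash.
  u <- axis$direction / sqrt(sum(axis$direction^2))
  B <- .rot_z_to(u)                           # maps +z onto the axis
  tof <- function(X) sweep(X, 2, axis$point) %*% B
  Mf <- tof(M); Rf <- tof(Rc)
  cyl <- function(X) list(r = sqrt(X[, 1]^2 + X[, 2]^2),
                          phi = atan2(X[, 2], X[, 1]) * 180 / pi, z = X[, 3])
  cm <- cyl(Mf); cr <- cyl(Rf)
  counts <- integer(n_ang)
  cut2 <- p$cutoff^2
  cand <- which(abs(outer(cm$z, cr$z, `-`)) < p$cutoff &
                  abs(outer(cm$r, cr$r, `-`)) < p$cutoff, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    i <- cand[, 1]; j <- cand[, 2]
    A <- cm$r[i]^2 + cr$r[j]^2 + (cm$z[i] - cr$z[j])^2 - cut2
    Bd <- 2 * cm$r[i] * cr$r[j]
    cth <- ifelse(Bd > 0, A / Bd, ifelse(A < 0, -Inf, Inf))
    always <- cth <= -1
    counts <- counts + sum(always)
    act <- which(cth > -1 & cth < 1)
    if (length(act) > 0) {
      w <- acos(cth[act]) * 180 / pi
      psi <- (cr$phi[j[act]] - cm$phi[i[act]]) %% 360
      k1 <- ceiling((psi - w) / step)
      k2 <- floor((psi + w) / step)
      for (q in seq_along(act)) {
        if (k2[q] < k1[q]) next
        idx <- (k1[q]:k2[q]) %% n_ang + 1L
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  best <- angles[which.min(counts)]  # which.min takes the first (smallest) angle
  list(best_angle = best, clash_count = min(counts),
       scan = data.frame(angle = angles, clashes = as.integer(counts)))
}

#' Strip side chains from a structure
#'
#' Retains backbone atoms (N, CA, C, O) and CB when present, mirroring the
#' docking convention of removing all side chains before pose search. On
#' C-alpha/C-beta fixtures this is the identity.
#'
#' @param s a [structure3d()].
#' @return a [structure3d()].
#' @export
strip_side_chains <- function(s) {
  keep <- s$atoms$name %in% c("N", "CA", "C", "O", "CB")
  out <- s
  out$atoms <- s$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

# centre-trimmed index correspondence between sequences of lengths na, nb
.centre_trim <- function(na, nb) {
  n <- min(na, nb)
  offa <- (na - n) %/% 2
  offb <- (nb - n) %/% 2
  list(a = offa + seq_len(n), b = offb + seq_len(n))
}

#' Template-guided docking of a groove-bearing bundle onto a receptor M4
#'
#' Implements the three-step template procedure: (1) the template's
#' groove-filling helix is superposed (C-alpha Kabsch, N-to-C correspondence,
#' centre-trimmed to the shorter segment) onto the receptor's target M4;
#' (2) the template is rotated about the fitted M4 axis to the orientation of
#' minimum steric clash against the receptor; (3) the query bundle is mapped
#' onto the oriented template by superposition over the shared atoms. The
#' filler helix itself is excluded from clash counting: it is the alignment
#' proxy for M4 and overlaps it by construction.
#'
#' @param template long-homolog [structure3d()] containing the filler helix.
#' @param filler [helix_segment()] of the groove-filling helix in `template`.
#' @param query short-bundle [structure3d()] to be docked.
#' @param receptor receptor [structure3d()].
#' @param target_m4 [helix_segment()] of the target M4 in `receptor`.
#' @param shared_atoms optional two-column matrix of row indices
#'   (query, template) defining the query-template correspondence; by default
#'   atoms are matched on (chain, residue number, atom name).
#' @param step scan step, degrees.
#' @param p a [clash_params()].
#' @param hard_ceiling if every scan angle has more clashes than this, the
#'   groove is considered occluded and an error of class
#'   `groovedock_occluded_error` is raised (the expected outcome when docking
#'   against a long-homolog bundle whose groove is filled).
#' @return object of class `dock_result`: `transform` (composite
#'   [rigid_transform()] applied to the query), `best_angle`, `scan`,
#'   `clash_count`, `query_docked`, `template_docked`, and `contacts`
#'   (residue pairs within 4.5 A between docked query and receptor).
#' @export
template_guided_dock <- function(template, filler, query, receptor, target_m4,
                                 shared_atoms = NULL, step = 1,
                                 p = clash_params(), hard_ceiling = 25) {
  f <- select_atoms(template, filler$chain, filler)
  m4 <- select_atoms(receptor, target_m4$chain, target_m4)
  f_ca <- coords(f)[f$atoms$name == "CA", , drop = FALSE]
  m4_ca <- coords(m4)[m4$atoms$name == "CA", , drop = FALSE]
  if (nrow(f_ca) < 4 || nrow(m4_ca) < 4)
    stop_gd("filler and target M4 need at least 4 C-alpha atoms each",
            class = "groovedock_value_error")
  corr <- .centre_trim(nrow(f_ca), nrow(m4_ca))
  t1 <- kabsch(f_ca[corr$a, , drop = FALSE], m4_ca[corr$b, , drop = FALSE])$transform

  axis <- fit_helix_axis(m4_ca)
  is_filler <- template$atoms$chain == filler$chain &
    template$atoms$resno >= filler$start & template$atoms$resno <= filler$end
  mobile <- template
  mobile$atoms <- template$atoms[!is_filler, , drop = FALSE]
  if (nrow(mobile$atoms) == 0)
    stop_gd("template has no atoms outside the filler helix",
            class = "groovedock_value_error")
  scan <- rotation_scan(apply_transform(t1, mobile), axis, receptor, step, p)
  if (scan$clash_count > hard_ceiling)
    stop_gd(paste0("groove occluded: minimum clash count %d exceeds ceiling %d ",
                   "at every scan angle"), scan$clash_count, hard_ceiling,
            class = "groovedock_occluded_error")
  t2 <- axis_rotation(scan$best_angle, axis$point, axis$direction)
  t12 <- compose_transform(t2, t1)

  # query -> template correspondence
  if (is.null(shared_atoms)) {
    qk <- paste(query$atoms$chain, query$atoms$resno, query$atoms$name)
    tk <- paste(template$atoms$chain, template$atoms$resno, template$atoms$name)
    qi <- which(qk %in% tk)
    ti <- match(qk[qi], tk)
  } else {
    qi <- shared_atoms[, 1]; ti <- shared_atoms[, 2]
  }
  if (length(qi) < 3)
    stop_gd("need at least 3 shared atoms between query and template",
            class = "groovedock_value_error")
  mq <- kabsch(coords(query)[qi, , drop = FALSE],
               coords(template)[ti, , drop = FALSE])$transform
  full <- compose_transform(t12, mq)
  query_docked <- apply_transform(full, query)
  template_docked <- apply_transform(t12, template)
  structure(list(transform = full, best_angle = scan$best_angle,
                 scan = scan$scan, clash_count = scan$clash_count,
                 query_docked = query_docked, template_docked = template_docked,
                 contacts = contact_pairs(query_docked, receptor),
                 buried_area = NA_real_, params = p, step = step),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> best_angle %.1f deg, clash_count %d, %d contact residue pairs\n",
              x$best_angle, x$clash_count, nrow(x$contacts)))
  if (!is.na(x$buried_area))
    cat(sprintf("  buried interface area: %.1f A^2\n", x$buried_area))
  invisible(x)
}
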