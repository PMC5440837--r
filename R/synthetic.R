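# Synthetic structure and assay-data generators. These produce every input the
# pipeline needs: idealized TM helix bundles (a "short" groove-bearing bundle,
# its "long" homolog whose extra N-terminal helices fill the groove, and a
# tetrameric receptor fixture with protruding M4 helices), planted ground-truth
# docking scenes, two-channel cell images with a known co-localized fraction,
# and BiFC intensity tables.
#
# All generators are pure functions of their parameter objects (including the
# seed): identical inputs give identical outputs.

#' Parameters of an ideal alpha-helix
#'
#' C-alpha atoms lie on a helix of radius `helix_radius` about the axis, with
#' `rise` angstrom and `twist` degrees per residue (canonical alpha-helix
#' values 1.5 A and 100 degrees). A pseudo C-beta is placed 1.5 A radially
#' outward from each C-alpha to mimic side-chain bulk on stripped structures.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise A per residue.
#' @param twist degrees per residue.
#' @param helix_radius C-alpha distance from the helix axis, A.
#' @param axis_point a point on the axis (position of residue 1's axial foot).
#' @param axis_direction axis direction (normalized internally).
#' @param phase azimuth of residue 1, degrees.
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(n_residues = 24, rise = 1.5, twist = 100,
                       helix_radius = 2.3, axis_point = c(0, 0, 0),
                       axis_direction = c(0, 0, 1), phase = 0) {
  if (n_residues < 4 || rise <= 0 || helix_radius <= 0)
    stop_gd("invalid helix spec: need n_residues >= 4, rise > 0, helix_radius > 0",
            class = "groovedock_value_error")
  d <- as.numeric(axis_direction)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12)
    stop_gd("axis_direction must be non-zero", class = "groovedock_value_error")
  structure(list(n_residues = as.integer(n_residues), rise = rise, twist = twist,
                 helix_radius = helix_radius, axis_point = as.numeric(axis_point),
                 axis_direction = d / nd, phase = phase), class = "helix_spec")
}

# rotation taking the +z axis onto unit vector d (minimal rotation; 180-degree
# flip about x when d == -z).
.rot_z_to <- function(d) {
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3], z[1] * d[2] - z[2] * d[1])
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Build an ideal helix as a structure
#'
#' Residue i places its C-alpha at
#' `axis_point + (i-1) * rise * axis_direction + helix_radius * (cos t, sin t)`
#' in the plane normal to the axis, with `t = phase + (i-1) * twist`; the
#' pseudo C-beta sits `cb_offset` A further out along the same radial ray.
#'
#' @param spec a [helix_spec()].
#' @param chain chain label for the helix.
#' @param resno_start residue number of the first residue.
#' @param cb_offset radial C-beta offset, A; `NA` for a C-alpha-only helix.
#' @return a [structure3d()].
#' @export
build_ideal_helix <- function(spec, chain = "A", resno_start = 1L, cb_offset = 1.5) {
  n <- spec$n_residues
  i <- seq_len(n) - 1
  th <- (spec$phase + i * spec$twist) * pi / 180
  R <- .rot_z_to(spec$axis_direction)
  e1 <- as.numeric(R %*% c(1, 0, 0)); e2 <- as.numeric(R %*% c(0, 1, 0))
  axial <- outer(i * spec$rise, spec$axis_direction)
  radial_dir <- outer(cos(th), e1) + outer(sin(th), e2)
  ca <- sweep(axial + spec$helix_radius * radial_dir, 2, spec$axis_point, `+`)
  resno <- resno_start + i
  if (is.na(cb_offset)) {
    atoms <- data.frame(name = "CA", element = "C",
                        x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        resno = resno, resid = "ALA", chain = chain,
                        stringsAsFactors = FALSE)
  } else {
    cb <- ca + cb_offset * radial_dir
    ord <- rep(seq_len(n), each = 2)
    sel <- rep(c(TRUE, FALSE), n)
    xyz <- matrix(NA_real_, 2 * n, 3)
    xyz[sel, ] <- ca; xyz[!sel, ] <- cb
    atoms <- data.frame(name = rep(c("CA", "CB"), n), element = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        resno = resno[ord], resid = "ALA", chain = chain,
                        stringsAsFactors = FALSE)
  }
  structure3d(atoms, id = sprintf("helix_%s", chain))
}

#' Parameters of a ring-shaped TM helix bundle
#'
#' Helices are placed on a ring with alternating up/down axis directions
#' (antiparallel TM topology). When `groove_gap` names a ring position, that
#' helix is omitted, leaving a lateral groove flanked by its two ring
#' neighbours -- the "short" bundle geometry.
#'
#' @param n_positions number of ring positions.
#' @param ring_radius ring radius, A.
#' @param groove_gap index (1-based) of the omitted position, or `NA` for a
#'   full ring. The default ring has the gap at the position pointing along
#'   -x from the bundle centre.
#' @param helix a [helix_spec()] giving the per-helix geometry (axis fields
#'   are overridden per position).
#' @param antiparallel alternate helix directions around the ring.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_positions = 12, ring_radius = 20, groove_gap = 7,
                        helix = helix_spec(), antiparallel = TRUE) {
  if (n_positions < 3)
    stop_gd("need at least 3 ring positions", class = "groovedock_value_error")
  if (!is.na(groove_gap) && (groove_gap < 1 || groove_gap > n_positions))
    stop_gd("groove_gap must be a ring position index in 1..%d", n_positions,
            class = "groovedock_value_error")
  structure(list(n_positions = as.integer(n_positions), ring_radius = ring_radius,
                 groove_gap = if (is.na(groove_gap)) NA_integer_ else as.integer(groove_gap),
                 helix = helix, antiparallel = antiparallel),
            class = "bundle_spec")
}

# ring-position geometry shared by the bundle builders
.ring_position <- function(spec, i) {
  chi <- (i - 1) * 2 * pi / spec$n_positions
  centre_xy <- spec$ring_radius * c(cos(chi), sin(chi))
  up <- if (spec$antiparallel) (i %% 2 == 1) else TRUE
  h <- spec$helix
  half <- (h$n_residues - 1) * h$rise / 2
  list(xy = centre_xy, up = up,
       axis_point = c(centre_xy, if (up) -half else half),
       axis_direction = c(0, 0, if (up) 1 else -1))
}

.bundle_helix <- function(spec, i, chain, label) {
  pos <- .ring_position(spec, i)
  h <- spec$helix
  hs <- helix_spec(h$n_residues, h$rise, h$twist, h$helix_radius,
                   axis_point = pos$axis_point, axis_direction = pos$axis_direction,
                   phase = h$phase)
  s <- build_ideal_helix(hs, chain = chain, resno_start = 1L)
  list(structure = s, label = label, chain = chain)
}

.assemble <- function(parts, id) {
  atoms <- do.call(rbind, lapply(parts, function(p) p$structure$atoms))
  s <- structure3d(atoms, id = id)
  attr(s, "helices") <- data.frame(
    label = vapply(parts, `[[`, "", "label"),
    chain = vapply(parts, `[[`, "", "chain"),
    start = vapply(parts, function(p) min(p$structure$atoms$resno), 0L),
    end   = vapply(parts, function(p) max(p$structure$atoms$resno), 0L),
    stringsAsFactors = FALSE)
  s
}

#' Build a ring bundle (with or without a groove)
#'
#' Each helix is its own chain (ring position i on chain `LETTERS[i]`,
#' labelled `H<i>`). The returned structure carries a `helices` attribute
#' (label/chain/residue-range table) and a `bundle` attribute describing the
#' ring geometry, including the groove slot used for docking.
#'
#' @param spec a [bundle_spec()].
#' @return a [structure3d()].
#' @export
build_bundle <- function(spec) {
  idx <- seq_len(spec$n_positions)
  if (!is.na(spec$groove_gap)) idx <- setdiff(idx, spec$groove_gap)
  parts <- lapply(idx, function(i)
    .bundle_helix(spec, i, chain = LETTERS[i], label = sprintf("H%02d", i)))
  s <- .assemble(parts, id = "bundle")
  ca <- s$atoms[s$atoms$name == "CA", c("x", "y", "z")]
  # generation check: inter-helix C-alpha pairs must stay >= 3 A
  ch <- s$atoms$chain[s$atoms$name == "CA"]
  X <- as.matrix(ca)
  d2 <- .pairwise_dist2(X, X)
  same <- outer(ch, ch, `==`)
  if (any(d2[!same] < 9))
    stop_gd("overlapping helices in bundle spec (inter-helix C-alpha pair < 3 A)",
            class = "groovedock_generation_error")
  slot <- if (is.na(spec$groove_gap)) NULL else {
    pos <- .ring_position(spec, spec$groove_gap)
    list(index = spec$groove_gap,
         point = c(pos$xy, 0),              # helices are z-centred at 0
         direction = c(0, 0, 1),            # slot parity chosen 'up' by default
         up = pos$up)
  }
  attr(s, "bundle") <- list(spec = spec, centre = c(0, 0, 0), slot = slot)
  s
}

# squared inter-point distances (rows of A vs rows of B)
.pairwise_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# peripheral helices of the "long" homolog: two extra N-terminal TMs sitting
# outside the ring beyond the groove slot, where they do not contact a docked
# receptor. Positions are in the bundle frame (ring centre at origin).
.peripheral_positions <- function(spec) {
  slot_chi <- (spec$groove_gap - 1) * 2 * pi / spec$n_positions
  r <- spec$ring_radius + 10
  lapply(c(-1, 1), function(sgn) {
    chi <- slot_chi + sgn * 45 * pi / 180
    r * c(cos(chi), sin(chi))
  })
}

#' Build the long/short homolog pair
#'
#' The "long" bundle carries three additional N-terminal helices relative to
#' the "short" one: a filler helix occupying the short bundle's groove slot,
#' plus two peripheral helices outside the ring. The short bundle is the
#' identical structure with the three extras removed, so the pair superposes
#' exactly on shared atoms -- mirroring the ancestral (long) versus bilaterian
#' (short) bundle relationship.
#'
#' @param spec a [bundle_spec()] with a groove position set.
#' @return list with `long`, `short` ([structure3d()]), and `filler`
#'   (a [helix_segment()] identifying the groove-filling helix in `long`).
#' @export
make_long_short_pair <- function(spec = bundle_spec()) {
  if (is.na(spec$groove_gap))
    stop_gd("spec must have a groove position for a long/short pair",
            class = "groovedock_value_error")
  short <- build_bundle(spec)
  # filler helix occupies the slot (parity forced 'up' so that its N->C
  # direction matches a protruding receptor M4 built 'up')
  h <- spec$helix
  slot <- attr(short, "bundle")$slot
  half <- (h$n_residues - 1) * h$rise / 2
  filler_chain <- LETTERS[spec$groove_gap]
  filler_spec <- helix_spec(h$n_residues, h$rise, h$twist, h$helix_radius,
                            axis_point = c(slot$point[1:2], -half),
                            axis_direction = c(0, 0, 1), phase = h$phase)
  filler <- list(structure = build_ideal_helix(filler_spec, chain = filler_chain),
                 label = sprintf("H%02d", spec$groove_gap), chain = filler_chain)
  peri <- .peripheral_positions(spec)
  peri_parts <- lapply(seq_along(peri), function(j) {
    ps <- helix_spec(h$n_residues, h$rise, h$twist, h$helix_radius,
                     axis_point = c(peri[[j]], if (j == 1) half else -half),
                     axis_direction = c(0, 0, if (j == 1) -1 else 1),
                     phase = h$phase)
    list(structure = build_ideal_helix(ps, chain = c("M", "N")[j]),
         label = sprintf("P%d", j), chain = c("M", "N")[j])
  })
  short_parts <- lapply(seq_len(nrow(attr(short, "helices"))), function(k) {
    hrow <- attr(short, "helices")[k, ]
    list(structure = select_atoms(short, hrow$chain), label = hrow$label,
         chain = hrow$chain)
  })
  long <- .assemble(c(peri_parts, list(filler), short_parts), id = "bundle_long")
  attr(long, "bundle") <- attr(short, "bundle")
  attr(long, "bundle")$filler_chain <- filler_chain
  list(long = long, short = short,
       filler = helix_segment(filler_chain, 1, h$n_residues,
                              label = sprintf("H%02d", spec$groove_gap)))
}

#' Build an occluded-groove docking scene
#'
#' Emulates the ancestral ("long") bundle in its native environment: the
#' groove slot is occupied by the filler helix, and the filler site is
#' surrounded by neighbouring membrane-arm helices (the crowd), as in the
#' membrane domain of the ancestral complex where the homolog packs against
#' its neighbouring subunits. Docking a bundle against this structure, with
#' the filler as the target helix, finds steric clashes at every rotation
#' angle -- the groove-occluded condition.
#'
#' @param spec a [bundle_spec()] with a groove position.
#' @param crowd_radius distance of the crowd helix axes from the filler axis, A.
#' @param crowd_step azimuthal spacing of crowd helices, degrees.
#' @return list with `receptor` (long bundle + crowd, a [structure3d()]) and
#'   `target` (the filler [helix_segment()]).
#' @export
make_occluded_scene <- function(spec = bundle_spec(), crowd_radius = 10.3,
                                crowd_step = 24) {
  pair <- make_long_short_pair(spec)
  binfo <- attr(pair$short, "bundle")
  slot_xy <- binfo$slot$point[1:2]
  ctr_dir <- atan2(-slot_xy[2], -slot_xy[1])   # azimuth of ring centre seen from slot
  h <- spec$helix
  half <- (h$n_residues - 1) * h$rise / 2
  # own ring neighbours sit at about +/- 75 degrees from the centre direction;
  # leave them out of the crowd ring
  nb_az <- ctr_dir + c(-1, 1) * 2 * asin(sin(pi / spec$n_positions)) # exact neighbour azimuths
  az <- seq(0, 2 * pi - 1e-9, by = crowd_step * pi / 180)
  keep <- vapply(az, function(a) {
    all(abs(((a - nb_az + pi) %% (2 * pi)) - pi) > 30 * pi / 180)
  }, TRUE)
  az <- az[keep]
  crowd <- lapply(seq_along(az), function(j) {
    p <- slot_xy + crowd_radius * c(cos(az[j]), sin(az[j]))
    ps <- helix_spec(h$n_residues, h$rise, h$twist, h$helix_radius,
                     axis_point = c(p, 0.75 + half),
                     axis_direction = c(0, 0, -1), phase = h$phase)
    ch <- c(as.character(0:9), letters)[j]
    list(structure = build_ideal_helix(ps, chain = ch),
         label = sprintf("X%02d", j), chain = ch)
  })
  long_parts <- lapply(seq_len(nrow(attr(pair$long, "helices"))), function(k) {
    hrow <- attr(pair$long, "helices")[k, ]
    list(structure = select_atoms(pair$long, hrow$chain), label = hrow$label,
         chain = hrow$chain)
  })
  rec <- .assemble(c(long_parts, crowd), id = "occluded_long_bundle")
  attr(rec, "bundle") <- attr(pair$long, "bundle")
  list(receptor = rec, target = pair$filler)
}

#' Build a tetrameric receptor fixture with protruding M4 helices
#'
#' Each subunit is a four-helix cluster -- M1 and M3 flanking helices, a short
#' pore-lining M2, and an outermost, radially protruding M4 -- arranged with
#' exact n-fold symmetry about the pore (z) axis. M4 protrudes so that its
#' outer face and the two shallow grooves between M4 and the flanking M1/M3
#' are solvent-exposed, which is what lets a groove-bearing bundle dock onto
#' it laterally.
#'
#' @param n_subunits number of subunits (>= 2; 4 mimics a tetramer).
#' @param helix a [helix_spec()] for the TM helices (M2 uses half the length).
#' @param m4_radius distance of the M4 axis from the pore axis, A.
#' @param flank_radius distance of the shared diagonal M1 flank helices from
#'   the pore axis, A; chosen so each M4 and its two flanks form shallow grooves
#'   snug enough to register a docked bundle to about a degree.
#' @param flank_z axial offset of the flank helices, A; a half-rise offset
#'   staggers their residue lattice against a docked bundle's.
#' @param flank_phase azimuthal phase of the flank helices, degrees; together
#'   with `flank_radius` it balances the two sides of each shallow groove.
#' @param m3_xy position of the M3 helix in the subunit frame (x towards M4), A.
#' @return list with `receptor` ([structure3d()]) and `m4_segments`
#'   (list of [helix_segment()]).
#' @export
make_receptor_fixture <- function(n_subunits = 4, helix = helix_spec(),
                                  m4_radius = 14, flank_radius = 11.85,
                                  flank_z = 0.75, flank_phase = 280,
                                  m3_xy = c(7.73, -3.77)) {
  if (n_subunits < 2)
    stop_gd("need at least 2 subunits", class = "groovedock_value_error")
  if (n_subunits > 8)
    stop_gd("at most 8 subunits supported (chain labels)", class = "groovedock_value_error")
  h <- helix
  n2 <- max(4L, h$n_residues %/% 2L)
  chains <- LETTERS[14 + seq_len(n_subunits)]   # "O", "P", ...
  wedge <- 180 / n_subunits                     # half the inter-subunit angle
  parts <- list(); m4_segments <- list()
  for (k in seq_len(n_subunits)) {
    psi <- (k - 1) * 2 * pi / n_subunits
    Rk <- matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, 3)
    place <- function(xy, up, n_res, resno_start, name, z_off = 0, ph0 = 0) {
      p <- as.numeric(Rk %*% c(xy, 0))
      hh <- (n_res - 1) * h$rise / 2
      psi_deg <- psi * 180 / pi
      hs <- helix_spec(n_res, h$rise, h$twist, h$helix_radius,
                       axis_point = p + c(0, 0, z_off + if (up) -hh else hh),
                       axis_direction = c(0, 0, if (up) 1 else -1),
                       # rotate the helix phase with the subunit so the fixture
                       # has exact n-fold symmetry (down helices sweep azimuth
                       # in the opposite sense)
                       phase = h$phase + ph0 + if (up) psi_deg else -psi_deg)
      s <- build_ideal_helix(hs, chain = chains[k], resno_start = resno_start)
      list(structure = s, label = sprintf("%s-%d", name, k), chain = chains[k])
    }
    # M1 sits on the inter-subunit diagonal, shared between neighbouring M4s:
    # each M4 is flanked laterally by its own subunit's M1 and the previous
    # subunit's M1, mirroring the domain-swapped packing of tetrameric
    # receptor TMDs
    m1_xy <- flank_radius * c(cos(wedge * pi / 180), sin(wedge * pi / 180))
    sub <- list(place(m1_xy, FALSE, h$n_residues, 1L, "M1", flank_z, flank_phase),
                place(c(4.0, 0), TRUE, n2, 101L, "M2"),
                place(m3_xy, FALSE, h$n_residues, 201L, "M3", flank_z),
                place(c(m4_radius, 0), TRUE, h$n_residues, 301L, "M4"))
    parts <- c(parts, sub)
    m4_segments[[k]] <- helix_segment(chains[k], 301L, 300L + h$n_residues,
                                      label = sprintf("M4-%d", k))
  }
  rec <- .assemble(parts, id = "receptor")
  attr(rec, "pore_axis") <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  attr(rec, "receptor") <- list(n_subunits = n_subunits, m4_radius = m4_radius,
                                helix = h)
  list(receptor = rec, m4_segments = m4_segments)
}

# signed angle (degrees) from vector a to vector b about unit axis u,
# both projected perpendicular to u.
.signed_angle <- function(a, b, u) {
  a <- a - sum(a * u) * u; b <- b - sum(b * u) * u
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  s <- sum(u * c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1]))
  atan2(s, sum(a * b)) * 180 / pi
}

# canonical groove-registered pose: maps the bundle so its slot axis lies on
# the target M4 axis (z-centres aligned) with the bundle centre pointing along
# the receptor's outward radial at that M4.
.registered_pose <- function(bundle, receptor, target_m4) {
  binfo <- attr(bundle, "bundle")
  if (is.null(binfo) || is.null(binfo$slot))
    stop_gd("bundle has no groove slot (build it with a groove position)",
            class = "groovedock_value_error")
  m4 <- select_atoms(receptor, target_m4$chain, target_m4)
  ax <- fit_helix_axis(coords(m4)[m4$atoms$name == "CA", , drop = FALSE])
  pore <- attr(receptor, "pore_axis")
  if (is.null(pore)) pore <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  # outward radial at M4: from the pore axis towards the M4 axis point
  w <- ax$point - pore$point
  w <- w - sum(w * ax$direction) * ax$direction
  outward <- w / sqrt(sum(w^2))
  # bundle frame: slot point/axis, with 'outward' = slot -> ring centre
  ob <- binfo$centre - binfo$slot$point
  ob <- ob - sum(ob * binfo$slot$direction) * binfo$slot$direction
  ob <- ob / sqrt(sum(ob^2))
  frame_of <- function(p, d, o) cbind(d, o, c(d[2] * o[3] - d[3] * o[2],
                                              d[3] * o[1] - d[1] * o[3],
                                              d[1] * o[2] - d[2] * o[1]))
  Fb <- frame_of(binfo$slot$point, binfo$slot$direction, ob)
  Fr <- frame_of(ax$point, ax$direction, outward)
  R <- Fr %*% t(Fb)
  rigid_transform(R, ax$point - as.numeric(R %*% binfo$slot$point))
}

#' Plant a ground-truth docked scene
#'
#' Builds a scene in which the short bundle's groove receives the receptor's
#' target M4, with the bundle sitting at the stated rotation about the M4 axis
#' relative to the M4 helix. The rotation is realized as the azimuthal phase
#' of the M4 helix: the scene's receptor carries the target M4 spun about its
#' own axis so that recovering the pose by template-guided docking requires a
#' rotation of exactly `true_angle` past the filler-superposition pose. The
#' planted pose is verified free of hard steric clashes (< 2 A heavy-atom
#' pairs).
#'
#' @param short_bundle groove-bearing bundle from [make_long_short_pair()].
#' @param receptor receptor structure from [make_receptor_fixture()].
#' @param target_m4 [helix_segment()] of the target M4 in `receptor`.
#' @param true_angle planted rotation about the M4 axis, degrees.
#' @param seed stored in the output for provenance; the construction itself is
#'   deterministic.
#' @return list with `scene` (list `bundle`, `receptor`), `ground_truth`
#'   (the exact [rigid_transform()] placing the input bundle), `true_angle`,
#'   and `target_m4`.
#' @export
plant_complex <- function(short_bundle, receptor, target_m4, true_angle,
                          seed = 1L) {
  binfo <- attr(short_bundle, "bundle")
  if (is.null(binfo) || is.null(binfo$slot))
    stop_gd("short_bundle must carry groove-slot metadata", class = "groovedock_value_error")
  reg <- .registered_pose(short_bundle, receptor, target_m4)
  # step-1 pose: where the filler-superposition would put the bundle with the
  # M4 phase as built
  h <- binfo$spec$helix
  half <- (h$n_residues - 1) * h$rise / 2
  filler_local <- build_ideal_helix(
    helix_spec(h$n_residues, h$rise, h$twist, h$helix_radius,
               axis_point = c(binfo$slot$point[1:2], -half),
               axis_direction = c(0, 0, 1), phase = h$phase),
    chain = "F")
  m4 <- select_atoms(receptor, target_m4$chain, target_m4)
  m4_ca <- coords(m4)[m4$atoms$name == "CA", , drop = FALSE]
  f_ca <- coords(filler_local)[filler_local$atoms$name == "CA", , drop = FALSE]
  corr <- .centre_trim(nrow(f_ca), nrow(m4_ca))
  step1 <- kabsch(f_ca[corr$a, , drop = FALSE], m4_ca[corr$b, , drop = FALSE])$transform
  ax <- fit_helix_axis(m4_ca)
  ob <- binfo$centre - binfo$slot$point
  theta_need <- .signed_angle(as.numeric(step1$R %*% ob),
                              as.numeric(reg$R %*% ob), ax$direction)
  spin <- (theta_need - true_angle) %% 360
  # spin the target M4 in place about its own axis
  rec2 <- receptor
  sel <- rec2$atoms$chain == target_m4$chain &
    rec2$atoms$resno >= target_m4$start & rec2$atoms$resno <= target_m4$end
  sp <- axis_rotation(spin, ax$point, ax$direction)
  xyz <- apply_transform(sp, as.matrix(rec2$atoms[sel, c("x", "y", "z")]))
  rec2$atoms[sel, c("x", "y", "z")] <- xyz
  placed <- apply_transform(reg, short_bundle)
  n_hard <- count_clashes(placed, rec2, clash_params(cutoff = 2.0))
  if (n_hard > 0)
    stop_gd("planted pose has %d hard clashes (< 2 A)", n_hard,
            class = "groovedock_generation_error")
  list(scene = list(bundle = placed, receptor = rec2),
       ground_truth = reg, true_angle = true_angle, target_m4 = target_m4,
       seed = seed)
}

#' Parameters for the two-channel co-localization image simulator
#'
#' Emulates widefield two-channel images of cells expressing two fluorescently
#' tagged proteins: diffraction-limited puncta, a fraction `coloc_fraction` of
#' which occupy the same positions in both channels, blurred by a Gaussian
#' PSF, on a constant background with Poisson (photon) or Gaussian (read)
#' noise.
#'
#' @param n_cells number of cells (images).
#' @param image_shape c(rows, cols) in pixels.
#' @param coloc_fraction fraction of puncta shared between channels, in 0..1.
#' @param puncta_count puncta per channel per cell.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param background constant background intensity (photons).
#' @param punctum_intensity integrated intensity per punctum (photons).
#' @param noise_model "poisson" or "gaussian".
#' @param noise_sd Gaussian read-noise sd (used when `noise_model` is
#'   "gaussian"; 0 gives noise-free images).
#' @param channel_gains relative gains of the two channels.
#' @param seed RNG seed.
#' @return object of class `coloc_sim_params`.
#' @export
coloc_sim_params <- function(n_cells = 30, image_shape = c(256, 256),
                             coloc_fraction = 0.5, puncta_count = 120,
                             psf_sigma = 1.5, background = 10,
                             punctum_intensity = 2000,
                             noise_model = c("poisson", "gaussian"),
                             noise_sd = 0, channel_gains = c(1, 0.8),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop_gd("coloc_fraction must be in [0, 1]", class = "groovedock_value_error")
  if (n_cells < 1 || puncta_count < 1 || any(image_shape < 8))
    stop_gd("counts and image dimensions must be positive", class = "groovedock_value_error")
  structure(list(n_cells = as.integer(n_cells), image_shape = as.integer(image_shape),
                 coloc_fraction = coloc_fraction, puncta_count = as.integer(puncta_count),
                 psf_sigma = psf_sigma, background = background,
                 punctum_intensity = punctum_intensity, noise_model = noise_model,
                 noise_sd = noise_sd, channel_gains = channel_gains,
                 seed = as.integer(seed)), class = "coloc_sim_params")
}

# separable truncated-Gaussian convolution (zero-padded)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  conv1 <- function(x) {       # along rows (dim 1)
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(nrow(x)) + off
      ok <- src >= 1 & src <= nrow(x)
      out[ok, ] <- out[ok, ] + k[j] * x[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Simulate two-channel cell images with known co-localized fraction
#'
#' @param p a [coloc_sim_params()].
#' @return list of cells; each cell is a list with matrices `ch1`, `ch2` and
#'   the ground-truth `rho`. Deterministic given `p` (including its seed).
#' @export
simulate_coloc_images <- function(p) {
  stopifnot(inherits(p, "coloc_sim_params"))
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  margin <- ceiling(3 * p$psf_sigma) + 1
  with_seed(p$seed, {
    lapply(seq_len(p$n_cells), function(cell) {
      n_sh <- round(p$coloc_fraction * p$puncta_count)
      n_ind <- p$puncta_count - n_sh
      draw <- function(n) cbind(sample(seq(margin, nr - margin), n, replace = TRUE),
                                sample(seq(margin, nc - margin), n, replace = TRUE))
      shared <- draw(n_sh)
      amp_sh <- p$punctum_intensity * exp(stats::rnorm(n_sh, 0, 0.3))
      own1 <- draw(n_ind); own2 <- draw(n_ind)
      amp1 <- p$punctum_intensity * exp(stats::rnorm(n_ind, 0, 0.3))
      amp2 <- p$punctum_intensity * exp(stats::rnorm(n_ind, 0, 0.3))
      raster <- function(centres, amps) {
        m <- matrix(0, nr, nc)
        if (nrow(centres) > 0)
          for (i in seq_len(nrow(centres)))
            m[centres[i, 1], centres[i, 2]] <- m[centres[i, 1], centres[i, 2]] + amps[i]
        m
      }
      g <- p$channel_gains
      ch1 <- g[1] * .gauss_blur(raster(rbind(shared, own1), c(amp_sh, amp1)),
                                p$psf_sigma) + p$background
      ch2 <- g[2] * .gauss_blur(raster(rbind(shared, own2), c(amp_sh, amp2)),
                                p$psf_sigma) + p$background
      if (p$noise_model == "poisson") {
        ch1 <- matrix(stats::rpois(length(ch1), ch1), nr, nc)
        ch2 <- matrix(stats::rpois(length(ch2), ch2), nr, nc)
      } else if (p$noise_sd > 0) {
        ch1 <- pmax(0, ch1 + stats::rnorm(length(ch1), 0, p$noise_sd))
        ch2 <- pmax(0, ch2 + stats::rnorm(length(ch2), 0, p$noise_sd))
      }
      list(ch1 = ch1, ch2 = ch2, rho = p$coloc_fraction, cell = cell)
    })
  })
}

#' Write simulated cells as two-page TIFF files
#'
#' One file per cell, two pages (channels). Intensities are stored as 32-bit
#' floats scaled by `scale`. Requires the \pkg{tiff} package.
#'
#' @param cells output of [simulate_coloc_images()].
#' @param dir output directory.
#' @param scale divisor applied before writing (TIFF floats are stored in
#'   0..1 by convention).
#' @return character vector of file paths.
#' @export
write_coloc_tiffs <- function(cells, dir, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_gd("the 'tiff' package is required to write TIFF files",
            class = "groovedock_io_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(cells), function(i) {
    f <- file.path(dir, sprintf("cell_%03d.tif", i))
    tiff::writeTIFF(list(cells[[i]]$ch1 / scale, cells[[i]]$ch2 / scale), f,
                    bits.per.sample = 32L)
    f
  }, "")
}

#' Read a two-page TIFF as a two-channel image
#' @param path TIFF path written by [write_coloc_tiffs()].
#' @param scale multiplier restoring the original intensity scale.
#' @return a [two_channel_image()].
#' @export
read_coloc_tiff <- function(path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_gd("the 'tiff' package is required to read TIFF files",
            class = "groovedock_io_error")
  pg <- tiff::readTIFF(path, all = TRUE)
  if (length(pg) < 2)
    stop_gd("'%s' does not contain two channels", path, class = "groovedock_io_error")
  two_channel_image(pg[[1]] * scale, pg[[2]] * scale)
}

#' Parameters for the BiFC intensity-table simulator
#'
#' Emulates per-cell intensity readouts of a split-Venus assay: a Cy3 channel
#' marking expression of the bait construct and a Venus channel reporting
#' complementation, both expressed relative to per-cell background.
#'
#' @param n_cells number of cells.
#' @param background_mean mean cell background intensity.
#' @param reporter_fold true Venus fold over background (>= 0).
#' @param cy3_fold true Cy3 fold over background (>= 0).
#' @param noise_cv multiplicative coefficient of variation applied
#'   independently to background, Cy3 and Venus.
#' @param group group label attached to the records.
#' @param seed RNG seed.
#' @return object of class `bifc_sim_params`.
#' @export
bifc_sim_params <- function(n_cells = 30, background_mean = 100,
                            reporter_fold = 5, cy3_fold = 5, noise_cv = 0.1,
                            group = "g1", seed = 1L) {
  if (reporter_fold < 0 || cy3_fold < 0 || noise_cv < 0)
    stop_gd("folds and noise_cv must be >= 0", class = "groovedock_value_error")
  structure(list(n_cells = as.integer(n_cells), background_mean = background_mean,
                 reporter_fold = reporter_fold, cy3_fold = cy3_fold,
                 noise_cv = noise_cv, group = group, seed = as.integer(seed)),
            class = "bifc_sim_params")
}

#' Simulate a BiFC intensity table
#'
#' @param p a [bifc_sim_params()].
#' @return data.frame with columns cell_id, group, background, cy3, venus.
#' @export
simulate_bifc <- function(p) {
  stopifnot(inherits(p, "bifc_sim_params"))
  noise <- function(n) {
    if (p$noise_cv == 0) rep(1, n) else pmax(0.05, 1 + p$noise_cv * stats::rnorm(n))
  }
  with_seed(p$seed, {
    bg <- p$background_mean * noise(p$n_cells)
    data.frame(cell_id = sprintf("%s_c%03d", p$group, seq_len(p$n_cells)),
               group = p$group,
               background = bg,
               cy3 = p$cy3_fold * bg * noise(p$n_cells),
               venus = p$reporter_fold * bg * noise(p$n_cells),
               stringsAsFactors = FALSE)
  })
}
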